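# End-to-end orchestration: one YAML config drives generation (or loading),
# clustering, cross-validated regression and the response-function stage,
# writing every artifact plus a machine-readable run manifest.

#' Run the full analysis pipeline from a configuration
#'
#' Stages: obtain frames (synthetic generation or feature/efficacy CSV
#' paths), fit the conformation-fraction efficacy model with nested
#' leave-one-out validation over the configured hyperparameter grid, rank
#' features by activation scores, and write all results under the output
#' directory. Every artifact is reproducible from the config plus its seed
#' alone; reruns with the same config are byte-identical.
#'
#' Config keys (YAML file or list): `out_dir`; `seed`; `stride`; `grid`
#' (lists `weights` of length-3 triples, `H`, `delta`, `C`); either
#' `synthetic` (arguments of [synthetic_study()]) or `features_csv` +
#' `efficacy_csv`; optional `erf_top_fraction`.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return (invisibly) the output directory, which contains
#'   `fractions.csv`, `predictions.csv`, `metrics.json`,
#'   `conformation_model.json`, `erf_scores.csv` and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("out_dir", "seed"))
    if (is.null(config[[key]])) stop("config lacks required key: ", key)
  seed <- as.integer(config$seed)
  stride <- as.integer(config$stride %||% 1L)

  if (!is.null(config$synthetic)) {
    sargs <- config$synthetic
    sargs$seed <- seed
    study <- do.call(synthetic_study, sargs)
    features <- study$features
    efficacies <- study$efficacies
  } else {
    if (is.null(config$features_csv) || is.null(config$efficacy_csv))
      stop("config needs either `synthetic` or `features_csv` + `efficacy_csv`")
    for (p in c(config$features_csv, config$efficacy_csv))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    features <- read_frames_csv(config$features_csv)
    efficacies <- read_efficacy_csv(config$efficacy_csv)
    study <- NULL
  }
  # fail fast before any heavy compute
  miss <- setdiff(unique(features$ligand), efficacies$ligand)
  if (length(miss))
    stop("missing efficacy for ligand(s): ", paste(miss, collapse = ", "))

  g <- config$grid %||% list()
  # config weights may carry serialization round-off; renormalize gently
  as_weights <- function(t) {
    t <- unlist(t)
    if (abs(sum(t) - 1) > 1e-6) stop("config weight triple does not sum to 1")
    t <- t / sum(t)
    distance_weights(t[[1]], t[[2]], t[[3]])
  }
  grid <- efficacy_grid(
    weights = if (is.null(g$weights)) default_weight_grid() else
      lapply(g$weights, as_weights),
    H = unlist(g$H) %||% 2:40,
    delta = unlist(g$delta) %||% 1:3,
    C = unlist(g$C))

  fit <- conf_efficacy(features, efficacies, grid, stride = stride)
  scores <- erf_scores(fit)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_fractions_csv(fit$fractions, file.path(out, "fractions.csv"))
  utils::write.csv(fit$cv$predictions, file.path(out, "predictions.csv"),
                   row.names = FALSE)
  write_conformation_json(fit$model, file.path(out, "conformation_model.json"))
  utils::write.csv(scores, file.path(out, "erf_scores.csv"),
                   row.names = FALSE)

  metrics <- list(G = as.list(fit$cv$metrics["G", ]),
                  B = as.list(fit$cv$metrics["B", ]))
  if (!is.null(study) && requireNamespace("mclust", quietly = TRUE)) {
    metrics$ari <- mclust::adjustedRandIndex(fit$model$conf_labels,
                                             study$features$template)
  }
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       digits = NA, auto_unbox = TRUE)

  manifest <- list(
    seed = seed, stride = stride,
    config = config[setdiff(names(config), "out_dir")],
    selected = list(C = fit$hp$C, H = fit$hp$H, delta = fit$hp$delta,
                    weights = as.list(unclass(fit$hp$weights))),
    fold_hyperparameters = lapply(fit$cv$folds, function(f)
      list(ligand = f$ligand, C = f$hp$C, H = f$hp$H, delta = f$hp$delta,
           weights = as.list(unclass(f$hp$weights)))),
    n_frames = n_frames(features), n_ligands = nrow(efficacies),
    package_version = as.character(utils::packageVersion("confeff")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
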