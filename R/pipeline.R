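#' Pipeline configuration
#'
#' Bundles inputs (file paths or a simulation config), analysis parameters
#' and stage toggles for [run_pipeline()]. Every stochastic stage draws its
#' sub-seeds from the single master `seed`, so a run is fully reproducible.
#'
#' @param interactions_csv,metadata_csv Input paths (ignored when `sim` is
#'   given).
#' @param sim A [sim_config()] to generate the experiment instead of reading
#'   files.
#' @param I_total Experiment-wide insect richness for connectance; `NULL`
#'   derives it from the data (the study's value is 92).
#' @param n_null Null-ensemble size per network (default 500).
#' @param restarts Modularity restarts for observed networks (default 20).
#' @param null_restarts Modularity restarts per null draw (default 5).
#' @param seed Master seed.
#' @param out_dir Output directory for CSVs and the manifest; `NULL` keeps
#'   results in memory only.
#' @param stages Character vector of stages to run, a subset of
#'   `c("metrics", "nulls", "diversity", "stats")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(interactions_csv = NULL, metadata_csv = NULL,
                            sim = NULL, I_total = NULL, n_null = 500L,
                            restarts = 20L, null_restarts = 5L, seed = 1L,
                            out_dir = NULL,
                            stages = c("metrics", "nulls", "diversity",
                                       "stats")) {
  if (is.null(sim) && (is.null(interactions_csv) || is.null(metadata_csv))) {
    stop("provide either `sim` or both input CSV paths")
  }
  bad <- setdiff(stages, c("metrics", "nulls", "diversity", "stats"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data ingest (or simulation), per-plot network construction,
#' structural metrics, null-model z-scores with the treatment departure
#' summary, per-treatment diversity, and the treatment-contrast mixed
#' models. Stage results are returned as a list and, when `out_dir` is set,
#' written as CSVs alongside a JSON manifest recording seeds and parameters.
#'
#' @param config A [pipeline_config()].
#' @return List with (depending on stages): `interactions`, `metadata`,
#'   `networks`, `metrics`, `z_scores`, `departures`, `diversity`,
#'   `effects`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cf <- config
  if (!is.null(cf$sim)) {
    sim <- simulate_experiment(cf$sim)
    interactions <- sim$interactions
    metadata <- sim$metadata
  } else {
    interactions <- read_interactions(cf$interactions_csv)
    metadata <- read_metadata(cf$metadata_csv)
  }
  I_total <- if (is.null(cf$I_total)) {
    length(unique(interactions$insect))
  } else {
    cf$I_total
  }
  networks <- build_all_networks(interactions, metadata)
  out <- list(interactions = interactions, metadata = metadata,
              networks = networks, I_total = I_total)

  if ("metrics" %in% cf$stages) {
    message("metrics: ", length(networks), " networks")
    out$metrics <- metrics_table(networks, I_total = I_total,
                                 seed = derive_seed(cf$seed, 1L),
                                 restarts = cf$restarts)
  }
  if ("nulls" %in% cf$stages) {
    if (is.null(out$metrics)) stop("stage 'nulls' requires stage 'metrics'")
    message("nulls: ", cf$n_null, " draws x ", length(networks), " networks")
    out$z_scores <- z_score_table(networks, out$metrics, n_null = cf$n_null,
                                  seed = derive_seed(cf$seed, 2L),
                                  I_total = I_total,
                                  restarts = cf$null_restarts)
    out$departures <- departure_summary(out$z_scores, metadata)
  }
  if ("diversity" %in% cf$stages) {
    message("diversity: per-treatment Hill numbers and coverage")
    out$diversity <- diversity_summary(interactions)
  }
  if ("stats" %in% cf$stages) {
    if (is.null(out$metrics)) stop("stage 'stats' requires stage 'metrics'")
    message("stats: treatment-contrast mixed models")
    out$effects <- effect_tables(out$metrics)
    if (!is.null(out$z_scores)) {
      out$z_effects <- z_effect_tables(out$z_scores, metadata)
    }
  }
  if (!is.null(cf$out_dir)) {
    out$manifest <- write_outputs(out, cf)
  }
  out
}

# Table-2-style model set over the per-network metric rows
RESPONSE_SET <- list(
  list(response = "display",           log = TRUE,  display = FALSE),
  list(response = "abundance",         log = TRUE,  display = TRUE),
  list(response = "insect_richness",   log = FALSE, display = TRUE),
  list(response = "weighted_degree",   log = FALSE, display = TRUE),
  list(response = "unweighted_degree", log = FALSE, display = TRUE),
  list(response = "connectance",       log = FALSE, display = TRUE),
  list(response = "nodf",              log = FALSE, display = TRUE),
  list(response = "nodfc",             log = FALSE, display = TRUE),
  list(response = "modularity",        log = FALSE, display = TRUE)
)

#' Fit the standard model set over a metrics table
#'
#' One mixed model per structural response (floral display, log abundance,
#' visitor richness, degrees, connectance, NODF, NODFc, modularity) with
#' treatment + log display fixed effects, block random intercept, and
#' interaction pruning; the display model itself omits the display
#' covariate.
#'
#' @param metrics Data frame from [metrics_table()] (with `treatment`,
#'   `block`, `display_log` columns).
#' @return Data frame of stacked effect tables with columns `response`,
#'   `contrast`, `estimate`, `t`, `p`, `R2m`, `R2c`, `interaction_kept`,
#'   `singular`.
#' @export
effect_tables <- function(metrics) {
  rows <- lapply(RESPONSE_SET, function(spec) {
    if (!spec$response %in% names(metrics)) return(NULL)
    fit <- try(fit_lmm(metrics, spec$response, log_response = spec$log,
                       include_display = spec$display), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    cbind(data.frame(response = fit$response, stringsAsFactors = FALSE),
          fit$table[c("contrast", "estimate", "t", "p")],
          data.frame(R2m = fit$R2m, R2c = fit$R2c,
                     interaction_kept = fit$interaction_kept,
                     singular = fit$singular))
  })
  do.call(rbind, rows)
}

#' Treatment-contrast models on null-model z-scores
#'
#' For each standardized metric, fits `z ~ treatment + (1 | block)` (no
#' display covariate) and reports the treatment-vs-control contrasts.
#'
#' @param z_table Output of [z_score_table()].
#' @param metadata Plot metadata (block/treatment lookup).
#' @return Stacked effect table as in [effect_tables()].
#' @export
z_effect_tables <- function(z_table, metadata) {
  df <- merge(z_table, metadata[c("plot", "block", "treatment")], by = "plot")
  zcols <- grep("^z_", names(df), value = TRUE)
  rows <- lapply(zcols, function(zc) {
    if (sum(!is.na(df[[zc]])) < 8) return(NULL)
    fit <- try(fit_lmm(df[!is.na(df[[zc]]), ], zc, include_display = FALSE),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    cbind(data.frame(response = zc, stringsAsFactors = FALSE),
          fit$table[c("contrast", "estimate", "t", "p")],
          data.frame(R2m = fit$R2m, R2c = fit$R2c,
                     interaction_kept = fit$interaction_kept,
                     singular = fit$singular))
  })
  do.call(rbind, rows)
}

write_outputs <- function(out, cf) {
  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(cf$out_dir, paste0(name, ".csv"))
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(out$metrics, "metrics")
  wr(out$z_scores, "z_scores")
  wr(out$departures, "departures")
  wr(out$diversity, "diversity")
  wr(out$effects, "effects")
  wr(out$z_effects, "z_effects")
  manifest <- list(
    package = "bloomnet",
    version = as.character(utils::packageVersion("bloomnet")),
    seed = cf$seed, n_null = cf$n_null, I_total = out$I_total,
    restarts = cf$restarts, stages = cf$stages,
    n_networks = length(out$networks),
    outputs = paths,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(cf$out_dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)), mp)
  }
  manifest
}
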