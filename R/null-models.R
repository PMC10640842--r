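#' Draw a fixed-margin random contingency table
#'
#' Samples a non-negative integer matrix uniformly from all tables with the
#' given row and column sums, via Patefield's conditional construction (the
#' `r2dtable` method). With a seed the draw is reproducible; the caller's RNG
#' state is untouched.
#'
#' @param row_sums,col_sums Non-negative integer margins with equal totals.
#' @param n Number of tables to draw (default 1).
#' @param seed Optional integer seed.
#' @return A matrix if `n = 1`, otherwise a list of matrices.
#' @export
patefield_sample <- function(row_sums, col_sums, n = 1L, seed = NULL) {
  row_sums <- as.integer(row_sums); col_sums <- as.integer(col_sums)
  if (sum(row_sums) != sum(col_sums)) {
    stop("margin mismatch: row and column totals differ")
  }
  if (sum(row_sums) <= 0) stop("margins must have a positive total")
  if (length(row_sums) == 1 || length(col_sums) == 1) {
    # a single row or column admits exactly one table
    unique_tab <- matrix(rep(col_sums, each = length(row_sums)),
                         length(row_sums), length(col_sums))
    if (length(col_sums) == 1) unique_tab[, 1] <- row_sums
    tabs <- rep(list(unique_tab), n)
    return(if (n == 1L) tabs[[1]] else tabs)
  }
  draw <- function() stats::r2dtable(n, row_sums, col_sums)
  tabs <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (n == 1L) tabs[[1]] else tabs
}

#' Null-model ensemble of network metrics
#'
#' Generates `n_null` fixed-margin null matrices for a network and scores
#' each with the same six structural metrics used for observed networks
#' (connectance, unweighted and weighted degree, NODF, NODFc, modularity).
#' Margins (and hence abundance, richness, and weighted degree) are
#' conserved by construction; metrics that are fully determined by the
#' margins come out degenerate and are flagged via `sigma = 0`.
#'
#' @param network A `plot_network`.
#' @param n_null Ensemble size (study default 500).
#' @param seed Master seed; each draw's modularity run gets a derived seed.
#' @param I_total Experiment-wide insect richness for connectance.
#' @param restarts Modularity restarts per null draw (default 5; null
#'   matrices are scored in bulk, observed networks get the full budget).
#' @param metrics Character vector of metrics to score.
#' @return A `null_ensemble`: list with `plot_id`, `n_null`, `draws` (matrix
#'   n_null x metrics), `mu`, `sigma`, and `degenerate` (logical per metric).
#' @export
null_ensemble <- function(network, n_null = 500L, seed = 1L, I_total,
                          restarts = 5L,
                          metrics = c("connectance", "unweighted_degree",
                                      "weighted_degree", "nodf", "nodfc",
                                      "modularity")) {
  A <- network$matrix
  rs <- rowSums(A); cs <- colSums(A)
  tabs <- patefield_sample(rs, cs, n = n_null, seed = derive_seed(seed, 0L))
  if (n_null == 1L) tabs <- list(tabs)
  plants_bloomed <- if (!is.null(network$meta)) {
    network$meta$plants_bloomed
  } else {
    nrow(A)
  }
  draws <- matrix(NA_real_, n_null, length(metrics),
                  dimnames = list(NULL, metrics))
  for (b in seq_len(n_null)) {
    Anull <- tabs[[b]]
    nw <- structure(list(matrix = Anull, plot_id = network$plot_id,
                         meta = network$meta), class = "plot_network")
    L <- sum(Anull > 0)
    S <- nrow(Anull) + ncol(Anull)
    for (met in metrics) {
      draws[b, met] <- switch(
        met,
        connectance = L / (plants_bloomed * I_total),
        unweighted_degree = L / S,
        weighted_degree = sum(Anull) / S,
        nodf = if (nrow(Anull) >= 2 || ncol(Anull) >= 2) nodf(Anull)
               else NA_real_,
        nodfc = if (nrow(Anull) * ncol(Anull) > 1)
                  suppressWarnings(nodfc(Anull)) else NA_real_,
        modularity = bipartite_modularity(nw, seed = derive_seed(seed, b),
                                          restarts = restarts)$Q,
        stop("unknown metric: ", met)
      )
    }
  }
  mu <- colMeans(draws)
  sigma <- apply(draws, 2, stats::sd)
  structure(list(plot_id = network$plot_id, n_null = n_null, draws = draws,
                 mu = mu, sigma = sigma,
                 degenerate = !is.na(sigma) & sigma == 0),
            class = "null_ensemble")
}

#' Standardize observed metrics against a null ensemble
#'
#' `z = (observed - null mean) / null sd` per metric. Metrics with zero null
#' spread (fixed by the margins) are reported as `NA`, never infinite.
#'
#' @param observed One-row metrics data frame from [compute_all()] (or a
#'   named numeric vector of metric values).
#' @param ensemble A `null_ensemble` for the same plot.
#' @return One-row data frame of z-scores with column `plot`.
#' @export
z_scores <- function(observed, ensemble) {
  if (is.data.frame(observed)) {
    if (!is.null(observed$plot) && !is.null(ensemble$plot_id) &&
        observed$plot != ensemble$plot_id) {
      stop("plot id mismatch: observed '", observed$plot, "' vs ensemble '",
           ensemble$plot_id, "'")
    }
    obs <- unlist(observed[intersect(colnames(ensemble$draws),
                                     names(observed))])
  } else {
    obs <- observed[intersect(colnames(ensemble$draws), names(observed))]
  }
  metrics <- colnames(ensemble$draws)
  z <- vapply(metrics, function(met) {
    s <- ensemble$sigma[[met]]
    if (is.na(s) || s == 0 || !met %in% names(obs)) return(NA_real_)
    (obs[[met]] - ensemble$mu[[met]]) / s
  }, numeric(1))
  out <- as.data.frame(as.list(z))
  names(out) <- paste0("z_", metrics)
  cbind(data.frame(plot = ensemble$plot_id, stringsAsFactors = FALSE), out)
}

#' Null-departure rule for one metric in one treatment
#'
#' A treatment's networks are declared to depart from the null expectation
#' when the mean +/- one standard deviation of their z-scores excludes zero.
#'
#' @param z Numeric vector of z-scores (one per network in the treatment);
#'   at least 2 non-missing values.
#' @return List with `departure` (logical), `mean`, `sd`, `lower`, `upper`.
#' @export
null_departure <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) < 2) stop("need >= 2 z-scores for the departure rule")
  mu <- mean(z); s <- stats::sd(z)
  list(departure = (mu - s > 0) || (mu + s < 0),
       mean = mu, sd = s, lower = mu - s, upper = mu + s)
}

#' Z-score table for a set of networks
#'
#' Runs [null_ensemble()] and [z_scores()] for each network.
#'
#' @param networks List of `plot_network`s.
#' @param observed Metrics data frame from [metrics_table()] (rows matched
#'   to networks by the `plot` column).
#' @param n_null Ensemble size per network.
#' @param seed Master seed (per-network sub-seeds derived).
#' @param I_total Experiment-wide insect richness.
#' @param ... Passed to [null_ensemble()].
#' @return Data frame of z-scores, one row per network.
#' @export
z_score_table <- function(networks, observed, n_null = 500L, seed = 1L,
                          I_total, ...) {
  rows <- lapply(seq_along(networks), function(i) {
    nw <- networks[[i]]
    ens <- null_ensemble(nw, n_null = n_null, seed = derive_seed(seed, i),
                         I_total = I_total, ...)
    z_scores(observed[observed$plot == nw$plot_id, , drop = FALSE], ens)
  })
  do.call(rbind, rows)
}

#' Treatment-level null-departure summary
#'
#' @param z_table Output of [z_score_table()].
#' @param metadata Plot metadata (to map plots to treatments); may be `NULL`
#'   if `z_table` already has a `treatment` column.
#' @return Data frame: treatment x metric with mean, sd and departure flag.
#' @export
departure_summary <- function(z_table, metadata = NULL) {
  if (!"treatment" %in% names(z_table)) {
    z_table <- merge(z_table, metadata[c("plot", "treatment")], by = "plot")
  }
  zcols <- grep("^z_", names(z_table), value = TRUE)
  out <- list()
  for (trt in sort(unique(z_table$treatment))) {
    sub <- z_table[z_table$treatment == trt, , drop = FALSE]
    for (zc in zcols) {
      z <- sub[[zc]]
      if (sum(!is.na(z)) < 2) next
      dep <- null_departure(z)
      out[[length(out) + 1]] <- data.frame(
        treatment = trt, metric = sub("^z_", "", zc),
        mean_z = dep$mean, sd_z = dep$sd, departure = dep$departure,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
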