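#' Nestedness based on overlap and decreasing fill (NODF)
#'
#' Classic paired-overlap nestedness on the binarized matrix. For every
#' ordered pair of rows (and of columns) in which the first member has
#' strictly greater fill, the pair contributes 100 x (shared presences) /
#' (fill of the sparser member); pairs with equal fill contribute 0. NODF is
#' the mean over all row pairs and column pairs, in [0, 100].
#'
#' @param x A `plot_network`, or a matrix (binarized internally as `x > 0`).
#' @return NODF value in \[0, 100\].
#' @export
nodf <- function(x) {
  B <- binarize(x)
  if (sum(B) == 0) stop("NODF undefined for an all-zero matrix")
  if (nrow(B) < 2 && ncol(B) < 2) {
    stop("NODF needs at least 2 rows or 2 columns")
  }
  total <- nodf_axis(B) + nodf_axis(t(B))
  n_pairs <- choose(nrow(B), 2) + choose(ncol(B), 2)
  100 * total / n_pairs
}

binarize <- function(x) {
  A <- if (inherits(x, "plot_network")) x$matrix else x
  storage.mode(A) <- "double"
  (A > 0) * 1
}

# sum of paired nestedness terms (as fractions) over row pairs of B
nodf_axis <- function(B) {
  m <- nrow(B)
  if (m < 2) return(0)
  fills <- rowSums(B)
  overlap <- tcrossprod(B)  # shared presences for each row pair
  lo <- outer(fills, fills, pmin)
  valid <- outer(fills, fills, "!=") & lo > 0
  contrib <- overlap / pmax(lo, 1)
  contrib[!valid] <- 0
  sum(contrib[upper.tri(contrib)])
}

#' Maximum attainable NODF for given dimensions and link count
#'
#' Finds the largest NODF over all binary matrices with `n_rows` x `n_cols`
#' cells, exactly `n_links` presences, and no empty row or column. For small
#' problems (`n_rows * n_cols <= exhaustive_limit`) all feasible matrices are
#' enumerated; otherwise a greedy nested seed is refined by first-improvement
#' single-link relocations until no move improves (bounded by `max_moves`).
#' The search is deterministic.
#'
#' @param n_rows,n_cols Matrix dimensions (each >= 1).
#' @param n_links Number of presences; must satisfy
#'   `max(n_rows, n_cols) <= n_links <= n_rows * n_cols`.
#' @param exhaustive_limit Cell-count threshold below which enumeration is
#'   exact (default 12).
#' @param max_moves Relocation budget for the hill climb (default 10000).
#' @return List with `nodf` (the maximum found) and `matrix` (an attaining
#'   configuration).
#' @export
max_nodf <- function(n_rows, n_cols, n_links,
                     exhaustive_limit = 12L, max_moves = 10000L) {
  m <- as.integer(n_rows); n <- as.integer(n_cols); L <- as.integer(n_links)
  if (L < max(m, n) || L > m * n) {
    stop("infeasible link count: need max(n_rows, n_cols) <= n_links <= ",
         "n_rows * n_cols")
  }
  key <- paste(m, n, L, sep = "x")
  cached <- .bloomnet_cache$maxnodf[[key]]
  if (!is.null(cached)) return(cached)
  res <- if (m * n <= exhaustive_limit) {
    max_nodf_exhaustive(m, n, L)
  } else {
    max_nodf_climb(m, n, L, max_moves)
  }
  .bloomnet_cache$maxnodf[[key]] <- res
  res
}

.bloomnet_cache <- new.env(parent = emptyenv())
.bloomnet_cache$maxnodf <- list()

max_nodf_exhaustive <- function(m, n, L) {
  cells <- utils::combn(m * n, L)
  best <- -1; best_mat <- NULL
  for (k in seq_len(ncol(cells))) {
    B <- matrix(0, m, n)
    B[cells[, k]] <- 1
    if (any(rowSums(B) == 0) || any(colSums(B) == 0)) next
    v <- nodf(B)
    if (v > best) { best <- v; best_mat <- B }
  }
  if (is.null(best_mat)) stop("no feasible matrix found")  # unreachable
  list(nodf = best, matrix = best_mat)
}

# nested seed: cover every row and column (first row + first column when
# feasible), then fill remaining links toward the top-left corner so the
# seed is already strongly nested; deterministic and cheap
max_nodf_seed <- function(m, n, L) {
  B <- matrix(0, m, n)
  if (L >= m + n - 1) {
    B[1, ] <- 1
    B[, 1] <- 1
  } else {
    # too few links for a full first row + column: staircase cover
    for (j in seq_len(n)) B[min(j, m), j] <- 1
    for (i in seq_len(m)) if (sum(B[i, ]) == 0) B[i, 1] <- 1
  }
  extra <- L - sum(B)
  while (extra > 0) {
    # frontier candidates: leftmost empty cell per row, topmost per column
    cand <- integer(0)
    for (i in seq_len(m)) {
      j <- match(0, B[i, ])
      if (!is.na(j)) cand <- c(cand, (j - 1) * m + i)
    }
    for (j in seq_len(n)) {
      i <- match(0, B[, j])
      if (!is.na(i)) cand <- c(cand, (j - 1) * m + i)
    }
    cand <- unique(cand)
    scores <- vapply(cand, function(cell) {
      B[cell] <- 1
      nodf(B)
    }, numeric(1))
    B[cand[which.max(scores)]] <- 1
    extra <- extra - 1
  }
  B
}

max_nodf_climb <- function(m, n, L, max_moves) {
  B <- max_nodf_seed(m, n, L)
  best <- nodf(B)
  moves <- 0L
  repeat {
    links <- which(B == 1)
    empties <- which(B == 0)
    rs <- rowSums(B); cs <- colSums(B)
    # best-improvement sweep over all coverage-preserving relocations
    best_move <- NULL; best_v <- best
    for (from in links) {
      fi <- (from - 1) %% m + 1; fj <- (from - 1) %/% m + 1
      for (to in empties) {
        ti <- (to - 1) %% m + 1; tj <- (to - 1) %/% m + 1
        if ((rs[fi] == 1 && ti != fi) || (cs[fj] == 1 && tj != fj)) next
        B[from] <- 0; B[to] <- 1
        v <- nodf(B)
        B[to] <- 0; B[from] <- 1
        moves <- moves + 1L
        if (v > best_v + 1e-12) { best_v <- v; best_move <- c(from, to) }
        if (moves >= max_moves) break
      }
      if (moves >= max_moves) break
    }
    if (is.null(best_move)) break
    B[best_move[1]] <- 0; B[best_move[2]] <- 1
    best <- best_v
    if (moves >= max_moves) break
  }
  list(nodf = best, matrix = B)
}

#' Size- and fill-corrected nestedness (NODFc)
#'
#' Normalizes NODF against the maximum attainable at the same dimensions and
#' link count, then corrects for matrix fill and size:
#' `NODFc = (NODF / max_NODF) / (C_fill * log(S_geom))`, with
#' `C_fill = L / (m * n)` the within-matrix fill and `S_geom = sqrt(m * n)`
#' the geometric mean dimension. This makes nestedness comparable across
#' networks of different size and sampling intensity.
#'
#' @param x A `plot_network` or matrix (binarized internally).
#' @param ... Passed to [max_nodf()].
#' @return NODFc value (unbounded above; typically order 1).
#' @export
nodfc <- function(x, ...) {
  B <- binarize(x)
  m <- nrow(B); n <- ncol(B)
  s_geom <- sqrt(m * n)
  if (log(s_geom) <= 0) {
    stop("NODFc undefined: geometric mean dimension must exceed 1")
  }
  L <- sum(B)
  mx <- max_nodf(m, n, L, ...)$nodf
  if (mx == 0) {
    # no nested configuration exists at these dims/fill (e.g. a fully
    # filled matrix, where all fills tie): the ratio is undefined
    warning("NODFc undefined: maximum NODF is 0 at ", m, "x", n,
            " with ", L, " links")
    return(NA_real_)
  }
  c_fill <- L / (m * n)
  (nodf(B) / mx) / (c_fill * log(s_geom))
}

#' Experiment-wide connectance
#'
#' The realized proportion of all potential interactions: links in the plot
#' network divided by (plants that bloomed in the plot) x (experiment-wide
#' insect richness). The denominator uses bloomed plants -- not just plants
#' that received visits -- and the full insect pool observed anywhere in the
#' experiment, so plots are comparable on a common scale.
#'
#' @param network A `plot_network`.
#' @param I_total Experiment-wide insect species richness (the study's value
#'   is 92).
#' @param plants_bloomed Bloomed plant count; defaults to the network
#'   metadata's `plants_bloomed`, falling back to the matrix row count.
#' @return Connectance in (0, 1].
#' @export
connectance_experiment_wide <- function(network, I_total,
                                        plants_bloomed = NULL) {
  A <- network$matrix
  if (is.null(plants_bloomed)) {
    plants_bloomed <- if (!is.null(network$meta)) {
      network$meta$plants_bloomed
    } else {
      nrow(A)
    }
  }
  if (plants_bloomed == 0) stop("connectance undefined: no plants bloomed")
  if (plants_bloomed < nrow(A)) {
    stop("plants_bloomed (", plants_bloomed, ") < plants in network (",
         nrow(A), ")")
  }
  L <- sum(A > 0)
  L / (plants_bloomed * I_total)
}

#' Network-mean degrees
#'
#' Unweighted degree = links / species; weighted degree = total visitor
#' abundance / species, with species = plants + insects present in the
#' realized network.
#'
#' @param network A `plot_network`.
#' @return Named numeric vector `c(unweighted, weighted)`.
#' @export
degrees <- function(network) {
  A <- network$matrix
  if (length(A) == 0 || sum(A) == 0) stop("degrees undefined: empty network")
  S <- nrow(A) + ncol(A)
  c(unweighted = sum(A > 0) / S, weighted = sum(A) / S)
}

#' Compute the full per-network metric row
#'
#' @param network A `plot_network` (metadata supplies block, treatment,
#'   bloomed plant count and floral display when present).
#' @param I_total Experiment-wide insect richness for the connectance
#'   denominator.
#' @param seed Seed for the modularity optimizer (deterministic output).
#' @param restarts Modularity optimizer restarts (default 20).
#' @param nodfc_args Extra arguments for [max_nodf()] via [nodfc()].
#' @return One-row data frame: identifiers, abundance, richness, links,
#'   degrees, connectance, NODF, NODFc, modularity.
#' @export
compute_all <- function(network, I_total, seed = 1L, restarts = 20L,
                        nodfc_args = list()) {
  A <- network$matrix
  meta <- network$meta
  dg <- degrees(network)
  L <- sum(A > 0)
  S <- nrow(A) + ncol(A)
  nodf_v <- if (nrow(A) >= 2 || ncol(A) >= 2) nodf(A) else NA_real_
  nodfc_v <- if (nrow(A) * ncol(A) > 1) {
    suppressWarnings(do.call(nodfc, c(list(A), nodfc_args)))
  } else {
    NA_real_
  }
  Q <- bipartite_modularity(network, seed = seed, restarts = restarts)$Q
  data.frame(
    plot = network$plot_id,
    block = if (!is.null(meta)) meta$block else NA_character_,
    treatment = if (!is.null(meta)) meta$treatment else NA_character_,
    abundance = sum(A),
    plant_richness = if (!is.null(meta)) meta$plants_bloomed else nrow(A),
    plants_visited = nrow(A),
    insect_richness = ncol(A),
    species_total = S,
    links = L,
    unweighted_degree = dg[["unweighted"]],
    weighted_degree = dg[["weighted"]],
    connectance = connectance_experiment_wide(network, I_total),
    nodf = nodf_v,
    nodfc = nodfc_v,
    modularity = Q,
    display = if (!is.null(meta)) meta$display else NA_real_,
    display_log = if (!is.null(meta)) meta$display_log else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Metric table for a list of networks
#'
#' @param networks List of `plot_network` objects (see
#'   [build_all_networks()]).
#' @param I_total Experiment-wide insect richness; defaults to the number of
#'   distinct insect species across all networks.
#' @param seed Master seed; each network's modularity run gets a derived
#'   sub-seed.
#' @param ... Passed to [compute_all()].
#' @return Data frame, one row per network.
#' @export
metrics_table <- function(networks, I_total = NULL, seed = 1L, ...) {
  if (is.null(I_total)) {
    I_total <- length(unique(unlist(lapply(networks,
                                           function(nw) colnames(nw$matrix)))))
  }
  rows <- lapply(seq_along(networks), function(i) {
    compute_all(networks[[i]], I_total = I_total,
                seed = derive_seed(seed, i), ...)
  })
  do.call(rbind, rows)
}
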