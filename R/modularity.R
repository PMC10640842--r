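#' Barber's weighted bipartite modularity
#'
#' Maximizes Barber's modularity
#' `Q = (1/F) * sum_ij (A_ij - k_i d_j / F) * delta(g_i, h_j)` over joint
#' partitions of the plant (row) and insect (column) nodes, where `F` is the
#' total interaction weight, `k_i` row sums and `d_j` column sums. The
#' optimizer is a weighted bipartite label-propagation with module
#' agglomeration (DIRTLPAwb+-style), run from multiple seeded restarts; the
#' best partition is returned. Output is deterministic given `seed`.
#'
#' @param network A `plot_network` or a non-negative weight matrix.
#' @param seed Integer seed controlling all restarts.
#' @param restarts Number of optimizer restarts (default 20). Ties in Q are
#'   broken toward fewer modules.
#' @return List with `Q`, `rows` and `cols` (integer module labels, relabeled
#'   consecutively), and `n_modules`.
#' @export
bipartite_modularity <- function(network, seed = 1L, restarts = 20L) {
  A <- if (inherits(network, "plot_network")) network$matrix else network
  if (length(A) == 0 || sum(A) == 0) stop("modularity undefined: empty network")
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  k <- rowSums(A); d <- colSums(A); F_tot <- sum(A)

  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1) seq_len(m) else NULL  # singleton init first, then random
    fit <- with_seed(derive_seed(seed, r),
                     lpa_agglom(A, k, d, F_tot, init))
    if (is.null(best) ||
        fit$Q > best$Q + 1e-12 ||
        (abs(fit$Q - best$Q) <= 1e-12 && fit$n_modules < best$n_modules)) {
      best <- fit
    }
  }
  best
}

barber_Q <- function(A, rlab, clab) {
  F_tot <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  same <- outer(rlab, clab, "==")
  sum((A - outer(k, d) / F_tot)[same]) / F_tot
}

# one optimizer run: label propagation to a local optimum, then greedy
# module agglomeration, alternating until neither improves
lpa_agglom <- function(A, k, d, F_tot, init = NULL) {
  m <- nrow(A); n <- ncol(A)
  rlab <- if (is.null(init)) sample.int(max(2L, ceiling(m / 2)), m, TRUE) else init
  clab <- propagate_cols(A, k, d, F_tot, rlab)

  repeat {
    res <- propagate(A, k, d, F_tot, rlab, clab)
    rlab <- res$rlab; clab <- res$clab
    res <- agglomerate(A, k, d, F_tot, rlab, clab)
    if (!res$merged) break
    rlab <- res$rlab; clab <- res$clab
  }
  relab <- relabel(rlab, clab)
  list(Q = barber_Q(A, relab$rows, relab$cols),
       rows = relab$rows, cols = relab$cols,
       n_modules = length(unique(c(relab$rows, relab$cols))))
}

# assign each column to the row-module with the largest modularity gain;
# a column whose every score is negative takes a fresh singleton module
# (contribution 0) rather than being forced into a bad one
propagate_cols <- function(A, k, d, F_tot, rlab) {
  free_base <- nrow(A) + ncol(A)
  vapply(seq_len(ncol(A)), function(j) {
    contrib <- A[, j] - k * d[j] / F_tot
    scores <- rowsum(contrib, rlab)
    if (max(scores) < 0) return(free_base + j)
    as.integer(rownames(scores)[which.max(scores)])
  }, integer(1))
}

propagate_rows <- function(A, k, d, F_tot, clab) {
  free_base <- 2L * (nrow(A) + ncol(A))
  vapply(seq_len(nrow(A)), function(i) {
    contrib <- A[i, ] - k[i] * d / F_tot
    scores <- rowsum(contrib, clab)
    if (max(scores) < 0) return(free_base + i)
    as.integer(rownames(scores)[which.max(scores)])
  }, integer(1))
}

propagate <- function(A, k, d, F_tot, rlab, clab, max_sweeps = 100L) {
  for (s in seq_len(max_sweeps)) {
    new_clab <- propagate_cols(A, k, d, F_tot, rlab)
    new_rlab <- propagate_rows(A, k, d, F_tot, new_clab)
    if (identical(new_rlab, rlab) && identical(new_clab, clab)) break
    rlab <- new_rlab; clab <- new_clab
  }
  list(rlab = rlab, clab = clab)
}

# greedily merge the module pair with the largest positive Q gain
agglomerate <- function(A, k, d, F_tot, rlab, clab) {
  merged_any <- FALSE
  repeat {
    mods <- sort(unique(c(rlab, clab)))
    if (length(mods) < 2) break
    K <- vapply(mods, function(g) sum(k[rlab == g]), numeric(1))
    D <- vapply(mods, function(g) sum(d[clab == g]), numeric(1))
    E <- matrix(0, length(mods), length(mods))
    for (a in seq_along(mods)) {
      ra <- rlab == mods[a]
      if (!any(ra)) next
      for (b in seq_along(mods)) {
        cb <- clab == mods[b]
        if (any(cb)) E[a, b] <- sum(A[ra, cb, drop = FALSE])
      }
    }
    best_gain <- 1e-12; best_pair <- NULL
    for (a in seq_len(length(mods) - 1)) {
      for (b in (a + 1):length(mods)) {
        gain <- (E[a, b] + E[b, a] - (K[a] * D[b] + K[b] * D[a]) / F_tot) / F_tot
        if (gain > best_gain) { best_gain <- gain; best_pair <- c(a, b) }
      }
    }
    if (is.null(best_pair)) break
    from <- mods[best_pair[2]]; to <- mods[best_pair[1]]
    rlab[rlab == from] <- to
    clab[clab == from] <- to
    merged_any <- TRUE
  }
  list(rlab = rlab, clab = clab, merged = merged_any)
}

relabel <- function(rlab, clab) {
  all_lab <- c(rlab, clab)
  new <- match(all_lab, unique(all_lab))
  list(rows = new[seq_along(rlab)], cols = new[-seq_along(rlab)])
}
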