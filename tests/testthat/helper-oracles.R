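# Independent oracles and tiny fixtures shared across test files.
# Oracles are deliberately written as slow, literal enumerations so they
# stay independent of the package's vectorized implementations.

# literal NODF: double loop over ordered pairs, per the paired-overlap
# definition (equal fills contribute 0)
nodf_oracle <- function(B) {
  B <- (B > 0) * 1
  pair_sum <- function(M) {
    m <- nrow(M)
    if (m < 2) return(0)
    tot <- 0
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        fi <- sum(M[i, ]); fj <- sum(M[j, ])
        if (fi == fj || min(fi, fj) == 0) next
        shared <- sum(M[i, ] == 1 & M[j, ] == 1)
        tot <- tot + shared / min(fi, fj)
      }
    }
    tot
  }
  100 * (pair_sum(B) + pair_sum(t(B))) /
    (choose(nrow(B), 2) + choose(ncol(B), 2))
}

# brute-force max NODF: enumerate every binary matrix with L links and no
# empty row/column, score with the oracle
max_nodf_oracle <- function(m, n, L) {
  cells <- combn(m * n, L)
  best <- -Inf
  for (k in seq_len(ncol(cells))) {
    B <- matrix(0, m, n)
    B[cells[, k]] <- 1
    if (any(rowSums(B) == 0) || any(colSums(B) == 0)) next
    v <- nodf_oracle(B)
    if (v > best) best <- v
  }
  best
}

# enumerate all non-negative integer tables with the given margins,
# together with their multivariate-hypergeometric weights
# (#arrangements = prod(r_i!) prod(c_j!) / prod(a_ij!)); returns tables and
# normalized probabilities
enumerate_tables <- function(r, c) {
  m <- length(r); n <- length(c)
  tabs <- list()
  recurse <- function(row_idx, remaining_c, acc) {
    if (row_idx > m) {
      if (all(remaining_c == 0)) tabs[[length(tabs) + 1]] <<- acc
      return()
    }
    fill_row <- function(col_idx, left, row_acc) {
      if (col_idx == n) {
        if (left <= remaining_c[n]) {
          recurse(row_idx + 1, remaining_c - c(row_acc, left),
                  rbind(acc, c(row_acc, left)))
        }
        return()
      }
      for (v in 0:min(left, remaining_c[col_idx])) {
        fill_row(col_idx + 1, left - v, c(row_acc, v))
      }
    }
    fill_row(1, r[row_idx], integer(0))
  }
  recurse(1, c, NULL)
  logw <- vapply(tabs, function(tb) {
    sum(lfactorial(r)) + sum(lfactorial(c)) - sum(lfactorial(tb))
  }, numeric(1))
  w <- exp(logw - max(logw))
  list(tables = tabs, prob = w / sum(w))
}

# small deterministic interaction table spanning 2 blocks x 4 treatments
toy_interactions <- function() {
  as_interaction_table(data.frame(
    plot = rep(c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8"),
               times = c(3, 2, 2, 1, 2, 2, 1, 2)),
    block = rep(c("b1", "b1", "b1", "b1", "b2", "b2", "b2", "b2"),
                times = c(3, 2, 2, 1, 2, 2, 1, 2)),
    treatment = rep(c("C", "F", "H", "HF", "C", "F", "H", "HF"),
                    times = c(3, 2, 2, 1, 2, 2, 1, 2)),
    plant = c("A", "A", "B", "A", "B", "A", "B", "A",
              "A", "B", "A", "B", "B", "A", "B"),
    insect = c("x", "y", "x", "x", "y", "x", "x", "y",
               "x", "y", "y", "x", "z", "x", "z"),
    count = c(2L, 1L, 3L, 1L, 2L, 2L, 1L, 1L,
              4L, 1L, 2L, 2L, 1L, 3L, 1L),
    stringsAsFactors = FALSE
  ))
}

toy_network <- function() {
  # 2x2 matrix [[2,4],[1,0]] used throughout the metric examples
  A <- matrix(c(2L, 1L, 4L, 0L), 2, 2,
              dimnames = list(c("plantA", "plantB"), c("ins1", "ins2")))
  structure(list(matrix = A, plot_id = "toy", meta = NULL),
            class = "plot_network")
}
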