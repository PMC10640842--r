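#' Hill-number diversity of order q
#'
#' Effective species count `qD = (sum p_i^q)^(1/(1-q))` with relative
#' abundances `p_i = x_i / n`; `q = 0` gives observed richness, `q = 1` the
#' exponential of Shannon entropy (by the limit), `q = 2` inverse Simpson.
#'
#' @param x Positive integer abundance vector (zeros are dropped).
#' @param q Diversity order, `q >= 0`.
#' @return Effective species count, in `[1, S_obs]`.
#' @export
hill_number <- function(x, q) {
  if (q < 0) stop("diversity order q must be >= 0")
  x <- x[x > 0]
  if (length(x) == 0 || sum(x) <= 0) stop("abundance vector is empty")
  p <- x / sum(x)
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Estimated sample coverage
#'
#' The probability that the next sampled individual belongs to an
#' already-observed species, estimated from singleton and doubleton counts:
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`.
#'
#' @param x Positive integer abundance vector with `sum(x) >= 2`.
#' @return Coverage in \[0, 1\].
#' @export
sample_coverage <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  if (n < 2) stop("sample coverage needs n >= 2 individuals")
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  a <- if ((n - 1) * f1 + 2 * f2 > 0) {
    (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  } else {
    0
  }
  1 - (f1 / n) * a
}

#' Rarefaction of Hill numbers by subsample size
#'
#' Interpolated (rarefied) diversity at sample sizes `m <= n`. Order 0 uses
#' the exact hypergeometric formula
#' `E[S_m] = sum_i (1 - choose(n - x_i, m)/choose(n, m))`; orders 1 and 2 use
#' the standard interpolated estimators built from the expected frequency
#' counts `E[f_k(m)] = sum_i choose(x_i,k) choose(n-x_i,m-k) / choose(n,m)`.
#'
#' @param x Positive integer abundance vector.
#' @param sizes Integer subsample sizes, each in `[1, n]`.
#' @param q Diversity order (0, 1 or 2).
#' @return Data frame with columns `m` and `qD`; `qD` is non-decreasing in
#'   `m` and equals the observed Hill number at `m = n`.
#' @export
rarefaction_curve <- function(x, sizes, q = 0) {
  x <- x[x > 0]
  n <- sum(x)
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("subsample sizes must be positive")
  if (any(sizes > n)) {
    stop("subsample size exceeds n = ", n, " (interpolation only)")
  }
  qD <- vapply(sizes, function(m) rarefy_one(x, n, m, q), numeric(1))
  data.frame(m = sizes, qD = qD)
}

rarefy_one <- function(x, n, m, q) {
  if (m == n) return(hill_number(x, q))
  if (q == 0) {
    # exact expected richness under hypergeometric subsampling
    return(sum(1 - exp(lchoose(n - x, m) - lchoose(n, m))))
  }
  # expected frequency counts of the subsample
  k <- seq_len(m)
  Efk <- vapply(k, function(kk) {
    sum(exp(lchoose(x, kk) + lchoose(n - x, m - kk) - lchoose(n, m)))
  }, numeric(1))
  pk <- k / m
  if (abs(q - 1) < 1e-9) {
    return(exp(-sum(pk * log(pk) * Efk)))
  }
  sum(pk^q * Efk)^(1 / (1 - q))
}

#' Per-treatment diversity summary
#'
#' Pools all specimens of each treatment across plots and reports observed
#' Hill numbers of orders 0, 1, 2 plus estimated sample coverage.
#'
#' @param table An `interaction_table`.
#' @return Data frame: treatment, n (specimens), q0, q1, q2, coverage.
#' @export
diversity_summary <- function(table) {
  out <- lapply(sort(unique(table$treatment)), function(trt) {
    sub <- table[table$treatment == trt, , drop = FALSE]
    ab <- tapply(sub$count, sub$insect, sum)
    data.frame(treatment = trt, n = sum(ab),
               q0 = hill_number(ab, 0), q1 = hill_number(ab, 1),
               q2 = hill_number(ab, 2), coverage = sample_coverage(ab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
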