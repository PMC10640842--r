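#' Fit the treatment-contrast linear mixed model
#'
#' Gaussian linear mixed model (REML) for one response over the plot table:
#' fixed effects are experimental treatment (reference level C) and
#' optionally the log floral display; random intercept is the experimental
#' block. When `test_interaction` is `TRUE` the treatment x display
#' interaction is fitted first and dropped unless at least one interaction
#' contrast has p < 0.05. Contrasts against the control (C-F, C-H, C-HF) are
#' reported with Satterthwaite t and p values.
#'
#' @param data Data frame with columns `treatment`, `block`, the response,
#'   and `display_log` when the display covariate is used.
#' @param response Name of the response column.
#' @param log_response Model `log(response)` instead of the raw response.
#' @param include_display Include `display_log` as a fixed covariate
#'   (default `TRUE`).
#' @param test_interaction Test and prune the treatment x display
#'   interaction (default `TRUE`; ignored without the display covariate).
#' @param alpha Interaction-retention threshold (default 0.05).
#' @return List of class `lmm_fit`: `table` (term, contrast, estimate, t, p),
#'   `R2m`, `R2c`, `interaction_kept`, `singular`, `model`, `response`.
#' @export
fit_lmm <- function(data, response, log_response = FALSE,
                    include_display = TRUE, test_interaction = TRUE,
                    alpha = 0.05) {
  df <- data[!is.na(data[[response]]), , drop = FALSE]
  df$.y <- df[[response]]
  if (log_response) {
    if (any(df$.y <= 0)) stop("log response requires positive values")
    df$.y <- log(df$.y)
  }
  df$treatment <- factor(df$treatment, levels = TREATMENT_LEVELS)
  df$block <- factor(df$block)
  if (nlevels(df$block) < 2) stop("need >= 2 blocks for the random effect")
  if (include_display && any(!is.finite(df$display_log))) {
    stop("non-finite display_log; display must be > 0")
  }

  rhs <- if (include_display) "treatment + display_log" else "treatment"
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | block)"))
  interaction_kept <- FALSE
  if (include_display && test_interaction) {
    form_int <- stats::as.formula(
      ".y ~ treatment + display_log + treatment:display_log + (1 | block)")
    fit_int <- suppressMessages(
      lmerTest::lmer(form_int, data = df, REML = TRUE))
    co <- stats::coef(summary(fit_int))
    int_rows <- grepl(":display_log", rownames(co))
    if (any(int_rows) && any(co[int_rows, "Pr(>|t|)"] < alpha, na.rm = TRUE)) {
      interaction_kept <- TRUE
      form <- form_int
      fit <- fit_int
    }
  }
  if (!interaction_kept) {
    fit <- suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE))
  }

  co <- stats::coef(summary(fit))
  terms <- rownames(co)
  contrast <- ifelse(
    terms %in% paste0("treatment", c("F", "H", "HF")),
    paste0("C-", sub("^treatment", "", terms)),
    ifelse(terms == "display_log", "log(Display)",
           ifelse(grepl(":display_log", terms),
                  paste0(sub("^treatment", "", sub(":display_log", "", terms)),
                         ":Display"),
                  terms)))
  tab <- data.frame(term = terms, contrast = contrast,
                    estimate = co[, "Estimate"], t = co[, "t value"],
                    p = co[, "Pr(>|t|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  r2 <- r2_nakagawa_lmm(fit)
  structure(list(table = tab, R2m = r2[["R2m"]], R2c = r2[["R2c"]],
                 interaction_kept = interaction_kept,
                 singular = lme4::isSingular(fit), model = fit,
                 response = if (log_response) paste0("log(", response, ")")
                            else response),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Mixed model for", x$response,
      if (x$interaction_kept) "(treatment x display interaction retained)",
      "\n")
  print(x$table, digits = 3)
  cat(sprintf("R2m = %.3f, R2c = %.3f%s\n", x$R2m, x$R2c,
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}

#' Marginal and conditional R-squared from variance components
#'
#' `R2m = s2_f / (s2_f + s2_a + s2_e)` and
#' `R2c = (s2_f + s2_a) / (s2_f + s2_a + s2_e)`, where `s2_f` is the
#' variance of the fixed-effect predictions, `s2_a` the random-intercept
#' variance and `s2_e` the residual variance.
#'
#' @param sigma2_f,sigma2_alpha,sigma2_eps Non-negative variance components.
#' @return Named vector `c(R2m, R2c)`.
#' @export
r2_nakagawa <- function(sigma2_f, sigma2_alpha, sigma2_eps) {
  if (any(c(sigma2_f, sigma2_alpha, sigma2_eps) < 0)) {
    stop("variance components must be >= 0")
  }
  tot <- sigma2_f + sigma2_alpha + sigma2_eps
  if (tot == 0) stop("all variance components are zero: R2 undefined")
  c(R2m = sigma2_f / tot, R2c = (sigma2_f + sigma2_alpha) / tot)
}

#' @rdname r2_nakagawa
#' @param model A fitted `lmer` model (single random intercept).
#' @export
r2_nakagawa_lmm <- function(model) {
  s2_f <- stats::var(as.vector(lme4::getME(model, "X") %*%
                                 lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  s2_a <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  s2_e <- attr(vc, "sc")^2
  if (s2_f + s2_a + s2_e < 1e-10) {
    # degenerate (constant response): no variance to explain
    return(c(R2m = 0, R2c = 0))
  }
  r2_nakagawa(s2_f, s2_a, s2_e)
}

#' Kruskal-Wallis with Dunn-type pairwise contrasts against control
#'
#' Tie-corrected Kruskal-Wallis H over all groups, then pairwise
#' treatment-vs-control comparisons as mean rank differences on the joint
#' ranking with a normal-approximation (Dunn-type) z test. P values are
#' Bonferroni-corrected with family size `bonferroni_m` (e.g. the number of
#' species tested when the test is applied per species).
#'
#' @param values Numeric response (e.g. plant species visited per plot).
#' @param groups Treatment codes, same length as `values`.
#' @param control Reference group (default `"C"`).
#' @param bonferroni_m Bonferroni family size (default 1: no correction).
#' @return List: `H`, `df`, `p_kw`, and `contrasts` (data frame with group,
#'   mean rank difference group - control, z, p, p_adj; groups with no
#'   observations are reported missing).
#' @export
kruskal_pairwise <- function(values, groups, control = "C",
                             bonferroni_m = 1L) {
  groups <- as.character(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2) stop("need >= 2 groups with data")
  kw <- stats::kruskal.test(values, factor(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr
  mean_ranks <- tapply(r, groups, mean)
  ns <- table(groups)
  others <- setdiff(sort(unique(groups)), control)
  if (!control %in% groups) stop("control group '", control, "' has no data")
  rows <- lapply(others, function(g) {
    diff <- mean_ranks[[g]] - mean_ranks[[control]]
    se <- sqrt(var_term * (1 / ns[[g]] + 1 / ns[[control]]))
    z <- if (se > 0) diff / se else NA_real_
    p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
    data.frame(group = g, mean_rank_diff = diff, z = z, p = p,
               p_adj = pmin(1, bonferroni_m * p), stringsAsFactors = FALSE)
  })
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_kw = kw$p.value, contrasts = do.call(rbind, rows))
}

#' Per-species treatment tests for the most abundant visitors
#'
#' For each of the `n_top` most abundant insect species, tests whether the
#' number of plant species it visited per plot differs between treatments
#' and control ([kruskal_pairwise()] with Bonferroni family `n_top`). Plots
#' where the species was not recorded contribute zero plants visited.
#'
#' @param table An `interaction_table`.
#' @param n_top Number of species to test (default 10).
#' @return Named list (by species) of [kruskal_pairwise()] results.
#' @export
top_visitor_tests <- function(table, n_top = 10L) {
  ab <- sort(tapply(table$count, table$insect, sum), decreasing = TRUE)
  top <- names(ab)[seq_len(min(n_top, length(ab)))]
  plots <- unique(table[c("plot", "treatment")])
  out <- lapply(top, function(sp) {
    sub <- table[table$insect == sp, , drop = FALSE]
    visited <- tapply(sub$plant, sub$plot, function(p) length(unique(p)))
    vals <- ifelse(plots$plot %in% names(visited),
                   visited[plots$plot], 0)
    kruskal_pairwise(as.numeric(vals), plots$treatment,
                     bonferroni_m = length(top))
  })
  stats::setNames(out, top)
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' @param data Data frame of network attributes.
#' @param variables Columns to correlate (default: all numeric columns).
#' @param alpha Significance threshold for the flag (default 0.05).
#' @return List of matrices `r`, `p`, and logical `significant`;
#'   zero-variance variables (and pairs with < 3 complete observations) are
#'   reported missing.
#' @export
correlation_matrix <- function(data, variables = NULL, alpha = 0.05) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- data[[variables[i]]]; xj <- data[[variables[j]]]
      ok <- stats::complete.cases(xi, xj)
      if (sum(ok) < 3) next
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, significant = !is.na(p) & p < alpha)
}
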