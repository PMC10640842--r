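test_that("variance-component R2 follows the closed form", {
  expect_equal(r2_nakagawa(1, 1, 2), c(R2m = 0.25, R2c = 0.5))
  expect_equal(unname(r2_nakagawa(2, 0, 2)[1]),
               unname(r2_nakagawa(2, 0, 2)[2]))  # no block variance
  expect_equal(unname(r2_nakagawa(0, 1, 1)[["R2m"]]), 0)
  expect_error(r2_nakagawa(0, 0, 0), "undefined")
  expect_error(r2_nakagawa(-1, 0, 1), ">= 0")
})

make_lmm_data <- function(seed = 1, n_blocks = 8, beta_display = 2,
                          trt_eff = c(C = 0, F = 0, H = 0, HF = 0),
                          sd_block = 1, sd_res = 0.5) {
  set.seed(seed)
  d <- expand.grid(block = paste0("b", seq_len(n_blocks)),
                   treatment = c("C", "F", "H", "HF"),
                   stringsAsFactors = FALSE)
  d$plot <- paste0(d$block, "_", d$treatment)
  d$display_log <- rnorm(nrow(d), 8, 0.5)
  b <- rnorm(n_blocks, 0, sd_block)
  d$y <- 1 + trt_eff[d$treatment] + beta_display * d$display_log +
    b[as.integer(factor(d$block))] + rnorm(nrow(d), 0, sd_res)
  d
}

test_that("mixed model recovers display slope and null treatment effects", {
  d <- make_lmm_data(seed = 42)
  fit <- fit_lmm(d, "y", test_interaction = FALSE)
  disp <- fit$table[fit$table$contrast == "log(Display)", ]
  expect_equal(disp$estimate, 2, tolerance = 0.15)
  trt <- fit$table[grepl("^C-", fit$table$contrast), ]
  expect_equal(nrow(trt), 3)
  expect_true(all(abs(trt$estimate) < 1))
  expect_true(fit$R2m <= fit$R2c)
  expect_true(fit$R2c <= 1)
})

test_that("a constant response yields zero effects and zero R2m", {
  d <- make_lmm_data(seed = 1)
  d$y <- 5
  fit <- suppressWarnings(suppressMessages(
    fit_lmm(d, "y", include_display = FALSE, test_interaction = FALSE)))
  expect_true(all(abs(fit$table$estimate) < 1e-8))
  expect_equal(fit$R2m, 0)
})

test_that("estimates are invariant to row order", {
  d <- make_lmm_data(seed = 7, trt_eff = c(C = 0, F = 2, H = -1, HF = 0))
  f1 <- fit_lmm(d, "y", test_interaction = FALSE)
  d2 <- d[rev(seq_len(nrow(d))), ]
  f2 <- fit_lmm(d2, "y", test_interaction = FALSE)
  expect_equal(f1$table$estimate, f2$table$estimate)
  expect_equal(f1$R2m, f2$R2m)
})

test_that("interaction is pruned when absent and kept when planted", {
  d <- make_lmm_data(seed = 3)
  fit <- fit_lmm(d, "y")
  expect_false(fit$interaction_kept)
  # plant a strong H x display interaction
  d$y <- d$y + ifelse(d$treatment == "H", 3 * d$display_log, 0)
  fit2 <- fit_lmm(d, "y")
  expect_true(fit2$interaction_kept)
  expect_true(any(grepl(":Display", fit2$table$contrast)))
})

test_that("contrast coverage is near nominal on simulated experiments", {
  truth <- c(C = 0, F = 1.5, H = -1, HF = 0)
  hits <- 0; reps <- 40
  for (s in seq_len(reps)) {
    d <- make_lmm_data(seed = 100 + s, trt_eff = truth)
    fit <- fit_lmm(d, "y", test_interaction = FALSE)
    fr <- fit$table[fit$table$contrast == "C-F", ]
    se <- fr$estimate / fr$t
    ci <- fr$estimate + c(-2, 2) * se
    if (ci[1] <= truth[["F"]] && truth[["F"]] <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("Kruskal-Wallis contrasts reproduce hand-ranked values", {
  res <- kruskal_pairwise(c(1, 2, 3, 4, 5, 6),
                          c("C", "C", "C", "F", "F", "F"))
  expect_equal(res$contrasts$mean_rank_diff, 3)  # ranks 2 vs 5
  # identical distributions: all mean rank differences 0
  res0 <- kruskal_pairwise(rep(c(1, 2), 4),
                           rep(c("C", "F", "H", "HF"), each = 2))
  expect_true(all(res0$contrasts$mean_rank_diff == 0))
  # Bonferroni scales the p-value, capped at 1
  r1 <- kruskal_pairwise(c(1, 2, 3, 7, 8, 9), rep(c("C", "F"), each = 3),
                         bonferroni_m = 1)
  r10 <- kruskal_pairwise(c(1, 2, 3, 7, 8, 9), rep(c("C", "F"), each = 3),
                          bonferroni_m = 10)
  expect_equal(r10$contrasts$p_adj,
               pmin(1, 10 * r1$contrasts$p))
})

test_that("top-visitor tests cover the most abundant species", {
  sim <- suppressMessages(simulate_experiment(sim_config(seed = 5)))
  res <- top_visitor_tests(sim$interactions, n_top = 5)
  expect_length(res, 5)
  ab <- sort(tapply(sim$interactions$count, sim$interactions$insect, sum),
             decreasing = TRUE)
  expect_identical(names(res), names(ab)[1:5])
  expect_true(all(vapply(res, function(r) {
    all(r$contrasts$p_adj >= r$contrasts$p - 1e-12, na.rm = TRUE)
  }, logical(1))))
})

test_that("correlation matrix matches the closed-form Pearson r", {
  d <- data.frame(a = c(1, 2, 4, 5, 7), b = c(2, 1, 5, 4, 8))
  d$c <- -d$a
  d$flat <- 1
  cm <- correlation_matrix(d)
  r_hand <- sum((d$a - mean(d$a)) * (d$b - mean(d$b))) /
    sqrt(sum((d$a - mean(d$a))^2) * sum((d$b - mean(d$b))^2))
  expect_equal(cm$r["a", "b"], r_hand)
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_true(all(is.na(cm$r["flat", c("a", "b", "c")])))
  expect_true(cm$significant["a", "c"])
})
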