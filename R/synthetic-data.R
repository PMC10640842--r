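#' Agrochemical application schedule
#'
#' Monthly tank concentrations (mg/L) for each compound over the three
#' application months, with the weekly application scheme: `applications`
#' sprays per month of `volume_l` litres over a plot of `area_m2` square
#' metres. Defaults reproduce the experiment's schedule: concentrations
#' decrease month by month (spring-weighted exposure) and plots are 2 x 2 m.
#'
#' @param concentrations Named list of length-3 numeric vectors (mg/L per
#'   month), one per compound.
#' @param applications Applications per month (default 4, weekly).
#' @param volume_l Water volume per application (default 10 L).
#' @param area_m2 Plot area (default 4 m^2).
#' @return List of class `application_schedule`.
#' @export
application_schedule <- function(
    concentrations = list(
      N = c(30, 20, 10),
      P = c(15, 10, 5),
      K = c(5.5, 3, 1),
      glyphosate = c(0.7, 0.3, 0.1)
    ),
    applications = 4L, volume_l = 10, area_m2 = 4) {
  if (area_m2 <= 0) stop("plot area must be > 0")
  if (applications <= 0 || volume_l <= 0) {
    stop("applications and volume must be > 0")
  }
  for (nm in names(concentrations)) {
    conc <- concentrations[[nm]]
    if (length(conc) != 3 || any(conc < 0)) {
      stop("each compound needs 3 non-negative monthly concentrations")
    }
    if (is.unsorted(rev(conc))) {
      stop("concentrations must be non-increasing across months (", nm, ")")
    }
  }
  structure(list(concentrations = concentrations,
                 applications = applications, volume_l = volume_l,
                 area_m2 = area_m2),
            class = "application_schedule")
}

#' Total seasonal application of a compound
#'
#' Sums the schedule over the season:
#' `total = sum_months(conc_mg_per_L x volume_L x applications) / area`,
#' converted to g/m^2. When a reference field rate is supplied the total is
#' also expressed as a percentage of it.
#'
#' @param schedule An [application_schedule()].
#' @param compound Compound name in the schedule.
#' @param reference_g_ha Optional reference annual field rate in g/ha (e.g.
#'   1440 g/ha for glyphosate).
#' @return List with `total_g_m2` and, when a reference is given,
#'   `total_g_ha` and `percent_of_reference`.
#' @export
total_application <- function(schedule, compound, reference_g_ha = NULL) {
  if (!compound %in% names(schedule$concentrations)) {
    stop("unknown compound: ", compound)
  }
  conc <- schedule$concentrations[[compound]]
  total_mg <- sum(conc) * schedule$volume_l * schedule$applications
  total_g_m2 <- total_mg / 1000 / schedule$area_m2
  out <- list(total_g_m2 = total_g_m2)
  if (!is.null(reference_g_ha)) {
    out$total_g_ha <- total_g_m2 * 1e4
    out$percent_of_reference <- 100 * out$total_g_ha / reference_g_ha
  }
  out
}

#' Configuration for the synthetic visitation experiment
#'
#' Defines the design (blocks x treatments, plant community, insect pool)
#' and the generative parameters. Defaults emulate the field study's
#' conditions: 8 blocks, one plot per treatment (C, F, H, HF) per block, 7
#' planted species, a ~90-species insect pool with log-normal activity
#' (realistic rarity), log-normal floral display independent of treatment,
#' a positive display-visitation relationship, a herbicide decrement on
#' visit abundance (`delta_H`, log scale) and a fertilizer multiplier on
#' species inclusion odds (`rho_F`) that raises realized visitor richness.
#'
#' @param n_blocks Blocks (site-years); default 8.
#' @param n_plants Planted species; default 7.
#' @param insect_pool Insect species pool size; default 90.
#' @param plant_attract Relative plant attractiveness (length `n_plants`).
#' @param activity_meanlog,activity_sdlog Log-normal insect activity.
#' @param display_meanlog,display_sdlog Log-normal floral display (mm^2).
#' @param display_block_sd SD of block-level shifts on log display.
#' @param beta_display Display exponent on expected visit abundance.
#' @param gamma_display Display exponent on species-inclusion odds.
#' @param alpha_activity Exponent linking activity to visit intensity
#'   (default 0.5: common species are disproportionately included but not
#'   proportionally superabundant per plot).
#' @param c_incl Inclusion-rate constant (sets baseline per-plot richness).
#' @param rho_F Fertilizer multiplier on inclusion odds (1 = no effect).
#' @param delta_H Herbicide decrement on log visit abundance (0 = none).
#' @param block_sd SD of block effects on log abundance.
#' @param dispersion Negative-binomial size (overdispersion) for counts.
#' @param mu_visits Baseline expected extra visits per included species.
#' @param p_nobloom Per-plant probability of failing to bloom in a plot.
#' @param seed Master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 8L, n_plants = 7L, insect_pool = 90L,
                       plant_attract = c(0.28, 0.20, 0.16, 0.12, 0.10,
                                         0.08, 0.06),
                       activity_meanlog = 0, activity_sdlog = 1.5,
                       display_meanlog = 8, display_sdlog = 0.5,
                       display_block_sd = 0.4,
                       beta_display = 1.0, gamma_display = 1.0,
                       alpha_activity = 0.5,
                       c_incl = 0.10, rho_F = 1.85, delta_H = 0.33,
                       block_sd = 0.4, dispersion = 1.5, mu_visits = 1.15,
                       p_nobloom = 0.04, seed = 1L) {
  if (length(plant_attract) != n_plants) {
    stop("plant_attract must have length n_plants")
  }
  if (rho_F <= 0 || dispersion <= 0 || c_incl <= 0) {
    stop("multiplicative parameters must be > 0")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a synthetic visitation experiment
#'
#' Generates a full randomized-block experiment under a [sim_config()]:
#' for each plot, floral display is drawn independently of treatment; each
#' insect species is included with probability driven by its activity, the
#' plot display, and (under fertilizer) the `rho_F` odds multiplier;
#' included species accrue negative-binomial visits with mean scaled by
#' activity, display and the herbicide decrement `exp(-delta_H)`, allocated
#' across bloomed plants by attractiveness; species drawing zero visits stay
#' unrecorded, so realized richness emerges from inclusion and counts
#' jointly. Same seed, same output.
#'
#' @param config A [sim_config()].
#' @return List: `interactions` (an `interaction_table`), `metadata` (plot
#'   metadata), and `truth` (the generating parameters and latent values).
#' @export
simulate_experiment <- function(config) {
  cf <- config
  with_seed(cf$seed, {
    activity <- stats::rlnorm(cf$insect_pool, cf$activity_meanlog,
                              cf$activity_sdlog)
    insects <- sprintf("ins_%03d", seq_len(cf$insect_pool))
    plants <- sprintf("plant_%d", seq_len(cf$n_plants))
    blocks <- sprintf("b%d", seq_len(cf$n_blocks))
    block_eff <- stats::rnorm(cf$n_blocks, 0, cf$block_sd)
    block_disp <- stats::rnorm(cf$n_blocks, 0, cf$display_block_sd)
    d_ref <- exp(cf$display_meanlog)

    recs <- list(); meta <- list()
    for (b in seq_len(cf$n_blocks)) {
      for (trt in TREATMENT_LEVELS) {
        plot_id <- paste0(blocks[b], "_", trt)
        display <- stats::rlnorm(1, cf$display_meanlog + block_disp[b],
                                 cf$display_sdlog)
        bloomed <- which(stats::runif(cf$n_plants) > cf$p_nobloom)
        if (length(bloomed) == 0) bloomed <- sample.int(cf$n_plants, 1)
        is_F <- trt %in% c("F", "HF")
        is_H <- trt %in% c("H", "HF")
        # species inclusion: base rate from activity, display on the odds,
        # fertilizer multiplies the odds
        pi_base <- 1 - exp(-cf$c_incl * activity)
        odds <- pi_base / (1 - pi_base) * (display / d_ref)^cf$gamma_display
        if (is_F) odds <- odds * cf$rho_F
        pi_s <- odds / (1 + odds)
        incl <- stats::runif(cf$insect_pool) < pi_s
        mu <- cf$mu_visits * activity^cf$alpha_activity *
          (display / d_ref)^cf$beta_display *
          exp(-cf$delta_H * is_H + block_eff[b])
        meta[[plot_id]] <- data.frame(
          plot = plot_id, block = blocks[b], treatment = trt,
          plants_bloomed = length(bloomed), display = display,
          stringsAsFactors = FALSE)
        for (s in which(incl)) {
          y <- stats::rnbinom(1, size = cf$dispersion, mu = mu[s])
          if (y == 0) next
          alloc <- stats::rmultinom(1, y,
                                    cf$plant_attract[bloomed] /
                                      sum(cf$plant_attract[bloomed]))[, 1]
          nz <- which(alloc > 0)
          if (length(nz) > 0) {
            recs[[length(recs) + 1]] <- data.frame(
              plot = plot_id, block = blocks[b], treatment = trt,
              plant = plants[bloomed][nz], insect = insects[s],
              count = alloc[nz], stringsAsFactors = FALSE)
          }
        }
      }
    }
    interactions <- as_interaction_table(do.call(rbind, recs))
    metadata <- as_plot_metadata(do.call(rbind, meta),
                                 n_plants = cf$n_plants)
    empty <- setdiff(metadata$plot, unique(interactions$plot))
    if (length(empty) > 0) {
      message("simulated plot(s) with no visits: ",
              paste(empty, collapse = ", "))
    }
    list(interactions = interactions, metadata = metadata,
         truth = list(config = cf, activity = activity,
                      block_effects = block_eff,
                      block_display_effects = block_disp))
  })
}

#' Deterministic fixture networks with known structure
#'
#' Small matrices for metric unit tests: `nested` (full overlap, strictly
#' decreasing fill, NODF = 100), `checkerboard` (equal fills, zero overlap,
#' NODF = 0), `modular` (two disconnected complete bipartite blocks of equal
#' total weight, Barber Q = 0.5), and `random` (seeded, no empty rows or
#' columns).
#'
#' @param kind One of `"nested"`, `"checkerboard"`, `"modular"`, `"random"`.
#' @param dims Integer `c(rows, cols)`.
#' @param seed Seed for `kind = "random"`.
#' @return A `plot_network` (metadata `NULL`).
#' @export
make_fixture_networks <- function(kind = c("nested", "checkerboard",
                                           "modular", "random"),
                                  dims = c(3L, 3L), seed = 1L) {
  kind <- match.arg(kind)
  m <- dims[1]; n <- dims[2]
  if (m < 1 || n < 1) stop("infeasible dims")
  A <- switch(kind,
    nested = {
      B <- matrix(0L, m, n)
      for (i in seq_len(m)) {
        w <- max(1L, n - i + 1L)
        B[i, seq_len(w)] <- 1L
      }
      B
    },
    checkerboard = {
      if (m != n) stop("checkerboard fixture needs square dims")
      diag(1L, m)
    },
    modular = {
      if (m < 2 || n < 2) stop("modular fixture needs dims >= 2")
      B <- matrix(0L, m, n)
      r1 <- seq_len(ceiling(m / 2)); c1 <- seq_len(ceiling(n / 2))
      B[r1, c1] <- 1L
      B[setdiff(seq_len(m), r1), setdiff(seq_len(n), c1)] <- 1L
      # equalize block weights
      w1 <- sum(B[r1, c1]); w2 <- sum(B) - w1
      if (w1 != w2) {
        lcm <- w1 * w2 / gcd2(w1, w2)
        B[r1, c1] <- B[r1, c1] * (lcm / w1)
        B[setdiff(seq_len(m), r1), setdiff(seq_len(n), c1)] <-
          B[setdiff(seq_len(m), r1), setdiff(seq_len(n), c1), drop = FALSE] *
          (lcm / w2)
      }
      storage.mode(B) <- "integer"
      B
    },
    random = with_seed(seed, {
      repeat {
        B <- matrix(stats::rpois(m * n, 1.2), m, n)
        if (all(rowSums(B) > 0) && all(colSums(B) > 0)) break
      }
      storage.mode(B) <- "integer"
      B
    })
  )
  dimnames(A) <- list(sprintf("plant_%d", seq_len(m)),
                      sprintf("ins_%03d", seq_len(n)))
  structure(list(matrix = A, plot_id = paste0("fixture_", kind), meta = NULL),
            class = "plot_network")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
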