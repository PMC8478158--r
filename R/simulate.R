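# Synthetic-experiment generator: pooled barcoded time-course samples
# with ground-truth sidecars, emulating the statistical structure the
# pipeline assumes - subset-specific lognormal expression, pulse-shaped
# DDR induction kinetics, survival-driven composition shifts, barcode /
# doublet / dead-cell artifacts - under a single seeded RNG stream.

SIM_SUBSETS <- c("t4_naive", "t4_cm", "t4_em", "t8_naive", "t8_cm", "t8_em",
                 "nk_bright16n", "nk_bright16p_57p", "nk_bright16p_57n",
                 "nk_dim16p_57p", "nk_dim16p_57n",
                 "b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l",
                 "b_trans", "b_cd21low", "pb_unsw", "pb_cs", "other")

#' Pulse-shaped DDR response curve
#'
#' `fold(t) = 1 + A * (t / tp) * exp(1 - t / tp)`: continuous, equal to 1
#' at t = 0, peaking at exactly `1 + A` at `t = tp`, decaying back toward
#' baseline - the simplest smooth pulse consistent with an early peak
#' (1 h class markers after ionizing radiation), a delayed peak (p53 at
#' 8 h; the 4-8 h class after UVC) and return toward 1 by 24 h.
#'
#' @param curve List with `amplitude` (A >= 0) and `peak_time` (tp > 0,
#'   hours); see [response_curve()].
#' @param t Hours (vectorised), t >= 0.
#' @return Fold >= 1.
#' @export
fold_at <- function(curve, t) {
  if (curve$peak_time <= 0) stop("config error: peak_time must be > 0")
  stopifnot(all(t >= 0))
  1 + curve$amplitude * (t / curve$peak_time) *
    exp(1 - t / curve$peak_time)
}

#' @rdname fold_at
#' @param amplitude Peak fold excess A (fold peaks at 1 + A).
#' @param peak_time Peak time tp in hours.
#' @export
response_curve <- function(amplitude, peak_time) {
  if (amplitude < 0) stop("config error: amplitude must be >= 0")
  list(amplitude = amplitude, peak_time = peak_time)
}

# subset x surface-marker expression-level table ("" = negative).
subset_level_table <- function() {
  markers <- c("CD45", "CD3", "CD4", "CD8", "CD45RA", "CD45RO", "CCR7",
               "CD69", "CD56", "CD16", "CD57", "CD19", "CD20", "IgD",
               "IgM", "IgGk", "IgGl", "CD27", "CD38", "CD21")
  L <- matrix("neg", length(SIM_SUBSETS), length(markers),
              dimnames = list(SIM_SUBSETS, markers))
  L[, "CD45"] <- "pos"
  tset <- function(rows, ...) {
    v <- c(...)
    for (m in names(v)) L[rows, m] <<- v[[m]]
  }
  tset(c("t4_naive", "t4_cm", "t4_em"), CD3 = "pos", CD4 = "pos")
  tset(c("t8_naive", "t8_cm", "t8_em"), CD3 = "pos", CD8 = "pos")
  tset(c("t4_naive", "t8_naive"), CD45RA = "pos", CCR7 = "pos")
  tset(c("t4_cm", "t8_cm"), CD45RO = "pos", CCR7 = "pos")
  tset(c("t4_em", "t8_em"), CD45RO = "pos")
  tset(c("nk_bright16n", "nk_bright16p_57p", "nk_bright16p_57n"),
       CD56 = "bright")
  tset(c("nk_dim16p_57p", "nk_dim16p_57n"), CD56 = "dim")
  tset(c("nk_bright16p_57p", "nk_bright16p_57n", "nk_dim16p_57p",
         "nk_dim16p_57n"), CD16 = "pos")
  tset(c("nk_bright16p_57p", "nk_dim16p_57p"), CD57 = "pos")
  brows <- c("b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l", "b_trans",
             "b_cd21low")
  tset(brows, CD19 = "pos", CD20 = "pos", CD21 = "pos")
  tset(c("pb_unsw", "pb_cs"), CD19 = "pos", CD27 = "pos", CD38 = "pos")
  tset("b_naive", IgD = "pos", IgM = "pos")
  tset("b_mz", CD27 = "pos", IgM = "pos", IgD = "pos")
  tset("b_igmonly", CD27 = "pos", IgM = "pos")
  tset("b_cs_k", CD27 = "pos", IgGk = "pos")
  tset("b_cs_l", CD27 = "pos", IgGl = "pos")
  tset("b_trans", IgD = "pos", IgM = "very_high", CD38 = "very_high")
  tset("b_cd21low", CD27 = "pos", IgM = "pos", CD21 = "neg")
  tset("pb_unsw", IgM = "pos")
  L
}

# Raw-scale medians by (marker, level); cv of the positive lognormal.
marker_level_medians <- function() {
  generic <- c(neg = 0, pos = 150, dim = 30, bright = 600, very_high = 1200)
  list(default = generic,
       CD56 = c(neg = 0, pos = 150, dim = 30, bright = 600,
                very_high = 1200),
       IgM = c(neg = 0, pos = 100, dim = 20, bright = 1200,
               very_high = 1200),
       CD38 = c(neg = 0, pos = 80, dim = 20, bright = 1000,
                very_high = 1000))
}

default_amplitudes_ir <- function() {
  A <- matrix(0, length(SIM_SUBSETS), 4,
              dimnames = list(SIM_SUBSETS, DDR_MARKERS))
  tn <- c("t4_naive", "t8_naive"); tm_cm <- c("t4_cm", "t8_cm")
  tm_em <- c("t4_em", "t8_em")
  nk <- c("nk_bright16n", "nk_bright16p_57p", "nk_bright16p_57n",
          "nk_dim16p_57p", "nk_dim16p_57n")
  nk_dim <- c("nk_dim16p_57p", "nk_dim16p_57n")
  b <- c("b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l", "b_trans",
         "b_cd21low", "pb_unsw", "pb_cs")
  A[tn, "gH2AX"] <- 3.0; A[tm_cm, "gH2AX"] <- 4.0; A[tm_em, "gH2AX"] <- 3.8
  A[nk, "gH2AX"] <- 6.0
  A[b, "gH2AX"] <- 1.5; A["b_naive", "gH2AX"] <- 1.2
  A["other", "gH2AX"] <- 2.0
  A[tn, "pATM"] <- 2.2; A[tm_cm, "pATM"] <- 1.8; A[tm_em, "pATM"] <- 1.5
  A[nk, "pATM"] <- 2.5; A[b, "pATM"] <- 1.8; A["other", "pATM"] <- 1.5
  A[c(tn, tm_cm, tm_em), "pCHK2"] <- 1.5
  A[nk, "pCHK2"] <- 1.2; A[b, "pCHK2"] <- 5.0; A["other", "pCHK2"] <- 1.0
  A[tn, "p53"] <- 3.0; A[tm_cm, "p53"] <- 2.2; A[tm_em, "p53"] <- 2.0
  A[nk, "p53"] <- 2.0; A[nk_dim, "p53"] <- 1.5
  A[b, "p53"] <- 2.5; A["other", "p53"] <- 1.5
  A
}

default_amplitudes_uvc <- function() {
  A <- default_amplitudes_ir()
  # CD4 > CD8 gH2AX after UVC; strong immature-NK response; damped p53
  A[c("t4_naive", "t4_cm", "t4_em"), "gH2AX"] <-
    A[c("t4_naive", "t4_cm", "t4_em"), "gH2AX"] + 0.8
  A["nk_bright16n", c("gH2AX", "p53")] <- c(7.0, 2.5)
  A[, "p53"] <- A[, "p53"] * 0.6
  A["nk_bright16n", "p53"] <- 2.5
  A[c("t4_naive", "t8_naive"), c("pATM", "pCHK2")] <-
    A[c("t4_naive", "t8_naive"), c("pATM", "pCHK2")] + 0.5
  A
}

default_peak_times <- function() {
  list(IR_2Gy = c(gH2AX = 1, pATM = 1, pCHK2 = 1, p53 = 8),
       UVC_100mJ = c(gH2AX = 6, pATM = 6, pCHK2 = 6, p53 = 8))
}

default_frequencies <- function() {
  c(t4_naive = 0.28, t4_cm = 0.08, t4_em = 0.06,
    t8_naive = 0.27, t8_cm = 0.04, t8_em = 0.02,
    nk_bright16n = 0.007, nk_bright16p_57p = 0.002,
    nk_bright16p_57n = 0.005, nk_dim16p_57p = 0.017,
    nk_dim16p_57n = 0.039,
    b_naive = 0.0405, b_mz = 0.0145, b_igmonly = 0.0095, b_cs_k = 0.006,
    b_cs_l = 0.003, b_trans = 0.0025, b_cd21low = 0.002,
    pb_unsw = 0.001, pb_cs = 0.001, other = 0.10)
}

default_survival <- function(timepoints = c(0, 1, 4, 8, 24)) {
  S <- matrix(1, length(SIM_SUBSETS), length(timepoints),
              dimnames = list(SIM_SUBSETS, as.character(timepoints)))
  b <- c("b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l", "b_trans",
         "b_cd21low", "pb_unsw", "pb_cs")
  decay <- stats::approx(c(0, 1, 4, 8, 24), c(1, 0.97, 0.92, 0.80, 0.50),
                         xout = timepoints)$y
  S[b, ] <- matrix(decay, length(b), length(timepoints), byrow = TRUE)
  S
}

default_cellcycle <- function() {
  C <- matrix(rep(c(0.90, 0.08, 0.02), each = length(SIM_SUBSETS)),
              length(SIM_SUBSETS), 3,
              dimnames = list(SIM_SUBSETS, c("G0", "G1", "S")))
  C[c("t4_naive", "t8_naive"), ] <- rep(c(0.92, 0.07, 0.01), each = 2)
  C[c("t4_cm", "t4_em", "t8_cm", "t8_em"), ] <-
    rep(c(0.80, 0.18, 0.02), each = 4)
  C["nk_bright16n", ] <- c(0.25, 0.25, 0.50)
  C[c("nk_bright16p_57p", "nk_bright16p_57n"), ] <-
    rep(c(0.40, 0.30, 0.30), each = 2)
  C[c("nk_dim16p_57p", "nk_dim16p_57n"), ] <-
    rep(c(0.50, 0.30, 0.20), each = 2)
  C[c("b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l", "b_trans",
      "b_cd21low", "pb_unsw", "pb_cs"), ] <-
    rep(c(0.85, 0.13, 0.02), each = 9)
  C
}

#' Default healthy-cohort simulation configuration
#'
#' Encodes the study's qualitative structure as generator defaults:
#' baseline composition near T 75%, NK 7%, B 8% of viable CD45+
#' lymphocytes; gH2AX amplitude ordering NK > T > B and a B-dominant
#' p-CHK2 response; early (1 h) peaks for gH2AX/p-ATM/p-CHK2 and an 8 h
#' p53 peak after ionizing radiation, 4-8 h peaks after UVC; naive T
#' cells with lower gH2AX but higher p-ATM/p53 than memory subsets; and a
#' B-cell survival multiplier falling to 0.5 by 24 h while NK survival
#' stays at 1.
#'
#' @param n_donors Number of virtual donors (study cohort: 26).
#' @param events_per_timepoint Events acquired per time-point sample.
#' @param condition Damage condition (`"IR_2Gy"` or `"UVC_100mJ"`).
#' @param timepoints Hours, subset of {0, 1, 4, 8, 24}.
#' @param seed RNG seed; the seed fully determines the output.
#' @return A `SimulationConfig` list.
#' @export
default_config_healthy <- function(n_donors = 26,
                                   events_per_timepoint = 20000,
                                   condition = "IR_2Gy",
                                   timepoints = c(0, 1, 4, 8, 24),
                                   seed = 1) {
  stopifnot(all(timepoints %in% c(0, 1, 4, 8, 24)), 0 %in% timepoints)
  amps <- if (condition == "IR_2Gy") default_amplitudes_ir()
          else default_amplitudes_uvc()
  structure(list(
    donors = data.frame(donor_id = sprintf("HD%02d", seq_len(n_donors)),
                        cohort = "control", stringsAsFactors = FALSE),
    condition = condition,
    timepoints = sort(timepoints),
    events_per_timepoint = events_per_timepoint,
    panel = default_panel(),
    scheme = barcode_scheme(),
    # keys chosen so every Pd channel is off in at least 40% of the pool,
    # keeping the robust per-channel rescaling well defined
    timepoint_labels = stats::setNames(
      c("BC01", "BC08", "BC15", "BC19", "BC20")[seq_along(timepoints)],
      as.character(sort(timepoints))),
    frequencies = default_frequencies(),
    levels = subset_level_table(),
    level_medians = marker_level_medians(),
    surface_cv = 0.5,
    ddr_baseline = c(gH2AX = 15, pATM = 10, pCHK2 = 8, p53 = 12),
    ddr_cv = 0.8,
    amplitudes = amps,
    peak_times = default_peak_times()[[condition]],
    survival = default_survival(sort(timepoints)),
    cellcycle = default_cellcycle(),
    cellcycle_medians = c(ki67 = 200, IdU = 150),
    zero_inflation = c(surface = 0.01, ddr = 0.03, cellcycle = 0.02),
    background_sigma = 1.5,
    dna_median = 300, dna_cv = 0.15,
    cisplatin_live_sigma = 3, cisplatin_dead_median = 80,
    cisplatin_dead_cv = 0.5,
    barcode_on_median = 500, barcode_on_cv = 0.3, barcode_off_sigma = 1,
    artifact = c(dead_rate = 0.05, doublet_rate = 0.03,
                 barcode_noise = 0.002),
    donor_effects = c(freq_sd = 0.10, amplitude_sd = 0.15,
                      baseline_sd = 0.10, survival_sd = 0.06),
    il2 = TRUE,
    seed = seed), class = "SimulationConfig")
}

#' Default ataxia-telangiectasia cohort configuration
#'
#' The healthy configuration with DDR amplitudes scaled to 5% (p-CHK2 to
#' 2%, i.e. effectively abolished), except for a retained partial gH2AX
#' response (25% of the healthy amplitude) in effector-memory T cells and
#' the CD56bright NK subsets, where H2AX phosphorylation can be
#' compensated by ATR/DNA-PKcs. B-cell survival at 24 h drops below the
#' healthy cohort's.
#'
#' @inheritParams default_config_healthy
#' @return A `SimulationConfig` list with `cohort = "AT"` donors.
#' @export
default_config_at <- function(n_donors = 3, events_per_timepoint = 20000,
                              condition = "IR_2Gy",
                              timepoints = c(0, 1, 4, 8, 24), seed = 1) {
  cfg <- default_config_healthy(n_donors, events_per_timepoint, condition,
                                timepoints, seed)
  cfg$donors <- data.frame(donor_id = sprintf("AT%02d", seq_len(n_donors)),
                           cohort = "AT", stringsAsFactors = FALSE)
  healthy_amp <- cfg$amplitudes
  cfg$amplitudes <- healthy_amp * 0.03
  cfg$amplitudes[, "pCHK2"] <- 0
  residual <- c("t4_em", "t8_em", "nk_bright16n", "nk_bright16p_57p",
                "nk_bright16p_57n")
  cfg$amplitudes[residual, "gH2AX"] <- healthy_amp[residual, "gH2AX"] * 0.25
  b <- c("b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l", "b_trans",
         "b_cd21low", "pb_unsw", "pb_cs")
  s24 <- cfg$survival[b, ncol(cfg$survival)]
  cfg$survival[b, ncol(cfg$survival)] <- pmin(s24, 0.35)
  cfg
}

validate_sim_config <- function(config) {
  if (sum(config$frequencies) > 1 + 1e-9)
    stop("config error: subset frequencies sum to more than 1")
  if (abs(sum(config$frequencies) - 1) > 1e-9)
    stop("config error: leaf subset frequencies must sum to 1")
  stopifnot(all(rowSums(config$cellcycle) - 1 < 1e-9))
  invisible(config)
}

# lognormal sdlog for a coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

sim_marker_block <- function(n, medians, sdlog, zi, bg_sigma) {
  x <- numeric(n)
  pos <- medians > 0
  if (any(pos))
    x[pos] <- stats::rlnorm(sum(pos), meanlog = log(medians[pos]),
                            sdlog = sdlog)
  if (any(!pos)) x[!pos] <- abs(stats::rnorm(sum(!pos), 0, bg_sigma))
  if (zi > 0 && any(pos)) {
    drop <- pos & (stats::runif(n) < zi)
    x[drop] <- 0
  }
  x
}

#' Simulate a complete pooled barcoded experiment
#'
#' Per donor, draws `events_per_timepoint` events for every time point
#' (subset labels by configured frequency times survival multiplier,
#' renormalised), assigns raw marker intensities (zero-inflated lognormal
#' positives over a low half-normal background), scales the DDR channels
#' by the subset/marker response curve at that time point, sets the Pd
#' barcode channels per the time point's key with multiplicative noise,
#' injects dead cells (high cisplatin) and doublets (channel-wise sums of
#' two events, so both the Ir and the Pd channels add), pools everything
#' into one file per donor and records the ground truth per event.
#'
#' @param config A `SimulationConfig` from [default_config_healthy()] or
#'   [default_config_at()].
#' @return List with `donors`: per donor a list of `frame` (pooled raw
#'   EventFrame), `truth` (per-event data.frame: `timepoint_h`, `subset`,
#'   `phase`, `live`, `doublet`) and `manifest`; plus the `config`.
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  panel <- config$panel
  markers <- panel$marker
  surf <- colnames(config$levels)
  meds_tab <- config$level_medians
  out <- vector("list", nrow(config$donors))
  names(out) <- config$donors$donor_id

  for (di in seq_len(nrow(config$donors))) {
    donor <- config$donors$donor_id[di]
    de <- config$donor_effects
    freq_d <- config$frequencies *
      stats::rlnorm(length(config$frequencies), -de[["freq_sd"]]^2 / 2,
                    de[["freq_sd"]])
    freq_d <- freq_d / sum(freq_d)
    amp_jit <- matrix(stats::rlnorm(length(config$amplitudes),
                                    -de[["amplitude_sd"]]^2 / 2,
                                    de[["amplitude_sd"]]),
                      nrow(config$amplitudes), ncol(config$amplitudes))
    amp_d <- config$amplitudes * amp_jit
    base_mult <- stats::rlnorm(length(markers), -de[["baseline_sd"]]^2 / 2,
                               de[["baseline_sd"]])
    names(base_mult) <- markers
    surv_d <- config$survival
    jit <- stats::rlnorm(length(surv_d), -de[["survival_sd"]]^2 / 2,
                         de[["survival_sd"]])
    surv_d <- surv_d * matrix(jit, nrow(surv_d), ncol(surv_d))
    surv_d[surv_d > 1] <- 1
    surv_d[, "0"] <- 1

    frames <- list(); truths <- list()
    for (ti in seq_along(config$timepoints)) {
      tp <- config$timepoints[ti]
      n <- config$events_per_timepoint
      n_dead <- stats::rbinom(1, n, config$artifact[["dead_rate"]])
      n_live <- n - n_dead
      w <- freq_d * surv_d[, as.character(tp)]
      subs <- sample(SIM_SUBSETS, n, replace = TRUE, prob = w / sum(w))
      live <- rep(TRUE, n)
      if (n_dead > 0) live[sample.int(n, n_dead)] <- FALSE
      si <- match(subs, SIM_SUBSETS)

      X <- matrix(0, n, nrow(panel), dimnames = list(NULL, panel$channel_id))
      sd_surf <- cv_to_sdlog(config$surface_cv)
      for (m in surf) {
        lv <- config$levels[si, m]
        tab <- if (!is.null(meds_tab[[m]])) meds_tab[[m]] else
          meds_tab$default
        med <- unname(tab[lv]) * base_mult[[m]]
        med[is.na(med)] <- 0
        X[, panel$channel_id[match(m, markers)]] <-
          sim_marker_block(n, med, sd_surf,
                           config$zero_inflation[["surface"]],
                           config$background_sigma)
      }
      # cell cycle phases and ki67/IdU
      cc <- config$cellcycle
      u <- stats::runif(n)
      g0 <- cc[si, "G0"]; g1 <- cc[si, "G1"]
      phase <- ifelse(u < g0, "G0", ifelse(u < g0 + g1, "G1", "S"))
      sd_cc <- cv_to_sdlog(config$surface_cv)
      ki_med <- ifelse(phase %in% c("G1", "S"),
                       config$cellcycle_medians[["ki67"]] *
                         base_mult[["ki67"]], 0)
      idu_med <- ifelse(phase == "S",
                        config$cellcycle_medians[["IdU"]] *
                          base_mult[["IdU"]], 0)
      X[, panel$channel_id[match("ki67", markers)]] <-
        sim_marker_block(n, ki_med, sd_cc,
                         config$zero_inflation[["cellcycle"]],
                         config$background_sigma)
      X[, panel$channel_id[match("IdU", markers)]] <-
        sim_marker_block(n, idu_med, sd_cc,
                         config$zero_inflation[["cellcycle"]],
                         config$background_sigma)
      # DDR channels
      sd_ddr <- cv_to_sdlog(config$ddr_cv)
      for (m in DDR_MARKERS) {
        folds <- fold_at(list(amplitude = 1,
                              peak_time = config$peak_times[[m]]), tp) - 1
        fold_vec <- 1 + amp_d[si, m] * folds
        med <- config$ddr_baseline[[m]] * base_mult[[m]] * fold_vec
        X[, panel$channel_id[match(m, markers)]] <-
          sim_marker_block(n, med, sd_ddr, config$zero_inflation[["ddr"]],
                           config$background_sigma)
      }
      # DNA, viability
      sd_dna <- cv_to_sdlog(config$dna_cv)
      for (ch in panel$channel_id[panel$role == "dna"])
        X[, ch] <- stats::rlnorm(n, log(config$dna_median), sd_dna)
      cis <- abs(stats::rnorm(n, 0, config$cisplatin_live_sigma))
      if (n_dead > 0)
        cis[!live] <- stats::rlnorm(n_dead,
                                    log(config$cisplatin_dead_median),
                                    cv_to_sdlog(config$cisplatin_dead_cv))
      X[, panel$channel_id[panel$role == "viability"][1]] <- cis
      # barcode channels
      key <- config$scheme$keys[
        config$timepoint_labels[[as.character(tp)]], ]
      sd_bc <- cv_to_sdlog(config$barcode_on_cv)
      bc_cols <- panel$channel_id[panel$role == "barcode"]
      for (b in seq_along(bc_cols)) {
        X[, bc_cols[b]] <- if (key[b] == 1)
          stats::rlnorm(n, log(config$barcode_on_median), sd_bc)
        else abs(stats::rnorm(n, 0, config$barcode_off_sigma))
      }
      noise <- stats::runif(n) < config$artifact[["barcode_noise"]]
      if (any(noise)) {
        off_cols <- bc_cols[key == 0]
        pick <- sample(off_cols, sum(noise), replace = TRUE)
        for (b in unique(pick)) {
          rows <- which(noise)[pick == b]
          X[rows, b] <- stats::rlnorm(length(rows),
                                      log(config$barcode_on_median), sd_bc)
        }
      }
      frames[[ti]] <- X
      truths[[ti]] <- data.frame(timepoint_h = tp, subset = subs,
                                 phase = phase, live = live,
                                 doublet = FALSE, stringsAsFactors = FALSE)
    }
    X <- do.call(rbind, frames)
    truth <- do.call(rbind, truths)
    # doublets: channel-wise sums of two independent pooled events
    n_tot <- nrow(X)
    n_dbl <- round(config$artifact[["doublet_rate"]] * n_tot)
    if (n_dbl > 0) {
      i1 <- sample.int(n_tot, n_dbl, replace = TRUE)
      i2 <- sample.int(n_tot, n_dbl, replace = TRUE)
      D <- X[i1, , drop = FALSE] + X[i2, , drop = FALSE]
      X <- rbind(X, D)
      truth <- rbind(truth, data.frame(
        timepoint_h = NA_real_, subset = NA_character_,
        phase = NA_character_,
        live = truth$live[i1] & truth$live[i2], doublet = TRUE,
        stringsAsFactors = FALSE))
    }
    ord <- sample.int(nrow(X))
    X <- X[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(truth) <- NULL
    manifest <- data.frame(
      sample_label = unname(config$timepoint_labels),
      donor_id = donor,
      condition = ifelse(config$timepoints == 0, "untreated",
                         config$condition),
      timepoint_h = config$timepoints,
      cohort = config$donors$cohort[di], il2 = config$il2,
      stringsAsFactors = FALSE)
    out[[donor]] <- list(
      frame = event_frame(X, panel,
                          meta = acquisition_meta(donor_id = donor,
                                                  cohort =
                                                    config$donors$cohort[di],
                                                  il2 = config$il2)),
      truth = truth, manifest = manifest)
  }
  list(donors = out, config = config)
}

# ---- ground-truth helpers -------------------------------------------------

# Which simulated leaf subsets satisfy each gated population's predicates,
# evaluated symbolically on the expression-level table.
leaf_membership <- function(config, spec = default_gating_spec()) {
  preds <- resolve_predicates(spec)
  L <- config$levels
  sat <- function(level, pred) {
    switch(pred,
           pos = level %in% c("pos", "dim", "bright", "very_high"),
           neg = , low = level == "neg",
           dim = level == "dim",
           bright = , very_high = level %in% c("bright", "very_high"),
           FALSE)
  }
  M <- matrix(FALSE, nrow(L), length(preds),
              dimnames = list(rownames(L), names(preds)))
  for (p in names(preds)) {
    keep <- rep(TRUE, nrow(L))
    pr <- preds[[p]]
    for (m in names(pr))
      keep <- keep & vapply(L[, m], sat, logical(1), pred = pr[[m]])
    M[, p] <- keep
  }
  M
}

#' Ground-truth population frequencies
#'
#' Expected percentage of viable CD45+ events per gated population at a
#' time point, from the configured leaf frequencies and survival
#' multipliers (no sampling noise, no donor effects).
#'
#' @param config SimulationConfig.
#' @param spec GatingSpec.
#' @param timepoint_h Time point (default 0).
#' @return data.frame `population`, `true_pct`.
#' @export
true_frequencies <- function(config, spec = default_gating_spec(),
                             timepoint_h = 0) {
  M <- leaf_membership(config, spec)
  w <- config$frequencies * config$survival[, as.character(timepoint_h)]
  w <- w / sum(w)
  data.frame(population = colnames(M),
             true_pct = 100 * as.vector(crossprod(M, w)),
             stringsAsFactors = FALSE)
}

#' Ground-truth fold induction of a gated population
#'
#' The event-weighted geometric mean of the leaf-level response curves:
#' leaves are weighted by frequency times survival at the queried time
#' point, matching what a geometric MFI over the pooled population
#' measures when baseline expression is common across leaves.
#'
#' @param config SimulationConfig.
#' @param population Gated population name.
#' @param marker DDR marker.
#' @param timepoint_h Time point in hours.
#' @param spec GatingSpec.
#' @return True fold induction (scalar).
#' @export
true_fold <- function(config, population, marker, timepoint_h,
                      spec = default_gating_spec()) {
  M <- leaf_membership(config, spec)
  leaves <- rownames(M)[M[, population]]
  if (length(leaves) == 0) return(NA_real_)
  w <- config$frequencies[leaves] *
    config$survival[leaves, as.character(timepoint_h)]
  w <- w / sum(w)
  g <- fold_at(list(amplitude = 1, peak_time = config$peak_times[[marker]]),
               timepoint_h) - 1
  folds <- 1 + config$amplitudes[leaves, marker] * g
  exp(sum(w * log(folds)))
}
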