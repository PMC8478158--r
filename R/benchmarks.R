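# Ground-truth benchmarks: run the full pipeline on seeded synthetic
# experiments and measure recovery of the configured truth. These back
# both the package's acceptance checks and the reproduction script.

derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 10007 + 131 * k) %% 2147483647
  as.integer(max(1, s))
}

b_leaves <- function() c("b_naive", "b_mz", "b_igmonly", "b_cs_k", "b_cs_l",
                         "b_trans", "b_cd21low", "pb_unsw", "pb_cs")

#' Fold-induction recovery benchmark
#'
#' Simulates a healthy cohort, runs the full pipeline (QC, debarcoding,
#' per-donor gating, geometric-MFI fold induction) and compares the
#' cross-donor mean fold per (population, marker, time point) with the
#' configured ground truth, for populations whose true frequency is at
#' least `min_freq_pct`.
#'
#' @param seed RNG seed.
#' @param n_donors Virtual donors (default 26, the study cohort size).
#' @param events_per_timepoint Events per time-point sample.
#' @param min_freq_pct Population-frequency floor in percent (default 2).
#' @return List: `table` (per-cell estimated vs true fold and relative
#'   error), `max_rel_err_pct`, and `survival` (the cohort survival
#'   table with per-time-point means for the three top-level lineages).
#' @export
benchmark_fold_recovery <- function(seed = 1, n_donors = 26,
                                    events_per_timepoint = 20000,
                                    min_freq_pct = 2) {
  cfg <- default_config_healthy(n_donors = n_donors,
                                events_per_timepoint = events_per_timepoint,
                                seed = seed)
  experiment <- simulate_experiment(cfg)
  res <- analyze_experiment(experiment)
  spec <- default_gating_spec()
  freqs <- true_frequencies(cfg, spec)
  pops <- freqs$population[freqs$true_pct >= min_freq_pct]
  kin <- res$kinetics
  kin <- kin[kin$population %in% pops & kin$timepoint_h > 0 &
               !is.na(kin$fold_induction), ]
  agg <- stats::aggregate(fold_induction ~ population + marker + timepoint_h,
                          kin, mean)
  agg$true_fold <- mapply(function(p, m, t)
    true_fold(cfg, p, m, t, spec), agg$population, agg$marker,
    agg$timepoint_h)
  agg$rel_err_pct <- 100 * abs(agg$fold_induction - agg$true_fold) /
    agg$true_fold
  surv <- res$survival
  core <- c("CD3+ T", "CD56dim CD16+ NK", "CD19+CD20+ B")
  comp <- stats::aggregate(pct_of_viable_CD45 ~ population + timepoint_h,
                           surv[surv$population %in% core, ], mean)
  list(table = agg, max_rel_err_pct = max(agg$rel_err_pct),
       survival = surv, composition_means = comp)
}

#' Subset-ordering reproducibility benchmark
#'
#' Across `n_seeds` independent simulated cohorts, checks whether the
#' pipeline reproduces the configured 1 h orderings: gH2AX induction
#' NK (CD56dim CD16+) > T (CD3+) > B (CD19+CD20+), and p-CHK2 B > T.
#'
#' @param n_seeds Number of seeds (default 20).
#' @param n_donors,events_per_timepoint Per-seed cohort size.
#' @param base_seed Seed stream origin.
#' @return List with `gh2ax_rate` and `pchk2_rate` (fractions of seeds),
#'   plus the per-seed mean folds.
#' @export
benchmark_ordering <- function(n_seeds = 20, n_donors = 4,
                               events_per_timepoint = 3000, base_seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    cfg <- default_config_healthy(
      n_donors = n_donors, events_per_timepoint = events_per_timepoint,
      seed = derive_seed(base_seed, k))
    res <- analyze_experiment(simulate_experiment(cfg))
    kin <- res$kinetics
    kin <- kin[kin$timepoint_h == 1 & !is.na(kin$fold_induction), ]
    m <- function(pop, mk)
      mean(kin$fold_induction[kin$population == pop & kin$marker == mk])
    data.frame(seed = k,
               gh2ax_nk = m("CD56dim CD16+ NK", "gH2AX"),
               gh2ax_t = m("CD3+ T", "gH2AX"),
               gh2ax_b = m("CD19+CD20+ B", "gH2AX"),
               pchk2_b = m("CD19+CD20+ B", "pCHK2"),
               pchk2_t = m("CD3+ T", "pCHK2"))
  })
  tab <- do.call(rbind, rows)
  gh <- tab$gh2ax_nk > tab$gh2ax_t & tab$gh2ax_t > tab$gh2ax_b
  pc <- tab$pchk2_b > tab$pchk2_t
  list(gh2ax_rate = mean(gh), pchk2_rate = mean(pc), table = tab)
}

#' AT / control discrimination benchmark
#'
#' Simulates control and ataxia-telangiectasia cohorts and asks whether
#' per-donor p-CHK2 fold induction at 1 h in CD19+CD20+ B cells separates
#' the cohorts with zero overlap, and whether the AT folds lie within
#' the abrogation band [0.8, 1.2].
#'
#' @param n_seeds Seeds (default 20).
#' @param n_controls,n_at Cohort sizes (default 10 and 3).
#' @param events_per_timepoint Per-sample events.
#' @param base_seed Seed stream origin.
#' @return List: `separated_rate`, `at_in_band_rate`, per-seed table.
#' @export
benchmark_at_discrimination <- function(n_seeds = 20, n_controls = 10,
                                        n_at = 3,
                                        events_per_timepoint = 6000,
                                        base_seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    ctl <- default_config_healthy(
      n_donors = n_controls, events_per_timepoint = events_per_timepoint,
      seed = derive_seed(base_seed, 2 * k))
    at <- default_config_at(
      n_donors = n_at, events_per_timepoint = events_per_timepoint,
      seed = derive_seed(base_seed, 2 * k + 1))
    fold_1h <- function(cfg) {
      kin <- analyze_experiment(simulate_experiment(cfg))$kinetics
      kin$fold_induction[kin$population == "CD19+CD20+ B" &
                           kin$marker == "pCHK2" & kin$timepoint_h == 1]
    }
    fc <- fold_1h(ctl); fa <- fold_1h(at)
    data.frame(seed = k, min_control = min(fc, na.rm = TRUE),
               max_at = max(fa, na.rm = TRUE),
               at_lo = min(fa, na.rm = TRUE),
               at_hi = max(fa, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  list(separated_rate = mean(tab$min_control > tab$max_at),
       at_in_band_rate = mean(tab$at_lo >= 0.8 & tab$at_hi <= 1.2),
       table = tab)
}

#' Debarcoding accuracy benchmark
#'
#' Measures singlet assignment accuracy against the generator's true
#' time-point labels, and the rejection rate of synthetic barcode
#' doublets (channel-wise sums of two events carrying different keys).
#'
#' @param seed RNG seed.
#' @param events_per_timepoint Events per time point (5 time points).
#' @param n_doublets Synthetic cross-key doublets to construct.
#' @return List: `singlet_accuracy`, `doublet_rejection`.
#' @export
benchmark_debarcoding <- function(seed = 1, events_per_timepoint = 2000,
                                  n_doublets = 2000) {
  cfg <- default_config_healthy(n_donors = 1,
                                events_per_timepoint = events_per_timepoint,
                                seed = seed)
  cfg$artifact[["doublet_rate"]] <- 0
  cfg$artifact[["dead_rate"]] <- 0
  sim <- simulate_experiment(cfg)
  d <- sim$donors[[1]]
  tf <- arcsinh_transform(d$frame)
  scheme <- barcode_scheme()
  asg <- debarcode(tf, scheme)$assignment
  true_label <- cfg$timepoint_labels[as.character(d$truth$timepoint_h)]
  singlet_accuracy <- mean(asg == true_label)

  set.seed(derive_seed(seed, 99))
  tp <- d$truth$timepoint_h
  i1 <- sample.int(nrow(d$frame$exprs), 4 * n_doublets, replace = TRUE)
  i2 <- sample.int(nrow(d$frame$exprs), 4 * n_doublets, replace = TRUE)
  diffkey <- which(tp[i1] != tp[i2])[seq_len(n_doublets)]
  D <- d$frame$exprs[i1[diffkey], ] + d$frame$exprs[i2[diffkey], ]
  pool <- event_frame(rbind(d$frame$exprs, D), cfg$panel)
  tf2 <- arcsinh_transform(pool)
  asg2 <- debarcode(tf2, scheme)$assignment
  dbl <- asg2[(nrow(d$frame$exprs) + 1):length(asg2)]
  list(singlet_accuracy = singlet_accuracy,
       doublet_rejection = mean(dbl == "UNASSIGNED"))
}

#' Gating frequency recovery benchmark
#'
#' Compares pipeline-estimated population frequencies (percent of viable
#' CD45+ events in the untreated sample) with label-based generator
#' ground truth, and verifies the membership hierarchy (child implies
#' parent) on the same run.
#'
#' @param seed RNG seed.
#' @param events_per_timepoint Untreated-sample size (default 50000).
#' @return List: `table` (population, estimated and true pct, error),
#'   `max_abs_err_pp` over populations with true frequency >= 2%,
#'   `hierarchy_ok`.
#' @export
benchmark_gating_recovery <- function(seed = 1,
                                      events_per_timepoint = 50000) {
  cfg <- default_config_healthy(n_donors = 1,
                                events_per_timepoint = events_per_timepoint,
                                timepoints = c(0, 1), seed = seed)
  sim <- simulate_experiment(cfg)
  d <- sim$donors[[1]]
  res <- analyze_pooled(d$frame, d$manifest)
  lab0 <- names(res$samples)[vapply(res$samples, function(f)
    f$meta$timepoint_h == 0, logical(1))]
  mem <- res$memberships[[lab0]]
  est <- population_frequencies(mem)

  spec <- default_gating_spec()
  lm <- leaf_membership(cfg, spec)
  truth0 <- d$truth[d$truth$timepoint_h %in% 0 & !d$truth$doublet &
                      d$truth$live, ]
  true_pct <- vapply(colnames(lm), function(p)
    100 * mean(truth0$subset %in% rownames(lm)[lm[, p]]), numeric(1))
  tab <- merge(est, data.frame(population = names(true_pct),
                               true_pct = unname(true_pct),
                               stringsAsFactors = FALSE), by = "population")
  tab$abs_err_pp <- abs(tab$pct - tab$true_pct)

  spec_parents <- vapply(spec, `[[`, character(1), "parent")
  hier_ok <- all(vapply(names(spec_parents), function(p) {
    pa <- spec_parents[[p]]
    if (is.na(pa)) return(TRUE)
    !any(mem[, p] & !mem[, pa])
  }, logical(1)))
  list(table = tab,
       max_abs_err_pp = max(tab$abs_err_pp[tab$true_pct >= 2]),
       hierarchy_ok = hier_ok)
}

#' Null-simulation type-I error of the Tukey layer
#'
#' Generates fold-induction tables under the null (every population
#' shares one response curve; lognormal donor and residual noise), runs
#' the two-way ANOVA Tukey comparisons within each time point and
#' reports the fraction of adjusted p values at or below 0.05.
#'
#' @param n_reps Repetitions (default 200).
#' @param n_donors Donors per repetition (default 26).
#' @param n_populations Populations (default 4).
#' @param donor_sd,resid_sd Lognormal noise scales.
#' @param seed RNG seed.
#' @return List: `type1_rate`, `n_comparisons`.
#' @export
benchmark_null_type1 <- function(n_reps = 200, n_donors = 26,
                                 n_populations = 4, donor_sd = 0.10,
                                 resid_sd = 0.10, seed = 1) {
  set.seed(seed)
  tps <- c(1, 4, 8, 24)
  curve <- response_curve(3, 1)
  n_sig <- 0; n_tot <- 0
  for (r in seq_len(n_reps)) {
    grid <- expand.grid(donor = seq_len(n_donors),
                        population = paste0("P", seq_len(n_populations)),
                        timepoint_h = tps)
    delta <- stats::rnorm(n_donors, 0, donor_sd)
    grid$fold_induction <- fold_at(curve, grid$timepoint_h) *
      exp(delta[grid$donor] + stats::rnorm(nrow(grid), 0, resid_sd))
    cmp <- two_way_anova_tukey(grid, "fold_induction", "population",
                               "timepoint_h")$comparisons
    cmp <- cmp[!cmp$skipped, ]
    n_sig <- n_sig + sum(cmp$p_adjusted <= 0.05)
    n_tot <- n_tot + nrow(cmp)
  }
  list(type1_rate = n_sig / n_tot, n_comparisons = n_tot)
}

#' Survival-shift detection benchmark
#'
#' Across seeds, simulates a healthy cohort, builds the survival
#' composition table and asks the statistics layer whether the B-cell
#' share of viable CD45+ lymphocytes changes between 0 h and 24 h
#' (expected: significant decline) and whether the CD56dim CD16+ NK
#' share changes (expected: non-significant).
#'
#' @param n_seeds Seeds (default 20).
#' @param n_donors,events_per_timepoint Per-seed cohort size.
#' @param base_seed Seed stream origin.
#' @return List: `b_significant_rate`, `nk_nonsignificant_rate`, table.
#' @export
benchmark_survival_detection <- function(n_seeds = 20, n_donors = 8,
                                         events_per_timepoint = 2500,
                                         base_seed = 1) {
  core <- c("CD3+ T", "CD56dim CD16+ NK", "CD19+CD20+ B")
  rows <- lapply(seq_len(n_seeds), function(k) {
    cfg <- default_config_healthy(
      n_donors = n_donors, events_per_timepoint = events_per_timepoint,
      seed = derive_seed(base_seed, 500 + k))
    surv <- analyze_experiment(simulate_experiment(cfg))$survival
    surv <- surv[surv$population %in% core, ]
    cmp <- two_way_anova_tukey(surv, "pct_of_viable_CD45", "timepoint_h",
                               "population")$comparisons
    p_at <- function(pop) {
      lab <- paste0("0 vs 24 @ ", pop)
      cmp$p_adjusted[cmp$comparison == lab]
    }
    data.frame(seed = k, p_b = p_at("CD19+CD20+ B"),
               p_nk = p_at("CD56dim CD16+ NK"))
  })
  tab <- do.call(rbind, rows)
  list(b_significant_rate = mean(tab$p_b <= 0.05),
       nk_nonsignificant_rate = mean(tab$p_nk > 0.05),
       table = tab)
}

#' Reproduce mean subset proportions from the deposited dataset
#'
#' Runs the shipped gating specification with per-donor estimated
#' thresholds over a local copy of the study's debarcoded FCS files and
#' returns mean subset proportions (percent of viable CD45+ events, and
#' of parent lineages for the T/B sub-compositions) before and 24 h
#' after irradiation. The deposited data are not distributed with the
#' package; `data_dir` must contain the downloaded FCS files plus a
#' `manifest.csv` with columns `file`, `donor_id`, `condition`,
#' `timepoint_h`.
#'
#' @param data_dir Directory holding the downloaded dataset.
#' @param panel,spec Panel and gating spec (package defaults).
#' @return data.frame of population means by time point.
#' @export
reproduce_deposited_composition <- function(data_dir,
                                            panel = default_panel(),
                                            spec = default_gating_spec()) {
  if (!dir.exists(data_dir))
    stop("deposited-data directory not found: ", data_dir,
         " (download the study dataset and provide a manifest.csv)")
  man <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  frames <- list(); memberships <- list()
  for (donor in unique(man$donor_id)) {
    md <- man[man$donor_id == donor, ]
    donor_frames <- lapply(seq_len(nrow(md)), function(i)
      read_fcs(file.path(data_dir, md$file[i]), panel = panel,
               meta = acquisition_meta(donor_id = donor,
                                       condition = md$condition[i],
                                       timepoint_h = md$timepoint_h[i])))
    donor_frames <- lapply(donor_frames, arcsinh_transform)
    pooled <- event_frame(do.call(rbind, lapply(donor_frames,
                                                function(f) f$exprs)),
                          donor_frames[[1]]$panel)
    pooled$transformed <- TRUE; pooled$cofactor <- 5
    pthr <- estimate_preprocess_thresholds(pooled)
    donor_frames <- lapply(donor_frames, function(f)
      gate_viable(gate_singlets(f, pthr), pthr))
    preds <- resolve_predicates(spec)
    gthr <- estimate_thresholds(pooled,
                                unique(c(unlist(lapply(preds, names)),
                                         "ki67", "IdU")))
    frames <- c(frames, donor_frames)
    memberships <- c(memberships,
                     lapply(donor_frames, assign_populations, spec = spec,
                            thr = gthr))
  }
  surv <- survival_proportions(frames, memberships)
  stats::aggregate(pct_of_viable_CD45 ~ population + timepoint_h, surv,
                   mean)
}
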