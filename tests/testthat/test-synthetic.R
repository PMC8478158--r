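test_that("the pulse curve satisfies its boundary and peak conditions", {
  crv <- response_curve(3, 1)
  expect_equal(fold_at(crv, 0), 1)
  expect_equal(fold_at(crv, 1), 4)
  expect_equal(fold_at(crv, 24), 1 + 3 * 24 * exp(-23), tolerance = 1e-12)
  expect_lt(fold_at(crv, 24) - 1, 1e-8)
  # the peak is the global maximum on a fine grid
  g <- seq(0, 24, by = 0.01)
  crv8 <- response_curve(2, 8)
  expect_equal(g[which.max(fold_at(crv8, g))], 8, tolerance = 0.01)
  expect_error(fold_at(response_curve(1, 0), 1), "peak_time")
  expect_error(response_curve(-1, 2), "amplitude")
})

test_that("healthy defaults encode the published response structure", {
  cfg <- default_config_healthy(n_donors = 2, events_per_timepoint = 100)
  A <- cfg$amplitudes
  t_rows <- c("t4_naive", "t4_cm", "t4_em", "t8_naive", "t8_cm", "t8_em")
  nk_dim <- c("nk_dim16p_57p", "nk_dim16p_57n")
  b_rows <- c("b_naive", "b_mz", "b_igmonly")
  expect_true(min(A[nk_dim, "gH2AX"]) > max(A[t_rows, "gH2AX"]))
  expect_true(min(A[t_rows, "gH2AX"]) > max(A[b_rows, "gH2AX"]))
  expect_true(min(A[b_rows, "pCHK2"]) > max(A[c(t_rows, nk_dim), "pCHK2"]))
  # naive T: lower gH2AX, higher p-ATM and p53 than memory
  expect_lt(A["t4_naive", "gH2AX"], A["t4_cm", "gH2AX"])
  expect_gt(A["t4_naive", "pATM"], A["t4_em", "pATM"])
  expect_gt(A["t4_naive", "p53"], A["t4_cm", "p53"])
  expect_equal(unname(cfg$peak_times[["p53"]]), 8)
  expect_equal(unname(cfg$peak_times[["gH2AX"]]), 1)
  expect_true(all(cfg$survival[, "0"] == 1))
  b_all <- grep("^b_|^pb_", rownames(cfg$survival), value = TRUE)
  expect_lt(max(cfg$survival[b_all, "24"]), 1)
  uvc <- default_config_healthy(n_donors = 1, events_per_timepoint = 100,
                                condition = "UVC_100mJ")
  expect_equal(unname(uvc$peak_times[["gH2AX"]]), 6)
})

test_that("AT defaults abolish p-CHK2 and deepen the B-cell decline", {
  at <- default_config_at(n_donors = 2, events_per_timepoint = 100)
  hd <- default_config_healthy(n_donors = 2, events_per_timepoint = 100)
  expect_true(all(at$amplitudes[, "pCHK2"] == 0))
  expect_true(all(at$amplitudes[, c("pATM", "p53")] <=
                    0.1 * hd$amplitudes[, c("pATM", "p53")] + 1e-12))
  expect_lt(at$survival["b_naive", "24"], hd$survival["b_naive", "24"])
  # residual gH2AX in effector memory T and CD56bright NK
  expect_gt(at$amplitudes["t4_em", "gH2AX"],
            at$amplitudes["t4_naive", "gH2AX"])
})

test_that("simulation is seed-deterministic and conserves event counts", {
  cfg <- default_config_healthy(n_donors = 2, events_per_timepoint = 500,
                                seed = 77)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$donors[[1]]$frame$exprs, s2$donors[[1]]$frame$exprs)
  expect_identical(s1$donors[[2]]$truth, s2$donors[[2]]$truth)

  d <- s1$donors[[1]]
  n_singlets <- sum(!d$truth$doublet)
  expect_equal(n_singlets, 500 * 5)
  expect_equal(nrow(d$frame$exprs), nrow(d$truth))
  tab <- table(d$truth$timepoint_h[!d$truth$doublet])
  expect_true(all(tab == 500))
})

test_that("the ground-truth sidecar matches the configured generator", {
  cfg <- default_config_healthy(n_donors = 1, events_per_timepoint = 4000,
                                seed = 78)
  d <- simulate_experiment(cfg)$donors[[1]]
  expect_lt(abs(mean(!d$truth$live[!d$truth$doublet]) - 0.05), 0.01)
  expect_lt(abs(mean(d$truth$doublet) - 0.03), 0.01)
  # configured truth for a leaf population is exact by construction
  expect_equal(true_fold(cfg, "CD56dim CD16+ NK", "gH2AX", 1),
               1 + unname(cfg$amplitudes["nk_dim16p_57n", "gH2AX"]))
  # sampled subset frequencies follow the (jittered) configuration
  t0 <- d$truth[d$truth$timepoint_h %in% 0 & !d$truth$doublet, ]
  b_frac <- mean(grepl("^b_|^pb_", t0$subset))
  expect_equal(b_frac, 0.08, tolerance = 0.03)
})

test_that("invalid configurations are rejected", {
  cfg <- default_config_healthy(n_donors = 1, events_per_timepoint = 100)
  cfg$frequencies[1] <- cfg$frequencies[1] + 0.5
  expect_error(simulate_experiment(cfg), "config error")
})
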