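test_that("geometric MFI follows its closed form and missing-value rule", {
  expect_equal(geometric_mfi(c(2, 8), min_events = 1), 4)
  expect_equal(geometric_mfi(c(1, 10, 100), min_events = 1), 10)
  expect_equal(geometric_mfi(c(0, 2, 8), min_events = 1), 4)
  expect_true(is.na(geometric_mfi(rep(2, 10), min_events = 30)))
  expect_true(is.na(geometric_mfi(c(0, 0, 5), min_events = 2)))
})

quant_fixture <- function(geo0 = 10, geo1 = 20, n = 64, donor = "D1") {
  panel <- default_panel()
  mkframe <- function(geo, tp, cond) {
    x <- matrix(1, n, nrow(panel), dimnames = list(NULL, panel$channel_id))
    for (m in c("gH2AX", "pATM", "pCHK2", "p53"))
      x[, panel$channel_id[match(m, panel$marker)]] <-
        geo * exp(scale(rnorm(n))[, 1])  # geometric mean exactly geo
    event_frame(x, panel,
                meta = acquisition_meta(donor_id = donor, condition = cond,
                                        timepoint_h = tp))
  }
  set.seed(41)
  f0 <- mkframe(geo0, 0, "untreated")
  f1 <- mkframe(geo1, 1, "IR_2Gy")
  mem <- matrix(TRUE, n, 2, dimnames = list(NULL, c("CD45+", "CD3+ T")))
  list(frames = list(f0, f1), memberships = list(mem, mem))
}

test_that("fold induction normalizes each donor to its untreated sample", {
  fx <- quant_fixture()
  tab <- fold_induction_table(fx$frames, fx$memberships, min_events = 10)
  t0 <- tab[tab$timepoint_h == 0, ]
  t1 <- tab[tab$timepoint_h == 1, ]
  expect_true(all(t0$fold_induction == 1))
  expect_equal(t1$fold_induction, rep(2, nrow(t1)), tolerance = 1e-9)
  expect_false(any(tab$flag_low_n))

  # missing untreated reference is a hard error
  expect_error(fold_induction_table(fx$frames[2], fx$memberships[2]),
               "reference error")
})

test_that("geometric MFI and fold induction are scale equivariant", {
  fx <- quant_fixture()
  tab1 <- fold_induction_table(fx$frames, fx$memberships, min_events = 10)
  scaled <- fx$frames
  j <- match("Sm147Di", colnames(scaled[[1]]$exprs))  # gH2AX channel
  for (i in 1:2) scaled[[i]]$exprs[, j] <- scaled[[i]]$exprs[, j] * 7
  tab2 <- fold_induction_table(scaled, fx$memberships, min_events = 10)
  g1 <- tab1[tab1$marker == "gH2AX", ]
  g2 <- tab2[tab2$marker == "gH2AX", ]
  expect_equal(g2$geo_mfi, 7 * g1$geo_mfi, tolerance = 1e-9)
  expect_equal(g2$fold_induction, g1$fold_induction, tolerance = 1e-9)
})

test_that("low-count cells are flagged missing, never zero", {
  fx <- quant_fixture(n = 20)
  tab <- fold_induction_table(fx$frames, fx$memberships, min_events = 30)
  expect_true(all(is.na(tab$geo_mfi)))
  expect_true(all(tab$flag_low_n))
})

test_that("survival proportions are percentages of viable CD45+", {
  panel <- default_panel()
  n <- 100
  x <- matrix(1, n, nrow(panel), dimnames = list(NULL, panel$channel_id))
  f <- event_frame(x, panel,
                   meta = acquisition_meta(donor_id = "D1",
                                           condition = "untreated",
                                           timepoint_h = 0))
  mem <- cbind("CD45+" = rep(TRUE, n), "CD3+ T" = c(rep(TRUE, 80),
                                                    rep(FALSE, 20)),
               "CD19+CD20+ B" = rep(FALSE, n))
  tab <- survival_proportions(list(f), list(mem))
  expect_equal(tab$pct_of_viable_CD45[tab$population == "CD3+ T"], 80)
  expect_equal(tab$pct_of_viable_CD45[tab$population == "CD19+CD20+ B"], 0)
})

test_that("stratified kinetics match the unstratified contract", {
  fx <- quant_fixture(n = 200)
  set.seed(42)
  phases <- lapply(fx$frames, function(f)
    factor(sample(c("G0", "G1", "S"), 200, TRUE, prob = c(0.5, 0.3, 0.2)),
           levels = c("G0", "G1", "S", "KI67NEG_IDUPOS")))
  tab <- stratified_kinetics(fx$frames, fx$memberships, phases,
                             min_events = 10)
  expect_setequal(unique(tab$stratum), c("ki67+", "ki67-"))
  t0 <- tab[tab$timepoint_h == 0 & !is.na(tab$fold_induction), ]
  expect_true(all(t0$fold_induction == 1))
  # the generator wrote identical response in both strata
  t1 <- tab[tab$timepoint_h == 1, ]
  for (mk in unique(t1$marker)) {
    a <- t1$fold_induction[t1$stratum == "ki67+" & t1$marker == mk &
                             t1$population == "CD45+"]
    b <- t1$fold_induction[t1$stratum == "ki67-" & t1$marker == mk &
                             t1$population == "CD45+"]
    expect_lt(abs(a - b) / b, 0.10)
  }
  # a ten-event stratum is missing, flagged
  tiny_phase <- lapply(fx$frames, function(f)
    factor(c(rep("G1", 10), rep("G0", 190)),
           levels = c("G0", "G1", "S", "KI67NEG_IDUPOS")))
  tab2 <- stratified_kinetics(fx$frames, fx$memberships, tiny_phase,
                              min_events = 30)
  expect_true(all(is.na(tab2$fold_induction[tab2$stratum == "ki67+"])))
})
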