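manual_thresholds <- function(markers, t1 = 1, t2 = 3) {
  data.frame(marker = markers, t1 = t1,
             t2 = ifelse(markers %in% c("CD56", "IgM", "CD38"), t2,
                         NA_real_),
             provenance = "manual", stringsAsFactors = FALSE)
}

test_that("valley thresholding splits well-separated modes", {
  set.seed(21)
  x <- c(rnorm(4000, 0.5, 0.3), rnorm(4000, 4.0, 0.5))
  thr <- estimate_thresholds(one_marker_frame(x), "CD3")
  expect_gt(thr$t1, 1.5)
  expect_lt(thr$t1, 3.0)
  # independent brute-force scan of a fine histogram between the modes
  h <- hist(x, breaks = seq(min(x) - 0.1, max(x) + 0.1, by = 0.05),
            plot = FALSE)
  mids <- h$mids[h$mids > 1 & h$mids < 3.5]
  brute <- mids[which.min(h$counts[h$mids > 1 & h$mids < 3.5])]
  expect_equal(thr$t1, brute, tolerance = 0.5)
})

test_that("unimodal channels fall back to the quantile rule", {
  set.seed(22)
  x <- abs(rnorm(3000, 0, 0.4))
  thr <- estimate_thresholds(one_marker_frame(x), "CD3", q = 0.95)
  expect_gte(thr$t1, quantile(x, 0.95) - 1e-9)
})

test_that("thresholds are invariant to event order", {
  set.seed(23)
  x <- c(rnorm(2000, 0.4, 0.3), rnorm(500, 4, 0.5))
  t1 <- estimate_thresholds(one_marker_frame(x), "CD3")
  t2 <- estimate_thresholds(one_marker_frame(sample(x)), "CD3")
  expect_equal(t1$t1, t2$t1, tolerance = 1e-12)
})

test_that("threshold estimation guards its preconditions", {
  expect_error(estimate_thresholds(one_marker_frame(rnorm(50)), "CD3"),
               "200 events")
  expect_error(estimate_thresholds(one_marker_frame(rep(1, 300)), "CD3"),
               "constant")
})

test_that("population assignment follows the predicate conjunctions", {
  panel <- default_panel()
  hi <- 4; lo <- 0.2; dim_v <- 2
  mk <- function(assign) {
    x <- matrix(lo, 1, nrow(panel), dimnames = list(NULL, panel$channel_id))
    for (m in names(assign))
      x[1, panel$channel_id[match(m, panel$marker)]] <- assign[[m]]
    x
  }
  rows <- rbind(
    mk(c(CD45 = hi, CD3 = hi, CD4 = hi, CD45RA = hi, CCR7 = hi)),
    mk(c(CD45 = hi, CD56 = dim_v, CD16 = hi)),
    mk(c(CD45 = hi, CD19 = hi, CD20 = hi, IgM = hi, CD38 = hi)))
  f <- event_frame(rows, panel, transformed = TRUE)
  spec <- default_gating_spec()
  thr <- manual_thresholds(unique(unlist(lapply(resolve_predicates(spec),
                                                names))))
  mem <- assign_populations(f, spec, thr)

  expect_true(all(mem[1, c("CD45+", "CD3+ T", "CD4 T", "naive CD4")]))
  expect_false(any(mem[1, c("CD8 T", "CD19+CD20+ B", "CD56dim CD16+ NK")]))
  expect_true(mem[2, "CD56dim CD16+ NK"])
  expect_false(mem[2, "CD56bright CD16+ NK"])
  expect_true(mem[3, "transitional B"])  # IgM and CD38 above t2
  expect_false(mem[3, "naive B"])        # IgD negative
  expect_true(mem[3, "CD19+CD20+ B"])    # parent membership overlaps
})

test_that("cell-cycle classification partitions events", {
  panel <- default_panel()
  ki <- panel$channel_id[match("ki67", panel$marker)]
  idu <- panel$channel_id[match("IdU", panel$marker)]
  x <- matrix(0.1, 4, nrow(panel), dimnames = list(NULL, panel$channel_id))
  x[2, ki] <- 4                    # G1
  x[3, c(ki, idu)] <- 4            # S
  x[4, idu] <- 4                   # ki67- IdU+
  f <- event_frame(x, panel, transformed = TRUE)
  thr <- manual_thresholds(c("ki67", "IdU"))
  ph <- classify_cell_cycle(f, thr)
  expect_equal(as.character(ph), c("G0", "G1", "S", "KI67NEG_IDUPOS"))
  expect_equal(sum(table(ph)), 4)
})

test_that("the default gating spec is complete, hierarchical and serializable", {
  spec <- default_gating_spec()
  expect_gte(length(spec), 25)
  preds <- resolve_predicates(spec)
  for (d in spec) {
    if (is.na(d$parent)) next
    parent_preds <- preds[[d$parent]]
    child_preds <- preds[[d$name]]
    expect_true(all(names(parent_preds) %in% names(child_preds)),
                info = d$name)
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gating_spec(spec, path)
  back <- read_gating_spec(path)
  expect_equal(resolve_predicates(back), preds)
})

test_that("hierarchy and sibling near-partition hold on simulated data", {
  cfg <- default_config_healthy(n_donors = 1, events_per_timepoint = 6000,
                                timepoints = c(0, 1), seed = 31)
  sim <- simulate_experiment(cfg)
  res <- analyze_pooled(sim$donors[[1]]$frame, sim$donors[[1]]$manifest)
  mem <- res$memberships[[1]]
  spec <- default_gating_spec()
  for (d in spec) {
    if (is.na(d$parent)) next
    expect_false(any(mem[, d$name] & !mem[, d$parent]), info = d$name)
  }
  cd4 <- mem[, "CD4 T"]
  covered <- mem[, "naive CD4"] | mem[, "CM CD4"] | mem[, "EM CD4"]
  expect_gte(mean(covered[cd4]), 0.95)
})

test_that("predicates requiring t2 fail loudly when t2 is missing", {
  f <- one_marker_frame(c(0.1, 5), marker = "CD56")
  spec <- structure(list("x" = list(name = "x", parent = NA_character_,
                                    predicates = c(CD56 = "bright"))),
                    class = "GatingSpec")
  thr <- data.frame(marker = "CD56", t1 = 1, t2 = NA_real_,
                    provenance = "manual")
  expect_error(assign_populations(f, spec, thr), "t2")
})
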