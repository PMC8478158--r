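test_that("the code book has 20 distinct 3-of-6 keys", {
  keys <- default_barcode_keys()
  expect_equal(nrow(keys), 20)
  expect_true(all(rowSums(keys) == 3))
  expect_equal(anyDuplicated(apply(keys, 1, paste, collapse = "")), 0)
  expect_error(barcode_scheme(keys = rbind(keys, keys[1, ])), "distinct")
  bad <- keys; bad[1, ] <- c(1, 1, 1, 1, 0, 0)
  expect_error(barcode_scheme(keys = bad), "3 of 6")
})

test_that("top-3 separation rule assigns keys and rejects doublet patterns", {
  f <- pinned_barcode_frame(rbind(
    c(0.9, 0.85, 0.95, 0.02, 0.05, 0.01),   # key {1,2,3} = BC01
    c(0.9, 0.9, 0.9, 0.9, 0.02, 0.02)))     # four high channels
  res <- debarcode(f, barcode_scheme())
  n <- nrow(f$exprs)
  expect_equal(res$assignment[n - 1], "BC01")
  expect_equal(res$separation[n - 1], 0.80, tolerance = 1e-9)
  expect_equal(res$separation[n], 0, tolerance = 1e-9)
  expect_equal(res$assignment[n], "UNASSIGNED")
  expect_equal(sum(res$yield_table$n_events), n)
})

test_that("assignments are invariant to Pd channel order", {
  d <- {
    cfg <- default_config_healthy(n_donors = 1,
                                  events_per_timepoint = 800, seed = 3)
    simulate_experiment(cfg)$donors[[1]]
  }
  tf <- arcsinh_transform(d$frame)
  res1 <- debarcode(tf, barcode_scheme())
  perm <- sample(ncol(tf$exprs))
  tf2 <- tf
  tf2$exprs <- tf$exprs[, perm]
  tf2$panel <- tf$panel[perm, ]
  res2 <- debarcode(tf2, barcode_scheme())
  expect_identical(res1$assignment, res2$assignment)
})

test_that("raising the separation cutoff never increases assignments", {
  cfg <- default_config_healthy(n_donors = 1, events_per_timepoint = 800,
                                seed = 5)
  tf <- arcsinh_transform(simulate_experiment(cfg)$donors[[1]]$frame)
  counts <- vapply(c(0, 0.15, 0.3, 0.5, 0.8), function(cut) {
    sum(debarcode(tf, barcode_scheme(separation_cutoff = cut))$assignment !=
          "UNASSIGNED")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split_by_sample conserves events and validates the manifest", {
  cfg <- default_config_healthy(n_donors = 1, events_per_timepoint = 600,
                                seed = 9)
  d <- simulate_experiment(cfg)$donors[[1]]
  tf <- arcsinh_transform(d$frame)
  used <- unname(cfg$timepoint_labels)
  scheme <- barcode_scheme(default_barcode_keys()[used, ])
  res <- debarcode(tf, scheme)
  frames <- split_by_sample(tf, res, d$manifest)
  n_assigned <- sum(vapply(frames, function(f) nrow(f$exprs), numeric(1)))
  expect_equal(n_assigned + sum(res$assignment == "UNASSIGNED"),
               nrow(tf$exprs))
  expect_setequal(names(frames), used)
  f1 <- frames[[cfg$timepoint_labels[["4"]]]]
  expect_equal(f1$meta$timepoint_h, 4)
  expect_equal(f1$meta$condition, "IR_2Gy")

  expect_error(split_by_sample(tf, res, d$manifest[1:2, ]),
               "manifest error")
})

test_that("degenerate constant Pd channels raise a configuration error", {
  f <- pinned_barcode_frame(NULL)
  f$exprs[, 2] <- 0.5
  expect_error(debarcode(f), "configuration error")
})

test_that("code book CSV roundtrips", {
  path <- withr::local_tempfile(fileext = ".csv")
  keys <- default_barcode_keys()
  write_codebook(keys, path)
  back <- read_codebook(path)
  expect_equal(unname(back), unname(keys))
  expect_identical(rownames(back), rownames(keys))
})
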