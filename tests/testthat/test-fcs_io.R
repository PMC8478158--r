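test_that("write/read roundtrip preserves shape, channel order and values", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(0:80, 1)
    f <- random_frame(n)
    path <- withr::local_tempfile(fileext = ".fcs")
    write_fcs(f, path)
    g <- read_fcs(path, panel = default_panel())
    expect_equal(dim(g$exprs), dim(f$exprs))
    expect_identical(colnames(g$exprs), colnames(f$exprs))
    if (n > 0)
      expect_lt(max(abs(g$exprs - f$exprs) / pmax(abs(f$exprs), 1)), 1e-6)
  }
})

test_that("float values written with DATATYPE F are read back exactly", {
  panel <- default_panel()[1, , drop = FALSE]
  f <- event_frame(matrix(c(1, 2, 3), ncol = 1), panel)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(f, path)
  g <- read_fcs(path)
  expect_equal(as.vector(g$exprs), c(1, 2, 3))
  expect_false(g$transformed)
})

test_that("empty frames roundtrip and non-finite values are rejected", {
  panel <- default_panel()
  f0 <- event_frame(matrix(numeric(0), 0, nrow(panel)), panel)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(f0, path)
  expect_equal(nrow(read_fcs(path)$exprs), 0)

  bad <- random_frame(5)
  bad$exprs[2, 3] <- NaN
  expect_error(write_fcs(bad, withr::local_tempfile()), "non-finite")
})

test_that("truncated DATA segments raise a truncation error", {
  f <- random_frame(50)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(f, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(bytes[1:(length(bytes) - 400)], path)
  expect_error(read_fcs(path), "truncation")
})

test_that("malformed headers raise format errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".fcs")
  writeBin(charToRaw(paste0("FCS9.9", strrep(" ", 100))), path)
  expect_error(read_fcs(path), "format error.*FCS version")
})

test_that("integer data with PnR masking is read", {
  # hand-built FCS 3.1, $DATATYPE I, 16-bit, $PnR 1024 (mask to 10 bits)
  path <- withr::local_tempfile(fileext = ".fcs")
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0", "$BEGINSTEXT", "0",
          "$ENDSTEXT", "0", "$BYTEORD", "1,2,3,4", "$DATATYPE", "I",
          "$MODE", "L", "$NEXTDATA", "0", "$PAR", "2", "$TOT", "3",
          "$P1B", "16", "$P1E", "0,0", "$P1N", "ChA", "$P1R", "1024",
          "$P2B", "16", "$P2E", "0,0", "$P2N", "ChB", "$P2R", "1024")
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_start <- 256
  data_start <- text_start + nchar(text)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_start,
                    text_start + nchar(text) - 1, data_start,
                    data_start + 12 - 1, 0, 0)
  con <- file(path, "wb")
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_start - nchar(header)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # values 5, 1023, and 1024 + 7 (masked to 7)
  writeBin(as.integer(c(5, 10, 1023, 2000, 1024 + 7, 1)), con, size = 2,
           endian = "little")
  close(con)
  g <- read_fcs(path)
  expect_equal(g$exprs[, "ChA"], c(5, 1023, 7))
  expect_equal(g$exprs[, "ChB"], c(10, 2000 %% 1024, 1))
})

test_that("panel validation reports missing roles and ignores column order", {
  f <- random_frame(20)
  expect_true(validate_panel(f, c("viability", "dna"))$pass)
  expect_true(validate_panel(f, character(0))$pass)

  perm <- sample(ncol(f$exprs))
  g <- event_frame(f$exprs[, perm], f$panel[perm, ], transformed = FALSE)
  expect_equal(validate_panel(g, c("viability", "dna"))$pass,
               validate_panel(f, c("viability", "dna"))$pass)

  noir <- f$panel$role != "dna"
  h <- event_frame(f$exprs[, noir], f$panel[noir, ])
  rep <- validate_panel(h, c("dna"))
  expect_false(rep$pass)
  expect_identical(rep$missing_roles, "dna")
})

test_that("unmatched channels are retained with role other", {
  panel <- default_panel()[1:3, ]
  f <- event_frame(matrix(1:6, 2, 3), panel)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(f, path)
  g <- read_fcs(path, panel = panel[1:2, ])
  expect_identical(g$panel$role, c(panel$role[1:2], "other"))
  expect_equal(ncol(g$exprs), 3)
})
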