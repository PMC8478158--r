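# FCS 3.0/3.1 event-file IO.
#
# Reader supports $DATATYPE F (32-bit float) and I (16/32-bit unsigned with
# $PnR bit masking), list mode, both byte orders, offsets taken from the
# header or from $BEGINDATA/$ENDDATA when the header slots are zero.
# Writer always emits FCS 3.1, $DATATYPE F, little-endian ($BYTEORD
# 1,2,3,4), $PnN = channel_id and $PnS = marker. Channel identity is by
# $PnN; $PnS is display only.

FCS_DELIM <- "/"

#' Write an EventFrame to an FCS 3.1 file
#'
#' @param frame EventFrame with finite intensities.
#' @param path Output file path.
#' @return `path`, invisibly. `read_fcs(write_fcs(f))` reproduces the
#'   intensity matrix to float32 precision.
#' @export
write_fcs <- function(frame, path) {
  stopifnot(inherits(frame, "EventFrame"))
  x <- frame$exprs
  if (nrow(x) > 0 && any(!is.finite(x)))
    stop("validation error: intensities contain non-finite values")
  npar <- ncol(x)
  tot <- nrow(x)
  rng <- function(j) {
    if (tot == 0) return(262144)
    max(262144, 2 ^ ceiling(log2(max(x[, j], 1) + 1)))
  }
  # twelve-character placeholders keep the TEXT length fixed when the
  # actual data offsets are substituted below
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "@BEGINDATA@@", "$ENDDATA", "@@ENDDATA@@@",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(npar), "$TOT", as.character(tot))
  for (j in seq_len(npar)) {
    kw <- c(kw,
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dN", j), frame$panel$channel_id[j],
            sprintf("$P%dR", j), format(rng(j), scientific = FALSE),
            sprintf("$P%dS", j), frame$panel$marker[j])
  }
  text <- paste0(FCS_DELIM, paste(kw, collapse = FCS_DELIM), FCS_DELIM)
  text_start <- 256L
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  nbytes <- 4L * npar * tot
  data_end <- if (nbytes > 0) data_start + nbytes - 1L else 0L
  text <- sub("@BEGINDATA@@", sprintf("%012d", data_start), text,
              fixed = TRUE)
  text <- sub("@@ENDDATA@@@", sprintf("%012d", if (nbytes > 0) data_end
                                      else 0), text, fixed = TRUE)
  off <- function(v) sprintf("%8d", v)
  header <- paste0("FCS3.1    ",
                   off(text_start), off(text_end),
                   if (data_end > 0 && data_end <= 99999999)
                     paste0(off(data_start), off(data_end))
                   else paste0(off(0), off(0)),
                   off(0), off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_start - nchar(header, type = "bytes")), con,
            eos = NULL)
  writeChar(text, con, eos = NULL)
  if (tot > 0)
    writeBin(as.vector(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  s <- rawToChar(raw_text)
  delim <- substr(s, 1, 1)
  body <- substr(s, 2, nchar(s))
  # trailing delimiter closes the last value
  toks <- strsplit(body, delim, fixed = TRUE)[[1]]
  # merge empty tokens arising from escaped (doubled) delimiters
  if (any(toks == "") && length(toks) %% 2 != 0) {
    out <- character(0)
    i <- 1
    while (i <= length(toks)) {
      t <- toks[i]
      while (i < length(toks) && toks[i + 1] == "") {
        t <- paste0(t, delim, if (i + 2 <= length(toks)) toks[i + 2] else "")
        i <- i + 2
      }
      out <- c(out, t)
      i <- i + 1
    }
    toks <- out
  }
  if (length(toks) %% 2 != 0)
    stop("format error: FCS TEXT segment has an unpaired keyword near '",
         utils::tail(toks, 1), "'")
  kw <- toks[seq(2, length(toks), by = 2)]
  names(kw) <- toupper(trimws(toks[seq(1, length(toks), by = 2)]))
  kw
}

fcs_keyword <- function(kw, name, required = TRUE) {
  i <- match(toupper(name), names(kw))
  if (is.na(i)) {
    if (required)
      stop("format error: missing required FCS keyword ", name)
    return(NULL)
  }
  unname(kw[[i]])
}

#' Read an FCS 3.0/3.1 file
#'
#' @param path FCS file path.
#' @param panel Optional panel data.frame; `$PnN` short names are matched
#'   case-insensitively against `panel$channel_id`. Unmatched channels are
#'   retained with role `"other"`.
#' @param meta Optional acquisition metadata to attach.
#' @return An [event_frame()] with raw (untransformed) intensities.
#' @export
read_fcs <- function(path, panel = NULL, meta = acquisition_meta()) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 58)
    stop("format error: file too short for an FCS header")
  version <- rawToChar(bytes[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("format error: unsupported FCS version '", version, "'")
  hdr_off <- function(i) {
    s <- trimws(rawToChar(bytes[(11 + 8 * (i - 1)):(10 + 8 * i)]))
    if (s == "") return(0)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop("format error: non-numeric header offset field ", i, " ('", s, "')")
    v
  }
  text_start <- hdr_off(1); text_end <- hdr_off(2)
  if (text_start <= 0 || text_end <= text_start ||
      text_end > length(bytes))
    stop("format error: invalid TEXT segment offsets in header")
  kw <- parse_fcs_text(bytes[(text_start + 1):(text_end + 1)])

  nd <- fcs_keyword(kw, "$NEXTDATA", required = FALSE)
  if (!is.null(nd) && as.numeric(nd) > 0)
    warning("multi-dataset FCS file; reading the first dataset only")
  mode <- fcs_keyword(kw, "$MODE")
  if (toupper(mode) != "L")
    stop("format error: unsupported $MODE '", mode, "' (list mode required)")
  dtype <- toupper(fcs_keyword(kw, "$DATATYPE"))
  if (!dtype %in% c("F", "I"))
    stop("format error: unsupported $DATATYPE '", dtype, "'")
  byteord <- fcs_keyword(kw, "$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("format error: unsupported $BYTEORD '", byteord, "'"))
  npar <- as.integer(fcs_keyword(kw, "$PAR"))
  tot <- as.integer(fcs_keyword(kw, "$TOT"))

  pnb <- vapply(seq_len(npar), function(j)
    as.integer(fcs_keyword(kw, sprintf("$P%dB", j))), integer(1))
  if (dtype == "F" && any(pnb != 32))
    stop("format error: $DATATYPE F requires $PnB = 32 (found ",
         paste(unique(pnb), collapse = ","), ")")
  if (dtype == "I" && !all(pnb %in% c(16L, 32L)))
    stop("format error: $DATATYPE I supports $PnB 16 or 32 only")
  if (dtype == "I" && length(unique(pnb)) != 1)
    stop("format error: mixed $PnB widths are not supported")
  pnn <- vapply(seq_len(npar), function(j)
    fcs_keyword(kw, sprintf("$P%dN", j)), character(1))
  pns <- vapply(seq_len(npar), function(j) {
    v <- fcs_keyword(kw, sprintf("$P%dS", j), required = FALSE)
    if (is.null(v)) "" else v
  }, character(1))

  if (tot == 0) {
    mat <- matrix(numeric(0), nrow = 0, ncol = npar)
  } else {
    data_start <- hdr_off(3); data_end <- hdr_off(4)
    if (data_start == 0) {
      data_start <- as.numeric(fcs_keyword(kw, "$BEGINDATA"))
      data_end <- as.numeric(fcs_keyword(kw, "$ENDDATA"))
    }
    bwidth <- pnb[1] / 8
    nbytes <- bwidth * npar * tot
    if (data_start + nbytes - 1 > length(bytes))
      stop("truncation error: $TOT = ", tot, " events require ", nbytes,
           " data bytes but the file ends early")
    seg <- bytes[(data_start + 1):(data_start + nbytes)]
    if (dtype == "F") {
      v <- readBin(seg, "numeric", n = npar * tot, size = 4, endian = endian)
      mat <- matrix(v, ncol = npar, byrow = TRUE)
    } else {
      v <- readBin(seg, "integer", n = npar * tot, size = bwidth,
                   signed = (bwidth == 4), endian = endian)
      v <- as.numeric(v)
      if (bwidth == 4) v[v < 0] <- v[v < 0] + 2^32
      pnr <- vapply(seq_len(npar), function(j) {
        r <- fcs_keyword(kw, sprintf("$P%dR", j), required = FALSE)
        if (is.null(r)) Inf else as.numeric(r)
      }, numeric(1))
      mask_bits <- 2 ^ ceiling(log2(pnr))
      mat <- matrix(v, ncol = npar, byrow = TRUE)
      for (j in seq_len(npar))
        if (is.finite(mask_bits[j])) mat[, j] <- mat[, j] %% mask_bits[j]
    }
  }

  out_panel <- data.frame(channel_id = pnn, metal = NA_character_,
                          marker = ifelse(pns == "", pnn, pns),
                          role = "other", stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    validate_panel_df(panel)
    idx <- match(tolower(pnn), tolower(panel$channel_id))
    hit <- !is.na(idx)
    out_panel$metal[hit] <- panel$metal[idx[hit]]
    out_panel$marker[hit] <- panel$marker[idx[hit]]
    out_panel$role[hit] <- panel$role[idx[hit]]
  }
  colnames(mat) <- pnn
  event_frame(mat, out_panel, meta = meta, transformed = FALSE)
}

#' Validate a panel against required roles
#'
#' Report-based check that an EventFrame's panel carries every role the
#' downstream pipeline needs (for preprocessing: `viability` and `dna`).
#'
#' @param frame EventFrame.
#' @param required_roles Character vector of roles.
#' @return A list with `pass` (logical), `missing_roles` and a per-role
#'   channel count table.
#' @export
validate_panel <- function(frame, required_roles = character(0)) {
  have <- table(factor(frame$panel$role, levels = panel_roles))
  missing <- required_roles[!(required_roles %in% frame$panel$role)]
  list(pass = length(missing) == 0, missing_roles = missing,
       role_counts = have)
}
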