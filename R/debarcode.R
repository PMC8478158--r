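# 20-plex palladium barcode deconvolution (3-of-6 doublet-filtering
# scheme): per event, the three highest rescaled Pd channels define the
# candidate key and the gap between the 3rd and 4th highest values is the
# separation used to reject doublets and low-confidence events.

PD_CHANNELS <- paste0("Pd", c(102, 104, 105, 106, 108, 110), "Di")

#' The 20-key 3-of-6 palladium code book
#'
#' All C(6,3) = 20 binary patterns over the six Pd masses (102, 104, 105,
#' 106, 108, 110), in deterministic lexicographic order, labelled
#' `BC01` ... `BC20`.
#'
#' @return A 20 x 6 0/1 matrix; rownames are sample labels, colnames the
#'   Pd channel ids.
#' @export
default_barcode_keys <- function() {
  combs <- utils::combn(6, 3)
  keys <- t(apply(combs, 2, function(i) as.integer(1:6 %in% i)))
  rownames(keys) <- sprintf("BC%02d", seq_len(nrow(keys)))
  colnames(keys) <- PD_CHANNELS
  keys
}

#' Construct a barcode scheme
#'
#' @param keys 0/1 key matrix (samples x 6 Pd channels) with rownames as
#'   sample labels; every row must have exactly three bits set and rows
#'   must be distinct. Default: the full 20-key code book.
#' @param pd_channels The six Pd channel ids, in key-column order.
#' @param separation_cutoff Events whose separation (3rd minus 4th highest
#'   rescaled Pd value) falls below this are left unassigned. Default 0.3.
#' @return A `BarcodeScheme` list.
#' @export
barcode_scheme <- function(keys = default_barcode_keys(),
                           pd_channels = PD_CHANNELS,
                           separation_cutoff = 0.3) {
  keys <- as.matrix(keys)
  if (ncol(keys) != 6 || length(pd_channels) != 6)
    stop("the scheme requires exactly six Pd channels")
  if (any(rowSums(keys) != 3))
    stop("every barcode key must have exactly 3 of 6 bits set")
  pat <- apply(keys, 1, paste, collapse = "")
  if (anyDuplicated(pat)) stop("barcode keys must be distinct")
  if (separation_cutoff < 0 || separation_cutoff > 1)
    stop("separation_cutoff must lie in [0, 1]")
  structure(list(keys = keys, pd_channels = pd_channels,
                 separation_cutoff = separation_cutoff),
            class = "BarcodeScheme")
}

# j-th largest value of each row of a small-column matrix, vectorised.
row_order_stats <- function(m, k_max) {
  out <- matrix(NA_real_, nrow(m), k_max)
  which_out <- matrix(NA_integer_, nrow(m), k_max)
  work <- m
  for (k in seq_len(k_max)) {
    j <- max.col(work, ties.method = "first")
    idx <- cbind(seq_len(nrow(m)), j)
    out[, k] <- work[idx]
    which_out[, k] <- j
    work[idx] <- -Inf
  }
  list(values = out, cols = which_out)
}

#' Deconvolve a pooled barcoded sample
#'
#' Each Pd channel is rescaled to `[0, 1]` by its robust (1st-99th
#' percentile) range over the pooled file; per event the three largest
#' rescaled channels name the candidate key. Events are left `UNASSIGNED`
#' when the separation is below the cutoff or the candidate bit pattern is
#' not in the code book.
#'
#' @param frame Transformed EventFrame containing all six Pd channels.
#' @param scheme [barcode_scheme()].
#' @return A `DebarcodeResult` list: `assignment` (per-event label or
#'   `"UNASSIGNED"`), `separation` (per-event), and `yield_table`.
#' @export
debarcode <- function(frame, scheme = barcode_scheme()) {
  stopifnot(inherits(frame, "EventFrame"), inherits(scheme, "BarcodeScheme"))
  if (!frame$transformed)
    stop("debarcode expects arcsinh-transformed intensities")
  j <- match(tolower(scheme$pd_channels), tolower(frame$panel$channel_id))
  if (anyNA(j))
    stop("panel error: missing Pd channel(s): ",
         paste(scheme$pd_channels[is.na(j)], collapse = ", "))
  x <- frame$exprs[, j, drop = FALSE]
  n <- nrow(x)
  if (n == 0)
    return(structure(list(assignment = character(0), separation = numeric(0),
                          yield_table = yield_table(character(0), scheme)),
                     class = "DebarcodeResult"))
  lo <- apply(x, 2, stats::quantile, probs = 0.01, names = FALSE)
  hi <- apply(x, 2, stats::quantile, probs = 0.99, names = FALSE)
  if (any(hi - lo < .Machine$double.eps^0.5))
    stop("configuration error: degenerate (constant) Pd channel range")
  r <- sweep(sweep(x, 2, lo, "-"), 2, hi - lo, "/")
  r[r < 0] <- 0; r[r > 1] <- 1
  os <- row_order_stats(r, 4)
  separation <- os$values[, 3] - os$values[, 4]
  pat <- matrix(0L, n, 6)
  pat[cbind(seq_len(n), os$cols[, 1])] <- 1L
  pat[cbind(seq_len(n), os$cols[, 2])] <- 1L
  pat[cbind(seq_len(n), os$cols[, 3])] <- 1L
  pat_str <- paste0(pat[, 1], pat[, 2], pat[, 3], pat[, 4], pat[, 5], pat[, 6])
  key_str <- apply(scheme$keys, 1, paste, collapse = "")
  lab <- rownames(scheme$keys)[match(pat_str, key_str)]
  lab[is.na(lab)] <- "UNASSIGNED"
  lab[separation < scheme$separation_cutoff] <- "UNASSIGNED"
  structure(list(assignment = lab, separation = separation,
                 yield_table = yield_table(lab, scheme)),
            class = "DebarcodeResult")
}

yield_table <- function(assignment, scheme) {
  lev <- c(rownames(scheme$keys), "UNASSIGNED")
  tab <- table(factor(assignment, levels = lev))
  data.frame(sample_label = names(tab), n_events = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Split a pooled frame into per-sample EventFrames
#'
#' @param frame The pooled EventFrame that was debarcoded.
#' @param result [debarcode()] result for the same frame.
#' @param manifest data.frame with columns `sample_label`, `donor_id`,
#'   `condition`, `timepoint_h`, and optionally `cohort`, `il2`; must
#'   cover every assigned label. `UNASSIGNED` events are dropped.
#' @return Named list of EventFrames (one per label present), each with
#'   acquisition metadata attached.
#' @export
split_by_sample <- function(frame, result, manifest) {
  stopifnot(length(result$assignment) == n_events(frame))
  labs <- setdiff(unique(result$assignment), "UNASSIGNED")
  missing <- setdiff(labs, manifest$sample_label)
  if (length(missing))
    stop("manifest error: label(s) not in manifest: ",
         paste(missing, collapse = ", "))
  if (length(labs) == 0) {
    warning("no events were assigned to any sample")
    return(list())
  }
  out <- lapply(labs, function(l) {
    f <- subset_events(frame, result$assignment == l)
    m <- manifest[manifest$sample_label == l, , drop = FALSE][1, ]
    f$meta <- acquisition_meta(
      donor_id = as.character(m$donor_id), condition = as.character(m$condition),
      timepoint_h = as.numeric(m$timepoint_h),
      cohort = if ("cohort" %in% names(m)) as.character(m$cohort) else "control",
      il2 = if ("il2" %in% names(m)) isTRUE(as.logical(m$il2)) else TRUE)
    f
  })
  names(out) <- labs
  out[order(names(out))]
}

#' Read / write a barcode code book as CSV
#'
#' CSV layout: `sample_label` column plus one 0/1 column per Pd channel.
#' @param path File path.
#' @rdname codebook_io
#' @return `read_codebook`: a key matrix suitable for [barcode_scheme()].
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  keys <- as.matrix(df[, setdiff(names(df), "sample_label"), drop = FALSE])
  rownames(keys) <- df$sample_label
  storage.mode(keys) <- "integer"
  keys
}

#' @param keys Key matrix (see [default_barcode_keys()]).
#' @rdname codebook_io
#' @export
write_codebook <- function(keys, path) {
  df <- data.frame(sample_label = rownames(keys), keys, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
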