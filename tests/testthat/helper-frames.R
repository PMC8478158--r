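# Shared fixtures, built in code.

random_frame <- function(n = 50, panel = default_panel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rexp(n * nrow(panel), rate = 0.01), nrow = n,
              ncol = nrow(panel))
  colnames(x) <- panel$channel_id
  event_frame(x, panel)
}

# A minimal one-marker transformed frame for threshold tests.
one_marker_frame <- function(values, marker = "CD3") {
  panel <- data.frame(channel_id = "X1", metal = "000Xx", marker = marker,
                      role = "surface", stringsAsFactors = FALSE)
  event_frame(matrix(values, ncol = 1), panel, transformed = TRUE)
}

# Transformed barcode-only frame whose per-channel 1st/99th percentiles
# are pinned to 0 and 1, so rescaling is the identity on [0, 1].
pinned_barcode_frame <- function(extra_rows) {
  panel <- default_panel()
  panel <- panel[panel$role == "barcode", ]
  base <- rbind(matrix(0, 300, 6), matrix(1, 300, 6))
  x <- rbind(base, extra_rows)
  colnames(x) <- panel$channel_id
  event_frame(x, panel, transformed = TRUE)
}
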