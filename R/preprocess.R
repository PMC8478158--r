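# arcsinh transformation, iridium singlet discrimination and cisplatin
# viability gating.

#' arcsinh transform an EventFrame
#'
#' Applies x -> asinh(x / cofactor) to the selected channel roles. The
#' cofactor default of 5 is the mass-cytometry convention. The transform
#' may be applied at most once per frame.
#'
#' @param frame Raw EventFrame.
#' @param cofactor Positive real, default 5.
#' @param roles Channel roles to transform; by default every measured
#'   channel, including the barcode channels (same cofactor).
#' @return Transformed EventFrame (`transformed = TRUE`).
#' @export
arcsinh_transform <- function(frame, cofactor = 5,
                              roles = c("surface", "intranuclear_ddr",
                                        "cellcycle", "barcode", "viability",
                                        "dna", "other")) {
  stopifnot(inherits(frame, "EventFrame"))
  if (cofactor <= 0) stop("cofactor must be > 0")
  if (frame$transformed)
    stop("state error: frame is already arcsinh transformed")
  j <- channels_for_role(frame, roles)
  frame$exprs[, j] <- asinh(frame$exprs[, j, drop = FALSE] / cofactor)
  frame$transformed <- TRUE
  frame$cofactor <- cofactor
  frame
}

#' Estimate preprocessing thresholds
#'
#' Singlet band: the main mode of the transformed Ir191 DNA channel
#' plus/minus `k_mad` times its MAD, applied jointly to Ir191 and Ir193.
#' Viability: a density-valley split of the transformed cisplatin channel
#' (live cells are cisplatin-low).
#'
#' @param frame Transformed EventFrame with `dna` and `viability` channels.
#' @param k_mad Width of the DNA band in MADs (default 3).
#' @return List with `dna_low`, `dna_high`, `viability_max`.
#' @export
estimate_preprocess_thresholds <- function(frame, k_mad = 3) {
  stopifnot(frame$transformed)
  jd <- channels_for_role(frame, "dna")
  if (length(jd) < 1) stop("panel error: no dna channels in panel")
  x <- frame$exprs[, jd[1]]
  d <- stats::density(x, n = 512)
  mode <- d$x[which.max(d$y)]
  s <- stats::mad(x)
  jv <- channels_for_role(frame, "viability")
  if (length(jv) < 1) stop("panel error: no viability channel in panel")
  v <- frame$exprs[, jv[1]]
  viab <- density_valley(v)
  if (is.na(viab)) viab <- stats::quantile(v, 0.95, names = FALSE)
  list(dna_low = mode - k_mad * s, dna_high = mode + k_mad * s,
       viability_max = viab)
}

# Deepest KDE minimum between the two dominant well-separated modes; NA
# when effectively unimodal. Kernel wiggle can split one population into
# adjacent local maxima, so the secondary mode must lie at least
# `min_sep_frac` of the grid range away from the primary one.
density_valley <- function(x, bw = "nrd0", n_grid = 512,
                           min_sep_frac = 0.10) {
  if (length(unique(x)) < 2) return(NA_real_)
  d <- stats::density(x, bw = bw, n = n_grid)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  if (length(locmax) < 2) return(NA_real_)
  primary <- locmax[which.max(y[locmax])]
  min_sep <- min_sep_frac * (max(d$x) - min(d$x))
  cand <- locmax[abs(d$x[locmax] - d$x[primary]) >= min_sep]
  if (length(cand) == 0) return(NA_real_)
  secondary <- cand[which.max(y[cand])]
  lo <- min(primary, secondary); hi <- max(primary, secondary)
  between <- seq(lo, hi)
  d$x[between[which.min(y[between])]]
}

#' Gate singlet events on the iridium DNA channels
#'
#' Retains events whose Ir191 and Ir193 transformed intensities both lie
#' in `[dna_low, dna_high]`; doublets carry roughly twice the singlet DNA
#' signal and fall above the band. Event order is preserved; the filter is
#' idempotent and commutes with [gate_viable()].
#'
#' @param frame Transformed EventFrame.
#' @param thr Thresholds from [estimate_preprocess_thresholds()] (or a
#'   manual override list with `dna_low < dna_high`).
#' @return Filtered EventFrame.
#' @export
gate_singlets <- function(frame, thr) {
  stopifnot(frame$transformed)
  if (!(thr$dna_low < thr$dna_high)) stop("dna_low must be < dna_high")
  jd <- channels_for_role(frame, "dna")
  if (length(jd) < 2) stop("panel error: both Ir DNA channels are required")
  if (n_events(frame) == 0) return(frame)
  x <- frame$exprs[, jd[1:2], drop = FALSE]
  keep <- x[, 1] >= thr$dna_low & x[, 1] <= thr$dna_high &
    x[, 2] >= thr$dna_low & x[, 2] <= thr$dna_high
  subset_events(frame, keep)
}

#' Gate viable (cisplatin-low) events
#'
#' @param frame Transformed EventFrame.
#' @param thr Threshold list with `viability_max` (transformed scale).
#' @return Filtered EventFrame; warns when no event survives.
#' @export
gate_viable <- function(frame, thr) {
  stopifnot(frame$transformed)
  jv <- channels_for_role(frame, "viability")
  if (length(jv) < 1) stop("panel error: viability channel is required")
  if (n_events(frame) == 0) return(frame)
  keep <- frame$exprs[, jv[1]] <= thr$viability_max
  if (!any(keep)) warning("all events fail the viability gate")
  subset_events(frame, keep)
}
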