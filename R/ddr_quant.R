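# Geometric-MFI fold-induction kinetics, survival composition and
# cell-cycle stratified variants.
#
# Geometric means are computed on the raw (untransformed) ion-count scale
# - the convention the source MFIs follow - over strictly positive values
# only; zero counts are excluded and counted. Fold induction is per donor:
# each time point is normalised to the same donor's untreated sample.

DDR_MARKERS <- c("gH2AX", "pATM", "pCHK2", "p53")

#' Geometric mean intensity
#'
#' Geometric mean of the strictly positive values; returns `NA` (flagged
#' missing, never zero) when fewer than `min_events` positive values are
#' available, because geometric means of tiny zero-inflated samples are
#' unstable.
#'
#' @param values Raw-scale intensities.
#' @param min_events Minimum number of positive values (default 30).
#' @return Positive scalar or `NA_real_`.
#' @export
#' @examples
#' geometric_mfi(c(2, 8), min_events = 1)   # 4
#' geometric_mfi(c(0, 2, 8), min_events = 1) # zeros excluded -> 4
geometric_mfi <- function(values, min_events = 30) {
  pos <- values[values > 0]
  if (length(pos) < min_events) return(NA_real_)
  exp(mean(log(pos)))
}

# Raw-scale values for a marker, inverting the arcsinh transform when the
# frame has been transformed (exact up to floating point).
raw_marker_values <- function(frame, marker) {
  x <- marker_values(frame, marker)
  if (frame$transformed) {
    cf <- frame$cofactor
    if (is.null(cf)) stop("transformed frame lacks a stored cofactor")
    x <- sinh(x) * cf
  }
  x
}

# Per-population geometric MFI of the given markers for one frame.
geo_mfi_by_population <- function(frame, membership, markers = DDR_MARKERS,
                                  min_events = 30) {
  rows <- list()
  mem <- membership
  n_member <- colSums(mem)
  for (mk in markers) {
    v <- raw_marker_values(frame, mk)
    pos <- v > 0
    logv <- ifelse(pos, log(pmax(v, .Machine$double.xmin)), 0)
    n_pos <- as.vector(crossprod(mem, as.numeric(pos)))
    sum_log <- as.vector(crossprod(mem, logv * pos))
    geo <- ifelse(n_pos >= min_events, exp(sum_log / n_pos), NA_real_)
    rows[[mk]] <- data.frame(
      population = colnames(mem), marker = mk,
      n_events = as.integer(n_member), n_pos = as.integer(n_pos),
      geo_mfi = geo, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

sample_key <- function(frame) {
  m <- frame$meta
  data.frame(donor = m$donor_id, cohort = m$cohort,
             condition = m$condition, timepoint_h = m$timepoint_h,
             stringsAsFactors = FALSE)
}

#' Fold-induction kinetics table
#'
#' One row per (donor, population, marker, time point): the raw-scale
#' geometric MFI and its fold induction relative to the same donor's
#' untreated (t = 0) sample. Rows whose positive-event count falls below
#' `min_events` carry `NA` with `flag_low_n = TRUE`; missingness
#' propagates into the fold.
#'
#' @param frames List of EventFrames (all time points, one or more
#'   donors), each carrying acquisition metadata.
#' @param memberships Parallel list of membership matrices from
#'   [assign_populations()].
#' @param markers DDR marker names (default gH2AX, pATM, pCHK2, p53).
#' @param min_events Minimum positive events per cell (default 30).
#' @return A `KineticsTable` data.frame.
#' @export
fold_induction_table <- function(frames, memberships,
                                 markers = DDR_MARKERS, min_events = 30) {
  stopifnot(length(frames) == length(memberships))
  per_frame <- lapply(seq_along(frames), function(i) {
    cbind(sample_key(frames[[i]]),
          geo_mfi_by_population(frames[[i]], memberships[[i]], markers,
                                min_events),
          row.names = NULL)
  })
  tab <- do.call(rbind, per_frame)
  out <- list()
  for (d in unique(tab$donor)) {
    td <- tab[tab$donor == d, , drop = FALSE]
    ref <- td[td$timepoint_h == 0, , drop = FALSE]
    if (nrow(ref) == 0)
      stop("reference error: donor ", d, " has no untreated (t = 0) sample")
    key <- paste(td$population, td$marker)
    ref_geo <- ref$geo_mfi[match(key, paste(ref$population, ref$marker))]
    td$fold_induction <- ifelse(td$timepoint_h == 0,
                                ifelse(is.na(td$geo_mfi), NA_real_, 1),
                                td$geo_mfi / ref_geo)
    out[[d]] <- td
  }
  tab <- do.call(rbind, out)
  tab$flag_low_n <- is.na(tab$geo_mfi)
  rownames(tab) <- NULL
  tab
}

#' Survival composition table
#'
#' Per population and time point, the population's share of the viable
#' CD45+ lymphocytes (in percent) - the composition-shift readout used to
#' describe differential radiosensitivity. Assumes the viability gate has
#' already been applied.
#'
#' @param frames List of viable-gated EventFrames.
#' @param memberships Parallel membership matrices.
#' @param denominator Denominator population (default `"CD45+"`).
#' @return A `SurvivalTable` data.frame with `pct_of_viable_CD45`.
#' @export
survival_proportions <- function(frames, memberships,
                                 denominator = "CD45+") {
  rows <- lapply(seq_along(frames), function(i) {
    fr <- population_frequencies(memberships[[i]], denominator)
    cbind(sample_key(frames[[i]]), fr, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "pct"] <- "pct_of_viable_CD45"
  tab$flag_no_denominator <- is.na(tab$pct_of_viable_CD45)
  tab
}

#' Cell-cycle stratified fold-induction kinetics
#'
#' The [fold_induction_table()] contract computed within ki67+ and ki67-
#' strata (or the full G0/G1/S/ki67-IdU+ partition when
#' `by = "phase"`).
#'
#' @param frames,memberships As in [fold_induction_table()].
#' @param phases Parallel list of phase factors from
#'   [classify_cell_cycle()].
#' @param by `"ki67"` (default: ki67+ = G1 or S, ki67- = G0 or
#'   ki67-IdU+) or `"phase"`.
#' @param markers,min_events As in [fold_induction_table()].
#' @return KineticsTable with an extra `stratum` column.
#' @export
stratified_kinetics <- function(frames, memberships, phases,
                                by = c("ki67", "phase"),
                                markers = DDR_MARKERS, min_events = 30) {
  by <- match.arg(by)
  stopifnot(length(frames) == length(phases))
  strata <- if (by == "ki67") {
    lapply(phases, function(ph)
      list("ki67+" = ph %in% c("G1", "S"),
           "ki67-" = ph %in% c("G0", "KI67NEG_IDUPOS")))
  } else {
    lapply(phases, function(ph)
      stats::setNames(lapply(levels(ph), function(l) ph == l), levels(ph)))
  }
  stratum_names <- names(strata[[1]])
  out <- lapply(stratum_names, function(s) {
    mems <- lapply(seq_along(memberships), function(i)
      memberships[[i]] & strata[[i]][[s]])
    tab <- fold_induction_table(frames, mems, markers, min_events)
    tab$stratum <- s
    tab
  })
  do.call(rbind, out)
}
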