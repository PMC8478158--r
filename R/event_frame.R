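#' Construct an EventFrame
#'
#' The package's event-level container: an events x channels intensity
#' matrix plus channel metadata (the panel), acquisition metadata and a
#' flag recording whether the arcsinh transform has been applied.
#'
#' @param exprs Numeric matrix, events in rows, channels in columns.
#'   Column names, when present, must equal `panel$channel_id`.
#' @param panel Panel data.frame (see [default_panel()]); one row per
#'   column of `exprs`.
#' @param meta Acquisition metadata list; see [acquisition_meta()].
#' @param transformed Logical; `TRUE` once intensities are on the arcsinh
#'   scale.
#' @return An object of class `EventFrame`.
#' @export
event_frame <- function(exprs, panel, meta = acquisition_meta(),
                        transformed = FALSE) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  validate_panel_df(panel)
  if (ncol(exprs) != nrow(panel))
    stop("exprs has ", ncol(exprs), " columns but panel describes ",
         nrow(panel), " channels")
  if (!is.null(colnames(exprs)) && nrow(panel) > 0 &&
      !identical(colnames(exprs), panel$channel_id))
    stop("exprs column names disagree with panel channel_id order")
  colnames(exprs) <- panel$channel_id
  if (!transformed && nrow(exprs) > 0 && any(exprs < 0, na.rm = TRUE))
    stop("raw intensities must be non-negative")
  structure(list(exprs = exprs, panel = panel, meta = meta,
                 transformed = isTRUE(transformed)),
            class = "EventFrame")
}

#' Acquisition metadata
#'
#' @param donor_id Donor label.
#' @param condition One of `"untreated"`, `"IR_2Gy"`, `"UVC_100mJ"`.
#' @param timepoint_h Hours post exposure; one of 0, 1, 4, 8, 24. The
#'   untreated sample is the time-0 reference, so `timepoint_h == 0` iff
#'   `condition == "untreated"`.
#' @param cohort `"control"` or `"AT"` (ataxia telangiectasia).
#' @param il2 Logical, IL-2 supplemented culture.
#' @return A named list.
#' @export
acquisition_meta <- function(donor_id = NA_character_,
                             condition = NA_character_,
                             timepoint_h = NA_real_,
                             cohort = "control", il2 = TRUE) {
  if (!is.na(condition)) {
    if (!condition %in% c("untreated", "IR_2Gy", "UVC_100mJ"))
      stop("unknown condition: ", condition)
    if (!is.na(timepoint_h)) {
      if ((timepoint_h == 0) != (condition == "untreated"))
        stop("timepoint_h must be 0 iff condition is 'untreated'")
    }
  }
  if (!is.na(timepoint_h) && !timepoint_h %in% c(0, 1, 4, 8, 24))
    stop("timepoint_h must be one of 0, 1, 4, 8, 24")
  list(donor_id = donor_id, condition = condition,
       timepoint_h = timepoint_h, cohort = cohort, il2 = isTRUE(il2))
}

#' @export
print.EventFrame <- function(x, ...) {
  cat("EventFrame:", nrow(x$exprs), "events x", ncol(x$exprs), "channels",
      if (x$transformed) "(arcsinh)" else "(raw)", "\n")
  if (!is.na(x$meta$donor_id))
    cat("  donor:", x$meta$donor_id, " condition:", x$meta$condition,
        " t =", x$meta$timepoint_h, "h\n")
  invisible(x)
}

#' @export
dim.EventFrame <- function(x) dim(x$exprs)

n_events <- function(frame) nrow(frame$exprs)

#' Extract intensities for a marker
#'
#' @param frame EventFrame.
#' @param marker Marker name as listed in the panel (case-insensitive).
#' @return Numeric vector of per-event intensities.
#' @export
marker_values <- function(frame, marker) {
  frame$exprs[, marker_column(frame, marker)]
}

marker_column <- function(frame, marker) {
  i <- match(tolower(marker), tolower(frame$panel$marker))
  if (is.na(i)) stop("marker not in panel: ", marker)
  i
}

channels_for_role <- function(frame, roles) {
  which(frame$panel$role %in% roles)
}

subset_events <- function(frame, keep) {
  frame$exprs <- frame$exprs[keep, , drop = FALSE]
  frame
}
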