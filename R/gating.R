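# Threshold estimation and event classification.

#' Estimate per-marker gate thresholds
#'
#' `method = "valley"` places t1 at the deepest kernel-density minimum
#' between the two largest modes of the transformed marker distribution
#' (Silverman bandwidth, 512-point grid, hence reproducible); when the
#' distribution is unimodal it falls back to the `q` quantile. For
#' two-level markers (dim/bright, "+"/"++") t2 is the density valley
#' among events above t1 when that restricted distribution is bimodal,
#' otherwise the midpoint between t1 and the upper mode.
#'
#' @param frame Transformed EventFrame with at least 200 events.
#' @param markers Marker names to threshold.
#' @param method `"valley"` (default) or `"quantile"`.
#' @param q Fallback/quantile probability (default 0.95).
#' @param two_level Markers that additionally need t2.
#' @return A `ThresholdSet` data.frame: `marker`, `t1`, `t2` (NA when not
#'   needed), `provenance = "estimated"`.
#' @export
estimate_thresholds <- function(frame, markers,
                                method = c("valley", "quantile"), q = 0.95,
                                two_level = intersect(TWO_LEVEL_DEFAULT,
                                                      markers)) {
  method <- match.arg(method)
  stopifnot(frame$transformed)
  if (n_events(frame) < 200)
    stop("estimation error: at least 200 events are required")
  rows <- lapply(markers, function(m) {
    x <- marker_values(frame, m)
    if (length(unique(x)) < 2)
      stop("estimation error: constant channel for marker ", m)
    t1 <- if (method == "valley") density_valley(x) else NA_real_
    if (is.na(t1)) t1 <- stats::quantile(x, q, names = FALSE)
    t2 <- NA_real_
    if (m %in% two_level) {
      hi <- x[x > t1]
      t2 <- if (length(unique(hi)) >= 2) density_valley(hi) else NA_real_
      if (is.na(t2)) {
        upper_mode <- if (length(hi) >= 2) {
          d <- stats::density(hi, n = 512)
          d$x[which.max(d$y)]
        } else max(x)
        t2 <- (t1 + upper_mode) / 2
      }
      if (t2 <= t1) t2 <- t1 + .Machine$double.eps^0.5
    }
    data.frame(marker = m, t1 = t1, t2 = t2, provenance = "estimated",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

threshold_for <- function(thr, marker) {
  i <- match(tolower(marker), tolower(thr$marker))
  if (is.na(i)) stop("no threshold for marker ", marker)
  list(t1 = thr$t1[i], t2 = thr$t2[i])
}

eval_predicate <- function(x, level, t) {
  switch(level,
         neg = x < t$t1,
         low = x < t$t1,
         pos = x >= t$t1,
         dim = {
           if (is.na(t$t2)) stop("spec error: level 'dim' needs t2")
           x >= t$t1 & x < t$t2
         },
         bright = ,
         very_high = {
           if (is.na(t$t2))
             stop("spec error: level '", level, "' needs t2")
           x >= t$t2
         },
         stop("unknown gate level: ", level))
}

#' Assign events to populations
#'
#' Evaluates every population's resolved predicate conjunction against
#' the transformed intensities. Memberships overlap by construction (an
#' event is simultaneously CD3+ and naive CD4, for instance); downstream
#' statistics treat populations independently.
#'
#' @param frame Transformed EventFrame.
#' @param spec A `GatingSpec` (default [default_gating_spec()]).
#' @param thr `ThresholdSet` from [estimate_thresholds()].
#' @return Logical membership matrix, events x populations.
#' @export
assign_populations <- function(frame, spec = default_gating_spec(), thr) {
  preds <- resolve_predicates(spec)
  markers <- unique(unlist(lapply(preds, names)))
  cols <- lapply(markers, function(m) marker_values(frame, m))
  names(cols) <- markers
  ts <- lapply(markers, function(m) threshold_for(thr, m))
  names(ts) <- markers
  mem <- matrix(FALSE, n_events(frame), length(preds),
                dimnames = list(NULL, names(preds)))
  for (p in names(preds)) {
    keep <- rep(TRUE, n_events(frame))
    pr <- preds[[p]]
    for (m in names(pr))
      keep <- keep & eval_predicate(cols[[m]], pr[[m]], ts[[m]])
    mem[, p] <- keep
  }
  mem
}

#' Classify cell-cycle phase from ki67 and IdU
#'
#' Four-way partition: `S` (ki67+ IdU+), `G1` (ki67+ IdU-), `G0`
#' (ki67- IdU-) and `KI67NEG_IDUPOS` (ki67- IdU+, the transient
#' arrested fraction seen after UVC; reported separately, never merged
#' into S).
#'
#' @param frame Transformed EventFrame with ki67 and IdU channels.
#' @param thr `ThresholdSet` covering `ki67` and `IdU`.
#' @return Factor of length `nrow(frame)` with the four phase levels.
#' @export
classify_cell_cycle <- function(frame, thr) {
  ki <- marker_values(frame, "ki67")
  idu <- marker_values(frame, "IdU")
  tk <- threshold_for(thr, "ki67")
  ti <- threshold_for(thr, "IdU")
  kip <- ki >= tk$t1
  idp <- idu >= ti$t1
  phase <- ifelse(kip & idp, "S",
                  ifelse(kip, "G1",
                         ifelse(idp, "KI67NEG_IDUPOS", "G0")))
  factor(phase, levels = c("G0", "G1", "S", "KI67NEG_IDUPOS"))
}

#' Population frequencies as percent of a denominator population
#'
#' @param membership Membership matrix from [assign_populations()].
#' @param denominator Column used as the denominator (default `"CD45+"`).
#' @return data.frame `population`, `n_events`, `pct`.
#' @export
population_frequencies <- function(membership, denominator = "CD45+") {
  denom <- sum(membership[, denominator])
  counts <- colSums(membership)
  data.frame(population = colnames(membership),
             n_events = as.integer(counts),
             pct = if (denom > 0) 100 * counts / denom else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write a ThresholdSet as CSV
#' @param thr ThresholdSet data.frame.
#' @param path File path.
#' @rdname threshold_io
#' @export
write_thresholds <- function(thr, path) {
  utils::write.csv(thr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname threshold_io
#' @export
read_thresholds <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
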