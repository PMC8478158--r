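# Declarative gating specification: each population is a conjunction of
# marker-level predicates, optionally nested under a parent population
# whose predicates it inherits. Level semantics (per marker thresholds t1
# and, where defined, t2 with t1 < t2):
#   neg:  x <  t1        pos:       x >= t1
#   dim:  t1 <= x < t2   bright:    x >= t2   (the literature's "high")
#   very_high ("++"): x >= t2      low: x < t1 (CD21^low / CD38^low gates)

GATE_LEVELS <- c("neg", "pos", "dim", "bright", "very_high", "low")
TWO_LEVEL_DEFAULT <- c("CD56", "IgM", "CD38")

population_def <- function(name, parent = NA_character_, ...) {
  parent <- as.character(parent)
  preds <- c(...)
  if (length(preds) == 0) stop("population '", name, "' has no predicates")
  bad <- setdiff(preds, GATE_LEVELS)
  if (length(bad)) stop("unknown gate level(s): ", paste(bad, collapse = ", "))
  list(name = name, parent = parent, predicates = preds)
}

#' The default lymphocyte gating specification
#'
#' The full hierarchy of CD45+ lymphocyte populations analysed by the
#' pipeline: CD3 T cells with CD4/CD8 naive, central-memory and
#' effector-memory subsets; the three canonical NK compartments
#' (CD56bright CD16-, CD56bright CD16+, CD56dim CD16+) with CD57
#' stratification of the CD16+ subsets; and the B-cell compartment (naive,
#' memory, unswitched/class-switched memory, MZ-like, transitional,
#' IgM-only, atypical memory, plasmablasts, CD21low CD38low). Children
#' inherit their parent's predicates, so membership in a child always
#' implies membership in the parent.
#'
#' @return A `GatingSpec`: list of population definitions, each with
#'   `name`, `parent` and a named character vector of `marker = level`
#'   predicates.
#' @export
default_gating_spec <- function() {
  p <- population_def
  spec <- list(
    p("CD45+", NA, CD45 = "pos"),
    p("CD3+ T", "CD45+", CD3 = "pos"),
    p("CD4 T", "CD3+ T", CD4 = "pos"),
    p("naive CD4", "CD4 T", CD45RA = "pos", CCR7 = "pos"),
    p("CM CD4", "CD4 T", CD45RO = "pos", CCR7 = "pos"),
    p("EM CD4", "CD4 T", CD45RO = "pos", CCR7 = "neg"),
    p("CD8 T", "CD3+ T", CD8 = "pos"),
    p("naive CD8", "CD8 T", CD45RA = "pos", CCR7 = "pos"),
    p("CM CD8", "CD8 T", CD45RO = "pos", CCR7 = "pos"),
    p("EM CD8", "CD8 T", CD45RO = "pos", CCR7 = "neg"),
    p("CD56bright CD16- NK", "CD45+", CD3 = "neg", CD56 = "bright",
      CD16 = "neg"),
    p("CD56bright CD16+ NK", "CD45+", CD3 = "neg", CD56 = "bright",
      CD16 = "pos"),
    p("CD56dim CD16+ NK", "CD45+", CD3 = "neg", CD56 = "dim", CD16 = "pos"),
    p("CD56bright CD16+ CD57+ NK", "CD56bright CD16+ NK", CD57 = "pos"),
    p("CD56bright CD16+ CD57- NK", "CD56bright CD16+ NK", CD57 = "neg"),
    p("CD56dim CD16+ CD57+ NK", "CD56dim CD16+ NK", CD57 = "pos"),
    p("CD56dim CD16+ CD57- NK", "CD56dim CD16+ NK", CD57 = "neg"),
    p("CD19+CD20+ B", "CD45+", CD3 = "neg", CD19 = "pos", CD20 = "pos"),
    p("naive B", "CD19+CD20+ B", CD27 = "neg", IgD = "pos"),
    p("memory B", "CD19+CD20+ B", CD27 = "pos"),
    p("unswitched memory B", "memory B", IgM = "pos"),
    p("class-switched memory B IgGk", "memory B", IgM = "neg", IgGk = "pos"),
    p("class-switched memory B IgGl", "memory B", IgM = "neg", IgGl = "pos"),
    p("MZ-like B", "unswitched memory B", IgD = "pos"),
    p("IgM-only B", "unswitched memory B", IgD = "neg"),
    p("transitional B", "CD19+CD20+ B", IgM = "very_high",
      CD38 = "very_high"),
    p("atypical memory B", "CD19+CD20+ B", CD27 = "neg", IgM = "neg",
      IgD = "neg"),
    p("unswitched plasmablasts", "CD45+", CD3 = "neg", CD19 = "pos",
      CD20 = "neg", CD27 = "pos", CD38 = "pos", IgM = "pos"),
    p("class-switched plasmablasts", "CD45+", CD3 = "neg", CD19 = "pos",
      CD20 = "neg", CD27 = "pos", CD38 = "pos", IgM = "neg"),
    p("CD21low CD38low B", "CD19+CD20+ B", CD21 = "low", CD38 = "low")
  )
  names(spec) <- vapply(spec, `[[`, character(1), "name")
  structure(spec, class = "GatingSpec")
}

#' Resolve the full predicate set of every population
#'
#' Walks the parent chain and merges inherited predicates (a child may
#' refine a marker it inherits; its own level wins).
#'
#' @param spec A `GatingSpec`.
#' @return Named list: population -> named character vector of
#'   `marker = level`.
#' @export
resolve_predicates <- function(spec) {
  resolve1 <- function(name, seen = character(0)) {
    if (name %in% seen) stop("cycle in gating spec at '", name, "'")
    def <- spec[[name]]
    if (is.null(def)) stop("unknown parent population: '", name, "'")
    own <- def$predicates
    if (is.na(def$parent)) return(own)
    inherited <- resolve1(def$parent, c(seen, name))
    c(inherited[setdiff(names(inherited), names(own))], own)
  }
  out <- lapply(names(spec), resolve1)
  names(out) <- names(spec)
  out
}

#' Serialize / deserialize a gating spec to YAML
#'
#' @param spec A `GatingSpec`.
#' @param path YAML file path.
#' @rdname gating_spec_io
#' @export
write_gating_spec <- function(spec, path) {
  doc <- lapply(unname(spec), function(d)
    list(name = d$name,
         parent = if (is.na(d$parent)) NULL else d$parent,
         predicates = as.list(d$predicates)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname gating_spec_io
#' @return `read_gating_spec`: a `GatingSpec`.
#' @export
read_gating_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  spec <- lapply(doc, function(d) {
    preds <- unlist(d$predicates)
    population_def(d$name,
                   if (is.null(d$parent)) NA_character_ else d$parent,
                   preds)
  })
  names(spec) <- vapply(spec, `[[`, character(1), "name")
  structure(spec, class = "GatingSpec")
}
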