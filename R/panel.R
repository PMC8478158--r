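#' Default antibody panel
#'
#' The channel/metal/marker table used throughout the package: 20 surface
#' markers, four intranuclear DNA damage response (DDR) markers
#' (gH2AX-147Sm, p-ATM-141Pr, p-CHK2 via anti-PE-161Dy, p53-150Nd), the
#' ki67/IdU cell-cycle pair, six palladium barcode channels, the cisplatin
#' viability channel and the two iridium DNA intercalator channels.
#'
#' Channel identity is carried by the FCS short name (`$PnN`, column
#' `channel_id`); `marker` is the biological label written to `$PnS`.
#'
#' @return A data.frame with columns `channel_id`, `metal`, `marker`,
#'   `role`. Roles are one of `surface`, `intranuclear_ddr`, `cellcycle`,
#'   `barcode`, `viability`, `dna`, `other`.
#' @export
#' @examples
#' p <- default_panel()
#' table(p$role)
default_panel <- function() {
  surface <- data.frame(
    channel_id = c("Sm154Di", "Er170Di", "Yb174Di", "Er168Di", "Tm169Di",
                   "Dy164Di", "Tb159Di", "Nd144Di", "Yb176Di", "Ho165Di",
                   "Dy163Di", "Nd142Di", "Yb171Di", "Nd146Di", "Yb172Di",
                   "Gd160Di", "Eu151Di", "Gd158Di", "Er167Di", "Sm152Di"),
    metal = c("154Sm", "170Er", "174Yb", "168Er", "169Tm", "164Dy", "159Tb",
              "144Nd", "176Yb", "165Ho", "163Dy", "142Nd", "171Yb", "146Nd",
              "172Yb", "160Gd", "151Eu", "158Gd", "167Er", "152Sm"),
    marker = c("CD45", "CD3", "CD4", "CD8", "CD45RA", "CD45RO", "CCR7",
               "CD69", "CD56", "CD16", "CD57", "CD19", "CD20", "IgD", "IgM",
               "IgGk", "IgGl", "CD27", "CD38", "CD21"),
    role = "surface",
    stringsAsFactors = FALSE)
  ddr <- data.frame(
    channel_id = c("Sm147Di", "Pr141Di", "Dy161Di", "Nd150Di"),
    metal = c("147Sm", "141Pr", "161Dy", "150Nd"),
    marker = c("gH2AX", "pATM", "pCHK2", "p53"),
    role = "intranuclear_ddr",
    stringsAsFactors = FALSE)
  cc <- data.frame(
    channel_id = c("Dy162Di", "I127Di"),
    metal = c("162Dy", "127I"),
    marker = c("ki67", "IdU"),
    role = "cellcycle",
    stringsAsFactors = FALSE)
  bc <- data.frame(
    channel_id = paste0("Pd", c(102, 104, 105, 106, 108, 110), "Di"),
    metal = paste0(c(102, 104, 105, 106, 108, 110), "Pd"),
    marker = paste0("BC", c(102, 104, 105, 106, 108, 110)),
    role = "barcode",
    stringsAsFactors = FALSE)
  misc <- data.frame(
    channel_id = c("Pt195Di", "Ir191Di", "Ir193Di"),
    metal = c("195Pt", "191Ir", "193Ir"),
    marker = c("cisplatin", "DNA1", "DNA2"),
    role = c("viability", "dna", "dna"),
    stringsAsFactors = FALSE)
  rbind(surface, ddr, cc, bc, misc)
}

panel_roles <- c("surface", "intranuclear_ddr", "cellcycle", "barcode",
                 "viability", "dna", "other")

validate_panel_df <- function(panel) {
  need <- c("channel_id", "metal", "marker", "role")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$channel_id))
    stop("panel channel_id values must be unique")
  bad <- setdiff(unique(panel$role), panel_roles)
  if (length(bad))
    stop("unknown panel role(s): ", paste(bad, collapse = ", "))
  invisible(panel)
}

#' Read a panel description from CSV or YAML
#'
#' @param path File path; format chosen by extension (`.csv` or
#'   `.yml`/`.yaml`). Must provide `channel_id`, `metal`, `marker`, `role`.
#' @return Panel data.frame (see [default_panel()]).
#' @export
read_panel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  panel <- if (ext %in% c("yml", "yaml")) {
    rows <- yaml::read_yaml(path)
    do.call(rbind, lapply(rows, function(r)
      data.frame(channel_id = r$channel_id, metal = r$metal,
                 marker = r$marker, role = r$role,
                 stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_panel_df(panel)
  panel
}

#' Write a panel description to CSV
#' @param panel Panel data.frame.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  validate_panel_df(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
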