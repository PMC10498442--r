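#' Element property table
#'
#' Returns the packaged table of element properties used throughout the
#' package: element symbol, van der Waals radius (Angstrom), atomic mass
#' (amu) and a metal flag.  Nonmetal radii are the Bondi set; every metal
#' (d- and f-block, alkali and alkaline-earth elements, and Al, Ga, In, Tl,
#' Sn, Pb, Bi) carries a uniform 2.0 Angstrom radius, appropriate for the
#' scaled-radius bond criterion used by [detect_bonds()].
#'
#' @param file Optional path to a user-supplied table with columns
#'   `symbol`, `vdw_radius`, `mass`, `is_metal` (tab-separated).  Defaults
#'   to the packaged table.
#' @return A data.frame with columns `symbol` (character), `vdw_radius`
#'   (numeric, Angstrom), `mass` (numeric, amu), `is_metal` (logical).
#' @export
element_table <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.metalff_env$elements)) return(.metalff_env$elements)
    file <- system.file("extdata", "elements.tsv", package = "metalff",
                        mustWork = TRUE)
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    tab$is_metal <- as.logical(tab$is_metal)
    .metalff_env$elements <- tab
    return(tab)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "vdw_radius", "mass", "is_metal") %in% names(tab)))
  if (anyDuplicated(tab$symbol))
    stop("duplicate element symbols in table: ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))
  if (any(tab$vdw_radius <= 0)) stop("vdw_radius must be positive")
  tab$is_metal <- as.logical(tab$is_metal)
  tab
}

.metalff_env <- new.env(parent = emptyenv())

#' Look up element properties
#'
#' @param symbols Character vector of element symbols.
#' @param table Element table (see [element_table()]).
#' @return Data frame row(s) of the table, in the order of `symbols`.
#' @export
element_info <- function(symbols, table = element_table()) {
  idx <- match(symbols, table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  table[idx, , drop = FALSE]
}

# vdW radius lookup tolerant of exotic symbols: unknown entries fall back to
# 2.0 Angstrom with a warning so unusual metals still parse downstream.
element_vdw <- function(symbols, table = element_table()) {
  idx <- match(symbols, table$symbol)
  r <- table$vdw_radius[idx]
  if (anyNA(r)) {
    warning("no radius for element(s) ",
            paste(unique(symbols[is.na(idx)]), collapse = ", "),
            "; using 2.0 Angstrom fallback")
    r[is.na(r)] <- 2.0
  }
  r
}

element_is_metal <- function(symbols, table = element_table()) {
  idx <- match(symbols, table$symbol)
  m <- table$is_metal[idx]
  m[is.na(m)] <- FALSE
  m
}

element_mass <- function(symbols, table = element_table()) {
  element_info(symbols, table)$mass
}
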