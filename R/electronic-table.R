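#' Atomic ionization potentials and electron affinities
#'
#' Loads the per-element electronic constants that power the QNA atomic
#' terms: the ground-state ionization potential (IP) and electron affinity
#' (EA), both in electron-volts. From these each element gets
#' `A = (IP + EA) / 2` (Mulliken electronegativity scale) and
#' `B = (IP - EA)^(-1/2)` (inverse square root of the chemical hardness
#' gap), the quantities entering the per-atom P and Q descriptors.
#'
#' The packaged table (`inst/extdata/element_electronic_constants.tsv`)
#' carries standard ground-state atomic values for H, C, N, O, F, P, S, Cl,
#' Br and I. Nitrogen's slightly negative EA is legitimate: only IP > EA is
#' required for B to be real.
#'
#' @param path Optional path to a user-supplied TSV with columns
#'   `element`, `ip_ev`, `ea_ev`; defaults to the packaged table.
#' @return A tibble with columns `element`, `ip_ev`, `ea_ev`, `A`, `B`.
#' @examples
#' element_electronic_table()
#' @export
element_electronic_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "element_electronic_constants.tsv",
                        package = "qnasom", mustWork = TRUE)
  }
  tab <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("element", "ip_ev", "ea_ev") %in% names(tab)))
  if (any(tab$ip_ev <= tab$ea_ev)) {
    bad <- tab$element[tab$ip_ev <= tab$ea_ev]
    stop("IP must exceed EA for every element; violated for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(tab,
    A = (.data$ip_ev + .data$ea_ev) / 2,
    B = (.data$ip_ev - .data$ea_ev)^(-0.5)
  )
}
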