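#' Build a per-atom SOM classification dataset
#'
#' Joins molecules with their QNA descriptors into one machine-learning
#' table: one row (instance) per heavy atom, label 1 for SOM atoms and 0
#' otherwise. Atoms of molecules without any SOM annotation enter as
#' negatives — every non-SOM heavy atom is a class-0 instance.
#'
#' @param molecules List of [molgraph()] objects.
#' @param descriptors Tibble from [qna_descriptors()] covering every
#'   molecule; if `NULL`, descriptors are computed on the fly.
#' @return A tibble with columns `mol_id`, `atom`, `element`, `P`, `Q`,
#'   `label` (integer 0/1), `reaction`, `isoform`, `synthetic` (always
#'   `FALSE` here; SMOTE rows flip it). Row order is molecule order then
#'   atom order, so the build is deterministic.
#' @export
build_dataset <- function(molecules, descriptors = NULL) {
  if (inherits(molecules, "molgraph")) molecules <- list(molecules)
  if (is.null(descriptors)) descriptors <- qna_descriptors(molecules)
  ids <- vapply(molecules, function(m) m$mol_id, character(1))
  if (!setequal(ids, unique(descriptors$mol_id))) {
    stop("descriptors do not cover the same molecules as `molecules`",
         call. = FALSE)
  }
  counts <- vapply(molecules, n_atoms, integer(1))
  if (nrow(descriptors) != sum(counts)) {
    stop("descriptor row count does not match total heavy-atom count",
         call. = FALSE)
  }
  descriptors |>
    dplyr::mutate(label = as.integer(.data$is_som), synthetic = FALSE) |>
    dplyr::select("mol_id", "atom", "element", "P", "Q", "label",
                  "reaction", "isoform", "synthetic")
}

#' Filter molecules by reaction type and/or isoform
#'
#' Selects the records whose metadata matches all non-empty criteria and
#' builds the per-atom dataset for that subset, mirroring the compilation of
#' modeling sets by (i) reaction type and (ii) isoform-reaction pair.
#'
#' @param molecules List of [molgraph()] objects.
#' @param reaction Optional reaction type; one of [reaction_types()].
#' @param isoform Optional isoform; one of [cyp_isoforms()].
#' @return A dataset tibble as from [build_dataset()], carrying the group
#'   key in attributes `reaction` and `isoform`.
#' @export
filter_by_group <- function(molecules, reaction = NULL, isoform = NULL) {
  if (inherits(molecules, "molgraph")) molecules <- list(molecules)
  if (!is.null(reaction) && !reaction %in% REACTION_TYPES) {
    stop("unknown reaction type '", reaction, "'; valid: ",
         paste(REACTION_TYPES, collapse = ", "), call. = FALSE)
  }
  if (!is.null(isoform) && !isoform %in% CYP_ISOFORMS) {
    stop("unknown isoform '", isoform, "'; valid: ",
         paste(CYP_ISOFORMS, collapse = ", "), call. = FALSE)
  }
  keep <- vapply(molecules, function(m) {
    (is.null(reaction) || identical(m$reaction_type, reaction)) &&
      (is.null(isoform) || identical(m$isoform, isoform))
  }, logical(1))
  out <- build_dataset(molecules[keep])
  attr(out, "reaction") <- reaction
  attr(out, "isoform") <- isoform
  out
}

#' Class-imbalance ratio of a dataset
#'
#' Ratio of SOM (label 1) to non-SOM (label 0) instances. Real SOM modeling
#' sets are heavily imbalanced, with ratios at or below 0.05.
#'
#' @param dataset A dataset tibble with a `label` column.
#' @return `#label1 / #label0` as a single number.
#' @export
imbalance_ratio <- function(dataset) {
  stopifnot("label" %in% names(dataset))
  n1 <- sum(dataset$label == 1L)
  n0 <- sum(dataset$label == 0L)
  if (n0 == 0L) stop("imbalance ratio undefined: no majority (label 0) instances",
                     call. = FALSE)
  n1 / n0
}
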