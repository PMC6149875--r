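#' Hydrogen-suppressed molecular graph
#'
#' A `molgraph` is the package's light container for one molecule: element
#' symbols and SOM (site-of-metabolism) flags for each heavy atom, an edge
#' list of bonds, and optional record metadata (CYP isoform, reaction type).
#' Hydrogens are excluded by construction; atom indices are 1-based over the
#' heavy atoms.
#'
#' @param mol_id Single string identifying the molecule.
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Two-column integer matrix of bonded atom index pairs
#'   (unordered; may have zero rows).
#' @param is_som Logical vector flagging SOM atoms. Defaults to all `FALSE`.
#' @param isoform Optional CYP isoform label (e.g. `"CYP3A4"`).
#' @param reaction_type Optional reaction-type label; see [reaction_types()].
#'
#' @return An object of class `molgraph`.
#' @examples
#' m <- molgraph("ethanol", c("C", "C", "O"), rbind(c(1, 2), c(2, 3)),
#'               is_som = c(FALSE, TRUE, FALSE))
#' n_atoms(m)
#' @export
molgraph <- function(mol_id, elements, bonds = NULL, is_som = NULL,
                     isoform = NULL, reaction_type = NULL) {
  stopifnot(is.character(mol_id), length(mol_id) == 1L)
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecule must have at least one heavy atom", call. = FALSE)
  if (any(elements %in% c("H", "D", "T"))) {
    stop("molgraph atoms must be heavy atoms (no hydrogens)", call. = FALSE)
  }
  if (is.null(is_som)) is_som <- rep(FALSE, n)
  is_som <- as.logical(is_som)
  stopifnot(length(is_som) == n, !anyNA(is_som))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
  }
  if (NROW(bonds) > 0L) {
    if (any(bonds < 1L) || any(bonds > n)) {
      stop("bond indices reference non-existent atoms in '", mol_id, "'",
           call. = FALSE)
    }
    if (any(bonds[, 1L] == bonds[, 2L])) {
      stop("self-bonds are not allowed in '", mol_id, "'", call. = FALSE)
    }
    # canonical order: low index first, then sorted; duplicates collapse
    bonds <- t(apply(bonds, 1L, sort))
    bonds <- unique(bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE])
  }
  structure(
    list(mol_id = mol_id, elements = elements, bonds = bonds,
         is_som = is_som, isoform = isoform, reaction_type = reaction_type),
    class = "molgraph"
  )
}

#' @rdname molgraph
#' @param x A `molgraph`.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "molgraph"))
  length(x$elements)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d heavy atoms, %d bonds, %d SOM",
              x$mol_id, n_atoms(x), nrow(x$bonds), sum(x$is_som)))
  if (!is.null(x$isoform)) cat(" |", x$isoform)
  if (!is.null(x$reaction_type)) cat(" |", x$reaction_type)
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.molgraph <- function(x, ...) {
  tibble::tibble(
    mol_id = x$mol_id,
    atom = seq_along(x$elements),
    element = x$elements,
    is_som = x$is_som
  )
}

#' Connectivity (adjacency) matrix of a molecule
#'
#' Returns the symmetric 0/1 adjacency matrix of the hydrogen-suppressed
#' molecular graph. Bond order is deliberately discarded: single, double and
#' aromatic bonds all contribute 1, since the QNA descriptors are defined on
#' topological connectivity only.
#'
#' @param molecule A [molgraph()].
#' @return An `n x n` symmetric 0/1 matrix with zero diagonal, `n` the number
#'   of heavy atoms.
#' @examples
#' connectivity_matrix(molgraph("m", c("C", "C", "O"), rbind(c(1, 2), c(2, 3))))
#' @export
connectivity_matrix <- function(molecule) {
  stopifnot(inherits(molecule, "molgraph"))
  n <- n_atoms(molecule)
  C <- matrix(0, n, n)
  b <- molecule$bonds
  if (nrow(b) > 0L) {
    C[b] <- 1
    C[b[, 2:1, drop = FALSE]] <- 1
  }
  C
}

# Largest connected component of a molgraph; used when an SDF record carries
# several fragments (salts, mixtures).
largest_component <- function(molecule) {
  n <- n_atoms(molecule)
  g <- igraph::graph_from_edgelist(
    matrix(as.numeric(molecule$bonds), ncol = 2L), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(molecule)
  keep <- which(comp$membership == which.max(comp$csize))
  remap <- match(seq_len(n), keep)
  b <- molecule$bonds
  b <- b[b[, 1L] %in% keep & b[, 2L] %in% keep, , drop = FALSE]
  b[] <- remap[b]
  molgraph(molecule$mol_id, molecule$elements[keep], b,
           molecule$is_som[keep], molecule$isoform, molecule$reaction_type)
}
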