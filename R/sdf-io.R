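#' Read a SOM-annotated SDF file
#'
#' Reads a multi-record MDL V2000 SDF file and returns hydrogen-suppressed
#' [molgraph()] objects. SOM (site-of-metabolism) annotations are carried in
#' an SDF data field `> <SOM>` holding whitespace- or comma-separated 1-based
#' atom indices in the file's own atom-block numbering (i.e. counting
#' hydrogens if the file writes them explicitly); they are remapped to
#' heavy-atom indices after hydrogen suppression. Optional `> <ISOFORM>` and
#' `> <REACTION>` fields populate the record metadata.
#'
#' Records without a `SOM` field are kept with all-negative labels and a
#' warning. A `SOM` index that is out of range or points at a hydrogen is an
#' error naming the molecule. Multi-fragment records (salts, mixtures) are
#' reduced to their largest connected component with a warning.
#'
#' @param path Path to an SDF file.
#' @return A list of [molgraph()] objects, one per SDF record.
#' @seealso [write_som_sdf()], [generate_molecules()]
#' @export
read_som_sdf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) return(list())

  sds <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("malformed SDF file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ok <- ChemmineR::validSDF(sds)
  if (!all(ok)) {
    stop("malformed molfile at record(s) ",
         paste(which(!ok), collapse = ", "), " in '", path, "'", call. = FALSE)
  }

  out <- vector("list", length(sds))
  for (i in seq_along(sds)) {
    sdf <- sds[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    db <- ChemmineR::datablock(sdf)
    mol_id <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(mol_id) || !nzchar(trimws(mol_id))) mol_id <- sprintf("mol_%04d", i)
    mol_id <- trimws(mol_id)

    elements <- sub("_\\d+$", "", rownames(ab))
    n_all <- length(elements)
    bonds_all <- if (NROW(bb) > 0L) {
      cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    } else {
      matrix(integer(0), ncol = 2L)
    }

    field <- function(name) if (name %in% names(db)) db[[name]] else NULL
    som_raw <- field("SOM")
    if (is.null(som_raw) || is.na(som_raw) || !nzchar(trimws(som_raw))) {
      if (is.null(som_raw)) {
        warning("record '", mol_id, "' has no SOM field; labelling all atoms non-SOM",
                call. = FALSE)
      }
      som_idx <- integer(0)
    } else {
      som_idx <- as.integer(strsplit(trimws(som_raw), "[,[:space:]]+")[[1]])
      if (anyNA(som_idx)) {
        stop("unparseable SOM field in record '", mol_id, "'", call. = FALSE)
      }
    }
    if (anyDuplicated(som_idx)) {
      stop("duplicate SOM indices in record '", mol_id, "'", call. = FALSE)
    }
    if (length(som_idx) && (any(som_idx < 1L) || any(som_idx > n_all))) {
      stop("SOM index out of atom-block range in record '", mol_id, "'",
           call. = FALSE)
    }
    if (any(elements[som_idx] == "H")) {
      stop("SOM index points at a hydrogen in record '", mol_id, "'",
           call. = FALSE)
    }

    # hydrogen suppression with index remap (SDF numbering -> heavy numbering)
    heavy <- which(elements != "H")
    remap <- match(seq_len(n_all), heavy)
    bonds <- bonds_all[bonds_all[, 1L] %in% heavy & bonds_all[, 2L] %in% heavy,
                       , drop = FALSE]
    bonds[] <- remap[bonds]
    is_som <- rep(FALSE, length(heavy))
    is_som[remap[som_idx]] <- TRUE

    iso <- field("ISOFORM")
    rxn <- field("REACTION")
    m <- molgraph(mol_id, elements[heavy], bonds, is_som,
                  isoform = if (!is.null(iso) && nzchar(iso)) iso else NULL,
                  reaction_type = if (!is.null(rxn) && nzchar(rxn)) rxn else NULL)
    nc <- n_components(m)
    if (nc > 1L) {
      warning("record '", mol_id, "' has ", nc,
              " fragments; keeping the largest connected component", call. = FALSE)
      m <- largest_component(m)
    }
    out[[i]] <- m
  }
  out
}

n_components <- function(molecule) {
  g <- igraph::graph_from_edgelist(
    matrix(as.numeric(molecule$bonds), ncol = 2L), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, n_atoms(molecule) - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Write molecules to a SOM-annotated SDF file
#'
#' Serialises [molgraph()] objects as MDL V2000 records with `SOM`,
#' `ISOFORM` and `REACTION` data fields. Atom order follows the internal
#' heavy-atom order; coordinates are written as zeros (the descriptors are
#' purely topological). SOM indices are emitted 1-based and ascending, so a
#' write/read cycle is a fixed point.
#'
#' @param molecules A list of [molgraph()] objects (may be empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_som_sdf <- function(molecules, path) {
  stopifnot(is.list(molecules))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in molecules) {
    stopifnot(inherits(m, "molgraph"))
    n <- n_atoms(m)
    nb <- nrow(m$bonds)
    rec <- c(
      m$mol_id,
      "  qnasom",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              0, 0, 0, m$elements),
      if (nb > 0L) sprintf("%3d%3d%3d  0", m$bonds[, 1L], m$bonds[, 2L], 1L),
      "M  END",
      "> <SOM>",
      paste(which(m$is_som), collapse = " "),
      ""
    )
    if (!is.null(m$isoform)) {
      rec <- c(rec, "> <ISOFORM>", m$isoform, "")
    }
    if (!is.null(m$reaction_type)) {
      rec <- c(rec, "> <REACTION>", m$reaction_type, "")
    }
    writeLines(c(rec, "$$$$"), con)
  }
  invisible(path)
}

#' Export per-atom descriptors as TSV
#'
#' @param descriptors A tibble as returned by [qna_descriptors()] or
#'   [build_dataset()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_tsv <- function(descriptors, path) {
  utils::write.table(descriptors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
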