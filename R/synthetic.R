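#' Generate synthetic SOM-annotated molecules
#'
#' Builds random connected molecular graphs (random spanning trees plus
#' occasional ring-closing edges, with per-element valence caps C:4, N:3,
#' O:2, S:2) and labels sites of metabolism with a known rule, so that the
#' whole pipeline — SDF round-trip, descriptors, balancing, classification,
#' evaluation — can be exercised against a known ground truth and a known
#' class imbalance.
#'
#' With `rule = "qna_threshold"` an atom is a SOM when its true Q descriptor
#' exceeds a threshold calibrated on the pooled descriptor distribution of
#' the generated set so that the global SOM:non-SOM ratio hits
#' `som_ratio` (real modeling sets sit at or below 0.05). The rule is
#' deterministic in the features, so a classifier's attainable balanced
#' accuracy is 1 at `label_noise = 0` and degrades as labels are flipped.
#' With `rule = "random"` labels are assigned by coin flips at the same
#' rate, carrying no signal. Each molecule also receives a uniform
#' reaction-type and isoform annotation for grouping tests.
#'
#' @param n_molecules Number of molecules.
#' @param atom_range Inclusive range of heavy-atom counts per molecule.
#' @param elements Named numeric vector of element sampling weights.
#' @param som_ratio Target global SOM:non-SOM count ratio.
#' @param rule `"qna_threshold"` (learnable) or `"random"` (pure noise).
#' @param label_noise Probability in \[0, 0.5) of flipping each atom's label.
#' @param ring_prob Probability that a molecule gains one ring-closing edge
#'   (a second is attempted at half that rate).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param sdf_path Optional path; when given, molecules are also written as
#'   annotated SDF.
#' @return List of [molgraph()] objects, with the calibrated threshold in
#'   attribute `"q_threshold"`.
#' @examples
#' mols <- generate_molecules(10, seed = 1)
#' length(mols)
#' @export
generate_molecules <- function(n_molecules,
                               atom_range = c(6L, 24L),
                               elements = c(C = 0.70, N = 0.12,
                                            O = 0.13, S = 0.05),
                               som_ratio = 0.05,
                               rule = c("qna_threshold", "random"),
                               label_noise = 0,
                               ring_prob = 0.4,
                               seed = 1L,
                               sdf_path = NULL) {
  rule <- match.arg(rule)
  stopifnot(n_molecules >= 1L, atom_range[1] >= 1L,
            atom_range[2] >= atom_range[1],
            som_ratio > 0, som_ratio <= 1,
            label_noise >= 0, label_noise < 0.5)
  withr::local_seed(seed)
  caps <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  stopifnot(all(names(elements) %in% names(caps)))

  mols <- purrr::map(seq_len(n_molecules), function(i) {
    n <- sample(atom_range[1]:atom_range[2], 1L)
    els <- sample(names(elements), n, replace = TRUE, prob = elements)
    deg <- integer(n)
    cap <- caps[els]
    bonds <- matrix(integer(0), ncol = 2L)
    if (n > 1L) {
      for (v in 2:n) {
        open <- which(deg[seq_len(v - 1L)] < cap[seq_len(v - 1L)])
        u <- if (length(open) == 1L) open else sample(open, 1L)
        bonds <- rbind(bonds, c(u, v))
        deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      }
      # optional ring closures between non-adjacent open-valence atoms
      n_rings <- stats::rbinom(1L, 1L, ring_prob) +
        stats::rbinom(1L, 1L, ring_prob / 2)
      for (r in seq_len(n_rings)) {
        open <- which(deg < cap)
        if (length(open) < 2L) break
        pairs <- t(utils::combn(open, 2L))
        adj <- paste(bonds[, 1L], bonds[, 2L])
        pairs <- pairs[!paste(pairs[, 1L], pairs[, 2L]) %in% adj, ,
                       drop = FALSE]
        if (nrow(pairs) == 0L) break
        pick <- pairs[sample.int(nrow(pairs), 1L), ]
        bonds <- rbind(bonds, pick)
        deg[pick] <- deg[pick] + 1L
      }
    }
    molgraph(sprintf("SYN%05d", i), els, bonds,
             isoform = sample(CYP_ISOFORMS, 1L),
             reaction_type = sample(REACTION_TYPES, 1L))
  })

  # labelling: calibrate a Q threshold on the pooled descriptor distribution
  desc <- qna_descriptors(mols)
  n_atoms_total <- nrow(desc)
  pos_fraction <- som_ratio / (1 + som_ratio)
  tau <- NA_real_
  if (rule == "qna_threshold") {
    n_pos <- max(1L, round(pos_fraction * n_atoms_total))
    tau <- sort(desc$Q, decreasing = TRUE)[n_pos]
    labels <- desc$Q >= tau
  } else {
    labels <- stats::runif(n_atoms_total) < pos_fraction
  }
  if (label_noise > 0) {
    flip <- stats::runif(n_atoms_total) < label_noise
    labels <- xor(labels, flip)
  }

  lab_by_mol <- split(labels, factor(desc$mol_id,
                                     levels = unique(desc$mol_id)))
  mols <- purrr::map(mols, function(m) {
    m$is_som <- unname(lab_by_mol[[m$mol_id]])
    m
  })
  attr(mols, "q_threshold") <- tau
  if (!is.null(sdf_path)) write_som_sdf(mols, sdf_path)
  mols
}

#' Generate a per-atom dataset in one call
#'
#' Convenience wrapper: [generate_molecules()] then [build_dataset()].
#'
#' @inheritParams generate_molecules
#' @param ... Passed to [generate_molecules()].
#' @return A dataset tibble.
#' @export
sim_som_dataset <- function(n_molecules, ...) {
  build_dataset(generate_molecules(n_molecules, ...))
}

#' Benchmark suite of grouped datasets
#'
#' Emulates the structure of reaction-type and isoform-reaction modeling
#' sets at reduced size: the seven reaction-type subsets plus five
#' isoform-reaction subsets (the representative pairs used for the second
#' compilation style).
#'
#' @param molecules List of [molgraph()] objects, e.g. from
#'   [generate_molecules()].
#' @return A named list with elements `by_reaction` (7 datasets) and
#'   `by_isoform_reaction` (5 datasets).
#' @export
make_benchmark_suite <- function(molecules) {
  by_reaction <- purrr::map(
    setNames(REACTION_TYPES, REACTION_TYPES),
    function(rx) filter_by_group(molecules, reaction = rx)
  )
  pairs <- list(
    c("CYP1A2", "aliphatic hydroxylation"),
    c("CYP1A2", "C-oxidation"),
    c("CYP3A4", "C-oxidation"),
    c("CYP2C19", "O-dealkylation"),
    c("CYP2C9", "S-oxidation")
  )
  by_iso <- purrr::map(pairs, function(p) {
    filter_by_group(molecules, reaction = p[2], isoform = p[1])
  })
  names(by_iso) <- vapply(pairs, function(p) paste(p[1], p[2], sep = "/"),
                          character(1))
  list(by_reaction = by_reaction, by_isoform_reaction = by_iso)
}
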