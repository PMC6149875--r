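#' Matrix exponential exp(-C/2) of a connectivity matrix
#'
#' Computes the exponential kernel `E = exp(-C/2)` of a symmetric 0/1
#' connectivity matrix by symmetric eigendecomposition:
#' `E = V diag(exp(-lambda/2)) V'`. The result is re-symmetrised to kill
#' last-bit asymmetry from floating-point round-off.
#'
#' @param C Square symmetric numeric matrix with zero diagonal.
#' @return A symmetric matrix of the same dimension.
#' @examples
#' matrix_exp_neg_half(matrix(c(0, 1, 1, 0), 2))  # cosh/sinh of 1/2
#' @export
matrix_exp_neg_half <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!isSymmetric(unname(C), tol = 1e-10)) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  eig <- eigen(C, symmetric = TRUE)
  E <- eig$vectors %*% (exp(-eig$values / 2) * t(eig$vectors))
  (E + t(E)) / 2
}

#' Per-atom QNA descriptors P and Q
#'
#' Computes the raw (un-normalized) Quantitative Neighborhoods of Atoms
#' descriptor pair for every heavy atom of one or more molecules. With
#' per-atom electronic terms `A_i = (IP_i + EA_i)/2` and
#' `B_i = (IP_i - EA_i)^(-1/2)` and the graph kernel `E = exp(-C/2)` of the
#' connectivity matrix `C`:
#' \deqn{P_i = B_i \sum_k E_{ik} B_k, \qquad
#'       Q_i = B_i \sum_k E_{ik} A_k B_k.}
#' Every atom's values therefore depend on the whole molecular graph, not
#' just its local neighbourhood.
#'
#' @param molecules A [molgraph()] or list of them.
#' @param table Electronic-constants table from [element_electronic_table()].
#' @return A tibble with one row per heavy atom: `mol_id`, `atom` (1-based),
#'   `element`, `P`, `Q`, plus `is_som` and any record metadata.
#' @examples
#' m <- molgraph("ethane", c("C", "C"), rbind(c(1, 2)))
#' qna_descriptors(m)
#' @export
qna_descriptors <- function(molecules, table = element_electronic_table()) {
  if (inherits(molecules, "molgraph")) molecules <- list(molecules)
  purrr::map_dfr(molecules, compute_pq, table = table)
}

compute_pq <- function(molecule, table = element_electronic_table()) {
  stopifnot(inherits(molecule, "molgraph"))
  idx <- match(molecule$elements, table$element)
  if (anyNA(idx)) {
    stop("element(s) not in electronic table for molecule '",
         molecule$mol_id, "': ",
         paste(unique(molecule$elements[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  A <- table$A[idx]
  B <- table$B[idx]
  E <- matrix_exp_neg_half(connectivity_matrix(molecule))
  P <- B * drop(E %*% B)
  Q <- B * drop(E %*% (A * B))
  stopifnot(all(is.finite(P)), all(is.finite(Q)))
  tibble::tibble(
    mol_id = molecule$mol_id,
    atom = seq_along(B),
    element = molecule$elements,
    P = P,
    Q = Q,
    is_som = molecule$is_som,
    isoform = if (is.null(molecule$isoform)) NA_character_ else molecule$isoform,
    reaction = if (is.null(molecule$reaction_type)) NA_character_ else
      molecule$reaction_type
  )
}

#' Z-score normalization fitted on a training partition
#'
#' `fit_normalizer()` records per-feature mean and population standard
#' deviation; `apply_normalizer()` maps `x` to `(x - mean)/sd`. Fit on the
#' training rows only and apply to held-out rows, so no test-set information
#' leaks into the feature scaling. A zero-variance feature is mapped to 0.
#'
#' @param data Data frame holding the feature columns.
#' @param features Character vector of feature column names.
#' @return `fit_normalizer()`: a `qna_normalizer` object;
#'   `apply_normalizer()`: `data` with the feature columns standardized.
#' @examples
#' d <- tibble::tibble(P = c(0, 2), Q = c(0, 2))
#' nz <- fit_normalizer(d)
#' apply_normalizer(nz, d)
#' @export
fit_normalizer <- function(data, features = c("P", "Q")) {
  stopifnot(is.data.frame(data), nrow(data) >= 2L,
            all(features %in% names(data)))
  mu <- vapply(data[features], mean, numeric(1))
  sigma <- vapply(data[features], function(x) sqrt(mean((x - mean(x))^2)),
                  numeric(1))
  structure(list(features = features, mean = mu, sd = sigma,
                 fitted_on = nrow(data)),
            class = "qna_normalizer")
}

#' @rdname fit_normalizer
#' @param params A fitted `qna_normalizer`.
#' @export
apply_normalizer <- function(params, data) {
  stopifnot(inherits(params, "qna_normalizer"), is.data.frame(data))
  for (f in params$features) {
    s <- params$sd[[f]]
    data[[f]] <- if (s == 0) 0 * data[[f]] else (data[[f]] - params$mean[[f]]) / s
  }
  data
}

#' @export
print.qna_normalizer <- function(x, ...) {
  cat("<qna_normalizer> fitted on", x$fitted_on, "rows\n")
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}
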