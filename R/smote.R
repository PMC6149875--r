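#' SMOTE oversampling of the minority (SOM) class
#'
#' Synthetic Minority Oversampling Technique in (P, Q) descriptor space:
#' each synthetic instance is `x + delta * (x_nn - x)` where `x` is a
#' minority instance, `x_nn` one of its `k` nearest minority neighbours
#' (Euclidean metric, neighbour search among minority points only) and
#' `delta` uniform on \[0, 1\]. Originals are kept unchanged; synthetic rows
#' are marked `synthetic = TRUE` and given `mol_id`s in a reserved
#' `"SMOTE_*"` namespace so they can never cross a molecule-level split
#' boundary. Apply to training partitions only — never to validation or
#' test folds.
#'
#' The number of synthetic points needed to reach `target_ratio`
#' (minority:majority, default 1) is spread as evenly as possible over the
#' minority instances; the remainder is assigned at random. Neighbour
#' distance ties break toward the lower row index, so a fixed seed gives a
#' bit-identical result.
#'
#' @param dataset Dataset tibble from [build_dataset()] (features `P`, `Q`,
#'   labels in `label`).
#' @param k_neighbors Number of minority neighbours (default 5). Clamped
#'   with a warning when fewer minority points exist.
#' @param target_ratio Desired minority:majority count ratio (default 1).
#' @param seed Optional integer seed for reproducibility.
#' @return The input tibble with synthetic minority rows appended.
#' @examples
#' d <- tibble::tibble(mol_id = "m", atom = 1:6, element = "C",
#'                     P = c(1, 1.1, 2, 2.1, 2.2, 2.3),
#'                     Q = c(1, 1.1, 2, 2.1, 2.2, 2.3),
#'                     label = c(1L, 1L, 0L, 0L, 0L, 0L),
#'                     reaction = NA, isoform = NA, synthetic = FALSE)
#' smote_oversample(d, k_neighbors = 1, seed = 1)
#' @export
smote_oversample <- function(dataset, k_neighbors = 5, target_ratio = 1,
                             seed = NULL) {
  stopifnot(all(c("P", "Q", "label") %in% names(dataset)),
            k_neighbors >= 1, target_ratio > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  minority <- which(dataset$label == 1L)
  n_min <- length(minority)
  n_maj <- sum(dataset$label == 0L)
  if (n_min < 2L) {
    stop("SMOTE needs at least 2 minority instances (no neighbour exists)",
         call. = FALSE)
  }
  n_new <- round(target_ratio * n_maj) - n_min
  if (n_new <= 0L) return(dataset)
  if (k_neighbors > n_min - 1L) {
    warning("k_neighbors clamped from ", k_neighbors, " to ", n_min - 1L,
            " (minority size)", call. = FALSE)
    k_neighbors <- n_min - 1L
  }

  X <- as.matrix(dataset[minority, c("P", "Q")])
  D <- as.matrix(stats::dist(X))
  # k nearest minority neighbours per minority point; ties -> lower index
  nn <- t(apply(D, 1L, function(d) {
    order(d, seq_along(d))[2:(k_neighbors + 1L)]
  }))
  nn <- matrix(nn, nrow = n_min)  # guard k = 1 dropping the dim

  # even spread of the synthetic budget; remainder at random
  per <- rep(n_new %/% n_min, n_min)
  rem <- n_new %% n_min
  if (rem > 0L) {
    extra <- sample.int(n_min, rem)
    per[extra] <- per[extra] + 1L
  }
  src <- rep(seq_len(n_min), per)
  nbr <- nn[cbind(src, sample.int(k_neighbors, n_new, replace = TRUE))]
  delta <- stats::runif(n_new)

  new_rows <- dataset[minority[src], ]
  new_rows$P <- X[src, 1L] + delta * (X[nbr, 1L] - X[src, 1L])
  new_rows$Q <- X[src, 2L] + delta * (X[nbr, 2L] - X[src, 2L])
  new_rows$mol_id <- sprintf("SMOTE_%06d", seq_len(n_new))
  new_rows$atom <- 1L
  new_rows$synthetic <- TRUE
  dplyr::bind_rows(dataset, new_rows)
}
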