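#' Confusion counts for binary SOM predictions
#'
#' Label 1 (SOM) is the positive class.
#'
#' @param labels Integer/logical vector of true labels (0/1).
#' @param predictions Hard predictions (0/1), same length.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  tibble::tibble(
    tp = sum(labels == 1L & predictions == 1L),
    fp = sum(labels == 0L & predictions == 1L),
    tn = sum(labels == 0L & predictions == 0L),
    fn = sum(labels == 1L & predictions == 0L)
  )
}

#' Sensitivity, specificity and balanced accuracy
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `BA = (Se+Sp)/2`. Balanced
#' accuracy is the headline metric for heavily imbalanced per-atom data,
#' where raw accuracy is dominated by the non-SOM class.
#'
#' @param counts One-row tibble from [confusion()].
#' @return A one-row tibble with `se`, `sp`, `ba`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  if (counts$tp + counts$fn == 0L || counts$tn + counts$fp == 0L) {
    stop("metrics undefined: one class is empty in the scored set",
         call. = FALSE)
  }
  se <- counts$tp / (counts$tp + counts$fn)
  sp <- counts$tn / (counts$tn + counts$fp)
  tibble::tibble(se = se, sp = sp, ba = (se + sp) / 2)
}

#' Rank-based (Mann-Whitney) ROC AUC
#'
#' Equals the probability that a random positive outscores a random
#' negative, with tied scores counting one half — identical to trapezoidal
#' integration of the ROC curve.
#'
#' @param labels True 0/1 labels.
#' @param scores Numeric scores (higher = more SOM-like).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # average ranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# molecule-level 2:1 split of unique mol_ids
split_molecules <- function(mol_ids, train_fraction = 2 / 3) {
  ids <- unique(mol_ids)
  n_train <- round(train_fraction * length(ids))
  train_ids <- sample(ids, n_train)
  list(train = train_ids, test = setdiff(ids, train_ids))
}

eval_one_split <- function(dataset, spec, train_ids, test_ids, balance,
                           smote_seed) {
  train <- dplyr::filter(dataset, .data$mol_id %in% train_ids)
  test <- dplyr::filter(dataset, .data$mol_id %in% test_ids)
  nz <- fit_normalizer(train)
  train <- apply_normalizer(nz, train)
  test <- apply_normalizer(nz, test)
  if (balance) train <- smote_oversample(train, seed = smote_seed)
  model <- fit_som_model(spec, train)
  p <- predict_proba(model, test)
  m <- classification_metrics(confusion(test$label, as.integer(p >= 0.5)))
  list(metrics = tibble::tibble(se = m$se, sp = m$sp, ba = m$ba,
                                auc = roc_auc(test$label, p)),
       scores = dplyr::mutate(
         dplyr::select(test, "mol_id", "atom", "label"), score = p),
       train = train, test = test)
}

new_som_eval <- function(per_repeat, protocol, scores = NULL, details = NULL) {
  summary <- tidyr::pivot_longer(per_repeat,
                                 cols = c("se", "sp", "ba", "auc"),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1L) stats::sd(.data$value) else NA_real_,
                     .groups = "drop")
  structure(list(per_repeat = per_repeat, summary = summary,
                 protocol = protocol, scores = scores, details = details),
            class = "som_eval")
}

#' Repeated 2:1 split evaluation
#'
#' The reference protocol: the dataset is split at molecule level (all atoms
#' of a molecule land on one side) into training and test sets in a 2:1
#' proportion; the split, normalization, optional SMOTE balancing of the
#' training side, fitting and test scoring are repeated `repeats` times and
#' the per-repeat metrics are averaged. The normalizer is fitted on each
#' training side only, and SMOTE never touches the test side, so no
#' information leaks across the split.
#'
#' @param dataset Per-atom dataset tibble from [build_dataset()].
#' @param spec A [som_classifier()] specification.
#' @param repeats Number of independent splits (default 5).
#' @param train_fraction Fraction of molecules in the training side
#'   (default 2/3).
#' @param balance Apply [smote_oversample()] to the training side?
#' @param seed Integer seed driving all splits and fits.
#' @param keep_details Keep per-repeat train/test frames (for audits).
#' @return A `som_eval` object; see [tidy.som_eval()] / [glance.som_eval()].
#' @export
repeated_split_eval <- function(dataset, spec, repeats = 5L,
                                train_fraction = 2 / 3, balance = FALSE,
                                seed = 1L, keep_details = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"), repeats >= 1L)
  real <- dplyr::filter(dataset, !.data$synthetic)
  if (length(unique(real$mol_id)) < 3L) {
    stop("dataset too small for a 2:1 molecule-level split", call. = FALSE)
  }
  details <- if (keep_details) vector("list", repeats) else NULL
  per_repeat <- purrr::map_dfr(seq_len(repeats), function(r) {
    withr::local_seed(seed + 7919L * r)
    sp <- split_molecules(real$mol_id, train_fraction)
    res <- eval_one_split(real, spec, sp$train, sp$test, balance,
                          smote_seed = seed + 104729L * r)
    if (keep_details) {
      details[[r]] <<- list(train_ids = sp$train, test_ids = sp$test,
                            train = res$train, test = res$test)
    }
    dplyr::mutate(res$metrics, repeat_id = r, .before = 1L)
  })
  new_som_eval(per_repeat,
               protocol = list(name = "repeated-split", repeats = repeats,
                               train_fraction = train_fraction,
                               balance = balance, seed = seed,
                               classifier = spec$kind),
               details = details)
}

#' Leave-one-molecule-out cross-validation
#'
#' Each fold holds out all atoms of one molecule; out-of-fold scores are
#' pooled and a single AUC (plus Se/Sp/BA at threshold 0.5) is computed on
#' the pooled scores, since per-fold AUC is undefined for single-molecule
#' folds.
#'
#' @inheritParams repeated_split_eval
#' @return A `som_eval` object with one pooled record and per-atom `scores`.
#' @export
loo_eval <- function(dataset, spec, balance = FALSE, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  real <- dplyr::filter(dataset, !.data$synthetic)
  ids <- unique(real$mol_id)
  if (length(ids) < 3L) stop("need at least 3 molecules for leave-one-out",
                             call. = FALSE)
  scores <- purrr::map_dfr(seq_along(ids), function(i) {
    withr::local_seed(seed + 7919L * i)
    train <- dplyr::filter(real, .data$mol_id != ids[i])
    test <- dplyr::filter(real, .data$mol_id == ids[i])
    nz <- fit_normalizer(train)
    train <- apply_normalizer(nz, train)
    test <- apply_normalizer(nz, test)
    if (balance) train <- smote_oversample(train, seed = seed + 104729L * i)
    model <- fit_som_model(spec, train)
    dplyr::mutate(dplyr::select(test, "mol_id", "atom", "label"),
                  score = predict_proba(model, test))
  })
  m <- classification_metrics(confusion(scores$label,
                                        as.integer(scores$score >= 0.5)))
  per <- tibble::tibble(repeat_id = 1L, se = m$se, sp = m$sp, ba = m$ba,
                        auc = roc_auc(scores$label, scores$score))
  new_som_eval(per,
               protocol = list(name = "leave-one-out", folds = length(ids),
                               balance = balance, seed = seed,
                               classifier = spec$kind),
               scores = scores)
}

#' Top-k SOM hit rate
#'
#' Fraction (as a percentage) of molecules whose `k` highest-scoring atoms
#' include at least one true SOM. Score ties break toward the lower atom
#' index. Molecules without any SOM are excluded with a warning; a molecule
#' with fewer than `k` atoms uses all of them.
#'
#' @param scores Tibble with `mol_id`, `atom`, `label`, `score` (e.g. the
#'   `scores` element of [loo_eval()]).
#' @param k Number of top-ranked atoms to inspect.
#' @return Percentage in \[0, 100\].
#' @export
top_k_hit_rate <- function(scores, k) {
  stopifnot(all(c("mol_id", "atom", "label", "score") %in% names(scores)),
            k >= 1L)
  has_som <- scores |>
    dplyr::group_by(.data$mol_id) |>
    dplyr::summarise(any_som = any(.data$label == 1L), .groups = "drop")
  if (any(!has_som$any_som)) {
    warning(sum(!has_som$any_som),
            " molecule(s) without a SOM excluded from Top-k", call. = FALSE)
  }
  hits <- scores |>
    dplyr::filter(.data$mol_id %in% has_som$mol_id[has_som$any_som]) |>
    dplyr::group_by(.data$mol_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$atom, .by_group = TRUE) |>
    dplyr::summarise(hit = any(.data$label[seq_len(min(k, dplyr::n()))] == 1L),
                     .groups = "drop")
  if (nrow(hits) == 0L) stop("no molecule with a SOM to rank", call. = FALSE)
  100 * mean(hits$hit)
}

#' @export
print.som_eval <- function(x, ...) {
  cat("<som_eval>", x$protocol$name, "|", x$protocol$classifier,
      if (isTRUE(x$protocol$balance)) "| SMOTE-balanced" else "", "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy and summarise evaluation reports
#'
#' `tidy()` returns the per-repeat metric records; `glance()` one row of
#' means and standard deviations across repeats.
#'
#' @param x A `som_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.som_eval <- function(x, ...) x$per_repeat

#' @rdname tidy.som_eval
#' @export
glance.som_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::mutate(wide, protocol = x$protocol$name,
                classifier = x$protocol$classifier,
                balanced = isTRUE(x$protocol$balance))
}

#' Export an evaluation report
#'
#' Writes the per-repeat records and aggregate summary as JSON or TSV.
#'
#' @param x A `som_eval` object.
#' @param path Output path; format chosen by extension (`.json` or `.tsv`).
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "som_eval"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(protocol = x$protocol, per_repeat = x$per_repeat,
           summary = x$summary),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x$per_repeat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
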