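test_that("confusion counts follow the standard table", {
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               tibble::tibble(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  withr::local_seed(1)
  y <- rbinom(500, 1, 0.3); p <- rbinom(500, 1, 0.5)
  cc <- confusion(y, p)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 500L)
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("Se, Sp and BA follow their definitions", {
  m <- classification_metrics(tibble::tibble(tp = 8L, fn = 2L,
                                             tn = 90L, fp = 10L))
  expect_equal(c(m$se, m$sp, m$ba), c(0.8, 0.9, 0.85))
  perfect <- classification_metrics(tibble::tibble(tp = 5L, fn = 0L,
                                                   tn = 7L, fp = 0L))
  expect_equal(c(perfect$se, perfect$sp, perfect$ba), c(1, 1, 1))
  # all-positive predictor on balanced data: Se 1, Sp 0, BA 1/2
  allpos <- classification_metrics(confusion(rep(c(1, 0), 10),
                                             rep(1, 20)))
  expect_equal(allpos$ba, 0.5)
  expect_error(classification_metrics(tibble::tibble(tp = 0L, fn = 0L,
                                                     tn = 3L, fp = 1L)),
               "undefined")
})

test_that("rank-based AUC handles perfect ranking and total ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("rank-based AUC equals trapezoidal ROC integration", {
  skip_if_not_installed("pROC")
  withr::local_seed(2)
  for (rep in 1:3) {
    y <- rbinom(200, 1, 0.3)
    s <- round(rnorm(200), 1)  # coarse scores force ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("repeated 2:1 splits are molecule-level with 5 aggregated records", {
  ds <- qna_dataset_cached(99, seed = 77)
  ev <- repeated_split_eval(ds, som_classifier("random_forest", seed = 1),
                            repeats = 5, seed = 3, keep_details = TRUE)
  expect_equal(nrow(tidy(ev)), 5L)
  expect_equal(nrow(ev$summary), 4L)
  for (det in ev$details) {
    expect_length(det$train_ids, 66L)
    expect_length(det$test_ids, 33L)
    expect_length(intersect(det$train_ids, det$test_ids), 0L)
  }
  # BA identity on every emitted record
  expect_equal(tidy(ev)$ba, (tidy(ev)$se + tidy(ev)$sp) / 2,
               tolerance = 1e-12)
  g <- glance(ev)
  expect_equal(g$mean_ba, mean(tidy(ev)$ba))
  expect_error(repeated_split_eval(ds[ds$mol_id == ds$mol_id[1], ],
                                   som_classifier("random_forest")),
               "too small")
})

test_that("leave-one-molecule-out pools out-of-fold scores", {
  mols <- generate_molecules(12, seed = 19)
  ds <- build_dataset(mols)
  ev <- loo_eval(ds, som_classifier("naive_bayes", seed = 1), seed = 4)
  expect_equal(nrow(ev$scores), nrow(ds))
  # each molecule's atoms scored exactly once, by a model that never saw them
  expect_equal(sort(unique(ev$scores$mol_id)), sort(unique(ds$mol_id)))
  expect_equal(nrow(tidy(ev)), 1L)
  expect_true(ev$per_repeat$auc >= 0 && ev$per_repeat$auc <= 1)
  expect_error(loo_eval(ds[ds$mol_id %in% unique(ds$mol_id)[1:2], ],
                        som_classifier("naive_bayes")), "at least 3")
})

test_that("LOO recovers a perfectly learnable rule", {
  ds <- qna_dataset_cached(60, seed = 207)
  ev <- loo_eval(ds, som_classifier("random_forest", seed = 1), seed = 5)
  expect_gte(ev$per_repeat$auc, 0.95)
})

test_that("Top-k hit rate follows its definition and is monotone in k", {
  sc <- tibble::tibble(
    mol_id = rep(c("a", "b"), each = 3),
    atom = rep(1:3, 2),
    label = c(1L, 0L, 0L, 0L, 0L, 1L),
    score = c(0.9, 0.5, 0.1, 0.9, 0.5, 0.1)
  )
  expect_equal(top_k_hit_rate(sc, 1), 50)   # only molecule a tops with a SOM
  expect_equal(top_k_hit_rate(sc, 3), 100)  # k = atom count: always a hit
  expect_lte(top_k_hit_rate(sc, 1), top_k_hit_rate(sc, 2))

  no_som <- dplyr::mutate(sc, label = ifelse(mol_id == "b", 0L, label))
  expect_warning(r <- top_k_hit_rate(no_som, 1), "without a SOM")
  expect_equal(r, 100)
})

test_that("random scores hit at the hypergeometric rate", {
  withr::local_seed(6)
  n_mol <- 400L; a <- 8L; s <- 2L; k <- 2L
  sc <- tibble::tibble(
    mol_id = rep(sprintf("m%03d", seq_len(n_mol)), each = a),
    atom = rep(seq_len(a), n_mol),
    label = as.integer(unlist(replicate(n_mol,
      seq_len(a) %in% sample.int(a, s), simplify = FALSE))),
    score = runif(n_mol * a)
  )
  expected <- 100 * (1 - choose(a - s, k) / choose(a, k))
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n_mol)
  expect_lt(abs(top_k_hit_rate(sc, k) - expected), 4 * se)
})

test_that("evaluation reports export to JSON and TSV", {
  ds <- qna_dataset_cached(60, seed = 207)
  ev <- repeated_split_eval(ds, som_classifier("naive_bayes", seed = 1),
                            repeats = 2, seed = 6)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, fj)
  write_eval_report(ev, ft)
  j <- jsonlite::read_json(fj)
  expect_length(j$per_repeat, 2L)
  expect_equal(nrow(utils::read.delim(ft)), 2L)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})
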