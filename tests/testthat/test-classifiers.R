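make_blobs <- function(n_per_class = 200L, sep = 6, seed = 1L) {
  withr::local_seed(seed)
  tibble::tibble(
    mol_id = sprintf("b%04d", seq_len(2L * n_per_class)), atom = 1L,
    element = "C",
    P = c(rnorm(n_per_class), rnorm(n_per_class, sep)),
    Q = c(rnorm(n_per_class), rnorm(n_per_class, sep)),
    label = rep(c(0L, 1L), each = n_per_class),
    reaction = NA_character_, isoform = NA_character_, synthetic = FALSE
  )
}

test_that("spec defaults encode the reference configurations", {
  rf <- som_classifier("random_forest")
  expect_equal(rf$hyper$ntree, 100L)
  expect_equal(rf$hyper$bag_fraction, 0.7)
  rbf <- som_classifier("rbf_network")
  expect_equal(rbf$hyper$n_clusters, 2L)
  expect_equal(rbf$hyper$activation_floor, 1e-8)
  mlp <- som_classifier("mlp")
  expect_equal(mlp$hyper$hidden, c(10L, 10L))
  expect_error(som_classifier("random_forest", bogus = 1), "unknown hyper")
})

test_that("random forest separates well-separated blobs perfectly", {
  d <- make_blobs()
  m <- fit_som_model(som_classifier("random_forest", seed = 2), d)
  acc <- mean(as.integer(predict_proba(m, d) >= 0.5) == d$label)
  expect_equal(acc, 1.0)
})

test_that("Gaussian naive Bayes posterior matches the closed-form Bayes rule", {
  withr::local_seed(7)
  n <- 300L
  d <- tibble::tibble(
    mol_id = "x", atom = 1L, element = "C",
    P = c(rnorm(n, 0, 1), rnorm(n, 2, 1.5)),
    Q = rnorm(2L * n),
    label = rep(c(0L, 1L), each = n),
    reaction = NA_character_, isoform = NA_character_, synthetic = FALSE
  )
  m <- fit_som_model(som_classifier("naive_bayes"), d)
  grid <- dplyr::mutate(d[1:50, ], P = seq(-3, 5, length.out = 50),
                        Q = seq(-2, 2, length.out = 50))
  p_hat <- predict_proba(m, grid)
  # independent closed form from the class-conditional Gaussian fits
  lik <- function(cls) {
    0.5 *
      dnorm(grid$P, mean(d$P[d$label == cls]), sd(d$P[d$label == cls])) *
      dnorm(grid$Q, mean(d$Q[d$label == cls]), sd(d$Q[d$label == cls]))
  }
  expect_equal(p_hat, lik(1) / (lik(0) + lik(1)), tolerance = 1e-9)
})

test_that("the RBF network recovers blob structure", {
  d <- make_blobs(seed = 3)
  m <- fit_som_model(som_classifier("rbf_network", seed = 4), d)
  centers <- m$fit$centers[order(m$fit$centers[, 1L]), ]
  expect_equal(unname(centers[1, ]), c(0, 0), tolerance = 0.3)
  expect_equal(unname(centers[2, ]), c(6, 6), tolerance = 0.3)
  held <- make_blobs(seed = 5)
  ba <- classification_metrics(
    confusion(held$label, as.integer(predict_proba(m, held) >= 0.5)))$ba
  expect_gte(ba, 0.95)
})

test_that("the MLP learns a separable problem", {
  d <- make_blobs(seed = 6)
  m <- fit_som_model(som_classifier("mlp", seed = 7), d)
  held <- make_blobs(seed = 8)
  ba <- classification_metrics(
    confusion(held$label, as.integer(predict_proba(m, held) >= 0.5)))$ba
  expect_gte(ba, 0.95)
})

test_that("probabilities are valid, order-invariant, and deterministic given a seed", {
  d <- make_blobs(n_per_class = 80L, seed = 9)
  for (kind in c("naive_bayes", "random_forest", "rbf_network", "mlp")) {
    m <- fit_som_model(som_classifier(kind, seed = 10), d)
    p <- predict_proba(m, d)
    expect_true(all(p >= 0 & p <= 1))
    perm <- sample(nrow(d))
    expect_equal(predict_proba(m, d[perm, ]), p[perm], tolerance = 1e-12)
    m2 <- fit_som_model(som_classifier(kind, seed = 10), d)
    expect_equal(predict_proba(m2, d), p, tolerance = 1e-12)
  }
  expect_error(fit_som_model(som_classifier("mlp"),
                             dplyr::filter(d, label == 0L)),
               "both classes")
})

test_that("a memorizing forest scores a training positive at or above 0.5", {
  d <- make_blobs(n_per_class = 50L, seed = 11)
  m <- fit_som_model(som_classifier("random_forest", seed = 12), d)
  pos <- dplyr::filter(d, label == 1L)
  expect_true(all(predict_proba(m, pos) >= 0.5))
})

test_that("AUC is invariant under monotone transforms of the probabilities", {
  d <- make_blobs(n_per_class = 100L, sep = 2, seed = 13)
  m <- fit_som_model(som_classifier("random_forest", seed = 14), d)
  p <- predict_proba(m, d)
  expect_equal(roc_auc(d$label, p), roc_auc(d$label, qlogis(pmin(pmax(
    p, 1e-6), 1 - 1e-6))), tolerance = 1e-12)
})

test_that("model persistence reloads bit-exactly", {
  d <- make_blobs(n_per_class = 60L, seed = 15)
  m <- fit_som_model(som_classifier("rbf_network", seed = 16), d)
  f <- withr::local_tempfile(fileext = ".rds")
  save_som_model(m, f)
  m2 <- load_som_model(f)
  expect_equal(predict_proba(m2, d), predict_proba(m, d), tolerance = 0)
  expect_error(load_som_model(withr::local_tempfile(fileext = ".rds",
    lines = "")), ".")
})

test_that("tidy and glance summarise fitted models", {
  d <- make_blobs(n_per_class = 60L, seed = 17)
  for (kind in c("naive_bayes", "random_forest", "rbf_network", "mlp")) {
    m <- fit_som_model(som_classifier(kind, seed = 18), d)
    expect_s3_class(tidy(m), "tbl_df")
    g <- glance(m)
    expect_equal(g$n_train, 120L)
    expect_equal(g$kind, kind)
  }
})
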