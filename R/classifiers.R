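#' Classifier specification
#'
#' Describes one of the four classifier configurations used for SOM/non-SOM
#' atom classification. Defaults reproduce the reference settings:
#'
#' * `naive_bayes` — Gaussian naive Bayes on the two continuous features.
#' * `random_forest` — 100 trees, each grown on a bootstrap sample of 70%
#'   of the training rows (bagging fraction 0.7, with replacement).
#' * `rbf_network` — radial-basis-function network: k-means with 2 clusters
#'   pre-trains the Gaussian basis centres, each basis width is the RMS
#'   radius of its cluster, unit activations below `1e-8` are clamped to 0,
#'   and a logistic output layer maps activations to a probability.
#' * `mlp` — multilayer perceptron with two hidden layers of 10 units,
#'   hyperbolic-tangent activations and a sigmoid output, trained by Adam
#'   with early stopping on an internal 20% validation carve-out.
#'
#' @param kind One of `"naive_bayes"`, `"random_forest"`, `"rbf_network"`,
#'   `"mlp"`.
#' @param seed Integer seed controlling all randomness in fitting.
#' @param ... Kind-specific overrides: `ntree`, `bag_fraction` (rf);
#'   `n_clusters`, `activation_floor` (rbf); `hidden`, `max_epochs`,
#'   `patience`, `val_fraction`, `learning_rate` (mlp).
#' @return A `classifier_spec` object.
#' @examples
#' som_classifier("random_forest", seed = 1)
#' @export
som_classifier <- function(kind = c("random_forest", "naive_bayes",
                                    "rbf_network", "mlp"),
                           seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    naive_bayes   = list(),
    random_forest = list(ntree = 100L, bag_fraction = 0.7),
    rbf_network   = list(n_clusters = 2L, activation_floor = 1e-8),
    mlp           = list(hidden = c(10L, 10L), max_epochs = 400L,
                         patience = 25L, val_fraction = 0.2,
                         learning_rate = 0.01)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(kind = kind, hyper = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", x$kind, "seed", x$seed, "\n")
  if (length(x$hyper)) utils::str(x$hyper, give.attr = FALSE)
  invisible(x)
}

#' Fit a SOM classifier
#'
#' Fits the classifier described by `spec` on a per-atom training dataset.
#' Features are the `P`, `Q` columns (normalize them first with a
#' [fit_normalizer()] fitted on this same training partition); the target is
#' `label`. Fitting is deterministic given `spec$seed`.
#'
#' @param spec A [som_classifier()] specification.
#' @param train Training dataset tibble with `P`, `Q`, `label`.
#' @return A `som_model` object usable with [predict_proba()].
#' @export
fit_som_model <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"),
            all(c("P", "Q", "label") %in% names(train)))
  y <- as.integer(train$label)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as.matrix(train[, c("P", "Q")])
  stopifnot(all(is.finite(X)))
  withr::local_seed(spec$seed)
  fit <- switch(spec$kind,
    naive_bayes   = e1071::naiveBayes(x = as.data.frame(X),
                                      y = factor(y, levels = c(0L, 1L))),
    random_forest = fit_rf(X, y, spec$hyper),
    rbf_network   = fit_rbf(X, y, spec$hyper),
    mlp           = fit_mlp(X, y, spec$hyper)
  )
  structure(
    list(spec = spec, fit = fit,
         n_train = nrow(train), class_counts = table(factor(y, c(0L, 1L)))),
    class = "som_model"
  )
}

fit_rf <- function(X, y, hp) {
  n <- nrow(X)
  randomForest::randomForest(
    x = X, y = factor(y, levels = c(0L, 1L)),
    ntree = hp$ntree,
    sampsize = max(2L, ceiling(hp$bag_fraction * n)),
    replace = TRUE
  )
}

fit_rbf <- function(X, y, hp) {
  km <- stats::kmeans(X, centers = hp$n_clusters, nstart = 5L)
  widths <- vapply(seq_len(hp$n_clusters), function(j) {
    pts <- X[km$cluster == j, , drop = FALSE]
    sqrt(mean(rowSums((pts - rep(km$centers[j, ], each = nrow(pts)))^2)))
  }, numeric(1))
  widths[widths == 0 | !is.finite(widths)] <- 1e-6
  A <- rbf_activations(X, km$centers, widths, hp$activation_floor)
  df <- as.data.frame(A)
  df$y <- y
  out <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  list(centers = km$centers, widths = widths,
       floor = hp$activation_floor, glm = out)
}

rbf_activations <- function(X, centers, widths, floor) {
  A <- vapply(seq_len(nrow(centers)), function(j) {
    d2 <- rowSums((X - rep(centers[j, ], each = nrow(X)))^2)
    exp(-d2 / (2 * widths[j]^2))
  }, numeric(nrow(X)))
  A <- matrix(A, nrow = nrow(X))
  A[A < floor] <- 0  # unit activation threshold
  colnames(A) <- paste0("phi", seq_len(ncol(A)))
  A
}

# Two-hidden-layer tanh perceptron with sigmoid output, trained by Adam on
# the cross-entropy loss; early stopping monitors log-loss on a 20% carve-out.
fit_mlp <- function(X, y, hp) {
  n <- nrow(X)
  val_idx <- sample.int(n, max(1L, round(hp$val_fraction * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

  sizes <- c(ncol(X), hp$hidden, 1L)
  init <- function(fan_in, fan_out) {
    matrix(stats::runif(fan_in * fan_out, -1, 1) / sqrt(fan_in),
           fan_in, fan_out)
  }
  W <- purrr::map2(sizes[-length(sizes)], sizes[-1], init)
  b <- purrr::map(sizes[-1], ~ rep(0, .x))

  forward <- function(Xm) {
    A <- list(Xm)
    for (l in seq_along(W)) {
      Z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
      A[[l + 1L]] <- if (l < length(W)) tanh(Z) else stats::plogis(Z)
    }
    A
  }
  logloss <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }

  mW <- purrr::map(W, ~ .x * 0); vW <- mW
  mb <- purrr::map(b, ~ .x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(W = W, b = b, loss = Inf); wait <- 0L; t <- 0L

  for (epoch in seq_len(hp$max_epochs)) {
    A <- forward(Xtr)
    L <- length(W)
    delta <- (A[[L + 1L]] - ytr) / nrow(Xtr)  # dLoss/dZ_out for sigmoid+CE
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(A[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (1 - A[[l]]^2)
    }
    t <- t + 1L
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
      mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
      W[[l]] <- W[[l]] - hp$learning_rate * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - hp$learning_rate * mhb / (sqrt(vhb) + eps)
    }
    val_loss <- logloss(drop(forward(Xva)[[length(sizes)]]), yva)
    if (val_loss < best$loss - 1e-6) {
      best <- list(W = W, b = b, loss = val_loss); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  list(W = best$W, b = best$b, val_loss = best$loss, epochs = epoch)
}

mlp_forward_proba <- function(fit, X) {
  A <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    A <- if (l < L) tanh(Z) else stats::plogis(Z)
  }
  drop(A)
}

#' Predict SOM probabilities
#'
#' Scores per-atom rows with a fitted model, returning the probability of
#' the SOM class (label 1). Threshold at 0.5 for hard labels feeding
#' sensitivity/specificity; use the probabilities directly for AUC and
#' Top-k ranking.
#'
#' @param model A `som_model` from [fit_som_model()].
#' @param newdata Tibble with `P`, `Q` columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "som_model"),
            all(c("P", "Q") %in% names(newdata)))
  X <- as.matrix(newdata[, c("P", "Q")])
  if (!all(is.finite(X))) stop("non-finite features in newdata", call. = FALSE)
  p <- switch(model$spec$kind,
    naive_bayes = stats::predict(model$fit, as.data.frame(X),
                                 type = "raw")[, "1"],
    random_forest = stats::predict(model$fit, X, type = "prob")[, "1"],
    rbf_network = {
      A <- rbf_activations(X, model$fit$centers, model$fit$widths,
                           model$fit$floor)
      drop(stats::predict(model$fit$glm, newdata = as.data.frame(A),
                          type = "response"))
    },
    mlp = mlp_forward_proba(model$fit, X)
  )
  p <- as.numeric(p)
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model>", x$spec$kind, "| trained on", x$n_train, "rows (",
      paste(x$class_counts, collapse = "/"), "per class )\n")
  invisible(x)
}

#' @export
glance.som_model <- function(x, ...) {
  tibble::tibble(
    kind = x$spec$kind,
    n_train = x$n_train,
    n_negative = as.integer(x$class_counts[["0"]]),
    n_positive = as.integer(x$class_counts[["1"]]),
    seed = x$spec$seed
  )
}

#' @export
tidy.som_model <- function(x, ...) {
  switch(x$spec$kind,
    random_forest = {
      imp <- randomForest::importance(x$fit)
      tibble::tibble(term = rownames(imp), importance = imp[, 1L])
    },
    rbf_network = tibble::tibble(
      term = names(stats::coef(x$fit$glm)),
      estimate = unname(stats::coef(x$fit$glm))
    ),
    naive_bayes = {
      tabs <- x$fit$tables
      purrr::map_dfr(names(tabs), function(f) {
        tibble::tibble(term = f, class = rownames(tabs[[f]]),
                       mean = tabs[[f]][, 1L], sd = tabs[[f]][, 2L])
      })
    },
    mlp = tibble::tibble(
      term = paste0("layer", seq_along(x$fit$W)),
      n_weights = vapply(x$fit$W, length, integer(1))
    )
  )
}

#' Save and restore a fitted model
#'
#' Single-file persistence with a format tag; reload is bit-exact.
#'
#' @param model A `som_model`.
#' @param path Destination file.
#' @return `save_som_model()`: invisibly `path`; `load_som_model()`: the model.
#' @export
save_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  saveRDS(list(format = "qnasom_model_v1", model = model), path)
  invisible(path)
}

#' @rdname save_som_model
#' @export
load_som_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "qnasom_model_v1")) {
    stop("not a qnasom model archive: ", path, call. = FALSE)
  }
  obj$model
}
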