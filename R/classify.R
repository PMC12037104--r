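# The reference classifier suite: kNN, ridge, thresholded support-vector
# regression, random forest and a small feed-forward network, with pinned
# hyperparameter grids selected by stratified cross-validated accuracy.

MODEL_FAMILIES <- c("knn", "ridge", "svr_threshold", "random_forest", "dnn")

#' Describe a classifier
#'
#' @param family One of `"knn"`, `"ridge"`, `"svr_threshold"`,
#'   `"random_forest"`, `"dnn"`.
#' @param hyperparameters Named list overriding the pinned defaults:
#'   `k` (kNN neighbours, grid `c(3, 5, 7)`), `lambda` (ridge penalty,
#'   grid `c(0.1, 1, 10)`), `cost` (SVR, 1), `threshold` (SVR decision
#'   threshold on the 0/1 regression output, 0.5), `ntree` (forest size,
#'   200), `hidden` (network layer sizes, `c(32, 16)`), `epochs` (200),
#'   `learning_rate` (1e-3). Grids with more than one value are resolved by
#'   cross-validated accuracy at training time.
#' @param seed Integer seed used for fold assignment and any stochastic
#'   fitting (forest bootstraps, network initialisation).
#' @param cv_folds Folds for hyperparameter selection (default 10; reduced
#'   automatically when a class has fewer samples than folds).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(family = "ridge", hyperparameters = list(),
                       seed = 42, cv_folds = 10) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  defaults <- switch(family,
    knn = list(k = c(3, 5, 7)),
    ridge = list(lambda = c(0.1, 1, 10)),
    svr_threshold = list(cost = 1, threshold = 0.5),
    random_forest = list(ntree = 200),
    dnn = list(hidden = c(32, 16), epochs = 200, learning_rate = 1e-3)
  )
  hp <- modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed), cv_folds = as.integer(cv_folds)),
            class = "model_spec")
}

# 0/1 label encoding; male = 0 / female = 1 by convention, otherwise the
# lexicographically larger level is the positive class.
encode_labels <- function(y) {
  lev <- levels(y)
  if (setequal(lev, c("male", "female"))) lev <- c("male", "female")
  setNames(as.numeric(factor(as.character(y), levels = lev)) - 1,
           NULL) -> code
  list(code = code, levels = lev)
}

#' Train a classifier on a cohort
#'
#' Fits the requested family on every sample of `train` (pass
#' `cohort_subset(x, "train")` for the training split). Hyperparameter
#' grids with more than one candidate are resolved by stratified
#' `cv_folds`-fold cross-validated accuracy; ties keep the first candidate.
#' Fitting is deterministic for a fixed `spec$seed`.
#'
#' @param train A [cohort()] with a complete abundance table and a binary
#'   target.
#' @param spec A [model_spec()].
#' @return A fitted `"metadrift_model"`.
#' @export
train_model <- function(train, spec = model_spec()) {
  stopifnot(inherits(train, "cohort"), inherits(spec, "model_spec"))
  check_abundance(train$abundance, complete = TRUE)
  x <- feature_matrix(train$abundance)
  y <- target_factor(train)
  if (length(unique(y)) < 2) {
    abort(sprintf("training target has a single class (`%s`).", unique(as.character(y))))
  }
  enc <- encode_labels(y)
  hp <- resolve_grid(x, enc, spec)
  fit <- withr::with_seed(spec$seed, fit_family(x, enc, spec$family, hp))
  structure(list(family = spec$family, spec = spec, hyperparameters = hp,
                 fit = fit, features = colnames(x), levels = enc$levels,
                 train_x = if (spec$family == "knn") x else NULL,
                 train_code = if (spec$family == "knn") enc$code else NULL),
            class = "metadrift_model")
}

#' @export
print.metadrift_model <- function(x, ...) {
  cat(sprintf("<metadrift_model> family=%s, %d features; hyperparameters: %s\n",
              x$family, length(x$features),
              paste(names(x$hyperparameters),
                    vapply(x$hyperparameters, function(h) toString(h), ""),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# stratified fold ids, deterministic for a seed
stratified_folds <- function(code, k, seed) {
  fold <- integer(length(code))
  withr::with_seed(seed, {
    for (cl in unique(code)) {
      rows <- which(code == cl)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  fold
}

resolve_grid <- function(x, enc, spec) {
  hp <- spec$hyperparameters
  grid_name <- switch(spec$family, knn = "k", ridge = "lambda", NULL)
  if (is.null(grid_name) || length(hp[[grid_name]]) <= 1) {
    if (!is.null(grid_name)) hp[[grid_name]] <- hp[[grid_name]][1]
    return(hp)
  }
  cand <- hp[[grid_name]]
  k <- min(spec$cv_folds, min(table(enc$code)))
  fold <- stratified_folds(enc$code, k, spec$seed)
  acc <- vapply(cand, function(v) {
    hp_v <- hp; hp_v[[grid_name]] <- v
    correct <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- withr::with_seed(spec$seed,
                              fit_family(x[tr, , drop = FALSE],
                                         list(code = enc$code[tr],
                                              levels = enc$levels),
                                         spec$family, hp_v))
      pred <- predict_code(list(family = spec$family, fit = fit,
                                hyperparameters = hp_v,
                                train_x = x[tr, , drop = FALSE],
                                train_code = enc$code[tr]),
                           x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == enc$code[!tr])
    }
    correct / length(enc$code)
  }, numeric(1))
  hp[[grid_name]] <- cand[which.max(acc)]
  hp
}

fit_family <- function(x, enc, family, hp) {
  switch(family,
    knn = list(),  # lazy learner; training data kept on the model object
    ridge = glmnet::glmnet(x, enc$code, alpha = 0, family = "gaussian",
                           lambda = sort(unique(c(hp$lambda, 0.1, 1, 10)),
                                         decreasing = TRUE)),
    svr_threshold = e1071::svm(x, enc$code, type = "eps-regression",
                               cost = hp$cost),
    random_forest = randomForest::randomForest(
      x, factor(enc$code, levels = c(0, 1)), ntree = hp$ntree),
    dnn = mlp_fit(x, enc$code, hidden = hp$hidden, epochs = hp$epochs,
                  lr = hp$learning_rate)
  )
}

# predicted 0/1 codes for a model-like list
predict_code <- function(model, x) {
  hp <- model$hyperparameters
  switch(model$family,
    knn = {
      k <- hp$k[1]
      as.integer(as.character(class::knn(model$train_x, x,
                                         factor(model$train_code), k = k)))
    },
    ridge = as.integer(predict(model$fit, x, s = hp$lambda[1]) > 0.5),
    svr_threshold = as.integer(predict(model$fit, x) > hp$threshold),
    random_forest = as.integer(as.character(predict(model$fit, x))),
    dnn = as.integer(mlp_predict(model$fit, x) > 0.5)
  )
}

#' Predict class labels for new samples
#'
#' @param object A fitted `"metadrift_model"`.
#' @param abundance Complete abundance tibble with the model's features.
#' @param ... Unused.
#' @return Factor of predicted labels with the model's level order.
#' @export
predict.metadrift_model <- function(object, abundance, ...) {
  check_abundance(abundance, complete = TRUE)
  feats <- feature_names(abundance)
  if (!setequal(feats, object$features)) {
    abort("feature mismatch between model and data.")
  }
  x <- feature_matrix(abundance)[, object$features, drop = FALSE]
  code <- withr::with_seed(object$spec$seed, predict_code(object, x))
  factor(object$levels[code + 1], levels = object$levels)
}

#' Evaluate a fitted classifier on a cohort split
#'
#' @param model A `"metadrift_model"`.
#' @param data A [cohort()].
#' @param split Which split tag(s) to evaluate (default `"test"`); use
#'   `"all"` for every sample regardless of assignment.
#' @return A `"prediction_result"`: list with `predictions` (tibble
#'   `sample_id`, `truth`, `predicted`, `correct`) and `accuracy`.
#' @export
evaluate <- function(model, data, split = "test") {
  stopifnot(inherits(model, "metadrift_model"), inherits(data, "cohort"))
  sub <- if (identical(split, "all")) data else cohort_subset(data, split)
  pred <- predict(model, sub$abundance)
  truth <- factor(as.character(target_factor(sub)), levels = model$levels)
  tab <- tibble(sample_id = sub$abundance$sample_id,
                truth = as.character(truth),
                predicted = as.character(pred),
                correct = truth == pred)
  structure(list(predictions = tab, accuracy = mean(tab$correct),
                 family = model$family, split = split),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s on %s: accuracy %.3f (n=%d)\n",
              x$family, toString(x$split), x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prediction_result <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.prediction_result <- function(x, ...) {
  tibble(family = x$family, split = toString(x$split),
         accuracy = x$accuracy, n = nrow(x$predictions))
}

# ---- minimal feed-forward network (ReLU hidden, sigmoid output, Adam) ----

mlp_fit <- function(x, y01, hidden = c(32, 16), epochs = 200, lr = 1e-3,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  n <- nrow(x); y <- as.numeric(y01)
  for (t in seq_len(epochs)) {
    # forward (full batch)
    a <- vector("list", L + 1L); a[[1]] <- x
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
    }
    p <- a[[L + 1]]
    delta <- (p - y) / n            # dL/dz at sigmoid + BCE
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      cor1 <- 1 - beta1^t; cor2 <- 1 - beta2^t
      W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
    }
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_predict <- function(fit, x) {
  L <- length(fit$W)
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}
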