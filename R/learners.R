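# Backends for the eight base-classification algorithms. Each learner is
# fitted through a uniform internal interface: fit_learner() returns an
# object whose predict_learner() method yields P(active) in [0, 1].
#
# Algorithm mapping: GLM = ridge-penalized binomial regression, CART = a
# single rpart decision tree, PLS = PLS-DA with class-score softmax
# probabilities, MLP = one-hidden-layer feed-forward network; RF, SVM, XGB,
# KNN as named. All fits are seeded and single-threaded.

.ALGORITHMS <- c("RF", "GLM", "SVM", "XGB", "KNN", "PLS", "CART", "MLP")

#' The eight supported base-classification algorithms
#' @return Character vector of algorithm codes.
#' @export
algorithms <- function() .ALGORITHMS

#' Default hyperparameter grid for a base algorithm
#'
#' Small, documented grids searched exhaustively during tuning. RF's
#' features-per-split is expressed as a multiple of sqrt(p) and resolved at
#' fit time; SVM's RBF gamma as a multiple of 1/p. All values can be
#' overridden by passing a custom grid to [tune_and_fit()].
#'
#' @param algorithm One of [algorithms()].
#' @return Named list of parameter value vectors.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    RF   = list(mtry_mult = c(0.5, 1, 2), num_trees = 500),
    GLM  = list(lambda = c(0, 0.01, 1)),
    SVM  = list(cost = c(0.1, 1, 10), gamma_mult = c(1, 10)),
    XGB  = list(max_depth = c(3, 6), eta = c(0.1, 0.3), nrounds = 200),
    KNN  = list(k = c(3, 5, 7, 9)),
    PLS  = list(ncomp = c(2, 4, 8)),
    CART = list(cp = c(0.001, 0.01, 0.1)),
    MLP  = list(size = c(5, 10, 20)),
    abort(sprintf("unknown algorithm '%s'", algorithm))
  )
}

# Cartesian product of a named grid, in fixed enumeration order (first
# parameter varying fastest); ties during tuning resolve to the first row.
grid_candidates <- function(grid) {
  if (!length(grid)) abort("empty hyperparameter grid")
  df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

feature_names <- function(p) paste0("f", seq_len(p))

fit_learner <- function(algorithm, X, y01, params, seed) {
  if (!algorithm %in% .ALGORITHMS) abort(sprintf("unknown algorithm '%s'", algorithm))
  if (length(unique(y01)) < 2L) abort("training labels contain a single class")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  colnames(X) <- feature_names(ncol(X))
  keep <- which(matrixStats_colVar(X) > 0)
  if (length(keep) == 0L) {
    warn("all feature columns are constant; fitting a prevalence-only model")
    return(structure(list(algorithm = "CONST", p = ncol(X),
                          prob = mean(y01)), class = "learner_fit"))
  }
  # distance/projection-based learners are sensitive to constant columns;
  # drop them and remember the mask for prediction
  use_mask <- algorithm %in% c("KNN", "PLS")
  Xf <- if (use_mask) X[, keep, drop = FALSE] else X
  fit <- withr::with_seed(seed, switch(algorithm,
    RF = {
      mtry <- max(1L, min(ncol(Xf), round(params$mtry_mult * sqrt(ncol(Xf)))))
      ranger::ranger(x = Xf, y = factor(y01, levels = c(0, 1)),
                     num.trees = params$num_trees %||% 500,
                     mtry = mtry, probability = TRUE,
                     num.threads = 1L, seed = seed)
    },
    GLM = suppressWarnings(
      glmnet::glmnet(Xf, y01, family = "binomial", alpha = 0,
                     lambda = params$lambda, standardize = FALSE)),
    SVM = e1071::svm(x = Xf, y = factor(y01, levels = c(0, 1)),
                     kernel = "radial", cost = params$cost,
                     gamma = (params$gamma_mult %||% 1) / ncol(Xf),
                     probability = TRUE, scale = FALSE),
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(Xf, label = y01),
      nrounds = params$nrounds %||% 200, verbose = 0),
    KNN = list(X = Xf, y = factor(y01, levels = c(0, 1)), k = params$k),
    PLS = {
      ncomp <- max(1L, min(params$ncomp, ncol(Xf), nrow(Xf) - 1L))
      mixOmics::plsda(Xf, factor(y01, levels = c(0, 1)), ncomp = ncomp,
                      scale = FALSE)
    },
    CART = {
      df <- data.frame(.y = factor(y01, levels = c(0, 1)), Xf,
                       check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp))
    },
    MLP = {
      utils::capture.output(m <- nnet::nnet(
        x = Xf, y = y01, size = params$size, maxit = 200,
        decay = 0.1, trace = FALSE, MaxNWts = 1e7, entropy = TRUE))
      m
    }
  ))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 p = ncol(X), keep = if (use_mask) keep else NULL,
                 seed = seed),
            class = "learner_fit")
}

predict_learner <- function(object, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (object$algorithm == "CONST") {
    return(rep(object$prob, nrow(X)))
  }
  if (ncol(X) != object$p) {
    abort(sprintf("feature width mismatch: model expects %d columns, got %d",
                  object$p, ncol(X)))
  }
  if (nrow(X) == 0L) return(numeric(0))
  colnames(X) <- feature_names(ncol(X))
  if (!is.null(object$keep)) X <- X[, object$keep, drop = FALSE]
  fit <- object$fit
  p <- switch(object$algorithm,
    RF = {
      pr <- predict(fit, data = X, num.threads = 1L)$predictions
      pr[, "1"]
    },
    GLM = as.numeric(predict(fit, newx = X, type = "response",
                             s = object$params$lambda)),
    SVM = {
      pr <- predict(fit, newdata = X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    XGB = predict(fit, newdata = xgboost::xgb.DMatrix(X)),
    KNN = withr::with_seed(object$seed, {
      pred <- class::knn(train = fit$X, test = X, cl = fit$y, k = fit$k,
                         prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    }),
    PLS = {
      pr <- predict(fit, newdata = X)$predict
      sc <- pr[, , dim(pr)[3], drop = TRUE]
      if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1,
                                         dimnames = list(NULL, colnames(pr)))
      e <- exp(sc - apply(sc, 1, max))
      (e / rowSums(e))[, "1"]
    },
    CART = {
      df <- data.frame(X, check.names = FALSE)
      predict(fit, newdata = df, type = "prob")[, "1"]
    },
    MLP = as.numeric(predict(fit, X))
  )
  unname(pmin(1, pmax(0, as.numeric(p))))
}

# column variances without an extra dependency
matrixStats_colVar <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}
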