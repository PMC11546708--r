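#' Classifier specification
#'
#' A pluggable description of one classification model family for the
#' ensemble: how to draw hyperparameter candidates, how to fit, and how
#' to predict a cancer probability in `[0, 1]`. Predictions at 0.5 give
#' the model's binary vote.
#'
#' @param name Unique model name.
#' @param sample_params `function(n)` returning a list of `n` candidate
#'   hyperparameter lists (drawn from the current RNG stream); the first
#'   candidate should be a sensible default. For families without
#'   tunable hyperparameters it may always return one empty candidate.
#' @param fit `function(X, y, params)` with `X` a numeric matrix
#'   (standardized by the harness) and `y` integer 0/1; returns a model.
#' @param predict `function(model, X)` returning cancer probabilities.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name, sample_params, fit, predict) {
  stopifnot(is.character(name), is.function(sample_params),
            is.function(fit), is.function(predict))
  structure(list(name = name, sample_params = sample_params, fit = fit,
                 predict = predict), class = "classifier_spec")
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

#' Default classifier suite
#'
#' Eight diverse model families (nine fitted models: the support vector
#' machine appears with radial and polynomial kernels): regularized
#' logistic regression, linear discriminant analysis, radial and
#' polynomial kernel SVMs, random forest, gradient boosting, k-nearest
#' neighbours, Gaussian naive Bayes, and a seed-averaged single-hidden-
#' layer neural network. The suite is a registry: pass a subset of
#' names, or your own [classifier_spec()] list, anywhere a classifier
#' suite is accepted.
#'
#' @param names Optional subset of suite names to return.
#' @return Named list of `classifier_spec` objects.
#' @export
default_classifiers <- function(names = NULL) {
  suite <- list(
    glmnet_logistic = classifier_spec(
      "glmnet_logistic",
      sample_params = function(n) {
        out <- list(list(alpha = 0.5, lambda = 0.01))
        while (length(out) < n)
          out[[length(out) + 1L]] <-
            list(alpha = runif1(0, 1), lambda = 10^runif1(-4, 0))
        out[seq_len(n)]
      },
      fit = function(X, y, params) {
        # glmnet requires >= 2 columns; pad one-lipid signatures
        pad <- ncol(X) < 2
        if (pad) X <- cbind(X, `.pad` = 0)
        list(fit = glmnet::glmnet(X, y, family = "binomial",
                                  alpha = params$alpha,
                                  lambda = params$lambda), pad = pad)
      },
      predict = function(model, X) {
        if (model$pad) X <- cbind(X, `.pad` = 0)
        as.numeric(stats::predict(model$fit, newx = X, type = "response"))
      }),
    lda = classifier_spec(
      "lda",
      sample_params = function(n) rep(list(list()), n),
      fit = function(X, y, params) {
        suppressWarnings(MASS::lda(X, grouping = factor(y, levels = 0:1)))
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model, X)$posterior[, "1"])
      }),
    svm_radial = classifier_spec(
      "svm_radial",
      sample_params = function(n) {
        out <- list(list(cost = 1, gamma = 0))  # 0 = auto (1/p)
        while (length(out) < n)
          out[[length(out) + 1L]] <-
            list(cost = 10^runif1(-2, 2), gamma = 10^runif1(-3, 0))
        out[seq_len(n)]
      },
      fit = function(X, y, params) {
        g <- if (params$gamma <= 0) 1 / ncol(X) else params$gamma
        e1071::svm(X, factor(y, levels = 0:1), kernel = "radial",
                   cost = params$cost, gamma = g, scale = FALSE)
      },
      predict = function(model, X) svm_prob(model, X)),
    svm_poly = classifier_spec(
      "svm_poly",
      sample_params = function(n) {
        out <- list(list(cost = 1, degree = 2))
        while (length(out) < n)
          out[[length(out) + 1L]] <-
            list(cost = 10^runif1(-2, 2), degree = sample(2:3, 1))
        out[seq_len(n)]
      },
      fit = function(X, y, params) {
        e1071::svm(X, factor(y, levels = 0:1), kernel = "polynomial",
                   degree = params$degree, cost = params$cost,
                   coef0 = 1, scale = FALSE)
      },
      predict = function(model, X) svm_prob(model, X)),
    random_forest = classifier_spec(
      "random_forest",
      sample_params = function(n) {
        out <- list(list(mtry_frac = 0, min_node = 1))  # 0 = auto
        while (length(out) < n)
          out[[length(out) + 1L]] <-
            list(mtry_frac = runif1(0.1, 0.9), min_node = sample(1:5, 1))
        out[seq_len(n)]
      },
      fit = function(X, y, params) {
        mtry <- if (params$mtry_frac <= 0) NULL
                else max(1L, floor(params$mtry_frac * ncol(X)))
        ranger::ranger(x = X, y = factor(y, levels = 0:1), num.trees = 200,
                       mtry = mtry, min.node.size = params$min_node,
                       probability = TRUE, num.threads = 1,
                       seed = sample.int(.Machine$integer.max, 1))
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model, data = X,
                                  num.threads = 1)$predictions[, "1"])
      }),
    gradient_boosting = classifier_spec(
      "gradient_boosting",
      sample_params = function(n) {
        out <- list(list(nrounds = 50, eta = 0.3, max_depth = 3))
        while (length(out) < n)
          out[[length(out) + 1L]] <-
            list(nrounds = sample(20:150, 1), eta = 10^runif1(-2, -0.2),
                 max_depth = sample(1:6, 1))
        out[seq_len(n)]
      },
      fit = function(X, y, params) {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = params$eta,
                        max_depth = params$max_depth, nthread = 1,
                        seed = sample.int(.Machine$integer.max, 1)),
          data = xgboost::xgb.DMatrix(X, label = y),
          nrounds = params$nrounds, verbose = 0)
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X)))
      }),
    knn = classifier_spec(
      "knn",
      sample_params = function(n) {
        out <- list(list(k = 5))
        while (length(out) < n)
          out[[length(out) + 1L]] <- list(k = sample(seq(3, 15, 2), 1))
        out[seq_len(n)]
      },
      fit = function(X, y, params) list(X = X, y = y, k = params$k),
      predict = function(model, X) {
        cl <- class::knn(model$X, X, factor(model$y, levels = 0:1),
                         k = model$k, prob = TRUE)
        pr <- attr(cl, "prob")
        ifelse(cl == "1", pr, 1 - pr)
      }),
    naive_bayes = classifier_spec(
      "naive_bayes",
      sample_params = function(n) rep(list(list()), n),
      fit = function(X, y, params) {
        e1071::naiveBayes(as.data.frame(X), factor(y, levels = 0:1))
      },
      predict = function(model, X) {
        as.numeric(stats::predict(model, as.data.frame(X),
                                  type = "raw")[, "1"])
      }),
    avg_nnet = classifier_spec(
      "avg_nnet",
      sample_params = function(n) {
        out <- list(list(size = 3, decay = 0.1))
        while (length(out) < n)
          out[[length(out) + 1L]] <-
            list(size = sample(1:7, 1), decay = 10^runif1(-3, 0))
        out[seq_len(n)]
      },
      fit = function(X, y, params) {
        # average over random restarts, the usual remedy for the
        # sensitivity of small nets to their initial weights
        lapply(1:3, function(i)
          nnet::nnet(X, y, size = params$size, decay = params$decay,
                     maxit = 150, entropy = TRUE, trace = FALSE))
      },
      predict = function(model, X) {
        rowMeans(vapply(model,
                        function(m) as.numeric(stats::predict(m, X)),
                        numeric(nrow(X))))
      })
  )
  if (is.null(names)) return(suite)
  miss <- setdiff(names, base::names(suite))
  if (length(miss)) stop("unknown classifier(s): ",
                         paste(miss, collapse = ", "))
  suite[names]
}

# SVM decision values mapped through a logistic link: monotone in the
# margin, orientation fixed so larger = more cancer-like. Same binary
# vote as the raw sign, defined probability-like score for ROC work.
# A positive decision value favours the FIRST class named in the
# column label ("0/1" means positive = class 0), hence the sign flip.
svm_prob <- function(model, X) {
  dv <- attr(stats::predict(model, X, decision.values = TRUE),
             "decision.values")
  flip <- if (colnames(dv)[1] == "0/1") -1 else 1
  stats::plogis(flip * as.numeric(dv))
}
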