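#' Specify a classifier
#'
#' The five classifier families used for voice-type discrimination, each
#' with its conventional hyperparameters: linear discriminant (`"ld"`);
#' medium decision tree (`"dt"`, at most 20 splits, Gini index); linear
#' support vector machine (`"svm"`, one-versus-one multiclass); weighted
#' k-nearest neighbours (`"knn"`, k = 10, Euclidean distance,
#' inverse-squared-distance weights); and a single-hidden-layer neural
#' network (`"nn"`, 100 units, softmax output trained under cross-entropy
#' with validation-based early stopping).
#'
#' @param kind One of `"ld"`, `"dt"`, `"svm"`, `"knn"`, `"nn"`.
#' @param ... Hyperparameter overrides: `max_splits` (dt), `k` (knn),
#'   `hidden` (nn), `decay` (nn weight decay).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("ld", "dt", "svm", "knn", "nn"), ...) {
  kind <- match.arg(kind)
  hyper <- switch(kind,
    ld  = list(),
    dt  = list(max_splits = 20L),
    svm = list(),
    knn = list(k = 10L),
    nn  = list(hidden = 100L, decay = 0, maxit_chunk = 50L,
               max_chunks = 8L, patience = 2L))
  over <- list(...)
  hyper[names(over)] <- over
  structure(list(kind = kind, hyper = hyper), class = "classifier_spec")
}

# Fit on a standardized feature matrix.  Returns an opaque model object
# carrying what .predict_vt needs.
.fit_vt <- function(spec, x, y) {
  y <- droplevels(as.factor(y))
  switch(spec$kind,
    ld = list(kind = "ld", fit = MASS::lda(x, grouping = y), levels = levels(y)),
    dt = {
      df <- data.frame(.y = y, x)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(cp = 0, xval = 0,
                                                         minsplit = 5))
      cpt <- fit$cptable
      ok <- which(cpt[, "nsplit"] <= spec$hyper$max_splits)
      fit <- rpart::prune(fit, cp = cpt[max(ok), "CP"])
      list(kind = "dt", fit = fit, levels = levels(y))
    },
    svm = list(kind = "svm",
               fit = e1071::svm(x, y, kernel = "linear", scale = FALSE),
               levels = levels(y)),
    knn = list(kind = "knn", x = x, y = y, k = spec$hyper$k,
               levels = levels(y)),
    nn = .fit_nn(spec, x, y))
  }

# Single-hidden-layer softmax network trained under cross-entropy.
# x_val/y_val enable early stopping: training proceeds in chunks and keeps
# the weights with the best validation cross-entropy, stopping after
# `patience` chunks without improvement.
.fit_nn <- function(spec, x, y, x_val = NULL, y_val = NULL) {
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  y_ind <- nnet::class.ind(y)
  h <- spec$hyper
  max_wts <- (ncol(x) + 1) * h$hidden + (h$hidden + 1) * length(lev) + 10
  fit <- nnet::nnet(x, y_ind, size = h$hidden, softmax = TRUE,
                    decay = h$decay, maxit = h$maxit_chunk,
                    MaxNWts = max_wts, trace = FALSE)
  if (is.null(x_val))
    return(list(kind = "nn", fit = fit, levels = lev))

  val_loss <- function(f) {
    p <- pmax(predict(f, x_val), 1e-12)
    -mean(log(p[cbind(seq_along(y_val), match(y_val, lev))]))
  }
  best <- fit; best_loss <- val_loss(fit); bad <- 0L
  for (chunk in seq_len(h$max_chunks - 1L)) {
    fit <- nnet::nnet(x, y_ind, size = h$hidden, softmax = TRUE,
                      decay = h$decay, maxit = h$maxit_chunk,
                      MaxNWts = max_wts, Wts = fit$wts, trace = FALSE)
    loss <- val_loss(fit)
    if (is.finite(loss) && loss < best_loss - 1e-6) {
      best <- fit; best_loss <- loss; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= h$patience) break
    }
  }
  if (!all(is.finite(best$wts))) stop("NN training did not converge",
                                      call. = FALSE)
  list(kind = "nn", fit = best, levels = lev)
}

# Predict classes and per-class scores on a standardized matrix.
.predict_vt <- function(model, x) {
  lev <- model$levels
  switch(model$kind,
    ld = {
      p <- predict(model$fit, x)
      list(class = factor(as.character(p$class), lev),
           scores = p$posterior[, lev, drop = FALSE])
    },
    dt = {
      p <- predict(model$fit, data.frame(x), type = "prob")
      cls <- lev[max.col(p[, lev, drop = FALSE], ties.method = "first")]
      list(class = factor(cls, lev), scores = p[, lev, drop = FALSE])
    },
    svm = {
      p <- predict(model$fit, x, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      sc <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
      # one-vs-one margins: accumulate signed margins per class, so ties in
      # the pairwise vote resolve by summed decision-function margin
      for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        sc[, pair[1]] <- sc[, pair[1]] + dv[, cn]
        sc[, pair[2]] <- sc[, pair[2]] - dv[, cn]
      }
      list(class = factor(as.character(p), lev), scores = sc)
    },
    knn = {
      d2 <- outer(rowSums(x^2), rowSums(model$x^2), "+") -
        2 * tcrossprod(x, model$x)
      d2[d2 < 0] <- 0
      sc <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
      for (i in seq_len(nrow(x))) {
        nb <- order(d2[i, ])[seq_len(min(model$k, ncol(d2)))]
        w <- 1 / (d2[i, nb] + 1e-12)
        for (l in lev) sc[i, l] <- sum(w[model$y[nb] == l])
        sc[i, ] <- sc[i, ] / sum(sc[i, ])
      }
      list(class = factor(lev[max.col(sc, ties.method = "first")], lev),
           scores = sc)
    },
    nn = {
      p <- predict(model$fit, x)
      if (is.null(dim(p))) p <- cbind(p, 1 - p)
      colnames(p) <- model$levels
      list(class = factor(lev[max.col(p, ties.method = "first")], lev),
           scores = p)
    })
}

# Column-wise z-scoring with training-set statistics.
.standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
}
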