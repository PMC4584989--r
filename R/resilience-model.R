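#' Robust baseline-profile outlier screen
#'
#' Flags subjects whose baseline cortisol or baseline STAI is extreme under a
#' robust z-score: `|x - median| / (1.4826 * MAD) > z_cut` on either feature.
#' The default cut of 2.5 is calibrated so that clearly discordant values of
#' the kind the screen exists for (cortisol near 1.4 micrograms/dl or STAI
#' near 70 against a cohort at 0.38 +/- 0.28 and 30 +/- 9) are flagged
#' reliably even in cohorts of ~20, where the sample MAD of a right-skewed
#' biomarker is itself noisy. When a feature's MAD is zero the screen falls
#' back to the
#' mean/SD rule for that feature (logged). Flagged subjects are excluded from
#' classifier training but retained in all reports.
#'
#' @param profiles `data.frame` with columns `subject_id`,
#'   `cortisol_baseline`, `stai_baseline` (additional columns pass through);
#'   at least 5 rows.
#' @param z_cut robust z-score threshold.
#' @return `profiles` with logical column `outlier` and character column
#'   `outlier_reason` (`NA` where not flagged) appended.
#' @export
#' @examples
#' pr <- data.frame(subject_id = sprintf("s%02d", 1:10),
#'                  cortisol_baseline = c(rep(0.4, 9), 1.9),
#'                  stai_baseline = rep(30, 10))
#' flag_outliers(pr)$outlier
flag_outliers <- function(profiles, z_cut = 2.5) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) < 5L) sr_stop("outlier screen requires >= 5 subjects")
  rz <- function(x, what) {
    med <- median(x)
    s <- mad(x)  # 1.4826 * median absolute deviation
    if (s == 0) {
      stage_log("model", "zero MAD on ", what, "; falling back to mean/SD")
      s <- sd(x)
      med <- mean(x)
      if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    }
    abs(x - med) / s
  }
  zc <- rz(profiles$cortisol_baseline, "cortisol")
  zs <- rz(profiles$stai_baseline, "STAI")
  profiles$outlier <- zc > z_cut | zs > z_cut
  reason <- rep(NA_character_, nrow(profiles))
  reason[zc > z_cut] <- sprintf("cortisol robust z = %.1f", zc[zc > z_cut])
  both <- zc > z_cut & zs > z_cut
  reason[zs > z_cut] <- sprintf("STAI robust z = %.1f", zs[zs > z_cut])
  reason[both] <- "cortisol and STAI extreme"
  profiles$outlier_reason <- reason
  profiles
}

# hinge "optimal" schedule constants (dloss(-typw) = 1 for hinge)
sgd_schedule <- function(alpha) {
  typw <- sqrt(1 / sqrt(alpha))
  eta0 <- typw / max(1, 1)
  list(t0 = 1 / (eta0 * alpha))
}

#' Fit the SGD hinge-loss linear resilience classifier
#'
#' One-vs-rest linear model over the two baseline features (cortisol, STAI),
#' trained by stochastic gradient descent on the hinge loss with an L2
#' penalty (`alpha = 1e-4`) and the "optimal" learning-rate schedule
#' `eta_t = 1 / (alpha * (t0 + t))`. Features are standardized to train-set
#' mean/SD by default (`classifier.standardize`; disable for boundary plots
#' on raw axes). Training is resubstitution-style: the full non-outlier,
#' labeled set learns the decision boundaries. Epoch order is shuffled under
#' the recorded seed, so refits with identical inputs are identical.
#'
#' @param features `data.frame` with columns `cortisol_baseline`,
#'   `stai_baseline`, `label`; rows already screened (non-outlier,
#'   experimental, labeled). At least two classes must be present.
#' @param config an [analysis_config()] (keys `classifier.*`).
#' @param seed integer seed for the per-epoch shuffle.
#' @return an object of class `sgd_classifier`: per-class weights (2 per
#'   class) and intercepts, class names, the standardization record, and the
#'   hyperparameters (alpha, loss, schedule, epochs run, seed).
#' @export
fit_classifier <- function(features, config = analysis_config(), seed = 1L) {
  stopifnot(all(c("cortisol_baseline", "stai_baseline", "label") %in%
                  names(features)))
  classes <- sort(unique(features$label))
  if (length(classes) < 2L)
    sr_stop("degenerate training set: a single class present")
  X <- as.matrix(features[, c("cortisol_baseline", "stai_baseline")])
  storage.mode(X) <- "double"
  if (isTRUE(config$classifier.standardize)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- c(0, 0); scl <- c(1, 1)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (all(apply(Xs, 2, sd_pop) < 1e-12))
    stage_log("model", "identical feature values for all subjects; ",
              "model will sit at chance level")
  Y <- outer(features$label, classes, function(a, b) ifelse(a == b, 1, -1))
  n <- nrow(Xs); k <- length(classes)
  alpha <- config$classifier.alpha
  t0 <- sgd_schedule(alpha)$t0
  W <- matrix(0, nrow = k, ncol = 2)
  b <- numeric(k)
  tstep <- 0
  best <- Inf; stall <- 0L; epochs_run <- 0L
  with_seed(seed, {
    for (ep in seq_len(config$classifier.max_epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        tstep <- tstep + 1
        eta <- 1 / (alpha * (t0 + tstep))
        x <- Xs[i, ]
        s <- drop(W %*% x) + b
        margin_bad <- Y[i, ] * s < 1
        W <- W * (1 - eta * alpha)
        if (any(margin_bad)) {
          W[margin_bad, ] <- W[margin_bad, , drop = FALSE] +
            eta * Y[i, margin_bad] %o% x
          b[margin_bad] <- b[margin_bad] + eta * Y[i, margin_bad]
        }
      }
      epochs_run <- ep
      S <- Xs %*% t(W) + matrix(b, n, k, byrow = TRUE)
      loss <- mean(pmax(0, 1 - Y * S)) + alpha * sum(W^2) / 2
      if (loss > best - config$classifier.tol) stall <- stall + 1L
      else stall <- 0L
      best <- min(best, loss)
      if (stall >= 5L) break
    }
  })
  structure(list(classes = classes, weights = W, intercepts = b,
                 center = ctr, scale = scl,
                 hyper = list(alpha = alpha, loss = "hinge",
                              learning_rate = "optimal", t0 = t0,
                              max_epochs = config$classifier.max_epochs,
                              tol = config$classifier.tol,
                              epochs_run = epochs_run, seed = seed,
                              standardize = isTRUE(config$classifier.standardize))),
            class = "sgd_classifier")
}

#' @export
print.sgd_classifier <- function(x, ...) {
  cat(sprintf("<sgd_classifier> %d classes (%s), hinge/L2 alpha=%g, %d epochs\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$hyper$alpha, x$hyper$epochs_run))
  invisible(x)
}

#' Predict resilience-trend classes
#'
#' Argmax of the per-class linear scores over standardized features.
#'
#' @param object an [fit_classifier()] model.
#' @param newdata `data.frame` with `cortisol_baseline` and `stai_baseline`.
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.sgd_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, c("cortisol_baseline", "stai_baseline")])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  S <- Xs %*% t(object$weights) +
    matrix(object$intercepts, nrow(Xs), length(object$classes), byrow = TRUE)
  object$classes[max.col(S, ties.method = "first")]
}

#' Confusion summary from label vectors
#'
#' @param truth,predicted character vectors of equal length.
#' @return an object of class `confusion_summary`: the confusion `table`
#'   (rows = truth), per-class correct counts, `accuracy` (= correct / total,
#'   exact fraction) and `n`.
#' @export
#' @examples
#' confusion_summary(c("a", "a", "b"), c("a", "b", "b"))$accuracy
confusion_summary <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  lev <- sort(unique(c(truth, predicted)))
  tab <- table(truth = factor(truth, lev), predicted = factor(predicted, lev))
  correct <- diag(tab)
  structure(list(confusion = tab, per_class_correct = correct,
                 per_class_n = rowSums(tab),
                 accuracy = sum(correct) / length(truth),
                 n = length(truth)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> accuracy %.1f%% (%d/%d)\n",
              100 * x$accuracy, sum(x$per_class_correct), x$n))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a classifier on labeled features
#'
#' Resubstitution (training-set) evaluation by default, matching the
#' small-sample protocol in which the full non-outlier set both trains and
#' scores the model; pass held-out rows for a validation estimate.
#'
#' @param model a fitted model with a `predict` method over the two baseline
#'   features.
#' @param features labeled `data.frame` (columns `cortisol_baseline`,
#'   `stai_baseline`, `label`).
#' @return a [confusion_summary()].
#' @export
evaluate <- function(model, features) {
  pred <- predict(model, features)
  confusion_summary(features$label, pred)
}

#' Comparison classifiers over the same two features
#'
#' The model-selection alternatives: logistic regression, perceptron
#' learning, linear-kernel SVM, 1 nearest-neighbor, Gaussian naive Bayes and
#' Gaussian mixture discriminant analysis, each fitted on (cortisol, STAI)
#' with the same evaluation contract as the SGD model.
#'
#' @param features labeled `data.frame` as for [fit_classifier()].
#' @param method one of `"logistic"`, `"perceptron"`, `"svm_linear"`,
#'   `"1nn"`, `"gnb"`, `"gmm"`.
#' @param seed integer seed (perceptron shuffles; others deterministic).
#' @return list with `model` (class `alt_classifier`, has a `predict`
#'   method) and `summary` (resubstitution [confusion_summary()]).
#' @export
alternative_classifier <- function(features, method, seed = 1L) {
  methods <- c("logistic", "perceptron", "svm_linear", "1nn", "gnb", "gmm")
  if (!is.character(method) || length(method) != 1L || !method %in% methods)
    sr_stop(paste0("unknown method: ", paste(method, collapse = ","),
                   " (choose one of ", paste(methods, collapse = ", "), ")"))
  X <- features[, c("cortisol_baseline", "stai_baseline")]
  y <- factor(features$label)
  fit <- switch(
    method,
    logistic = nnet::multinom(y ~ cortisol_baseline + stai_baseline,
                              data = cbind(X, y = y), trace = FALSE),
    perceptron = fit_perceptron(as.matrix(X), y, seed),
    svm_linear = e1071::svm(x = X, y = y, kernel = "linear", scale = TRUE),
    `1nn` = list(train = X, cl = y),
    gnb = e1071::naiveBayes(x = X, y = y),
    # mclust resolves helper functions in the caller's environment, so the
    # call is evaluated with the mclust namespace as lookup parent
    gmm = eval(quote(MclustDA(X, y, modelType = "MclustDA", verbose = FALSE)),
               envir = list2env(list(X = X, y = y),
                                parent = asNamespace("mclust")))
  )
  model <- structure(list(method = method, fit = fit), class = "alt_classifier")
  pred <- predict(model, X)
  list(model = model, summary = confusion_summary(as.character(y), pred))
}

# plain multiclass perceptron (OVR, unit learning rate, update on mistakes)
fit_perceptron <- function(X, y, seed, epochs = 100L) {
  classes <- levels(y)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  Y <- outer(as.character(y), classes, function(a, b) ifelse(a == b, 1, -1))
  W <- matrix(0, length(classes), ncol(X)); b <- numeric(length(classes))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nrow(Xs))) {
        s <- drop(W %*% Xs[i, ]) + b
        wrong <- Y[i, ] * s <= 0
        if (any(wrong)) {
          W[wrong, ] <- W[wrong, , drop = FALSE] + Y[i, wrong] %o% Xs[i, ]
          b[wrong] <- b[wrong] + Y[i, wrong]
        }
      }
    }
  })
  list(classes = classes, W = W, b = b, center = ctr, scale = scl)
}

#' @export
predict.alt_classifier <- function(object, newdata, ...) {
  X <- newdata[, c("cortisol_baseline", "stai_baseline")]
  out <- switch(
    object$method,
    logistic = as.character(predict(object$fit, newdata = X)),
    perceptron = {
      f <- object$fit
      Xs <- sweep(sweep(as.matrix(X), 2, f$center), 2, f$scale, `/`)
      S <- Xs %*% t(f$W) + matrix(f$b, nrow(Xs), length(f$classes), byrow = TRUE)
      f$classes[max.col(S, ties.method = "first")]
    },
    svm_linear = as.character(predict(object$fit, X)),
    `1nn` = as.character(class::knn1(object$fit$train, X, object$fit$cl)),
    gnb = as.character(predict(object$fit, X)),
    gmm = as.character(predict(object$fit, newdata = X)$classification)
  )
  out
}

#' Serialize / load a fitted SGD classifier as a flat text record
#'
#' @param model an `sgd_classifier`.
#' @param path file path.
#' @return `write_classifier()` returns `path`; `read_classifier()` the
#'   model.
#' @export
write_classifier <- function(model, path) {
  h <- model$hyper
  lines <- c(
    paste0("classes\t", paste(model$classes, collapse = ",")),
    paste0("weights\t", paste(format(t(model$weights), digits = 17),
                              collapse = ",")),
    paste0("intercepts\t", paste(format(model$intercepts, digits = 17),
                                 collapse = ",")),
    paste0("center\t", paste(format(model$center, digits = 17), collapse = ",")),
    paste0("scale\t", paste(format(model$scale, digits = 17), collapse = ",")),
    paste0("alpha\t", format(h$alpha, digits = 17)),
    paste0("loss\t", h$loss),
    paste0("learning_rate\t", h$learning_rate),
    paste0("max_epochs\t", h$max_epochs),
    paste0("tol\t", format(h$tol, digits = 17)),
    paste0("epochs_run\t", h$epochs_run),
    paste0("seed\t", h$seed),
    paste0("standardize\t", h$standardize))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  kv <- strsplit(readLines(path), "\t", fixed = TRUE)
  rec <- setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
  classes <- strsplit(rec$classes, ",", fixed = TRUE)[[1]]
  num <- function(s) as.numeric(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
  W <- matrix(num(rec$weights), nrow = length(classes), byrow = TRUE)
  structure(list(classes = classes, weights = W,
                 intercepts = num(rec$intercepts),
                 center = num(rec$center), scale = num(rec$scale),
                 hyper = list(alpha = as.numeric(rec$alpha), loss = rec$loss,
                              learning_rate = rec$learning_rate,
                              t0 = sgd_schedule(as.numeric(rec$alpha))$t0,
                              max_epochs = as.integer(rec$max_epochs),
                              tol = as.numeric(rec$tol),
                              epochs_run = as.integer(rec$epochs_run),
                              seed = as.integer(rec$seed),
                              standardize = as.logical(rec$standardize))),
            class = "sgd_classifier")
}

#' Decision-boundary grid of a fitted classifier
#'
#' Evaluates the predicted class over a rectangular grid of the
#' (cortisol, STAI) plane, for boundary plots or geometry checks.
#'
#' @param model a model with a `predict` method over the two features.
#' @param cortisol_range,stai_range numeric `c(min, max)`.
#' @param n grid resolution per axis.
#' @return `data.frame` with `cortisol_baseline`, `stai_baseline`,
#'   `predicted`.
#' @export
decision_grid <- function(model, cortisol_range = c(0, 1.5),
                          stai_range = c(20, 80), n = 60L) {
  g <- expand.grid(
    cortisol_baseline = seq(cortisol_range[1], cortisol_range[2], length.out = n),
    stai_baseline = seq(stai_range[1], stai_range[2], length.out = n))
  g$predicted <- predict(model, g)
  g
}
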