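#' Random forest classifier (fit and predict)
#'
#' Bagged classification trees with Gini splitting and per-split feature
#' subsampling, for two-class problems.  Returns held-out predictions and
#' the mean-decrease-in-Gini importance of each feature.  `ntree = 1` with
#' `mtry = ncol(x)` gives a single (bootstrapped) classification tree.
#'
#' @param x Training matrix (rows = recordings, columns = features).
#' @param y Training labels (factor or character, 2 levels).
#' @param newdata Matrix to classify.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param min_node Minimum node size to attempt a split (default 2 =
#'   fully grown trees).
#' @return List: `prediction` (labels for `newdata`), `vote` (fraction of
#'   trees voting the second level), `importance` (named, per feature).
#' @export
random_forest <- function(x, y, newdata, ntree = 500,
                          mtry = max(1, floor(sqrt(ncol(x)))),
                          min_node = 2) {
  x <- as.matrix(x); newdata <- as.matrix(newdata)
  y <- factor(y)
  if (nlevels(y) != 2) stop("random_forest is two-class")
  fit <- .rf_fit_predict(x, as.integer(y) - 1L, newdata,
                         as.integer(ntree), as.integer(mtry),
                         as.integer(min_node))
  names(fit$importance) <- colnames(x)
  fit$prediction <- levels(y)[fit$prediction + 1L]
  fit
}

#' RBF-kernel support vector classifier (fit and predict)
#'
#' Soft-margin C-SVC with a Gaussian radial kernel
#' `K(u, v) = exp(-gamma |u - v|^2)`, solved by sequential minimal
#' optimisation.  Intended for the small per-age problems of this package
#' (tens of recordings); inputs should already be standardised (see
#' [train_eval()], which standardises with training-fold statistics).
#'
#' @param x Training matrix.
#' @param y Training labels (2 levels).
#' @param newdata Matrix to classify.
#' @param gamma Kernel width; default `1/ncol(x)` (1/11 for the full
#'   feature vector).
#' @param C Box constraint (default 1).
#' @param tol KKT tolerance.
#' @param max_passes Passes without update before stopping.
#' @return List: `prediction` (labels), `decision` (signed values).
#' @export
svm_rbf <- function(x, y, newdata, gamma = 1 / ncol(x), C = 1,
                    tol = 1e-3, max_passes = 10) {
  x <- as.matrix(x); newdata <- as.matrix(newdata)
  y <- factor(y)
  if (nlevels(y) != 2) stop("svm_rbf is two-class")
  yy <- ifelse(as.integer(y) == 2, 1, -1)
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n); b <- 0
  fcache <- function(i) sum(alpha * yy * K[, i]) + b
  passes <- 0; iter <- 0; max_iter <- 200 * n
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1
    changed <- 0
    for (i in seq_len(n)) {
      Ei <- fcache(i) - yy[i]
      if ((yy[i] * Ei < -tol && alpha[i] < C) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample(seq_len(n)[-i], 1)
        Ej <- fcache(j) - yy[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yy[i] != yy[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L == H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yy[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
          yy[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
          yy[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1
        else if (aj > 0 && aj < C) b2
        else (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  Kt <- rbf_kernel(newdata, x, gamma)
  dec <- as.numeric(Kt %*% (alpha * yy)) + b
  list(prediction = levels(y)[ifelse(dec >= 0, 2, 1)], decision = dec)
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

#' Principal component projection of feature vectors
#'
#' Standard PCA after centring and scaling each feature to unit variance
#' (variance normalisation).  Zero-variance features cannot be scaled and
#' are dropped with a warning.
#'
#' @param x Numeric matrix, recordings x features (no `NA`; impute first).
#' @param labels Optional per-recording labels carried onto the result.
#' @return List of class `pca_result`: `projections` (scores matrix),
#'   `variance_fractions`, `cumulative_variance`, `rotation`, `labels`,
#'   `dropped` (names of zero-variance features).
#' @export
pca_project <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 recordings")
  if (anyNA(x)) stop("x contains NA; impute undefined features first")
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(projections = pc$x, variance_fractions = vf,
                 cumulative_variance = cumsum(vf), rotation = pc$rotation,
                 labels = labels, dropped = dropped),
            class = "pca_result")
}

# Stratified 2/3 train / 1/3 test split; returns logical train indicator.
# Guarantees both classes in both partitions (resampling cannot be needed
# with per-class splitting, provided each class has >= 2 members).
stratified_split <- function(y, train_frac = 2 / 3) {
  y <- factor(y)
  train <- logical(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    if (length(idx) < 2)
      stop("class '", lv, "' has fewer than 2 members; cannot split")
    n_tr <- max(1, min(length(idx) - 1, round(train_frac * length(idx))))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# Median-impute NA entries using training-fold medians (fallback 0 when a
# column is entirely NA in the fold).
impute_by_train <- function(xtr, xte) {
  for (j in seq_len(ncol(xtr))) {
    med <- stats::median(xtr[, j], na.rm = TRUE)
    if (is.na(med)) med <- 0
    xtr[is.na(xtr[, j]), j] <- med
    xte[is.na(xte[, j]), j] <- med
  }
  list(train = xtr, test = xte)
}

#' One train/test evaluation
#'
#' Splits the recordings into a stratified two-thirds training set and
#' one-third test set, fits the requested classifier, and returns the
#' percentage of correct held-out classifications.  Undefined feature
#' values are imputed with training-set medians; for the SVM, features are
#' additionally standardised with training-set statistics (no leakage).
#'
#' @param x Feature matrix (rows = recordings).
#' @param y Labels (2 classes).
#' @param method `"forest"` or `"svm"`.
#' @param split_seed Integer seed controlling the split (and the model's
#'   own randomness).
#' @param ntree,mtry Forest size (forest only).
#' @param gamma,C SVM kernel width and box constraint (svm only);
#'   `gamma = NULL` means `1/ncol(x)`.
#' @return List: `accuracy` (percent correct), `importance` (forest only,
#'   unnormalised Gini decreases), `n_test`.
#' @export
train_eval <- function(x, y, method = c("forest", "svm"), split_seed = 1,
                       ntree = 500, mtry = NULL, gamma = NULL, C = 1) {
  method <- match.arg(method)
  x <- as.matrix(x); y <- factor(y)
  set.seed(as.integer(split_seed) %% 2147483647)
  tr <- stratified_split(y)
  imp <- impute_by_train(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
  xtr <- imp$train; xte <- imp$test
  ytr <- y[tr]; yte <- y[!tr]
  if (method == "forest") {
    if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
    fit <- random_forest(xtr, ytr, xte, ntree = ntree, mtry = mtry)
    acc <- 100 * mean(fit$prediction == as.character(yte))
    list(accuracy = acc, importance = fit$importance, n_test = sum(!tr))
  } else {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    zte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    fit <- svm_rbf(ztr, ytr, zte, gamma = gamma, C = C)
    acc <- 100 * mean(fit$prediction == as.character(yte))
    list(accuracy = acc, importance = NULL, n_test = sum(!tr))
  }
}

#' Repeated-split classifier evaluation
#'
#' Repeats [train_eval()] over `n_repeats` random stratified splits and
#' aggregates: mean and SD of held-out accuracy, and (forest) the Gini
#' importances averaged over repeats, normalised so the top feature scores
#' exactly 1.
#'
#' @param x,y,method,ntree,gamma,C As in [train_eval()].
#' @param n_repeats Number of random splits (default 500).
#' @param seed Master seed; repeat `r` uses a seed derived from it by a
#'   fixed rule.
#' @return List of class `classification_result`: `method`,
#'   `mean_accuracy` (%), `accuracy_sd`, `accuracies`, `n_repeats`,
#'   `importance` (normalised; `NULL` for svm).
#' @export
evaluate_classifier <- function(x, y, method = c("forest", "svm"),
                                n_repeats = 500, seed = 1, ntree = 500,
                                gamma = NULL, C = 1) {
  method <- match.arg(method)
  stopifnot(n_repeats >= 1)
  acc <- numeric(n_repeats)
  imp_sum <- NULL
  for (r in seq_len(n_repeats)) {
    res <- train_eval(x, y, method = method,
                      split_seed = derive_seed(seed, r),
                      ntree = ntree, gamma = gamma, C = C)
    acc[r] <- res$accuracy
    if (!is.null(res$importance)) {
      if (is.null(imp_sum)) imp_sum <- res$importance
      else imp_sum <- imp_sum + res$importance
    }
  }
  importance <- NULL
  if (!is.null(imp_sum)) {
    importance <- imp_sum / n_repeats
    if (max(importance) > 0) importance <- importance / max(importance)
  }
  structure(list(method = method, mean_accuracy = mean(acc),
                 accuracy_sd = stats::sd(acc), accuracies = acc,
                 n_repeats = n_repeats, importance = importance),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: %.1f%% +- %.1f over %d splits\n",
              x$method, x$mean_accuracy, x$accuracy_sd, x$n_repeats))
  if (!is.null(x$importance)) {
    cat("importance (top first):\n")
    imp <- sort(x$importance, decreasing = TRUE)
    for (i in seq_along(imp))
      cat(sprintf("  %-20s %.2f\n", names(imp)[i], imp[i]))
  }
  invisible(x)
}

# Deterministic per-repeat seed below 2^31.
derive_seed <- function(seed, r) {
  (as.double(seed) * 69621 + r * 104729) %% 2147483629
}

#' Accuracy as features are added in importance order
#'
#' Re-evaluates the classifier using only the top `k` features of a given
#' importance ranking, for `k = 1 ... length(ranking)`.
#'
#' @param x,y,method As in [evaluate_classifier()].
#' @param ranking Character vector: all feature (column) names of `x` in
#'   decreasing importance order.
#' @param n_repeats,seed,ntree,gamma,C Passed through.
#' @return Data frame: `k`, `feature` (the feature added at rank k),
#'   `mean_accuracy`, `accuracy_sd`.
#' @export
incremental_performance <- function(x, y, ranking,
                                    method = c("forest", "svm"),
                                    n_repeats = 100, seed = 1, ntree = 500,
                                    gamma = NULL, C = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (!setequal(ranking, colnames(x)))
    stop("ranking must cover exactly the columns of x")
  rows <- lapply(seq_along(ranking), function(k) {
    xx <- x[, ranking[seq_len(k)], drop = FALSE]
    g <- if (is.null(gamma) && method == "svm") 1 / ncol(x) else gamma
    res <- evaluate_classifier(xx, y, method = method,
                               n_repeats = n_repeats, seed = seed,
                               ntree = ntree, gamma = g, C = C)
    data.frame(k = k, feature = ranking[k],
               mean_accuracy = res$mean_accuracy,
               accuracy_sd = res$accuracy_sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature matrix of a tidy feature table
#'
#' @param features Data frame from [features_table()].
#' @return List: `x` (numeric matrix of the 11 features), `y` (region
#'   factor), `age_div`.
#' @export
feature_matrix <- function(features) {
  x <- as.matrix(features[, feature_names()])
  rownames(x) <- features$array_id
  list(x = x, y = factor(features$region), age_div = features$age_div)
}
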