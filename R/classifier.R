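#' Radial basis function kernel
#'
#' \eqn{K(x_i, x_j) = \exp(-\gamma \|x_i - x_j\|^2)}.
#'
#' @param xi,xj numeric vectors of equal length.
#' @param gamma positive kernel parameter.
#' @return kernel value in (0, 1].
#' @export
rbf_kernel <- function(xi, xj, gamma) {
  if (length(xi) != length(xj))
    stop("feature vectors must have equal dimensionality")
  if (gamma < 0) stop("gamma must be non-negative")
  exp(-gamma * sum((xi - xj)^2))
}

# pairwise RBF kernel matrix between rows of A and rows of B
rbf_kernel_matrix <- function(A, B, gamma) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

standardize_fit <- function(X, method = "minmax") {
  if (method == "none")
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  if (method == "zscore") {
    mu <- colMeans(X)
    s <- apply(X, 2, stats::sd)
  } else {                                   # svm-scale convention: [0, 1]
    mu <- apply(X, 2, min)
    s <- apply(X, 2, max) - mu
  }
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

standardize_apply <- function(X, st)
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")

# fixed class order: declared factor levels, else order of first appearance
class_order <- function(y) if (is.factor(y)) levels(y) else
  unique(as.character(y))

as_feature_matrix <- function(newdata, d) {
  if (is.null(dim(newdata))) {
    if (length(newdata) != d) stop("feature length mismatch")
    matrix(as.numeric(newdata), 1)
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != d) stop("feature length mismatch")
    newdata
  }
}

#' Train a binary nu-SVM with RBF kernel
#'
#' Solves the nu-parameterized dual problem to the given termination
#' tolerance (via the LIBSVM solver in \pkg{e1071}). The stored decision
#' function is evaluated by this package as
#' \eqn{f(x) = \mathrm{sgn}(\sum_i \alpha_i y_i K(x_i, x) + b)}.
#' Trained models satisfy the nu-property: the fraction of margin errors is
#' at most nu, and nu is at most the fraction of support vectors.
#'
#' Feature rescaling (training-set statistics, folded into the model):
#' `"minmax"` (default) maps each feature to [0, 1], the convention of the
#' svm-scale tool that ships with LIBSVM; `"zscore"` standardizes to unit
#' variance; `"none"` feeds native scales to the kernel. Min-max keeps
#' squared distances O(1) regardless of dimensionality, so the whole usual
#' gamma range remains usable (with d z-scored features, distances
#' concentrate near 2d and the RBF kernel collapses at large gamma).
#'
#' @param X numeric samples x features matrix.
#' @param y labels with exactly two classes (factor or character).
#' @param nu nu parameter in (0, 1]; must be feasible for the class balance
#'   (nu <= 2 min(n+, n-) / l).
#' @param gamma RBF kernel parameter.
#' @param tol termination tolerance of the optimizer.
#' @param scale feature rescaling: `"minmax"`, `"zscore"` or `"none"`.
#' @return an object of class `"nu_svm"` with support vectors, dual
#'   coefficients (alpha_i y_i), bias, gamma, nu and standardization.
#' @export
train_nu_svm <- function(X, y, nu = 0.5, gamma = 1 / ncol(X), tol = 1e-6,
                         scale = c("minmax", "zscore", "none")) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features contain NaN/Inf")
  y <- factor(y)
  if (nlevels(y) != 2)
    stop(sprintf("binary subproblem requires exactly 2 classes, got %d",
                 nlevels(y)))
  cnt <- table(y)
  l <- length(y)
  if (nu > 2 * min(cnt) / l)
    stop(sprintf(paste0("nu = %g is infeasible for this class balance: ",
                        "with %d vs %d samples the margin-error bound ",
                        "cannot exceed 2*min/l = %.3f"),
                 nu, cnt[1], cnt[2], 2 * min(cnt) / l))
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  scale <- match.arg(scale)
  st <- standardize_fit(X, scale)
  Xs <- standardize_apply(X, st)
  fit <- e1071::svm(Xs, y, scale = FALSE, type = "nu-classification",
                    kernel = "radial", gamma = gamma, nu = nu,
                    tolerance = tol)
  # e1071/libsvm: decision value positive -> first label in fit$labels order
  lv <- levels(y)[fit$labels]
  structure(list(sv = unname(fit$SV), coefs = drop(fit$coefs),
                 rho = fit$rho, gamma = gamma, nu = nu, tol = tol,
                 pos_label = lv[1], neg_label = lv[2],
                 levels = levels(y), n_train = l,
                 center = st$center, scale = st$scale),
            class = "nu_svm")
}

#' Decision values of a binary nu-SVM
#'
#' Evaluates \eqn{\sum_i \alpha_i y_i K(x_i, x) - \rho} for each row of
#' `newdata` (positive values vote for the model's `pos_label`).
#'
#' @param model a `"nu_svm"`.
#' @param newdata samples x features matrix (unstandardized).
#' @return numeric vector of decision values.
#' @export
decision_values <- function(model, newdata) {
  stopifnot(inherits(model, "nu_svm"))
  newdata <- as_feature_matrix(newdata, ncol(model$sv))
  Xs <- standardize_apply(newdata, list(center = model$center,
                                        scale = model$scale))
  K <- rbf_kernel_matrix(Xs, model$sv, model$gamma)
  drop(K %*% model$coefs) - model$rho
}

#' @export
predict.nu_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  ifelse(f >= 0, object$pos_label, object$neg_label)
}

#' Train a one-vs-one multi-class nu-SVM
#'
#' One binary nu-SVM per unordered class pair; prediction is by majority
#' vote with ties broken by the fixed class order.
#'
#' @inheritParams train_nu_svm
#' @param classes class order used for voting tie-breaks; defaults to the
#'   factor levels of `y`.
#' @return an object of class `"ovo_svm"`.
#' @export
train_ovo <- function(X, y, nu = 0.5, gamma = 1 / ncol(X), tol = 1e-6,
                      classes = NULL, scale = c("minmax", "zscore", "none")) {
  X <- as.matrix(X)
  if (is.null(classes)) classes <- class_order(y)
  y <- as.character(y)
  if (!all(y %in% classes)) stop("labels outside the declared class set")
  if (length(classes) < 2) stop("at least two classes required")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    sel <- y %in% p
    train_nu_svm(X[sel, , drop = FALSE], factor(y[sel], levels = p),
                 nu = nu, gamma = gamma, tol = tol, scale = scale)
  })
  structure(list(models = models, pairs = pairs, classes = classes,
                 gamma = gamma, nu = nu),
            class = "ovo_svm")
}

#' @export
predict.ovo_svm <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata, ncol(object$models[[1]]$sv))
  votes <- matrix(0L, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (k in seq_along(object$models)) {
    mk <- object$models[[k]]
    p <- object$pairs[[k]]
    # orient the decision so positive votes the pair's first class in the
    # fixed class order (the solver may order labels by data occurrence)
    f <- decision_values(mk, newdata) *
      (if (identical(mk$pos_label, p[1])) 1 else -1)
    win <- ifelse(f >= 0, p[1], p[2])   # sgn(0) votes the pair's first class
    for (cl in p) votes[, cl] <- votes[, cl] + (win == cl)
  }
  apply(votes, 1, function(v) object$classes[which.max(v)])
}

#' Round-robin (leave-one-out) cross-validation
#'
#' Each of the l samples is held out once; the one-vs-one nu-SVM is trained
#' on the remaining l - 1 samples (feature standardization refit inside each
#' fold) and tested on the held-out sample. With the 12-subject x 3-condition
#' design this is the 36-round round robin.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param nu,gamma,tol nu-SVM parameters.
#' @param classes fixed class order for voting tie-breaks.
#' @return an object of class `"cv_result"`: `rounds`, per-round
#'   `predictions` (data.frame of true/predicted), overall `accuracy`, and
#'   `per_class` recall.
#' @export
round_robin_cv <- function(X, y, nu = 0.5, gamma = 1 / ncol(X), tol = 1e-6,
                           classes = NULL, scale = c("minmax", "zscore", "none")) {
  X <- as.matrix(X)
  if (is.null(classes)) classes <- class_order(y)
  y <- as.character(y)
  l <- nrow(X)
  if (l < 6) stop("round-robin CV needs at least 6 samples")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  pred <- character(l)
  for (i in seq_len(l)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < length(classes))
      stop(sprintf("class absent from the training fold of round %d", i))
    m <- train_ovo(X[-i, , drop = FALSE], ytr, nu = nu, gamma = gamma,
                   tol = tol, classes = classes, scale = scale)
    pred[i] <- predict(m, X[i, , drop = FALSE])
  }
  per_class <- vapply(classes, function(cl) {
    sel <- y == cl
    mean(pred[sel] == cl)
  }, numeric(1))
  structure(list(rounds = l,
                 predictions = data.frame(round = seq_len(l), true = y,
                                          predicted = pred),
                 accuracy = mean(pred == y),
                 per_class = per_class,
                 gamma = gamma, nu = nu),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d rounds, gamma = %g, nu = %g: accuracy %.1f%%\n",
              x$rounds, x$gamma, x$nu, 100 * x$accuracy))
  for (cl in names(x$per_class))
    cat(sprintf("  %-8s %.1f%%\n", cl, 100 * x$per_class[cl]))
  invisible(x)
}

#' Kernel-parameter sweep
#'
#' Runs [round_robin_cv()] at each gamma. The default grid is the four
#' settings 0.0001, 0.01, 1 and 1/(number of features), with nu fixed at
#' 0.5.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param gammas gamma values; defaults to `c(1e-4, 1e-2, 1, 1/ncol(X))`.
#' @param nu,tol nu-SVM parameters.
#' @param classes fixed class order.
#' @return an object of class `"kernel_sweep"`: list of `cv_result`s plus a
#'   `summary` data.frame (gamma, accuracy, one recall column per class).
#' @export
kernel_sweep <- function(X, y, gammas = NULL, nu = 0.5, tol = 1e-6,
                         classes = NULL, scale = c("minmax", "zscore", "none")) {
  X <- as.matrix(X)
  if (is.null(gammas)) gammas <- c(1e-4, 1e-2, 1, 1 / ncol(X))
  if (!length(gammas)) stop("gamma list must not be empty")
  results <- lapply(gammas, function(g)
    round_robin_cv(X, y, nu = nu, gamma = g, tol = tol, classes = classes,
                   scale = scale))
  summary <- data.frame(gamma = gammas,
                        accuracy = vapply(results, `[[`, numeric(1),
                                          "accuracy"))
  pc <- do.call(rbind, lapply(results, `[[`, "per_class"))
  summary <- cbind(summary, as.data.frame(pc))
  structure(list(results = results, summary = summary, nu = nu),
            class = "kernel_sweep")
}

#' @export
print.kernel_sweep <- function(x, ...) {
  cat("<kernel_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Label-permutation chance level
#'
#' Estimates the classifier's chance-level accuracy by running the round
#' robin on seeded random permutations of the class labels. With three
#' balanced classes the mean converges to 1/3 (the 33\% chance level).
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param n_perm number of permutations.
#' @param gamma,nu,tol nu-SVM parameters.
#' @param seed RNG seed (mandatory: permutation draws are stochastic).
#' @return list: `mean_accuracy`, `accuracies` (one per permutation).
#' @export
permutation_chance <- function(X, y, n_perm = 100, gamma = 0.01, nu = 0.5,
                               tol = 1e-6, seed, scale = c("minmax", "zscore", "none")) {
  if (missing(seed)) stop("a seed is mandatory for permutation draws")
  classes <- class_order(y)
  y <- as.character(y)
  acc <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    yp <- sample(y)
    round_robin_cv(X, yp, nu = nu, gamma = gamma, tol = tol,
                   classes = classes, scale = scale)$accuracy
  }, numeric(1)))
  list(mean_accuracy = mean(acc), accuracies = acc)
}
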