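#' Balanced class weights
#'
#' Weight \eqn{w_c = n / (2 n_c)} for class \eqn{c}: the minority class gets
#' the larger weight, inversely proportional to its frequency, and the
#' effective sample size is preserved (equal classes give unit weights).
#'
#' @param y binary 0/1 vector.
#' @return named numeric vector \code{c("0" = w0, "1" = w1)}.
#' @export
class_weights <- function(y) {
  y <- check_binary(y)
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0L || n1 == n) stop("both classes must be present", call. = FALSE)
  c("0" = n / (2 * (n - n1)), "1" = n / (2 * n1))
}

check_binary <- function(y) {
  y <- as.numeric(y)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("'y' must be a binary 0/1 vector", call. = FALSE)
  y
}

expand_weights <- function(weights, y) {
  if (is.null(weights)) weights <- class_weights(y)
  if (length(weights) == 2L) {
    if (is.null(names(weights))) names(weights) <- c("0", "1")
    return(unname(weights[as.character(y)]))
  }
  if (length(weights) != length(y))
    stop("'weights' must be per-class (length 2) or per-sample", call. = FALSE)
  weights
}

#' Smallest penalty nulling every coefficient
#'
#' With all coefficients at zero the intercept equals the weighted log-odds
#' of the labels; the null solution satisfies the optimality conditions iff
#' the penalty is at least the largest absolute weighted gradient
#' \eqn{\max_j |(1/n) \sum_i w_i x_{ij} (y_i - \bar p)|}.
#'
#' @param X numeric matrix (subjects x genes).
#' @param y binary labels.
#' @param weights per-class or per-sample weights; default balanced.
#' @return the critical penalty \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(X, y, weights = NULL) {
  y <- check_binary(y)
  w <- expand_weights(weights, y)
  pbar <- sum(w * y) / sum(w)
  max(abs(crossprod(X, w * (y - pbar)))) / nrow(X)
}

#' Fit a class-weighted L1-penalized logistic regression
#'
#' Minimizes \deqn{-\frac{1}{n}\sum_i w_{y_i}\left[y_i \log\sigma(\eta_i) +
#' (1-y_i)\log(1-\sigma(\eta_i))\right] + \lambda \sum_j |\beta_j|} with
#' \eqn{\eta_i = \beta_0 + x_i\beta} and an unpenalized intercept, by cyclic
#' coordinate descent with soft-thresholding on a quadratic majorization of
#' the loss. Multiple penalties are solved in the given order with warm
#' starts. Boolean columns share a scale, so features are not standardized.
#'
#' @param X numeric matrix (subjects x genes), rows aligned with \code{y}.
#' @param y binary 0/1 labels.
#' @param lambda penalty (scalar or vector), \eqn{\lambda \ge 0}; multiplies
#'   the L1 term of the per-sample-averaged loss.
#' @param weights per-class (length 2, as from [class_weights()]) or
#'   per-sample weights; \code{NULL} (default) uses balanced class weights.
#' @param tol convergence tolerance on the objective change per sweep.
#' @param max_iter maximum number of full coordinate sweeps per penalty.
#' @return object of class \code{xburden_lasso}: \code{beta} (genes x
#'   penalties), \code{intercept}, \code{lambda}, \code{objective},
#'   \code{iterations}, \code{trace} (per-sweep objective values).
#' @export
fit_weighted_lasso <- function(X, y, lambda, weights = NULL, tol = 1e-7,
                               max_iter = 10000L) {
  X <- as.matrix(X) * 1.0
  y <- check_binary(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y", call. = FALSE)
  if (any(lambda < 0)) stop("'lambda' must be >= 0", call. = FALSE)
  w <- expand_weights(weights, y)
  fit <- cd_lasso_path(X, y, w, as.numeric(lambda), tol, as.integer(max_iter))
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)
    stop(sprintf(paste0("coordinate descent did not converge for lambda = %s",
                        " within %d sweeps (last objective change %.3g);",
                        " increase max_iter or tol"),
                 paste(signif(lambda[bad], 4), collapse = ", "),
                 max_iter,
                 {
                   tr <- fit$trace[[bad[1]]]
                   m <- length(tr)
                   if (m >= 2) tr[m - 1] - tr[m] else NA_real_
                 }), call. = FALSE)
  }
  rownames(fit$beta) <- colnames(X)
  structure(list(beta = fit$beta, intercept = as.numeric(fit$intercept),
                 lambda = as.numeric(lambda),
                 objective = as.numeric(fit$objective),
                 iterations = as.integer(fit$iterations),
                 trace = fit$trace, weights = w),
            class = "xburden_lasso")
}

#' Predicted case probabilities from a fitted model
#'
#' @param object an \code{xburden_lasso} fit.
#' @param newdata matrix with the same columns as the training matrix.
#' @param lambda which penalty to use (defaults to the only/first one).
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.xburden_lasso <- function(object, newdata, lambda = NULL, ...) {
  l <- pick_lambda(object, lambda)
  eta <- object$intercept[l] + as.matrix(newdata) %*% object$beta[, l]
  as.numeric(stats::plogis(eta))
}

pick_lambda <- function(object, lambda) {
  if (is.null(lambda)) return(1L)
  l <- which(abs(object$lambda - lambda) < 1e-12)
  if (length(l) != 1L) stop("'lambda' not in the fitted path", call. = FALSE)
  l
}

#' Stratified k-fold cross-validation of the weighted lasso
#'
#' Splits subjects into class-stratified folds from the given seed, fits the
#' penalty path on each set of k-1 training folds (with per-fold balanced
#' class weights) and scores accuracy on the held-out fold, so every subject
#' is predicted exactly once per penalty by a model that never saw it. The
#' selected penalty maximizes the mean fold accuracy, ties going to the
#' larger (sparser) penalty; out-of-fold predictions at that penalty are
#' aggregated into a single confusion matrix and metric set.
#'
#' Fold assignment is derived from the subject order sorted by row name (or
#' index when unnamed), so results are invariant to row permutations of the
#' same labelled data.
#'
#' @param X boolean gene matrix (subjects x genes).
#' @param y binary labels aligned with rows of X.
#' @param lambda optional penalty grid; default log-spaced over
#'   \code{[lambda_max * lambda_min_ratio, lambda_max]}.
#' @param nlambda,lambda_min_ratio grid size (default 50) and span. The
#'   default span is 1e-4 when subjects outnumber genes and 0.01 otherwise:
#'   with more genes than subjects the boolean matrix is typically separable,
#'   and penalties near zero produce degenerate, slowly-converging fits.
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param tol,max_iter solver controls, see [fit_weighted_lasso()].
#' @return object of class \code{xburden_cv}: the grid, per-fold accuracies,
#'   their mean and SD, \code{lambda_best}, out-of-fold probabilities and
#'   hard labels, confusion matrix and metrics, fold assignment, and
#'   \code{model}, a full-data refit at the chosen penalty.
#' @export
cross_validate <- function(X, y, lambda = NULL, nlambda = 50L,
                           lambda_min_ratio = NULL, n_folds = 10L, seed = 1L,
                           tol = 1e-7, max_iter = 10000L) {
  X <- as.matrix(X) * 1.0
  y <- check_binary(y)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (ncol(X) >= nrow(X)) 0.01 else 1e-4
  if (n_folds < 2L) stop("'n_folds' must be at least 2", call. = FALSE)
  n <- nrow(X)
  if (min(sum(y), n - sum(y)) < n_folds)
    stop("a fold would lack a class; use fewer folds", call. = FALSE)
  if (is.null(lambda)) {
    lmax <- lambda_max(X, y)
    if (lmax <= 0) stop("labels carry no signal gradient; check input",
                        call. = FALSE)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  nl <- length(lambda)

  fold <- stratified_folds(y, rownames(X), n_folds, seed)
  acc <- matrix(NA_real_, nl, n_folds)
  oof <- matrix(NA_real_, n, nl)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(y[train])) < 2L)
      stop("a training partition lacks a class; use fewer folds",
           call. = FALSE)
    fit <- fit_weighted_lasso(X[train, , drop = FALSE], y[train], lambda,
                              tol = tol, max_iter = max_iter)
    eta <- sweep(X[test, , drop = FALSE] %*% fit$beta, 2, fit$intercept, `+`)
    prob <- stats::plogis(eta)
    oof[test, ] <- prob
    acc[, f] <- colMeans((prob >= 0.5) == y[test])
  }
  mean_acc <- rowMeans(acc)
  sd_acc <- apply(acc, 1, sd)
  best <- which.max(mean_acc)  # lambda is decreasing: ties -> larger lambda
  oof_prob <- oof[, best]
  metrics <- aggregate_confusion(oof_prob, y)
  model <- fit_weighted_lasso(X, y, lambda[best], tol = tol,
                              max_iter = max_iter)
  structure(list(lambda = lambda, fold_accuracy = acc, mean_accuracy = mean_acc,
                 sd_accuracy = sd_acc, lambda_best = lambda[best],
                 oof_prob = oof_prob, oof_label = as.integer(oof_prob >= 0.5),
                 confusion = metrics$confusion, metrics = metrics,
                 fold = fold, y = y, seed = seed, model = model),
            class = "xburden_cv")
}

# class-stratified fold assignment, reproducible from the seed and invariant
# to row order of the same labelled subjects
stratified_folds <- function(y, ids, n_folds, seed) {
  n <- length(y)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(n))
  ord <- order(ids)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in c(0, 1)) {
      members <- ord[y[ord] == cls]
      perm <- if (length(members) > 1L) sample(members) else members
      fold[perm] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  fold
}

#' Fold-aggregated confusion matrix and metrics
#'
#' Sums out-of-fold predictions into one confusion matrix (hard labels from
#' probability at or above 0.5) and derives accuracy, precision, sensitivity,
#' specificity and ROC-AUC. The AUC is the Mann-Whitney statistic of the
#' out-of-fold probabilities with midrank tie handling, so all-equal
#' probabilities give 0.5. Ratios with a zero denominator are reported as
#' \code{NA}, not 0.
#'
#' @param prob out-of-fold probabilities, or an \code{xburden_cv} object.
#' @param labels binary labels (ignored when \code{prob} is a CV result).
#' @return list with \code{confusion} (named TP/FP/TN/FN counts),
#'   \code{accuracy}, \code{precision}, \code{sensitivity},
#'   \code{specificity}, \code{auc}.
#' @export
aggregate_confusion <- function(prob, labels = NULL) {
  if (inherits(prob, "xburden_cv")) {
    labels <- prob$y
    prob <- prob$oof_prob
  }
  if (length(prob) == 0L) stop("empty prediction set", call. = FALSE)
  y <- check_binary(labels)
  hard <- prob >= 0.5
  tp <- sum(hard & y == 1); fp <- sum(hard & y == 0)
  tn <- sum(!hard & y == 0); fn <- sum(!hard & y == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(prob)  # midranks
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = ratio(tp + tn, length(y)),
       precision = ratio(tp, tp + fp),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       auc = auc)
}

#' Rank genes by model coefficient
#'
#' Nonzero-coefficient genes sorted by decreasing absolute coefficient,
#' annotated \code{susceptible} (positive weight) or \code{protective}
#' (negative weight); ties break lexicographically by gene symbol.
#'
#' @param model an \code{xburden_lasso} fit (or \code{xburden_cv}, in which
#'   case its full-data refit at the chosen penalty is ranked).
#' @param lambda which penalty of a path fit to rank.
#' @return data frame with columns gene, coefficient, direction.
#' @export
rank_features <- function(model, lambda = NULL) {
  if (inherits(model, "xburden_cv")) model <- model$model
  stopifnot(inherits(model, "xburden_lasso"))
  l <- pick_lambda(model, lambda)
  coef <- model$beta[, l]
  genes <- rownames(model$beta)
  nz <- which(coef != 0)
  ord <- nz[order(-abs(coef[nz]), genes[nz])]
  data.frame(gene = genes[ord], coefficient = unname(coef[ord]),
             direction = ifelse(coef[ord] > 0, "susceptible", "protective"),
             stringsAsFactors = FALSE, row.names = NULL)
}
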