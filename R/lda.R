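#' Wilks' lambda for a feature subset
#'
#' `Lambda = det(W) / det(T)` where W is the pooled within-class scatter
#' and T the total scatter of the chosen feature columns. Values near 0
#' indicate well-separated classes; 1 means the class means coincide.
#'
#' @param X numeric matrix, replicates x features (named columns).
#' @param labels class labels, one per row.
#' @param subset feature names (or indices) to use; default all.
#' @return Wilks' lambda in `(0, 1]`.
#' @export
wilksLambda <- function(X, labels, subset = colnames(X)) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  Xs <- X[, subset, drop = FALSE]
  # lambda is invariant to per-feature scaling; standardise for numerics
  sds <- apply(Xs, 2, stats::sd)
  if (any(!is.finite(sds) | sds == 0))
    stop("collinear features: scatter matrix is singular")
  Xs <- sweep(Xs, 2, sds, "/")
  Tm <- crossprod(scale(Xs, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(Xs), ncol(Xs))
  for (g in levels(labels)) {
    Xg <- Xs[labels == g, , drop = FALSE]
    W <- W + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  if (qr(Tm)$rank < ncol(Xs) || qr(W)$rank < ncol(Xs))
    stop("collinear features: scatter matrix is singular")
  dT <- det(Tm)
  dW <- det(W)
  if (!is.finite(dT) || dT <= 0 || !is.finite(dW) || dW < 0)
    stop("collinear features: scatter matrix is singular")
  dW / dT
}

#' Greedy forward feature selection by Wilks' lambda
#'
#' Stepwise forward selection: at each step the candidate minimising
#' Wilks' lambda is admitted if the partial-F test comparing the model
#' with and without it,
#' `F = (Lambda_old / Lambda_new - 1) (n - g - p) / (g - 1)`
#' (n replicates, g classes, p variables already entered; df `g-1`,
#' `n-g-p`), has `p <= niveau`. Selection stops when no candidate
#' qualifies. Candidates whose admission would make the within-class
#' scatter singular are skipped; if the selection cannot proceed at all
#' because of collinearity, the NCD (TF = 0.5) features (basic and
#' standardized) are removed and selection restarts once.
#'
#' @param X replicates x features matrix with column names.
#' @param labels class labels.
#' @param niveau maximum partial-F p-value for admission.
#' @return list with `features` (ordered selected names) and `trace`
#'   (data.frame: step, feature, lambda, Fvalue, pvalue).
#' @export
greedyWilks <- function(X, labels, niveau = 0.05) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  res <- tryCatch(.greedyWilksCore(X, labels, niveau),
                  error = function(e) e)
  if (inherits(res, "error")) {
    drop <- grepl("^ncd(_std)?_tf50", colnames(X))
    if (!any(drop)) stop(res)
    message("collinearity during stepwise selection; ",
            "removing NCD (TF = 0.5) features and restarting")
    res <- .greedyWilksCore(X[, !drop, drop = FALSE], labels, niveau)
  }
  res
}

.greedyWilksCore <- function(X, labels, niveau) {
  n <- nrow(X)
  g <- nlevels(labels)
  selected <- character()
  lambdaOld <- 1
  trace <- data.frame(step = integer(), feature = character(),
                      lambda = numeric(), Fvalue = numeric(),
                      pvalue = numeric())
  candidates <- sort(colnames(X))
  repeat {
    p <- length(selected)
    if (n - g - p <= 0) break
    lam <- vapply(candidates, function(f) {
      tryCatch(wilksLambda(X, labels, c(selected, f)),
               error = function(e) NA_real_)
    }, numeric(1))
    lam <- lam[is.finite(lam) & lam > 0]
    if (!length(lam)) {
      if (!length(selected))
        stop("collinear features: no admissible first variable")
      break
    }
    best <- names(lam)[which.min(lam)]  # ties: lexicographic (sorted)
    lambdaNew <- lam[[best]]
    Fv <- (lambdaOld / lambdaNew - 1) * (n - g - p) / (g - 1)
    pv <- stats::pf(Fv, g - 1, n - g - p, lower.tail = FALSE)
    if (!is.finite(pv) || pv > niveau) break
    selected <- c(selected, best)
    trace <- rbind(trace, data.frame(step = length(selected), feature = best,
                                     lambda = lambdaNew, Fvalue = Fv,
                                     pvalue = pv))
    lambdaOld <- lambdaNew
    candidates <- setdiff(candidates, best)
    if (!length(candidates)) break
  }
  if (!length(selected))
    stop("no feature admitted at niveau = ", niveau)
  list(features = selected, trace = trace)
}

#' Fit a linear discriminant classifier
#'
#' Estimates class means and the pooled within-class covariance of the
#' selected features; prediction assigns the class maximising the linear
#' discriminant score
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log(prior_k)`.
#' Priors default to the training class frequencies (uniform for the
#' balanced designs used here).
#'
#' @param X replicates x features matrix.
#' @param labels class labels.
#' @param features feature names to use (e.g. from [greedyWilks()]).
#' @param priors optional named class priors.
#' @param trace optional selection trace to store in the model.
#' @return A [WilksLDA-class].
#' @export
fitLDA <- function(X, labels, features = colnames(X), priors = NULL,
                   trace = NULL) {
  X <- as.matrix(X)[, features, drop = FALSE]
  labels <- as.factor(labels)
  g <- nlevels(labels)
  if (g < 2) stop("need at least 2 classes")
  cnt <- table(labels)
  if (any(cnt <= length(features)))
    stop("each class needs more replicates than selected features")
  mus <- t(vapply(levels(labels), function(k)
    colMeans(X[labels == k, , drop = FALSE]), numeric(ncol(X))))
  if (ncol(X) == 1) {
    mus <- matrix(mus, ncol = 1, dimnames = list(levels(labels), features))
  }
  W <- matrix(0, ncol(X), ncol(X))
  for (k in levels(labels)) {
    Xk <- X[labels == k, , drop = FALSE]
    W <- W + crossprod(scale(Xk, center = TRUE, scale = FALSE))
  }
  S <- W / (nrow(X) - g)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("pooled within-class covariance is singular; reduce the feature set")
  if (is.null(priors)) priors <- as.numeric(cnt) / nrow(X)
  priors <- priors / sum(priors)
  names(priors) <- levels(labels)
  dimnames(S) <- list(features, features)
  colnames(mus) <- features
  if (is.null(trace))
    trace <- data.frame(step = integer(), feature = character(),
                        lambda = numeric(), Fvalue = numeric(),
                        pvalue = numeric())
  new("WilksLDA", features = features, trace = trace, classMeans = mus,
      pooledCov = S, priors = priors, classes = levels(labels))
}

#' Predict classes with a fitted discriminant model
#'
#' @param object a [WilksLDA-class].
#' @param newdata replicates x features matrix containing the model's
#'   feature columns.
#' @return factor of predicted classes; the score matrix is attached as
#'   attribute `scores`.
#' @export
setMethod("predict", "WilksLDA", function(object, newdata) {
  X <- as.matrix(newdata)[, object@features, drop = FALSE]
  Sinv <- solve(object@pooledCov)
  K <- length(object@classes)
  scores <- matrix(NA_real_, nrow(X), K,
                   dimnames = list(NULL, object@classes))
  for (k in seq_len(K)) {
    mu <- object@classMeans[k, ]
    a <- Sinv %*% mu
    scores[, k] <- X %*% a - 0.5 * sum(mu * a) + log(object@priors[k])
  }
  pred <- factor(object@classes[max.col(scores, ties.method = "first")],
                 levels = object@classes)
  attr(pred, "scores") <- scores
  pred
})

#' Evaluate a discriminant model on held-out replicates
#'
#' Row-normalised confusion matrix (true class x predicted class
#' proportions), per-class accuracy (the diagonal) and the unweighted
#' mean of per-class accuracies. A class absent from the test set is
#' reported as an `NaN` row and excluded from the mean.
#'
#' @param model a [WilksLDA-class].
#' @param X test feature matrix.
#' @param labels true test labels.
#' @return list with `confusion`, `perClass`, `meanAccuracy`.
#' @export
evaluateLDA <- function(model, X, labels) {
  labels <- factor(labels, levels = model@classes)
  pred <- predict(model, X)
  tab <- table(true = labels, predicted = pred)
  n <- rowSums(tab)
  conf <- sweep(as.matrix(tab), 1, n, "/")
  conf[n == 0, ] <- NaN
  perClass <- diag(conf)
  list(confusion = conf, perClass = perClass,
       meanAccuracy = mean(perClass, na.rm = TRUE))
}
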