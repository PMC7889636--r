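#' Partial least-squares discriminant analysis (NIPALS)
#'
#' Supervised projection maximizing covariance between the autoscaled
#' feature matrix and the one-hot-coded group membership. Components are
#' extracted by the NIPALS iteration (alternating weight/score regressions
#' to convergence, with X-loading deflation between components), so
#' successive X-score vectors are mutually orthogonal. Per-animal scores on
#' the first axes (`Y1`, `Y2`, ...) are returned together with their group
#' means and standard errors.
#'
#' @param x numeric matrix or data.frame of features (animals x features).
#' @param groups factor/character of group labels (>= 2 levels).
#' @param ncomp number of components (default 2; capped at `ncol(x)`).
#' @param scale autoscale features to unit variance (features mix units:
#'   degrees, mm^2, mmHg.s/g — so this defaults on).
#' @param tol NIPALS convergence tolerance on the score vector.
#' @param max_iter iteration cap per component.
#' @return object of class `plsda`: `scores` (T), `weights` (W), `loadings`
#'   (P), `y_loadings` (Q), `x_center`, `x_scale`, `y_center`, `levels`,
#'   `group_scores` (mean and SE of each score per group),
#'   `residual_norms` (Frobenius norm of the X residual after each
#'   component), `iterations`.
#' @export
fit_plsda <- function(x, groups, ncomp = 2, scale = TRUE, tol = 1e-10,
                      max_iter = 1e4) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (nrow(x) != length(groups)) stop("nrow(x) must match length(groups)")
  ncomp <- min(ncomp, ncol(x))
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  if (any(scl == 0))
    stop("constant feature column(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  X <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  Y <- stats::model.matrix(~ groups - 1)
  colnames(Y) <- levels(groups)
  yctr <- colMeans(Y)
  Yc <- sweep(Y, 2, yctr)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, ncol(Y), ncomp); Tm <- matrix(0, n, ncomp)
  iters <- integer(ncomp); rnorm_ <- numeric(ncomp)
  Xd <- X; Yd <- Yc
  for (a in seq_len(ncomp)) {
    if (sum(Yd^2) < 1e-24 * max(sum(Yc^2), 1e-300) ||
        sum(Xd^2) < 1e-24 * max(sum(X^2), 1e-300)) {
      ncomp <- a - 1L                      # nothing left to model
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Q <- Q[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      iters <- iters[seq_len(ncomp)]; rnorm_ <- rnorm_[seq_len(ncomp)]
      break
    }
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt)[, 1] / sum(tt^2)
      u <- (Yd %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (it == max_iter)
      stop("NIPALS failed to converge for component ", a,
           " after ", max_iter, " iterations (score change ",
           signif(sqrt(sum((tt - t_old)^2)), 3), ")")
    ## fix sign: largest-|weight| entry positive
    s <- sign(w[which.max(abs(w))])
    w <- s * w; tt <- s * tt; q <- s * q
    pl <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tt
    iters[a] <- it
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, q)
    rnorm_[a] <- sqrt(sum(Xd^2))
  }
  colnames(Tm) <- paste0("Y", seq_len(ncomp))
  rownames(W) <- rownames(P) <- colnames(x)
  gs <- do.call(rbind, lapply(levels(groups), function(g) {
    sel <- groups == g
    data.frame(group = g, axis = colnames(Tm),
               mean = colMeans(Tm[sel, , drop = FALSE]),
               se = apply(Tm[sel, , drop = FALSE], 2, stats::sd) /
                 sqrt(sum(sel)),
               row.names = NULL)
  }))
  structure(list(scores = Tm, weights = W, loadings = P, y_loadings = Q,
                 x_center = ctr, x_scale = scl, y_center = yctr,
                 levels = levels(groups), groups = groups,
                 group_scores = gs, residual_norms = rnorm_,
                 iterations = iters, ncomp = ncomp),
            class = "plsda")
}

#' Predict from a PLS-DA model
#'
#' @param object a `plsda` model.
#' @param newdata feature matrix with the training columns.
#' @param type `"class"` (default), `"scores"`, or `"response"` (the
#'   regression prediction of the dummy matrix).
#' @param ... unused.
#' @return predicted classes, score matrix, or response matrix.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "scores",
                                                    "response"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, names(object$x_center), drop = FALSE]
  X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  ## scores via the weight rotation W (P'W)^-1
  Rm <- object$weights %*% solve(crossprod(object$loadings, object$weights))
  Tn <- X %*% Rm
  colnames(Tn) <- colnames(object$scores)
  if (type == "scores") return(Tn)
  Yhat <- Tn %*% t(object$y_loadings)
  Yhat <- sweep(Yhat, 2, object$y_center, "+")
  colnames(Yhat) <- object$levels
  if (type == "response") return(Yhat)
  factor(object$levels[max.col(Yhat)], levels = object$levels)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP over all extracted components: importance of feature j is
#' `sqrt(p * sum_a ssy_a (w_ja)^2 / sum_a ssy_a)` where `ssy_a` is the
#' Y-variance captured by component a.
#'
#' @param model a `plsda` model.
#' @return named numeric vector, one VIP per feature.
#' @export
vip <- function(model) {
  ssy <- colSums(model$scores^2) * colSums(model$y_loadings^2)
  w2 <- sweep(model$weights^2, 2,
              colSums(model$weights^2), "/")
  v <- sqrt(nrow(model$weights) * (w2 %*% ssy) / sum(ssy))
  setNames(v[, 1], rownames(model$weights))
}

## stratified k-fold assignment (group-balanced), deterministic under seed
.stratified_folds <- function(groups, folds, seed) {
  .with_seed(seed, {
    f <- integer(length(groups))
    for (g in unique(groups)) {
      i <- which(groups == g)
      f[i] <- (sample(seq_along(i)) - 1L) %% folds + 1L
    }
    f
  })
}

## cross-validated classification accuracy of a PLS-DA on (x, groups)
.cv_accuracy <- function(x, groups, ncomp, folds, seed) {
  fold <- .stratified_folds(groups, folds, seed)
  hit <- 0L
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(groups[tr])) < 2) next
    m <- fit_plsda(x[tr, , drop = FALSE], groups[tr],
                   ncomp = min(ncomp, ncol(x)))
    pr <- predict(m, x[!tr, , drop = FALSE])
    hit <- hit + sum(pr == groups[!tr])
  }
  hit / length(groups)
}

#' Stepwise variable elimination for PLS-DA
#'
#' Backward elimination: at each step the feature with the smallest VIP (on
#' a full-data fit over the currently retained features) is provisionally
#' removed; the removal is kept while the cross-validated classification
#' accuracy does not fall more than `tol` below the best accuracy seen so
#' far. With `tol = Inf` elimination runs down to a single feature.
#' Deterministic given `seed` (used for the CV folds).
#'
#' @param x feature matrix.
#' @param groups group labels.
#' @param tol allowed CV-accuracy degradation before stopping.
#' @param ncomp PLS components.
#' @param folds CV folds.
#' @param seed fold seed.
#' @return list: `retained` (feature names), `model` (final `plsda` fit),
#'   `history` (per-step accuracy), `stable` (whether the selection-free
#'   baseline CV accuracy beats the majority-class rate beyond a one-sided
#'   binomial fluctuation), `chance` (majority-class rate).
#' @export
stepwise_elimination <- function(x, groups, tol = 0.05, ncomp = 2,
                                 folds = 5, seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (ncol(x) < 2) stop("need at least 2 features")
  groups <- factor(groups)
  keep <- colnames(x)
  acc <- .cv_accuracy(x, groups, ncomp, folds, seed)
  best <- acc
  hist <- data.frame(step = 0L, removed = NA_character_,
                     n_features = length(keep), cv_accuracy = acc)
  step <- 0L
  while (length(keep) > 1L) {
    m <- fit_plsda(x[, keep, drop = FALSE], groups,
                   ncomp = min(ncomp, length(keep)))
    cand <- names(which.min(vip(m)))
    trial <- setdiff(keep, cand)
    acc_t <- .cv_accuracy(x[, trial, drop = FALSE], groups,
                          ncomp, folds, seed)
    if (is.finite(tol) && acc_t < best - tol) break
    keep <- trial
    best <- max(best, acc_t)
    step <- step + 1L
    hist <- rbind(hist, data.frame(step = step, removed = cand,
                                   n_features = length(keep),
                                   cv_accuracy = acc_t))
  }
  final <- fit_plsda(x[, keep, drop = FALSE], groups,
                     ncomp = min(ncomp, length(keep)))
  chance <- max(table(groups)) / length(groups)
  ## "stable" = the *pre-selection* CV accuracy beats the majority-class
  ## rate by more than a one-sided 5% binomial fluctuation; the accuracies
  ## seen during elimination steer the search and are selection-biased, so
  ## they are not reused as evidence
  margin <- 1.645 * sqrt(chance * (1 - chance) / length(groups))
  list(retained = keep, model = final, history = hist,
       stable = hist$cv_accuracy[1] >= chance + margin,
       chance = chance)
}

#' @export
print.plsda <- function(x, ...) {
  cat("<plsda> ", length(x$levels), " groups, ", nrow(x$weights),
      " features, ", x$ncomp, " components (NIPALS, ",
      paste(x$iterations, collapse = "/"), " iterations)\n", sep = "")
  invisible(x)
}
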