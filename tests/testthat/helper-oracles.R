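# independent PLS oracle: per component, the weight vector is the leading
# left singular vector of the X-residual / Y-residual cross-covariance;
# scores, loadings and deflation follow the standard regression relations.
svd_pls_oracle <- function(X, Y, ncomp) {
  Xd <- scale(X)
  Yd <- scale(Y, scale = FALSE)
  Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    sv <- svd(crossprod(Xd, Yd))
    w <- sv$u[, 1]
    w <- w * sign(w[which.max(abs(w))])
    tt <- Xd %*% w
    p <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    q <- crossprod(Yd, tt)[, 1] / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, q)
    Tm[, a] <- tt
  }
  Tm
}
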