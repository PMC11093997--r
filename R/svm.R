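# Linear multi-class SVM (one-vs-one). No SVM package ships with this
# environment, so this is a minimal L2-regularized squared-hinge linear SVM
# trained by BFGS on the (differentiable) primal; with C = 1 and z-scored
# features it behaves like the usual linear fitcecoc/LIBLINEAR setup on the
# small trial counts used here.

svm_binary_train <- function(X, y, C = 1) {
  # y in {-1, +1}
  n <- nrow(X); p <- ncol(X)
  obj <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- 1 - y * (drop(X %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2) / n
  }
  grad <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- 1 - y * (drop(X %*% w) + b)
    act <- pmax(m, 0)
    gw <- w - 2 * C * drop(crossprod(X, y * act)) / n
    gb <- -2 * C * sum(y * act) / n
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  list(w = fit$par[1:p], b = fit$par[p + 1])
}

svm_ovo_train <- function(X, labels, C = 1) {
  cls <- sort(unique(labels))
  pairs <- utils::combn(cls, 2)
  models <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    idx <- labels %in% c(a, b)
    y <- ifelse(labels[idx] == a, 1, -1)
    c(svm_binary_train(X[idx, , drop = FALSE], y, C), list(pos = a, neg = b))
  })
  list(models = models, classes = cls)
}

svm_ovo_predict <- function(fit, X) {
  votes <- matrix(0L, nrow(X), length(fit$classes),
                  dimnames = list(NULL, as.character(fit$classes)))
  for (m in fit$models) {
    f <- drop(X %*% m$w) + m$b
    winner <- ifelse(f >= 0, as.character(m$pos), as.character(m$neg))
    for (cl in unique(winner))
      votes[winner == cl, cl] <- votes[winner == cl, cl] + 1L
  }
  fit$classes[max.col(votes, ties.method = "first")]
}
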