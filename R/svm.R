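#' Train a class-weighted RBF-kernel SVM
#'
#' C-support vector classification with a radial basis kernel
#' K(u, v) = exp(-gamma * ||u - v||^2), solved by SMO (see
#' `src/svm_smo.cpp`). Class imbalance is handled by scaling the box
#' constraint of one class: with `weight_mode = "positive"` (default) the
#' minority positive class gets C * weight_ratio, the standard balancing;
#' `weight_mode = "negative"` instead up-weights the negative class.
#' A Platt sigmoid fitted on the training decision values maps scores to
#' (0, 1) probabilities.
#'
#' @param features Numeric matrix (rows = instances).
#' @param labels 0/1 vector, both classes present.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width (default 1 / ncol).
#' @param weight_ratio Class weight multiplier, typically the
#'   negative/positive count ratio; default computed from `labels`.
#' @param weight_mode `"positive"` (weight the positive class, default)
#'   or `"negative"`.
#' @param eps SMO stopping tolerance (default 1e-3).
#' @param max_iter SMO iteration cap.
#' @return A `ptmx_svm` model object.
#' @export
train_svm <- function(features, labels, cost = 1, gamma = NULL,
                      weight_ratio = NULL,
                      weight_mode = c("positive", "negative"),
                      eps = 1e-3, max_iter = 200000L) {
  weight_mode <- match.arg(weight_mode)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y01 <- as.integer(labels)
  if (length(unique(y01)) < 2L) stop("both classes must be present")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (is.null(weight_ratio)) weight_ratio <- sum(y01 == 0) / sum(y01 == 1)
  y <- ifelse(y01 == 1L, 1, -1)
  wpos <- if (weight_mode == "positive") weight_ratio else 1
  wneg <- if (weight_mode == "negative") weight_ratio else 1
  if (length(unique(apply(X, 1, paste, collapse = ","))) == 1L)
    warning("all feature rows identical; fit is degenerate")
  K <- .rbf_kernel_cpp(X, gamma)
  Cvec <- ifelse(y > 0, cost * wpos, cost * wneg)
  fit <- .smo_train_cpp(K, y, Cvec, eps, as.integer(max_iter))
  dec <- as.numeric(K %*% (fit$alpha * y)) + fit$b
  platt <- .platt_fit(dec, y01)
  structure(list(X = X, y = y, alpha = fit$alpha, b = fit$b,
                 cost = cost, gamma = gamma,
                 weight_ratio = weight_ratio, weight_mode = weight_mode,
                 platt = platt, converged = fit$converged),
            class = "ptmx_svm")
}

#' Predict with a trained SVM
#'
#' @param object A `ptmx_svm` model.
#' @param newdata Feature matrix with the same column width as training.
#' @param type `"probability"` (Platt-calibrated, default) or
#'   `"decision"` (raw margin).
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.ptmx_svm <- function(object, newdata,
                             type = c("probability", "decision"), ...) {
  type <- match.arg(type)
  Xn <- as.matrix(newdata)
  storage.mode(Xn) <- "double"
  if (ncol(Xn) != ncol(object$X))
    stop("newdata has ", ncol(Xn), " columns; model expects ", ncol(object$X))
  K <- .rbf_cross_cpp(object$X, Xn, object$gamma)
  dec <- as.numeric(K %*% (object$alpha * object$y)) + object$b
  if (type == "decision") return(dec)
  1 / (1 + exp(object$platt$A * dec + object$platt$B))
}

#' @export
print.ptmx_svm <- function(x, ...) {
  cat(sprintf(
    "ptmx_svm: RBF C-SVC, n=%d, cost=%g, gamma=%g, %s-class weight %g, %d SVs\n",
    nrow(x$X), x$cost, x$gamma, x$weight_mode, x$weight_ratio,
    sum(x$alpha > 1e-8)))
  invisible(x)
}

# Platt's sigmoid calibration (Lin, Lin & Weng 2007 Newton iteration)
# fitted on training decision values.
.platt_fit <- function(dec, y01) {
  prior1 <- sum(y01 == 1L); prior0 <- sum(y01 == 0L)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y01 == 1L, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fApB <- dec * A + B
  obj_of <- function(fApB) {
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- obj_of(fApB)
  for (it in 1:100) {
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dec * dec * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    repeat {
      newA <- A + stepsize * dA; newB <- B + stepsize * dB
      newf <- obj_of(dec * newA + newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fApB <- dec * A + B; fval <- newf; break
      }
      stepsize <- stepsize / 2
      if (stepsize < 1e-10) break
    }
    if (stepsize < 1e-10) break
  }
  list(A = A, B = B)
}
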