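#' Firth bias-reduced logistic regression
#'
#' Fits a binary logistic regression by maximum penalized likelihood with
#' the Jeffreys-prior penalty, `l(beta) + 0.5 * log det I(beta)` (Firth's
#' bias reduction).  Unlike ordinary maximum likelihood, the penalized
#' estimates exist and are finite even under complete or quasi-complete
#' separation, which is essential when modelling rare pixel-conversion
#' events in small rings.
#'
#' The fit uses Fisher scoring on the modified score
#' `U*(beta) = X' (y - p + h (1/2 - p))`, where `h` are the hat values of
#' the weighted design, with step-halving whenever a step fails to
#' increase the penalized log-likelihood.  Convergence is declared when
#' the sup-norm of the modified score falls below `tol`.
#'
#' @param formula Model formula with a binary (0/1 or logical) response.
#' @param data Data frame.
#' @param weights Optional non-negative frequency weights.
#' @param tol Convergence tolerance on the modified-score sup-norm
#'   (default 1e-10; Newton steps converge quadratically, so the tight
#'   tolerance costs at most an iteration or two).
#' @param max_iter Maximum number of scoring iterations (default 100).
#' @return An object of class `firthglm` with components `coefficients`,
#'   `se`, `vcov`, `loglik` (penalized), `iter`, `converged`,
#'   `fitted.values`, `linear.predictors`, `y`, `n`, `call`, `terms`,
#'   `xlevels`.
#' @seealso [summary.firthglm()], [predict.firthglm()]
#' @examples
#' d <- data.frame(y = c(0, 0, 0, 1, 1), x = c(1, 2, 3, 4, 5))
#' f <- firth_glm(y ~ x, d)   # separated data: still finite
#' coef(f)
#' @export
firth_glm <- function(formula, data, weights = NULL, tol = 1e-10,
                      max_iter = 100L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  if (length(w) != length(y) || any(w < 0))
    stop("'weights' must be non-negative and match the response length")
  fit <- firth_logit(X, y, w, tol = tol, max_iter = max_iter)
  fit$call <- cl
  fit$terms <- attr(mf, "terms")
  fit$xlevels <- stats::.getXlevels(attr(mf, "terms"), mf)
  fit$formula <- formula
  fit
}

#' Low-level Firth solver on a prepared design matrix
#'
#' Maximizes the Jeffreys-penalized log-likelihood for a binary response
#' given a numeric design matrix.  `w` are frequency weights (aggregated
#' Bernoulli rows), under which the information matrix and penalized
#' likelihood equal those of the disaggregated data.
#'
#' @param X Numeric design matrix (including the intercept column).
#' @param y Binary response vector.
#' @param w Non-negative frequency weights.
#' @param tol,max_iter As in [firth_glm()].
#' @param start Optional starting coefficients (default zero).
#' @return A `firthglm` object (without formula/terms components).
#' @export
firth_logit <- function(X, y, w = rep(1, length(y)), tol = 1e-10,
                        max_iter = 100L, start = NULL) {
  X <- as.matrix(X)
  p_dim <- ncol(X)
  qrX <- qr(sqrt(pmax(w, 1e-12)) * X)
  if (qrX$rank < p_dim) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p_dim]]
    stop(sprintf("rank-deficient design matrix; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- if (is.null(start)) rep(0, p_dim) else start
  penalized_ll <- function(beta) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    ll <- sum(w * (y * stats::plogis(eta, log.p = TRUE) +
                     (1 - y) * stats::plogis(-eta, log.p = TRUE)))
    W <- w * pr * (1 - pr)
    info <- crossprod(X, X * W)
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  ll_old <- penalized_ll(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    W <- w * pr * (1 - pr)
    info <- crossprod(X, X * W)
    info_inv <- chol2inv(chol(info))
    h <- rowSums((X %*% info_inv) * X) * W   # hat values of sqrt(W) X
    score <- drop(crossprod(X, w * (y - pr) + h * (0.5 - pr)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    step <- drop(info_inv %*% score)
    # step-halving on penalized-likelihood decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- penalized_ll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { beta_new <- beta; ll_new <- ll_old; break }
    }
    beta <- beta_new
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  pr <- stats::plogis(eta)
  W <- w * pr * (1 - pr)
  info <- crossprod(X, X * W)
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, se = sqrt(diag(vcov)), vcov = vcov,
                 loglik = as.numeric(ll_old), iter = iter,
                 converged = converged, fitted.values = pr,
                 linear.predictors = eta, y = y, weights = w,
                 n = sum(w), X = X),
            class = "firthglm")
}

#' @export
print.firthglm <- function(x, ...) {
  cat("Firth bias-reduced logistic regression\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 5))
  if (!x$converged) cat("\nWARNING: did not converge\n")
  invisible(x)
}

#' Summary of a Firth logistic fit
#'
#' @param object A [firth_glm()] fit.
#' @param ... Unused.
#' @return An object of class `summary.firthglm` containing the
#'   coefficient table (estimate, SE, Wald z, two-sided p) and odds
#'   ratios.
#' @export
summary.firthglm <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `Odds ratio` = exp(est),
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 iter = object$iter, converged = object$converged,
                 n = object$n, call = object$call),
            class = "summary.firthglm")
}

#' @export
print.summary.firthglm <- function(x, ...) {
  cat("Firth bias-reduced logistic regression\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("\nn = %g, penalized log-likelihood = %.4f (%d iterations%s)\n\n",
              x$n, x$loglik, x$iter,
              if (x$converged) "" else ", NOT converged"))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.firthglm <- function(object, ...) object$coefficients

#' @export
vcov.firthglm <- function(object, ...) object$vcov

#' @export
logLik.firthglm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Wald confidence intervals for a Firth fit
#' @param object A `firthglm` object.
#' @param parm Coefficients to include (names or indices; default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.firthglm <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  if (missing(parm)) parm <- names(est)
  q <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = est[parm] - q * object$se[parm],
        upper = est[parm] + q * object$se[parm])
}

#' Predictions from a Firth logistic fit
#'
#' @param object A [firth_glm()] fit.
#' @param newdata Optional data frame; default is the training data.
#' @param type `"link"` (linear predictor) or `"response"` (probability).
#' @param ... Unused.
#' @export
predict.firthglm <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    object$linear.predictors
  } else {
    if (is.null(object$terms))
      stop("model was fitted without a formula; supply no 'newdata'")
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    drop(stats::model.matrix(tt, mf) %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.firthglm <- function(object,
                               type = c("pearson", "response", "deviance"),
                               ...) {
  type <- match.arg(type)
  y <- object$y; p <- object$fitted.values
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p))))
}

#' Simulate binary responses from a fitted Firth model
#' @param object A `firthglm` object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
simulate.firthglm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
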