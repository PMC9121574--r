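#' Firth bias-reduced logistic regression
#'
#' Fits a logistic regression by maximizing the Jeffreys-prior penalized
#' log-likelihood \deqn{\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det
#' X^\top W X, \qquad W = \mathrm{diag}\{\pi_i(1-\pi_i)\},} which yields
#' finite, bias-reduced estimates even under complete or quasi-complete
#' separation — the regime of rare-variant burden tests, where a handful of
#' carriers may all be cases. Newton-Raphson iterations use the modified
#' score \eqn{U^*_r = \sum_i x_{ir}\{y_i - \pi_i + h_i(1/2 - \pi_i)\}} with
#' \eqn{h_i} the hat-matrix leverages, with step-halving whenever a step
#' would decrease the penalized log-likelihood.
#'
#' @param formula model formula with a binary (0/1 or two-level factor)
#'   response.
#' @param data a data frame holding the variables in `formula`.
#' @param max_iter maximum Newton iterations.
#' @param tol_score convergence tolerance on the maximum absolute modified
#'   score component.
#' @param tol_beta convergence tolerance on the maximum absolute coefficient
#'   update.
#' @return An object of class `"firth_glm"`: a list with elements
#'   `coefficients`, `vcov` (inverse Fisher information at the estimate),
#'   `loglik` (penalized), `loglik_unpenalized`, `iter`, `converged`,
#'   `max_score`, plus the model frame bookkeeping used by methods.
#' @examples
#' d <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(0, 0, 0, 1, 1, 1))
#' f <- firth_glm(y ~ x, d)   # completely separated, still finite
#' coef(f)
#' @seealso [firth_plr_test()] for penalized likelihood-ratio tests,
#'   [confint.firth_glm()] for Wald and profile intervals.
#' @export
firth_glm <- function(formula, data, max_iter = 100L,
                      tol_score = 1e-6, tol_beta = 1e-8) {
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE,
                           na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- firth_fit(X, y, max_iter = max_iter,
                   tol_score = tol_score, tol_beta = tol_beta)
  fit$call <- match.call()
  fit$formula <- formula
  fit$terms <- attr(mf, "terms")
  fit$xlevels <- stats::.getXlevels(attr(mf, "terms"), mf)
  fit
}

#' Low-level Firth logistic fit on a design matrix
#'
#' The computational engine behind [firth_glm()] and every burden test.
#' Accepts an explicit design matrix so the PheWAS grid can reuse one model
#' matrix across thousands of fits. Coefficients named in `fixed` are held
#' at the supplied values while all others are re-maximized and the
#' determinant penalty is recomputed from the full design — the constrained
#' fit needed by the penalized likelihood-ratio test and by profile
#' penalized-likelihood confidence limits.
#'
#' @param X numeric design matrix (including an intercept column if one is
#'   wanted). Rank-deficient columns are dropped with a warning.
#' @param y binary response vector (0/1), `length(y) == nrow(X)`.
#' @param fixed optional named numeric vector: coefficients (by column name
#'   or index) held fixed at the given values.
#' @param beta_start optional starting values.
#' @inheritParams firth_glm
#' @return A `"firth_glm"` object (see [firth_glm()]); `converged` is
#'   `FALSE` (with everything else still populated) if the score tolerance
#'   was not met within `max_iter` iterations.
#' @export
firth_fit <- function(X, y, fixed = NULL, beta_start = NULL,
                      max_iter = 100L, tol_score = 1e-6, tol_beta = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  if (any(!y %in% c(0, 1)))
    stop("y must be binary (0/1)")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))

  # drop degenerate (rank-deficient) columns, keep fixed ones if possible
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    warning("design matrix rank-deficient; dropping column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  free <- seq_len(p)
  beta <- rep(0, p)
  names(beta) <- colnames(X)
  if (!is.null(fixed)) {
    idx <- if (is.null(names(fixed)) || any(!nzchar(names(fixed))))
      as.integer(seq_along(fixed)) else match(names(fixed), colnames(X))
    if (anyNA(idx))
      stop("fixed coefficient not found in design: ",
           paste(names(fixed)[is.na(idx)], collapse = ", "))
    beta[idx] <- as.numeric(fixed)
    free <- setdiff(free, idx)
  }
  if (!is.null(beta_start)) beta[free] <- beta_start[free]

  state <- .firth_state(X, y, beta)
  iter <- 0L
  converged <- FALSE
  max_score <- max(abs(state$U[free]), 0)
  while (iter < max_iter && length(free) > 0L) {
    iter <- iter + 1L
    delta <- rep(0, p)
    delta[free] <- tryCatch(
      solve(state$I[free, free, drop = FALSE], state$U[free]),
      error = function(e) stop("Fisher information singular at iteration ",
                               iter, ": ", conditionMessage(e)))
    # step-halving: accept only steps that do not decrease penalized loglik
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_state <- .firth_state(X, y, cand)
      if (cand_state$pll >= state$pll - 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    beta <- cand
    state <- cand_state
    max_score <- max(abs(state$U[free]))
    if (max_score < tol_score && max(abs(step * delta)) < tol_beta) {
      converged <- TRUE
      break
    }
  }
  if (length(free) == 0L) converged <- TRUE

  vc <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  vc[free, free] <- solve(state$I[free, free, drop = FALSE])
  structure(list(
    coefficients = beta,
    vcov = vc,
    loglik = state$pll,
    loglik_unpenalized = state$ll,
    fitted_values = state$pi,
    linear_predictors = drop(X %*% beta),
    hat = state$h,
    iter = iter,
    converged = converged,
    max_score = max_score,
    free = free,
    X = X,
    y = y,
    n = length(y)
  ), class = "firth_glm")
}

# penalized loglik, modified score and Fisher information at beta
.firth_state <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  Xw <- X * sqrt(w)
  I <- crossprod(Xw)
  R <- tryCatch(chol(I), error = function(e) NULL)
  if (is.null(R)) {
    # ridge epsilon only to evaluate a degenerate boundary state
    R <- chol(I + diag(1e-10, ncol(I)))
  }
  logdet <- 2 * sum(log(diag(R)))
  # leverages of the weighted hat matrix H = W^1/2 X (X'WX)^-1 X' W^1/2
  h <- colSums(forwardsolve(t(R), t(Xw))^2)
  ll <- sum(y * eta - log1p(exp(eta)))
  U <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  list(pi = pi, h = h, ll = ll, pll = ll + 0.5 * logdet, U = U, I = I)
}

#' Penalized likelihood-ratio test for one model term
#'
#' Compares the full Firth fit against a constrained fit in which the tested
#' coefficient is fixed at zero while all other coefficients are
#' re-maximized and the determinant penalty is recomputed. The statistic
#' \eqn{2(\ell^*_{full} - \ell^*_0)} is referred to a chi-squared
#' distribution with one degree of freedom. This is the test behind every
#' burden, interaction and gene-set p-value in the PheWAS grid.
#'
#' @param X design matrix.
#' @param y binary response.
#' @param term column name or index of the coefficient tested against zero.
#' @param fit optional pre-computed full fit (saves one maximization).
#' @inheritParams firth_glm
#' @return list with `statistic`, `p_value`, `fit_full`, `fit_null`;
#'   `p_value` is `NA` when the constrained fit fails to converge.
#' @export
firth_plr_test <- function(X, y, term, fit = NULL, max_iter = 100L,
                           tol_score = 1e-6, tol_beta = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.character(term)) {
    j <- match(term, colnames(X))
    if (is.na(j)) stop("term '", term, "' not found in design matrix")
  } else j <- as.integer(term)
  if (is.null(fit))
    fit <- firth_fit(X, y, max_iter = max_iter,
                     tol_score = tol_score, tol_beta = tol_beta)
  if (!(colnames(X)[j] %in% names(fit$coefficients)))
    stop("tested term '", colnames(X)[j],
         "' was dropped as rank-deficient; test undefined")
  fixed <- stats::setNames(0, colnames(X)[j])
  fit0 <- firth_fit(fit$X, fit$y, fixed = fixed, max_iter = max_iter,
                    tol_score = tol_score, tol_beta = tol_beta)
  stat <- max(0, 2 * (fit$loglik - fit0$loglik))
  p <- if (fit0$converged && fit$converged)
    stats::pchisq(stat, df = 1, lower.tail = FALSE) else NA_real_
  list(statistic = stat, p_value = p, fit_full = fit, fit_null = fit0)
}

#' Wald confidence interval and odds ratio for a fitted term
#'
#' @param fit a converged `"firth_glm"` fit.
#' @param term coefficient name or index.
#' @param level confidence level.
#' @return named vector `c(or, lower, upper)` on the odds-ratio scale.
#' @export
firth_wald_ci <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "firth_glm"))
  if (!isTRUE(fit$converged))
    stop("Wald interval refused: fit did not converge")
  j <- if (is.character(term)) match(term, names(fit$coefficients))
       else as.integer(term)
  if (is.na(j)) stop("term not found")
  b <- unname(fit$coefficients[j])
  se <- sqrt(fit$vcov[j, j])
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(b), lower = exp(b - z * se), upper = exp(b + z * se))
}

#' @export
print.firth_glm <- function(x, ...) {
  cat("Firth bias-reduced logistic regression\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat("\nCoefficients:\n")
  print(x$coefficients)
  cat("\nPenalized log-likelihood:", format(x$loglik),
      " iterations:", x$iter,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.firth_glm <- function(object, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- b / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  tab <- cbind(Estimate = b, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = p)
  out <- list(call = object$call, coefficients = tab,
              loglik = object$loglik, iter = object$iter,
              converged = object$converged, n = object$n)
  class(out) <- "summary.firth_glm"
  out
}

#' @export
print.summary.firth_glm <- function(x, ...) {
  cat("Firth bias-reduced logistic regression\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nn =", x$n, " penalized log-likelihood =", format(x$loglik),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.firth_glm <- function(object, ...) object$coefficients

#' @export
vcov.firth_glm <- function(object, ...) object$vcov

#' @export
logLik.firth_glm <- function(object, penalized = TRUE, ...) {
  val <- if (penalized) object$loglik else object$loglik_unpenalized
  structure(val, df = length(object$free), nobs = object$n,
            class = "logLik")
}

#' Confidence intervals for Firth logistic coefficients
#'
#' Wald intervals (`exp` optional via [firth_wald_ci()]) by default;
#' `type = "profile"` inverts the penalized likelihood-ratio test by
#' bisection, giving profile penalized-likelihood limits that respect the
#' asymmetry of sparse-data likelihoods.
#'
#' @param object a converged `"firth_glm"` fit.
#' @param parm coefficients to include (names or indices); all by default.
#' @param level confidence level.
#' @param type `"wald"` or `"profile"`.
#' @param ... unused.
#' @export
confint.firth_glm <- function(object, parm, level = 0.95,
                              type = c("wald", "profile"), ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  if (is.numeric(parm)) parm <- names(cf)[parm]
  a <- (1 - level) / 2
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, paste0(format(100 * c(a, 1 - a),
                                                    trim = TRUE), " %")))
  if (type == "wald") {
    z <- stats::qnorm(1 - a)
    se <- sqrt(diag(object$vcov))[parm]
    out[, 1] <- cf[parm] - z * se
    out[, 2] <- cf[parm] + z * se
    return(out)
  }
  crit <- stats::qchisq(level, df = 1)
  for (nm in parm) {
    prof <- function(v) {
      f0 <- firth_fit(object$X, object$y, fixed = stats::setNames(v, nm))
      2 * (object$loglik - f0$loglik) - crit
    }
    se <- sqrt(object$vcov[nm, nm])
    for (side in 1:2) {
      sgn <- if (side == 1) -1 else 1
      lo <- cf[nm]
      hi <- cf[nm] + sgn * 4 * se
      tries <- 0
      while (prof(hi) < 0 && tries < 10) {
        hi <- cf[nm] + sgn * 2 * abs(hi - cf[nm])
        tries <- tries + 1
      }
      out[nm, side] <- tryCatch(
        stats::uniroot(prof, sort(c(lo, hi)), tol = 1e-6)$root,
        error = function(e) NA_real_)
    }
  }
  out
}

#' @export
predict.firth_glm <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictors
  } else {
    if (is.null(object$terms))
      stop("predict with newdata requires a fit from firth_glm(formula, data)")
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    X <- X[, names(object$coefficients), drop = FALSE]
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.firth_glm <- function(object,
                                type = c("response", "pearson", "deviance"),
                                ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted_values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu))))
}

#' @export
simulate.firth_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted_values
  out <- as.data.frame(
    replicate(nsim, stats::rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
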