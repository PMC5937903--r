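#' @export
print.relme <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model (profile REML)\n")
  cat(sprintf("  n = %d observations in %d plexes (%d dropped)\n",
              x$n_obs, x$n_groups, x$n_dropped))
  cat(sprintf("  b0 = %.*g, b1 = %.*g (se %.*g)\n",
              digits, x$b0, digits, x$b1, digits, x$se_b1))
  cat(sprintf("  sigma_B^2 = %.*g, sigma_e^2 = %.*g (lambda = %.*g%s)\n",
              digits, x$sigma_B2, digits, x$sigma_e2, digits, x$lambda,
              if (x$boundary) ", boundary" else ""))
  cat(sprintf("  REML log-likelihood = %.*g\n", digits, x$reml_loglik))
  invisible(x)
}

#' @export
coef.relme <- function(object, ...) {
  c(b0 = object$b0, b1 = object$b1)
}

#' @export
vcov.relme <- function(object, ...) {
  # slope block only is exposed; intercept covariance is rarely needed here
  matrix(object$se_b1^2, 1, 1, dimnames = list("b1", "b1"))
}

#' @export
logLik.relme <- function(object, ...) {
  structure(object$reml_loglik, df = 4L, nobs = object$n_obs,
            class = "logLik")
}

#' Predictions from a random-intercept fit
#'
#' @param object a [relme] fit.
#' @param x predictor values; defaults to the training data.
#' @param groups group labels aligned with `x`; groups unseen at fit time
#'   (or `level = "population"`) get a zero random-effect prediction.
#' @param level `"plex"` adds the group BLUP, `"population"` uses the fixed
#'   part only.
#' @param ... unused.
#' @export
predict.relme <- function(object, x = object$x, groups = object$groups,
                          level = c("plex", "population"), ...) {
  level <- match.arg(level)
  eta <- object$b0 + object$b1 * x
  if (level == "plex") {
    b <- object$blups[as.character(groups)]
    b[is.na(b)] <- 0
    eta <- eta + unname(b)
  }
  eta
}

#' @export
fitted.relme <- function(object, ...) predict(object)

#' @export
residuals.relme <- function(object,
                            type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "conditional") object$y - fitted(object)
  else object$y - (object$b0 + object$b1 * object$x)
}

#' Simulate responses from a fitted random-intercept model
#'
#' Draws new plex deviations and residuals at the estimated variance
#' components and returns simulated log2 responses over the training design.
#'
#' @param object a [relme] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed, handled as in [stats::simulate].
#' @param ... unused.
#' @export
simulate.relme <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gi <- as.integer(object$groups)
  q <- object$n_groups
  eta <- object$b0 + object$b1 * object$x
  out <- replicate(nsim, {
    B <- stats::rnorm(q, 0, sqrt(object$sigma_B2))
    eta + B[gi] + stats::rnorm(object$n_obs, 0, sqrt(object$sigma_e2))
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
summary.relme <- function(object, ...) {
  p <- wald_p(object)
  as_ <- association_stats(object)
  structure(list(fit = object, p = p, r = as_$r, R2 = as_$R2,
                 b1_pct = percent_change(object$b1)),
            class = "summary.relme")
}

#' @export
print.summary.relme <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  Wald two-sided p = %.3g\n", x$p))
  cat(sprintf("  r = %.3f, R^2 = %.3f (observed vs BLUP prediction)\n",
              x$r, x$R2))
  cat(sprintf("  b1 = %+.1f%% change per 2-fold abundance increase\n",
              x$b1_pct))
  invisible(x)
}
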