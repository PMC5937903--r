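#' Random-intercept linear mixed model by profile REML
#'
#' Fits the model \deqn{y_{rk} = b_0 + b_1 x_{rk} + B_r + \varepsilon_{rk}}
#' where \eqn{B_r \sim N(0, \sigma_B^2)} is a random intercept for group
#' (plex) \eqn{r} and \eqn{\varepsilon \sim N(0, \sigma_e^2)}. In the
#' intended application \eqn{y} is the log2 plasma concentration of a
#' carotenoid, \eqn{x} the log2 relative abundance of one protein, and the
#' groups are iTRAQ experiments, so that \eqn{B_r} absorbs shared
#' batch-level measurement effects.
#'
#' Estimation profiles the REML log-likelihood down to the single variance
#' ratio \eqn{\lambda = \sigma_B^2/\sigma_e^2}: for fixed \eqn{\lambda} the
#' generalized-least-squares fixed effects and the residual variance have
#' closed forms via the within-group half-weighting transform
#' \eqn{\tilde v_i = v_i - \theta_r \bar v_r} with
#' \eqn{\theta_r = 1 - (1 + n_r\lambda)^{-1/2}}. The profiled criterion is
#' maximized over \eqn{\log\lambda} by a coarse log-spaced grid bracket on
#' \eqn{[10^{-8}, 10^{6}]} followed by golden-section/parabolic refinement
#' (\code{\link[stats]{optimize}}). A boundary solution \eqn{\hat\lambda = 0}
#' (\eqn{\hat\sigma_B^2 = 0}) is accepted and reduces the fit to ordinary
#' least squares on the pooled data.
#'
#' Incomplete cases (any of \code{y}, \code{x}, \code{groups} missing) are
#' dropped before fitting; the number dropped is recorded in the result.
#'
#' @param x numeric predictor (log2 relative abundance), or a formula
#'   \code{y ~ x} for the formula method.
#' @param y numeric response (log2 concentration), same length as \code{x}.
#' @param groups group labels (plex identifiers); coerced to factor.
#' @param min_n minimum number of complete observations required; fewer
#'   raises a condition of class \code{"relme_skip"} so that screening
#'   callers can skip-and-log rather than abort.
#' @param min_groups minimum number of distinct groups (default 2).
#' @param lambda_grid log-spaced bracketing grid for the variance ratio.
#' @param ... passed between methods.
#'
#' @return An object of class \code{"relme"}: a list with elements
#'   \code{b0}, \code{b1} (raw slope on the log2-log2 scale), \code{se_b1},
#'   \code{sigma_B2}, \code{sigma_e2}, \code{lambda} (\eqn{\hat\lambda}),
#'   \code{blups} (named per-group predicted deviations \eqn{\hat B_r}),
#'   \code{n_obs}, \code{n_groups}, \code{n_dropped}, \code{reml_loglik},
#'   \code{converged}, \code{boundary} and the model frame pieces
#'   (\code{y}, \code{x}, \code{groups}).
#'
#' @seealso [wald_p()], [percent_change()], [association_stats()],
#'   [predict.relme()], [simulate.relme()]
#' @examples
#' set.seed(1)
#' g <- rep(1:10, each = 7)
#' x <- rnorm(70)
#' y <- 0.2 + 0.6 * x + rnorm(10, 0, 0.5)[g] + rnorm(70, 0, 0.3)
#' fit <- relme(x, y, g)
#' coef(fit)
#' wald_p(fit)
#' @export
relme <- function(x, ...) UseMethod("relme")

#' @rdname relme
#' @param data data frame in which to evaluate the formula and `groups`.
#' @export
relme.formula <- function(x, data, groups, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.pass)
  if (ncol(mf) != 2L)
    stop("formula must have the form y ~ x with a single predictor")
  g <- eval(substitute(groups), data, parent.frame())
  relme.default(mf[[2L]], mf[[1L]], g, ...)
}

#' @rdname relme
#' @export
relme.default <- function(x, y, groups, min_n = 10L, min_groups = 2L,
                          lambda_grid = 10^seq(-8, 6, length.out = 33L),
                          ...) {
  if (length(y) != length(x) || length(y) != length(groups))
    stop("y, x and groups must have equal length")
  ok <- stats::complete.cases(y, x, groups)
  n_dropped <- sum(!ok)
  y <- as.numeric(y[ok]); x <- as.numeric(x[ok])
  g <- factor(groups[ok])
  N <- length(y)
  if (N < min_n)
    stop(relme_condition("relme_skip",
                         sprintf("only %d complete observations (floor %d)",
                                 N, min_n)))
  if (nlevels(g) < min_groups)
    stop(relme_condition("relme_insufficient_groups",
                         sprintf("only %d distinct group(s), need >= %d",
                                 nlevels(g), min_groups)))
  if (stats::var(x) <= 0)
    stop(relme_condition("relme_no_slope_variance",
                         "predictor has zero variance"))

  gi <- as.integer(g)
  nr <- tabulate(gi, nbins = nlevels(g))
  # group means are lambda-free; precompute expanded per observation
  gm_y <- as.vector(rowsum(y, gi)) / nr
  gm_x <- as.vector(rowsum(x, gi)) / nr
  env <- list(y = y, x = x, gi = gi, nr = nr, N = N,
              gmy = gm_y[gi], gmx = gm_x[gi])

  prof <- function(loglam) relme_profile(loglam, env)$loglik

  # lambda = 0 (OLS) limit competes with the positive-lambda bracket
  ll0 <- relme_profile(-Inf, env)$loglik
  gl <- log(lambda_grid)
  llg <- vapply(gl, prof, numeric(1))
  i <- which.max(llg)
  boundary <- FALSE; converged <- TRUE
  if (ll0 >= llg[i]) {
    sol <- relme_profile(-Inf, env)
    boundary <- TRUE
  } else if (i == 1L) {
    # maximum below the grid floor: indistinguishable from 0
    sol <- relme_profile(-Inf, env)
    boundary <- TRUE
  } else if (i == length(gl)) {
    opt <- stats::optimize(prof, c(gl[i - 1L], gl[i]), maximum = TRUE,
                           tol = 1e-9)
    sol <- relme_profile(if (opt$objective >= llg[i]) opt$maximum else gl[i],
                         env)
    converged <- opt$objective >= llg[i]  # FALSE if stuck at the cap
  } else {
    opt <- stats::optimize(prof, c(gl[i - 1L], gl[i + 1L]), maximum = TRUE,
                           tol = 1e-9)
    sol <- if (opt$objective >= llg[i]) relme_profile(opt$maximum, env)
           else relme_profile(gl[i], env)
  }

  blups <- relme_blups(sol, env)
  names(blups) <- levels(g)
  structure(list(
    b0 = sol$b0, b1 = sol$b1, se_b1 = sol$se_b1,
    sigma_B2 = sol$lambda * sol$sigma_e2, sigma_e2 = sol$sigma_e2,
    lambda = sol$lambda, blups = blups,
    n_obs = N, n_groups = nlevels(g), n_dropped = n_dropped,
    reml_loglik = sol$loglik, converged = converged, boundary = boundary,
    y = y, x = x, groups = g,
    call = match.call()), class = "relme")
}

# profiled REML pieces at log(lambda); loglam = -Inf gives the OLS limit.
relme_profile <- function(loglam, env) {
  lam <- exp(loglam)
  th <- if (is.finite(loglam)) 1 - 1 / sqrt(1 + env$nr * lam)
        else rep(0, length(env$nr))
  tg <- th[env$gi]
  yt <- env$y - tg * env$gmy
  xt <- env$x - tg * env$gmx
  c1 <- 1 - tg
  a11 <- sum(c1 * c1); a12 <- sum(c1 * xt); a22 <- sum(xt * xt)
  q1 <- sum(c1 * yt);  q2 <- sum(xt * yt);  yy <- sum(yt * yt)
  det <- a11 * a22 - a12 * a12
  b0 <- (a22 * q1 - a12 * q2) / det
  b1 <- (a11 * q2 - a12 * q1) / det
  rss <- max(yy - b0 * q1 - b1 * q2, 0)
  s2 <- rss / (env$N - 2)
  ldV <- if (is.finite(loglam)) sum(log1p(env$nr * lam)) else 0
  ll <- -0.5 * ((env$N - 2) * (log(2 * pi * max(s2, .Machine$double.xmin)) + 1)
                + ldV + log(det))
  se_b1 <- sqrt(s2 * a11 / det)
  list(lambda = if (is.finite(loglam)) lam else 0,
       b0 = b0, b1 = b1, se_b1 = se_b1, sigma_e2 = s2, loglik = ll)
}

# shrinkage predictors B_hat_r = n_r*lambda/(1 + n_r*lambda) * mean residual
relme_blups <- function(sol, env) {
  if (sol$lambda == 0) return(rep(0, length(env$nr)))
  res <- env$y - sol$b0 - sol$b1 * env$x
  mres <- as.vector(rowsum(res, env$gi)) / env$nr
  (env$nr * sol$lambda / (1 + env$nr * sol$lambda)) * mres
}

relme_condition <- function(class, msg) {
  structure(class = c(class, "relme_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Two-sided Wald p-value for the slope
#'
#' Tests \eqn{H_0: b_1 = 0} with the normal reference
#' \eqn{p = 2(1 - \Phi(|b_1/\mathrm{se}(b_1)|))}, treating the variance
#' ratio as known at its REML estimate. With hundreds of observations over
#' tens of plexes the normal reference is adequate; no degrees-of-freedom
#' correction is applied.
#'
#' @param fit a [relme] fit.
#' @return two-sided p-value in \[0, 1\]. A degenerate fit with
#'   \code{se_b1 == 0} and a nonzero slope returns 0 with a warning.
#' @export
wald_p <- function(fit) {
  stopifnot(inherits(fit, "relme"))
  if (fit$se_b1 == 0) {
    if (fit$b1 == 0) return(1)
    warning("degenerate inference: se(b1) = 0 with nonzero slope; p = 0")
    return(0)
  }
  2 * stats::pnorm(-abs(fit$b1 / fit$se_b1))
}

#' Percent change in concentration per 2-fold abundance increase
#'
#' Transforms a slope \eqn{b_1} on the log2-log2 scale into the percent
#' change in concentration per doubling (100% increase) of protein relative
#' abundance: \eqn{(2^{b_1} - 1) \times 100}. A slope of 1 is +100%
#' (concentration doubles with the protein), a slope of -1 is -50%.
#'
#' @param b1 numeric slope(s) on the log2-log2 scale.
#' @return percent change, strictly increasing in \code{b1} and bounded
#'   below by -100.
#' @export
percent_change <- function(b1) {
  stopifnot(is.numeric(b1), all(is.finite(b1)))
  (2^b1 - 1) * 100
}

#' BLUP-based correlation and goodness of fit
#'
#' Computes the association summary reported per protein: the Pearson
#' correlation between observed log2 concentrations and their model
#' predictions \eqn{\hat y_{rk} = \hat b_0 + \hat b_1 x_{rk} + \hat B_r}
#' (fixed part plus the plex BLUP), signed by the slope, and
#' \eqn{R^2 = r^2}. The sign is taken from \eqn{\hat b_1} because the
#' correlation of observations with their own predictions is non-negative
#' by construction.
#'
#' @param fit a [relme] fit.
#' @param y,x,groups optional data to evaluate on; default to the data the
#'   model was fitted to.
#' @return list with elements \code{r} and \code{R2}; both \code{NA} with a
#'   \code{degenerate} flag when the predictions have zero variance.
#' @export
association_stats <- function(fit, y = fit$y, x = fit$x,
                              groups = fit$groups) {
  stopifnot(inherits(fit, "relme"))
  yhat <- predict(fit, x = x, groups = groups)
  if (stats::sd(yhat) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, R2 = NA_real_, degenerate = TRUE))
  rho <- stats::cor(y, yhat)
  r <- sign(fit$b1) * abs(rho)
  list(r = r, R2 = r^2, degenerate = FALSE)
}
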