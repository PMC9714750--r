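#' Fit the two-state activation model to a normalized lifetime series
#'
#' Weighted nonlinear least squares of the two-state ratio
#' \eqn{(1+x)/(1+K_d x)}, \eqn{x = e^{-(\Delta E - T\Delta S)/RT}}, to the
#' normalized points inside the fit window, in the parameters
#' (\eqn{\Delta E}, \eqn{\Delta S}, \eqn{K_d}). The reference lifetime tau0
#' is fixed from the baseline stage, not co-fitted. Initialization is
#' deterministic: \eqn{\Delta E^0 = 100} kJ/mol, \eqn{\Delta S^0} chosen so
#' \eqn{\Delta E^0/\Delta S^0} equals the temperature of the steepest
#' observed drop, and \eqn{K_d^0 = 1/\min(\mathrm{ratio})}.
#'
#' Standard deviations come from the covariance of the fit (default) or
#' from a nonparametric residual bootstrap (seeded, >= 500 replicates). The
#' midpoint temperature \eqn{T_{MP} = \Delta E/(\Delta S + R\ln K_d)} and
#' its SD (delta method, or bootstrap spread) are propagated through.
#'
#' @param series a [temperature_series()] with `ratio` present (normalized).
#' @param roi a [roi_config()]; only points inside `fit_window` are fitted.
#' @param init optional [two_state_params()] overriding the default start.
#' @param uncertainty `"covariance"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (>= 500) when
#'   `uncertainty = "bootstrap"`.
#' @param seed integer seed for the bootstrap resampling.
#' @param tau0 reference lifetime attached to the fitted parameters;
#'   defaults to `series$provenance$tau0` or 28.7 ms.
#' @return an object of class `transition_fit_result`: `params`
#'   (a [two_state_params()]), `sd` (named: delta_E, delta_S, K_d), `T_MP`
#'   and `T_MP_sd`, `reduced_chi2`, `residuals`, `n_points`, `converged`,
#'   `method_meta`.
#' @export
fit_transition <- function(series, roi = roi_config(), init = NULL,
                           uncertainty = c("covariance", "bootstrap"),
                           n_boot = 500L, seed = 1L, tau0 = NULL) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(roi, "roi_config"))
  uncertainty <- match.arg(uncertainty)
  if (is.null(series$ratio))
    stop("series has no ratio values; normalize it first")
  inside <- series$temperatures >= roi$fit_window[1] &
    series$temperatures <= roi$fit_window[2]
  if (sum(inside) < 6L)
    stop("too few points: need >= 6 inside the fit window, got ", sum(inside))
  tt <- series$temperatures[inside]
  r <- series$ratio[inside]
  if (min(r) >= 0.95)
    stop("non-identifiable: no transition in window (min ratio ",
         format(min(r), digits = 3), " >= 0.95)")
  w <- if (!is.null(series$sd)) 1 / pmax(series$sd[inside], 1e-12)^2
       else rep(1, length(tt))
  if (is.null(tau0))
    tau0 <- if (!is.null(series$provenance$tau0)) series$provenance$tau0
            else 28.7

  if (is.null(init)) {
    drops <- -diff(r) / diff(tt)
    t_steep <- (tt[which.max(drops)] + tt[which.max(drops) + 1L]) / 2
    init <- list(delta_E = 100,
                 delta_S = 100 * 1000 / t_steep,
                 K_d = max(1 / min(r), 1 + 1e-6))
  }

  fit <- .fit_ratio_points(tt, r, w, init)
  if (!fit$converged)
    warning("transition fit did not converge; result flagged")
  params <- two_state_params(fit$par[1], fit$par[2], fit$par[3], tau0 = tau0)
  resid <- r - two_state_ratio(params, tt)
  dof <- length(tt) - 3L
  reduced_chi2 <- sum(w * resid^2) / dof

  if (uncertainty == "covariance") {
    covmat <- .fit_covariance(fit, tt, w, dof)
    sds <- sqrt(pmax(diag(covmat), 0))
    tmp_sd <- .midpoint_sd(params, covmat)
    meta <- list(method = "covariance", optimizer = "levenberg-marquardt")
  } else {
    if (n_boot < 500L) stop("bootstrap requires >= 500 replicates")
    boot <- withr::with_seed(as.integer(seed), {
      fitted_r <- two_state_ratio(params, tt)
      reps <- replicate(n_boot, {
        rb <- fitted_r + sample(resid, replace = TRUE)
        fb <- .fit_ratio_points(tt, pmax(rb, 1e-9), w, init)
        c(fb$par, .tmp_of(fb$par))
      })
      reps
    })
    sds <- apply(boot[1:3, , drop = FALSE], 1, stats::sd)
    tmp_sd <- stats::sd(boot[4, ])
    meta <- list(method = "bootstrap", optimizer = "levenberg-marquardt",
                 n_boot = as.integer(n_boot), seed = as.integer(seed))
  }
  names(sds) <- c("delta_E", "delta_S", "K_d")

  structure(
    list(
      params = params,
      sd = sds,
      T_MP = midpoint_temperature(params),
      T_MP_sd = tmp_sd,
      reduced_chi2 = reduced_chi2,
      residuals = resid,
      temperatures = tt,
      n_points = length(tt),
      converged = fit$converged,
      method_meta = meta
    ),
    class = "transition_fit_result"
  )
}

#' @export
print.transition_fit_result <- function(x, ...) {
  p <- x$params
  cat("<transition_fit_result>\n")
  cat(sprintf("  delta_E = %.4g +/- %.2g kJ/mol\n", p$delta_E, x$sd["delta_E"]))
  cat(sprintf("  delta_S = %.4g +/- %.2g J/(mol K)\n", p$delta_S,
              x$sd["delta_S"]))
  cat(sprintf("  K_d     = %.4g +/- %.2g\n", p$K_d, x$sd["K_d"]))
  cat(sprintf("  T_MP    = %.2f +/- %.2g K\n", x$T_MP, x$T_MP_sd))
  cat(sprintf("  reduced chi2 = %.4g on %d points (%s SDs)%s\n",
              x$reduced_chi2, x$n_points, x$method_meta$method,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

.tmp_of <- function(par) par[1] * 1000 / (par[2] + R_GAS * log(par[3]))

.ratio_model <- function(par, tt) {
  lx <- -(par[1] * 1000 - tt * par[2]) / (R_GAS * tt)
  lx <- pmin(pmax(lx, -700), 700)
  exp(log1p(exp(lx)) - log1p(par[3] * exp(lx)))
}

.fit_ratio_points <- function(tt, r, w, init) {
  sw <- sqrt(w)
  resid_fn <- function(par) sw * (r - .ratio_model(par, tt))
  fit <- minpack.lm::nls.lm(
    par = c(init$delta_E, init$delta_S, init$K_d),
    fn = resid_fn,
    lower = c(1e-6, 1e-6, 1),
    upper = c(Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                         ptol = 1e-12))
  list(par = fit$par, converged = fit$info %in% 1:4, nls = fit,
       rss = sum(resid_fn(fit$par)^2))
}

# covariance of (dE, dS, Kd): s^2 (J' J)^-1 with J the weighted-model
# Jacobian at the optimum, by central finite differences
.fit_covariance <- function(fit, tt, w, dof) {
  par <- fit$par
  sw <- sqrt(w)
  J <- vapply(1:3, function(k) {
    h <- max(1e-6, 1e-6 * abs(par[k]))
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    sw * (.ratio_model(pp, tt) - .ratio_model(pm, tt)) / (2 * h)
  }, numeric(length(tt)))
  s2 <- fit$rss / dof
  tryCatch(s2 * solve(crossprod(J)),
           error = function(e) matrix(NA_real_, 3, 3))
}
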