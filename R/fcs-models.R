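#' Triplet-diffusion autocorrelation model
#'
#' Standard single-component 3D diffusion model with a triplet blinking
#' term,
#' \deqn{G(\tau) = \frac{1}{N}\left(1 + \frac{T}{1-T} e^{-\tau/\tau_{tr}}\right)
#'   \left(1 + \frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1 + \frac{\tau}{S^2 \tau_D}\right)^{-1/2}.}
#' At `tau = 0` and `T = 0` the amplitude is `1/N`, the reciprocal of the
#' mean number of molecules in the effective volume.
#'
#' @param tau lag times, us.
#' @param n mean molecule number N (> 0).
#' @param tau_d diffusion time, us (> 0).
#' @param triplet_fraction T in `[0, 1)`.
#' @param triplet_tau triplet relaxation time, us.
#' @param structure_parameter axial-to-lateral ratio S (> 0).
#' @return G values, same length as `tau`.
#' @export
triplet_diffusion_model <- function(tau, n, tau_d, triplet_fraction,
                                    triplet_tau, structure_parameter) {
  if (n <= 0 || tau_d <= 0 || structure_parameter <= 0) {
    stop("n, tau_d and structure_parameter must be positive")
  }
  if (triplet_fraction < 0 || triplet_fraction >= 1) {
    stop("triplet_fraction must be in [0, 1): T = 1 is singular")
  }
  trip <- if (triplet_fraction > 0) {
    1 + triplet_fraction / (1 - triplet_fraction) * exp(-tau / triplet_tau)
  } else {
    1
  }
  (1 / n) * trip / (1 + tau / tau_d) /
    sqrt(1 + tau / (structure_parameter^2 * tau_d))
}

#' Pure-diffusion correlation model
#'
#' The triplet-diffusion model with the triplet term absent; used for
#' cross-correlation curves, where independent blinking of the two
#' fluorophores does not correlate.
#'
#' @inheritParams triplet_diffusion_model
#' @export
pure_diffusion_model <- function(tau, n, tau_d, structure_parameter) {
  triplet_diffusion_model(tau, n, tau_d, 0, 1, structure_parameter)
}

# default bounds for free parameters, on the fitted scale (us for times)
.fit_bounds <- function(curve) {
  max_lag <- max(curve$lags)
  list(n = c(1e-4, 1e8),
       tau_d = c(min(curve$lags) / 2, 10 * max_lag),
       triplet_fraction = c(0, 0.5),
       triplet_tau = c(1, 50),
       # free structure parameters are confined to the physical confocal
       # range; outside it the axial term trades against tau_d on a flat
       # chi-square ridge
       structure_parameter = c(2, 10))
}

.fit_init <- function(curve, model) {
  g0 <- mean(head(curve$g, 3))
  n0 <- if (is.finite(g0) && g0 > 0) 1 / g0 else NA_real_
  half <- if (is.finite(g0) && g0 > 0) {
    below <- which(curve$g <= g0 / 2)
    if (length(below)) curve$lags[below[1]] else max(curve$lags) / 4
  } else {
    max(curve$lags) / 10
  }
  list(n = n0, tau_d = half, triplet_fraction = 0.1, triplet_tau = 5,
       structure_parameter = 5)
}

#' Fit a correlation model to a measured curve
#'
#' Weighted least squares (weights `1/sigma^2`, falling back to unweighted
#' when no uncertainties are available) via Levenberg-Marquardt with at
#' least five perturbed initializations; the best chi-square wins, ties
#' broken by the smaller diffusion time. Parameters in `fixed` are held at
#' the given values (the structure parameter is normally fixed from
#' calibration for all sample fits, and the triplet relaxation time may be
#' fixed too). A triplet relaxation time fitted into the diffusion decay
#' (`triplet_tau >= tau_d / 5`) disqualifies that start unless no start
#' conforms.
#'
#' @param curve a [correlation_curve()].
#' @param model `"triplet_diffusion"` or `"pure_diffusion"`.
#' @param fixed named list of parameters to fix (e.g.
#'   `list(structure_parameter = 5)`).
#' @param init optional named list overriding the automatic initial values.
#' @param bounds optional named list of `c(lower, upper)` pairs.
#' @param n_starts number of perturbed starts (>= 5 recommended).
#' @param max_lag optional upper fit-window limit (us): lags above it are
#'   excluded from the fit. Long-lag points carry no model information once
#'   the correlation has decayed but are sensitive to slow baseline
#'   distortions, so calibration and measurement fits use a window of
#'   [half_decay_lag()] multiples (see those functions); `NULL` fits all
#'   lags.
#' @return an object of class `fcs_fit` with elements `par` (named
#'   parameter vector), `se`, `chi2`, `dof`, `model`, `fixed`,
#'   `converged`, `flags`.
#' @export
fit_curve <- function(curve, model = c("triplet_diffusion", "pure_diffusion"),
                      fixed = list(), init = list(), bounds = list(),
                      n_starts = 5, max_lag = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "correlation_curve"))
  if (!is.null(max_lag)) {
    keep <- curve$lags <= max_lag
    if (sum(keep) < 8) keep <- seq_along(curve$lags) <= 8
    curve <- correlation_curve(curve$lags[keep], curve$g[keep],
                               curve$sigma[keep], curve$kind,
                               curve$settings)
  }
  par_names <- if (model == "triplet_diffusion") {
    c("n", "tau_d", "triplet_fraction", "triplet_tau", "structure_parameter")
  } else {
    c("n", "tau_d", "structure_parameter")
  }
  fixed <- fixed[names(fixed) %in% par_names]
  free <- setdiff(par_names, names(fixed))
  if (length(curve$lags) < 3 * length(free)) {
    stop("curve has too few lags for the number of free parameters")
  }

  defaults <- .fit_init(curve, model)
  if (!is.finite(defaults$n)) {
    return(.fit_failure(model, fixed, "non-positive amplitude"))
  }
  init_all <- modifyList(defaults, init)
  b <- modifyList(.fit_bounds(curve), bounds)

  w <- if (all(is.na(curve$sigma))) {
    rep(1, length(curve$g))
  } else {
    s <- curve$sigma
    pos <- s[is.finite(s) & s > 0]
    if (!length(pos)) {
      rep(1, length(curve$g))
    } else {
      s[!is.finite(s) | s <= 0] <- min(pos)
      1 / s^2
    }
  }

  model_fun <- function(p) {
    full <- c(p, unlist(fixed))
    if (model == "triplet_diffusion") {
      triplet_diffusion_model(curve$lags, full[["n"]], full[["tau_d"]],
                              full[["triplet_fraction"]],
                              full[["triplet_tau"]],
                              full[["structure_parameter"]])
    } else {
      pure_diffusion_model(curve$lags, full[["n"]], full[["tau_d"]],
                           full[["structure_parameter"]])
    }
  }
  resid_fun <- function(p) {
    p <- setNames(pmin(pmax(p, vapply(b[free], `[`, 0, 1)),
                       vapply(b[free], `[`, 0, 2)), free)
    sqrt(w) * (model_fun(p) - curve$g)
  }

  # the pure-diffusion optimum is a guaranteed-feasible start for the nested
  # triplet model (T = 0): the triplet fit can then never end up worse
  pure_start <- NULL
  if (model == "triplet_diffusion" && all(c("n", "tau_d") %in% free)) {
    fixed_pure <- fixed[names(fixed) %in%
                          c("n", "tau_d", "structure_parameter")]
    if (!"structure_parameter" %in% names(fixed_pure)) {
      fixed_pure$structure_parameter <- init_all$structure_parameter
    }
    fp <- tryCatch(
      fit_curve(curve, "pure_diffusion", fixed = fixed_pure,
                init = init, bounds = bounds, n_starts = 5),
      error = function(e) NULL)
    if (!is.null(fp) && isTRUE(fp$converged)) {
      pure_start <- c(fp$par["n"], fp$par["tau_d"],
                      triplet_fraction = 0,
                      triplet_tau = init_all$triplet_tau,
                      structure_parameter =
                        fp$par[["structure_parameter"]])
    }
  }

  # deterministic perturbation ladder over (tau_d, T): no RNG in the fit path
  tau_fac <- c(1, 0.3, 3, 1, 0.3, 3, 0.1, 10, 0.03, 30)
  t_init <- c(0.05, 0.05, 0.05, 0.3, 0.3, 0.3, 0.05, 0.05, 0.05, 0.05)
  n_fac <- c(1, 1, 1, 1, 1, 1, 2, 0.5, 1, 1)
  n_starts <- max(n_starts,
                  if (model == "triplet_diffusion") 8 else 5)

  fits <- list()
  for (k in seq_len(n_starts + !is.null(pure_start))) {
    p0 <- unlist(init_all[free])
    if (k > n_starts) {
      p0 <- pure_start[free]
    } else {
      fk <- tau_fac[(k - 1) %% length(tau_fac) + 1]
      nk <- n_fac[(k - 1) %% length(n_fac) + 1]
      if ("tau_d" %in% free) p0[["tau_d"]] <- init_all$tau_d * fk
      if ("n" %in% free) p0[["n"]] <- init_all$n * nk
      if ("triplet_fraction" %in% free) {
        p0[["triplet_fraction"]] <- t_init[(k - 1) %% length(t_init) + 1]
      }
    }
    lower <- vapply(b[free], `[`, 0, 1)
    upper <- vapply(b[free], `[`, 0, 2)
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    par <- setNames(fit$par, free)
    full <- c(par, unlist(fixed))[par_names]
    conformant <- TRUE
    # a material triplet term must relax well below the diffusion decay,
    # otherwise the two terms swap roles on noisy curves
    if (model == "triplet_diffusion" &&
        full[["triplet_fraction"]] > 0.01 &&
        full[["triplet_tau"]] >= full[["tau_d"]] / 5) {
      conformant <- FALSE
    }
    fits[[length(fits) + 1]] <- list(fit = fit, par = par, full = full,
                                     chi2 = fit$deviance,
                                     conformant = conformant)
  }
  if (!is.null(pure_start)) {
    # the nested T = 0 solution is itself a valid candidate: the triplet
    # model can then never report a worse chi-square than pure diffusion
    par0 <- pure_start[free]
    fits[[length(fits) + 1]] <- list(
      fit = NULL, par = par0,
      full = c(par0, unlist(fixed))[par_names],
      chi2 = sum(resid_fun(par0)^2), conformant = TRUE)
  }
  if (!length(fits)) {
    return(.fit_failure(model, fixed, "no start converged"))
  }
  pool <- Filter(function(f) f$conformant, fits)
  if (!length(pool)) pool <- fits
  ord <- order(vapply(pool, function(f) f$chi2, 0),
               vapply(pool, function(f) f$full[["tau_d"]], 0))
  best <- pool[[ord[1]]]

  dof <- length(curve$g) - length(free)
  se <- rep(NA_real_, length(free))
  cov <- tryCatch({
    h <- best$fit$hessian
    s2 <- best$chi2 / max(dof, 1)
    v <- solve(h) * 2 * s2 # nls.lm hessian is 2 J'J at the optimum scale
    v
  }, error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))

  structure(list(
    model = model,
    par = best$full,
    free = free,
    fixed = fixed,
    se = setNames(se, free),
    chi2 = best$chi2,
    dof = dof,
    converged = TRUE,
    conformant = best$conformant,
    flags = character(0),
    kind = curve$kind
  ), class = "fcs_fit")
}

#' Half-decay lag of a correlation curve
#'
#' The first lag at which the curve falls below half its early amplitude
#' (mean of the first three lags); a model-free scale estimate used to set
#' fit windows.
#'
#' @param curve a [correlation_curve()].
#' @return a lag in us.
#' @export
half_decay_lag <- function(curve) {
  g0 <- mean(head(curve$g, 3))
  if (!is.finite(g0) || g0 <= 0) return(max(curve$lags))
  below <- which(curve$g <= g0 / 2)
  if (length(below)) curve$lags[below[1]] else max(curve$lags)
}

.fit_failure <- function(model, fixed, reason) {
  structure(list(model = model, par = NULL, free = character(0),
                 fixed = fixed, se = NULL, chi2 = NA_real_, dof = NA_integer_,
                 converged = FALSE, conformant = FALSE,
                 flags = c("fit_failure", reason), kind = NA_character_),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("fcs_fit (%s): FAILED (%s)\n", x$model,
                paste(x$flags, collapse = "; ")))
  } else {
    cat(sprintf("fcs_fit (%s): %s | chi2 = %.4g (dof %d)\n", x$model,
                paste(sprintf("%s = %.4g", names(x$par), x$par),
                      collapse = ", "),
                x$chi2, x$dof))
  }
  invisible(x)
}
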