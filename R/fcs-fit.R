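# Fitting the closed-form correlation model to measured curves and chaining
# through calibration to diffusion coefficients and hydrodynamic radii.

.PARAM_NAMES <- c("n_molecules", "t_d1", "t_d2", "fraction_1", "aspect_ratio",
                  "triplet_amplitude", "triplet_lifetime", "baseline")

.DEFAULT_BOUNDS <- list(
  n_molecules = c(1e-6, 1e9),
  t_d1 = c(1e-9, 10),
  t_d2 = c(1e-9, 10),
  fraction_1 = c(0, 1),
  aspect_ratio = c(1, 100),
  triplet_amplitude = c(0, 10),
  triplet_lifetime = c(1e-9, 1),
  baseline = c(-1, 1)
)

# Run code with a local, seeded RNG state without disturbing the caller's.
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for fitting the FCS model
#'
#' @param fixed Named list of parameters held constant during the fit (for
#'   example `aspect_ratio`, or `t_d1` pinned to the calibration dye's
#'   diffusion time). Parameters of [fcs_params()] not listed here are free.
#' @param initial Named list of starting values for free parameters; any
#'   omitted are filled by a data-driven heuristic (N from 1/G at the first
#'   lag, the slow diffusion time from the half-decay lag).
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults are broad physical bounds.
#' @param weighting `"none"` or `"sigma"` (weight residuals by 1/sigma where
#'   the curve provides per-lag standard errors).
#' @param max_iterations Maximum Levenberg-Marquardt iterations.
#' @param seed Integer seed for the multi-start jitter (fits are
#'   deterministic given the config and this seed).
#' @details The default `fixed` set fits a single-component curve with the
#'   slow species as component 2 (`fraction_1 = 0`, component 1 inert), the
#'   aspect ratio pinned at 5 and no triplet — i.e. free `n_molecules`,
#'   `t_d2` and `baseline`. For the two-component free-dye workflow, fix
#'   `t_d1` to the calibration dye's diffusion time and free `fraction_1`
#'   (and the triplet parameters if needed).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(fixed = list(fraction_1 = 0, t_d1 = 1e-6,
                                    aspect_ratio = 5, triplet_amplitude = 0,
                                    triplet_lifetime = 5e-6),
                       initial = list(), bounds = list(),
                       weighting = c("none", "sigma"),
                       max_iterations = 200L, seed = 1L) {
  weighting <- match.arg(weighting)
  bad <- setdiff(names(fixed), .PARAM_NAMES)
  if (length(bad)) {
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(names(initial), .PARAM_NAMES)
  if (length(bad)) {
    stop("unknown initial parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  b <- .DEFAULT_BOUNDS
  for (nm in names(bounds)) b[[nm]] <- bounds[[nm]]
  structure(list(fixed = fixed, initial = initial, bounds = b,
                 weighting = weighting,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Data-driven starting values for the free parameters.
.init_heuristic <- function(curve, fixed) {
  g1 <- curve$values[1]
  b0_guess <- mean(utils::tail(curve$values, max(3, length(curve$values) %/% 10)))
  amp <- g1 - b0_guess
  n_guess <- if (amp > 0) 1 / amp else 1
  half <- b0_guess + amp / 2
  below <- which(curve$values <= half)
  td2_guess <- if (length(below)) curve$lags[below[1]] else
    curve$lags[length(curve$lags) %/% 2]
  init <- list(
    n_molecules = max(n_guess, 1e-3),
    t_d2 = max(td2_guess, 2 * min(curve$lags)),
    fraction_1 = 0.5,
    aspect_ratio = 5,
    triplet_amplitude = 0.1,
    triplet_lifetime = 5e-6,
    baseline = 0
  )
  init$t_d1 <- if (!is.null(fixed$t_d1)) fixed$t_d1 else init$t_d2 / 10
  init
}

.assemble_params <- function(free_values, fixed) {
  all <- as.list(free_values)
  for (nm in names(fixed)) all[[nm]] <- fixed[[nm]]
  do.call(fcs_params, all[.PARAM_NAMES])
}

#' Fit the two-component + triplet model to a correlation curve
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm]) of
#' [model_correlation()] against a measured [correlation_curve()], with
#' per-parameter box bounds, optional 1/sigma weighting, and a seeded
#' multi-start fallback (three jittered restarts) if the first attempt does
#' not converge. When both diffusion times are free the components are
#' relabeled after the fit so that `t_d1 <= t_d2` (swapping
#' `fraction_1 <-> 1 - fraction_1`), removing the label-switching ambiguity.
#'
#' @param curve A [correlation_curve()].
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `params` ([fcs_params()] at the
#'   optimum), `stderr` (per-free-parameter standard errors from the
#'   linearized covariance at the optimum), `reduced_chi_square`,
#'   `converged`, `n_points`, `free` (names of the fitted parameters).
#' @export
fit_curve <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(config, "fit_config"))
  if (stats::sd(curve$values) == 0) {
    stop("degenerate (constant) curve: nothing to fit", call. = FALSE)
  }
  free_names <- setdiff(.PARAM_NAMES, names(config$fixed))
  if (length(curve$lags) < length(free_names)) {
    stop("curve has fewer points than free parameters", call. = FALSE)
  }
  weights <- if (config$weighting == "sigma" && !is.null(curve$sigma) &&
                 all(curve$sigma > 0)) 1 / curve$sigma else
    rep(1, length(curve$lags))

  init <- .init_heuristic(curve, config$fixed)
  for (nm in names(config$initial)) init[[nm]] <- config$initial[[nm]]
  lower <- vapply(free_names, function(nm) config$bounds[[nm]][1], numeric(1))
  upper <- vapply(free_names, function(nm) config$bounds[[nm]][2], numeric(1))
  start0 <- pmin(pmax(unlist(init[free_names]), lower), upper)

  residual_fn <- function(p) {
    params <- .assemble_params(stats::setNames(as.list(p), free_names),
                               config$fixed)
    (curve$values - model_correlation(params, curve$lags)) * weights
  }

  run_lm <- function(start) {
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = residual_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iterations, ftol = 1e-12, ptol = 1e-12)
    )
  }

  fit <- run_lm(start0)
  converged <- fit$info %in% 1:4
  if (!converged) {
    restarts <- .with_seed(config$seed, lapply(1:3, function(i) {
      jitter <- exp(stats::runif(length(start0), -0.7, 0.7))
      pmin(pmax(start0 * jitter, lower), upper)
    }))
    for (start in restarts) {
      alt <- run_lm(start)
      if (alt$deviance < fit$deviance) fit <- alt
      if (fit$info %in% 1:4) break
    }
    converged <- fit$info %in% 1:4
  }

  est <- stats::setNames(fit$par, free_names)
  # component relabeling: slow species is always component 2
  if (all(c("t_d1", "t_d2") %in% free_names) && est["t_d1"] > est["t_d2"]) {
    est[c("t_d1", "t_d2")] <- est[c("t_d2", "t_d1")]
    if ("fraction_1" %in% free_names) {
      est["fraction_1"] <- 1 - est["fraction_1"]
    }
  }

  n <- length(curve$lags)
  p <- length(free_names)
  dof <- max(n - p, 1)
  red_chisq <- fit$deviance / dof
  stderr <- rep(NA_real_, p)
  h <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(h, "try-error")) {
    v <- diag(h) * red_chisq
    stderr <- ifelse(v >= 0, sqrt(v), NA_real_)
  }
  names(stderr) <- free_names

  structure(
    list(params = .assemble_params(as.list(est), config$fixed),
         stderr = stderr, reduced_chi_square = red_chisq,
         converged = converged, n_points = n, free = free_names),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("FCS fit (%s) on %d points, reduced chi-square %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$reduced_chi_square))
  print(x$params)
  invisible(x)
}

#' Mean diffusion correlation time over repeat fits
#'
#' @param results List of [fit_curve()] results; unconverged fits are
#'   dropped.
#' @param component `1` or `2`: which diffusion time to pool.
#' @return List with `mean` (seconds), `se` (standard error of the mean; 0
#'   with `se_defined = FALSE` for a single repeat) and `n`.
#' @export
mean_diffusion_time <- function(results, component = 2) {
  stopifnot(component %in% c(1, 2))
  ok <- Filter(function(r) inherits(r, "fit_result") && r$converged, results)
  if (!length(ok)) {
    stop("no converged fit results to pool", call. = FALSE)
  }
  field <- if (component == 1) "t_d1" else "t_d2"
  td <- vapply(ok, function(r) r$params[[field]], numeric(1))
  n <- length(td)
  list(mean = mean(td),
       se = if (n > 1) stats::sd(td) / sqrt(n) else 0,
       se_defined = n > 1,
       n = n)
}

#' Diffusion properties of a sample from its correlation curve
#'
#' Composes the full derivation chain: fit the correlation model, take the
#' chosen component's diffusion correlation time, convert to a diffusion
#' coefficient through the focal-volume calibration, and to a hydrodynamic
#' radius through Stokes-Einstein.
#'
#' @param curve A [correlation_curve()].
#' @param config A [fit_config()].
#' @param calibration A [focal_volume_calibration()].
#' @param conditions A [solvent_conditions()].
#' @param component `1` or `2`: which fitted diffusion time to convert (by
#'   convention component 2 is the slow species, i.e. the labeled protein
#'   when component 1 is pinned to the free dye).
#' @return An object of class `diffusion_properties`:
#'   `diffusion_coefficient` (m^2/s), `hydrodynamic_radius` (m),
#'   `conditions`, and the underlying `fit`.
#' @export
analyze_sample <- function(curve, config, calibration,
                           conditions = solvent_conditions(), component = 2) {
  stopifnot(component %in% c(1, 2))
  fit <- fit_curve(curve, config)
  td <- if (component == 1) fit$params$t_d1 else fit$params$t_d2
  D <- diffusion_from_time(td, calibration)
  structure(
    list(diffusion_coefficient = D,
         hydrodynamic_radius = hydrodynamic_radius(D, conditions),
         conditions = conditions, t_d = td, component = component,
         fit = fit),
    class = "diffusion_properties"
  )
}

#' @export
print.diffusion_properties <- function(x, ...) {
  cat("Diffusion properties\n")
  cat(sprintf("  t_D (component %d) = %.4g s\n", x$component, x$t_d))
  cat(sprintf("  D  = %.4g m^2/s (%.3g x 10^-10 m^2/s)\n",
              x$diffusion_coefficient, x$diffusion_coefficient * 1e10))
  cat(sprintf("  RH = %.4g m (%.3g nm) at T = %.2f K, eta = %.3g Pa s\n",
              x$hydrodynamic_radius, x$hydrodynamic_radius * 1e9,
              x$conditions$temperature, x$conditions$viscosity))
  invisible(x)
}
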