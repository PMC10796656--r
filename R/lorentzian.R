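#' Default Lorentzian pool table
#'
#' Six-pool lineshape model for Z-spectrum fitting: water plus the five
#' resolvable solute/MT resonances.  Centers sit at the canonical chemical
#' shifts; widths are literature-typical full-widths-at-half-maximum and can
#' be overridden via the config.
#'
#' @return Data frame with columns `role`, `center_ppm`, `fwhm_ppm`.
#' @export
lorentzian_pools_default <- function() {
  data.frame(role = c("water", "amide", "guanidyl_amine", "noe_m1p6",
                      "mt", "noe_m3p5"),
             center_ppm = c(0, 3.5, 2, -1.6, -2.4, -3.5),
             fwhm_ppm = c(2.0, 1.0, 1.5, 1.5, 25.0, 3.5))
}

#' Evaluate a multi-pool Lorentzian model
#'
#' `Z(d) = z0 - sum_i A_i (w_i/2)^2 / ((w_i/2)^2 + (d - c_i)^2)`.
#'
#' @param pools Data frame with columns `amplitude` (>= 0), `fwhm_ppm` (> 0)
#'   and `center_ppm`; zero rows give the constant spectrum `z0`.
#' @param z0 Baseline (dimensionless).
#' @param grid An [offset_grid()].
#' @return A [zspectrum()] on `grid`.
#' @export
lorentzian_model <- function(pools, z0, grid) {
  grid <- offset_grid(grid)
  d <- as.numeric(grid)
  z <- rep(z0, length(d))
  if (nrow(pools) > 0) {
    stopifnot(all(pools$amplitude >= 0), all(pools$fwhm_ppm > 0))
    for (i in seq_len(nrow(pools))) {
      hw2 <- (pools$fwhm_ppm[i] / 2)^2
      z <- z - pools$amplitude[i] * hw2 / (hw2 + (d - pools$center_ppm[i])^2)
    }
  }
  zspectrum(grid, z)
}

#' Lorentzian fit configuration
#'
#' @param pools Pool table ([lorentzian_pools_default()]); centers are always
#'   fixed.
#' @param free_widths Also fit the widths (with a warning: 13 parameters
#'   against 11 points is barely determined on the default sparse grid).
#' @param amplitude_upper Upper bound for every amplitude (lower is 0).
#' @param z0_bounds Baseline bounds.
#' @param init_amplitude,init_z0 Starting values; `init_z0 = NULL` uses
#'   `max(z)`.
#' @param maxiter,ptol Optimizer control (Levenberg-Marquardt bounded least
#'   squares).
#' @return A `lorentzian_config` list.
#' @export
lorentzian_config <- function(pools = lorentzian_pools_default(),
                              free_widths = FALSE, amplitude_upper = 1,
                              z0_bounds = c(0.5, 1.1),
                              init_amplitude = 0.05, init_z0 = NULL,
                              maxiter = 1024L, ptol = 1e-10) {
  stopifnot(all(c("role", "center_ppm", "fwhm_ppm") %in% names(pools)))
  structure(list(pools = pools, free_widths = free_widths,
                 amplitude_upper = amplitude_upper, z0_bounds = z0_bounds,
                 init_amplitude = init_amplitude, init_z0 = init_z0,
                 maxiter = as.integer(maxiter), ptol = ptol),
            class = "lorentzian_config")
}

#' Fit a multi-pool Lorentzian model to a sparse Z-spectrum
#'
#' Bounded Levenberg-Marquardt least squares on the spectrum's offsets.  The
#' default model fits the baseline `z0` plus six amplitudes with centers and
#' widths fixed (7 free parameters against the 11 sparse points); fitting is
#' refused when free parameters outnumber points.
#'
#' @param spectrum A [zspectrum()] (typically on the sparse grid).
#' @param config A [lorentzian_config()].
#' @return A `cest_lorentzian` fit: pool table with fitted `amplitude`,
#'   `z0`, `ssr` (sum of squared residuals at the input offsets),
#'   `converged`, `niter`, plus the input spectrum and config.
#' @export
fit_lorentzian <- function(spectrum, config = lorentzian_config()) {
  stopifnot(inherits(spectrum, "zspectrum"),
            inherits(config, "lorentzian_config"))
  pools <- config$pools
  np <- nrow(pools)
  nfree <- 1 + np + if (config$free_widths) np else 0
  if (length(spectrum$z) < nfree)
    stop("refusing to fit ", nfree, " free parameters to only ",
         length(spectrum$z), " points")
  if (config$free_widths)
    warning("free-widths fit is barely determined on a sparse grid")
  d <- spectrum$offsets_ppm; zobs <- spectrum$z
  z0_init <- if (is.null(config$init_z0)) max(zobs) else config$init_z0

  unpack <- function(par) {
    p <- pools
    p$amplitude <- par[2:(1 + np)]
    if (config$free_widths) p$fwhm_ppm <- par[(2 + np):(1 + 2 * np)]
    p
  }
  resid_fn <- function(par) {
    p <- unpack(par)
    z <- rep(par[1], length(d))
    for (i in seq_len(np)) {
      hw2 <- (p$fwhm_ppm[i] / 2)^2
      z <- z - p$amplitude[i] * hw2 / (hw2 + (d - p$center_ppm[i])^2)
    }
    z - zobs
  }
  par0 <- c(z0_init, rep(config$init_amplitude, np))
  lower <- c(config$z0_bounds[1], rep(0, np))
  upper <- c(config$z0_bounds[2], rep(config$amplitude_upper, np))
  if (config$free_widths) {
    par0 <- c(par0, pools$fwhm_ppm)
    lower <- c(lower, rep(0.05, np))
    upper <- c(upper, rep(100, np))
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = config$maxiter, ptol = config$ptol,
                              maxfev = 100000))
  pfit <- unpack(fit$par)
  structure(list(pools = pfit, z0 = fit$par[1],
                 ssr = sum(resid_fn(fit$par)^2),
                 converged = fit$info %in% 1:4, niter = fit$niter,
                 info = fit$info, message = fit$message,
                 spectrum = spectrum, config = config),
            class = "cest_lorentzian")
}

#' @export
print.cest_lorentzian <- function(x, ...) {
  cat("Multi-pool Lorentzian fit: z0 =", signif(x$z0, 6),
      ", SSR =", signif(x$ssr, 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$pools, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cest_lorentzian <- function(object, ...) {
  stats::setNames(c(object$z0, object$pools$amplitude),
                  c("z0", object$pools$role))
}

#' Evaluate a Lorentzian fit on a (dense) grid
#'
#' The baseline method's reconstruction: the fitted lineshape model applied
#' on an arbitrary offset grid.
#'
#' @param object A `cest_lorentzian` fit.
#' @param grid Target [offset_grid()] (default the 101-point dense grid).
#' @param ... Unused.
#' @return A [zspectrum()].
#' @export
predict.cest_lorentzian <- function(object, grid = dense_offsets(), ...) {
  lorentzian_model(object$pools, object$z0, grid)
}

#' @export
residuals.cest_lorentzian <- function(object, ...) {
  predict(object, offset_grid(object$spectrum$offsets_ppm))$z -
    object$spectrum$z
}

#' Export a Lorentzian fit as JSON
#'
#' @param fit A `cest_lorentzian`.
#' @param path Output path.
#' @export
write_lorentzian_json <- function(fit, path) {
  stopifnot(inherits(fit, "cest_lorentzian"))
  jsonlite::write_json(list(z0 = fit$z0, pools = fit$pools, ssr = fit$ssr,
                            converged = fit$converged, niter = fit$niter),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Lorentzian baseline reconstruction of an image stack
#'
#' Fits the multi-pool Lorentzian model to every masked pixel's sparse
#' spectrum and evaluates the fit on the dense grid.  Pixels with identical
#' sparse spectra (common in noiseless phantoms) are fitted once and shared.
#'
#' @param stack A sparse `cest_stack`.
#' @param config A [lorentzian_config()].
#' @param dense Target dense grid.
#' @return A dense `cest_stack` with metadata `method = "lorentzian"`.
#' @export
reconstruct_stack_lorentzian <- function(stack, config = lorentzian_config(),
                                         dense = dense_offsets()) {
  stopifnot(inherits(stack, "cest_stack"))
  dense <- offset_grid(dense)
  d <- dim(stack$data)
  idx <- which(stack$mask)
  X <- matrix(stack$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  key <- apply(X, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  lut <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    fit <- fit_lorentzian(zspectrum(stack$offsets_ppm, X[i, ]), config)
    assign(key[i], predict(fit, dense)$z, envir = lut)
  }
  K <- length(dense)
  out <- matrix(NA_real_, d[1] * d[2], K)
  for (j in seq_along(idx)) out[idx[j], ] <- get(key[j], envir = lut)
  cest_stack(array(out, c(d[1], d[2], K)), as.numeric(dense),
             mask = stack$mask, meta = list(method = "lorentzian"))
}
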