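#' Assemble the Bloch-McConnell generator at one RF offset
#'
#' Builds the coupled linear system `dM/dt = A M + b` for the 7-pool model in
#' the frame rotating at the RF frequency: per-pool 3x3 Bloch blocks
#' (relaxation `R1 = 1/T1`, `R2 = 1/T2`, off-resonance
#' `dw_i = (delta_i - offset) * 1e-6 * gamma * B0`, nutation
#' `w1 = gamma * B1`), star-topology exchange between water and each solute
#' on all three magnetization components, and longitudinal recovery
#' `b[Mz_i] = fs_i / T1_i`.  Pool equilibrium magnitudes are `M0_i = fs_i`
#' with water 1.  State order is (Mx, My, Mz) per pool, water first.
#'
#' @param tissue A [tissue_model()].
#' @param pulse A [saturation_pulse()] (continuous wave).
#' @param scanner A [scanner_config()].
#' @param offset_ppm RF offset from water (ppm, scalar).
#' @return List with `A` (21 x 21 matrix, s^-1) and `b` (length-21 vector,
#'   s^-1).
#' @export
bm_system <- function(tissue, pulse, scanner, offset_ppm) {
  stopifnot(inherits(tissue, "tissue_model"),
            inherits(pulse, "saturation_pulse"),
            inherits(scanner, "scanner_config"),
            length(offset_ppm) == 1, is.finite(offset_ppm))
  a <- .tissue_arrays(tissue)
  if (!all(is.finite(unlist(a[c("fs", "ksw", "t1", "t2")]))))
    stop("non-finite tissue parameters")
  bm_system_cpp(a$fs, a$ksw, a$t1, a$t2, a$delta, offset_ppm,
                pulse$b1_uT, scanner$b0_T)
}

#' Z-spectrum container
#'
#' @param grid An [offset_grid()].
#' @param z Numeric vector of normalized water Mz values, same length as the
#'   grid; must lie within the physical bound `[-1, 1]` (tolerance 1e-9).
#' @return A `zspectrum` object (list with `offsets_ppm` and `z`).
#' @export
zspectrum <- function(grid, z) {
  grid <- offset_grid(grid)
  z <- as.numeric(z)
  if (length(z) != length(grid))
    stop("z and grid lengths differ (", length(z), " vs ", length(grid), ")")
  if (any(!is.finite(z)) || any(z < -1 - 1e-9) || any(z > 1 + 1e-9))
    stop("Z values outside the physical bound [-1, 1]")
  structure(list(offsets_ppm = as.numeric(grid), z = z), class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat("Z-spectrum:", length(x$z), "offsets in [",
      min(x$offsets_ppm), ",", max(x$offsets_ppm), "] ppm; Z range [",
      signif(min(x$z), 4), ",", signif(max(x$z), 4), "]\n")
  invisible(x)
}

#' @export
plot.zspectrum <- function(x, ...) {
  graphics::plot(x$offsets_ppm, x$z, type = "b", pch = 16, cex = 0.6,
                 xlim = rev(range(x$offsets_ppm)),
                 xlab = "offset (ppm)", ylab = expression(M[z] / M[0]), ...)
  invisible(x)
}

#' Simulate the Z-value at a single RF offset
#'
#' Computes `Z = Mz_water(t_sat) / M0_water` from the matrix-exponential
#' solution `M(t) = expm(A t) (M(0) - Mss) + Mss` with `Mss = -A^-1 b` and
#' thermal-equilibrium start (`Mx = My = 0`, `Mz = M0` per pool).  When `A`
#' is numerically singular (condition number above 1e12) the solver falls
#' back to adaptive ODE integration.
#'
#' @inheritParams bm_system
#' @return Scalar Z value.
#' @export
simulate_zvalue <- function(tissue, pulse, scanner, offset_ppm) {
  a <- .tissue_arrays(tissue)
  if (!all(is.finite(unlist(a[c("fs", "ksw", "t1", "t2")]))))
    stop("non-finite tissue parameters")
  z <- bm_zvalue_cpp(a$fs, a$ksw, a$t1, a$t2, a$delta, offset_ppm,
                     pulse$b1_uT, pulse$duration_s, scanner$b0_T)
  if (is.na(z))
    z <- simulate_zvalue_ode(tissue, pulse, scanner, offset_ppm)
  z
}

#' Reference ODE solution of the Bloch-McConnell system
#'
#' Integrates `dM/dt = A M + b` with an adaptive-step stiff solver
#' (relative tolerance 1e-8).  Serves as the independent cross-check of the
#' matrix-exponential path and as the fallback for singular `A`.
#'
#' @inheritParams bm_system
#' @param rtol,atol Integration tolerances passed to [deSolve::lsoda()].
#' @return Scalar Z value.
#' @export
simulate_zvalue_ode <- function(tissue, pulse, scanner, offset_ppm,
                                rtol = 1e-8, atol = 1e-10) {
  sys <- bm_system(tissue, pulse, scanner, offset_ppm)
  fs <- .tissue_arrays(tissue)$fs
  m0 <- rep(0, 21); m0[3 * (0:6) + 3] <- fs
  out <- deSolve::lsoda(y = m0, times = c(0, pulse$duration_s),
                        func = "bm_ode_deriv", initfunc = "bm_ode_init",
                        dllname = "cestrecon",
                        parms = c(as.vector(sys$A), sys$b),
                        rtol = rtol, atol = atol, maxsteps = 500000)
  out[nrow(out), 1 + 3] / fs[1]
}

#' Simulate a Z-spectrum on an offset grid
#'
#' Elementwise application of [simulate_zvalue()].
#'
#' @inheritParams bm_system
#' @param grid An [offset_grid()] (non-empty).
#' @return A [zspectrum()] on the same grid.
#' @export
simulate_zspectrum <- function(tissue, pulse = saturation_pulse(),
                               scanner = scanner_config(),
                               grid = dense_offsets()) {
  grid <- offset_grid(grid)
  a <- .tissue_arrays(tissue)
  z <- bm_zspectra_cpp(matrix(a$fs, 1), matrix(a$ksw, 1), matrix(a$t1, 1),
                       matrix(a$t2, 1), a$delta, as.numeric(grid),
                       pulse$b1_uT, pulse$duration_s, scanner$b0_T)
  z <- drop(z)
  if (anyNA(z)) {
    for (k in which(is.na(z)))
      z[k] <- tryCatch(
        simulate_zvalue_ode(tissue, pulse, scanner, grid[k]),
        error = function(e) stop("simulation failed at offset ", grid[k],
                                 " ppm: ", conditionMessage(e)))
  }
  zspectrum(grid, z)
}

#' Generate a paired sparse/dense training dataset
#'
#' Samples `n` tissue-parameter vectors uniformly within `bounds` and
#' simulates each tissue on both the sparse and the dense offset grid.
#' The full-scale protocol uses n = 350,000; smaller n gives a scaled-down
#' dataset with identical structure.  The generator is a pure function of
#' its configuration and seed.
#'
#' @param n Number of tissues (>= 1).
#' @param sparse,dense Offset grids, defaults [sparse_offsets()] /
#'   [dense_offsets()].
#' @param pulse,scanner Acquisition settings.
#' @param bounds Sampling bounds, see [param_bounds()].
#' @param seed Integer RNG seed; recorded in the result.
#' @param noise_sigma Standard deviation of optional i.i.d. Gaussian noise
#'   added to every Z value (default 0 = noiseless).
#' @return A `cest_dataset`: list with matrices `sparse_z` (n x 11),
#'   `dense_z` (n x 101), `params` (n x 20), the `seed` and a `meta` block
#'   (grids, pulse, scanner, bounds, noise_sigma).
#' @export
generate_dataset <- function(n, sparse = sparse_offsets(),
                             dense = dense_offsets(),
                             pulse = saturation_pulse(),
                             scanner = scanner_config(),
                             bounds = param_bounds(), seed = 1L,
                             noise_sigma = 0) {
  stopifnot(n >= 1, noise_sigma >= 0)
  sparse <- offset_grid(sparse); dense <- offset_grid(dense)
  .check_bounds(bounds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- sample_params(n, bounds)
  a <- .params_to_arrays(params)
  zs <- bm_zspectra_cpp(a$fs, a$ksw, a$t1, a$t2, a$delta, as.numeric(sparse),
                        pulse$b1_uT, pulse$duration_s, scanner$b0_T)
  zd <- bm_zspectra_cpp(a$fs, a$ksw, a$t1, a$t2, a$delta, as.numeric(dense),
                        pulse$b1_uT, pulse$duration_s, scanner$b0_T)
  if (anyNA(zs) || anyNA(zd))
    stop("simulation produced singular systems; no partial dataset returned")
  if (noise_sigma > 0) {
    zs <- zs + matrix(stats::rnorm(length(zs), 0, noise_sigma), nrow(zs))
    zd <- zd + matrix(stats::rnorm(length(zd), 0, noise_sigma), nrow(zd))
  }
  structure(list(sparse_z = zs, dense_z = zd, params = params, seed = seed,
                 meta = list(sparse = as.numeric(sparse),
                             dense = as.numeric(dense),
                             pulse = unclass(pulse),
                             scanner = unclass(scanner),
                             bounds = bounds, noise_sigma = noise_sigma)),
            class = "cest_dataset")
}

#' @export
print.cest_dataset <- function(x, ...) {
  cat("CEST training dataset:", nrow(x$sparse_z), "paired spectra (",
      ncol(x$sparse_z), "sparse /", ncol(x$dense_z), "dense offsets ), seed",
      x$seed, "\n")
  invisible(x)
}

#' Write / read a dataset container
#'
#' Single-file container holding the three arrays plus a JSON metadata block
#' (seed, grids, pulse, scanner, bounds).
#'
#' @param dataset A `cest_dataset`.
#' @param path File path.
#' @return `read_dataset()` returns the `cest_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cest_dataset"))
  obj <- unclass(dataset)
  obj$meta_json <- jsonlite::toJSON(obj$meta, auto_unbox = TRUE, digits = NA)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  obj <- readRDS(path)
  obj$meta_json <- NULL
  structure(obj, class = "cest_dataset")
}

# preserve caller RNG state around seeded sections
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
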