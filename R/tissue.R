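#' @useDynLib cestrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical pool order: water first, then solutes downfield to upfield
.POOL_ROLES <- c("water", "amide", "guanidyl_amine", "hydroxyl",
                 "noe_m1p6", "mt", "noe_m3p5")
.POOL_DELTA <- c(water = 0, amide = 3.5, guanidyl_amine = 2, hydroxyl = 1.3,
                 noe_m1p6 = -1.6, mt = -2.4, noe_m3p5 = -3.5)

# canonical packing of the 20 free parameters into a named vector
.PARAM_NAMES <- c("water_t1", "water_t2",
                  as.vector(t(outer(.POOL_ROLES[-1], c("fs", "ksw", "t2"),
                                    paste, sep = "_"))))

#' Gyromagnetic ratio of the proton
#'
#' @return Proton gyromagnetic ratio in rad s^-1 T^-1.
#' @export
gamma_proton <- function() 2.6752218744e8

#' Pool specification
#'
#' One proton pool of the multi-pool exchange model: a pool-size fraction
#' relative to water, a solute-to-water exchange rate, relaxation times and a
#' chemical-shift offset from water.
#'
#' @param role One of `"water"`, `"amide"`, `"guanidyl_amine"`, `"hydroxyl"`,
#'   `"noe_m1p6"`, `"mt"`, `"noe_m3p5"`. The resonance offset is fixed by the
#'   role (0, 3.5, 2, 1.3, -1.6, -2.4, -3.5 ppm respectively).
#' @param fs Pool-size fraction relative to water (dimensionless, > 0;
#'   water has `fs = 1`).
#' @param ksw Solute-to-water exchange rate (s^-1, >= 0); must be `NA` for
#'   water.
#' @param t1,t2 Longitudinal / transverse relaxation times (s, > 0).
#' @return A `pool_spec` object (named list).
#' @export
pool_spec <- function(role, fs, ksw = NA_real_, t1, t2) {
  role <- match.arg(role, .POOL_ROLES)
  stopifnot(is.finite(fs), fs > 0, is.finite(t1), t1 > 0,
            is.finite(t2), t2 > 0)
  if (role == "water") {
    if (!is.na(ksw)) stop("water pool has no exchange rate; leave ksw = NA")
  } else {
    stopifnot(is.finite(ksw), ksw >= 0)
  }
  structure(list(role = role, fs = fs, ksw = ksw, t1 = t1, t2 = t2,
                 delta_ppm = unname(.POOL_DELTA[role])),
            class = "pool_spec")
}

#' Seven-pool tissue model
#'
#' Assembles the full tissue parameterization: exactly one pool per role,
#' water first.  Back-exchange rates `kws_i = ksw_i * fs_i / fs_water` are
#' derived so that magnetization is conserved at thermal equilibrium.
#'
#' @param pools A list of seven [pool_spec()] objects covering every role.
#' @return A `tissue_model` object with elements `pools` (reordered
#'   canonically) and `kws` (named numeric, derived back-exchange rates).
#' @export
tissue_model <- function(pools) {
  roles <- vapply(pools, function(p) p$role, character(1))
  if (!setequal(roles, .POOL_ROLES) || anyDuplicated(roles))
    stop("tissue_model needs exactly one pool for each of the 7 roles")
  pools <- pools[match(.POOL_ROLES, roles)]
  fsw <- pools[[1]]$fs
  kws <- vapply(pools[-1], function(p) p$ksw * p$fs / fsw, numeric(1))
  names(kws) <- .POOL_ROLES[-1]
  structure(list(pools = pools, kws = kws), class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("7-pool tissue model\n")
  df <- do.call(rbind, lapply(x$pools, function(p)
    data.frame(role = p$role, fs = p$fs, ksw = p$ksw,
               t1_s = p$t1, t2_s = p$t2, delta_ppm = p$delta_ppm)))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

# pool-wise parameter vectors in canonical order, for the C++ backend
.tissue_arrays <- function(tissue) {
  list(fs   = vapply(tissue$pools, `[[`, numeric(1), "fs"),
       ksw  = c(0, vapply(tissue$pools[-1], `[[`, numeric(1), "ksw")),
       t1   = vapply(tissue$pools, `[[`, numeric(1), "t1"),
       t2   = vapply(tissue$pools, `[[`, numeric(1), "t2"),
       delta = unname(.POOL_DELTA))
}

#' Saturation pulse
#'
#' Continuous-wave RF saturation of given amplitude and duration.  Defaults
#' follow the acquisition protocol the package targets: 1.2 uT for 1.5 s.
#'
#' @param b1_uT RF amplitude in microtesla (> 0).
#' @param duration_s Saturation duration in seconds (> 0).
#' @param shape Pulse shape; only `"cw"` (continuous wave) is supported.
#' @return A `saturation_pulse` object.
#' @export
saturation_pulse <- function(b1_uT = 1.2, duration_s = 1.5, shape = "cw") {
  shape <- match.arg(shape, "cw")
  stopifnot(is.finite(b1_uT), b1_uT > 0, is.finite(duration_s), duration_s > 0)
  structure(list(b1_uT = b1_uT, duration_s = duration_s, shape = shape),
            class = "saturation_pulse")
}

#' Scanner configuration
#'
#' @param b0_T Static field strength in tesla (default 7.0).
#' @return A `scanner_config` object; `ppm2rad` is the conversion factor from
#'   ppm to rad/s at this field (`gamma * B0 * 1e-6`).
#' @export
scanner_config <- function(b0_T = 7.0) {
  stopifnot(is.finite(b0_T), b0_T > 0)
  structure(list(b0_T = b0_T, gamma_rad_per_s_per_T = gamma_proton(),
                 ppm2rad = gamma_proton() * b0_T * 1e-6),
            class = "scanner_config")
}

#' Frequency-offset grids
#'
#' `offset_grid()` validates an arbitrary grid; `sparse_offsets()` returns the
#' 11-offset acquisition schedule and `dense_offsets()` the 101-point uniform
#' grid from -6 to 6 ppm that reconstruction targets.
#'
#' @param offsets_ppm Numeric vector of finite frequency offsets (ppm);
#'   sorted increasingly and must be free of duplicates.
#' @return Numeric vector of class `offset_grid`.
#' @export
offset_grid <- function(offsets_ppm) {
  if (length(offsets_ppm) == 0) stop("offset grid must be non-empty")
  if (!all(is.finite(offsets_ppm))) stop("offsets must be finite")
  offsets_ppm <- sort(as.numeric(offsets_ppm))
  if (any(diff(offsets_ppm) <= 0)) stop("offsets must be distinct")
  structure(offsets_ppm, class = "offset_grid")
}

#' @rdname offset_grid
#' @export
sparse_offsets <- function() {
  offset_grid(c(-6.00, -3.60, -2.64, -1.68, -1.20,
                0.96, 1.92, 2.76, 3.36, 3.96, 6.00))
}

#' @rdname offset_grid
#' @export
dense_offsets <- function() offset_grid(seq(-6, 6, length.out = 101))

#' Tissue-parameter bounds
#'
#' Lower/upper bounds for the 20 free tissue parameters used to sample
#' training data: `fs`, `ksw` and `t2` for each of the six solute pools plus
#' `t1` and `t2` for water.  All solute `t1` are fixed at 1 s and water `fs`
#' at 1; resonance offsets are fixed per role.  Values are stored in absolute
#' units (fractions and seconds).
#'
#' @return A data frame with columns `name`, `role`, `param`, `lower`,
#'   `upper`, one row per free parameter, in the canonical packing order.
#' @export
param_bounds <- function() {
  b <- rbind(
    c("water",          "t1",  1,       3),
    c("water",          "t2",  20e-3,   100e-3),
    c("amide",          "fs",  0.1e-3,  3e-3),
    c("amide",          "ksw", 1,       100),
    c("amide",          "t2",  0.5e-3,  100e-3),
    c("guanidyl_amine", "fs",  0.1e-3,  2e-3),
    c("guanidyl_amine", "ksw", 100,     1000),
    c("guanidyl_amine", "t2",  0.1e-3,  5e-3),
    c("hydroxyl",       "fs",  0.1e-3,  10e-3),
    c("hydroxyl",       "ksw", 100,     2000),
    c("hydroxyl",       "t2",  0.1e-3,  5e-3),
    c("noe_m1p6",       "fs",  1e-3,    5e-3),
    c("noe_m1p6",       "ksw", 1,       50),
    c("noe_m1p6",       "t2",  0.1e-3,  1e-3),
    c("mt",             "fs",  10e-3,   200e-3),
    c("mt",             "ksw", 1,       50),
    c("mt",             "t2",  0.01e-3, 0.1e-3),
    c("noe_m3p5",       "fs",  10e-3,   50e-3),
    c("noe_m3p5",       "ksw", 1,       40),
    c("noe_m3p5",       "t2",  1e-3,    10e-3))
  df <- data.frame(role = b[, 1], param = b[, 2],
                   lower = as.numeric(b[, 3]), upper = as.numeric(b[, 4]))
  df$name <- paste(df$role, df$param, sep = "_")
  df <- df[match(.PARAM_NAMES, df$name), c("name", "role", "param", "lower", "upper")]
  rownames(df) <- NULL
  df
}

.check_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("name", "lower", "upper") %in% names(bounds)))
  if (!identical(bounds$name, .PARAM_NAMES))
    stop("bounds must contain the 20 canonical parameters in canonical order")
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)) ||
      any(bounds$lower > bounds$upper))
    stop("invalid bounds: need finite lower <= upper")
  invisible(bounds)
}

#' Sample tissue parameters uniformly within bounds
#'
#' Each free parameter is drawn independently and uniformly on its
#' `[lower, upper]` interval; fixed parameters (solute `t1` = 1 s, water
#' `fs` = 1, all resonance offsets) are set exactly.
#'
#' @param n Number of parameter vectors to draw.
#' @param bounds Bounds data frame as returned by [param_bounds()].
#' @return `sample_params()`: an `n x 20` matrix with canonical column names.
#'   `sample_tissue()`: a single [tissue_model()].
#' @export
sample_params <- function(n, bounds = param_bounds()) {
  .check_bounds(bounds)
  stopifnot(n >= 1)
  p <- matrix(stats::runif(n * 20), n, 20)
  p <- sweep(p, 2, bounds$upper - bounds$lower, `*`)
  p <- sweep(p, 2, bounds$lower, `+`)
  colnames(p) <- bounds$name
  p
}

#' @rdname sample_params
#' @export
sample_tissue <- function(bounds = param_bounds()) {
  tissue_from_params(drop(sample_params(1, bounds)))
}

#' Build a tissue model from a packed 20-parameter vector
#'
#' @param theta Numeric vector of length 20 in the canonical order of
#'   [param_bounds()] (`water_t1`, `water_t2`, then `fs`, `ksw`, `t2` per
#'   solute pool).
#' @return A [tissue_model()].
#' @export
tissue_from_params <- function(theta) {
  stopifnot(length(theta) == 20)
  theta <- as.numeric(theta)
  pools <- list(pool_spec("water", fs = 1, t1 = theta[1], t2 = theta[2]))
  for (i in seq_along(.POOL_ROLES[-1])) {
    role <- .POOL_ROLES[-1][i]
    o <- 2 + 3 * (i - 1)
    pools[[i + 1]] <- pool_spec(role, fs = theta[o + 1], ksw = theta[o + 2],
                                t1 = 1, t2 = theta[o + 3])
  }
  tissue_model(pools)
}

#' Tissue model at the midpoint of all parameter bounds
#'
#' @param bounds Bounds data frame, see [param_bounds()].
#' @return A [tissue_model()] with every free parameter at `(lower+upper)/2`.
#' @export
tissue_midpoint <- function(bounds = param_bounds()) {
  .check_bounds(bounds)
  tissue_from_params((bounds$lower + bounds$upper) / 2)
}

# expand an n x 20 parameter matrix into per-pool matrices for the C++ batch
.params_to_arrays <- function(params) {
  n <- nrow(params)
  fs <- matrix(0, n, 7); ksw <- matrix(0, n, 7)
  t1 <- matrix(1, n, 7); t2 <- matrix(0, n, 7)
  fs[, 1] <- 1; t1[, 1] <- params[, 1]; t2[, 1] <- params[, 2]
  for (i in 1:6) {
    o <- 2 + 3 * (i - 1)
    fs[, i + 1] <- params[, o + 1]
    ksw[, i + 1] <- params[, o + 2]
    t2[, i + 1] <- params[, o + 3]
  }
  list(fs = fs, ksw = ksw, t1 = t1, t2 = t2, delta = unname(.POOL_DELTA))
}
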