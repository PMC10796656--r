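#' Region parameter presets for the digital phantom
#'
#' Three tissue presets (gray-matter-like, white-matter-like, tumor-like)
#' shipped as a JSON config; each is a full 20-parameter vector inside the
#' sampling bounds.  The tumor preset has elevated amide pool size and
#' exchange rate, longer water relaxation and a reduced semi-solid MT pool.
#'
#' @param path Optional path to an alternative JSON preset file.
#' @return Named list of 20-parameter vectors (see [param_bounds()]).
#' @export
phantom_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phantom_presets.json",
                        package = "cestrecon")
  presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(presets, function(p) unlist(p)[.PARAM_NAMES])
}

#' Digital phantom specification
#'
#' An elliptical "brain" mask holding three labeled regions (gray-matter-like
#' rim, white-matter-like core, tumor-like focal disc), each with its own
#' tissue parameter vector.
#'
#' @param height,width Image dimensions (default 64 x 64).
#' @param regions Named list of 20-parameter vectors, see
#'   [phantom_presets()].
#' @param noise_sigma Standard deviation of i.i.d. Gaussian noise added to
#'   every masked Z value (default 0 = noiseless).
#' @param seed Integer seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 64L, width = 64L,
                         regions = phantom_presets(), noise_sigma = 0,
                         seed = 1L) {
  stopifnot(height >= 8, width >= 8, noise_sigma >= 0,
            all(c("gm_like", "wm_like", "tumor_like") %in% names(regions)))
  structure(list(height = as.integer(height), width = as.integer(width),
                 regions = regions, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# label map: 0 background, 1 gm_like, 2 wm_like, 3 tumor_like
.phantom_labels <- function(h, w) {
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  brain <- ((row - cy) / (0.46 * h))^2 + ((col - cx) / (0.42 * w))^2 <= 1
  core <- ((row - cy) / (0.30 * h))^2 + ((col - cx) / (0.26 * w))^2 <= 1
  tum <- (row - 0.36 * h)^2 + (col - 0.32 * w)^2 <= (0.11 * min(h, w))^2
  lab <- matrix(0L, h, w)
  lab[brain] <- 1L
  lab[brain & core] <- 2L
  lab[brain & tum] <- 3L
  lab
}

#' Generate a digital CEST phantom
#'
#' Simulates each region's Z-spectrum once on both grids via
#' [simulate_zspectrum()] and broadcasts it to the region's pixels; optional
#' i.i.d. Gaussian noise is then added per pixel and offset.  The phantom
#' stands in for in vivo acquisitions when validating the reconstruction
#' pipeline end to end; it is a pure function of its spec, grids and
#' acquisition settings.
#'
#' @param spec A [phantom_spec()].
#' @param sparse,dense Offset grids.
#' @param pulse,scanner Acquisition settings.
#' @param bounds Sampling bounds; region parameters outside them are an
#'   error, which keeps phantoms inside the training domain.
#' @return List with `sparse` and `dense` [cest_stack()]s (same mask) and
#'   the integer `labels` matrix (0 background, 1 gray-matter-like,
#'   2 white-matter-like, 3 tumor-like).
#' @export
make_phantom <- function(spec = phantom_spec(), sparse = sparse_offsets(),
                         dense = dense_offsets(), pulse = saturation_pulse(),
                         scanner = scanner_config(), bounds = param_bounds()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .check_bounds(bounds)
  region_names <- c("gm_like", "wm_like", "tumor_like")
  for (rn in region_names) {
    th <- spec$regions[[rn]]
    if (length(th) != 20 || anyNA(th))
      stop("region '", rn, "' must supply all 20 parameters")
    bad <- th < bounds$lower - 1e-12 | th > bounds$upper + 1e-12
    if (any(bad))
      stop("region '", rn, "' parameters outside bounds: ",
           paste(bounds$name[bad], collapse = ", "))
  }
  lab <- .phantom_labels(spec$height, spec$width)
  mask <- lab > 0L
  grids <- list(sparse = offset_grid(sparse), dense = offset_grid(dense))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  stacks <- lapply(grids, function(g) {
    K <- length(g)
    flat <- matrix(NA_real_, spec$height * spec$width, K)
    for (r in 1:3) {
      zs <- simulate_zspectrum(tissue_from_params(spec$regions[[region_names[r]]]),
                               pulse, scanner, g)
      px <- which(lab == r)
      flat[px, ] <- matrix(zs$z, length(px), K, byrow = TRUE)
    }
    if (spec$noise_sigma > 0) {
      idx <- which(mask)
      flat[idx, ] <- flat[idx, ] +
        matrix(stats::rnorm(length(idx) * K, 0, spec$noise_sigma),
               length(idx), K)
    }
    cest_stack(array(flat, c(spec$height, spec$width, K)), as.numeric(g),
               mask = mask, meta = list(phantom_seed = spec$seed,
                                        noise_sigma = spec$noise_sigma))
  })
  list(sparse = stacks$sparse, dense = stacks$dense, labels = lab)
}
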