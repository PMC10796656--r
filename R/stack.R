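#' CEST image stack
#'
#' An H x W x K cube of Z-values with its offset grid, an optional inclusion
#' mask and an optional unsaturated reference image.  Unmasked pixels may be
#' `NA`; masked pixels must be finite.
#'
#' @param data Numeric H x W x K array (K = number of offsets).
#' @param offsets_ppm Offset grid of length K.
#' @param mask Optional H x W logical inclusion mask (default all `TRUE`).
#' @param s0 Optional H x W reference image (signal units); present when the
#'   data have been normalized as `raw / s0`.
#' @param meta Optional metadata list.
#' @return A `cest_stack` object.
#' @export
cest_stack <- function(data, offsets_ppm, mask = NULL, s0 = NULL,
                       meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  grid <- offset_grid(offsets_ppm)
  if (dim(data)[3] != length(grid))
    stop("third dimension (", dim(data)[3], ") != grid length (",
         length(grid), ")")
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:2]))
  mz <- data[rep(mask, dim(data)[3])]
  if (any(!is.finite(mz)))
    stop("non-finite Z-values inside the mask")
  if (!is.null(s0)) stopifnot(all(dim(s0) == dim(mask)))
  structure(list(data = data, offsets_ppm = as.numeric(grid), mask = mask,
                 s0 = s0, meta = meta),
            class = "cest_stack")
}

#' @export
print.cest_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("CEST image stack:", d[1], "x", d[2], "pixels x", d[3], "offsets;",
      sum(x$mask), "masked pixels\n")
  invisible(x)
}

#' Normalize a raw signal stack by its unsaturated reference
#'
#' `data = raw / s0` pixelwise; Z-spectra are conventionally reported as
#' `S/S0`.
#'
#' @param raw H x W x K array of raw signal.
#' @param s0 H x W unsaturated reference; must be strictly positive inside
#'   the mask.
#' @param offsets_ppm Offset grid of length K.
#' @param mask Optional inclusion mask.
#' @param clip Optional upper clip applied to the normalized data (e.g.
#'   1.05); recorded in the metadata.
#' @return A normalized [cest_stack()] carrying `s0`.
#' @export
normalize_stack <- function(raw, s0, offsets_ppm, mask = NULL, clip = NULL) {
  stopifnot(is.array(raw), length(dim(raw)) == 3,
            all(dim(s0) == dim(raw)[1:2]))
  if (is.null(mask)) mask <- matrix(TRUE, dim(raw)[1], dim(raw)[2])
  nbad <- sum(s0[mask] <= 0)
  if (nbad > 0)
    stop(nbad, " masked pixels have non-positive reference signal")
  data <- sweep(raw, c(1, 2), s0, `/`)
  if (!is.null(clip)) data <- pmin(data, clip)
  data[rep(!mask, dim(raw)[3])] <- NA_real_
  cest_stack(data, offsets_ppm, mask = mask, s0 = s0,
             meta = list(normalized = TRUE, clip = clip))
}

#' Write / read a CEST stack as NIfTI with an offsets sidecar
#'
#' The image is one 3-D NIfTI volume (offsets along the third dimension); the
#' offset grid is a one-column CSV sidecar; mask and reference are optional
#' companion volumes.
#'
#' @param stack A `cest_stack`.
#' @param path NIfTI path (e.g. `stack.nii.gz`); the sidecar is written next
#'   to it as `<path>_offsets.csv`, mask as `<path>_mask.nii.gz`.
#' @return `read_stack()` returns the `cest_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cest_stack"))
  RNifti::writeNifti(stack$data, path)
  utils::write.csv(data.frame(offset_ppm = stack$offsets_ppm),
                   paste0(path, "_offsets.csv"), row.names = FALSE)
  RNifti::writeNifti(array(as.integer(stack$mask), dim = dim(stack$mask)),
                     paste0(path, "_mask.nii.gz"))
  if (!is.null(stack$s0)) RNifti::writeNifti(stack$s0, paste0(path, "_s0.nii.gz"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  data <- array(RNifti::readNifti(path), dim = dim(RNifti::readNifti(path)))
  off <- utils::read.csv(paste0(path, "_offsets.csv"))$offset_ppm
  mask_path <- paste0(path, "_mask.nii.gz")
  mask <- if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    matrix(as.logical(m), dim(m)[1], dim(m)[2])
  } else NULL
  s0_path <- paste0(path, "_s0.nii.gz")
  s0 <- if (file.exists(s0_path)) {
    s <- RNifti::readNifti(s0_path); matrix(as.numeric(s), dim(s)[1], dim(s)[2])
  } else NULL
  cest_stack(data, off, mask = mask, s0 = s0)
}

#' Pixel-wise reconstruction of a dense stack from a sparse stack
#'
#' Applies a trained sequence-to-sequence model to every masked pixel's
#' sparse Z-spectrum; unmasked pixels are filled with `NA` and never read.
#'
#' @param model A trained `cest_seq2seq` whose bound sparse grid equals the
#'   stack's grid.
#' @param stack A sparse `cest_stack`.
#' @return A dense `cest_stack` on the model's dense grid, same mask.
#' @export
reconstruct_stack <- function(model, stack) {
  stopifnot(inherits(model, "cest_seq2seq"), inherits(stack, "cest_stack"),
            isTRUE(model$trained))
  if (!isTRUE(all.equal(stack$offsets_ppm, model$grids$sparse)))
    stop("stack grid [", paste(signif(stack$offsets_ppm, 3), collapse = ", "),
         "] does not match the model's sparse grid [",
         paste(signif(model$grids$sparse, 3), collapse = ", "), "]")
  d <- dim(stack$data)
  idx <- which(stack$mask)
  X <- matrix(stack$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  Y <- predict(model, X)
  K <- model$config$output_len
  out <- matrix(NA_real_, d[1] * d[2], K)
  out[idx, ] <- Y
  cest_stack(array(out, c(d[1], d[2], K)), model$grids$dense,
             mask = stack$mask,
             meta = list(reconstructed_by = model$config$architecture))
}
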