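# Reconstruction scoring: absolute error modulus, pooled regression,
# SSIM and PSNR, computed per offset frame over the inclusion mask.

.check_pair <- function(recon, truth) {
  stopifnot(inherits(recon, "cest_stack"), inherits(truth, "cest_stack"))
  if (!isTRUE(all.equal(recon$offsets_ppm, truth$offsets_ppm)))
    stop("offset grids differ")
  if (!all(dim(recon$data) == dim(truth$data)))
    stop("stack dimensions differ")
  if (!identical(recon$mask, truth$mask))
    stop("masks differ")
  invisible(TRUE)
}

#' Absolute error modulus
#'
#' `|recon - truth| * 100`, in percent of the normalized Z signal, over
#' masked pixels, with per-offset means.
#'
#' @param recon,truth `cest_stack`s on the same grid and mask.
#' @return List with `map` (H x W x K array, `NA` outside the mask) and
#'   `per_offset` (length-K vector of means over the mask).
#' @export
abs_error_modulus <- function(recon, truth) {
  .check_pair(recon, truth)
  map <- abs(recon$data - truth$data) * 100
  K <- dim(map)[3]
  m <- matrix(map, ncol = K)[which(recon$mask), , drop = FALSE]
  list(map = map, per_offset = colMeans(m))
}

#' Pooled regression of reconstruction on ground truth
#'
#' Ordinary least squares of reconstructed Z-values on true Z-values pooled
#' over all masked pixels and all offsets;
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param recon,truth `cest_stack`s, or plain numeric matrices/vectors of
#'   paired values.
#' @return List with `slope`, `intercept`, `r2` and `n`.
#' @export
regression_r2 <- function(recon, truth) {
  if (inherits(recon, "cest_stack")) {
    .check_pair(recon, truth)
    K <- dim(recon$data)[3]
    idx <- which(recon$mask)
    x <- as.vector(matrix(truth$data, ncol = K)[idx, ])
    y <- as.vector(matrix(recon$data, ncol = K)[idx, ])
  } else {
    x <- as.vector(truth); y <- as.vector(recon)
  }
  if (length(x) < 2) stop("need at least 2 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant ground truth: R^2 undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ssres <- sum((y - intercept - slope * x)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) { if (ssres == 0) 1 else -Inf } else 1 - ssres / sstot
  list(slope = slope, intercept = intercept, r2 = r2, n = length(x))
}

# separable Gaussian filtering with zero padding; callers crop the border
# so padding never reaches retained pixels
.gauss_kernel1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

.gauss_filter2 <- function(img, k) {
  r <- (length(k) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  tmp <- matrix(0, h, w)
  for (j in seq_along(k)) {
    s <- j - r - 1
    rows_out <- max(1, 1 - s):min(h, h - s)
    tmp[rows_out, ] <- tmp[rows_out, ] + k[j] * img[rows_out + s, ]
  }
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {
    s <- j - r - 1
    cols_out <- max(1, 1 - s):min(w, w - s)
    out[, cols_out] <- out[, cols_out] + k[j] * tmp[, cols_out + s]
  }
  out
}

# single-frame SSIM map (standard Gaussian-window algorithm, window 11,
# sigma 1.5, K1 = 0.01, K2 = 0.03, sample-covariance normalization)
.ssim_map <- function(x, y, data_range = 1, size = 11L, sigma = 1.5) {
  k <- .gauss_kernel1d(size, sigma)
  np <- size^2
  cov_norm <- np / (np - 1)
  ux <- .gauss_filter2(x, k); uy <- .gauss_filter2(y, k)
  uxx <- .gauss_filter2(x * x, k); uyy <- .gauss_filter2(y * y, k)
  uxy <- .gauss_filter2(x * y, k)
  vx <- cov_norm * (uxx - ux^2); vy <- cov_norm * (uyy - uy^2)
  cxy <- cov_norm * (uxy - ux * uy)
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  ((2 * ux * uy + c1) * (2 * cxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
}

#' Per-offset SSIM
#'
#' Structural similarity per offset frame with a Gaussian window (size 11,
#' sigma 1.5), stabilizers `K1 = 0.01`, `K2 = 0.03` and data range 1.0.
#' Values outside the mask are zero-filled in both frames before windowed
#' filtering; the SSIM map is averaged over masked pixels inside the
#' crop border (half window width), so border padding never contributes.
#'
#' @param recon,truth `cest_stack`s on the same grid and mask.
#' @param data_range Dynamic range of the normalized signal (default 1.0).
#' @return Length-K vector of SSIM values.
#' @export
ssim_per_offset <- function(recon, truth, data_range = 1) {
  .check_pair(recon, truth)
  K <- dim(recon$data)[3]
  pad <- 5L
  h <- dim(recon$data)[1]; w <- dim(recon$data)[2]
  inner <- matrix(FALSE, h, w)
  inner[(pad + 1):(h - pad), (pad + 1):(w - pad)] <- TRUE
  sel <- recon$mask & inner
  if (!any(sel)) stop("mask empty after border crop")
  vapply(seq_len(K), function(kk) {
    x <- recon$data[, , kk]; y <- truth$data[, , kk]
    x[!recon$mask] <- 0; y[!truth$mask] <- 0
    mean(.ssim_map(x, y, data_range)[sel])
  }, numeric(1))
}

#' Per-offset PSNR
#'
#' `10 log10(data_range^2 / MSE)` in dB per offset frame over masked pixels.
#' Identical frames give `+Inf`, which [evaluate_stacks()] excludes from the
#' grand mean with a warning.
#'
#' @inheritParams ssim_per_offset
#' @return Length-K vector of PSNR values (dB).
#' @export
psnr_per_offset <- function(recon, truth, data_range = 1) {
  .check_pair(recon, truth)
  K <- dim(recon$data)[3]
  idx <- which(recon$mask)
  rm_ <- matrix(recon$data, ncol = K)[idx, , drop = FALSE]
  tm_ <- matrix(truth$data, ncol = K)[idx, , drop = FALSE]
  mse <- colMeans((rm_ - tm_)^2)
  10 * log10(data_range^2 / mse)
}

#' Full evaluation report
#'
#' Scores a reconstructed stack against ground truth with all four
#' instruments: per-offset mean absolute error modulus, per-offset SSIM and
#' PSNR with grand means, and the pooled regression over masked pixels and
#' offsets.
#'
#' @inheritParams ssim_per_offset
#' @param method Label for the reconstruction method (stored in the report).
#' @return A `cest_eval_report` list: `per_offset` data frame
#'   (`offset_ppm`, `mae_pct`, `ssim`, `psnr_db`), `regression`, grand means
#'   `mean_mae_pct`, `mean_ssim`, `mean_psnr_db`, and counts `n_pixels`,
#'   `n_offsets`.
#' @export
evaluate_stacks <- function(recon, truth, data_range = 1, method = NA_character_) {
  .check_pair(recon, truth)
  mae <- abs_error_modulus(recon, truth)
  ssim <- ssim_per_offset(recon, truth, data_range)
  psnr <- psnr_per_offset(recon, truth, data_range)
  reg <- regression_r2(recon, truth)
  finite_psnr <- psnr[is.finite(psnr)]
  if (length(finite_psnr) < length(psnr))
    warning("excluding ", length(psnr) - length(finite_psnr),
            " infinite PSNR frame(s) from the grand mean")
  structure(list(method = method,
                 per_offset = data.frame(offset_ppm = recon$offsets_ppm,
                                         mae_pct = mae$per_offset,
                                         ssim = ssim, psnr_db = psnr),
                 regression = reg,
                 mean_mae_pct = mean(mae$per_offset),
                 mean_ssim = mean(ssim),
                 mean_psnr_db = mean(finite_psnr),
                 n_pixels = sum(recon$mask),
                 n_offsets = length(recon$offsets_ppm)),
            class = "cest_eval_report")
}

#' @export
print.cest_eval_report <- function(x, ...) {
  cat("Reconstruction evaluation",
      if (!is.na(x$method)) paste0("(", x$method, ")"), "\n")
  cat(sprintf("  pixels %d x offsets %d\n", x$n_pixels, x$n_offsets))
  cat(sprintf("  mean |error| %.3f%%   mean SSIM %.4f   mean PSNR %.2f dB\n",
              x$mean_mae_pct, x$mean_ssim, x$mean_psnr_db))
  cat(sprintf("  pooled regression: slope %.4f intercept %.4f R2 %.4f\n",
              x$regression$slope, x$regression$intercept, x$regression$r2))
  invisible(x)
}

#' Write evaluation report(s) to JSON / CSV
#'
#' `write_report_json()` serializes one report; `report_table()` assembles
#' the mean-SSIM/PSNR comparison table (methods as columns) from several
#' reports.
#'
#' @param report A `cest_eval_report` (or a list of them for
#'   `report_table()`).
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cest_eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_report_json
#' @export
report_table <- function(report) {
  stopifnot(is.list(report), all(vapply(report, inherits, logical(1),
                                        "cest_eval_report")))
  methods <- vapply(report, function(r) as.character(r$method), character(1))
  tab <- rbind(SSIM = vapply(report, function(r) r$mean_ssim, numeric(1)),
               PSNR = vapply(report, function(r) r$mean_psnr_db, numeric(1)))
  colnames(tab) <- methods
  tab
}
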