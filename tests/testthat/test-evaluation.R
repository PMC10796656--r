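make_stack <- function(data, offsets, mask = NULL) {
  cest_stack(data, offsets, mask = mask)
}

test_that("absolute error modulus matches analytic and loop oracles", {
  truth <- make_stack(array(0.50, c(8, 8, 3)), c(-1, 0, 1))
  recon <- make_stack(array(0.53, c(8, 8, 3)), c(-1, 0, 1))
  mae <- abs_error_modulus(recon, truth)
  expect_equal(mae$per_offset, rep(3.0, 3))
  expect_true(all(abs(mae$map - 3.0) < 1e-12))

  set.seed(31)
  a <- array(runif(8 * 8 * 3), c(8, 8, 3))
  b <- array(runif(8 * 8 * 3), c(8, 8, 3))
  mask <- matrix(runif(64) > 0.3, 8, 8)
  a[array(rep(!mask, 3), dim(a))] <- NA
  b[array(rep(!mask, 3), dim(b))] <- NA
  sa <- make_stack(a, c(-1, 0, 1), mask); sb <- make_stack(b, c(-1, 0, 1), mask)
  mae2 <- abs_error_modulus(sa, sb)
  loop <- sapply(1:3, function(k) {
    s <- 0; nvis <- 0
    for (i in 1:8) for (j in 1:8) if (mask[i, j]) {
      s <- s + abs(a[i, j, k] - b[i, j, k]) * 100; nvis <- nvis + 1
    }
    s / nvis
  })
  expect_equal(mae2$per_offset, loop, tolerance = 1e-12)

  expect_equal(abs_error_modulus(sa, sa)$per_offset, rep(0, 3))
})

test_that("pooled regression recovers exact linear relations", {
  set.seed(8)
  truth <- make_stack(array(runif(6 * 6 * 4), c(6, 6, 4)), 1:4)
  ident <- regression_r2(truth, truth)
  expect_equal(ident$slope, 1); expect_equal(ident$intercept, 0)
  expect_equal(ident$r2, 1)

  lin <- make_stack(2 * truth$data + 0.1, 1:4)
  r <- regression_r2(lin, truth)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 0.1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  # closed-form oracle: R^2 equals squared correlation for simple OLS
  noisy <- make_stack(truth$data + array(rnorm(6 * 6 * 4, 0, 0.2),
                                         c(6, 6, 4)), 1:4)
  r2 <- regression_r2(noisy, truth)$r2
  expect_equal(r2, cor(as.vector(truth$data), as.vector(noisy$data))^2,
               tolerance = 1e-10)

  const <- make_stack(array(0.5, c(6, 6, 4)), 1:4)
  expect_error(regression_r2(noisy, const), "constant ground truth")
})

test_that("SSIM matches the reference implementation and its identities", {
  set.seed(424242)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(pmin(1, pmax(0, x + rnorm(64 * 64, 0, 0.05))), 64, 64)
  sx <- make_stack(array(c(x), c(64, 64, 1)), 0)
  sy <- make_stack(array(c(y), c(64, 64, 1)), 0)
  # frozen value from scikit-image structural_similarity with Gaussian
  # weights (sigma 1.5, 11x11 window), sample covariance, data_range 1
  expect_equal(ssim_per_offset(sx, sy), 0.9853547283404085, tolerance = 1e-6)
  expect_equal(ssim_per_offset(sx, sx), 1.0)
  expect_equal(ssim_per_offset(sx, sy), ssim_per_offset(sy, sx))
})

test_that("PSNR follows its analytic definition with an infinity sentinel", {
  truth <- make_stack(array(0.5, c(16, 16, 2)), c(0, 1))
  recon <- make_stack(array(0.6, c(16, 16, 2)), c(0, 1))
  expect_equal(psnr_per_offset(recon, truth), rep(20, 2), tolerance = 1e-12)
  expect_true(all(psnr_per_offset(truth, truth) == Inf))
})

test_that("metrics ignore unmasked pixels entirely", {
  set.seed(9)
  mask <- matrix(FALSE, 20, 20); mask[5:16, 5:16] <- TRUE
  base <- array(runif(20 * 20 * 2), c(20, 20, 2))
  noise <- base + array(rnorm(20 * 20 * 2, 0, 0.03), c(20, 20, 2))
  poison <- function(a, val) { a[array(rep(!mask, 2), dim(a))] <- val; a }
  t1 <- make_stack(poison(base, 0.1), c(0, 1), mask)
  r1 <- make_stack(poison(noise, 0.1), c(0, 1), mask)
  t2 <- make_stack(poison(base, 9999), c(0, 1), mask)
  r2 <- make_stack(poison(noise, -9999), c(0, 1), mask)
  expect_equal(abs_error_modulus(r1, t1)$per_offset,
               abs_error_modulus(r2, t2)$per_offset)
  expect_equal(psnr_per_offset(r1, t1), psnr_per_offset(r2, t2))
  expect_equal(regression_r2(r1, t1), regression_r2(r2, t2))
  # SSIM zero-fills outside the mask, so poisoned values cannot leak
  expect_equal(ssim_per_offset(r1, t1), ssim_per_offset(r2, t2))
})

test_that("added noise degrades mean SSIM and PSNR", {
  set.seed(14)
  base <- array(runif(32 * 32 * 2), c(32, 32, 2))
  truth <- make_stack(base, c(0, 1))
  for (s in 1:3) {
    small <- make_stack(base + array(rnorm(length(base), 0, 0.01), dim(base)),
                        c(0, 1))
    big <- make_stack(base + array(rnorm(length(base), 0, 0.08), dim(base)),
                      c(0, 1))
    expect_gt(mean(ssim_per_offset(small, truth)),
              mean(ssim_per_offset(big, truth)))
    expect_gt(mean(psnr_per_offset(small, truth)),
              mean(psnr_per_offset(big, truth)))
  }
})

test_that("evaluation report aggregates its parts consistently", {
  set.seed(77)
  base <- array(runif(16 * 16 * 3, 0.2, 0.9), c(16, 16, 3))
  truth <- make_stack(base, c(-1, 0, 1))
  recon <- make_stack(base + array(rnorm(length(base), 0, 0.02), dim(base)),
                      c(-1, 0, 1))
  rep <- evaluate_stacks(recon, truth, method = "test")
  expect_s3_class(rep, "cest_eval_report")
  expect_equal(rep$mean_mae_pct, mean(rep$per_offset$mae_pct))
  expect_equal(rep$mean_ssim, mean(rep$per_offset$ssim))
  expect_equal(rep$mean_psnr_db, mean(rep$per_offset$psnr_db))
  expect_equal(rep$n_pixels, 256)
  expect_true(all(rep$per_offset$ssim <= 1))

  ident <- suppressWarnings(evaluate_stacks(truth, truth, method = "identity"))
  expect_equal(ident$mean_ssim, 1)
  expect_equal(ident$mean_mae_pct, 0)

  single <- evaluate_stacks(make_stack(base[, , 1, drop = FALSE], 0),
                            make_stack(base[, , 1, drop = FALSE] + 0.01, 0))
  expect_equal(single$mean_psnr_db, single$per_offset$psnr_db)

  tab <- report_table(list(rep, ident))
  expect_equal(dim(tab), c(2, 2))
  expect_equal(tab["SSIM", "identity"], 1)
})
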