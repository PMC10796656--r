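test_that("lorentzian model evaluates the analytic lineshape", {
  grid <- dense_offsets()
  empty <- lorentzian_pools_default()[0, ]
  empty$amplitude <- numeric(0)
  z <- lorentzian_model(empty, 0.97, grid)
  expect_equal(z$z, rep(0.97, 101))

  one <- data.frame(role = "water", center_ppm = 1.2, fwhm_ppm = 0.8,
                    amplitude = 0.4)
  g <- offset_grid(c(1.2 - 0.4, 1.2, 1.2 + 0.4))
  z1 <- lorentzian_model(one, 1, g)
  expect_equal(z1$z[2], 1 - 0.4)
  expect_equal(z1$z[1], 1 - 0.2)
  expect_equal(z1$z[3], 1 - 0.2)
})

test_that("two-pool evaluation matches a direct sum oracle", {
  pools <- data.frame(role = c("a", "b"), center_ppm = c(-3, 3),
                      fwhm_ppm = c(0.5, 0.5), amplitude = c(0.3, 0.2))
  grid <- offset_grid(seq(-5, 5, by = 0.5))
  z <- lorentzian_model(pools, 1, grid)$z
  d <- as.numeric(grid)
  direct <- 1 -
    0.3 * 0.25^2 / (0.25^2 + (d + 3)^2) -
    0.2 * 0.25^2 / (0.25^2 + (d - 3)^2)
  expect_lt(max(abs(z - direct)), 1e-12)
})

test_that("amplitudes and baseline are recovered exactly on self-generated data", {
  pools <- lorentzian_pools_default()
  pools$amplitude <- c(0.55, 0.04, 0.03, 0.05, 0.12, 0.06)
  truth_z0 <- 0.99
  sp <- lorentzian_model(pools, truth_z0, sparse_offsets())
  fit <- fit_lorentzian(sp)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$pools$amplitude - pools$amplitude)), 1e-6)
  expect_lt(abs(fit$z0 - truth_z0), 1e-6)
  # residual invariant: model at input offsets reproduces stored SSR
  zhat <- predict(fit, offset_grid(sp$offsets_ppm))$z
  expect_lt(abs(sum((zhat - sp$z)^2) - fit$ssr), 1e-12)
})

test_that("least squares beats an exhaustive grid search on a one-pool fit", {
  pool <- data.frame(role = "water", center_ppm = 0, fwhm_ppm = 2,
                     amplitude = 0.4)
  sp <- lorentzian_model(pool, 0.98, sparse_offsets())
  cfg <- lorentzian_config(pools = pool[, c("role", "center_ppm", "fwhm_ppm")])
  fit <- fit_lorentzian(sp, cfg)
  shape <- (1)^2 / (1 + sp$offsets_ppm^2)  # (w/2)^2 / ((w/2)^2 + d^2), w = 2
  grid_a <- seq(0, 1, by = 1e-4)
  grid_z0 <- seq(0.5, 1.1, by = 1e-4)
  best <- Inf
  for (a in grid_a) {
    r <- outer(grid_z0, rep(1, length(shape))) -
      matrix(a * shape, length(grid_z0), length(shape), byrow = TRUE)
    ss <- rowSums(sweep(r, 2, sp$z)^2)
    best <- min(best, min(ss))
  }
  expect_lte(fit$ssr, best + 1e-12)
})

test_that("underdetermined fits are refused and free widths warn", {
  sp <- lorentzian_model(lorentzian_pools_default()[1:2, ] |>
                           transform(amplitude = c(0.5, 0.05)), 1,
                         offset_grid(c(-2, -1, 0, 1, 2)))
  expect_error(fit_lorentzian(sp), "refusing to fit")
  sp11 <- zspectrum(sparse_offsets(), rep(0.8, 11))
  expect_error(fit_lorentzian(sp11, lorentzian_config(free_widths = TRUE)),
               "refusing to fit")
  # 13 free parameters vs 21 points: allowed but warns
  sp21 <- lorentzian_model(transform(lorentzian_pools_default(),
                                     amplitude = 0.05), 1,
                           offset_grid(seq(-5, 5, by = 0.5)))
  expect_warning(fit_lorentzian(sp21, lorentzian_config(free_widths = TRUE)),
                 "barely determined")
})

test_that("relaxing an amplitude bound never increases the residual", {
  tissue <- tissue_midpoint()
  sp <- simulate_zspectrum(tissue, default_pulse, default_scanner,
                           sparse_offsets())
  tight <- fit_lorentzian(sp, lorentzian_config(amplitude_upper = 0.02))
  loose <- fit_lorentzian(sp, lorentzian_config(amplitude_upper = 1))
  expect_lte(loose$ssr, tight$ssr + 1e-12)
})

test_that("fitting is deterministic", {
  sp <- simulate_zspectrum(tissue_midpoint(), default_pulse, default_scanner,
                           sparse_offsets())
  f1 <- fit_lorentzian(sp)
  f2 <- fit_lorentzian(sp)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$ssr, f2$ssr)
})

test_that("baseline misfits the central band more than the wings on BM spectra", {
  tissue <- tissue_midpoint()
  sp <- simulate_zspectrum(tissue, default_pulse, default_scanner,
                           sparse_offsets())
  truth <- simulate_zspectrum(tissue, default_pulse, default_scanner,
                              dense_offsets())
  recon <- predict(fit_lorentzian(sp), dense_offsets())
  err <- abs(recon$z - truth$z)
  central <- abs(truth$offsets_ppm) <= 2
  expect_gt(mean(err[central]), mean(err[!central]))
})

test_that("dense evaluation of a fit has the expected grid behaviour", {
  pools <- lorentzian_pools_default()
  pools$amplitude <- rep(0.05, 6)
  sp <- lorentzian_model(pools, 1, sparse_offsets())
  fit <- fit_lorentzian(sp)
  dense <- predict(fit)
  expect_length(dense$z, 101)
  at_inputs <- predict(fit, offset_grid(sp$offsets_ppm))
  expect_equal(at_inputs$z, sp$z, tolerance = 1e-6)
})
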