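test_that("decoupled limit: zero exchange gives block-diagonal A and recovery-only b", {
  th <- (param_bounds()$lower + param_bounds()$upper) / 2
  th[seq(4, 20, by = 3)] <- 0  # all ksw = 0
  tissue <- tissue_from_params(th)
  sys <- bm_system(tissue, default_pulse, default_scanner, 3.5)
  expect_equal(dim(sys$A), c(21, 21))
  off_block <- matrix(TRUE, 21, 21)
  for (p in 0:6) off_block[3 * p + 1:3, 3 * p + 1:3] <- FALSE
  expect_true(all(sys$A[off_block] == 0))
  # b carries fs_i / t1_i at longitudinal positions only
  a <- tissue_from_params(th)
  fs <- c(1, th[seq(3, 20, by = 3)])
  t1 <- c(th[1], rep(1, 6))
  expect_equal(sys$b[3 * (0:6) + 3], fs / t1)
  expect_true(all(sys$b[-(3 * (0:6) + 3)] == 0))
})

test_that("A is a stable generator across sampled tissues (eigenvalue scan)", {
  set.seed(11)
  params <- sample_params(1000)
  worst <- -Inf
  for (i in seq_len(nrow(params))) {
    sys <- bm_system(tissue_from_params(params[i, ]), default_pulse,
                     default_scanner, 3.5)
    worst <- max(worst, max(Re(eigen(sys$A, only.values = TRUE)$values)))
  }
  expect_lte(worst, 1e-10)
})

test_that("water-only spectra are symmetric with their minimum on resonance", {
  tissue <- water_only_tissue()
  zs <- simulate_zspectrum(tissue, default_pulse, default_scanner,
                           dense_offsets())
  z <- zs$z
  expect_lt(max(abs(z - rev(z))), 1e-9)
  expect_equal(zs$offsets_ppm[which.min(z)], 0)
})

test_that("matrix-exponential and adaptive-ODE paths agree", {
  tissue <- tissue_midpoint()
  ze <- simulate_zvalue(tissue, default_pulse, default_scanner, 3.5)
  zo <- simulate_zvalue_ode(tissue, default_pulse, default_scanner, 3.5)
  expect_lt(abs(ze - zo), 1e-6)

  set.seed(21)
  params <- sample_params(20)
  for (i in seq_len(nrow(params))) {
    tt <- tissue_from_params(params[i, ])
    for (o in as.numeric(sparse_offsets())) {
      d <- abs(simulate_zvalue(tt, default_pulse, default_scanner, o) -
               simulate_zvalue_ode(tt, default_pulse, default_scanner, o))
      expect_lt(d, 1e-6)
    }
  }
})

test_that("simulated spectra respect physical bounds", {
  ds <- small_dataset()
  expect_true(all(ds$sparse_z >= -1e-4 & ds$sparse_z <= 1 + 1e-6))
  expect_true(all(ds$dense_z >= -1e-4 & ds$dense_z <= 1 + 1e-6))
  off_res <- abs(ds$meta$dense) >= 0.3
  expect_true(all(ds$dense_z[, off_res] >= 0))
})

test_that("Z at 3.5 ppm is non-increasing in amide pool size", {
  bounds <- param_bounds()
  th <- (bounds$lower + bounds$upper) / 2
  i_amide_fs <- which(bounds$name == "amide_fs")
  zs <- vapply(seq(bounds$lower[i_amide_fs], bounds$upper[i_amide_fs],
                   length.out = 10), function(fs) {
    th2 <- th; th2[i_amide_fs] <- fs
    simulate_zvalue(tissue_from_params(th2), default_pulse, default_scanner,
                    3.5)
  }, numeric(1))
  expect_true(all(diff(zs) <= 1e-12))
})

test_that("uniform sampling honours bounds, fixed values and distribution", {
  bounds <- param_bounds()
  set.seed(5)
  tt <- sample_tissue()
  amide <- tt$pools[[2]]
  expect_equal(amide$role, "amide")
  expect_equal(amide$delta_ppm, 3.5)
  expect_equal(amide$t1, 1)
  mt <- tt$pools[[6]]
  expect_gte(mt$fs, 10e-3); expect_lte(mt$fs, 200e-3)
  expect_equal(mt$delta_ppm, -2.4)

  set.seed(99)
  p <- sample_params(10000)
  expect_true(all(sweep(p, 2, bounds$lower, `>=`)))
  expect_true(all(sweep(p, 2, bounds$upper, `<=`)))
  ks <- suppressWarnings(stats::ks.test(p[, "water_t1"], "punif", 1, 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate bounds collapse sampling to a point", {
  bounds <- param_bounds()
  bounds$upper <- bounds$lower
  set.seed(1)
  p <- sample_params(3, bounds)
  expect_equal(p[1, ], p[2, ])
  expect_equal(p[2, ], p[3, ])
  ds <- generate_dataset(3, bounds = bounds, seed = 4)
  expect_equal(ds$dense_z[1, ], ds$dense_z[3, ])
})

test_that("dataset generation is a pure function of config and seed", {
  ds1 <- generate_dataset(8, seed = 123)
  ds2 <- generate_dataset(8, seed = 123)
  expect_identical(ds1, ds2)
  ds3 <- generate_dataset(8, seed = 124)
  expect_false(identical(ds1$dense_z, ds3$dense_z))
})

test_that("dataset has aligned paired dimensions on the default grids", {
  ds <- small_dataset()
  expect_equal(dim(ds$sparse_z), c(40, 11))
  expect_equal(dim(ds$dense_z), c(40, 101))
  expect_equal(dim(ds$params), c(40, 20))
  expect_equal(ds$meta$sparse, as.numeric(sparse_offsets()))
  expect_equal(ds$meta$dense, as.numeric(dense_offsets()))
})

test_that("zspectrum simulation validates its grid and stays consistent", {
  tissue <- tissue_midpoint()
  expect_error(simulate_zspectrum(tissue, default_pulse, default_scanner,
                                  numeric(0)), "non-empty")
  zs <- simulate_zspectrum(tissue, default_pulse, default_scanner, 0.0)
  expect_equal(zs$z,
               simulate_zvalue(tissue, default_pulse, default_scanner, 0.0))
  expect_error(zspectrum(c(1, 2), c(0.5, 0.5, 0.5)), "lengths differ")
  expect_error(zspectrum(c(1, 2), c(0.5, 1.5)), "physical bound")
})

test_that("dataset container round-trips through its file format", {
  ds <- small_dataset()
  path <- tempfile(fileext = ".rds")
  write_dataset(ds, path)
  expect_identical(read_dataset(path), ds)
  unlink(path)
})
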