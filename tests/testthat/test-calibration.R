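test_that("load decomposition follows the pitch/roll trigonometry", {
  expect_equal(as.numeric(decompose_load(10, 90, 0)), c(10, 0, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(decompose_load(10, 0, 37)), c(0, 0, 10),
               tolerance = 1e-12)
  expect_equal(as.numeric(decompose_load(10, 45, 45)),
               c(5, 5, 10 / sqrt(2)), tolerance = 1e-9)
  # magnitude is preserved for every angle pair
  set.seed(7)
  for (k in 1:25) {
    f <- runif(1, 0, 10); a <- runif(1, -90, 90); b <- runif(1, 0, 90)
    d <- decompose_load(f, a, b)
    expect_equal(sqrt(sum(as.numeric(d)^2)), f, tolerance = 1e-10)
  }
  expect_error(decompose_load(-1, 0, 0), "load_mag")
  expect_error(decompose_load(1, 120, 0), "pitch_deg")
})

test_that("default grid has 350 points and sweeps are reproducible", {
  grid <- calibration_grid()
  expect_identical(nrow(grid), 350L)
  expect_identical(length(unique(grid$pitch_deg)), 10L)
  expect_identical(length(unique(grid$roll_deg)), 7L)
  expect_identical(length(unique(grid$load_mN)), 5L)
  s1 <- generate_sweep(noise_sd = 0.02, seed = 9)
  s2 <- generate_sweep(noise_sd = 0.02, seed = 9)
  expect_identical(s1, s2)
  expect_error(calibration_grid(pitch_deg = numeric(0)), "non-empty")
})

test_that("noiseless sweeps lie exactly on the forward model", {
  sweep <- generate_sweep(noise_sd = 0)
  G <- forward_matrix(reference_calibration())
  lam <- as.matrix(sweep[, paste0("dlam", 1:4, "_nm")])
  f <- as.matrix(sweep[, c("fx_mN", "fy_mN", "fz_mN")])
  expect_equal(lam, f %*% t(G), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("noiseless fit recovers the ground-truth matrices exactly", {
  sweep <- generate_sweep(noise_sd = 0)
  model <- fit_calibration(sweep)
  expect_equal(model$c_tran, ref_ctran, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(model$a_axi, ref_aaxi, tolerance = 1e-12)
  expect_equal(model$fit$slopes$slope, rep(1, 3), tolerance = 1e-9)
  expect_equal(model$fit$mae$mae_mN, rep(0, 3), tolerance = 1e-9)
})

test_that("fit matches a normal-equations oracle on a small instance", {
  grid <- calibration_grid(pitch_deg = c(-60, 30, 75),
                           roll_deg = c(0, 45), load_mN = c(3, 9))
  sweep <- generate_sweep(grid, noise_sd = 0.05, seed = 13)
  model <- fit_calibration(sweep)
  # oracle: explicit normal equations for the forward map, then explicit
  # pseudoinverses built from the SVD
  f <- as.matrix(sweep[, c("fx_mN", "fy_mN", "fz_mN")])
  lam <- as.matrix(sweep[, paste0("dlam", 1:4, "_nm")])
  G <- t(solve(t(f) %*% f) %*% t(f) %*% lam)
  pinv <- function(m, tol = 1e-10) {
    s <- svd(m)
    keep <- s$d > tol * max(s$d)
    s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
      t(s$u[, keep, drop = FALSE])
  }
  expect_equal(model$a_axi, pinv(G)[3, ], tolerance = 1e-8)
  cmr <- (diag(3) - matrix(1 / 3, 3, 3)) %*% cbind(diag(3), 0)
  expect_equal(unname(model$c_tran),
               unname((cbind(diag(2), 0) %*% pinv(cmr %*% G))),
               tolerance = 1e-8)
})

test_that("rank-deficient sweeps fail naming the dead axis", {
  grid <- calibration_grid(pitch_deg = 90, roll_deg = 0) # fz never excited
  sweep <- generate_sweep(grid, noise_sd = 0)
  expect_error(fit_calibration(sweep), "singular fit")
})

test_that("decoding error grows with wavelength noise", {
  mae_at <- function(noise_sd) {
    maes <- vapply(1:3, function(s) {
      sweep <- generate_sweep(noise_sd = noise_sd, seed = 100 + s)
      mean(fit_calibration(sweep)$fit$mae$mae_mN)
    }, 0)
    mean(maes)
  }
  errs <- vapply(c(0.005, 0.05, 0.5), mae_at, 0)
  expect_true(all(diff(errs) > 0))
})

test_that("fit report bins residuals in ten 1 mN bins and ignores order", {
  sweep <- generate_sweep(noise_sd = 0.01, seed = 23)
  model <- fit_calibration(sweep)
  bins <- model$fit$residual_bins
  expect_identical(nrow(bins), 30L) # 10 bins x 3 axes
  expect_true(all(table(bins$axis) == 10))
  shuffled <- sweep[sample(nrow(sweep)), ]
  report <- evaluate_fit(shuffled, model)
  expect_equal(report$slopes, model$fit$slopes)
  expect_equal(report$mae, model$fit$mae)
})

test_that("tidy and glance expose coefficients and fit quality", {
  sweep <- generate_sweep(noise_sd = 0.01, seed = 29)
  model <- fit_calibration(sweep)
  td <- tidy(model)
  expect_identical(nrow(td), 10L) # 6 transverse + 4 axial coefficients
  expect_equal(td$estimate[td$component == "a_axi"], model$a_axi)
  expect_equal(td$estimate[td$component == "c_tran" & td$row == 1],
               model$c_tran[1, ])
  gl <- glance(model)
  expect_identical(gl$n, 350L)
  expect_true(all(abs(c(gl$slope_fx, gl$slope_fy, gl$slope_fz) - 1) < 0.05))
})

test_that("sweep CSV round-trips", {
  sweep <- generate_sweep(noise_sd = 0.01, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sweep, path)
  back <- read_sweep(path)
  expect_equal(as.data.frame(back), as.data.frame(sweep), tolerance = 1e-9)
})
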