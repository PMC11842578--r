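test_that("Bragg wavelength is twice index times period", {
  expect_equal(bragg_wavelength(grating_spec(1.45, 535)), 1551.5)
  expect_equal(bragg_wavelength(grating_spec(1.0000001, 0.5)),
               1.0000001, tolerance = 1e-6)
  # linear in the period at fixed index
  expect_equal(bragg_wavelength(grating_spec(1.45, 1070)),
               2 * bragg_wavelength(grating_spec(1.45, 535)))
  expect_error(grating_spec(1.45, -1), "grating_period")
  expect_error(grating_spec(0.9, 535), "effective_index")
})

test_that("wavelength shift is linear in strain and temperature", {
  spec <- grating_spec(strain_coeff = 0.0012, temp_coeff = 0.010)
  expect_equal(wavelength_shift(100, 2, spec), 0.14)
  expect_equal(wavelength_shift(0, 0, spec), 0)
  # pure temperature gives the same shift on fibres sharing the coefficient
  shifts <- vapply(1:4, function(i) wavelength_shift(0, 3, spec), 0)
  expect_true(all(shifts == shifts[1]))
})

test_that("tip strain follows cantilever bending and is linear", {
  geom <- needle_geometry(youngs_modulus = 6, inertia_torque = 1,
                          tube_radius = 1, fbg_distance = 3)
  expect_equal(tip_strain(2, geom), 1)
  expect_equal(tip_strain(0, geom), 0)
  expect_equal(tip_strain(4, geom) / tip_strain(2, geom), 2)
  geom2 <- needle_geometry(6, 1, 1, 6) # doubled fbg distance
  expect_equal(tip_strain(2, geom2) / tip_strain(2, geom), 2)
  expect_error(needle_geometry(0, 1, 1, 1), "youngs_modulus")
})

test_that("common-mode rejection subtracts the mean and sums to zero", {
  expect_equal(common_mode_reject(c(7, 7, 7)), c(0, 0, 0))
  expect_equal(common_mode_reject(c(3, 0, 0)), c(2, -1, -1))
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(3, sd = 10)
    expect_equal(sum(common_mode_reject(x)), 0, tolerance = 1e-12)
  }
  expect_error(common_mode_reject(c(1, 2)), "3 entries")
  # matrix form operates row-wise
  m <- matrix(c(3, 0, 0, 1, 1, 1), nrow = 2, byrow = TRUE)
  expect_equal(common_mode_reject(m),
               matrix(c(2, -1, -1, 0, 0, 0), nrow = 2, byrow = TRUE))
})

test_that("transverse decoding applies the 2x3 matrix", {
  cal <- reference_calibration()
  expect_equal(unname(transverse_force(c(0, 0, 0), cal)), c(0, 0))
  expect_equal(unname(transverse_force(c(1, 0, 0), cal)), c(-0.025, -0.143))
  # the reference rows sum to zero, so a pure common mode decodes to zero
  expect_equal(unname(transverse_force(c(1, 1, 1), cal)), c(0, 0),
               tolerance = 1e-12)
  expect_error(transverse_force(c(1, 2), cal), "3 entries")
})

test_that("axial decoding is the dot product with the 1x4 row", {
  cal <- reference_calibration()
  expect_equal(axial_force(c(0, 0, 0, 0), cal), 0)
  expect_equal(axial_force(c(0, 0, 0, 1), cal), 0.382)
  expect_equal(axial_force(c(1, 1, 1, 1), cal), 0.230)
  expect_error(axial_force(c(1, 2, 3), cal), "4 entries")
})

test_that("force composition yields Euclidean magnitudes", {
  f <- compose_force(0, 0, 0)
  expect_equal(f$ft_mN, 0)
  expect_equal(f$f_total_mN, 0)
  f <- compose_force(3, 4, 0)
  expect_equal(f$ft_mN, 5)
  expect_equal(f$f_total_mN, 5)
  # the prototype's measured split: 3.1 mN transverse + 2.4 mN axial
  f <- compose_force(3.1, 0, 2.4)
  expect_equal(round(f$f_total_mN, 1), 3.9)
  # ft <= f_total always, equal iff fz = 0
  set.seed(4)
  comp <- compose_force(rnorm(50), rnorm(50), rnorm(50))
  expect_true(all(comp$ft_mN <= comp$f_total_mN + 1e-12))
  expect_equal(comp$ft_mN[comp$fz_mN == 0], comp$f_total_mN[comp$fz_mN == 0])
})

test_that("decoding maps are linear and reject common mode", {
  cal <- reference_calibration()
  set.seed(21)
  for (k in 1:10) {
    x <- rnorm(3); y <- rnorm(3); a <- rnorm(1); b <- rnorm(1)
    expect_equal(unname(transverse_force(a * x + b * y, cal)),
                 a * unname(transverse_force(x, cal)) +
                   b * unname(transverse_force(y, cal)),
                 tolerance = 1e-12)
    z <- rnorm(4); w <- rnorm(4)
    expect_equal(axial_force(a * z + b * w, cal),
                 a * axial_force(z, cal) + b * axial_force(w, cal),
                 tolerance = 1e-12)
    # adding a constant to all three centred inputs leaves transverse
    # output unchanged (rows of the reference matrix sum to zero)
    cshift <- rnorm(1)
    expect_equal(unname(transverse_force(x + cshift, cal)),
                 unname(transverse_force(x, cal)), tolerance = 1e-12)
  }
})

test_that("consistent forward matrix inverts the decoders exactly", {
  cal <- reference_calibration()
  G <- forward_matrix(cal)
  set.seed(31)
  for (k in 1:10) {
    f <- rnorm(3, sd = 5)
    lam <- drop(G %*% f)
    ds <- common_mode_reject(lam[1:3])
    expect_equal(unname(transverse_force(ds, cal)), f[1:2],
                 tolerance = 1e-10)
    expect_equal(axial_force(lam, cal), f[3], tolerance = 1e-10)
  }
})

test_that("physical forward chain round-trips through a fitted calibration", {
  geom <- needle_geometry(youngs_modulus = 70e3, inertia_torque = 0.05,
                          tube_radius = 0.5, fbg_distance = 2)
  G_phys <- physical_forward_matrix(geom, grating_spec(), axial_gain = 0.4)
  sweep <- generate_sweep(truth = G_phys, noise_sd = 0)
  model <- fit_calibration(sweep)
  set.seed(41)
  for (k in 1:5) {
    f <- rnorm(3, sd = 4)
    lam <- drop(G_phys %*% f)
    expect_equal(unname(transverse_force(common_mode_reject(lam[1:3]), model)),
                 f[1:2], tolerance = 1e-8)
    expect_equal(axial_force(lam, model), f[3], tolerance = 1e-8)
  }
})

test_that("calibration JSON round-trips", {
  cal <- reference_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$c_tran, cal$c_tran)
  expect_equal(back$a_axi, cal$a_axi)
  expect_equal(back$fiber_subset, cal$fiber_subset)
})
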