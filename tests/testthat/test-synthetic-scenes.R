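test_that("vesicle scenes are pure-component with exact linear mixing", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_mlv_scene(g, 1, refs, intensity_scale = 500, seed = 4,
                       size = 48)
  # every in-disk pixel's spectrum is proportional to the assigned component
  lab <- sc$phantom$compartments
  inside <- lab == 1L
  expect_gt(sum(inside), 0)
  comp <- sc$phantom$vesicle_component[1]
  spec <- refs$spectra[[comp]]$values
  flat <- matrix(sc$stack$counts, nrow = 48 * 48)
  for (p in which(inside)[1:5]) {
    expect_equal(flat[p, ] / sum(flat[p, ]), spec, tolerance = 1e-12)
  }
  # background pixels carry zero expected counts at zero background level
  expect_true(all(flat[!inside, ] == 0))
  # linear mixing identity holds exactly
  s <- sapply(refs$spectra, function(x) x$values)
  af <- matrix(sc$phantom$abundances, nrow = 48 * 48)
  expect_equal(flat, af %*% t(s), tolerance = 1e-12)
})

test_that("ROI mean over a noiseless vesicle returns its reference spectrum", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_mlv_scene(g, 3, refs, intensity_scale = 900, seed = 7,
                       size = 64)
  for (v in 1:3) {
    roi <- sc$phantom$compartments == v
    got <- normalize_spectrum(roi_mean_spectrum(sc$stack, roi), "unit-area")
    want <- refs$spectra[[sc$phantom$vesicle_component[v]]]$values
    expect_equal(got$values, want, tolerance = 1e-12)
  }
})

test_that("scene generation is bit-reproducible and leaves the RNG alone", {
  g <- grid17()
  refs <- basis2(g)
  a <- make_mlv_scene(g, 4, refs, seed = 9, size = 48)
  b <- make_mlv_scene(g, 4, refs, seed = 9, size = 48)
  expect_identical(a$stack$counts, b$stack$counts)
  expect_identical(a$phantom$abundances, b$phantom$abundances)
  c_ <- make_mlv_scene(g, 4, refs, seed = 10, size = 48)
  expect_false(identical(a$phantom$vesicle_centres,
                         c_$phantom$vesicle_centres))
  # generator must not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(make_cell_scene(g, refs, size = 64, seed = 5))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("cell phantom compartments carry the configured mixtures", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_cell_scene(g, refs, size = 64, seed = 2)
  lab <- sc$phantom$compartments
  ab <- sc$phantom$abundances
  for (cmp in list(c("pm", 0.75), c("cytoplasm", 0.3), c("droplet", 0.95))) {
    m <- lab == cmp[1]
    f <- ab[, , 1][m] / (ab[, , 1][m] + ab[, , 2][m])
    expect_equal(unique(round(f, 12)), as.numeric(cmp[2]))
  }
  expect_true(all(ab[, , 1][lab == "nucleus"] == 0))
  # pm_apolar_fraction = 1 leaves only the apolar component on the PM
  sc1 <- make_cell_scene(g, refs, size = 64, pm_apolar_fraction = 1,
                         seed = 2)
  pm <- sc1$phantom$compartments == "pm"
  expect_true(all(sc1$phantom$abundances[, , 2][pm] == 0))
  expect_true(all(sc1$phantom$abundances[, , 1][pm] > 0))
  # droplets brighter than cytoplasm when configured so
  tot <- channel_sum_of(sc$stack)
  expect_gt(min(tot[lab == "droplet"]), max(tot[lab == "cytoplasm"]))
  expect_error(make_cell_scene(g, refs, size = 16), "fit")
  expect_error(make_cell_scene(g, refs, size = 64,
                               pm_apolar_fraction = 1.2), "\\[0, 1\\]")
})

test_that("two-dye scenes keep the second dye off the plasma membrane", {
  g <- grid29()
  refs <- basis4(g)
  sc <- make_two_dye_scene(g, refs, seed = 3, size = 96)
  lab <- sc$phantom$compartments
  ab <- sc$phantom$abundances
  pm <- lab == "pm"
  expect_true(all(ab[, , 3][pm] == 0))
  expect_true(all(ab[, , 4][pm] == 0))
  expect_true(all(ab[, , 1][pm] > 0))
  dr <- lab == "droplet"
  expect_true(all(ab[, , 1][dr] > 0) && all(ab[, , 3][dr] > 0))
  expect_true(all(ab[, , 2][dr] == 0) && all(ab[, , 4][dr] == 0))
  expect_error(make_two_dye_scene(g, basis2(g), seed = 1), "4 components")
})

test_that("poisson noise has the right mean and is seed-deterministic", {
  g <- channel_grid(400, 10, 2)
  exp_counts <- array(50, dim = c(100, 100, 2))
  a <- add_poisson_noise(exp_counts, seed = 5, grid = g)
  b <- add_poisson_noise(exp_counts, seed = 5, grid = g)
  expect_identical(a$counts, b$counts)
  # Monte-Carlo mean of 20000 draws at expectation 50: within 3 sigma
  expect_lt(abs(mean(a$counts) - 50), 3 * sqrt(50 / 20000))
  # zero expectation gives exactly zero counts
  z <- add_poisson_noise(array(0, dim = c(4, 4, 2)), seed = 1, grid = g)
  expect_true(all(z$counts == 0))
  expect_error(add_poisson_noise(array(-1, dim = c(2, 2, 2)), seed = 1,
                                 grid = g), "nonnegative")
})

test_that("noiseless fraction equals the configured compartment fraction", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_cell_scene(g, refs, size = 64, seed = 8,
                        pm_apolar_fraction = 0.6,
                        cytoplasm_apolar_fraction = 0.25)
  am <- unmix_fixed(sc$stack, refs, unmix_params(n_iterations = 300))
  fm <- fraction_map(am)
  lab <- sc$phantom$compartments
  expect_equal(median(fm$fraction[lab == "pm"]), 0.6, tolerance = 1e-3)
  expect_equal(median(fm$fraction[lab == "cytoplasm"]), 0.25,
               tolerance = 1e-3)
})
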