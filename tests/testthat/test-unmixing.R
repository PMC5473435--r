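test_that("generalized KL divergence matches the closed form", {
  expect_equal(kl_divergence(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(kl_divergence(0, 5), 5)                 # 0*log(0) = 0
  expect_equal(kl_divergence(2, 1), 2 * log(2) - 1)
  expect_gte(kl_divergence(c(3, 0, 7), c(2.5, 1, 8)), 0)
  expect_error(kl_divergence(c(1, 2), c(1, 0)), "zero")
  expect_error(kl_divergence(c(-1), c(1)), "nonnegative")
})

test_that("pixel masks follow the stated threshold conventions", {
  g <- channel_grid(400, 10, 4)
  counts <- array(0, dim = c(2, 2, 4))
  counts[1, 1, ] <- c(10, 10, 10, 10)   # sum 40  < 50 -> background
  counts[1, 2, ] <- c(20, 10, 10, 10)   # sum 50  -> NOT background
  counts[2, 1, ] <- c(4000, 0, 0, 0)    # channel at 4000 -> saturated
  counts[2, 2, ] <- c(3999, 100, 0, 0)
  st <- lambda_stack(counts, g)
  m <- pixel_masks(st, unmix_params())
  expect_true(m$background[1, 1])
  expect_false(m$background[1, 2])
  expect_false(m$background[2, 1])
  expect_true(m$saturation[2, 1])
  expect_false(m$saturation[2, 2])
  # all-zero pixel is background
  expect_true(m$background[1, 1])
})

test_that("fixed unmixing recovers pure and mixed noiseless pixels", {
  g <- grid17()
  refs <- basis2(g)
  s <- sapply(refs$spectra, function(x) x$values)
  h <- 4; w <- 4
  counts <- array(0, dim = c(h, w, 17))
  truth <- array(0, dim = c(h, w, 2))
  set.seed(21)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    a <- c(runif(1, 100, 900), runif(1, 100, 900))
    if (i == 1 && j == 1) a <- c(1200, 0)   # pure pixel, 12.0 x 100
    truth[i, j, ] <- a
    counts[i, j, ] <- s %*% a
  }
  st <- lambda_stack(counts, g)
  am <- unmix_fixed(st, refs,
                    unmix_params(n_iterations = 300,
                                 background_spectrum = "none"))
  expect_lt(max(abs(am$values - truth)) / max(truth), 1e-3)
  # pure pixel: the other component is essentially absent
  expect_lt(am$values[1, 1, 2], 1e-3 * 1200)
  # mixture example: 0.3 A + 0.7 B at unit total
  px <- lambda_stack(array(s %*% c(0.3, 0.7) * 100,
                           dim = c(1, 1, 17)), g)
  am2 <- unmix_fixed(px, refs,
                     unmix_params(n_iterations = 400,
                                  background_threshold = 0,
                                  background_spectrum = "none"))
  expect_equal(as.numeric(am2$values[1, 1, ]), c(30, 70), tolerance = 1e-3)
})

test_that("fixed unmixing agrees with the direct linear-solve oracle", {
  for (setup in list(list(g = grid17(), refs = basis2(grid17()), k = 2),
                     list(g = grid29(), refs = basis4(grid29()), k = 4))) {
    set.seed(31 + setup$k)
    h <- 8; w <- 8
    s <- sapply(setup$refs$spectra, function(x) x$values)
    truth <- array(runif(h * w * setup$k, 50, 600), dim = c(h, w, setup$k))
    counts <- array(matrix(truth, ncol = setup$k) %*% t(s),
                    dim = c(h, w, setup$g$n_channels))
    st <- lambda_stack(counts, setup$g)
    # dense mixtures everywhere: disable the minimal-values background
    # component so the solver is compared to the oracle in isolation
    am <- unmix_fixed(st, setup$refs,
                      unmix_params(n_iterations = 500,
                                   background_spectrum = "none"))
    oracle <- solve_abundances(st, setup$refs)
    expect_lt(max(abs(am$values - oracle) / pmax(oracle, 1)), 1e-3)
  }
})

test_that("background pixels are zeroed and flagged, not fitted", {
  g <- grid17()
  refs <- basis2(g)
  s <- sapply(refs$spectra, function(x) x$values)
  counts <- array(0, dim = c(2, 2, 17))
  counts[1, 1, ] <- s %*% c(300, 200)
  counts[2, 2, ] <- s %*% c(20, 10)   # sum 30 < 50 -> background
  st <- lambda_stack(counts, g)
  am <- unmix_fixed(st, refs, unmix_params(n_iterations = 100))
  expect_true(am$background_mask[2, 2])
  expect_equal(as.numeric(am$values[2, 2, ]), c(0, 0))
  expect_gt(am$values[1, 1, 1], 0)
  # an all-background stack returns zero maps with a warning
  dark <- lambda_stack(array(1, dim = c(2, 2, 17)), g)
  expect_warning(amd <- unmix_fixed(dark, refs), "background")
  expect_true(all(amd$values == 0))
})

test_that("component count above channel count is rejected", {
  g <- channel_grid(440, 10, 3)
  refs <- reference_set(lapply(1:4, function(i) {
    gaussian_emission(440 + 6 * i, 25, g, paste0("c", i))
  }))
  st <- lambda_stack(array(100, dim = c(2, 2, 3)), g)
  expect_error(unmix_fixed(st, refs, unmix_params()), "channels")
})

test_that("KL objective is non-increasing across sweeps on random stacks", {
  g <- grid17()
  refs <- basis2(g)
  for (seed in 1:3) {
    set.seed(seed)
    counts <- array(rpois(16 * 16 * 17, 40), dim = c(16, 16, 17))
    st <- lambda_stack(counts, g)
    am <- unmix_fixed(st, refs, unmix_params(n_iterations = 40))
    expect_true(all(diff(am$objective) <= 1e-8 * abs(am$objective[1])))
    bl <- unmix_blind(st, 2, unmix_params(n_iterations = 40, seed = seed))
    expect_true(all(diff(bl$objective) <= 1e-6 * abs(bl$objective[1])))
  }
})

test_that("blind mode recovers disjoint pure components at high SNR", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_mlv_scene(g, 4, refs, intensity_scale = 4000, seed = 5,
                       size = 64)
  noisy <- add_poisson_noise(sc$stack, seed = 6)
  bl <- unmix_blind(noisy, 2, unmix_params(n_iterations = 100, seed = 7))
  est <- sapply(bl$refs$spectra, function(s) s$values)
  truth <- sapply(refs$spectra, function(s) s$values)
  expect_gte(best_perm_cosine(est, truth), 0.99)
  expect_true(all(diff(bl$objective) <= 1e-6 * abs(bl$objective[1])))
})

test_that("blind rank-1 factorization of a uniform stack returns its spectrum", {
  g <- grid17()
  spec <- gaussian_emission(470, 50, g)
  counts <- array(rep(spec$values * 2000, each = 64), dim = c(8, 8, 17))
  st <- lambda_stack(counts, g)
  bl <- unmix_blind(st, 1, unmix_params(n_iterations = 60, seed = 2))
  expect_gte(cosine_sim(bl$refs$spectra[[1]]$values, spec$values), 0.9999)
})

test_that("unmixing is deterministic given stack, params and seed", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_mlv_scene(g, 3, refs, intensity_scale = 600, seed = 11,
                       size = 48)
  noisy <- add_poisson_noise(sc$stack, seed = 12)
  p <- unmix_params(n_iterations = 30, seed = 13)
  a <- unmix_blind(noisy, 2, p)
  b <- unmix_blind(noisy, 2, p)
  expect_identical(a$maps$values, b$maps$values)
  expect_identical(sapply(a$refs$spectra, `[[`, "values"),
                   sapply(b$refs$spectra, `[[`, "values"))
  f1 <- unmix_fixed(noisy, refs, p)
  f2 <- unmix_fixed(noisy, refs, p)
  expect_identical(f1$values, f2$values)
})

test_that("poisson-noised two-component scenes recover fractions to 0.05", {
  g <- grid17()
  refs <- basis2(g)
  sc <- make_cell_scene(g, refs, size = 96, seed = 14)
  noisy <- add_poisson_noise(sc$stack, seed = 15)
  am <- unmix_fixed(noisy, refs, unmix_params(n_iterations = 60))
  fm <- fraction_map(am)
  truth <- sc$phantom$abundances
  tfrac <- truth[, , 1] / pmax(truth[, , 1] + truth[, , 2], 1e-12)
  ok <- fm$defined & (truth[, , 1] + truth[, , 2] > 0)
  mae <- mean(abs(fm$fraction[ok] - tfrac[ok]))
  expect_lte(mae, 0.05)
})
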