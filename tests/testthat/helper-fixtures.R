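# shared fixtures: grids, bases and small oracles used across test files

grid17 <- function() build_channel_grid(418, 584, 9.8)
grid29 <- function() build_channel_grid(418, 700, 9.8)

basis2 <- function(grid = grid17()) two_state_refs(grid)

basis4 <- function(grid = grid29()) {
  reference_set(
    gaussian_emission(440, 45, grid, "dye1_apolar"),
    gaussian_emission(490, 55, grid, "dye1_polar"),
    gaussian_emission(590, 45, grid, "dye2_apolar"),
    gaussian_emission(630, 55, grid, "dye2_polar"))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

channel_sum_of <- function(stack) apply(stack$counts, c(1, 2), sum)

# fresh scratch directory per call (cleaned up by R's tempdir teardown)
withr_tempdir <- function() {
  d <- tempfile("lambdamap-test-")
  dir.create(d)
  d
}

same_grid_pub <- function(a, b) {
  a$n_channels == b$n_channels &&
    abs(a$start_nm - b$start_nm) < 1e-9 &&
    abs(a$step_nm - b$step_nm) < 1e-9
}

# brute-force permutation matching: best min-over-components cosine
best_perm_cosine <- function(est, truth) {
  k <- ncol(truth)
  perms <- gtools_permutations(k)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    sims <- vapply(seq_len(k), function(j) {
      cosine_sim(est[, perms[i, j]], truth[, j])
    }, numeric(1))
    best <- max(best, min(sims))
  }
  best
}

# tiny permutation enumerator (avoids a package dependency)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# independent oracle: per-pixel unconstrained least-squares solve of the
# C x K linear system (valid on noiseless mixtures, where the exact
# solution is nonnegative)
solve_abundances <- function(stack, refs) {
  s <- sapply(refs$spectra, function(sp) sp$values)
  d <- dim(stack$counts)
  flat <- matrix(stack$counts, nrow = d[1] * d[2])
  a <- t(qr.solve(s, t(flat)))
  array(a, dim = c(d[1], d[2], ncol(s)))
}

# abundance_maps built directly from known component images (bypasses
# unmixing; used to test the fraction mapper in isolation)
maps_from_planes <- function(i1, i2, grid = grid17(),
                             background = matrix(FALSE, nrow(i1), ncol(i1))) {
  structure(list(
    values = array(c(i1, i2), dim = c(nrow(i1), ncol(i1), 2)),
    names = c("apolar", "polar"),
    background_mask = background,
    saturation_mask = matrix(FALSE, nrow(i1), ncol(i1)),
    grid = grid, pixel_size_nm = 100), class = "abundance_maps")
}
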