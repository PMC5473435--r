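#' @title Ground-truthed synthetic scenes
#' @description Generators for phantom lambda stacks with exactly known
#'   per-pixel component abundances: vesicle fields for reference-spectrum
#'   work, a cell phantom (plasma-membrane ring, cytoplasm, lipid droplets,
#'   empty nucleus) for fraction-recovery checks, and a four-component
#'   two-dye scene. Expected counts obey the linear mixing identity
#'   `E[counts] = sum_k abundance_k * spectrum_k` exactly; Poisson shot
#'   noise is added separately with [add_poisson_noise()].
#' @name synthetic_scenes
NULL

# internal: evaluate expr with a private, seeded RNG stream
with_rng <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# internal: logical disk mask on an H x W raster (centre & radius in pixels)
disk_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# internal: expected counts H x W x C from abundances H x W x K and a
# reference set (unit-area spectra): the linear mixing identity.
expected_counts <- function(abund, refs) {
  d <- dim(abund)
  s <- ref_matrix(refs)                        # C x K
  flat <- matrix(abund, nrow = d[1] * d[2])    # P x K
  array(flat %*% t(s), dim = c(d[1], d[2], nrow(s)))
}

# internal: assemble the (stack, phantom) return pair
new_phantom <- function(abund, refs, grid, pixel_size_nm, params, seed,
                        compartments = NULL, background_level = 0) {
  exp_counts <- expected_counts(abund, refs)
  if (background_level > 0) exp_counts <- exp_counts + background_level
  phantom <- structure(
    list(abundances = abund, component_names = refs$names,
         compartments = compartments, pixel_size_nm = pixel_size_nm,
         params = params, seed = seed, expected = exp_counts, grid = grid),
    class = "scene_phantom")
  list(stack = lambda_stack(exp_counts, grid, pixel_size_nm),
       phantom = phantom)
}

#' @export
print.scene_phantom <- function(x, ...) {
  d <- dim(x$abundances)
  cat(sprintf("<scene_phantom> %d x %d px, components: %s (seed %d)\n",
              d[1], d[2], paste(x$component_names, collapse = ", "), x$seed))
  invisible(x)
}

# internal: place n disjoint disks by rejection sampling
place_disks <- function(n, h, w, r, margin = 1, max_tries = 2000) {
  centres <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centres) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop(sprintf("could not place %d disjoint vesicles after %d tries",
                   n, max_tries), call. = FALSE)
    }
    cy <- stats::runif(1, r + margin, h - r - margin)
    cx <- stats::runif(1, r + margin, w - r - margin)
    if (nrow(centres) == 0 ||
        all((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2 > (2 * r + 2)^2)) {
      centres <- rbind(centres, c(cy, cx))
    }
  }
  centres
}

#' Synthetic field of pure-component vesicles
#'
#' Emulates a reference acquisition on multilamellar vesicles (MLVs) of
#' defined composition: disjoint filled disks, each carrying exactly one
#' pure reference component, on a zero (or flat) background. The mean ROI
#' spectrum over any vesicle of the noiseless stack equals the assigned
#' reference spectrum, which is how reference curves are extracted in
#' practice.
#'
#' @param grid A [channel_grid()].
#' @param n_vesicles Number of vesicles (disks); components are assigned by
#'   cycling through the reference set.
#' @param component_spectra A [reference_set()] on `grid`.
#' @param intensity_scale Expected per-pixel channel-sum inside a vesicle
#'   (counts); expected counts are `intensity_scale * spectrum` (unit area).
#' @param seed Integer seed; generation is bit-reproducible.
#' @param size Image edge length in pixels (default 64).
#' @param vesicle_radius_px Disk radius in pixels.
#' @param background_level Flat expected count added to every voxel
#'   (default 0).
#' @param pixel_size_nm Pixel size (nm), default 100.
#' @return A list with `stack` (the noiseless expected [lambda_stack()]) and
#'   `phantom` (a `scene_phantom` with truth abundance maps, the component
#'   assignment, and the expected counts). Add shot noise with
#'   [add_poisson_noise()].
#' @export
make_mlv_scene <- function(grid, n_vesicles, component_spectra,
                           intensity_scale = 1000, seed = 1, size = 64,
                           vesicle_radius_px = max(3, round(size / 12)),
                           background_level = 0, pixel_size_nm = 100) {
  stopifnot(inherits(grid, "channel_grid"),
            inherits(component_spectra, "reference_set"))
  if (n_vesicles < 1) stop("`n_vesicles` must be >= 1", call. = FALSE)
  if (!same_grid(component_spectra$grid, grid)) {
    stop("reference spectra are not on the stack grid", call. = FALSE)
  }
  k <- length(component_spectra)
  h <- w <- as.integer(size)
  with_rng(seed, {
    centres <- place_disks(n_vesicles, h, w, vesicle_radius_px)
    abund <- array(0, dim = c(h, w, k))
    assignment <- integer(n_vesicles)
    labels <- matrix(0L, h, w)
    for (v in seq_len(n_vesicles)) {
      comp <- ((v - 1L) %% k) + 1L
      assignment[v] <- comp
      m <- disk_mask(h, w, centres[v, 1], centres[v, 2], vesicle_radius_px)
      plane <- abund[, , comp]
      plane[m] <- intensity_scale
      abund[, , comp] <- plane
      labels[m] <- v
    }
    params <- list(n_vesicles = n_vesicles, intensity_scale = intensity_scale,
                   size = size, vesicle_radius_px = vesicle_radius_px,
                   background_level = background_level)
    out <- new_phantom(abund, component_spectra, grid, pixel_size_nm, params,
                       seed, compartments = labels,
                       background_level = background_level)
    out$phantom$vesicle_component <- assignment
    out$phantom$vesicle_centres <- centres
    out
  })
}

#' Synthetic cell phantom
#'
#' A single round cell with four compartments of exactly known two-component
#' (apolar/polar) composition: an annular plasma membrane (PM), interior
#' cytoplasm, bright circular lipid droplets, and an empty nucleus. The PM
#' default of 0.75 apolar reflects the literature estimate that the plasma
#' membrane of live mammalian cells is about three quarters ordered; the
#' cytoplasm (0.30) and droplet (0.95) defaults are placeholders chosen to
#' be respectively disordered-dominated and strongly apolar, since no
#' quantitative intracellular values are established.
#'
#' @param grid A [channel_grid()].
#' @param refs A two-component [reference_set()] (apolar first) on `grid`.
#' @param size Image edge length in pixels (default 512, matching a typical
#'   acquisition; use 64 for fast tests).
#' @param pm_apolar_fraction,cytoplasm_apolar_fraction,droplet_apolar_fraction
#'   Apolar fraction of each compartment, in \[0, 1\].
#' @param pm_thickness_px PM ring thickness in pixels (default 2, i.e.
#'   200 nm at the default pixel size — the optical resolution limit).
#' @param n_droplets Number of lipid droplets placed in the cytoplasm.
#' @param pm_intensity,cytoplasm_intensity,droplet_intensity Expected
#'   per-pixel channel-sum (counts) in each compartment.
#' @param background_level Flat expected count per voxel outside the cell.
#' @param seed Integer seed (droplet placement).
#' @param pixel_size_nm Pixel size (nm), default 100.
#' @return A list with `stack` (noiseless expected [lambda_stack()]) and
#'   `phantom` (truth maps plus a `compartments` label matrix with values
#'   `"background"`, `"pm"`, `"cytoplasm"`, `"droplet"`, `"nucleus"`).
#' @export
make_cell_scene <- function(grid, refs,
                            size = 512,
                            pm_apolar_fraction = 0.75,
                            cytoplasm_apolar_fraction = 0.3,
                            droplet_apolar_fraction = 0.95,
                            pm_thickness_px = 2,
                            n_droplets = 6,
                            pm_intensity = 2000,
                            cytoplasm_intensity = 1200,
                            droplet_intensity = 3000,
                            background_level = 0,
                            seed = 1,
                            pixel_size_nm = 100) {
  stopifnot(inherits(grid, "channel_grid"), inherits(refs, "reference_set"))
  if (length(refs) != 2L) {
    stop("cell phantom needs exactly two components (apolar, polar)",
         call. = FALSE)
  }
  fr <- c(pm_apolar_fraction, cytoplasm_apolar_fraction,
          droplet_apolar_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("compartment apolar fractions must lie in [0, 1]", call. = FALSE)
  }
  h <- w <- as.integer(size)
  cell_r <- 0.42 * size
  nuc_r <- 0.16 * size
  drop_r <- max(2, round(size / 24))
  if (cell_r - pm_thickness_px <= nuc_r + 2 * drop_r + 2) {
    stop("cell geometry does not fit the image at this size", call. = FALSE)
  }
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  cell <- disk_mask(h, w, cy, cx, cell_r)
  inner <- disk_mask(h, w, cy, cx, cell_r - pm_thickness_px)
  nucleus <- disk_mask(h, w, cy, cx, nuc_r)
  pm <- cell & !inner
  with_rng(seed, {
    droplets <- matrix(FALSE, h, w)
    placed <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(placed) < n_droplets) {
      tries <- tries + 1
      if (tries > 2000) {
        stop("could not place disjoint droplets in the cytoplasm",
             call. = FALSE)
      }
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, nuc_r + drop_r + 2,
                          cell_r - pm_thickness_px - drop_r - 2)
      dcy <- cy + rad * sin(ang); dcx <- cx + rad * cos(ang)
      if (nrow(placed) == 0 ||
          all((placed[, 1] - dcy)^2 + (placed[, 2] - dcx)^2 >
              (2 * drop_r + 2)^2)) {
        placed <- rbind(placed, c(dcy, dcx))
        droplets <- droplets | disk_mask(h, w, dcy, dcx, drop_r)
      }
    }
    cytoplasm <- inner & !nucleus & !droplets
    comp <- matrix("background", h, w)
    comp[cytoplasm] <- "cytoplasm"
    comp[droplets] <- "droplet"
    comp[nucleus] <- "nucleus"
    comp[pm] <- "pm"

    abund <- array(0, dim = c(h, w, 2))
    paint <- function(abund, mask, total, f_apolar) {
      a1 <- abund[, , 1]; a2 <- abund[, , 2]
      a1[mask] <- total * f_apolar
      a2[mask] <- total * (1 - f_apolar)
      abund[, , 1] <- a1; abund[, , 2] <- a2
      abund
    }
    abund <- paint(abund, pm, pm_intensity, pm_apolar_fraction)
    abund <- paint(abund, cytoplasm, cytoplasm_intensity,
                   cytoplasm_apolar_fraction)
    abund <- paint(abund, droplets, droplet_intensity,
                   droplet_apolar_fraction)
    params <- list(size = size, pm_apolar_fraction = pm_apolar_fraction,
                   cytoplasm_apolar_fraction = cytoplasm_apolar_fraction,
                   droplet_apolar_fraction = droplet_apolar_fraction,
                   pm_thickness_px = pm_thickness_px,
                   n_droplets = n_droplets, pm_intensity = pm_intensity,
                   cytoplasm_intensity = cytoplasm_intensity,
                   droplet_intensity = droplet_intensity,
                   background_level = background_level)
    new_phantom(abund, refs, grid, pixel_size_nm, params, seed,
                compartments = comp, background_level = background_level)
  })
}

#' Synthetic two-dye, four-component scene
#'
#' A cell phantom stained with two solvatochromic dyes, each with an apolar
#' and a polar spectral state (four components in total): lipid droplets
#' carry both dyes' apolar states, internal membranes carry both polar
#' states, and the plasma membrane carries only the first dye's apolar
#' state — the second dye leaves the PM unstained, as red droplet stains
#' do. Spectra for the second dye are synthetic Gaussian stand-ins, not
#' measured curves.
#'
#' @param grid A [channel_grid()] wide enough to cover all four components
#'   (a 29-channel 418–700 nm class grid).
#' @param four_component_refs A [reference_set()] with exactly 4 components
#'   ordered (dye1-apolar, dye1-polar, dye2-apolar, dye2-polar).
#' @param seed Integer seed.
#' @param size Image edge length in pixels (default 128).
#' @param intensity_scale Expected channel-sum scale (counts).
#' @param pixel_size_nm Pixel size (nm), default 100.
#' @return A list with `stack` and `phantom` as in [make_cell_scene()].
#' @export
make_two_dye_scene <- function(grid, four_component_refs, seed = 1,
                               size = 128, intensity_scale = 1500,
                               pixel_size_nm = 100) {
  stopifnot(inherits(grid, "channel_grid"),
            inherits(four_component_refs, "reference_set"))
  if (length(four_component_refs) != 4L) {
    stop("two-dye scene needs exactly 4 components", call. = FALSE)
  }
  if (!same_grid(four_component_refs$grid, grid)) {
    stop("reference spectra are not on the stack grid", call. = FALSE)
  }
  h <- w <- as.integer(size)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  cell_r <- 0.42 * size
  pm_t <- 2
  cell <- disk_mask(h, w, cy, cx, cell_r)
  inner <- disk_mask(h, w, cy, cx, cell_r - pm_t)
  pm <- cell & !inner
  internal <- disk_mask(h, w, cy, cx, 0.26 * size) &
    !disk_mask(h, w, cy, cx, 0.12 * size)
  drop_r <- max(2, round(size / 24))
  rad_lo <- 0.26 * size + drop_r
  rad_hi <- cell_r - pm_t - drop_r - 2
  if (rad_lo >= rad_hi) {
    stop("image too small for the two-dye cell geometry", call. = FALSE)
  }
  with_rng(seed, {
    droplets <- matrix(FALSE, h, w)
    for (i in 1:4) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, rad_lo, rad_hi)
      droplets <- droplets |
        disk_mask(h, w, cy + rad * sin(ang), cx + rad * cos(ang), drop_r)
    }
    internal <- internal & !droplets
    abund <- array(0, dim = c(h, w, 4))
    set_comp <- function(abund, mask, comp, val) {
      plane <- abund[, , comp]; plane[mask] <- val; abund[, , comp] <- plane
      abund
    }
    # PM: dye1-apolar only (no second-dye staining of the PM)
    abund <- set_comp(abund, pm, 1, intensity_scale)
    # internal membranes: the two polar states
    abund <- set_comp(abund, internal, 2, 0.6 * intensity_scale)
    abund <- set_comp(abund, internal, 4, 0.5 * intensity_scale)
    # droplets: the two apolar states
    abund <- set_comp(abund, droplets, 1, 0.8 * intensity_scale)
    abund <- set_comp(abund, droplets, 3, 1.2 * intensity_scale)
    comp <- matrix("background", h, w)
    comp[inner] <- "interior"
    comp[internal] <- "internal_membrane"
    comp[droplets] <- "droplet"
    comp[pm] <- "pm"
    params <- list(size = size, intensity_scale = intensity_scale)
    new_phantom(abund, four_component_refs, grid, pixel_size_nm, params,
                seed, compartments = comp)
  })
}

#' Add Poisson shot noise to an expected-count stack
#'
#' Draws one independent Poisson count per voxel with mean equal to the
#' expected value — the shot-noise model that the Poisson-likelihood
#' unmixer assumes. Reproducible given the seed.
#'
#' @param expected A [lambda_stack()] of expected (possibly non-integer)
#'   counts, or a nonnegative numeric array.
#' @param seed Integer seed.
#' @return A [lambda_stack()] of integer counts (same grid and pixel size
#'   when the input is a stack; a default grid must be supplied otherwise).
#' @param grid,pixel_size_nm Used only when `expected` is a bare array.
#' @export
add_poisson_noise <- function(expected, seed, grid = NULL,
                              pixel_size_nm = 100) {
  if (inherits(expected, "lambda_stack")) {
    grid <- expected$grid
    pixel_size_nm <- expected$pixel_size_nm
    expected <- expected$counts
  }
  if (is.null(grid)) stop("`grid` required for a bare array", call. = FALSE)
  if (any(!is.finite(expected)) || any(expected < 0)) {
    stop("expected counts must be finite and nonnegative", call. = FALSE)
  }
  d <- dim(expected)
  counts <- with_rng(seed, stats::rpois(length(expected), expected))
  lambda_stack(array(as.numeric(counts), dim = d), grid, pixel_size_nm)
}
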