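#' Emission spectrum on a channel grid
#'
#' A binned emission spectrum: one nonnegative intensity per channel of a
#' [channel_grid()]. Spectra are stored per channel (what a spectral detector
#' delivers), not as continuous curves.
#'
#' @param grid A [channel_grid()].
#' @param values Nonnegative numeric vector, one value per channel; must not
#'   be all zero.
#' @param name Text label for the component (e.g. `"apolar"`).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(grid, values, name = "component") {
  stopifnot(inherits(grid, "channel_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_channels) {
    stop(sprintf("spectrum has %d values but grid has %d channels",
                 length(values), grid$n_channels), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("spectrum values must be finite and nonnegative", call. = FALSE)
  }
  if (all(values == 0)) stop("spectrum is all zero", call. = FALSE)
  structure(list(grid = grid, values = values, name = as.character(name)),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> '%s', %d channels, peak at %.4g nm\n",
              x$name, x$grid$n_channels,
              channel_centers(x$grid)[which.max(x$values)]))
  invisible(x)
}

#' Normalize an emission spectrum
#'
#' `unit-area` scales the values to sum to 1 (the convention required before
#' unmixing, so that abundances are comparable across components);
#' `unit-max` scales the maximum to 1 (convenient for plotting).
#'
#' @param spec An [emission_spectrum()].
#' @param mode `"unit-area"` (default) or `"unit-max"`.
#' @return The rescaled [emission_spectrum()]; shape is preserved.
#' @export
normalize_spectrum <- function(spec, mode = c("unit-area", "unit-max")) {
  stopifnot(inherits(spec, "emission_spectrum"))
  mode <- match.arg(mode)
  denom <- switch(mode, "unit-area" = sum(spec$values),
                  "unit-max" = max(spec$values))
  if (denom <= 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  emission_spectrum(spec$grid, spec$values / denom, spec$name)
}

#' Resample a spectrum onto another channel grid
#'
#' Values are linearly interpolated (in channel-centre wavelength) at the
#' target grid's channel centres, clipped at zero; target channels whose
#' centres fall outside the source centre range are set to zero.
#'
#' @param spec An [emission_spectrum()].
#' @param target A [channel_grid()] overlapping the source wavelength range.
#' @return An [emission_spectrum()] on `target`.
#' @export
resample_spectrum <- function(spec, target) {
  stopifnot(inherits(spec, "emission_spectrum"),
            inherits(target, "channel_grid"))
  if (same_grid(spec$grid, target)) {
    return(emission_spectrum(target, spec$values, spec$name))
  }
  src_x <- channel_centers(spec$grid)
  tgt_x <- channel_centers(target)
  if (max(tgt_x) < min(src_x) || min(tgt_x) > max(src_x)) {
    stop("target grid does not overlap the source wavelength range",
         call. = FALSE)
  }
  vals <- if (length(src_x) == 1L) {
    ifelse(abs(tgt_x - src_x) <= spec$grid$step_nm / 2, spec$values, 0)
  } else {
    stats::approx(src_x, spec$values, xout = tgt_x, rule = 1)$y
  }
  vals[is.na(vals)] <- 0
  vals <- pmax(vals, 0)
  if (all(vals == 0)) {
    stop("resampling left no signal on the target grid", call. = FALSE)
  }
  emission_spectrum(target, vals, spec$name)
}

#' Gaussian model emission spectrum
#'
#' A unit-area Gaussian evaluated at channel centres: the simplest
#' two-parameter stand-in for a solvatochromic probe's emission band. The
#' apolar (ordered, dehydrated) state of laurdan-family probes peaks near
#' 440 nm, the polar (water-exposed) state near 490 nm.
#'
#' @param peak_nm Peak emission wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm); must be positive.
#' @param grid A [channel_grid()].
#' @param name Component label.
#' @return A unit-area [emission_spectrum()].
#' @examples
#' g <- build_channel_grid(418, 584, 9.8)
#' blue <- gaussian_emission(440, 45, g, "apolar")
#' @export
gaussian_emission <- function(peak_nm, fwhm_nm, grid, name = "component") {
  stopifnot(inherits(grid, "channel_grid"))
  if (!is.numeric(fwhm_nm) || fwhm_nm <= 0) {
    stop("`fwhm_nm` must be positive", call. = FALSE)
  }
  sd_nm <- fwhm_nm / (2 * sqrt(2 * log(2)))
  vals <- stats::dnorm(channel_centers(grid), mean = peak_nm, sd = sd_nm)
  normalize_spectrum(emission_spectrum(grid, vals, name), "unit-area")
}

#' Mean spectrum over a region of interest
#'
#' Extracts the per-channel arithmetic mean over the pixels selected by a
#' logical mask — the standard way of reading a reference emission curve off
#' a lambda stack of pure-phase vesicles.
#'
#' @param stack A [lambda_stack()].
#' @param roi_mask Logical H×W matrix, same spatial size as the stack; at
#'   least one `TRUE` pixel.
#' @param name Label for the extracted spectrum.
#' @return An [emission_spectrum()] on the stack's grid.
#' @export
roi_mean_spectrum <- function(stack, roi_mask, name = "roi") {
  stopifnot(inherits(stack, "lambda_stack"))
  d <- dim(stack$counts)
  storage.mode(roi_mask) <- "logical"
  if (!identical(dim(roi_mask), d[1:2])) {
    stop("`roi_mask` must match the stack's H x W dimensions", call. = FALSE)
  }
  if (!any(roi_mask, na.rm = TRUE)) stop("empty ROI", call. = FALSE)
  sel <- which(roi_mask)
  flat <- matrix(stack$counts, nrow = d[1] * d[2], ncol = d[3])
  emission_spectrum(stack$grid, colMeans(flat[sel, , drop = FALSE]), name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference spectrum set
#'
#' An ordered collection of named emission spectra sharing one channel grid —
#' the basis used for spectral unmixing. By convention the *apolar* component
#' comes first; the fraction map reports the first component's share.
#' Spectra are unit-area normalized on construction.
#'
#' @param ... [emission_spectrum()] objects (or a single list of them).
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(...) {
  spectra <- list(...)
  if (length(spectra) == 1L && !inherits(spectra[[1]], "emission_spectrum")) {
    spectra <- spectra[[1]]
  }
  if (length(spectra) < 1L) stop("need at least one spectrum", call. = FALSE)
  if (!all(vapply(spectra, inherits, TRUE, "emission_spectrum"))) {
    stop("all elements must be emission_spectrum objects", call. = FALSE)
  }
  g <- spectra[[1]]$grid
  if (!all(vapply(spectra, function(s) same_grid(s$grid, g), TRUE))) {
    stop("all spectra must share one channel grid", call. = FALSE)
  }
  nms <- vapply(spectra, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("component names must be unique", call. = FALSE)
  spectra <- lapply(spectra, normalize_spectrum, mode = "unit-area")
  structure(list(spectra = spectra, grid = g, names = nms),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d components on %d channels: %s\n",
              length(x$spectra), x$grid$n_channels,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$spectra)

# internal: channels x components matrix of unit-area spectra
ref_matrix <- function(refs) {
  stopifnot(inherits(refs, "reference_set"))
  m <- vapply(refs$spectra, function(s) s$values,
              numeric(refs$grid$n_channels))
  m <- matrix(m, nrow = refs$grid$n_channels)
  colnames(m) <- refs$names
  m
}

#' Lateral optical resolution of a scanning microscope
#'
#' The diffraction-limited lateral resolution, `0.4 * wavelength / NA`. At
#' 500 nm emission through an NA 1.2 objective this is 167 nm — about two
#' 100 nm pixels, which is why single-pixel heterogeneity in fraction images
#' cannot be read as real membrane domains.
#'
#' @param wavelength_nm Emission wavelength (nm), positive.
#' @param numerical_aperture Objective numerical aperture, positive.
#' @return Resolution in nm (not rounded).
#' @examples
#' round(lateral_resolution(500, 1.2))  # 167
#' @export
lateral_resolution <- function(wavelength_nm, numerical_aperture) {
  if (!is.numeric(wavelength_nm) || any(wavelength_nm <= 0) ||
      !is.numeric(numerical_aperture) || any(numerical_aperture <= 0)) {
    stop("wavelength and numerical aperture must be positive", call. = FALSE)
  }
  0.4 * wavelength_nm / numerical_aperture
}
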