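#' Optical band filter
#'
#' A set of closed wavelength passbands, as realized by bandpass/long-pass
#' filter combinations on a cytometer detector. Overlapping or touching
#' intervals are merged. Standard filter codes can be decoded with
#' [decode_filter_code()]: `"450/50 BP"` means centre 450 nm, width 50 nm,
#' i.e. \[425, 475\].
#'
#' @param passbands An n×2 matrix (or 2-vector) of \[lo, hi\] intervals in
#'   nm, `lo <= hi`.
#' @param name Filter label.
#' @return An object of class `band_filter`.
#' @export
band_filter <- function(passbands, name = "band") {
  pb <- matrix(as.numeric(passbands), ncol = 2)
  if (any(!is.finite(pb[, 1])) || any(pb[, 1] > pb[, 2])) {
    stop("passbands must be finite [lo, hi] intervals with lo <= hi",
         call. = FALSE)
  }
  pb <- pb[order(pb[, 1]), , drop = FALSE]
  merged <- pb[1, , drop = FALSE]
  for (i in seq_len(nrow(pb))[-1]) {
    last <- nrow(merged)
    if (pb[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], pb[i, 2])
    } else {
      merged <- rbind(merged, pb[i, ])
    }
  }
  structure(list(passbands = merged, name = as.character(name)),
            class = "band_filter")
}

#' Decode standard filter codes into a band filter
#'
#' Understands `"<centre>/<width> BP"` bandpass codes (interval
#' `centre ± width/2`) and `"<edge>LP"` long-pass codes (`[edge, Inf)`);
#' multiple codes are intersected, as when a long-pass sits in front of a
#' bandpass. The cytometer channels used for laurdan-family ratios decode
#' to \[425, 475\] (`"450/50 BP"`) and \[515, 545\]
#' (`"505LP" + "530/30 BP"`).
#'
#' @param ... Filter code strings.
#' @param name Filter label.
#' @return A [band_filter()].
#' @examples
#' decode_filter_code("505LP", "530/30 BP")$passbands  # 515 545
#' @export
decode_filter_code <- function(..., name = NULL) {
  codes <- c(...)
  lo <- -Inf; hi <- Inf
  for (code in codes) {
    code <- trimws(code)
    if (grepl("^\\d+(\\.\\d+)?\\s*LP$", code, ignore.case = TRUE)) {
      edge <- as.numeric(sub("\\s*LP$", "", code, ignore.case = TRUE))
      lo <- max(lo, edge)
    } else if (grepl("^\\d+(\\.\\d+)?\\s*/\\s*\\d+(\\.\\d+)?(\\s*BP)?$",
                     code, ignore.case = TRUE)) {
      parts <- as.numeric(strsplit(sub("\\s*BP$", "", code,
                                       ignore.case = TRUE), "/")[[1]])
      lo <- max(lo, parts[1] - parts[2] / 2)
      hi <- min(hi, parts[1] + parts[2] / 2)
    } else {
      stop(sprintf("unrecognized filter code '%s'", code), call. = FALSE)
    }
  }
  if (!is.finite(hi)) {
    stop("long-pass alone gives an unbounded band; add a bandpass",
         call. = FALSE)
  }
  if (!is.finite(lo)) lo <- 0
  if (lo > hi) stop("filter codes intersect to an empty band", call. = FALSE)
  band_filter(c(lo, hi), name %||% paste(codes, collapse = " + "))
}

#' Band-integrated intensity of a spectrum
#'
#' Sums channel values weighted by the fraction of each channel's
#' wavelength interval covered by the filter passbands: a channel half
#' inside the band contributes half its value. Returns 0 (with a warning)
#' when the filter misses the grid entirely.
#'
#' @param spec An [emission_spectrum()].
#' @param filter A [band_filter()].
#' @return A single nonnegative number.
#' @export
band_intensity <- function(spec, filter) {
  stopifnot(inherits(spec, "emission_spectrum"),
            inherits(filter, "band_filter"))
  edges <- channel_edges(spec$grid)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  w <- spec$grid$step_nm
  cover <- numeric(length(lo))
  for (i in seq_len(nrow(filter$passbands))) {
    a <- filter$passbands[i, 1]; b <- filter$passbands[i, 2]
    cover <- cover + pmax(0, pmin(hi, b) - pmax(lo, a))
  }
  cover <- pmin(cover, w)       # merged bands cannot over-cover a channel
  if (all(cover == 0)) {
    warning(sprintf("filter '%s' does not overlap the spectral grid",
                    filter$name))
    return(0)
  }
  sum(spec$values * cover / w)
}

# the cytometer band pair used as a GP-like proxy
band_450 <- function() decode_filter_code("450/50 BP", name = "450/50")
band_530 <- function() decode_filter_code("505LP", "530/30 BP",
                                          name = "505LP+530/30")

#' Blue/green emission band ratio (450/530)
#'
#' The flow-cytometry proxy for membrane order: band intensity through a
#' 450/50 bandpass (\[425, 475\] nm, the ordered-state emission) divided by
#' band intensity through a 505 long-pass plus 530/30 bandpass
#' (\[515, 545\] nm, the water-exposed emission). Scale-invariant in the
#' spectrum; higher ratios mean more apolar probe environments, and
#' cholesterol depletion lowers it.
#'
#' @param spec An [emission_spectrum()].
#' @return A single positive number.
#' @export
ratio_450_530 <- function(spec) {
  num <- band_intensity(spec, band_450())
  den <- band_intensity(spec, band_530())
  if (den <= 0) {
    stop("zero intensity in the 530 band; ratio undefined", call. = FALSE)
  }
  num / den
}

#' Synthetic ensemble of per-cell spectra
#'
#' Emulates a stained cell suspension read on a cytometer: each cell's
#' expected spectrum is a two-state mixture
#' `scale * (f * apolar + (1 - f) * polar)` with per-cell lognormal
#' brightness, truncated-normal jitter on the apolar fraction, and
#' optional Poisson counting noise per channel.
#'
#' @param n_cells Number of cells (>= 1).
#' @param apolar_fraction Mean apolar fraction of the population, \[0, 1\].
#' @param refs A two-component [reference_set()] (apolar first).
#' @param mean_total_counts Mean expected channel-summed counts per cell.
#' @param fraction_sd Per-cell standard deviation of the apolar fraction
#'   (truncated to \[0, 1\]).
#' @param brightness_cv Coefficient of variation of per-cell brightness.
#' @param poisson_noise Draw Poisson counts per channel (default TRUE).
#' @param condition Label attached to every cell (e.g. treatment group).
#' @param seed Integer seed.
#' @return An object of class `cell_ensemble`: list of
#'   [emission_spectrum()] per cell, per-cell scales and true fractions,
#'   the condition label, and generation parameters.
#' @export
make_cell_ensemble <- function(n_cells, apolar_fraction, refs,
                               mean_total_counts = 5000,
                               fraction_sd = 0.03, brightness_cv = 0.25,
                               poisson_noise = TRUE,
                               condition = sprintf("f=%.2f", apolar_fraction),
                               seed = 1) {
  stopifnot(inherits(refs, "reference_set"))
  if (length(refs) != 2L) {
    stop("cell ensembles use a two-component (apolar, polar) basis",
         call. = FALSE)
  }
  if (n_cells < 1) stop("need at least one cell", call. = FALSE)
  if (apolar_fraction < 0 || apolar_fraction > 1) {
    stop("`apolar_fraction` must lie in [0, 1]", call. = FALSE)
  }
  s <- ref_matrix(refs)
  with_rng(seed, {
    sdlog <- sqrt(log(1 + brightness_cv^2))
    scales <- stats::rlnorm(n_cells, log(mean_total_counts) - sdlog^2 / 2,
                            sdlog)
    fr <- pmin(pmax(stats::rnorm(n_cells, apolar_fraction, fraction_sd),
                    0), 1)
    spectra <- lapply(seq_len(n_cells), function(i) {
      mu <- scales[i] * (fr[i] * s[, 1] + (1 - fr[i]) * s[, 2])
      v <- if (poisson_noise) stats::rpois(length(mu), mu) else mu
      if (all(v == 0)) v <- mu + .kl_eps   # pathological all-zero draw
      emission_spectrum(refs$grid, v, sprintf("cell_%d", i))
    })
    structure(list(spectra = spectra, scales = scales,
                   true_fractions = fr, condition = condition,
                   params = list(n_cells = n_cells,
                                 apolar_fraction = apolar_fraction,
                                 mean_total_counts = mean_total_counts,
                                 fraction_sd = fraction_sd,
                                 brightness_cv = brightness_cv,
                                 poisson_noise = poisson_noise),
                   seed = as.integer(seed)),
              class = "cell_ensemble")
  })
}

#' @export
print.cell_ensemble <- function(x, ...) {
  cat(sprintf("<cell_ensemble> %d cells, condition '%s'\n",
              length(x$spectra), x$condition))
  invisible(x)
}

#' Summarize band intensities and ratios over cell ensembles
#'
#' Per condition: mean band intensity in the 450 and 530 channels, the
#' mean of per-cell 450/530 ratios (the primary statistic), and the ratio
#' of the mean intensities (reported alongside, since the two can differ
#' for broad brightness distributions).
#'
#' @param ... One or more `cell_ensemble` objects (or a single list of
#'   them).
#' @return A data.frame with one row per condition: `condition`,
#'   `n_cells`, `mean_i450`, `mean_i530`, `mean_ratio`, `ratio_of_means`.
#' @export
ensemble_summary <- function(...) {
  ensembles <- list(...)
  if (length(ensembles) == 1L && !inherits(ensembles[[1]], "cell_ensemble")) {
    ensembles <- ensembles[[1]]
  }
  if (length(ensembles) < 1L ||
      !all(vapply(ensembles, inherits, TRUE, "cell_ensemble"))) {
    stop("supply one or more cell_ensemble objects", call. = FALSE)
  }
  f450 <- band_450(); f530 <- band_530()
  rows <- lapply(ensembles, function(e) {
    i450 <- vapply(e$spectra, band_intensity, numeric(1), filter = f450)
    i530 <- vapply(e$spectra, band_intensity, numeric(1), filter = f530)
    if (any(i530 <= 0)) {
      stop("a cell has zero 530-band intensity; ratio undefined",
           call. = FALSE)
    }
    data.frame(condition = e$condition, n_cells = length(e$spectra),
               mean_i450 = mean(i450), mean_i530 = mean(i530),
               mean_ratio = mean(i450 / i530),
               ratio_of_means = mean(i450) / mean(i530),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
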