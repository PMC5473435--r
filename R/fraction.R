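#' Fractional-intensity map of a two-component decomposition
#'
#' Converts a two-component abundance stack into fractional intensities by
#' dividing the first component's image by the total-intensity image:
#' `f = I1 / (I1 + I2)`. Because the two fractions always sum to 1, a
#' single number per pixel indexes the composition. By the package's
#' convention the first component is the *apolar* one, so high fractions
#' mean ordered, dehydrated membrane environments. Pixels with zero total
#' intensity or flagged as background have an undefined fraction, stored as
#' `NA` — never as 0 or 0.5 — and are excluded from rendering and
#' statistics.
#'
#' @param two_maps An `abundance_maps` object with exactly two components
#'   (see [unmix_fixed()]).
#' @return An object of class `fraction_map`: `fraction` (H×W in \[0,1\],
#'   `NA` where undefined), `total_intensity` (H×W), `defined` (logical
#'   H×W), plus component names and pixel size.
#' @export
fraction_map <- function(two_maps) {
  stopifnot(inherits(two_maps, "abundance_maps"))
  if (dim(two_maps$values)[3] != 2L) {
    stop("fraction mapping needs exactly two components", call. = FALSE)
  }
  d <- dim(two_maps$values)
  i1 <- matrix(two_maps$values[, , 1], d[1], d[2])
  i2 <- matrix(two_maps$values[, , 2], d[1], d[2])
  total <- i1 + i2
  defined <- total > 0 & !two_maps$background_mask
  fraction <- matrix(NA_real_, nrow(total), ncol(total))
  fraction[defined] <- i1[defined] / total[defined]
  structure(list(fraction = fraction, total_intensity = total,
                 defined = defined, component_names = two_maps$names,
                 pixel_size_nm = two_maps$pixel_size_nm),
            class = "fraction_map")
}

#' @export
print.fraction_map <- function(x, ...) {
  cat(sprintf(
    "<fraction_map> %d x %d px, '%s' fraction; %d defined px, median %.3f\n",
    nrow(x$fraction), ncol(x$fraction), x$component_names[1],
    sum(x$defined), stats::median(x$fraction, na.rm = TRUE)))
  invisible(x)
}

#' Convert a fraction to generalized polarisation (GP)
#'
#' `GP = 2 * fraction - 1`: the fraction of apolar signal and the classic
#' GP index carry the same information on different scales (\[0,1\] vs
#' \[-1,1\]). `NA` (undefined pixels) passes through; values outside
#' \[0,1\] beyond float round-off are rejected.
#'
#' @param fraction Numeric vector/matrix of fractions in \[0, 1\] (or NA).
#' @return`2 * fraction - 1`, same shape.
#' @examples
#' fraction_to_gp(c(0, 0.5, 0.75, 1))  # -1  0  0.5  1
#' @export
fraction_to_gp <- function(fraction) {
  bad <- !is.na(fraction) & (fraction < -1e-9 | fraction > 1 + 1e-9)
  if (any(bad)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  2 * pmin(pmax(fraction, 0), 1) - 1
}

#' GP map from two raw spectral channels
#'
#' The classic two-channel generalized polarisation image,
#' `(I_blue - I_green) / (I_blue + I_green)`, computed directly from two
#' channels of a lambda stack (conventionally the 440 nm and 490 nm
#' channels). Wherever both routes see the same two intensities this
#' equals `2 * fraction - 1` exactly.
#'
#' @param stack A [lambda_stack()].
#' @param ch_blue_index,ch_green_index Distinct 1-based channel indices
#'   (blue = ordered-state band, green = water-exposed band).
#' @return H×W numeric matrix in \[-1, 1\], `NA` where both channels are 0.
#' @export
gp_map_from_channels <- function(stack, ch_blue_index, ch_green_index) {
  stopifnot(inherits(stack, "lambda_stack"))
  nc <- dim(stack$counts)[3]
  idx <- c(ch_blue_index, ch_green_index)
  if (any(idx < 1 | idx > nc)) stop("channel index out of range",
                                    call. = FALSE)
  if (ch_blue_index == ch_green_index) {
    stop("the two channel indices must be distinct", call. = FALSE)
  }
  d <- dim(stack$counts)
  ib <- matrix(stack$counts[, , ch_blue_index], d[1], d[2])
  ig <- matrix(stack$counts[, , ch_green_index], d[1], d[2])
  tot <- ib + ig
  gp <- matrix(NA_real_, nrow(ib), ncol(ib))
  ok <- tot > 0
  gp[ok] <- (ib[ok] - ig[ok]) / tot[ok]
  gp
}

#' Nearest-channel index for a wavelength
#'
#' Convenience for picking the classic GP channels: the grid channel whose
#' interval contains (or whose centre is nearest to) the given wavelength.
#'
#' @param grid A [channel_grid()].
#' @param wavelength_nm Target wavelength (nm).
#' @return 1-based channel index.
#' @export
channel_index <- function(grid, wavelength_nm) {
  which.min(abs(channel_centers(grid) - wavelength_nm))
}

#' Discrete lookup table over the unit fraction interval
#'
#' Partitions \[0, 1\] into `length(colours)` contiguous bins with relative
#' widths `bin_widths` (denominator = their sum); bins are half-open
#' `[lo, hi)` with the last bin closed at 1, so every fraction maps to
#' exactly one colour.
#'
#' @param colours Character vector of R colours or a 3-row/3-column RGB
#'   matrix in \[0, 1\], ordered from fraction 0 upward.
#' @param bin_widths Positive integer relative widths, one per colour.
#' @return An object of class `discrete_lut` with `rgb` (n×3 matrix),
#'   `bin_widths` and `edges` (length n+1, from 0 to 1).
#' @export
discrete_lut <- function(colours, bin_widths) {
  if (is.character(colours)) {
    rgbm <- t(grDevices::col2rgb(colours)) / 255
  } else {
    rgbm <- as.matrix(colours)
    if (ncol(rgbm) != 3) rgbm <- t(rgbm)
  }
  if (any(bin_widths <= 0)) stop("bin widths must be positive", call. = FALSE)
  if (nrow(rgbm) != length(bin_widths)) {
    stop("need one bin width per colour", call. = FALSE)
  }
  edges <- c(0, cumsum(bin_widths) / sum(bin_widths))
  edges[length(edges)] <- 1
  structure(list(rgb = rgbm, bin_widths = as.numeric(bin_widths),
                 edges = edges),
            class = "discrete_lut")
}

#' The six-colour membrane-order LUT
#'
#' The standard six-discrete-colour blue-to-red LUT with relative bin
#' widths 2,3,3,3,3,2 over a denominator of 16 (bin edges at 0, 2/16,
#' 5/16, 8/16, 11/16, 14/16, 1). Dark blue sits at *high* fraction —
#' very ordered, apolar membrane — and red at low fraction
#' (water-exposed, disordered), matching the convention that the first
#' unmixed component is the apolar one.
#'
#' @return A [discrete_lut()].
#' @export
lut_six_colour <- function() {
  discrete_lut(c("#D40000", "#FF8C00", "#FFE100", "#00C000",
                 "#00B4FF", "#00008B"),
               c(2, 3, 3, 3, 3, 2))
}

# internal: bin index for fractions under the half-open convention
lut_bin <- function(fraction, lut) {
  idx <- findInterval(fraction, lut$edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  pmin(pmax(idx, 1L), nrow(lut$rgb))
}

#' Render a fraction map as an intensity-scaled colour image
#'
#' Each defined pixel gets the LUT colour of its fraction bin, scaled by
#' `min(total_intensity / ceiling, 1)` so that colour brightness carries
#' the total signal; undefined pixels are black. Scaling is linear with
#' clipping at the ceiling (no gamma).
#'
#' @param fmap A [fraction_map()].
#' @param lut A [discrete_lut()]; default [lut_six_colour()].
#' @param intensity_ceiling Positive number, or `"auto"` (the maximum
#'   total intensity over defined pixels).
#' @return An H×W×3 RGB array in \[0, 1\].
#' @export
colorize_fraction <- function(fmap, lut = lut_six_colour(),
                              intensity_ceiling = "auto") {
  stopifnot(inherits(fmap, "fraction_map"), inherits(lut, "discrete_lut"))
  h <- nrow(fmap$fraction); w <- ncol(fmap$fraction)
  img <- array(0, dim = c(h, w, 3))
  if (!any(fmap$defined)) {
    warning("no defined pixels; returning an all-black image")
    return(img)
  }
  ceiling_val <- if (identical(intensity_ceiling, "auto")) {
    max(fmap$total_intensity[fmap$defined])
  } else {
    as.numeric(intensity_ceiling)
  }
  if (!is.finite(ceiling_val) || ceiling_val <= 0) {
    stop("`intensity_ceiling` must be positive", call. = FALSE)
  }
  sel <- which(fmap$defined)
  bins <- lut_bin(fmap$fraction[sel], lut)
  scale <- pmin(fmap$total_intensity[sel] / ceiling_val, 1)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- lut$rgb[bins, ch] * scale
    img[, , ch] <- plane
  }
  img
}

#' 2D intensity histogram of a two-component decomposition
#'
#' Bins every included pixel by its two unmixed intensities `(I1, I2)` —
#' the image-analysis analogue of a flow-cytometry dot plot. Background
#' and undefined pixels are omitted; the histogram total therefore equals
#' the number of included pixels. Axes can be binned linearly or on
#' `log10(1 + I)`.
#'
#' @param two_maps An `abundance_maps` with exactly two components.
#' @param n_bins Number of bins per axis (>= 2).
#' @param scale `"linear"` (default) or `"log"`.
#' @return An object of class `intensity_histogram`: `counts` (n×n matrix,
#'   rows = I1 bins), `breaks1`, `breaks2` (intensity-scale bin edges),
#'   `scale`, and `n_included`.
#' @export
intensity_histogram_2d <- function(two_maps, n_bins = 64,
                                   scale = c("linear", "log")) {
  stopifnot(inherits(two_maps, "abundance_maps"))
  scale <- match.arg(scale)
  if (dim(two_maps$values)[3] != 2L) {
    stop("histogram needs exactly two components", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("`n_bins` must be >= 2",
                                         call. = FALSE)
  inc <- !two_maps$background_mask &
    (two_maps$values[, , 1] + two_maps$values[, , 2] > 0)
  i1 <- two_maps$values[, , 1][inc]
  i2 <- two_maps$values[, , 2][inc]
  tr <- if (scale == "log") function(x) log10(1 + x) else identity
  inv <- if (scale == "log") function(x) 10^x - 1 else identity
  t1 <- tr(i1); t2 <- tr(i2)
  brk <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1)
  }
  b1 <- brk(t1); b2 <- brk(t2)
  c1 <- pmin(findInterval(t1, b1, rightmost.closed = TRUE), n_bins)
  c2 <- pmin(findInterval(t2, b2, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(c1, levels = seq_len(n_bins)),
               factor(c2, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, breaks1 = inv(b1), breaks2 = inv(b2),
                 scale = scale, n_included = length(i1),
                 component_names = two_maps$names),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d x %d bins (%s), %d pixels\n",
              nrow(x$counts), ncol(x$counts), x$scale, x$n_included))
  invisible(x)
}

#' @export
plot.intensity_histogram <- function(x, ...) {
  graphics::image(x$breaks1, x$breaks2, log10(1 + x$counts),
                  xlab = paste(x$component_names[1], "intensity"),
                  ylab = paste(x$component_names[2], "intensity"),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Polygon gate in two-component intensity space
#'
#' A named simple polygon in `(I1, I2)` space, used to select pixel
#' populations on the 2D intensity histogram and project them back into
#' the image — the image analogue of flow-cytometry gating. Points on the
#' polygon boundary count as inside.
#'
#' @param vertices An n×2 numeric matrix (or data.frame) of polygon
#'   vertices, n >= 3, in intensity units (I1, I2).
#' @param name Gate label.
#' @return An object of class `gate`.
#' @export
gate_polygon <- function(vertices, name = "gate") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3 || any(!is.finite(v))) {
    stop("a gate needs >= 3 finite (I1, I2) vertices", call. = FALSE)
  }
  # drop a repeated closing vertex
  if (all(v[1, ] == v[nrow(v), ]) && nrow(v) > 3) v <- v[-nrow(v), ]
  if (polygon_is_degenerate(v)) {
    stop("degenerate (zero-area or self-touching) gate polygon",
         call. = FALSE)
  }
  structure(list(vertices = v, name = as.character(name)), class = "gate")
}

# internal: degenerate if all vertices collinear
polygon_is_degenerate <- function(v) {
  n <- nrow(v)
  area2 <- sum(v[, 1] * v[c(2:n, 1), 2] - v[c(2:n, 1), 1] * v[, 2])
  abs(area2) < 1e-12
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd (ray-casting) membership with an explicit on-segment check so
#' that points exactly on the polygon boundary are inside — gates drawn as
#' the bounding box of the data must capture every point.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param vertices n×2 polygon vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_along(x), function(i) {
    px <- x[i]; py <- y[i]
    inside <- FALSE
    for (j in seq_len(n)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xe[j]; y2 <- ye[j]
      # on-segment: collinear and within the bounding box
      cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
      if (abs(cross) <= 1e-9 * max(1, abs(x2 - x1), abs(y2 - y1)) &&
          px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
          py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12) {
        return(TRUE)
      }
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Project an intensity-space gate back into the image
#'
#' Marks every included pixel whose `(I1, I2)` intensities fall inside the
#' gate polygon (boundary inclusive) and renders the fraction map
#' restricted to those pixels; everything else is black.
#'
#' @param two_maps An `abundance_maps` with exactly two components.
#' @param gate A [gate_polygon()].
#' @param fmap The matching [fraction_map()]; computed from `two_maps`
#'   when omitted.
#' @param lut A [discrete_lut()].
#' @param intensity_ceiling As in [colorize_fraction()].
#' @return A list: `mask` (logical H×W) and `image` (H×W×3 RGB).
#' @export
gate_to_image <- function(two_maps, gate, fmap = fraction_map(two_maps),
                          lut = lut_six_colour(),
                          intensity_ceiling = "auto") {
  stopifnot(inherits(two_maps, "abundance_maps"), inherits(gate, "gate"))
  if (dim(two_maps$values)[3] != 2L) {
    stop("gating needs exactly two components", call. = FALSE)
  }
  d <- dim(two_maps$values)
  i1 <- matrix(two_maps$values[, , 1], d[1], d[2])
  i2 <- matrix(two_maps$values[, , 2], d[1], d[2])
  inc <- fmap$defined
  mask <- matrix(FALSE, nrow(i1), ncol(i1))
  sel <- which(inc)
  if (length(sel)) {
    mask[sel] <- point_in_polygon(i1[sel], i2[sel], gate$vertices)
  }
  img <- colorize_fraction(fmap, lut, intensity_ceiling)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!mask] <- 0
    img[, , ch] <- plane
  }
  list(mask = mask, image = img)
}
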