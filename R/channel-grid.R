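#' Spectral channel grid
#'
#' A channel grid describes how a spectral detector bins emitted light: a
#' first bin starting at `start_nm`, bins of constant width `step_nm`, and
#' `n_channels` contiguous bins. Channel `i` (1-based) occupies the half-open
#' wavelength interval `[start + (i-1)*step, start + i*step)` and its centre
#' is `start + (i - 0.5) * step`.
#'
#' @param start_nm Lower edge of the first channel, in nm.
#' @param step_nm Channel width, in nm; must be positive.
#' @param n_channels Number of channels; must be a positive integer.
#' @return An object of class `channel_grid`.
#' @seealso [build_channel_grid()] to construct a grid from its outer edges.
#' @examples
#' g <- channel_grid(418, 9.8, 17)
#' channel_centers(g)
#' @export
channel_grid <- function(start_nm, step_nm, n_channels) {
  stopifnot(is.numeric(start_nm), length(start_nm) == 1L, is.finite(start_nm))
  if (!is.numeric(step_nm) || length(step_nm) != 1L || !is.finite(step_nm) ||
      step_nm <= 0) {
    stop("`step_nm` must be a single positive number (nm)", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  structure(
    list(start_nm = as.numeric(start_nm), step_nm = as.numeric(step_nm),
         n_channels = n_channels),
    class = "channel_grid"
  )
}

#' Build a channel grid from its outer wavelength edges
#'
#' The number of channels is `round((end_nm - start_nm) / step_nm)`: the
#' stated endpoints are interpreted as outer bin *edges*. This reproduces the
#' standard spectral-detector acquisitions of 17 channels between 418 and
#' 584 nm and 29 channels between 418 and 700 nm at 9.8 nm resolution.
#'
#' @param start_nm Lower edge of the first channel (nm).
#' @param end_nm Upper edge of the last channel (nm); must exceed `start_nm`.
#' @param step_nm Channel width (nm); must be positive.
#' @return A [channel_grid()].
#' @examples
#' build_channel_grid(418, 584, 9.8)$n_channels  # 17
#' build_channel_grid(418, 700, 9.8)$n_channels  # 29
#' @export
build_channel_grid <- function(start_nm, end_nm, step_nm) {
  if (!is.numeric(step_nm) || length(step_nm) != 1L || step_nm <= 0) {
    stop("`step_nm` must be positive", call. = FALSE)
  }
  if (!is.numeric(end_nm) || !is.numeric(start_nm) || end_nm <= start_nm) {
    stop("`end_nm` must exceed `start_nm`", call. = FALSE)
  }
  n <- as.integer(round((end_nm - start_nm) / step_nm))
  if (n < 1L) stop("span shorter than one channel", call. = FALSE)
  channel_grid(start_nm, step_nm, n)
}

#' Channel centre wavelengths
#' @param grid A [channel_grid()].
#' @return Numeric vector of channel centres (nm), strictly increasing.
#' @export
channel_centers <- function(grid) {
  stopifnot(inherits(grid, "channel_grid"))
  grid$start_nm + (seq_len(grid$n_channels) - 0.5) * grid$step_nm
}

#' Channel edge wavelengths
#' @param grid A [channel_grid()].
#' @return Numeric vector of `n_channels + 1` bin edges (nm).
#' @export
channel_edges <- function(grid) {
  stopifnot(inherits(grid, "channel_grid"))
  grid$start_nm + (0:grid$n_channels) * grid$step_nm
}

#' @export
print.channel_grid <- function(x, ...) {
  cat(sprintf("<channel_grid> %d channels of %.4g nm from %.4g to %.4g nm\n",
              x$n_channels, x$step_nm, x$start_nm,
              x$start_nm + x$n_channels * x$step_nm))
  invisible(x)
}

# internal: grids identical up to float tolerance
same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "channel_grid") && inherits(b, "channel_grid") &&
    a$n_channels == b$n_channels &&
    abs(a$start_nm - b$start_nm) <= tol &&
    abs(a$step_nm - b$step_nm) <= tol
}
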