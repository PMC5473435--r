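#' Lambda stack (multi-channel spectral image)
#'
#' A lambda stack is an image acquired as a stack of narrow spectral
#' channels: an H×W×C array of nonnegative counts with a [channel_grid()]
#' describing the spectral binning and the physical pixel size.
#'
#' @param counts Numeric H×W×C array of nonnegative counts (C = number of
#'   channels); an H×W matrix is accepted for a single-channel stack.
#' @param grid A [channel_grid()] with `n_channels == dim(counts)[3]`.
#' @param pixel_size_nm Physical pixel edge length in nm (default 100, the
#'   typical high-zoom two-photon acquisition).
#' @return An object of class `lambda_stack`.
#' @export
lambda_stack <- function(counts, grid, pixel_size_nm = 100) {
  stopifnot(inherits(grid, "channel_grid"))
  if (is.matrix(counts)) counts <- array(counts, dim = c(dim(counts), 1L))
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`counts` must be an H x W x C array", call. = FALSE)
  }
  if (dim(counts)[3] != grid$n_channels) {
    stop(sprintf("stack has %d channel planes but grid declares %d channels",
                 dim(counts)[3], grid$n_channels), call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be positive", call. = FALSE)
  }
  structure(list(counts = counts, grid = grid,
                 pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "lambda_stack")
}

#' @export
print.lambda_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<lambda_stack> %d x %d px (%g nm/px), %d channels, total counts %.4g\n",
    d[1], d[2], x$pixel_size_nm, d[3], sum(x$counts)))
  invisible(x)
}

#' @export
dim.lambda_stack <- function(x) dim(x$counts)

# internal: flatten to channels x pixels matrix (pixels in column-major
# image order, i.e. pixel p = (row, col) with p = row + (col-1)*H)
stack_matrix <- function(stack) {
  d <- dim(stack$counts)
  t(matrix(stack$counts, nrow = d[1] * d[2], ncol = d[3]))
}

# internal: per-pixel channel sum as an H x W matrix
channel_sum <- function(stack) {
  d <- dim(stack$counts)
  matrix(rowSums(matrix(stack$counts, nrow = d[1] * d[2])), d[1], d[2])
}
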