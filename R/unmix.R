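#' Unmixing parameters
#'
#' Settings for the Poisson-likelihood spectral decomposition. The defaults
#' are the standard Poisson-NMF working settings for fixed-spectrum
#' decompositions of two-photon lambda stacks: ten iterations, background
#' threshold 50 counts (applied to the per-pixel channel sum), saturation
#' threshold 4000 counts (per channel), spectrum-update pixel stride
#' ("subsamples") 2, segregation bias 0, and a "minimal values" background
#' spectrum.
#'
#' @param n_iterations Number of multiplicative update sweeps (>= 1).
#' @param background_threshold Pixels whose channel sum is strictly below
#'   this are treated as background: excluded from fitting, abundances set
#'   to zero.
#' @param saturation_threshold A pixel with any channel at or above this is
#'   flagged saturated; saturated pixels are excluded from spectrum
#'   estimation (blind mode and the background spectrum) but still fitted.
#' @param subsample_stride In blind mode, spectrum updates use every
#'   `subsample_stride`-th usable pixel; abundance updates always use all
#'   non-background pixels.
#' @param segregation_bias Weight of an optional penalty on spatial overlap
#'   of normalized abundance maps (blind mode). The default 0 makes the
#'   term inert; the penalty's exact form is this package's own stand-in
#'   and only the zero setting is canonical.
#' @param background_spectrum `"minimal-values"` (per-channel minimum over
#'   non-saturated pixels, fitted as an extra fixed component and dropped
#'   from the output) or `"none"`.
#' @param seed Integer seed for blind-mode initialization.
#' @return An object of class `unmix_params`.
#' @export
unmix_params <- function(n_iterations = 10,
                         background_threshold = 50,
                         saturation_threshold = 4000,
                         subsample_stride = 2,
                         segregation_bias = 0,
                         background_spectrum = c("minimal-values", "none"),
                         seed = 1) {
  background_spectrum <- match.arg(background_spectrum)
  n_iterations <- as.integer(n_iterations)
  subsample_stride <- as.integer(subsample_stride)
  if (is.na(n_iterations) || n_iterations < 1L) {
    stop("`n_iterations` must be >= 1", call. = FALSE)
  }
  if (background_threshold < 0 || saturation_threshold < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  if (is.na(subsample_stride) || subsample_stride < 1L) {
    stop("`subsample_stride` must be >= 1", call. = FALSE)
  }
  if (segregation_bias < 0) {
    stop("`segregation_bias` must be >= 0", call. = FALSE)
  }
  structure(list(n_iterations = n_iterations,
                 background_threshold = as.numeric(background_threshold),
                 saturation_threshold = as.numeric(saturation_threshold),
                 subsample_stride = subsample_stride,
                 segregation_bias = as.numeric(segregation_bias),
                 background_spectrum = background_spectrum,
                 seed = as.integer(seed)),
            class = "unmix_params")
}

#' Generalized Kullback-Leibler divergence (Poisson deviance)
#'
#' `sum_i observed_i * log(observed_i / model_i) - observed_i + model_i`,
#' with the convention `0 * log(0) = 0`. This is the objective that the
#' multiplicative NMF updates minimize; it equals half the Poisson deviance
#' of the model, so minimizing it is maximum-likelihood estimation under
#' shot noise.
#'
#' @param observed Nonnegative numeric vector/array (counts).
#' @param model Numeric vector/array, positive wherever `observed > 0`.
#' @return A single nonnegative number.
#' @examples
#' kl_divergence(2, 1)  # 2*log(2) - 1
#' @export
kl_divergence <- function(observed, model) {
  observed <- as.numeric(observed); model <- as.numeric(model)
  if (length(observed) != length(model)) {
    stop("`observed` and `model` must have equal length", call. = FALSE)
  }
  if (any(observed < 0) || any(model < 0)) {
    stop("inputs must be nonnegative", call. = FALSE)
  }
  if (any(model == 0 & observed > 0)) {
    stop("model is zero where observed counts are positive", call. = FALSE)
  }
  pos <- observed > 0
  sum(observed[pos] * log(observed[pos] / model[pos])) - sum(observed) +
    sum(model)
}

#' Background and saturation masks
#'
#' Background: per-pixel channel sum strictly below
#' `background_threshold` (a pixel summing exactly to the threshold is not
#' background). Saturated: any channel at or above `saturation_threshold`.
#' The two flags are recorded independently.
#'
#' @param stack A [lambda_stack()].
#' @param params An [unmix_params()].
#' @return A list with logical H×W matrices `background` and `saturation`.
#' @export
pixel_masks <- function(stack, params = unmix_params()) {
  stopifnot(inherits(stack, "lambda_stack"), inherits(params, "unmix_params"))
  d <- dim(stack$counts)
  flat <- matrix(stack$counts, nrow = d[1] * d[2])
  bg <- matrix(rowSums(flat) < params$background_threshold, d[1], d[2])
  sat <- matrix(apply(flat, 1, max) >= params$saturation_threshold,
                d[1], d[2])
  list(background = bg, saturation = sat)
}

# internal: constructor for the abundance-map container
abundance_maps <- function(values, names, background_mask, saturation_mask,
                           grid, pixel_size_nm) {
  structure(list(values = values, names = names,
                 background_mask = background_mask,
                 saturation_mask = saturation_mask,
                 grid = grid, pixel_size_nm = pixel_size_nm),
            class = "abundance_maps")
}

#' @export
print.abundance_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<abundance_maps> %d x %d px, %d components (%s); %d background, %d saturated px\n",
    d[1], d[2], d[3], paste(x$names, collapse = ", "),
    sum(x$background_mask), sum(x$saturation_mask)))
  invisible(x)
}

# numerical guard inside logs and denominators of multiplicative updates
.kl_eps <- 1e-12

# internal: one multiplicative KL abundance update (S fixed)
# y, m: C x P; a: K x P; returns updated a
update_abundances <- function(a, s, y) {
  m <- s %*% a + .kl_eps
  a * (crossprod(s, y / m)) / (colSums(s) + .kl_eps)
}

# internal: minimal-values background spectrum (unit area), or NULL
minimal_background <- function(stack, masks, params) {
  if (params$background_spectrum != "minimal-values") return(NULL)
  d <- dim(stack$counts)
  flat <- matrix(stack$counts, nrow = d[1] * d[2])
  ok <- !as.vector(masks$saturation)
  if (!any(ok)) ok <- rep(TRUE, nrow(flat))
  b <- apply(flat[ok, , drop = FALSE], 2, min)
  if (all(b == 0)) NULL else b / sum(b)
}

#' Fixed-reference Poisson unmixing
#'
#' Decomposes every non-background pixel's spectrum into a nonnegative
#' combination of the reference spectra by minimizing the generalized
#' Kullback-Leibler divergence ([kl_divergence()]) between observed counts
#' and the linear model `S a` — the maximum-likelihood fit under Poisson
#' shot noise. Abundances are fitted by multiplicative KL updates with the
#' spectra held fixed; the objective is non-increasing across sweeps. When
#' `background_spectrum = "minimal-values"`, the per-channel minimum over
#' non-saturated pixels is fitted as one extra fixed component and dropped
#' from the output. Saturated pixels are flagged but still fitted.
#'
#' An abundance is the component's total (channel-summed) intensity at the
#' pixel, since reference spectra are unit-area.
#'
#' @param stack A [lambda_stack()].
#' @param refs A [reference_set()]; resampled onto the stack's grid if
#'   recorded on a different one.
#' @param params An [unmix_params()]; the default runs ten sweeps. Raise
#'   `n_iterations` (100-300) when abundances must be converged tightly.
#' @return An `abundance_maps` object: H×W×K nonnegative `values` (zero at
#'   background pixels), component `names`, the two masks, and the
#'   objective trace `objective` (one value per sweep, summed over fitted
#'   pixels).
#' @examples
#' g <- build_channel_grid(418, 584, 9.8)
#' refs <- reference_set(gaussian_emission(440, 45, g, "apolar"),
#'                       gaussian_emission(490, 50, g, "polar"))
#' sc <- make_mlv_scene(g, 3, refs, intensity_scale = 800, seed = 2)
#' noisy <- add_poisson_noise(sc$stack, seed = 3)
#' am <- unmix_fixed(noisy, refs, unmix_params(n_iterations = 50))
#' @export
unmix_fixed <- function(stack, refs, params = unmix_params()) {
  stopifnot(inherits(stack, "lambda_stack"), inherits(refs, "reference_set"),
            inherits(params, "unmix_params"))
  if (!same_grid(refs$grid, stack$grid)) {
    refs <- reference_set(lapply(refs$spectra, resample_spectrum,
                                 target = stack$grid))
  }
  s <- ref_matrix(refs)                       # C x K, unit-area columns
  d <- dim(stack$counts)
  k <- ncol(s)
  masks <- pixel_masks(stack, params)
  b <- minimal_background(stack, masks, params)
  if (!is.null(b)) s <- cbind(s, background = b)
  if (ncol(s) > nrow(s)) {
    stop(sprintf("%d components exceed the %d channels", ncol(s), nrow(s)),
         call. = FALSE)
  }
  fit <- !as.vector(masks$background)
  values <- array(0, dim = c(d[1], d[2], k))
  obj <- numeric(0)
  if (!any(fit)) {
    warning("all pixels fall below the background threshold; ",
            "returning all-zero abundance maps")
  } else {
    y <- stack_matrix(stack)[, fit, drop = FALSE]  # C x P
    a <- matrix(rep(colSums(y) / ncol(s), each = ncol(s)),
                nrow = ncol(s))                    # equal split start
    obj <- numeric(params$n_iterations)
    for (it in seq_len(params$n_iterations)) {
      a <- update_abundances(a, s, y)
      obj[it] <- kl_divergence(y, s %*% a + .kl_eps)
    }
    flat <- matrix(0, nrow = d[1] * d[2], ncol = k)
    flat[fit, ] <- t(a[seq_len(k), , drop = FALSE])
    values <- array(flat, dim = c(d[1], d[2], k))
  }
  out <- abundance_maps(values, refs$names, masks$background,
                        masks$saturation, stack$grid, stack$pixel_size_nm)
  out$objective <- obj
  out
}

#' Blind Poisson NMF unmixing
#'
#' Joint estimation of component spectra and abundances by alternating
#' multiplicative KL updates — spectral decomposition without knowing the
#' spectra in advance. Each sweep first updates the spectra using every
#' `subsample_stride`-th usable (non-background, non-saturated) pixel, then
#' renormalizes them to unit area (pushing the scale into the abundances),
#' then updates the abundances over all non-background pixels. Spectra are
#' initialized from lightly smoothed spectra of randomly chosen usable
#' pixels (seeded), abundances uniformly; identical inputs and seed give
#' bit-identical output. Components are reported in discovered order —
#' blind NMF is identifiable only up to permutation.
#'
#' @param stack A [lambda_stack()].
#' @param n_components Number of components to recover (1 to the channel
#'   count).
#' @param params An [unmix_params()]; `seed` controls initialization and
#'   `segregation_bias` adds the optional overlap penalty.
#' @return A list: `refs` (the recovered [reference_set()], unit-area),
#'   `maps` (an `abundance_maps`), and `objective` (KL objective per sweep
#'   over the fitted pixels).
#' @export
unmix_blind <- function(stack, n_components, params = unmix_params()) {
  stopifnot(inherits(stack, "lambda_stack"), inherits(params, "unmix_params"))
  d <- dim(stack$counts)
  k <- as.integer(n_components)
  if (is.na(k) || k < 1L || k > d[3]) {
    stop("`n_components` must be between 1 and the channel count",
         call. = FALSE)
  }
  masks <- pixel_masks(stack, params)
  fit <- !as.vector(masks$background)
  usable <- fit & !as.vector(masks$saturation)
  if (sum(usable) < k) {
    stop("fewer usable pixels than components", call. = FALSE)
  }
  yall <- stack_matrix(stack)
  y <- yall[, fit, drop = FALSE]
  sub_idx <- seq(1, ncol(y), by = params$subsample_stride)
  sub_idx <- sub_idx[usable[fit][sub_idx]]
  if (length(sub_idx) < k) sub_idx <- which(usable[fit])
  beta <- params$segregation_bias

  s <- with_rng(params$seed, {
    seeds <- sample(which(usable), k)
    m <- yall[, seeds, drop = FALSE]
    # light 3-channel moving-average smoothing, then unit area
    sm <- apply(m, 2, function(v) {
      n <- length(v)
      (v + c(v[1], v[-n]) + c(v[-1], v[n])) / 3
    })
    sm <- sm + .kl_eps
    sweep(sm, 2, colSums(sm), "/")
  })
  a <- matrix(rep(colSums(y) / k, each = k), nrow = k)
  obj <- numeric(params$n_iterations)
  for (it in seq_len(params$n_iterations)) {
    # spectrum half-step on the pixel subsample
    ys <- y[, sub_idx, drop = FALSE]
    as_ <- a[, sub_idx, drop = FALSE]
    m <- s %*% as_ + .kl_eps
    s <- s * ((ys / m) %*% t(as_)) /
      (matrix(rowSums(as_), nrow(s), k, byrow = TRUE) + .kl_eps)
    scale <- colSums(s) + .kl_eps
    s <- sweep(s, 2, scale, "/")
    a <- a * scale
    # abundance half-step on all fitted pixels
    m <- s %*% a + .kl_eps
    num <- crossprod(s, y / m)
    den <- colSums(s) + .kl_eps              # length k, recycled per row
    if (beta > 0) {
      tot <- rowSums(a) + .kl_eps            # per-map totals, length k
      ahat <- a / tot
      overlap_grad <- (matrix(colSums(ahat), k, ncol(a), byrow = TRUE) -
                         ahat) / tot
      a <- a * num / (matrix(den, k, ncol(a)) + beta * overlap_grad)
    } else {
      a <- a * num / den
    }
    obj[it] <- kl_divergence(y, s %*% a + .kl_eps)
  }
  flat <- matrix(0, nrow = d[1] * d[2], ncol = k)
  flat[fit, ] <- t(a)
  values <- array(flat, dim = c(d[1], d[2], k))
  nms <- paste0("component_", seq_len(k))
  refs <- reference_set(lapply(seq_len(k), function(j) {
    emission_spectrum(stack$grid, pmax(s[, j], 0) + .kl_eps, nms[j])
  }))
  maps <- abundance_maps(values, nms, masks$background, masks$saturation,
                         stack$grid, stack$pixel_size_nm)
  list(refs = refs, maps = maps, objective = obj)
}
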