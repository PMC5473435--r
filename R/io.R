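#' @title Readers, writers and the run manifest
#' @description Lambda stacks travel as multi-page TIFF (channel-major
#'   pages, 16-bit unsigned counts) with a plain-text YAML sidecar holding
#'   the channel grid and pixel size; float maps are 32-bit float TIFF;
#'   RGB renderings are PNG; spectra and tables are CSV. Every pipeline
#'   run emits a YAML manifest recording version, parameters, seeds and
#'   input digests so outputs are re-derivable.
#' @name cli_io
NULL

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".grid.yaml")

# 16-bit TIFF stores values / 65535; counts above that cannot round-trip
.tiff_max <- 65535

#' Write a lambda stack as multi-page TIFF plus sidecar
#'
#' Pages are channel-major (page i = channel i), 16-bit unsigned. The
#' channel grid and pixel size go into an ImageJ-style TIFF description
#' and a YAML sidecar `<stem>.grid.yaml`.
#'
#' @param stack A [lambda_stack()]; counts must not exceed 65535.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_lambda_stack <- function(stack, path) {
  stopifnot(inherits(stack, "lambda_stack"))
  counts <- round(stack$counts)
  if (max(counts) > .tiff_max) {
    stop("counts exceed the 16-bit TIFF range", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(counts)[3]),
                  function(c) counts[, , c] / .tiff_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(start_nm = stack$grid$start_nm,
                        step_nm = stack$grid$step_nm,
                        n_channels = stack$grid$n_channels,
                        pixel_size_nm = stack$pixel_size_nm),
                   sidecar_path(path))
  invisible(path)
}

#' Read a lambda stack from multi-page TIFF
#'
#' The channel grid is resolved with precedence: explicit
#' `grid_override` > YAML sidecar (`<stem>.grid.yaml`). A declared channel
#' count that disagrees with the page count is a format error; a stack
#' with no grid from either source is a configuration error.
#'
#' @param path `.tif` path.
#' @param grid_override Optional [channel_grid()] taking precedence over
#'   file metadata.
#' @param pixel_size_nm Optional override of the pixel size (nm).
#' @return A [lambda_stack()].
#' @export
read_lambda_stack <- function(path, grid_override = NULL,
                              pixel_size_nm = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  counts <- array(0, dim = c(h, w, n))
  for (i in seq_len(n)) counts[, , i] <- round(pages[[i]] * .tiff_max)

  grid <- grid_override
  px <- pixel_size_nm
  if (is.null(grid)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- yaml::read_yaml(sc)
      if (!is.null(meta$n_channels) && meta$n_channels != n) {
        stop(sprintf(
          "format error: sidecar declares %d channels but TIFF has %d pages",
          meta$n_channels, n), call. = FALSE)
      }
      grid <- channel_grid(meta$start_nm, meta$step_nm, n)
      px <- px %||% meta$pixel_size_nm
    }
  } else if (grid$n_channels != n) {
    stop(sprintf(
      "format error: override grid declares %d channels but TIFF has %d pages",
      grid$n_channels, n), call. = FALSE)
  }
  if (is.null(grid)) {
    stop("configuration error: no channel grid from override or sidecar",
         call. = FALSE)
  }
  lambda_stack(counts, grid, px %||% 100)
}

#' Write a float image (or multi-component map stack) as 32-bit float TIFF
#'
#' TIFF float samples are stored affinely rescaled to \[0, 1\] (the range
#' the TIFF writer accepts), with the offset and scale recorded in a YAML
#' sidecar `<stem>.scale.yaml`; `NA` pixels are stored as extra mask pages
#' after the value pages. [read_float_map()] inverts the encoding, so
#' round-trips preserve values to 32-bit float precision and keep `NA`
#' exactly.
#'
#' @param values H×W matrix or H×W×K array (any finite values, `NA`
#'   allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_float_map <- function(values, path) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  k <- dim(values)[3]
  finite <- values[is.finite(values)]
  offset <- if (length(finite)) min(finite) else 0
  scale <- if (length(finite)) max(finite) - offset else 1
  if (scale == 0) scale <- 1
  pages <- vector("list", 2L * k)
  for (i in seq_len(k)) {
    m <- values[, , i]
    na <- !is.finite(m)
    m[na] <- offset
    pages[[i]] <- (m - offset) / scale
    pages[[k + i]] <- na * 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(offset = offset, scale = scale,
                        n_value_pages = k), scale_sidecar_path(path))
  invisible(path)
}

scale_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".scale.yaml")
}

#' Read a float TIFF written by [write_float_map()]
#' @param path Input path.
#' @return H×W matrix (single value page) or H×W×K array, with `NA`
#'   restored from the mask pages.
#' @export
read_float_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- scale_sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("missing scale sidecar %s", sc), call. = FALSE)
  }
  meta <- yaml::read_yaml(sc)
  k <- meta$n_value_pages
  if (length(pages) != 2L * k) {
    stop("float TIFF page count disagrees with its scale sidecar",
         call. = FALSE)
  }
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), k))
  for (i in seq_len(k)) {
    m <- pages[[i]] * meta$scale + meta$offset
    m[pages[[k + i]] > 0.5] <- NA_real_
    arr[, , i] <- m
  }
  if (k == 1L) arr[, , 1] else arr
}

#' Write reference spectra as CSV
#'
#' Dialect: header `wavelength_nm,<name1>,<name2>,...`, one row per
#' channel centre, '.' decimal separator, UTF-8.
#'
#' @param refs A [reference_set()] (or single [emission_spectrum()]).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(refs, path) {
  if (inherits(refs, "emission_spectrum")) refs <- reference_set(refs)
  stopifnot(inherits(refs, "reference_set"))
  df <- data.frame(wavelength_nm = channel_centers(refs$grid))
  for (s in refs$spectra) df[[s$name]] <- s$values
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read reference spectra from CSV
#'
#' Expects the [write_spectra_csv()] dialect. The channel grid is inferred
#' from the wavelength column (centres, constant step), or supplied.
#'
#' @param path Input `.csv` path.
#' @param grid Optional [channel_grid()]; must match the row count.
#' @return A [reference_set()].
#' @export
read_spectra_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"wavelength_nm" %in% names(df) || ncol(df) < 2) {
    stop("spectrum CSV needs a wavelength_nm column plus components",
         call. = FALSE)
  }
  wl <- df$wavelength_nm
  if (is.null(grid)) {
    if (length(wl) < 2) stop("cannot infer a grid from one row",
                             call. = FALSE)
    step <- diff(wl)
    if (max(abs(step - step[1])) > 1e-6 * step[1]) {
      stop("wavelength column is not evenly spaced; pass `grid`",
           call. = FALSE)
    }
    grid <- channel_grid(wl[1] - step[1] / 2, step[1], length(wl))
  } else if (grid$n_channels != length(wl)) {
    stop("grid channel count does not match the CSV rows", call. = FALSE)
  }
  comp <- setdiff(names(df), "wavelength_nm")
  reference_set(lapply(comp, function(nm) {
    emission_spectrum(grid, df[[nm]], nm)
  }))
}

#' Write an RGB array as PNG
#' @param img H×W×3 array in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a discrete LUT from a plain-text file
#'
#' One line per colour, `R,G,B,width` with R,G,B in 0-255 and a positive
#' integer relative bin width; `#` comments and blank lines are ignored.
#'
#' @param path LUT file path.
#' @return A [discrete_lut()].
#' @export
read_lut_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty LUT file", call. = FALSE)
  m <- do.call(rbind, lapply(lines, function(l) {
    v <- as.numeric(strsplit(l, ",")[[1]])
    if (length(v) != 4 || any(is.na(v))) {
      stop(sprintf("bad LUT line: '%s' (want R,G,B,width)", l),
           call. = FALSE)
    }
    v
  }))
  discrete_lut(m[, 1:3, drop = FALSE] / 255, m[, 4])
}

#' Read a polygon gate from JSON
#'
#' Schema: `{"name": "...", "vertices": [[i1, i2], ...]}` with intensities
#' in unmixed-component units.
#'
#' @param path JSON file path.
#' @return A [gate_polygon()].
#' @export
read_gate_file <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(g$vertices)) stop("gate JSON needs a 'vertices' field",
                                call. = FALSE)
  gate_polygon(g$vertices, g$name %||% "gate")
}

#' Build a run manifest
#'
#' Records tool version, the command/stage, all parameters, seeds, digests
#' of input files and a timestamp, so any output can be re-derived from
#' (inputs, manifest). Timestamps are informational; everything else is
#' deterministic.
#'
#' @param command Stage or subcommand name.
#' @param params Named list of parameters (must be YAML-serializable).
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param seed Integer seed(s) used.
#' @return A named list (class `run_manifest`).
#' @export
run_manifest <- function(command, params = list(), inputs = character(),
                         seed = NULL) {
  digests <- if (length(inputs)) {
    ex <- file.exists(inputs)
    d <- rep(NA_character_, length(inputs))
    d[ex] <- unname(tools::md5sum(inputs[ex]))
    stats::setNames(as.list(d), inputs)
  } else NULL
  structure(list(
    tool = "lambdamap",
    version = as.character(utils::packageVersion("lambdamap")),
    command = command,
    parameters = params,
    seed = seed,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a bundle of pipeline outputs to a directory
#'
#' Deterministic file naming: abundance maps `abundances.tif` (float,
#' channel-major components), masks `background_mask.png` /
#' `saturation_mask.png`, fraction map `fraction_map.tif`, rendering
#' `fraction_rgb.png`, spectra `spectra.csv`, 2D histogram
#' `histogram2d.csv`, and always `manifest.yaml`.
#'
#' @param out_dir Output directory (created if needed).
#' @param manifest A [run_manifest()].
#' @param maps Optional `abundance_maps`.
#' @param fmap Optional [fraction_map()].
#' @param rgb Optional H×W×3 rendering.
#' @param refs Optional [reference_set()].
#' @param hist2d Optional `intensity_histogram`.
#' @param gate_mask Optional logical gate-membership matrix.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(out_dir, manifest, maps = NULL, fmap = NULL,
                          rgb = NULL, refs = NULL, hist2d = NULL,
                          gate_mask = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory %s", out_dir),
         call. = FALSE)
  }
  written <- character()
  put <- function(name) file.path(out_dir, name)
  if (!is.null(maps)) {
    write_float_map(maps$values, put("abundances.tif"))
    png::writePNG(maps$background_mask * 1, put("background_mask.png"))
    png::writePNG(maps$saturation_mask * 1, put("saturation_mask.png"))
    written <- c(written, put(c("abundances.tif", "background_mask.png",
                                "saturation_mask.png")))
  }
  if (!is.null(fmap)) {
    write_float_map(fmap$fraction, put("fraction_map.tif"))
    written <- c(written, put("fraction_map.tif"))
  }
  if (!is.null(rgb)) {
    write_rgb_png(rgb, put("fraction_rgb.png"))
    written <- c(written, put("fraction_rgb.png"))
  }
  if (!is.null(refs)) {
    write_spectra_csv(refs, put("spectra.csv"))
    written <- c(written, put("spectra.csv"))
  }
  if (!is.null(hist2d)) {
    df <- data.frame(
      bin1 = rep(seq_len(nrow(hist2d$counts)), ncol(hist2d$counts)),
      bin2 = rep(seq_len(ncol(hist2d$counts)),
                 each = nrow(hist2d$counts)),
      count = as.integer(hist2d$counts))
    utils::write.csv(df, put("histogram2d.csv"), row.names = FALSE)
    written <- c(written, put("histogram2d.csv"))
  }
  if (!is.null(gate_mask)) {
    png::writePNG(gate_mask * 1, put("gate_mask.png"))
    written <- c(written, put("gate_mask.png"))
  }
  yaml::write_yaml(unclass(manifest), put("manifest.yaml"))
  written <- c(written, put("manifest.yaml"))
  invisible(written)
}
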