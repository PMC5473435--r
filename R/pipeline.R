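#' Default Gaussian two-state reference pair
#'
#' The built-in model basis for laurdan-family probes: a unit-area
#' Gaussian peaked at 440 nm (apolar, ordered) and one at 490 nm (polar,
#' water-exposed), in that order.
#'
#' @param grid A [channel_grid()].
#' @param apolar_peak_nm,polar_peak_nm Peak wavelengths (nm).
#' @param apolar_fwhm_nm,polar_fwhm_nm Band widths (nm). Polar emission is
#'   modelled slightly broader, as relaxed-state emission is.
#' @return A two-component [reference_set()] (apolar first).
#' @export
two_state_refs <- function(grid, apolar_peak_nm = 440, polar_peak_nm = 490,
                           apolar_fwhm_nm = 45, polar_fwhm_nm = 55) {
  reference_set(
    gaussian_emission(apolar_peak_nm, apolar_fwhm_nm, grid, "apolar"),
    gaussian_emission(polar_peak_nm, polar_fwhm_nm, grid, "polar"))
}

# internal: run expr, rethrowing any error tagged with the stage name
pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# internal: channel grid from a config block
grid_from_config <- function(g) {
  if (is.null(g)) return(build_channel_grid(418, 584, 9.8))
  if (!is.null(g$end_nm)) {
    build_channel_grid(g$start_nm, g$end_nm, g$step_nm)
  } else {
    channel_grid(g$start_nm, g$step_nm, g$n_channels)
  }
}

#' Run the full decomposition pipeline from a configuration
#'
#' Chains the stages: synthetic-scene generation (optional) or stack
#' reading, spectral unmixing (fixed or blind), fraction mapping with
#' colour rendering and the 2D intensity histogram, optional gating, and
#' output writing with a run manifest. Any stage failure aborts with the
#' stage name in the error message; configuration problems are caught
#' before any computation.
#'
#' @param config A named list or path to a YAML file. Recognized blocks:
#'   \describe{
#'     \item{`seed`}{Master integer seed (default 1); scene noise and
#'       blind-mode initialization derive from it.}
#'     \item{`out_dir`}{Output directory; omit to skip writing files.}
#'     \item{`stack`}{Path to a lambda-stack TIFF (alternative to
#'       `synth`).}
#'     \item{`synth`}{`kind` (`"cell"`, `"mlv"`, `"two_dye"`), `size`,
#'       `grid` (`start_nm`/`end_nm`/`step_nm` or
#'       `start_nm`/`step_nm`/`n_channels`), `noise` (logical,
#'       default TRUE), plus the kind's generator arguments.}
#'     \item{`refs_csv`}{Reference-spectra CSV for fixed-mode unmixing of
#'       a read stack; synthetic runs default to the scene's own basis.}
#'     \item{`unmix`}{`mode` (`"fixed"` or `"blind"`), `components`
#'       (blind), `iterations`, `background_threshold`,
#'       `saturation_threshold`, `subsample_stride`, `segregation_bias`,
#'       `background_spectrum`.}
#'     \item{`fraction`}{`lut` (path to a LUT file; default the built-in
#'       six-colour LUT), `ceiling` (number or `"auto"`),
#'       `histogram_bins`, `histogram_scale`.}
#'     \item{`gate`}{Path to a gate JSON to project back into the image.}
#'   }
#' @return A list with `stack`, `phantom` (synthetic runs), `refs`,
#'   `maps`, `fmap` (two-component runs), `rgb`, `hist2d`, `gate_result`,
#'   `manifest`, and `files` (paths written, if `out_dir` was set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  seed <- as.integer(config$seed %||% 1)

  # -- validation before any compute
  pipeline_stage("config", {
    if (is.null(config$stack) && is.null(config$synth)) {
      stop("need either `stack` (a TIFF path) or a `synth` block")
    }
    if (!is.null(config$stack) && !file.exists(config$stack)) {
      stop(sprintf("stack file not found: %s", config$stack))
    }
    mode <- config$unmix$mode %||% "fixed"
    if (!mode %in% c("fixed", "blind")) {
      stop(sprintf("unknown unmix mode '%s'", mode))
    }
    if (mode == "fixed" && !is.null(config$stack) &&
        is.null(config$refs_csv)) {
      stop("fixed-mode unmixing of a read stack needs `refs_csv`")
    }
    if (mode == "blind" && is.null(config$unmix$components)) {
      stop("blind mode needs `unmix$components`")
    }
    if (!is.null(config$refs_csv) && !file.exists(config$refs_csv)) {
      stop(sprintf("reference CSV not found: %s", config$refs_csv))
    }
    if (!is.null(config$gate) && !file.exists(config$gate)) {
      stop(sprintf("gate file not found: %s", config$gate))
    }
  })

  phantom <- NULL
  scene_refs <- NULL
  stack <- pipeline_stage("input", {
    if (!is.null(config$synth)) {
      sy <- config$synth
      grid <- grid_from_config(sy$grid)
      kind <- sy$kind %||% "cell"
      scene <- switch(kind,
        cell = {
          scene_refs <- two_state_refs(grid)
          make_cell_scene(
            grid, scene_refs,
            size = sy$size %||% 512,
            pm_apolar_fraction = sy$pm_apolar_fraction %||% 0.75,
            cytoplasm_apolar_fraction =
              sy$cytoplasm_apolar_fraction %||% 0.3,
            droplet_apolar_fraction =
              sy$droplet_apolar_fraction %||% 0.95,
            n_droplets = sy$n_droplets %||% 6,
            seed = seed)
        },
        mlv = {
          scene_refs <- two_state_refs(grid)
          make_mlv_scene(grid, sy$n_vesicles %||% 4, scene_refs,
                         intensity_scale = sy$intensity_scale %||% 1000,
                         size = sy$size %||% 128, seed = seed)
        },
        two_dye = {
          scene_refs <- reference_set(
            gaussian_emission(440, 45, grid, "dye1_apolar"),
            gaussian_emission(490, 55, grid, "dye1_polar"),
            gaussian_emission(590, 45, grid, "dye2_apolar"),
            gaussian_emission(630, 55, grid, "dye2_polar"))
          make_two_dye_scene(grid, scene_refs, seed = seed,
                             size = sy$size %||% 128)
        },
        stop(sprintf("unknown synth kind '%s'", kind))
      )
      phantom <- scene$phantom
      if (isTRUE(sy$noise %||% TRUE)) {
        add_poisson_noise(scene$stack, seed = seed + 1L)
      } else {
        scene$stack
      }
    } else {
      read_lambda_stack(config$stack)
    }
  })

  params <- pipeline_stage("unmix", {
    u <- config$unmix %||% list()
    unmix_params(
      n_iterations = u$iterations %||% 10,
      background_threshold = u$background_threshold %||% 50,
      saturation_threshold = u$saturation_threshold %||% 4000,
      subsample_stride = u$subsample_stride %||% 2,
      segregation_bias = u$segregation_bias %||% 0,
      background_spectrum = u$background_spectrum %||% "minimal-values",
      seed = seed)
  })
  mode <- config$unmix$mode %||% "fixed"
  refs <- maps <- NULL
  pipeline_stage("unmix", {
    if (mode == "fixed") {
      refs <- if (!is.null(config$refs_csv)) {
        read_spectra_csv(config$refs_csv)
      } else scene_refs
      maps <- unmix_fixed(stack, refs, params)
    } else {
      res <- unmix_blind(stack, config$unmix$components, params)
      refs <- res$refs
      maps <- res$maps
    }
  })

  fmap <- rgb_img <- hist2d <- gate_result <- NULL
  if (dim(maps$values)[3] == 2L) {
    pipeline_stage("fraction_mapper", {
      fr <- config$fraction %||% list()
      lut <- if (!is.null(fr$lut)) read_lut_file(fr$lut) else
        lut_six_colour()
      fmap <- fraction_map(maps)
      rgb_img <- colorize_fraction(fmap, lut, fr$ceiling %||% "auto")
      hist2d <- intensity_histogram_2d(
        maps, n_bins = fr$histogram_bins %||% 64,
        scale = fr$histogram_scale %||% "linear")
      if (!is.null(config$gate)) {
        gate_result <- gate_to_image(maps, read_gate_file(config$gate),
                                      fmap, lut, fr$ceiling %||% "auto")
      }
    })
  }

  manifest <- run_manifest(
    command = "pipeline",
    params = config[setdiff(names(config), "out_dir")],
    inputs = c(config$stack, config$refs_csv, config$gate,
               config$fraction$lut),
    seed = seed)

  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- pipeline_stage("write", {
      write_outputs(config$out_dir, manifest, maps = maps, fmap = fmap,
                    rgb = rgb_img, refs = refs, hist2d = hist2d,
                    gate_mask = gate_result$mask)
    })
  }
  list(stack = stack, phantom = phantom, refs = refs, maps = maps,
       fmap = fmap, rgb = rgb_img, hist2d = hist2d,
       gate_result = gate_result, manifest = manifest, files = files)
}
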