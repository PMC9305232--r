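#' Pipeline configuration
#'
#' Bundles every tunable of the quantification chain — binarization,
#' cleaning, box-counting and ROI extraction — into one validated object
#' that round-trips losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]). All defaults match the individual
#' functions' documented defaults.
#'
#' @param binarize_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity cutoff for `binarize_method = "fixed"`.
#' @param invert dark-hyphae-on-bright polarity flag.
#' @param min_cluster_px,connectivity,smoothing_radius_px see
#'   [clean_mask()].
#' @param grid_sizes_px,anchor see [box_count()].
#' @param source raster for box counting: `"skeleton"` or `"clean_mask"`.
#' @param roi_side_px ROI side; `NULL` processes each image whole.
#' @param rng_seed seed used by synthetic presets.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(binarize_method = "otsu",
                            fixed_threshold = NULL,
                            invert = FALSE,
                            min_cluster_px = 20L,
                            connectivity = 8L,
                            smoothing_radius_px = 0L,
                            grid_sizes_px = c(8L, 16L, 32L, 64L),
                            anchor = "topleft",
                            source = "skeleton",
                            roi_side_px = NULL,
                            rng_seed = 1L) {
  cfg <- list(binarize_method = match.arg(binarize_method, c("otsu", "fixed")),
              fixed_threshold = fixed_threshold,
              invert = isTRUE(invert),
              min_cluster_px = as.integer(min_cluster_px),
              connectivity = as.integer(connectivity),
              smoothing_radius_px = as.integer(smoothing_radius_px),
              grid_sizes_px = as.integer(grid_sizes_px),
              anchor = match.arg(anchor, c("topleft", "topright",
                                           "bottomleft", "bottomright")),
              source = match.arg(source, c("skeleton", "clean_mask")),
              roi_side_px = if (is.null(roi_side_px)) NULL
                            else as.integer(roi_side_px),
              rng_seed = as.integer(rng_seed))
  if (!cfg$connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  if (cfg$min_cluster_px < 1L) stop("`min_cluster_px` must be >= 1")
  if (cfg$smoothing_radius_px < 0L) stop("`smoothing_radius_px` must be >= 0")
  if (!length(cfg$grid_sizes_px) || any(cfg$grid_sizes_px < 1L))
    stop("`grid_sizes_px` must be positive integers")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

pkg_version <- function() as.character(utils::packageVersion("myconet"))

# Resolve the `images` argument of run_architecture_pipeline into a named
# list of network_image objects.
resolve_images <- function(images, cfg) {
  if (is.character(images) && length(images) == 1L &&
      images %in% c("fixtures", "gradient", "gradient_up", "gradient_down")) {
    preset <- images
    if (preset == "fixtures") {
      fx <- list(make_fixture("filled_square", 640L),
                 make_fixture("hline", 640L),
                 make_fixture("single_pixel", 640L),
                 make_fixture("sierpinski_carpet", 729L))
      imgs <- lapply(fx, function(f)
        network_image(f$image, provenance = paste0("fixture:", f$name)))
      names(imgs) <- vapply(fx, `[[`, "", "name")
      return(imgs)
    }
    fr <- if (preset == "gradient_down") c(0.08, 0.06, 0.04)
          else c(0.04, 0.06, 0.08)
    prm <- synthetic_network_params(rng_seed = cfg$rng_seed)
    imgs <- generate_gradient_series(prm, 3L, fr)
    names(imgs) <- sprintf("%s_loc%d", preset, seq_along(imgs))
    return(imgs)
  }
  if (is.character(images)) {
    out <- list(); errs <- character(0)
    for (pth in images) {
      img <- tryCatch(read_network_image(pth), error = function(e) e)
      if (inherits(img, "error")) {
        errs <- c(errs, conditionMessage(img))
        message("skipping unreadable image: ", pth)
      } else out[[pth]] <- img
    }
    attr(out, "errors") <- errs
    return(out)
  }
  if (inherits(images, "network_image")) images <- list(images)
  if (is.null(names(images)))
    names(images) <- sprintf("image%02d", seq_along(images))
  images
}

#' Run the architecture quantification pipeline
#'
#' End-to-end chain for each input image: binarize, clean (closing +
#' small-cluster removal), skeletonize, box-count and fit the mass fractal
#' dimension, and measure surface density — one tidy row per (image, ROI).
#' When `cfg$roi_side_px` is set and an image is larger, non-overlapping
#' ROIs of that side are tiled left-to-right across the image (the
#' barrier-to-centre axis); otherwise the whole image is one ROI.
#'
#' @param images character vector of PNG/TIFF paths, a list of
#'   [network_image]s, or a synthetic preset: `"fixtures"`,
#'   `"gradient"`/`"gradient_up"`, `"gradient_down"`.
#' @param cfg a [pipeline_config()].
#' @return data.frame with one row per (image, ROI): `image`, `roi_label`,
#'   `D_m`, `r_squared`, `coverage_frac`, `coverage_percent`, one `N_s<g>`
#'   column per grid size, `config_hash`, `version`. Deterministic given
#'   config and inputs.
#' @export
run_architecture_pipeline <- function(images, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  imgs <- resolve_images(images, cfg)
  if (!length(imgs))
    stop("no readable input images")
  hash <- config_hash(cfg)
  ver <- pkg_version()
  rows <- list()
  for (nm in names(imgs)) {
    img <- imgs[[nm]]
    rois <- list(img)
    labs <- 1L
    if (!is.null(cfg$roi_side_px)) {
      d <- dim(img$pixels)
      n_fit <- d[2] %/% cfg$roi_side_px
      if (d[1] >= cfg$roi_side_px && n_fit >= 1L) {
        specs <- lapply(seq_len(n_fit), function(i)
          roi_spec(c(0L, (i - 1L) * cfg$roi_side_px),
                   cfg$roi_side_px, label = i))
        rois <- extract_rois(img, specs)
        labs <- seq_len(n_fit)
      }
    }
    for (k in seq_along(rois)) {
      bin <- binarize(rois[[k]], method = cfg$binarize_method,
                      fixed_threshold = cfg$fixed_threshold,
                      invert = cfg$invert)
      cln <- clean_mask(bin, min_cluster_px = cfg$min_cluster_px,
                        connectivity = cfg$connectivity,
                        smoothing_radius_px = cfg$smoothing_radius_px)
      counted <- if (cfg$source == "skeleton") skeletonize(cln)$pixels
                 else cln$pixels
      curve <- box_count(counted, cfg$grid_sizes_px, anchor = cfg$anchor)
      est <- estimate_dimension(curve)
      dens <- surface_density(cln$pixels)
      row <- data.frame(image = nm, roi_label = labs[k],
                        D_m = est$D_m, r_squared = est$r_squared,
                        coverage_frac = dens$coverage_frac,
                        coverage_percent = dens$coverage_percent)
      for (j in seq_along(curve$grid_sizes_px))
        row[[paste0("N_s", curve$grid_sizes_px[j])]] <-
          curve$occupied_counts[j]
      row$config_hash <- hash
      row$version <- ver
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the assay pipeline: calibration plus transfer efficiency
#'
#' Fits per-strain copy-number-to-biomass calibrations from a calibration
#' table, then computes per-replicate quantum-dot transfer efficiency.
#' The assay table may carry biomass directly
#' (`biomass_focal_comp_mg`, `biomass_focal_in_central_mg`) or raw qPCR
#' copy numbers (`copies_focal_comp`, `copies_focal_in_central` plus a
#' `strain` column), which are converted through the fitted calibration.
#' When the focal strain cannot be distinguished from its partner by qPCR
#' (genetically near-identical strains), all central-compartment biomass is
#' attributed to the focal strain; this default attribution is logged
#' prominently.
#'
#' @param calibration data.frame or CSV path with `strain`, `copy_number`,
#'   `biomass_mg`.
#' @param assay data.frame or CSV path; see Details for accepted schemas.
#' @param through_origin force zero-intercept calibrations.
#' @return list of class `assay_result`: `$calibration`
#'   (`calibration_models` table), `$efficiency` (per-replicate table),
#'   `$excluded`, `$config_hash`, `$version`.
#' @export
run_assay_pipeline <- function(calibration, assay, through_origin = FALSE) {
  if (is.character(calibration))
    calibration <- utils::read.csv(calibration, stringsAsFactors = FALSE)
  if (is.character(assay))
    assay <- utils::read.csv(assay, stringsAsFactors = FALSE)
  models <- fit_calibration(calibration, through_origin = through_origin)
  has_biomass <- all(c("biomass_focal_comp_mg", "biomass_focal_in_central_mg")
                     %in% names(assay))
  if (!has_biomass) {
    need <- c("strain", "copies_focal_comp", "copies_focal_in_central")
    miss <- setdiff(need, names(assay))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "),
           " (supply biomass columns or raw copy-number columns)")
    message("attributing all central-compartment biomass to the focal strain",
            " (qPCR-indistinguishable strains)")
    conv <- function(strain, copies) {
      m <- models[models$strain == strain, , drop = FALSE]
      if (nrow(m) != 1L)
        stop("no calibration model for strain '", strain, "'")
      as.numeric(copies_to_biomass(m, copies))
    }
    assay$biomass_focal_comp_mg <- mapply(conv, assay$strain,
                                          assay$copies_focal_comp)
    assay$biomass_focal_in_central_mg <- mapply(conv, assay$strain,
                                                assay$copies_focal_in_central)
  }
  eff <- transfer_efficiency(assay)
  structure(list(calibration = models,
                 efficiency = eff$table,
                 excluded = eff$excluded,
                 config_hash = rlang::hash(list(through_origin = through_origin)),
                 version = pkg_version()),
            class = "assay_result")
}

#' Write a results table as CSV with a provenance header
#'
#' @param tab data.frame from a pipeline run.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
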