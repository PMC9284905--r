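# Synthetic DXA abdominal phantoms with analytically known fat layout.

#' Phantom configuration
#'
#' Describes an abdominal cross-section modelled as an ellipse (transverse
#' diameter `width`, anteroposterior `sagittal`) wrapped by a subcutaneous fat
#' layer (SFL) whose inner boundary is the concentric ellipse with both
#' semi-axes reduced by `sfl_thickness`. Tissue in each compartment is a
#' homogeneous fat/lean mixture: `sfl_fat_fraction` and
#' `visceral_fat_fraction` are volume fractions of fat. The scan is
#' projectional, so a pixel's mass is the tissue volume in the vertical slab
#' behind it times density; all truth quantities have closed forms.
#'
#' @param width Transverse (left-right) external diameter, cm.
#' @param sagittal Anteroposterior external diameter, cm.
#' @param sfl_thickness Subcutaneous fat layer thickness, cm. Must be smaller
#'   than half of both diameters.
#' @param sfl_fat_fraction,visceral_fat_fraction Fat volume fraction of the
#'   subcutaneous annulus and of the visceral interior, each in `[0, 1]`.
#' @param roi_height Height of the abdominal region of interest along the body
#'   axis, cm; snapped to a whole number of pixel rows.
#' @param pixel_width,pixel_height Pixel dimensions, cm.
#' @param fat_density,lean_density Tissue densities, g/cm^3. Defaults are
#'   standard soft-tissue values (fat 0.90, lean 1.05).
#' @param seed Integer seed kept with the configuration. The phantom itself is
#'   deterministic; the seed is recorded so that fixture manifests are
#'   self-describing.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(width = 30, sagittal = 22, sfl_thickness = 2,
                           sfl_fat_fraction = 0.8, visceral_fat_fraction = 0.3,
                           roi_height = 9.6, pixel_width = 0.48,
                           pixel_height = 0.96, fat_density = 0.90,
                           lean_density = 1.05, seed = 1L) {
  check_positive(c(width, sagittal, roi_height), "width/sagittal/roi_height")
  check_positive(c(pixel_width, pixel_height), "pixel dimensions")
  check_positive(c(fat_density, lean_density), "densities")
  if (sfl_thickness < 0 || sfl_thickness >= min(width, sagittal) / 2) {
    stop_domain(
      "`sfl_thickness` must satisfy 0 <= t < min(width, sagittal)/2.",
      "vatmets_geometry_error"
    )
  }
  for (f in c(sfl_fat_fraction, visceral_fat_fraction)) {
    if (f < 0 || f > 1) {
      stop_domain("fat fractions must lie in [0, 1].", "vatmets_domain_error")
    }
  }
  structure(
    list(
      width = width, sagittal = sagittal, sfl_thickness = sfl_thickness,
      sfl_fat_fraction = sfl_fat_fraction,
      visceral_fat_fraction = visceral_fat_fraction,
      roi_height = roi_height, pixel_width = pixel_width,
      pixel_height = pixel_height, fat_density = fat_density,
      lean_density = lean_density, seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' Generate a DXA abdominal phantom
#'
#' Builds the pixel grid of an elliptical abdomen phantom (see
#' [phantom_config()]) together with its analytic ground truth. The grid is
#' aligned so that the left skin edge coincides with a strip junction -- the
#' analogue of analysis boxes adjusted to follow the abdominal contour -- with
#' two columns of air margin on each side. Per-pixel masses are computed from
#' exact closed-form ellipse slab areas, so the summed grid mass equals the
#' analytic tissue mass to machine precision.
#'
#' @param config A [phantom_config()].
#' @return A list of class `dxa_phantom` with elements
#'   \describe{
#'     \item{grid}{the [dxa_grid()] of per-pixel masses;}
#'     \item{truth}{one-row tibble: `true_abfm`, `true_vfm`, `true_sfm`
#'       (grams per 1-cm slice), `true_width`, `true_sagittal`,
#'       `true_sfl_width` (cm), the four boundary x-coordinates (cm from the
#'       grid's left edge) and `roi_height`;}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_config(width = 24, sagittal = 24))
#' ph$truth$true_vfm + ph$truth$true_sfm == ph$truth$true_abfm
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  pw <- config$pixel_width
  ph <- config$pixel_height
  a <- config$width / 2
  b <- config$sagittal / 2
  t <- config$sfl_thickness
  ai <- a - t
  bi <- b - t
  rf <- config$fat_density
  rl <- config$lean_density
  fs <- config$sfl_fat_fraction
  fv <- config$visceral_fat_fraction

  n_rows <- max(1L, as.integer(round(config$roi_height / ph)))
  roi_height <- n_rows * ph
  n_cols <- 4L + as.integer(ceiling(config$width / pw))
  cx <- 2 * pw + a # ellipse centre: left skin edge on a strip junction
  x_left <- (seq_len(n_cols) - 1) * pw

  outer_slab <- ellipse_slab_area(a, b, x_left - cx, x_left + pw - cx)
  inner_slab <- ellipse_slab_area(ai, bi, x_left - cx, x_left + pw - cx)
  # grams per column per 1 cm of axial height
  fat_col <- rf * (fs * (outer_slab - inner_slab) + fv * inner_slab)
  lean_col <- rl * ((1 - fs) * (outer_slab - inner_slab) + (1 - fv) * inner_slab)

  grid <- dxa_grid(
    fat = matrix(fat_col * ph, n_rows, n_cols, byrow = TRUE),
    lean = matrix(lean_col * ph, n_rows, n_cols, byrow = TRUE),
    pixel_width = pw, pixel_height = ph
  )

  area_outer <- pi * a * b
  area_inner <- pi * ai * bi
  true_sfm <- fs * rf * (area_outer - area_inner)
  true_vfm <- fv * rf * area_inner
  truth <- tibble(
    true_abfm = true_vfm + true_sfm,
    true_vfm = true_vfm,
    true_sfm = true_sfm,
    true_width = config$width,
    true_sagittal = config$sagittal,
    true_sfl_width = t,
    outer_left_x = cx - a,
    inner_left_x = cx - ai,
    inner_right_x = cx + ai,
    outer_right_x = cx + a,
    roi_height = roi_height
  )
  structure(list(grid = grid, truth = truth, config = config),
            class = "dxa_phantom")
}

#' @export
print.dxa_phantom <- function(x, ...) {
  cat(sprintf(
    "<dxa_phantom> %.1f x %.1f cm ellipse, SFL %.2f cm; AbFM %.1f g (VFM %.1f, SFM %.1f) per 1-cm slice\n",
    x$truth$true_width, x$truth$true_sagittal, x$truth$true_sfl_width,
    x$truth$true_abfm, x$truth$true_vfm, x$truth$true_sfm
  ))
  print(x$grid)
  invisible(x)
}

#' Write / read a phantom as plain-text files
#'
#' The grid is stored as one CSV matrix per tissue component plus a JSON
#' sidecar holding the pixel geometry, configuration and analytic truth.
#'
#' @param phantom A `dxa_phantom` from [generate_phantom()].
#' @param dir Directory to write into (created if needed).
#' @param name Stem used for the file names.
#' @return `write_phantom()` returns the sidecar path invisibly;
#'   `read_phantom()` returns a `dxa_phantom`.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  stopifnot(inherits(phantom, "dxa_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (comp in c("fat", "lean", "bone")) {
    utils::write.table(
      phantom$grid[[comp]],
      file.path(dir, paste0(name, "_", comp, ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  sidecar <- list(
    pixel_width = phantom$grid$pixel_width,
    pixel_height = phantom$grid$pixel_height,
    config = unclass(phantom$config),
    truth = as.list(phantom$truth)
  )
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir, name = "phantom") {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                                 simplifyVector = TRUE)
  comps <- lapply(c("fat", "lean", "bone"), function(comp) {
    as.matrix(utils::read.table(
      file.path(dir, paste0(name, "_", comp, ".csv")),
      sep = ",", header = FALSE
    ))
  })
  grid <- dxa_grid(comps[[1]], comps[[2]], comps[[3]],
                   pixel_width = sidecar$pixel_width,
                   pixel_height = sidecar$pixel_height)
  cfg <- do.call(phantom_config, sidecar$config)
  structure(
    list(grid = grid, truth = as_tibble(sidecar$truth), config = cfg),
    class = "dxa_phantom"
  )
}
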