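# Landmark-referenced cross-sections, en-face projections, ROI intensity
# ratios, and refractive-index depth calibration.
#
# Structural ratios are measured on the 8-bit log-compressed display image
# (the rendering a reader would measure in Fiji); angiography ratios are
# measured on linear speckle-variance maps. Both are ratios of ROI means, so
# they are invariant to any positive rescaling of the whole image.

#' Extract umbo-referenced cross-sections
#'
#' Returns the XZ B-scan at the umbo's slow position and the YZ slice at the
#' umbo's fast position, both oriented depth x lateral (rows = depth), with
#' the umbo's in-plane pixel coordinates attached.
#'
#' @param volume `oct_volume` (any kind: structural, display, SV).
#' @param umbo integer (slow, fast, depth) 1-based voxel coordinates of the
#'   malleus umbo landmark.
#' @return list with `xz` (depth x fast), `yz` (depth x slow), `plane_ids`,
#'   and `umbo_in_plane` (row, col) per plane.
#' @export
extract_cross_sections <- function(volume, umbo) {
  a <- if (inherits(volume, "oct_volume")) volume$data else volume
  d <- dim(a)
  umbo <- as.integer(umbo)
  if (length(umbo) != 3L || any(umbo < 1L) || any(umbo > d))
    stop(sprintf("umbo (%s) outside volume %s",
                 paste(umbo, collapse = ","), paste(d, collapse = " x ")))
  xz <- t(a[umbo[1], , ])   # depth x fast
  yz <- t(a[, umbo[2], ])   # depth x slow
  list(xz = xz, yz = yz,
       plane_ids = c(xz = sprintf("xz@slow=%d", umbo[1]),
                     yz = sprintf("yz@fast=%d", umbo[2])),
       umbo_in_plane = list(xz = c(row = umbo[3], col = umbo[2]),
                            yz = c(row = umbo[3], col = umbo[1])))
}

#' Averaged-intensity en-face (XY) projection
#'
#' Mean of the volume over an inclusive depth window; with the window placed
#' on the membrane stratum this is the topographic XY view showing the TM
#' with the malleus. The clinical rendering uses a 40-50 pixel window on the
#' 2048-deep grid; scale accordingly for other grids.
#'
#' @param volume `oct_volume` or slow x fast x depth array.
#' @param z_lo,z_hi inclusive 1-based depth window.
#' @return matrix (slow x fast).
#' @export
enface_projection <- function(volume, z_lo, z_hi) {
  a <- if (inherits(volume, "oct_volume")) volume$data else volume
  nz <- dim(a)[3]
  z_lo <- as.integer(z_lo); z_hi <- as.integer(z_hi)
  if (z_lo < 1L || z_hi > nz || z_lo > z_hi)
    stop(sprintf("depth window [%d, %d] invalid for depth %d", z_lo, z_hi, nz))
  rowMeans(a[, , z_lo:z_hi, drop = FALSE], dims = 2)
}

#' Mean pixel intensity over a rectangular ROI
#'
#' @param image numeric matrix.
#' @param box an [roi_box()], fully inside the image.
#' @return arithmetic mean of the pixels in the box.
#' @export
roi_mean <- function(image, box) {
  ix <- box_indices(box, image)
  mean(image[ix$rows, ix$cols])
}

ratio_result <- function(kind, num, den, mass_box, ref_box, ear_id = NA,
                         class_label = NA, extra = list()) {
  if (den <= 0) stop(kind, " ratio: reference ROI mean must be > 0")
  structure(c(list(kind = kind, numerator_mean = num, denominator_mean = den,
                   ratio = num / den, mass_box = mass_box, ref_box = ref_box,
                   ear_id = ear_id, class_label = class_label), extra),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result %s> %s/%s ratio = %.4g (%.4g / %.4g)\n",
              x$kind, as.character(x$ear_id), as.character(x$class_label),
              x$ratio, x$numerator_mean, x$denominator_mean))
  invisible(x)
}

#' Structural mass-to-membrane intensity ratio
#'
#' Mean display intensity in the mass ROI divided by the mean display
#' intensity in the tympanic-membrane ROI, on a log-compressed cross-section
#' display image (see [render_display()]). For normal ears the "mass" box is
#' placed in the aerated mesotympanum at a depth comparable to where masses
#' sit. If the matching linear image is supplied, the linear-domain ratio is
#' recorded alongside for comparison.
#'
#' @param display_image matrix, 8-bit display cross-section.
#' @param mass_box,tm_box disjoint [roi_box()]es inside the image.
#' @param linear_image optional matrix of linear intensity, same shape.
#' @param ear_id,class_label provenance.
#' @return `ratio_result` with `kind = "structural"`.
#' @export
structural_ratio <- function(display_image, mass_box, tm_box,
                             linear_image = NULL, ear_id = NA,
                             class_label = NA) {
  if (!boxes_disjoint(mass_box, tm_box))
    stop("mass and TM ROIs must be disjoint")
  num <- roi_mean(display_image, mass_box)
  den <- roi_mean(display_image, tm_box)
  extra <- list()
  if (!is.null(linear_image)) {
    if (!all(dim(linear_image) == dim(display_image)))
      stop("linear_image must match display_image in shape")
    extra$ratio_linear <- roi_mean(linear_image, mass_box) /
      roi_mean(linear_image, tm_box)
  }
  ratio_result("structural", num, den, mass_box, tm_box, ear_id, class_label,
               extra)
}

#' Angiography mass-to-lateral-process ratio
#'
#' Mean speckle variance in the mass ROI of an en-face SV map, normalized to
#' the mean SV in a box over the malleus lateral process (which carries the
#' vascular-strip signal and is a readily identifiable landmark). Clinical
#' box sizes are 100 x 100 (mass) and 50 x 50 (lateral process) pixels on
#' the 417 x 1280 en-face grid; use [scale_roi_size()] for smaller grids and
#' record the scaling.
#'
#' @param enface_sv matrix (slow x fast) of speckle variance.
#' @param mass_box,malleus_box [roi_box()]es inside the map.
#' @param ear_id,class_label provenance.
#' @return `ratio_result` with `kind = "angio"`.
#' @export
angio_ratio <- function(enface_sv, mass_box, malleus_box, ear_id = NA,
                        class_label = NA) {
  num <- roi_mean(enface_sv, mass_box)
  den <- roi_mean(enface_sv, malleus_box)
  ratio_result("angio", num, den, mass_box, malleus_box, ear_id, class_label)
}

#' Refractive-index depth calibration
#'
#' OCT measures optical path length; physical depth is optical path divided
#' by the medium's refractive index. Air is fixed at n = 1.0; soft tissue is
#' assumed n = 1.4, with a plausible range of 1.33-1.45 across soft-tissue
#' and tumor types.
#'
#' @param n_tissue assumed tissue refractive index.
#' @param n_tissue_range plausible (low, high) tissue index range.
#' @return list with `n_air`, `n_tissue`, `n_tissue_range`.
#' @export
depth_calibration <- function(n_tissue = 1.4, n_tissue_range = c(1.33, 1.45)) {
  n_tissue_range <- sort(as.numeric(n_tissue_range))
  if (n_tissue < n_tissue_range[1] || n_tissue > n_tissue_range[2])
    stop("n_tissue must lie within n_tissue_range")
  list(n_air = 1.0, n_tissue = n_tissue, n_tissue_range = n_tissue_range)
}

#' Convert optical path length to physical depth
#'
#' A 1 mm optical path measured in air is 1 mm of physical depth; in tissue
#' (assumed n = 1.4) it is 1/1.4 mm.
#'
#' @param path_mm optical path length(s), mm, >= 0.
#' @param medium "air" or "tissue".
#' @param cal a [depth_calibration()].
#' @return physical depth, mm.
#' @export
optical_to_physical_depth <- function(path_mm, medium = c("air", "tissue"),
                                      cal = depth_calibration()) {
  medium <- match.arg(medium)
  if (any(path_mm < 0)) stop("optical path length must be >= 0")
  n <- if (medium == "air") cal$n_air else cal$n_tissue
  path_mm / n
}

#' Relative depth uncertainty from the assumed tissue refractive index
#'
#' If the true tissue index lies in `n_tissue_range` but depths are converted
#' with the assumed `n_tissue`, the relative depth error at a true index `n`
#' is `n_tissue / n - 1`. Returns the signed bounds at the range endpoints
#' and their maximum magnitude.
#'
#' @param cal a [depth_calibration()].
#' @return list with `bounds` (signed, `c(lower=, upper=)`) and `max_abs`.
#' @export
depth_uncertainty <- function(cal = depth_calibration()) {
  b <- cal$n_tissue / cal$n_tissue_range - 1   # at (low, high) true index
  bounds <- c(lower = min(b), upper = max(b))
  list(bounds = bounds, max_abs = max(abs(bounds)))
}

#' Per-A-line air gap between a mass and the tympanic membrane
#'
#' Given the TM inner-surface and mass top-surface depth indices over a
#' common (x, y) footprint, computes the per-A-line gap in mm, converted
#' with the refractive index of air (n = 1.0) since the gap is the aerated
#' middle-ear space. A-lines where the mass surface lies above the TM inner
#' surface are flagged and excluded from the summary.
#'
#' @param tm_inner integer matrix of TM inner-surface depth indices.
#' @param mass_top integer matrix of mass top-surface depth indices (NA
#'   outside the mass footprint), same shape.
#' @param z_spacing_mm axial (optical-path) pixel spacing, mm.
#' @param n_medium refractive index of the gap medium (air = 1.0).
#' @return list with `gap_mm` (per-A-line matrix, NA outside footprint),
#'   `min_mm`, `max_mm`, `n_flagged`, `n_alines`.
#' @export
tumor_tm_gap <- function(tm_inner, mass_top, z_spacing_mm, n_medium = 1.0) {
  if (!all(dim(tm_inner) == dim(mass_top)))
    stop("surfaces must share a common (x, y) footprint grid")
  if (z_spacing_mm <= 0) stop("z_spacing_mm must be positive")
  gap_px <- mass_top - tm_inner
  flagged <- !is.na(gap_px) & gap_px < 0L
  gap_mm <- pmax(gap_px, 0L) * z_spacing_mm / n_medium
  gap_mm[flagged] <- NA_real_
  ok <- !is.na(gap_mm)
  if (!any(ok)) stop("no valid A-lines in the footprint")
  list(gap_mm = gap_mm,
       min_mm = min(gap_mm[ok]), max_mm = max(gap_mm[ok]),
       n_flagged = sum(flagged), n_alines = sum(ok))
}

#' Log-compressed 8-bit display rendering
#'
#' `display = clip(10*log10(I / I_max) + DR, 0, DR) * 255 / DR`, rounded
#' half-up to integers: the brightest voxel maps to 255 and anything DR dB
#' or more below it maps to 0. Deterministic, so ratios measured on display
#' images are bit-stable.
#'
#' @param volume `oct_volume`, 3-D array, or 2-D matrix of linear intensity.
#' @param dynamic_range_db display window, dB (> 0).
#' @param i_max normalization intensity; defaults to the data maximum.
#' @return integer array/matrix of the same shape, values 0-255, with the
#'   window recorded in `attr(, "display_window")`.
#' @export
render_display <- function(volume, dynamic_range_db = 40, i_max = NULL) {
  a <- if (inherits(volume, "oct_volume")) volume$data else volume
  if (length(a) == 0L) stop("empty volume")
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
  i_max <- i_max %||% max(a)
  if (i_max <= 0) stop("volume has no positive intensity to window")
  db <- 10 * log10(a / i_max) + dynamic_range_db
  db <- pmin(pmax(db, 0), dynamic_range_db)
  out <- round_half_up(db * 255 / dynamic_range_db)
  out <- array(as.integer(out), dim = dim(a) %||% length(a))
  if (is.matrix(a)) dim(out) <- dim(a)
  attr(out, "display_window") <- c(dynamic_range_db = dynamic_range_db,
                                   i_max = i_max)
  out
}
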