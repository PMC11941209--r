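# Volume interchange: multi-page TIFF (pages = slow-axis B-scans, each page
# fast x depth) with a JSON sidecar carrying pixel spacing, axis order,
# refractive-index assumptions, seed, and preset. 16-bit integer data
# round-trips exactly; floating-point data (linear intensity, speckle
# variance) is stored as 32-bit float scaled into [0, 1] with the scale
# factor recorded in the sidecar.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an OCT volume as multi-page TIFF + JSON sidecar
#'
#' @param volume an `oct_volume`. Integer-valued data in 0..65535 is stored
#'   as 16-bit (exact); anything else as scaled 32-bit float.
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  a <- volume$data
  d <- dim(a)
  is_int16 <- all(a == floor(a)) && max(a) <= 65535 && min(a) >= 0
  if (is_int16) {
    scale <- 65535
    encoding <- "uint16"
    bps <- 16L
  } else {
    scale <- max(a)
    if (scale <= 0) scale <- 1
    encoding <- "float32_scaled"
    bps <- 32L
  }
  pages <- lapply(seq_len(d[1]), function(iy) a[iy, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bps)
  meta <- list(
    axis_order = "slow,fast,depth (pages = slow; page rows = fast)",
    shape = d,
    pixel_spacing_mm = as.list(volume$pixel_spacing),
    z_axis = "optical path, air n = 1.0; assumed tissue n = 1.4",
    encoding = encoding, scale = scale,
    meta = volume$meta
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' If the JSON sidecar is missing, pixel spacing defaults to 1 mm with a
#' warning, and the default is flagged in the returned metadata.
#'
#' @param path TIFF path.
#' @return an `oct_volume`.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d1))
      stop(sprintf("page %d has shape %s, expected %s", i,
                   paste(dim(pages[[i]]), collapse = " x "),
                   paste(d1, collapse = " x ")))
  }
  sc_path <- sidecar_path(path)
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    spacing <- unlist(sc$pixel_spacing_mm)[c("y", "x", "z")]
    scale <- sc$scale
    encoding <- sc$encoding
    meta <- as.list(sc$meta)
    meta$spacing_defaulted <- FALSE
  } else {
    warning("sidecar ", sc_path, " missing; defaulting pixel spacing to 1 mm")
    spacing <- c(y = 1, x = 1, z = 1)
    scale <- 1
    encoding <- "unknown"
    meta <- list(spacing_defaulted = TRUE)
  }
  a <- array(0, dim = c(length(pages), d1[1], d1[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]] * scale
  if (identical(encoding, "uint16")) a <- round(a)
  oct_volume(a, pixel_spacing = spacing, meta = meta)
}

#' Write phantom ground truth (label map TIFF + JSON)
#'
#' @param truth a `phantom_truth`.
#' @param path output TIFF path for the label map; landmarks, designed gap,
#'   and surfaces go into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  lab <- truth$label_map
  vol <- oct_volume(array(as.numeric(lab), dim = dim(lab)),
                    pixel_spacing = truth$pixel_spacing,
                    meta = list(kind = "label_map",
                                labels = as.list(PHANTOM_LABELS)))
  write_volume(vol, path)
  extra <- list(landmarks = truth$landmarks, gap_mm = truth$gap_mm,
                class_preset = truth$class_preset,
                tm_inner_surface = truth$tm_inner_surface,
                mass_top_surface = truth$mass_top_surface)
  jsonlite::write_json(extra,
                       paste0(tools::file_path_sans_ext(path), "_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a per-ear ROI/landmark YAML config
#'
#' Expected fields: `ear_id`, `class`, `landmarks` (named lists of
#' slow/fast/depth), `boxes` (named, each with `origin`, `size`,
#' `plane_id`), `projection_window` (z_lo, z_hi). Missing sections are
#' returned as NULL.
#'
#' @param path YAML file path.
#' @return list with parsed `roi_box` objects under `$boxes`.
#' @export
read_ear_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$boxes)) {
    cfg$boxes <- lapply(cfg$boxes, function(b)
      roi_box(unlist(b$origin), unlist(b$size),
              plane_id = b$plane_id %||% NA_character_))
  }
  cfg
}

#' Write a per-ear ROI/landmark YAML config
#'
#' @param cfg list in the layout documented in [read_ear_config()] (boxes
#'   may be `roi_box` objects).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_ear_config <- function(cfg, path) {
  if (!is.null(cfg$boxes)) {
    cfg$boxes <- lapply(cfg$boxes, function(b) {
      if (inherits(b, "roi_box"))
        list(origin = as.integer(b$origin), size = as.integer(b$size),
             plane_id = b$plane_id)
      else b
    })
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# md5 digest of an in-memory object via its canonical JSON rendering
object_digest <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Build a run manifest
#'
#' Records the package version, master seed, a digest of the configuration,
#' and the md5 digest of every output file, so a rerun with identical inputs
#' can be verified byte-for-byte for deterministic stages.
#'
#' @param master_seed integer master seed of the run.
#' @param config configuration list (digested, not stored verbatim).
#' @param files character vector of output file paths to digest.
#' @param warnings character vector of machine-readable warnings.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(master_seed, config = list(), files = character(0),
                         warnings = character(0)) {
  files <- files[file.exists(files)]
  structure(list(
    tool = "meoct",
    version = as.character(utils::packageVersion("meoct")),
    master_seed = as.integer(master_seed),
    config_digest = object_digest(config),
    file_digests = as.list(tools::md5sum(files)),
    warnings = warnings,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "run_manifest")
}
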