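# End-to-end per-ear analysis and cohort report: simulate -> angiography ->
# quantify -> statistics, with ROI placement derived from ground truth (or
# supplied per-ear config), tidy ratio tables, pairwise tests, and a
# manifest-logged output bundle.

# clamp a centered box inside an image
centered_box <- function(center, size, img_dim, plane_id) {
  org <- as.integer(round(center - size / 2))
  org <- pmax(1L, pmin(org, img_dim - size + 1L))
  roi_box(org, size, plane_id = plane_id)
}

# reference grids of the clinical acquisition (used only for ROI scaling)
REF_ENFACE <- c(417L, 1280L)   # slow x fast
REF_BSCAN  <- c(2048L, 1280L)  # depth x fast

#' Derive default ROI/landmark configuration for a synthetic ear
#'
#' Encodes the measurement protocol: the structural plane is the
#' umbo-referenced XZ cross-section (shifted to the mass's own slow position
#' when the mass misses the umbo plane — recorded in provenance); the
#' structural mass box (100 x 100 on the clinical B-scan grid, scaled) is
#' centered on the mass cross-section, or in the aerated mesotympanum at a
#' comparable depth for normal ears; the TM box (20 x 50, scaled) sits on
#' the membrane away from the malleus handle. The angiography mass box
#' (100 x 100 on the clinical en-face grid, scaled) is centered on the mass
#' footprint (or the matching mesotympanic region for normals) and the
#' 50 x 50 (scaled) reference box sits over the malleus lateral process.
#'
#' @param ear an `me_ear`.
#' @return config list (see [read_ear_config()]) with `boxes`,
#'   `structural_slow_index`, `projection_window`, `landmarks`, and
#'   `roi_scaling` provenance.
#' @export
derive_rois <- function(ear) {
  truth <- ear$truth
  d <- dim(truth$label_map)             # slow x fast x depth
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  um <- truth$landmarks$umbo
  lp <- truth$landmarks$malleus_lateral_process

  sz_mass_xz <- scale_roi_size(c(100L, 100L), REF_BSCAN, c(nz, nx))
  sz_tm_xz   <- scale_roi_size(c(20L, 50L), REF_BSCAN, c(nz, nx))
  sz_mass_en <- scale_roi_size(c(100L, 100L), REF_ENFACE, c(ny, nx))
  sz_lp_en   <- scale_roi_size(c(50L, 50L), REF_ENFACE, c(ny, nx))

  slow_plane <- um["slow"]; plane_note <- "umbo"
  has_mass <- !is.null(truth$mass_top_surface)
  if (has_mass) {
    sl <- truth$mass_mask[slow_plane, , ]      # fast x depth
    if (sum(sl) < prod(sz_mass_xz)) {
      # mass misses (or barely grazes) the umbo plane: use its own plane
      per_slow <- apply(truth$mass_mask, 1, sum)
      slow_plane <- which.max(per_slow)
      sl <- truth$mass_mask[slow_plane, , ]
      plane_note <- "mass_centroid"
    }
    w <- which(sl, arr.ind = TRUE)             # (fast, depth)
    mass_center_xz <- c(mean(w[, 2]), mean(w[, 1]))   # (depth, fast)
  } else {
    # aerated mesotympanum at a similar depth as the middle-ear masses
    ix <- min(nx, um["fast"] + as.integer(round(1.0 / (8 / nx))))
    ztop <- truth$tm_inner_surface[slow_plane, ix]
    zbot <- truth$prom_surface[slow_plane, ix]
    mass_center_xz <- c((ztop + zbot) / 2, ix)
  }
  mass_box_xz <- centered_box(mass_center_xz, sz_mass_xz, c(nz, nx),
                              sprintf("xz@slow=%d", slow_plane))

  # TM box: on the membrane, offset laterally from the malleus handle
  ix_tm <- max(1L, um["fast"] - as.integer(round(1.2 / (8 / nx))))
  lab_line <- truth$label_map[slow_plane, ix_tm, ]
  tm_z <- which(lab_line == PHANTOM_LABELS["tm"])
  tm_center <- if (length(tm_z)) mean(tm_z) else
    truth$tm_inner_surface[slow_plane, ix_tm] - 2
  tm_box_xz <- centered_box(c(tm_center, ix_tm), sz_tm_xz, c(nz, nx),
                            sprintf("xz@slow=%d", slow_plane))

  # angiography en-face boxes
  if (has_mass) {
    fp <- apply(truth$mass_mask, c(1, 2), any)
    w <- which(fp, arr.ind = TRUE)
    mass_center_en <- c(mean(w[, 1]), mean(w[, 2]))
  } else {
    mass_center_en <- c(um["slow"] + round(0.8 * ny / 6),
                        um["fast"] + round(1.0 * nx / 8))
  }
  mass_box_en <- centered_box(mass_center_en, sz_mass_en, c(ny, nx),
                              "enface")
  lp_box_en <- centered_box(c(lp["slow"], lp["fast"]), sz_lp_en, c(ny, nx),
                            "enface")

  # depth window: membrane stratum through the promontory face
  z_lo <- max(1L, min(truth$tm_inner_surface) -
                as.integer(round(0.3 * nz / 4)))
  z_hi <- min(nz, max(truth$prom_surface))
  # en-face structural window on the membrane stratum (clinical 40-50 px of
  # 2048 deep), centered just below the shallowest membrane point
  w_tm <- max(1L, as.integer(round(45 * nz / 2048)))
  tm_lo <- max(1L, min(truth$tm_inner_surface) - w_tm)

  list(
    ear_id = ear$ear_id, class = ear$class_label,
    structural_slow_index = unname(slow_plane),
    structural_plane = plane_note,
    boxes = list(mass_structural = mass_box_xz, tm_structural = tm_box_xz,
                 mass_angio = mass_box_en, malleus_angio = lp_box_en),
    projection_window = list(angio = c(z_lo = unname(z_lo),
                                       z_hi = unname(z_hi)),
                             structural = c(z_lo = unname(tm_lo),
                                            z_hi = unname(tm_lo + w_tm))),
    landmarks = truth$landmarks,
    roi_scaling = list(ref_enface = REF_ENFACE, ref_bscan = REF_BSCAN,
                       grid = d)
  )
}

#' Analyze one ear: angiography, ratios, gap
#'
#' Runs speckle-variance assembly (if raw stacks are present), renders the
#' display volume, extracts the umbo-referenced cross-sections, measures the
#' structural and angiography ROI ratios, and, when a mass is present, the
#' per-A-line mass-to-membrane air gap.
#'
#' @param ear an `me_ear`.
#' @param config ROI config (default [derive_rois()]).
#' @param dynamic_range_db display window for structural quantification.
#' @param norm speckle-variance normalization ("n" or "n-1").
#' @return list with `ratios` (two-row data.frame: structural + angio),
#'   `gap` (list or NULL), `config`, `sv_enface`, `display_xz`.
#' @export
run_ear_analysis <- function(ear, config = NULL, dynamic_range_db = 40,
                             norm = "n") {
  stopifnot(inherits(ear, "me_ear"))
  config <- config %||% derive_rois(ear)
  sv <- ear$sv_volume %||% assemble_angio_volume(ear$stacks, norm = norm,
                                                 pixel_spacing =
                                                   ear$volume$pixel_spacing)

  disp <- render_display(ear$volume, dynamic_range_db = dynamic_range_db)
  dvol <- oct_volume(array(as.numeric(disp), dim = dim(disp)),
                     pixel_spacing = ear$volume$pixel_spacing)
  iy <- config$structural_slow_index
  xz_disp <- t(dvol$data[iy, , ])            # depth x fast
  xz_lin <- t(ear$volume$data[iy, , ])

  sr <- structural_ratio(xz_disp, config$boxes$mass_structural,
                         config$boxes$tm_structural,
                         linear_image = xz_lin,
                         ear_id = ear$ear_id, class_label = ear$class_label)

  zw <- config$projection_window$angio
  sv_en <- angio_enface(sv, zw["z_lo"], zw["z_hi"])
  ar <- angio_ratio(sv_en, config$boxes$mass_angio,
                    config$boxes$malleus_angio,
                    ear_id = ear$ear_id, class_label = ear$class_label)

  gap <- NULL
  if (!is.null(ear$truth$mass_top_surface)) {
    gap <- tumor_tm_gap(ear$truth$tm_inner_surface,
                        ear$truth$mass_top_surface,
                        ear$volume$pixel_spacing["z"], n_medium = 1.0)
  }

  prov <- function(b) sprintf("%s[%d,%d %dx%d]", b$plane_id, b$origin[1],
                              b$origin[2], b$size[1], b$size[2])
  ratios <- data.frame(
    ear_id = ear$ear_id, class = ear$class_label,
    kind = c("structural", "angio"),
    numerator = c(sr$numerator_mean, ar$numerator_mean),
    denominator = c(sr$denominator_mean, ar$denominator_mean),
    ratio = c(sr$ratio, ar$ratio),
    ratio_linear = c(sr$ratio_linear %||% NA_real_, NA_real_),
    roi = c(paste(prov(config$boxes$mass_structural),
                  prov(config$boxes$tm_structural), sep = " / "),
            paste(prov(config$boxes$mass_angio),
                  prov(config$boxes$malleus_angio), sep = " / ")),
    gap_max_mm = if (is.null(gap)) NA_real_ else gap$max_mm,
    stringsAsFactors = FALSE
  )
  list(ratios = ratios, gap = gap, config = config, sv_enface = sv_en,
       display_xz = xz_disp)
}

#' Tidy ratio table for a whole cohort
#'
#' @param cohort an `me_cohort` (or plain list of `me_ear`).
#' @param ... passed to [run_ear_analysis()].
#' @return data.frame, two rows (structural, angio) per ear.
#' @export
cohort_ratios <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, function(e) run_ear_analysis(e, ...)$ratios))
}

#' End-to-end cohort report
#'
#' Analyzes every ear (failures are isolated per ear and reported, the run
#' continues), writes the tidy ratios CSV, pairwise test CSV, per-ear
#' cross-section and angiography-overlay PNGs, a markdown summary with group
#' means +/- SE, and a run manifest with file digests.
#'
#' @param cohort an `me_cohort`.
#' @param out_dir output directory (created if needed).
#' @param write_images write per-ear PNGs?
#' @param dynamic_range_db display window.
#' @return list with `ratios`, `comparisons` (per kind), `failed`,
#'   `manifest`, invisibly.
#' @export
run_report <- function(cohort, out_dir, write_images = FALSE,
                       dynamic_range_db = 40) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); failed <- character(0)
  for (e in cohort) {
    res <- tryCatch(run_ear_analysis(e, dynamic_range_db = dynamic_range_db),
                    error = function(err) err)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s: %s", e$ear_id, conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- res$ratios
    if (write_images) {
      png::writePNG(res$display_xz / 255,
                    file.path(out_dir, paste0(e$ear_id, "_xz.png")))
      base_en <- enface_projection(e$volume,
                                   res$config$projection_window$structural["z_lo"],
                                   res$config$projection_window$structural["z_hi"])
      thr <- stats::quantile(res$sv_enface, 0.95, names = FALSE)
      ov <- angio_overlay(base_en, res$sv_enface, threshold = thr)
      png::writePNG(ov, file.path(out_dir, paste0(e$ear_id, "_overlay.png")))
    }
  }
  if (!length(rows)) stop("no ear analyzed successfully")
  ratios <- do.call(rbind, rows)
  ratios_csv <- file.path(out_dir, "ratios.csv")
  utils::write.csv(ratios, ratios_csv, row.names = FALSE)

  comparisons <- list(); tests_rows <- list()
  for (kind in unique(ratios$kind)) {
    df <- data.frame(label = ratios$class[ratios$kind == kind],
                     value = ratios$ratio[ratios$kind == kind])
    cmp <- compare_all(df)
    comparisons[[kind]] <- cmp
    if (nrow(cmp$tests))
      tests_rows[[kind]] <- cbind(kind = kind, cmp$tests)
  }
  tests <- if (length(tests_rows)) do.call(rbind, tests_rows) else
    data.frame()
  tests_csv <- file.path(out_dir, "tests.csv")
  utils::write.csv(tests, tests_csv, row.names = FALSE)

  md <- file.path(out_dir, "report.md")
  con <- file(md, "w"); on.exit(close(con), add = TRUE)
  writeLines(c("# Middle-ear OCT cohort report", ""), con)
  for (kind in names(comparisons)) {
    s <- comparisons[[kind]]$summaries
    writeLines(sprintf("## %s ratios", kind), con)
    writeLines(sprintf("- %s: %.3f +/- %.3f (mean +/- SE, n = %d)%s",
                       s$label, s$mean, s$se, s$n,
                       ifelse(s$se_defined, "", " [n = 1, descriptive only]")),
               con)
    tst <- comparisons[[kind]]$tests
    if (nrow(tst))
      writeLines(sprintf("- %s vs %s: t = %.3f, df = %g, p = %.4g%s",
                         tst$group1, tst$group2, tst$t, tst$df, tst$p,
                         ifelse(tst$significant, " (significant)", "")), con)
    writeLines(sprintf("- comparisons run (uncorrected): %d",
                       comparisons[[kind]]$n_comparisons), con)
    writeLines("", con)
  }
  if (length(failed))
    writeLines(c("## Failed ears", paste0("- ", failed)), con)

  outputs <- c(ratios_csv, tests_csv, md,
               if (write_images) list.files(out_dir, "\\.png$",
                                            full.names = TRUE))
  manifest <- run_manifest(attr(cohort, "master_seed") %||% NA_integer_,
                           config = list(dynamic_range_db = dynamic_range_db,
                                         n_ears = length(cohort)),
                           files = outputs, warnings = failed)
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ratios = ratios, comparisons = comparisons, failed = failed,
                 manifest = manifest))
}
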