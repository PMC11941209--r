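# Synthetic middle-ear OCT phantom: geometry, optics, speckle, flow.
#
# The scene is a parametric middle ear viewed from the ear canal: a curved
# tympanic membrane (TM) whose apex is the umbo, the malleus handle with its
# lateral process embedded on the medial TM surface, the incudostapedial
# joint, the bony cochlear promontory as the deep wall, an air-filled
# mesotympanum, and (for the mass presets) a soft-tissue mass molded beneath
# the TM with a designed air gap. All depths are optical-path mm measured
# from the probe (air n = 1); the phantom does not re-stretch the axis inside
# tissue.

PHANTOM_LABELS <- c(air = 0L, tm = 1L, malleus = 2L, is_joint = 3L,
                    promontory = 4L, mass = 5L)

#' Optical and flow properties of the static tissue classes
#'
#' Relative backscatter (dimensionless), intensity attenuation (per mm,
#' applied as round-trip `exp(-2*a*z)`), and the inter-repeat complex-field
#' correlation `flow_rho` (1 = static, 0 = fully decorrelated). The malleus
#' carries a reduced `flow_rho` standing in for the vascular strip that
#' overlies the handle and lateral process, which is what makes the lateral
#' process a usable angiography normalization region.
#'
#' @return data.frame with columns label, backscatter, attenuation, flow_rho.
#' @export
tissue_presets <- function() {
  data.frame(
    label       = c("air", "tm", "malleus", "is_joint", "promontory"),
    backscatter = c(0,     1.0,  1.0,       1.1,        0.9),
    attenuation = c(0,     2.0,  4.0,       4.0,        3.0),
    flow_rho    = c(1,     1.0,  0.65,      1.0,        1.0),
    stringsAsFactors = FALSE
  )
}

# per-class mass optics; flow_rho is the vessel decorrelation, vascular_fraction
# scales it into the effective voxel correlation 1 - vf*(1 - rho)
mass_presets <- function() {
  list(
    glomus = list(backscatter = 0.8, attenuation = 2.5, flow_rho = 0.20,
                  vascular_fraction = 1.0, gap_mm = 0.10,
                  thickness_mm = NA_real_, footprint_radius_mm = 1.3,
                  center_offset_mm = c(x = 0.8, y = 0.8)),
    cholesteatoma = list(backscatter = 0.9, attenuation = 3.0, flow_rho = 1.0,
                  vascular_fraction = 0.0, gap_mm = 0.0,
                  thickness_mm = 1.2, footprint_radius_mm = 1.1,
                  center_offset_mm = c(x = 1.2, y = -0.8)),
    schwannoma = list(backscatter = 0.7, attenuation = 2.2, flow_rho = 0.75,
                  vascular_fraction = 1.0, gap_mm = 0.05,
                  thickness_mm = NA_real_, footprint_radius_mm = 1.4,
                  center_offset_mm = c(x = 1.0, y = 0.5))
  )
}

#' Build a phantom scene for one of the four clinical presentations
#'
#' Returns the full geometric/optical description of one synthetic ear.
#' `jitter = TRUE` draws mild per-ear anatomical variation (TM sag and
#' standoff, mass position/extent/gap, mass optics and vascularity) from the
#' seed, so a cohort is more than speckle replicates of one geometry.
#'
#' @param preset one of "normal", "glomus", "cholesteatoma", "schwannoma".
#' @param seed integer RNG seed (drives jitter only; rendering is
#'   deterministic given the scene).
#' @param grid_shape integer (slow, fast, depth) voxel counts.
#' @param fov_mm named numeric field of view `c(y=, x=, z=)` in mm
#'   (z optical path).
#' @param n_repeats consecutive B-scans per slow position for angiography.
#' @param jitter draw per-ear anatomical variation?
#' @param gap_mm override the designed mass-to-TM air gap (max over the
#'   apposition footprint), mm.
#' @param noise_floor additive expected-intensity noise floor (linear units).
#' @return An object of class `phantom_scene`.
#' @export
scene_preset <- function(preset = c("normal", "glomus", "cholesteatoma",
                                    "schwannoma"),
                         seed = 1L,
                         grid_shape = c(64L, 256L, 512L),
                         fov_mm = c(y = 6, x = 8, z = 4),
                         n_repeats = 4L,
                         jitter = FALSE,
                         gap_mm = NULL,
                         noise_floor = 1.5e-3) {
  preset <- match.arg(preset)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be three positive voxel counts (slow, fast, depth)")
  fov <- as.numeric(fov_mm); names(fov) <- c("y", "x", "z")
  if (any(fov <= 0)) stop("fov_mm must be positive")

  set.seed(as.integer(seed))
  ju <- function(lo, hi) if (jitter) stats::runif(1, lo, hi) else (lo + hi) / 2

  xc <- fov["x"] / 2; yc <- fov["y"] / 2
  tm <- list(center_mm = c(x = unname(xc), y = unname(yc)),
             edge_z_mm = ju(0.75, 0.85),
             sag_mm = ju(0.9, 1.1),
             width_mm = 1.6,
             thickness_mm = 0.12)
  malleus <- list(lp_offset_y_mm = -1.6, handle_radius_mm = 0.22,
                  lp_radius_mm = 0.38)
  isj <- list(center_mm = c(x = unname(xc) + 1.8, y = unname(yc) - 0.4,
                            z = 2.9),
              radius_mm = 0.3)
  promontory <- list(base_z_mm = 3.4, dome_mm = 0.35, dome_width_mm = 2.2,
                     center_mm = c(x = unname(xc) + 0.6, y = unname(yc)))

  mass <- NULL
  if (preset != "normal") {
    mp <- mass_presets()[[preset]]
    off <- mp$center_offset_mm
    if (jitter) off <- off + stats::runif(2, -0.25, 0.25)
    g <- gap_mm %||% switch(preset,
      glomus = if (jitter) stats::runif(1, 0.02, 0.18) else mp$gap_mm,
      cholesteatoma = 0.0,
      schwannoma = mp$gap_mm)
    rho <- switch(preset,
      glomus = if (jitter) stats::runif(1, 0.15, 0.30) else mp$flow_rho,
      cholesteatoma = 1.0,
      schwannoma = mp$flow_rho)
    mass <- list(
      center_mm = c(x = unname(xc) + unname(off[1]),
                    y = unname(yc) + unname(off[2])),
      footprint_radius_mm = mp$footprint_radius_mm * ju(0.85, 1.1),
      gap_mm = g,
      thickness_mm = mp$thickness_mm,
      backscatter = mp$backscatter * ju(0.9, 1.08),
      attenuation = mp$attenuation,
      flow_rho = rho,
      vascular_fraction = mp$vascular_fraction
    )
  } else if (!is.null(gap_mm)) {
    stop("gap_mm has no meaning for the normal preset (no mass)")
  }

  scene <- structure(list(
    class_preset = preset, seed = as.integer(seed),
    grid_shape = grid_shape, fov_mm = fov,
    pixel_spacing = c(y = unname(fov["y"] / grid_shape[1]),
                      x = unname(fov["x"] / grid_shape[2]),
                      z = unname(fov["z"] / grid_shape[3])),
    tm = tm, malleus = malleus, isj = isj, promontory = promontory,
    mass = mass, tissue = tissue_presets(),
    noise_floor = noise_floor, n_repeats = as.integer(n_repeats)
  ), class = "phantom_scene")
  validate_scene(scene)
  scene
}

validate_scene <- function(scene) {
  gs <- scene$grid_shape
  if (any(gs <= 0L)) stop("phantom_scene: grid_shape must be positive")
  if (any(scene$pixel_spacing <= 0)) stop("phantom_scene: spacing must be positive")
  if (scene$class_preset == "normal" && !is.null(scene$mass))
    stop("phantom_scene: normal preset must not carry a mass")
  # umbo and lateral process must land inside the grid
  um <- scene$tm$center_mm
  z_umbo <- scene$tm$edge_z_mm + scene$tm$sag_mm + scene$tm$thickness_mm
  lp_y <- um["y"] + scene$malleus$lp_offset_y_mm
  if (um["x"] <= 0 || um["x"] >= scene$fov_mm["x"] ||
      um["y"] <= 0 || um["y"] >= scene$fov_mm["y"] ||
      z_umbo <= 0 || z_umbo >= scene$fov_mm["z"])
    stop("phantom_scene: umbo outside the volume")
  if (lp_y <= 0 || lp_y >= scene$fov_mm["y"])
    stop("phantom_scene: malleus lateral process outside the volume")
  invisible(scene)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene %s> grid %d x %d x %d, fov %.3g x %.3g x %.3g mm\n",
              x$class_preset, x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$fov_mm["y"], x$fov_mm["x"], x$fov_mm["z"]))
  if (!is.null(x$mass))
    cat(sprintf("  mass: r=%.2f mm gap=%.3f mm rho=%.2f\n",
                x$mass$footprint_radius_mm, x$mass$gap_mm, x$mass$flow_rho))
  invisible(x)
}

# voxel-center coordinates along one axis
axis_mm <- function(n, d) (seq_len(n) - 0.5) * d

# first voxel index whose center lies at or beyond z_mm (1-based)
z_index_at <- function(z_mm, dz) as.integer(ceiling(z_mm / dz + 0.5 - 1e-9))

#' Rasterize a phantom scene into voxel-level ground truth
#'
#' Produces the per-voxel tissue label map and flow-correlation map, the
#' landmark coordinates (umbo, malleus lateral process), the TM inner-surface
#' and mass top-surface depth indices, and the designed mass-to-TM gap.
#'
#' Masses are molded beneath the membrane: over the apposition footprint the
#' continuous mass top surface is `tm_inner + gap_mm * min(1, (rho/0.8)^2)`
#' with `rho` the normalized footprint radius, so the designed air gap runs
#' from 0 at the contact apex up to `gap_mm` (its maximum), which it holds on
#' the outer plateau of the footprint.
#'
#' @param scene a `phantom_scene`.
#' @return An object of class `phantom_truth`: list with `label_map` (integer
#'   array, levels in `attr(,"labels")`), `rho_map`, `mass_mask`, `landmarks`
#'   (1-based (slow, fast, depth) voxel coords), `tm_inner_surface`,
#'   `mass_top_surface` (NA outside the footprint), `gap_mm`, `class_preset`.
#' @export
phantom_truth <- function(scene) {
  validate_scene(scene)
  gs <- scene$grid_shape; ny <- gs[1]; nx <- gs[2]; nz <- gs[3]
  sp <- scene$pixel_spacing
  yv <- axis_mm(ny, sp["y"]); xv <- axis_mm(nx, sp["x"])
  zv <- axis_mm(nz, sp["z"]); dz <- sp["z"]

  xc <- scene$tm$center_mm["x"]; yc <- scene$tm$center_mm["y"]
  px <- matrix(xv, ny, nx, byrow = TRUE)   # x coordinate of each (y, x) cell
  py <- matrix(yv, ny, nx)

  # membrane: Gaussian bump, apex (deepest point) at the umbo
  r2 <- (px - xc)^2 + (py - yc)^2
  tm_z <- scene$tm$edge_z_mm +
    scene$tm$sag_mm * exp(-r2 / (2 * scene$tm$width_mm^2))
  tm_inner_z <- tm_z + scene$tm$thickness_mm

  # promontory: deep bony wall bulging toward the membrane
  pr <- scene$promontory
  rp2 <- (px - pr$center_mm["x"])^2 + (py - pr$center_mm["y"])^2
  prom_z <- pr$base_z_mm - pr$dome_mm * exp(-rp2 / (2 * pr$dome_width_mm^2))

  # malleus handle: capsule from the lateral process to the umbo, medial to TM
  lp_x <- xc; lp_y <- yc + scene$malleus$lp_offset_y_mm
  lp_z <- scene$tm$edge_z_mm + scene$tm$thickness_mm +
    scene$tm$sag_mm * exp(-(lp_y - yc)^2 / (2 * scene$tm$width_mm^2)) +
    0.5 * scene$malleus$lp_radius_mm
  um_x <- xc; um_y <- yc
  um_z <- unname(tm_inner_z[which.min(abs(yv - yc)), which.min(abs(xv - xc))]) +
    scene$malleus$handle_radius_mm
  seg <- c(um_x - lp_x, um_y - lp_y, um_z - lp_z)
  segL2 <- sum(seg^2)

  # mass surfaces (continuous, mm)
  mass <- scene$mass
  if (!is.null(mass)) {
    rm2 <- (px - mass$center_mm["x"])^2 + (py - mass$center_mm["y"])^2
    rho_n <- sqrt(rm2) / mass$footprint_radius_mm
    in_fp <- rho_n <= 1
    mass_top_z <- ifelse(in_fp,
                         tm_inner_z + mass$gap_mm * pmin(1, (rho_n / 0.8)^2),
                         NA_real_)
    mass_bot_z <- if (is.na(mass$thickness_mm)) prom_z else
      pmin(mass_top_z + mass$thickness_mm, prom_z)
  }

  lab <- array(PHANTOM_LABELS["air"], dim = gs)
  rho_map <- array(1.0, dim = gs)
  rho_tab <- stats::setNames(scene$tissue$flow_rho, scene$tissue$label)
  mass_rho <- if (!is.null(mass))
    1 - mass$vascular_fraction * (1 - mass$flow_rho) else NA_real_

  isj <- scene$isj
  hr2 <- scene$malleus$handle_radius_mm^2
  lpr2 <- scene$malleus$lp_radius_mm^2
  isjr2 <- isj$radius_mm^2

  for (k in seq_len(nz)) {
    z <- zv[k]
    sl <- matrix(PHANTOM_LABELS["air"], ny, nx)
    sl[z >= prom_z] <- PHANTOM_LABELS["promontory"]
    if (!is.null(mass)) {
      mk <- !is.na(mass_top_z) & z >= mass_top_z & z <= mass_bot_z
      sl[mk] <- PHANTOM_LABELS["mass"]
    }
    sl[z >= tm_z & z < tm_inner_z] <- PHANTOM_LABELS["tm"]
    # handle capsule distance
    t <- ((px - lp_x) * seg[1] + (py - lp_y) * seg[2] + (z - lp_z) * seg[3]) / segL2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (lp_x + t * seg[1]))^2 + (py - (lp_y + t * seg[2]))^2 +
          (z - (lp_z + t * seg[3]))^2
    sl[d2 <= hr2] <- PHANTOM_LABELS["malleus"]
    d2lp <- (px - lp_x)^2 + (py - lp_y)^2 + (z - lp_z)^2
    sl[d2lp <= lpr2] <- PHANTOM_LABELS["malleus"]
    d2i <- (px - isj$center_mm["x"])^2 + (py - isj$center_mm["y"])^2 +
           (z - isj$center_mm["z"])^2
    sl[d2i <= isjr2] <- PHANTOM_LABELS["is_joint"]
    lab[, , k] <- sl
    rk <- matrix(1.0, ny, nx)
    for (nmlab in names(rho_tab))
      rk[sl == PHANTOM_LABELS[nmlab]] <- rho_tab[nmlab]
    if (!is.null(mass)) rk[sl == PHANTOM_LABELS["mass"]] <- mass_rho
    rho_map[, , k] <- rk
  }

  iy_um <- which.min(abs(yv - um_y)); ix_um <- which.min(abs(xv - um_x))
  iy_lp <- which.min(abs(yv - lp_y)); ix_lp <- which.min(abs(xv - lp_x))
  landmarks <- list(
    umbo = c(slow = iy_um, fast = ix_um,
             depth = z_index_at(unname(tm_inner_z[iy_um, ix_um]), dz)),
    malleus_lateral_process = c(slow = iy_lp, fast = ix_lp,
                                depth = z_index_at(lp_z, dz))
  )

  tm_inner_idx <- matrix(z_index_at(tm_inner_z, dz), ny, nx)
  prom_idx <- matrix(pmin(z_index_at(prom_z, dz), nz), ny, nx)
  mass_top_idx <- NULL
  if (!is.null(mass)) {
    mass_top_idx <- matrix(NA_integer_, ny, nx)
    ok <- !is.na(mass_top_z)
    mass_top_idx[ok] <- z_index_at(mass_top_z[ok], dz)
  }

  structure(list(
    label_map = structure(lab, labels = PHANTOM_LABELS),
    rho_map = rho_map,
    mass_mask = lab == PHANTOM_LABELS["mass"],
    landmarks = landmarks,
    tm_inner_surface = tm_inner_idx,
    prom_surface = prom_idx,
    mass_top_surface = mass_top_idx,
    gap_mm = if (!is.null(mass)) mass$gap_mm else NA_real_,
    class_preset = scene$class_preset,
    pixel_spacing = sp
  ), class = "phantom_truth")
}

#' Expected (speckle-free) intensity volume of a scene
#'
#' Per voxel, `mu = backscatter * exp(-2 * sum_above(attenuation * dz)) +
#' noise_floor`: single-backscatter Beer-Lambert depth attenuation of the
#' round-trip signal along each A-line (the attenuation sum excludes the
#' voxel itself), plus a constant additive noise floor. Deterministic given
#' the scene. Soft-tissue masses therefore shadow everything beneath them,
#' including the cochlear promontory.
#'
#' @param scene a `phantom_scene`.
#' @param components if TRUE return `list(mean = oct_volume,
#'   signal = array, noise_floor =, truth = phantom_truth)`; the signal/noise
#'   split is what the repeat-stack sampler needs.
#' @return `oct_volume` of expected linear intensity (or the component list).
#' @export
render_mean_intensity <- function(scene, components = FALSE) {
  truth <- phantom_truth(scene)
  gs <- scene$grid_shape; nz <- gs[3]; dz <- scene$pixel_spacing["z"]
  lab <- truth$label_map

  b_tab <- stats::setNames(scene$tissue$backscatter, scene$tissue$label)
  a_tab <- stats::setNames(scene$tissue$attenuation, scene$tissue$label)
  bs <- array(0, dim = gs); at <- array(0, dim = gs)
  for (nm in names(b_tab)) {
    sel <- lab == PHANTOM_LABELS[nm]
    bs[sel] <- b_tab[nm]; at[sel] <- a_tab[nm]
  }
  if (!is.null(scene$mass)) {
    sel <- lab == PHANTOM_LABELS["mass"]
    bs[sel] <- scene$mass$backscatter; at[sel] <- scene$mass$attenuation
  }

  # cumulative attenuation above each voxel, per A-line
  m <- matrix(at, ncol = nz)
  cs <- m
  for (k in seq_len(nz)[-1]) cs[, k] <- cs[, k - 1] + m[, k]
  trans <- exp(-2 * dz * (cs - m))            # excludes the voxel itself
  signal <- array(as.vector(matrix(bs, ncol = nz) * trans), dim = gs)

  mu <- oct_volume(signal + scene$noise_floor,
                   pixel_spacing = scene$pixel_spacing,
                   meta = list(preset = scene$class_preset, seed = scene$seed,
                               noise_floor = scene$noise_floor,
                               kind = "expected_intensity"))
  if (!components) return(mu)
  list(mean = mu, signal = signal, noise_floor = scene$noise_floor,
       truth = truth)
}

#' Draw one fully developed speckle realization of a mean-intensity volume
#'
#' Per voxel the detected intensity is `|E|^2` with `E` a zero-mean circular
#' complex Gaussian field of variance `mu`, i.e. intensity is exponentially
#' distributed with mean `mu` (fully developed speckle). Reproducible under a
#' fixed seed.
#'
#' @param mean_volume `oct_volume` (or bare array) of expected intensity,
#'   all values >= 0.
#' @param seed integer RNG seed.
#' @return `oct_volume` of speckled linear intensity.
#' @export
sample_speckle_volume <- function(mean_volume, seed = 1L) {
  mu <- if (inherits(mean_volume, "oct_volume")) mean_volume$data else mean_volume
  if (!is.array(mu) || length(dim(mu)) != 3L)
    stop("mean_volume must be a 3-D array or oct_volume")
  if (any(mu < 0)) stop("mean intensity must be non-negative")
  set.seed(as.integer(seed))
  I <- array(mu * stats::rexp(length(mu)), dim = dim(mu))
  sp <- if (inherits(mean_volume, "oct_volume")) mean_volume$pixel_spacing
        else c(y = 1, x = 1, z = 1)
  meta <- if (inherits(mean_volume, "oct_volume")) mean_volume$meta else list()
  meta$kind <- "structural"; meta$speckle_seed <- as.integer(seed)
  oct_volume(I, pixel_spacing = sp, meta = meta)
}

#' Sample consecutive B-scans with flow-dependent temporal decorrelation
#'
#' The complex field at each pixel follows a first-order autoregressive
#' process across repeats: `E_1 ~ CN(0, mu)`,
#' `E_(i+1) = rho * E_i + sqrt(1 - rho^2) * xi_i`, `xi_i ~ CN(0, mu)`, so the
#' lag-k field correlation is `rho^k` and the lag-k intensity correlation is
#' `rho^(2k)`. Static tissue (`rho = 1`) repeats identically; flowing blood
#' (`rho < 1`) decorrelates. An optional additive detection-noise field,
#' independent across repeats with variance `noise_floor`, models the system
#' noise floor (default 0: the pure AR(1) model).
#'
#' @param mean_bscan matrix (fast x depth) of per-pixel signal mean
#'   intensity, >= 0 (excluding the noise floor).
#' @param rho matrix of inter-repeat field correlations in `[0, 1]`, same
#'   shape as `mean_bscan` (a scalar is recycled).
#' @param n_repeats number of consecutive B-scans, >= 2.
#' @param seed integer RNG seed.
#' @param noise_floor additive noise-field intensity variance (>= 0).
#' @param slow_index slow-axis position tag carried into the stack.
#' @return An object of class `repeat_stack`: `data` is an
#'   `n_repeats x fast x depth` array of intensities.
#' @export
sample_repeat_stack <- function(mean_bscan, rho, n_repeats = 4L, seed = 1L,
                                noise_floor = 0, slow_index = 1L) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 2L)
    stop("n_repeats must be >= 2 (speckle variance is undefined otherwise)")
  mu <- as.matrix(mean_bscan)
  if (any(mu < 0)) stop("mean_bscan must be non-negative")
  if (length(rho) == 1L) rho <- matrix(rho, nrow(mu), ncol(mu))
  rho <- as.matrix(rho)
  if (!all(dim(rho) == dim(mu))) stop("rho must match mean_bscan in shape")
  if (any(rho < 0 | rho > 1)) stop("rho values must lie in [0, 1]")
  if (noise_floor < 0) stop("noise_floor must be >= 0")

  set.seed(as.integer(seed))
  npix <- length(mu)
  s <- sqrt(as.vector(mu) / 2)           # per-quadrature field SD
  sn <- sqrt(noise_floor / 2)
  r <- as.vector(rho); innov <- sqrt(1 - r^2)
  out <- array(0, dim = c(n_repeats, nrow(mu), ncol(mu)))

  Er <- s * stats::rnorm(npix); Ei <- s * stats::rnorm(npix)
  for (i in seq_len(n_repeats)) {
    if (i > 1L) {
      Er <- r * Er + innov * s * stats::rnorm(npix)
      Ei <- r * Ei + innov * s * stats::rnorm(npix)
    }
    if (noise_floor > 0) {
      nr <- sn * stats::rnorm(npix); ni <- sn * stats::rnorm(npix)
      out[i, , ] <- (Er + nr)^2 + (Ei + ni)^2
    } else {
      out[i, , ] <- Er^2 + Ei^2
    }
  }
  structure(list(data = out, n_repeats = n_repeats,
                 slow_index = as.integer(slow_index),
                 meta = list(seed = as.integer(seed),
                             noise_floor = noise_floor)),
            class = "repeat_stack")
}

#' @export
print.repeat_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<repeat_stack> %d repeats of %d x %d (fast x depth), slow=%d\n",
              d[1], d[2], d[3], x$slow_index))
  invisible(x)
}

#' Simulate one synthetic ear (structural volume + repeat stacks + truth)
#'
#' Derives independent sub-seeds for the scene jitter, the structural speckle
#' realization, and every slow position's repeat stack from the single ear
#' seed, so the whole ear is reproducible.
#'
#' @param preset clinical class preset.
#' @param seed integer ear seed.
#' @param grid_shape,fov_mm,n_repeats,jitter passed to [scene_preset()].
#' @param keep_stacks if FALSE, drop the repeat stacks and keep only the
#'   assembled speckle-variance volume (memory saver), see [speckle_variance()].
#' @param ear_id identifier carried into results.
#' @return An object of class `me_ear`: list with `ear_id`, `class_label`,
#'   `volume` (`oct_volume`), `stacks` (list of `repeat_stack` per slow
#'   position) or `sv_volume`, `truth`, `scene`.
#' @export
simulate_ear <- function(preset, seed = 1L,
                         grid_shape = c(32L, 96L, 192L),
                         fov_mm = c(y = 6, x = 8, z = 4),
                         n_repeats = 4L, jitter = TRUE,
                         keep_stacks = TRUE, ear_id = NULL) {
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max, size = 2L + grid_shape[1])
  scene <- scene_preset(preset, seed = sub[1], grid_shape = grid_shape,
                        fov_mm = fov_mm, n_repeats = n_repeats,
                        jitter = jitter)
  comp <- render_mean_intensity(scene, components = TRUE)
  vol <- sample_speckle_volume(comp$mean, seed = sub[2])
  vol$meta$ear_seed <- as.integer(seed)

  ny <- grid_shape[1]
  stacks <- vector("list", ny)
  for (iy in seq_len(ny)) {
    stacks[[iy]] <- sample_repeat_stack(
      comp$signal[iy, , ], comp$truth$rho_map[iy, , ],
      n_repeats = n_repeats, seed = sub[2L + iy],
      noise_floor = comp$noise_floor, slow_index = iy)
  }
  ear <- list(ear_id = ear_id %||% sprintf("%s_seed%d", preset, seed),
              class_label = preset, seed = as.integer(seed),
              volume = vol, stacks = stacks, truth = comp$truth,
              scene = scene)
  if (!keep_stacks) {
    ear$sv_volume <- assemble_angio_volume(stacks)
    ear$stacks <- NULL
  }
  structure(ear, class = "me_ear")
}

#' @export
print.me_ear <- function(x, ...) {
  cat(sprintf("<me_ear %s> class=%s seed=%d\n", x$ear_id, x$class_label,
              x$seed))
  invisible(x)
}

#' Simulate a cohort of synthetic ears
#'
#' Default arm sizes mirror the clinical study: 6 normal, 6 glomus,
#' 4 cholesteatoma, 1 schwannoma. Per-ear seeds are drawn deterministically
#' from the master seed, so the whole cohort reproduces under the same seed.
#'
#' @param presets named integer vector of per-class ear counts.
#' @param seed master RNG seed.
#' @param grid_shape per-ear voxel grid (slow, fast, depth).
#' @param n_repeats consecutive B-scans per slow position.
#' @param keep_stacks keep raw repeat stacks (see [simulate_ear()]).
#' @param fov_mm field of view, mm.
#' @return list of `me_ear` objects (class `me_cohort`).
#' @export
build_cohort <- function(presets = c(normal = 6L, glomus = 6L,
                                     cholesteatoma = 4L, schwannoma = 1L),
                         seed = 1L,
                         grid_shape = c(32L, 96L, 192L),
                         n_repeats = 4L, keep_stacks = FALSE,
                         fov_mm = c(y = 6, x = 8, z = 4)) {
  known <- c("normal", "glomus", "cholesteatoma", "schwannoma")
  if (is.null(names(presets)) || !all(names(presets) %in% known))
    stop("presets must be a named count vector over: ",
         paste(known, collapse = ", "))
  if (any(presets < 0)) stop("preset counts must be >= 0")
  total <- sum(presets)
  set.seed(as.integer(seed))
  ear_seeds <- sample.int(.Machine$integer.max, size = max(total, 1L))
  ears <- vector("list", total)
  i <- 0L
  for (cls in names(presets)) {
    for (k in seq_len(presets[[cls]])) {
      i <- i + 1L
      ears[[i]] <- simulate_ear(cls, seed = ear_seeds[i],
                                grid_shape = grid_shape, fov_mm = fov_mm,
                                n_repeats = n_repeats, jitter = TRUE,
                                keep_stacks = keep_stacks,
                                ear_id = sprintf("ear%02d_%s", i, cls))
    }
  }
  structure(ears, class = "me_cohort", master_seed = as.integer(seed))
}

#' @export
print.me_cohort <- function(x, ...) {
  cls <- vapply(x, function(e) e$class_label, character(1))
  cat(sprintf("<me_cohort> %d ears (%s), master seed %d\n", length(x),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                    collapse = ", "),
              attr(x, "master_seed")))
  invisible(x)
}
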