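# Speckle-variance OCT angiography.
#
# Flow contrast is the per-pixel temporal variance of linear intensity across
# N consecutive B-scans acquired at the same slow-axis position: static
# tissue keeps its speckle pattern from repeat to repeat (variance ~ 0),
# moving scatterers decorrelate it (variance ~ mean intensity squared).
# Variance is computed on linear intensity, never on log-compressed display
# values, which would conflate brightness with flow.

#' Speckle variance of a repeat stack
#'
#' Per pixel, `SV = (1/N) * sum_i (I_i - Ibar)^2` with `Ibar` the per-pixel
#' mean over the N repeats (population normalization; sample `1/(N-1)`
#' normalization available via `norm = "n-1"`). Computed as a centered
#' two-pass sum, so SV is exactly invariant to a constant intensity offset.
#'
#' @param stack a `repeat_stack` (or bare `n_repeats x rows x cols` array).
#' @param norm `"n"` (population, default) or `"n-1"` (sample).
#' @return An object of class `angiogram`: `sv` matrix in intensity^2 units
#'   on the same pixel grid as one B-scan, plus provenance.
#' @export
speckle_variance <- function(stack, norm = c("n", "n-1")) {
  norm <- match.arg(norm)
  a <- if (inherits(stack, "repeat_stack")) stack$data else stack
  if (!is.array(a) || length(dim(a)) != 3L)
    stop("stack must be an n_repeats x rows x cols array")
  n <- dim(a)[1]
  if (n < 2L) stop("speckle variance needs at least 2 repeats")
  ibar <- colMeans(a)                         # rows x cols
  dev2 <- sweep(a, c(2, 3), ibar, "-")^2
  denom <- if (norm == "n") n else n - 1L
  sv <- colSums(dev2) / denom
  structure(list(sv = sv, n_repeats = n, norm = norm,
                 slow_index = if (inherits(stack, "repeat_stack"))
                   stack$slow_index else NA_integer_),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("<angiogram> %d x %d, N=%d, norm=1/%s, slow=%s\n",
              nrow(x$sv), ncol(x$sv), x$n_repeats,
              if (x$norm == "n") "N" else "(N-1)",
              as.character(x$slow_index)))
  invisible(x)
}

#' Assemble per-position angiograms into a speckle-variance volume
#'
#' Stacks must cover contiguous, strictly increasing slow-axis positions;
#' gaps, duplicates, or shuffled order are rejected.
#'
#' @param stacks list of `repeat_stack` objects (one per slow position), or a
#'   list of `angiogram` objects.
#' @param norm passed to [speckle_variance()] when raw stacks are given.
#' @param pixel_spacing optional spacing carried into the volume metadata.
#' @return `oct_volume` whose data is SV (slow x fast x depth), with
#'   `meta$n_repeats` and `meta$kind = "speckle_variance"`.
#' @export
assemble_angio_volume <- function(stacks, norm = c("n", "n-1"),
                                  pixel_spacing = c(y = 1, x = 1, z = 1)) {
  norm <- match.arg(norm)
  if (length(stacks) == 0L) stop("no stacks supplied")
  angios <- lapply(stacks, function(s)
    if (inherits(s, "angiogram")) s else speckle_variance(s, norm = norm))
  idx <- vapply(angios, function(a) a$slow_index, integer(1))
  if (anyNA(idx)) stop("stacks must carry slow_index positions")
  if (anyDuplicated(idx)) stop("duplicate slow indices: ",
                               paste(idx[duplicated(idx)], collapse = ", "))
  if (any(diff(idx) != 1L))
    stop("slow indices must be contiguous and increasing; got: ",
         paste(idx, collapse = ", "))
  nrep <- unique(vapply(angios, function(a) a$n_repeats, integer(1)))
  if (length(nrep) != 1L) stop("stacks disagree on n_repeats")
  d <- dim(angios[[1]]$sv)
  vol <- array(0, dim = c(length(angios), d[1], d[2]))
  for (i in seq_along(angios)) {
    if (!all(dim(angios[[i]]$sv) == d))
      stop("stack at slow index ", idx[i], " has mismatched B-scan shape")
    vol[i, , ] <- angios[[i]]$sv
  }
  oct_volume(vol, pixel_spacing = pixel_spacing,
             meta = list(kind = "speckle_variance", n_repeats = nrep,
                         norm = norm, slow_range = range(idx)))
}

#' En-face projection of a speckle-variance volume
#'
#' Mean (default) or maximum projection of SV over an inclusive depth window
#' `[z_lo, z_hi]` (1-based indices).
#'
#' @param sv_volume `oct_volume` of SV (or bare slow x fast x depth array).
#' @param z_lo,z_hi inclusive depth window, `1 <= z_lo <= z_hi <= depth`.
#' @param reduce `"mean"` (default) or `"max"`.
#' @return matrix (slow x fast) SV map.
#' @export
angio_enface <- function(sv_volume, z_lo, z_hi, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  a <- if (inherits(sv_volume, "oct_volume")) sv_volume$data else sv_volume
  nz <- dim(a)[3]
  z_lo <- as.integer(z_lo); z_hi <- as.integer(z_hi)
  if (z_lo < 1L || z_hi > nz || z_lo > z_hi)
    stop(sprintf("depth window [%d, %d] invalid for depth %d", z_lo, z_hi, nz))
  sub <- a[, , z_lo:z_hi, drop = FALSE]
  if (reduce == "mean") rowMeans(sub, dims = 2)
  else apply(sub, c(1, 2), max)
}

#' Overlay an angiography map on a structural en-face image
#'
#' Grayscale structural base with pixels whose SV exceeds a threshold tinted
#' red, tint strength proportional to SV above the threshold. The default
#' threshold is the 95th percentile of SV within a supplied static-tissue
#' mask (self-normalizing; typically the TM region of the same volume).
#'
#' @param enface_structural matrix, structural base (any non-negative scale).
#' @param enface_angio matrix of SV, same shape.
#' @param threshold SV tint threshold; if NULL, computed from `static_mask`.
#' @param static_mask logical matrix marking static reference tissue, used
#'   only when `threshold` is NULL.
#' @param quantile percentile used for the mask-derived threshold.
#' @return `height x width x 3` RGB array in `[0, 1]`, with the threshold in
#'   `attr(, "threshold")`.
#' @export
angio_overlay <- function(enface_structural, enface_angio, threshold = NULL,
                          static_mask = NULL, quantile = 0.95) {
  if (!all(dim(enface_structural) == dim(enface_angio)))
    stop("structural and angiography maps must share the same shape")
  if (is.null(threshold)) {
    if (is.null(static_mask))
      stop("supply either a threshold or a static_mask to derive one")
    if (!all(dim(static_mask) == dim(enface_angio)))
      stop("static_mask must match the image shape")
    threshold <- stats::quantile(enface_angio[static_mask], quantile,
                                 names = FALSE)
  }
  base <- enface_structural / max(enface_structural, 1e-300)
  svmax <- max(enface_angio)
  t <- if (svmax > 0) pmin(enface_angio / svmax, 1)
       else matrix(0, nrow(enface_angio), ncol(enface_angio))
  t[enface_angio <= threshold] <- 0
  rgb <- array(0, dim = c(nrow(base), ncol(base), 3))
  rgb[, , 1] <- base + (1 - base) * t
  rgb[, , 2] <- base * (1 - t)
  rgb[, , 3] <- base * (1 - t)
  attr(rgb, "threshold") <- threshold
  rgb
}
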