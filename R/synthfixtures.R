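# Synthetic fixtures with known ground truth. A thresholded Gaussian random
# field emulates trabecular bone (controllable volume fraction and strut
# scale); analytic plate and bar-pattern phantoms provide exact references
# for morphometry and spatial-resolution analysis. These stand in for
# cadaver, clinical and physical-phantom scans, which cannot be shipped.

#' Specification for a synthetic trabecular volume
#'
#' @param extents 3 positive integers (slice, row, col).
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param target_bvtv bone volume fraction in (0, 1); enforced by quantile
#'   thresholding of the random field, so the realized fraction is within one
#'   quantile step.
#' @param feature_scale_um characteristic strut thickness in micrometres;
#'   the field is smoothed with kernel sd `feature_scale_um/voxel_size_um/2`.
#' @param bone_level,background_level grayscale levels in `[0,1]`,
#'   `bone_level > background_level`.
#' @param noise_sd additive Gaussian noise sd (float01 units).
#' @param blur_sd_vox grayscale blur sd in voxels applied before noise.
#' @param seed integer seed; equal seeds give bit-identical volumes.
#' @return a `trabecular_spec` list.
#' @export
trabecular_spec <- function(extents = c(64, 64, 64), voxel_size_um = 50,
                            target_bvtv = 0.3, feature_scale_um = 150,
                            bone_level = 0.8, background_level = 0.2,
                            noise_sd = 0.05, blur_sd_vox = 0.5, seed = 1L) {
  extents <- as.integer(rep(extents, length.out = 3L))
  if (any(extents < 1L)) stop("extents must be positive")
  assert_scalar_num(voxel_size_um, "voxel_size_um", positive = TRUE)
  if (target_bvtv <= 0 || target_bvtv >= 1)
    stop("target_bvtv must be strictly inside (0, 1)")
  assert_scalar_num(feature_scale_um, "feature_scale_um", positive = TRUE)
  if (bone_level <= background_level)
    stop("bone_level must exceed background_level")
  if (noise_sd < 0 || blur_sd_vox < 0) stop("noise/blur sds must be >= 0")
  structure(list(extents = extents, voxel_size_um = voxel_size_um,
                 target_bvtv = target_bvtv, feature_scale_um = feature_scale_um,
                 bone_level = bone_level, background_level = background_level,
                 noise_sd = noise_sd, blur_sd_vox = blur_sd_vox,
                 seed = as.integer(seed)),
            class = "trabecular_spec")
}

#' Generate a synthetic trabecular volume with known morphometry
#'
#' White noise is smoothed with a Gaussian of sd
#' `feature_scale_um / voxel_size_um / 2` voxels and thresholded at the
#' `1 - target_bvtv` quantile; the binary microstructure is rendered at the
#' bone/background grayscale levels, blurred, and corrupted with Gaussian
#' noise, then clipped to `[0, 1]`.
#'
#' @param spec a [trabecular_spec()].
#' @param thickness_reference also compute Tb.Th/Tb.Sp of the clean mask via
#'   [local_thickness()] (self-consistent reference; no closed form exists
#'   for random fields). Default TRUE.
#' @return list with `volume` (float01 [new_volume()]) and `ground_truth`
#'   (list: `mask`, `bvtv` = exact foreground fraction, `tbth_um`, `tbsp_um`).
#' @export
make_trabecular <- function(spec, thickness_reference = TRUE) {
  stopifnot(inherits(spec, "trabecular_spec"))
  field_sd <- spec$feature_scale_um / spec$voxel_size_um / 2
  if (min(spec$extents) < 4 * field_sd)
    stop("extents too small to support feature_scale_um at this voxel size")
  out <- with_seed(spec$seed, {
    field <- array(rnorm(prod(spec$extents)), spec$extents)
    field <- gaussian_blur(field, field_sd)
    thr <- quantile(field, 1 - spec$target_bvtv, names = FALSE)
    mask <- field > thr
    gray <- spec$background_level +
      (spec$bone_level - spec$background_level) * mask
    if (spec$blur_sd_vox > 0) gray <- gaussian_blur(gray, spec$blur_sd_vox)
    if (spec$noise_sd > 0)
      gray <- gray + array(rnorm(length(gray), sd = spec$noise_sd), dim(gray))
    list(mask = mask, gray = clip01(gray))
  })
  gt <- list(mask = out$mask, bvtv = mean(out$mask))
  if (thickness_reference) {
    gt$tbth_um <- mean_thickness(out$mask, "foreground", spec$voxel_size_um)
    gt$tbsp_um <- mean_thickness(out$mask, "background", spec$voxel_size_um)
  }
  vol <- new_volume(out$gray, spec$voxel_size_um, "float01",
                    meta = list(modality = "synthetic_trabecular",
                                seed = spec$seed,
                                target_bvtv = spec$target_bvtv))
  list(volume = vol, ground_truth = gt)
}

#' Parallel-plate phantom with analytic thickness and separation
#'
#' Slabs normal to the slice axis: `plate_thickness_vox` foreground slices
#' followed by `gap_vox` background slices, repeating.
#'
#' @param plate_thickness_vox,gap_vox slab and gap extents in voxels (>= 1).
#' @param extents volume extents (slice, row, col); the slice extent should
#'   be a multiple of the period for exact volume fractions.
#' @param voxel_size_um voxel size in micrometres.
#' @param bone_level,background_level grayscale levels.
#' @return list with `volume` and `ground_truth` (`mask`, `bvtv`,
#'   `tbth_um = thickness * voxel`, `tbsp_um = gap * voxel`).
#' @export
make_plate_phantom <- function(plate_thickness_vox, gap_vox,
                               extents = c(48, 32, 32), voxel_size_um = 50,
                               bone_level = 0.8, background_level = 0.2) {
  t <- as.integer(plate_thickness_vox); g <- as.integer(gap_vox)
  if (t < 1L || g < 1L) stop("thickness and gap must be >= 1 voxel")
  extents <- as.integer(rep(extents, length.out = 3L))
  if (extents[1] < t + g) stop("plate pattern does not fit the slice extent")
  # start with half a gap so no plate touches a volume face: face half-gaps
  # then read like interior gaps and the thickness map is exact everywhere
  off <- ((t + g) - g %/% 2L) %% (t + g)
  phase <- ((seq_len(extents[1]) - 1L + off) %% (t + g)) < t
  mask <- array(rep(phase, times = prod(extents[2:3])), extents)
  gray <- background_level + (bone_level - background_level) * mask
  vol <- new_volume(gray, voxel_size_um, "float01",
                    meta = list(modality = "plate_phantom"))
  gt <- list(mask = mask, bvtv = mean(mask), tbth_um = t * voxel_size_um,
             tbsp_um = g * voxel_size_um)
  list(volume = vol, ground_truth = gt)
}

#' Specification for a line-pair quality-assurance phantom
#'
#' Six bar-pattern groups at the given spatial frequencies (line pairs per
#' centimetre; one line pair = one bar + one gap), plus uniform material
#' inserts and a uniform noise region, are laid out as horizontal bands with
#' bars modulating along the column axis. Default frequencies are six
#' geometrically spaced groups over 2-10 lp/cm, bracketing the 3.5-8.3 lp/cm
#' range where clinical CBCT resolving power lives.
#'
#' @param pixel_size_um in-plane pixel size in micrometres.
#' @param group_frequencies_lp_per_cm strictly increasing, length 6 by
#'   default; every bar period must span at least 2 pixels.
#' @param bar_level,background_level bar and gap grayscale levels.
#' @param uniform_inserts data.frame with columns `label`, `level`; the first
#'   two rows are the material pair used for MTF normalization.
#' @param slices number of identical slices (noise varies per slice).
#' @param noise_sd per-slice additive Gaussian noise sd.
#' @param band_px band height in pixels; `width_px` image width.
#' @param seed integer seed.
#' @return a `line_pair_spec` list.
#' @export
line_pair_spec <- function(pixel_size_um = 200,
                           group_frequencies_lp_per_cm =
                             round(2 * (10 / 2)^((0:5) / 5), 2),
                           bar_level = 0.8, background_level = 0.2,
                           uniform_inserts = data.frame(
                             label = c("materialA", "materialB"),
                             level = c(0.8, 0.2)),
                           slices = 8L, noise_sd = 0, band_px = 14L,
                           width_px = 128L, seed = 1L) {
  f <- group_frequencies_lp_per_cm
  if (any(diff(f) <= 0)) stop("group frequencies must be strictly increasing")
  period_px <- 10000 / (f * pixel_size_um)
  if (any(period_px < 2))
    stop("bar period below 2 pixels: frequency not representable")
  if (nrow(uniform_inserts) < 2L)
    stop("need at least two uniform inserts (the material pair)")
  structure(list(pixel_size_um = pixel_size_um,
                 group_frequencies_lp_per_cm = f, bar_level = bar_level,
                 background_level = background_level,
                 uniform_inserts = uniform_inserts, slices = as.integer(slices),
                 noise_sd = noise_sd, band_px = as.integer(band_px),
                 width_px = as.integer(width_px), seed = as.integer(seed)),
            class = "line_pair_spec")
}

# Exact pixel coverage of the bar phase of a 50%-duty square wave of period p
# (pixel units) over [a, b): bars occupy the first half of each period.
bar_coverage <- function(a, b, p) {
  Fn <- function(u) floor(u / p) * (p / 2) + pmin(u %% p, p / 2)
  (Fn(b) - Fn(a)) / (b - a)
}

#' Render a line-pair phantom volume
#'
#' Bar groups are rendered with exact pixel-area integration (boundary pixels
#' take partial values), which is what makes the standard-deviation MTF
#' readout analytically predictable.
#'
#' @param spec a [line_pair_spec()].
#' @return list with `volume` (float01), `rois` (a `roi_set`: per-group ROIs
#'   covering whole periods, material ROIs, noise ROI) and `spec`.
#' @export
make_line_pair_phantom <- function(spec) {
  stopifnot(inherits(spec, "line_pair_spec"))
  f <- spec$group_frequencies_lp_per_cm
  ng <- length(f)
  bands <- ng + nrow(spec$uniform_inserts) + 1L  # groups + inserts + noise
  H <- bands * spec$band_px
  W <- spec$width_px
  img <- matrix(spec$background_level, H, W)
  inset <- 2L
  rois <- list(groups = vector("list", ng))
  period_px <- 10000 / (f * spec$pixel_size_um)
  for (g in seq_len(ng)) {
    r0 <- (g - 1L) * spec$band_px + 1L
    rows <- (r0 + inset):(r0 + spec$band_px - 1L - inset)
    p <- period_px[g]
    nper <- max(1L, floor((W - 2L * inset) / p))
    allcols <- (inset + 1L):W
    # pattern phase starts at column inset+1; exact pixel-area coverage
    cov <- bar_coverage(allcols - 1L - inset, allcols - inset, p)
    img[rows, allcols] <- rep(
      spec$background_level + (spec$bar_level - spec$background_level) * cov,
      each = length(rows))
    # ROI spans a whole number of periods so the sd readout is unbiased
    roi_cols <- c(inset + 1L, inset + floor(nper * p))
    rois$groups[[g]] <- list(rows = range(rows), cols = roi_cols,
                             freq_lp_cm = f[g])
  }
  rois$materials <- vector("list", nrow(spec$uniform_inserts))
  for (m in seq_len(nrow(spec$uniform_inserts))) {
    r0 <- (ng + m - 1L) * spec$band_px + 1L
    rows <- (r0 + inset):(r0 + spec$band_px - 1L - inset)
    img[rows, ] <- spec$uniform_inserts$level[m]
    rois$materials[[m]] <- list(rows = range(rows), cols = c(inset + 1L, W - inset),
                                label = spec$uniform_inserts$label[m],
                                level = spec$uniform_inserts$level[m])
  }
  r0 <- (bands - 1L) * spec$band_px + 1L
  rows <- (r0 + inset):(r0 + spec$band_px - 1L - inset)
  rois$noise <- list(rows = range(rows), cols = c(inset + 1L, W - inset))
  class(rois) <- "roi_set"

  data <- with_seed(spec$seed, {
    a <- array(0, c(spec$slices, H, W))
    for (s in seq_len(spec$slices)) {
      sl <- img
      if (spec$noise_sd > 0)
        sl <- sl + matrix(rnorm(length(sl), sd = spec$noise_sd), H, W)
      a[s, , ] <- sl
    }
    clip01(a)
  })
  vol <- new_volume(data, spec$pixel_size_um, "float01",
                    meta = list(modality = "line_pair_phantom"))
  list(volume = vol, rois = rois, spec = spec)
}

#' Slanted high-contrast edge phantom
#'
#' A binary step whose boundary makes `angle_deg` with the column axis,
#' rendered with linearized pixel-area coverage; an alternative fixture for
#' edge-based resolution estimation.
#'
#' @param angle_deg edge tilt in degrees (0 = vertical step).
#' @param levels two distinct grayscale levels (left, right).
#' @param extents (slice, row, col) extents.
#' @param edge_col column position of the edge at the image's vertical centre.
#' @return a float01 volume.
#' @export
make_edge_phantom <- function(angle_deg = 3, levels = c(0.2, 0.8),
                              extents = c(1, 64, 64), edge_col = NULL) {
  if (length(levels) != 2L || levels[1] == levels[2])
    stop("need two distinct levels")
  extents <- as.integer(rep(extents, length.out = 3L))
  H <- extents[2]; W <- extents[3]
  if (is.null(edge_col)) edge_col <- W / 2
  tn <- tan(angle_deg * pi / 180)
  rowc <- seq_len(H) - 0.5
  colc <- seq_len(W) - 0.5
  # signed distance of each pixel centre from the edge, in pixels
  dmat <- outer(rowc, colc, function(y, x) x - (edge_col + tn * (y - H / 2)))
  cov <- pmin(1, pmax(0, dmat + 0.5))  # coverage of the "right" phase
  img <- levels[1] + (levels[2] - levels[1]) * cov
  data <- aperm(array(img, c(H, W, extents[1])), c(3, 1, 2))
  new_volume(clip01(data), 1, "float01",
             meta = list(modality = "edge_phantom", angle_deg = angle_deg,
                         edge_col = edge_col))
}
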