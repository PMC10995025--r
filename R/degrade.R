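# Training-pair synthesis: the two-stage degradation cascade (resample the
# high-resolution scan to the target grid, then degrade it by a factor of
# four to make the network input), patch tiling, and patient-grouped
# cross-validation splits.

#' A fixed x4 resolution cascade
#'
#' @param input_um,target_um voxel sizes of the degraded network input and
#'   the high-resolution target; `input_um` must equal `4 * target_um`.
#'   Named presets: "200to50", "400to100", "488to122".
#' @return a `resolution_cascade` list with fields `input_um`, `target_um`,
#'   `factor = 4`.
#' @export
resolution_cascade <- function(input_um = NULL, target_um = NULL) {
  if (is.character(input_um)) {
    preset <- match.arg(input_um, c("200to50", "400to100", "488to122"))
    v <- switch(preset, "200to50" = c(200, 50), "400to100" = c(400, 100),
                "488to122" = c(488, 122))
    input_um <- v[1]; target_um <- v[2]
  }
  if (abs(input_um - 4 * target_um) > 1e-9)
    stop("cascade requires input_um = 4 * target_um")
  structure(list(input_um = input_um, target_um = target_um, factor = 4L),
            class = "resolution_cascade")
}

#' Resample a high-resolution volume to the cascade's target grid
#'
#' Linear anti-aliased resampling per axis to `target_um`, followed by a
#' Gaussian filter (kernel size 7, sd 0.5 voxels) to mitigate residual
#' aliasing. Output extents are `round(n * voxel_in / target_um)` per axis.
#'
#' @param hr a volume with voxel size <= `target_um` on every axis.
#' @param cascade a [resolution_cascade()].
#' @return the target-resolution volume (float01 convention preserved).
#' @export
make_target <- function(hr, cascade) {
  stopifnot(is_volume(hr), inherits(cascade, "resolution_cascade"))
  if (any(hr$voxel_size_um > cascade$target_um + 1e-9))
    stop("make_target only downsamples: input is coarser than the target grid")
  d <- dim(hr$data)
  new_d <- pmax(1L, as.integer(round(d * hr$voxel_size_um / cascade$target_um)))
  x <- hr$data
  # gaussian pre-blur per axis for anti-aliasing, then linear interpolation
  down <- d / new_d
  x <- gaussian_blur(x, pmax(0, (down - 1) / 2))
  x <- resample_array(x, new_d, method = "linear", antialias = FALSE)
  x <- gaussian_blur(x, 0.5, size = 7L)
  if (hr$dtype_tag == "float01") x <- clip01(x)
  new_volume(x, cascade$target_um, hr$dtype_tag, hr$meta)
}

#' Degrade a target volume into the matching network input
#'
#' Downscale by exactly four (block averaging), Gaussian blur (sd 1.0
#' voxels), then median filtering (kernel size 3), simulating the lower
#' clinical imaging quality. In 2D mode the degradation acts in-plane only
#' (per axial slice); in 3D mode on all axes.
#'
#' @param target a volume at the cascade's target resolution.
#' @param dims 2 (in-plane, per slice) or 3.
#' @return the input-resolution volume; extents `floor(n / 4)` on degraded
#'   axes.
#' @export
make_input <- function(target, dims = 3L) {
  stopifnot(is_volume(target), dims %in% c(2L, 3L))
  axes <- if (dims == 3L) 1:3 else 2:3
  d <- dim(target$data)
  if (any(d[axes] < 4L)) stop("target extents must be >= 4 on degraded axes")
  x <- block_average(target$data, 4L, axes)
  if (dims == 3L) {
    x <- gaussian_blur(x, 1.0, size = 5L)
    x <- median_filter(x, 3L)
  } else {
    for (s in seq_len(dim(x)[1])) {
      sl <- x[s, , ]
      sl <- gaussian_blur(sl, 1.0, size = 5L)
      x[s, , ] <- median_filter(sl, 3L)
    }
  }
  if (target$dtype_tag == "float01") x <- clip01(x)
  vox <- target$voxel_size_um
  vox[axes] <- vox[axes] * 4
  new_volume(x, vox, target$dtype_tag, target$meta)
}

#' Tile a co-registered (input, target) volume pair into patch pairs
#'
#' In 3D mode patches are cubes (`patch_lr`^3 against `(4*patch_lr)`^3); in
#' 2D mode per-slice squares. The target grid must be four times the input
#' grid on tiled axes; in 2D mode the slice counts must either match
#' (in-plane degradation) or differ by a factor four, in which case input
#' slice s pairs with the centre target slice `4*(s-1)+2`.
#'
#' @param lr,hr input- and target-resolution volumes.
#' @param patch_lr input patch side (default 32).
#' @param stride tiling stride on the input grid; default `patch_lr`
#'   (non-overlapping partition).
#' @param dims 2 or 3.
#' @param sample_id,patient_id provenance identifiers attached to every pair.
#' @return list of `patch_pair` objects with fields `lr`, `hr`, `sample_id`,
#'   `patient_id`, `origin` (input-grid offset, 1-based).
#' @export
tile_patches <- function(lr, hr, patch_lr = 32L, stride = patch_lr,
                         dims = 3L, sample_id = "s1", patient_id = "p1") {
  stopifnot(is_volume(lr), is_volume(hr), dims %in% c(2L, 3L))
  dl <- dim(lr$data); dh <- dim(hr$data)
  ph <- 4L * patch_lr
  pairs <- list()
  starts <- function(n, w) if (n < w) integer(0) else seq(1L, n - w + 1L, by = stride)
  if (dims == 3L) {
    if (!all(dh == 4L * dl)) stop("misaligned pair: hr extents must be 4 x lr")
    for (z in starts(dl[1], patch_lr)) for (y in starts(dl[2], patch_lr))
      for (x in starts(dl[3], patch_lr)) {
        hz <- 4L * (z - 1L) + 1L; hy <- 4L * (y - 1L) + 1L; hx <- 4L * (x - 1L) + 1L
        pairs[[length(pairs) + 1L]] <- patch_pair(
          lr$data[z:(z + patch_lr - 1L), y:(y + patch_lr - 1L),
                  x:(x + patch_lr - 1L)],
          hr$data[hz:(hz + ph - 1L), hy:(hy + ph - 1L), hx:(hx + ph - 1L)],
          sample_id, patient_id, c(z, y, x))
      }
  } else {
    if (!all(dh[2:3] == 4L * dl[2:3]))
      stop("misaligned pair: hr in-plane extents must be 4 x lr")
    if (!(dh[1] == dl[1] || dh[1] == 4L * dl[1]))
      stop("misaligned pair: slice counts must match or differ by factor 4")
    for (s in seq_len(dl[1])) {
      hs <- if (dh[1] == dl[1]) s else 4L * (s - 1L) + 2L
      for (y in starts(dl[2], patch_lr)) for (x in starts(dl[3], patch_lr)) {
        hy <- 4L * (y - 1L) + 1L; hx <- 4L * (x - 1L) + 1L
        pairs[[length(pairs) + 1L]] <- patch_pair(
          lr$data[s, y:(y + patch_lr - 1L), x:(x + patch_lr - 1L)],
          hr$data[hs, hy:(hy + ph - 1L), hx:(hx + ph - 1L)],
          sample_id, patient_id, c(s, y, x))
      }
    }
  }
  pairs
}

#' Construct a patch pair
#'
#' @param lr,hr input and target patches (matrix for 2D, 3D array for 3D);
#'   hr extents must be four times lr extents.
#' @param sample_id,patient_id provenance.
#' @param origin input-grid offset.
#' @return a `patch_pair`.
#' @export
patch_pair <- function(lr, hr, sample_id = "s1", patient_id = "p1",
                       origin = NULL) {
  lr <- as.array(lr); hr <- as.array(hr)
  if (!all(dim(hr) == 4L * dim(lr)))
    stop("hr patch extents must be 4 x lr patch extents")
  structure(list(lr = lr, hr = hr, sample_id = sample_id,
                 patient_id = patient_id, origin = origin),
            class = "patch_pair")
}

#' Patient-grouped k-fold splits
#'
#' Every patient's patches land in exactly one validation fold; patients are
#' shuffled with the seed and dealt round-robin, so fold patient counts are
#' balanced within one.
#'
#' @param pairs list of `patch_pair` objects.
#' @param k number of folds.
#' @param seed integer seed for the patient shuffle.
#' @return list of k splits, each `list(train = idx, val = idx)`.
#' @export
grouped_kfold <- function(pairs, k = 4L, seed = 1L) {
  pid <- vapply(pairs, function(p) as.character(p$patient_id), character(1))
  patients <- unique(pid)
  if (length(patients) < k)
    stop("fewer distinct patients (", length(patients), ") than folds (", k, ")")
  shuffled <- with_seed(seed, sample(patients))
  fold_of <- setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  lapply(seq_len(k), function(f) {
    val <- unname(which(fold_of[pid] == f))
    list(train = setdiff(seq_along(pairs), val), val = val)
  })
}
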