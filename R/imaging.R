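#' Construct a CT volume
#'
#' Wraps a 3D intensity array together with its voxel spacing. The third
#' array dimension is the axial (slice) axis. Intensities are Hounsfield
#' units before windowing with [clip_rescale_hu()], and 8-bit integers in
#' `[0, 255]` afterwards.
#'
#' @param intensities numeric 3D array.
#' @param voxel_spacing numeric length-3, (x, y, z) spacing in mm; all > 0.
#' @param windowed logical; `TRUE` once intensities are 8-bit values.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(intensities, voxel_spacing = c(1, 1, 1), windowed = FALSE) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (length(intensities) == 0L)
    stop("empty volume")
  storage.mode(intensities) <- "double"
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be three positive values (mm)")
  if (windowed && (any(intensities < 0) || any(intensities > 255) ||
                   any(intensities != floor(intensities))))
    stop("windowed volumes must hold integers in [0, 255]")
  structure(list(intensities = intensities,
                 voxel_spacing = voxel_spacing,
                 windowed = windowed),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %s\n",
              d[1], d[2], d[3], x$voxel_spacing[1], x$voxel_spacing[2],
              x$voxel_spacing[3],
              if (x$windowed) "windowed [0,255]" else "Hounsfield units"))
  invisible(x)
}

#' Window Hounsfield units to 8-bit bone range
#'
#' Clips CT intensities to `[-10, 1000]` HU (highlighting bone) and rescales
#' linearly to integers in `[0, 255]`: `v -> round((clip(v) + 10) / 1010 * 255)`
#' with half-up rounding.
#'
#' @param volume a `ct_volume` in Hounsfield units.
#' @return A windowed `ct_volume` with integer intensities in `[0, 255]`.
#' @export
clip_rescale_hu <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- pmin(pmax(volume$intensities, -10), 1000)
  out <- round_half_up((v + 10) / 1010 * 255)
  ct_volume(out, volume$voxel_spacing, windowed = TRUE)
}

#' Axial maximum intensity projection stack
#'
#' Partitions the axial slices into consecutive non-overlapping slabs of
#' `ceiling(thickness_mm / z_spacing)` slices (the last slab may be partial;
#' it is kept so no slice is lost) and takes the per-pixel maximum over each
#' slab. An optional slice range restricts the projection to a manually
#' identified pelvic region.
#'
#' @param volume a `ct_volume`.
#' @param thickness_mm slab thickness in mm; must be at least the z spacing.
#' @param slice_range optional integer `c(first, last)` (1-based, inclusive)
#'   axial crop applied before projecting.
#' @return A `mip_stack`: list of 2D slices plus slab metadata.
#' @export
axial_mip <- function(volume, thickness_mm = 8, slice_range = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  zsp <- volume$voxel_spacing[3]
  if (thickness_mm < zsp)
    stop("`thickness_mm` must be >= the axial voxel spacing")
  x <- volume$intensities
  if (!is.null(slice_range)) {
    slice_range <- as.integer(slice_range)
    if (length(slice_range) != 2L || slice_range[1] < 1L ||
        slice_range[2] > dim(x)[3] || slice_range[1] > slice_range[2])
      stop("invalid `slice_range`")
    x <- x[, , slice_range[1]:slice_range[2], drop = FALSE]
  }
  slab <- as.integer(ceiling(thickness_mm / zsp))
  nz <- dim(x)[3]
  groups <- split(seq_len(nz), (seq_len(nz) - 1L) %/% slab)
  slices <- lapply(groups, function(idx) {
    apply(x[, , idx, drop = FALSE], c(1, 2), max)
  })
  names(slices) <- NULL
  structure(list(slices = slices,
                 slab_thickness_mm = thickness_mm,
                 slab_size = slab,
                 source_spacing = volume$voxel_spacing),
            class = "mip_stack")
}

#' @export
print.mip_stack <- function(x, ...) {
  cat(sprintf("<mip_stack> %d slices of %d x %d px (%g mm slabs, %d source slices each)\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$slab_thickness_mm, x$slab_size))
  invisible(x)
}

#' Intensity augmentation parameters
#'
#' A mild photometric perturbation of a windowed scan: contrast scaling about
#' mid-gray followed by an additive intensity shift. The identity is
#' `(shift = 0, contrast = 1)`.
#'
#' @param intensity_shift integer shift in 8-bit intensity units.
#' @param contrast_factor positive contrast multiplier.
#' @export
augmentation_params <- function(intensity_shift = 0L, contrast_factor = 1.0) {
  if (!is.finite(contrast_factor) || contrast_factor <= 0)
    stop("`contrast_factor` must be > 0")
  if (intensity_shift != round(intensity_shift))
    stop("`intensity_shift` must be an integer")
  structure(list(intensity_shift = as.integer(intensity_shift),
                 contrast_factor = as.numeric(contrast_factor)),
            class = "augmentation_params")
}

#' Apply a photometric augmentation to a windowed volume
#'
#' Computes `clip(round(127.5 + c * (v - 127.5)) + s, 0, 255)` with half-up
#' rounding: contrast about mid-gray, then additive shift, then clipping.
#'
#' @param volume a windowed `ct_volume`.
#' @param params an `augmentation_params` object.
#' @return The augmented windowed `ct_volume`.
#' @export
apply_augmentation <- function(volume, params) {
  stopifnot(inherits(volume, "ct_volume"), inherits(params, "augmentation_params"))
  if (!volume$windowed)
    stop("volume must be windowed to [0, 255] before augmentation")
  v <- round_half_up(127.5 + params$contrast_factor * (volume$intensities - 127.5))
  v <- pmin(pmax(v + params$intensity_shift, 0), 255)
  ct_volume(v, volume$voxel_spacing, windowed = TRUE)
}

#' The self-ensembling augmentation grid
#'
#' The Cartesian product of intensity shifts `{-2, -1, 0, 1, 2}` (8-bit
#' units) and contrast factors `{0.8, 0.9, 1.0, 1.1, 1.2}`: 25 augmented
#' scans in fixed lexicographic order (shift slow, contrast fast). The
#' identity cell `(0, 1.0)` serves as the original scan.
#'
#' @param shifts,contrasts override the default grids.
#' @return A data.frame with columns `augmentation_id` (0-based),
#'   `intensity_shift`, `contrast_factor`.
#' @export
augmentation_grid <- function(shifts = c(-2L, -1L, 0L, 1L, 2L),
                              contrasts = c(0.8, 0.9, 1.0, 1.1, 1.2)) {
  g <- expand.grid(contrast_factor = contrasts, intensity_shift = shifts,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(augmentation_id = seq_len(nrow(g)) - 1L,
             intensity_shift = as.integer(g$intensity_shift),
             contrast_factor = g$contrast_factor)
}

#' Read / write a CT volume as NIfTI
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param windowed whether the stored intensities are already 8-bit.
#' @return `read_nifti_volume()` returns a `ct_volume`.
#' @export
read_nifti_volume <- function(path, windowed = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(arr, sp, windowed = windowed)
}

#' @rdname read_nifti_volume
#' @param volume a `ct_volume` to write.
#' @export
write_nifti_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$voxel_spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
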