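#' Construct a 3D left-ventricle mask stack
#'
#' A `mask_stack` couples a binary 3D voxel array, indexed (slice z, row y,
#' column x), with its physical voxel spacing. Volumes derived from it are in
#' microlitres (1 mm^3 = 1 uL).
#'
#' @param voxels 3D array of 0/1 (or logical) values, dimension order (z, y, x).
#' @param spacing_mm Numeric length-3, voxel spacing (dz, dy, dx) in mm.
#'   Defaults to the acquisition resolution 1.5 x 0.5 x 0.5 mm.
#' @param label Free-text identifier carried through reports.
#' @return An object of class `mask_stack`.
#' @export
#' @examples
#' m <- mask_stack(array(0L, c(4, 8, 8)))
#' lv_volume(m)
mask_stack <- function(voxels, spacing_mm = c(1.5, 0.5, 0.5), label = "") {
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  if (length(dim(voxels)) != 3) stopf("mask voxels must be a 3D array")
  if (any(!is.finite(voxels)) || !is_binary(voxels))
    stopf("mask voxel values must all be 0 or 1")
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stopf("spacing_mm must be 3 positive numbers (dz, dy, dx)")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 label = as.character(label)),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("<mask_stack '%s'> %s voxels @ (%.3g, %.3g, %.3g) mm, %d foreground (%.1f uL)\n",
              x$label, paste(dim(x$voxels), collapse = "x"),
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              sum(x$voxels), lv_volume(x)))
  invisible(x)
}

# Validate a probability map (plain 3D array in [0,1]).
check_prob_map <- function(values) {
  if (length(dim(values)) != 3) stopf("probability map must be a 3D array")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stopf("probability map values must lie in [0, 1]")
  invisible(values)
}

#' Construct a cine series
#'
#' A `cine_series` is a temporally ordered set of cardiac phases for one
#' animal/timepoint. Each phase may carry an intensity image, a binary mask
#' (`mask_stack`) and/or a probability map; all volumes share one shape and
#' spacing.
#'
#' @param phases List of phase entries; each a list with elements
#'   `phase_index` (0-based int), and optionally `image` (3D array),
#'   `mask` (`mask_stack`) and `prob` (3D array in `[0,1]`).
#' @param spacing_mm Shared voxel spacing (dz, dy, dx) in mm.
#' @param temporal_resolution_ms Time between consecutive phases (default 8).
#' @param label Identifier.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(phases, spacing_mm = c(1.5, 0.5, 0.5),
                        temporal_resolution_ms = 8, label = "") {
  if (length(phases) < 2) stopf("a cine series needs at least 2 phases")
  idx <- vapply(phases, function(p) as.integer(p$phase_index), integer(1))
  if (!identical(idx, seq_along(phases) - 1L))
    stopf("phase_index must increase strictly from 0")
  shp <- NULL
  for (p in phases) {
    for (field in c("image", "prob")) {
      if (!is.null(p[[field]])) {
        if (any(!is.finite(p[[field]]))) stopf("non-finite voxels in %s", field)
        shp <- check_shape(shp, dim(p[[field]]))
      }
    }
    if (!is.null(p$mask)) {
      if (!inherits(p$mask, "mask_stack")) stopf("phase masks must be mask_stack objects")
      shp <- check_shape(shp, dim(p$mask$voxels))
    }
  }
  structure(list(phases = phases, spacing_mm = as.numeric(spacing_mm),
                 temporal_resolution_ms = temporal_resolution_ms,
                 label = as.character(label)),
            class = "cine_series")
}

check_shape <- function(ref, shp) {
  if (!is.null(ref) && !identical(as.integer(ref), as.integer(shp)))
    stopf("all phase volumes must share one shape (found %s vs %s)",
          paste(ref, collapse = "x"), paste(shp, collapse = "x"))
  shp
}

#' @export
print.cine_series <- function(x, ...) {
  has <- function(f) sum(vapply(x$phases, function(p) !is.null(p[[f]]), logical(1)))
  cat(sprintf("<cine_series '%s'> %d phases (%g ms apart), %d images / %d masks / %d prob maps\n",
              x$label, length(x$phases), x$temporal_resolution_ms,
              has("image"), has("mask"), has("prob")))
  invisible(x)
}

#' @rdname cine_series
#' @param x A `cine_series`.
#' @export
n_phases <- function(x) length(x$phases)

#' Pre-processing specification
#'
#' Target grid and normalisation used to bring acquired stacks onto the
#' standard analysis grid of 12 x 86 x 98 voxels.
#'
#' @param target_shape Integer length-3 output dims (z, y, x).
#' @param normalisation `"minmax"` (observed min to 0, max to 1) or
#'   `"zscore"` (mean 0, sd 1).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_shape = c(12L, 86L, 98L),
                            normalisation = c("minmax", "zscore")) {
  normalisation <- match.arg(normalisation)
  if (length(target_shape) != 3 || any(target_shape < 1))
    stopf("target_shape must be 3 dims >= 1")
  structure(list(target_shape = as.integer(target_shape),
                 normalisation = normalisation),
            class = "preprocess_spec")
}

#' Resize and normalise an intensity stack
#'
#' Resamples a 3D intensity array to the spec's target grid by trilinear
#' interpolation, then normalises: min-max to `[0, 1]`, or z-score to mean 0
#' and unit sd. A constant image normalises to all zeros (with a warning under
#' min-max). Companion masks should be resized with [resize_mask()], which
#' uses nearest-neighbour sampling and so stays binary.
#'
#' @param stack 3D numeric array (z, y, x), finite.
#' @param spec A [preprocess_spec()].
#' @return 3D array with dims `spec$target_shape`.
#' @export
resize_normalise <- function(stack, spec = preprocess_spec()) {
  if (length(dim(stack)) != 3) stopf("input must be a 3D array")
  if (any(!is.finite(stack))) stopf("input has non-finite voxels")
  out <- resize_array(stack, spec$target_shape, "linear")
  rng <- range(out)
  if (spec$normalisation == "minmax") {
    if (rng[1] == rng[2]) {
      warnf("constant image under minmax normalisation; returning all zeros")
      out[] <- 0
    } else {
      out <- (out - rng[1]) / (rng[2] - rng[1])
    }
  } else {
    s <- stats::sd(out)
    if (s == 0) out[] <- 0 else out <- (out - mean(out)) / s
  }
  out
}

#' @rdname resize_normalise
#' @param mask A `mask_stack` (or bare binary 3D array).
#' @export
resize_mask <- function(mask, spec = preprocess_spec()) {
  vox <- if (inherits(mask, "mask_stack")) mask$voxels else mask
  out <- resize_array(vox, spec$target_shape, "nearest")
  out <- array(as.integer(out > 0.5), dim(out))
  if (inherits(mask, "mask_stack")) {
    # voxel size changes with the grid so that physical extent is preserved
    sp <- mask$spacing_mm * (dim(vox) - 1L) /
      pmax(spec$target_shape - 1L, 1L)
    mask_stack(out, ifelse(is.finite(sp) & sp > 0, sp, mask$spacing_mm), mask$label)
  } else {
    out
  }
}

# ---- NIfTI I/O ------------------------------------------------------------

#' Read a cine series from NIfTI
#'
#' Accepts either one 4D NIfTI file (phase axis declared via `layout`) or a
#' directory of per-phase 3D NIfTI files whose names sort by phase. Spacing is
#' taken from the NIfTI header and mapped to (dz, dy, dx).
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a directory of them.
#' @param layout Axis order of the stored array as a string over letters
#'   t, z, y, x (phase, slice, row, column). Default `"tzyx"`; a 3D file or
#'   directory member uses the trailing three letters.
#' @param kind `"image"`, `"mask"` (binarised at 0.5) or `"prob"`.
#' @param temporal_resolution_ms,label Passed to [cine_series()].
#' @return A [cine_series()].
#' @export
read_cine_nifti <- function(path, layout = "tzyx",
                            kind = c("image", "mask", "prob"),
                            temporal_resolution_ms = 8, label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("no such file or directory: %s", path)
  ax <- strsplit(layout, "")[[1]]
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (!length(files)) stopf("no NIfTI files in %s", path)
    vols <- lapply(files, RNifti::readNifti)
    ax3 <- setdiff(ax, "t")
    arrs <- lapply(vols, function(v) reorder_axes(unclass_nifti(v), ax3))
    spacing <- spacing_from_header(vols[[1]], ax3)
  } else {
    img <- RNifti::readNifti(path)
    a <- unclass_nifti(img)
    if (length(dim(a)) != 4) stopf("expected a 4D NIfTI file, got %dD", length(dim(a)))
    a <- reorder_axes(a, ax)  # to (t, z, y, x)
    arrs <- lapply(seq_len(dim(a)[1]), function(i) a[i, , , ])
    spacing <- spacing_from_header(img, ax)
  }
  shp <- dim(arrs[[1]])
  for (a in arrs) check_shape(shp, dim(a))
  if (any(!vapply(arrs, function(a) all(is.finite(a)), logical(1))))
    stopf("non-finite voxels in %s", path)
  phases <- lapply(seq_along(arrs), function(i) {
    a <- arrs[[i]]
    switch(kind,
           image = list(phase_index = i - 1L, image = a),
           mask = list(phase_index = i - 1L,
                       mask = mask_stack(array(as.integer(a > 0.5), dim(a)), spacing)),
           prob = list(phase_index = i - 1L, prob = check_prob_map(a)))
  })
  cine_series(phases, spacing_mm = spacing,
              temporal_resolution_ms = temporal_resolution_ms, label = label)
}

unclass_nifti <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim(a))
}

# Permute a stored array with axes named by `ax` into canonical order
# (t,)z,y,x and return it.
reorder_axes <- function(arr, ax) {
  want <- if (length(ax) == 4) c("t", "z", "y", "x") else c("z", "y", "x")
  if (!setequal(ax, want) || length(ax) != length(dim(arr)))
    stopf("layout '%s' does not match a %dD volume", paste(ax, collapse = ""), length(dim(arr)))
  aperm(arr, match(want, ax))
}

spacing_from_header <- function(img, ax) {
  pd <- RNifti::pixdim(img)
  names(pd) <- ax[seq_along(pd)]
  out <- pd[c("z", "y", "x")]
  if (any(is.na(out)) || any(out <= 0)) out[is.na(out) | out <= 0] <- 1
  as.numeric(out)
}

#' Write a cine series to a 4D NIfTI file
#'
#' Inverse of [read_cine_nifti()]: stores the chosen channel of every phase as
#' one 4D volume in the given axis layout, with voxel spacing in the header.
#'
#' @param series A [cine_series()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param what `"image"`, `"mask"` or `"prob"`.
#' @param layout Axis order to store (string over t, z, y, x).
#' @return `path`, invisibly.
#' @export
write_cine_nifti <- function(series, path, what = c("image", "mask", "prob"),
                             layout = "tzyx") {
  what <- match.arg(what)
  ax <- strsplit(layout, "")[[1]]
  get1 <- function(p) switch(what, image = p$image, prob = p$prob,
                             mask = if (!is.null(p$mask)) p$mask$voxels)
  arrs <- lapply(series$phases, get1)
  if (any(vapply(arrs, is.null, logical(1))))
    stopf("some phases lack a '%s' volume", what)
  a4 <- array(0, c(length(arrs), dim(arrs[[1]])))
  for (i in seq_along(arrs)) a4[i, , , ] <- arrs[[i]]
  # permute canonical (t, z, y, x) into the requested storage layout
  a4 <- aperm(a4, match(ax, c("t", "z", "y", "x")))
  img <- RNifti::asNifti(a4)
  sp <- c(t = 1, z = series$spacing_mm[1], y = series$spacing_mm[2],
          x = series$spacing_mm[3])
  RNifti::pixdim(img) <- as.numeric(sp[ax])
  RNifti::writeNifti(img, path)
  invisible(path)
}
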