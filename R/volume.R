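#' Voxel volume with physical spacing
#'
#' Container for a 3D image grid with per-axis physical voxel spacing.
#' The axis convention is `(row = axial/depth, column = lateral,
#' slice = elevational)`; a single-slice volume is flagged as 2D mode.
#' Binary volumes contain only 0/1 (stored as `logical`); intensity
#' volumes are nonnegative numerics.
#'
#' @param data 3D array (a matrix is promoted to a single-slice volume).
#' @param spacing numeric length-3, voxel size in mm per axis
#'   (axial, lateral, elevational). All components must be positive.
#' @param origin numeric length-3 physical offset in mm of voxel `(1,1,1)`.
#' @param mode `"3D"` or `"2D"`; defaults to `"2D"` when the volume has a
#'   single slice.
#' @return An object of class `voxel_volume`: a list with elements `data`,
#'   `spacing`, `origin` and `mode`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0), mode = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a matrix or 3D array")
  if (any(dim(data) < 1L)) stop("all data dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm); it is never assumed")
  if (is.logical(data)) {
    binary <- TRUE
  } else {
    u <- unique(as.vector(data))
    binary <- all(u %in% c(0, 1))
    if (binary) data <- array(data > 0, dim = dim(data))
    else if (any(data < 0, na.rm = TRUE))
      stop("intensity volumes must be nonnegative")
  }
  if (is.null(mode)) mode <- if (dim(data)[3] == 1L) "2D" else "3D"
  mode <- match.arg(mode, c("2D", "3D"))
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         mode = mode, binary = binary),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %dx%dx%d voxels, spacing (%.3g, %.3g, %.3g) mm, %s, %s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    if (x$binary) "binary" else "intensity", x$mode))
  if (x$binary)
    cat(sprintf("  foreground voxels: %d (%.3g%%)\n", sum(x$data),
                100 * mean(x$data)))
  invisible(x)
}

is_binary_volume <- function(v) inherits(v, "voxel_volume") && isTRUE(v$binary)

#' Assemble a volume from an ordered stack of 2D slices
#'
#' Stacks co-registered 2D microvessel images along the elevational axis in
#' acquisition order. Input may be a list of matrices or a character vector
#' of single-page TIFF paths. Spacing must always be supplied (or stored in
#' a sidecar read by [read_volume()]); isotropy is never assumed.
#'
#' @param slices list of equally shaped matrices, or character vector of
#'   TIFF file paths read in the given order.
#' @param spacing voxel spacing in mm, `(axial, lateral, elevational)`.
#' @param origin physical origin, mm.
#' @return A [voxel_volume()] ; single-slice input is flagged 2D mode.
#' @export
load_stack <- function(slices, spacing, origin = c(0, 0, 0)) {
  if (missing(spacing) || is.null(spacing))
    stop("'spacing' is required; slice stacks carry no elevational step")
  if (is.character(slices))
    slices <- lapply(slices, function(p) {
      m <- tiff::readTIFF(p, as.is = FALSE)
      if (length(dim(m)) == 3L) m <- m[, , 1] # collapse grayscale channels
      m
    })
  if (!is.list(slices) || length(slices) < 1L)
    stop("need at least one slice")
  shapes <- vapply(slices, function(s) paste(dim(s), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("mixed slice shapes: ", paste(unique(shapes), collapse = ", "))
  d <- dim(slices[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  voxel_volume(arr, spacing = spacing, origin = origin)
}

#' Binarize an intensity volume
#'
#' Converts an intensity volume to a binary vessel mask, either at a fixed
#' threshold or with Otsu's method on the pooled voxel histogram. Binary
#' input is returned unchanged (idempotent). A constant volume under Otsu
#' falls back to an empty mask with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold fixed threshold; voxels strictly above it are vessel.
#' @return Binary `voxel_volume` with a `threshold` attribute recording the
#'   value used.
#' @export
binarize <- function(volume, method = c("fixed", "otsu"), threshold = 0) {
  stopifnot(inherits(volume, "voxel_volume"))
  method <- match.arg(method)
  if (volume$binary) return(volume)
  x <- volume$data
  if (method == "otsu") {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant-intensity volume: Otsu undefined, returning empty mask")
      out <- voxel_volume(array(FALSE, dim(x)), volume$spacing, volume$origin,
                          volume$mode)
      attr(out, "threshold") <- NA_real_
      return(out)
    }
    thr <- EBImage::otsu(matrix(as.vector(x), ncol = 1L), range = rng,
                         levels = 256L)
  } else {
    thr <- threshold
  }
  out <- voxel_volume(array(x > thr, dim(x)), volume$spacing, volume$origin,
                      volume$mode)
  attr(out, "threshold") <- thr
  out
}

#' Euclidean distance transform in physical units
#'
#' Exact anisotropic Euclidean distance transform: for each foreground voxel
#' the distance (mm) to the nearest background voxel centre, 0 on
#' background. Used for centerline radii and for physical-distance dilation.
#'
#' @param volume binary [voxel_volume()] or logical array.
#' @param spacing required when `volume` is a bare array.
#' @return numeric array of distances (mm), same shape as the input.
#' @export
distance_transform <- function(volume, spacing = NULL) {
  if (inherits(volume, "voxel_volume")) {
    if (!volume$binary) stop("distance_transform needs a binary volume")
    spacing <- volume$spacing
    m <- volume$data
  } else {
    if (is.null(spacing)) stop("'spacing' required for array input")
    m <- volume
    if (is.matrix(m)) m <- array(m, dim = c(dim(m), 1L))
  }
  d <- cpp_edt(as.logical(m), dim(m), as.numeric(spacing))
  array(d, dim(m))
}

#' Dilate a lesion mask by a physical margin
#'
#' Morphological dilation by a Euclidean ball of the given radius in
#' physical units, respecting anisotropic spacing: the output contains every
#' voxel whose centre lies within `margin_mm` of some input mask voxel
#' centre. Used to include the peritumoral zone (typically 2--5 mm,
#' depending on mass size) in the analysis region.
#'
#' @param mask binary [voxel_volume()].
#' @param margin_mm nonnegative dilation margin, mm; 0 is the identity.
#' @return Binary `voxel_volume` containing the dilated mask.
#' @export
dilate_mask <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "voxel_volume"), isTRUE(mask$binary))
  if (!is.finite(margin_mm) || margin_mm < 0)
    stop("'margin_mm' must be >= 0")
  if (margin_mm == 0) return(mask)
  dist_to_mask <- distance_transform(
    voxel_volume(!mask$data, mask$spacing, mask$origin, mask$mode))
  out <- mask$data | (dist_to_mask <= margin_mm)
  voxel_volume(array(out, dim(mask$data)), mask$spacing, mask$origin,
               mask$mode)
}

#' Write / read a volume with spacing metadata
#'
#' `write_volume` stores a volume as NIfTI (`.nii` / `.nii.gz`, spacing in
#' the header) or as a multi-page TIFF plus a JSON sidecar
#' (`<path>.meta.json`) carrying spacing, origin and mode; `read_volume`
#' reverses either, reproducing data and spacing exactly.
#'
#' @param volume a [voxel_volume()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `voxel_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$data * 1.0)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    d <- dim(volume$data)
    x <- volume$data * 1.0
    mx <- max(x)
    scale <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(d[3]), function(k) x[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(spacing = volume$spacing, origin = volume$origin,
                 mode = volume$mode, binary = volume$binary, scale = scale)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension: ", path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    spc <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img), dim = dim(img))
    return(voxel_volume(arr, spacing = spc))
  }
  if (grepl("\\.tiff?$", path)) {
    metapath <- paste0(path, ".meta.json")
    if (!file.exists(metapath))
      stop("missing spacing sidecar ", metapath, "; spacing is never assumed")
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) {
      p <- pages[[k]]
      if (length(dim(p)) == 3L) p <- p[, , 1]
      arr[, , k] <- p * meta$scale
    }
    if (isTRUE(meta$binary)) arr <- array(arr > 0.5, dim(arr))
    return(voxel_volume(arr, spacing = meta$spacing, origin = meta$origin,
                        mode = meta$mode))
  }
  stop("unsupported extension: ", path)
}

#' Slice with the largest lesion cross-section
#'
#' Returns the elevational slice index maximizing the lesion-mask pixel
#' count; ties resolve to the lowest index. This is the slice used for
#' single-plane (2D-mode) quantification.
#'
#' @param mask binary [voxel_volume()] lesion mask.
#' @return integer slice index.
#' @export
largest_lesion_slice <- function(mask) {
  stopifnot(inherits(mask, "voxel_volume"), isTRUE(mask$binary))
  counts <- apply(mask$data, 3, sum)
  which.max(counts) # which.max takes the first maximum: lowest index on ties
}

# Extract slice k as a 2D-mode voxel_volume (same in-plane spacing)
volume_slice <- function(volume, k) {
  d <- dim(volume$data)
  stopifnot(k >= 1, k <= d[3])
  voxel_volume(array(volume$data[, , k], dim = c(d[1], d[2], 1L)),
               volume$spacing, volume$origin, mode = "2D")
}
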