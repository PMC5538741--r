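#' @useDynLib cpinjury, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd quantile rnorm runif rbinom optim lm lm.wfit coef
#'   pf pt anova as.formula predict mad cor setNames aggregate median var
#' @importFrom utils write.csv read.csv head
NULL

#' 3D image volume
#'
#' A minimal container for a 3D scalar grid: a numeric array plus the voxel
#' spacing in mm and a modality tag. All pipeline stages consume and return
#' this class; world coordinates are voxel index (1-based) scaled by spacing,
#' with the origin at the grid centre.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param modality character tag, e.g. "T1" or "T2".
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), modality = "T1") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s: %s voxels @ %s mm>\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel volume in mm^3
#' @param x an `image_volume`, or a numeric spacing vector.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(x) {
  sp <- if (inherits(x, "image_volume")) x$spacing else as.numeric(x)
  prod(sp)
}

#' World coordinates of every voxel
#'
#' Coordinates in mm of all voxel centres, origin at the grid centre so that
#' mirrored anatomy is exactly symmetric on even-sized grids.
#'
#' @param dim integer length-3 grid size.
#' @param spacing voxel size mm.
#' @return list of three arrays (x, y, z), each of dimension `dim`.
#' @keywords internal
voxel_coords_mm <- function(dim, spacing) {
  ax <- lapply(1:3, function(i) (seq_len(dim[i]) - (dim[i] + 1) / 2) * spacing[i])
  list(x = array(rep(ax[[1]], times = dim[2] * dim[3]), dim),
       y = array(rep(rep(ax[[2]], each = dim[1]), times = dim[3]), dim),
       z = array(rep(ax[[3]], each = dim[1] * dim[2]), dim))
}

#' Read a NIfTI-1 volume
#'
#' Reads a NIfTI file, normalises the data to a canonical (RAS-like) axis
#' order via RNifti, and extracts voxel spacing from the header.
#'
#' @param path file path (.nii or .nii.gz).
#' @param modality modality tag to attach.
#' @return an `image_volume`.
#' @export
read_volume <- function(path, modality = "T1") {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file: ", conditionMessage(e)))
  aff <- RNifti::xform(img)
  if (abs(det(aff[1:3, 1:3])) < 1e-12) stop("non-invertible affine in NIfTI header")
  spc <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  image_volume(arr, spacing = spc, modality = modality)
}

#' Write a volume as NIfTI-1
#' @param vol an `image_volume` (or plain 3D array).
#' @param path output path; ".nii.gz" recommended.
#' @param spacing spacing override when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data
    spc <- vol$spacing
  } else {
    arr <- vol
    spc <- if (is.null(spacing)) c(1, 1, 1) else spacing
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spc
  RNifti::writeNifti(img, path)
  invisible(path)
}

# internal: coerce image_volume-or-array to array
as_vol_array <- function(x) if (inherits(x, "image_volume")) x$data else x
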