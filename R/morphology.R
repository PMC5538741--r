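# Binary 3D morphology built on the exact Euclidean distance transform.
# A "ball" structuring element of radius r mm is realised by thresholding the
# EDT, so all operations respect anisotropic voxel spacing exactly.

# dim-preserving set membership for label arrays
arr_in <- function(a, set) array(a %in% set, dim(a))

#' Euclidean distance transform
#'
#' Distance in mm from every voxel to the nearest `TRUE` voxel of `mask`.
#'
#' @param mask logical 3D array.
#' @param spacing voxel size mm.
#' @return numeric array of distances (0 on the mask, Inf if mask empty).
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  d2 <- edt_sq_cpp(as.logical(mask), dim(mask), as.numeric(spacing))
  array(sqrt(d2), dim(mask))
}

#' @rdname morphology
#' @export
mask_dilate <- function(mask, radius_mm, spacing = c(1, 1, 1)) {
  if (radius_mm <= 0) return(mask)
  distance_transform(mask, spacing) <= radius_mm + 1e-9
}

#' Ball morphology on 3D masks
#'
#' Dilation, erosion, opening and closing with a Euclidean ball of radius
#' `radius_mm`, implemented via the distance transform.
#'
#' @param mask logical 3D array.
#' @param radius_mm ball radius in mm.
#' @param spacing voxel size mm.
#' @return logical array of the same shape.
#' @name morphology
#' @export
mask_erode <- function(mask, radius_mm, spacing = c(1, 1, 1)) {
  if (radius_mm <= 0) return(mask)
  !mask_dilate(!mask, radius_mm, spacing)
}

#' @rdname morphology
#' @export
mask_open <- function(mask, radius_mm, spacing = c(1, 1, 1)) {
  mask_dilate(mask_erode(mask, radius_mm, spacing), radius_mm, spacing)
}

#' @rdname morphology
#' @details `mask_close` pads the grid by the ball radius before operating so
#'   closures near the field-of-view border are not clipped by the grid.
#' @export
mask_close <- function(mask, radius_mm, spacing = c(1, 1, 1)) {
  if (radius_mm <= 0) return(mask)
  pad <- pmin(ceiling(radius_mm / spacing) + 1L, 64L)
  d <- dim(mask)
  big <- array(FALSE, d + 2L * pad)
  ix <- lapply(1:3, function(a) seq_len(d[a]) + pad[a])
  big[ix[[1]], ix[[2]], ix[[3]]] <- mask
  out <- mask_erode(mask_dilate(big, radius_mm, spacing), radius_mm, spacing)
  out[ix[[1]], ix[[2]], ix[[3]]]
}

#' Connected components (6-connectivity)
#' @param mask logical 3D array.
#' @return integer array; 0 = background, components numbered from 1.
#' @export
connected_components <- function(mask) {
  array(label_components_cpp(as.logical(mask), dim(mask)), dim(mask))
}

#' Largest connected component of a mask
#' @param mask logical 3D array.
#' @return logical array keeping only the largest 6-connected component.
#' @export
largest_component <- function(mask) {
  lab <- connected_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

#' Fill interior holes of a mask
#'
#' Background components not touching the grid border are interior holes and
#' are added to the mask.
#' @param mask logical 3D array.
#' @return logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  lab <- connected_components(!mask)
  if (max(lab) == 0L) return(mask)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  mask | (lab > 0L & !arr_in(lab, border))
}

#' Otsu threshold
#'
#' Threshold maximising between-class variance over a fixed histogram.
#' @param x numeric vector or array of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) stop("constant image: no threshold exists")
  br <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Gaussian-like soft prior from a label mask: exp(-d^2 / (2 sigma^2)) of the
# distance to the mask, which is cheap and monotone in distance.
soft_prior_from_mask <- function(mask, sigma_mm, spacing) {
  d <- distance_transform(mask, spacing)
  exp(-d^2 / (2 * sigma_mm^2))
}
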