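#' Voxel-wise mean, SE and z-statistic map of one CAP
#'
#' Aggregates the member volumes of a CAP: per voxel the mean across
#' members, the standard error (within-cluster SD across member volumes
#' divided by sqrt(n)), and `z = mean / se`, which quantifies how
#' significantly the CAP deviates from zero at each voxel. Voxels with zero
#' SE — and every voxel of a singleton CAP — are flagged undefined rather
#' than erroring, since singleton clusters legitimately occur high in the
#' hierarchy.
#'
#' @param vm a `volume_matrix` (or plain N x V matrix).
#' @param members integer vector of member row indices (>= 1 row).
#' @param cap_label optional label stored in the result.
#' @param sd_denom `"sample"` (n - 1, default) or `"population"` (n) for the
#'   within-cluster SD.
#' @return an object of class `cap_zmap`: list with `cap_label`,
#'   `n_members`, `mean`, `se`, `z` (V-vectors) and `undefined` (logical
#'   V-vector).
#' @export
compute_cap_zmap <- function(vm, members, cap_label = NULL,
                             sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  x <- if (inherits(vm, "volume_matrix")) vm$values else as.matrix(vm)
  members <- as.integer(members)
  if (length(members) < 1L) stop("empty member set", call. = FALSE)
  if (any(members < 1L | members > nrow(x)))
    stop("member indices out of range", call. = FALSE)
  xm <- x[members, , drop = FALSE]
  n <- length(members)
  mu <- colMeans(xm)
  if (n < 2L) {
    se <- rep(NA_real_, ncol(x))
    z <- rep(NA_real_, ncol(x))
    undef <- rep(TRUE, ncol(x))
  } else {
    denom <- if (sd_denom == "sample") n - 1L else n
    ss <- colSums(xm^2) - n * mu^2
    ss[ss < 0] <- 0
    se <- sqrt(ss / denom) / sqrt(n)
    undef <- se == 0
    z <- ifelse(undef, NA_real_, mu / se)
  }
  structure(list(cap_label = cap_label, n_members = n,
                 mean = mu, se = se, z = z, undefined = undef),
            class = "cap_zmap")
}

#' z-maps for every unique CAP in a labeling
#'
#' @param vm a `volume_matrix`.
#' @param labeling a `cap_labeling`.
#' @param caps unique CAP labels to compute (default: all).
#' @param sd_denom passed to [compute_cap_zmap()].
#' @return named list of `cap_zmap` objects.
#' @export
compute_all_zmaps <- function(vm, labeling, caps = names(labeling$members),
                              sd_denom = "sample") {
  out <- lapply(caps, function(cl)
    compute_cap_zmap(vm, cap_members(labeling, cl), cap_label = cl,
                     sd_denom = sd_denom))
  names(out) <- caps
  out
}

#' @export
print.cap_zmap <- function(x, ...) {
  cat(sprintf("cap_zmap %s: %d members, %d/%d voxels defined\n",
              if (is.null(x$cap_label)) "" else x$cap_label,
              x$n_members, sum(!x$undefined), length(x$z)))
  invisible(x)
}

#' Unflatten an in-mask voxel vector to a 3D image array
#'
#' @param values V-vector in the `which(mask)` (x-fastest) order.
#' @param mask 3D logical array with V true voxels.
#' @param fill value outside the mask.
#' @return 3D numeric array.
#' @export
unmask <- function(values, mask, fill = 0) {
  mask <- mask != 0
  if (length(values) != sum(mask))
    stop(sprintf("vector length %d does not match %d in-mask voxels",
                 length(values), sum(mask)), call. = FALSE)
  img <- array(fill, dim(mask))
  img[mask] <- values
  img
}

#' Export a CAP z-map as a NIfTI-1 image
#'
#' Writes the z-statistic in-mask, 0 outside the mask, and NaN at flagged
#' (undefined) voxels, copying geometry from a reference image when given.
#' Written as float64 so a round-trip read reproduces the values exactly.
#'
#' @param zmap a `cap_zmap`.
#' @param mask 3D logical array matching the map's voxel count.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param reference optional NIfTI image (or path) supplying the header
#'   geometry; must match the mask grid.
#' @return invisibly, the path written.
#' @export
export_zmap <- function(zmap, mask, path, reference = NULL) {
  mask <- mask != 0
  if (length(zmap$z) != sum(mask))
    stop("z-map voxel count does not match mask", call. = FALSE)
  vals <- zmap$z
  vals[zmap$undefined] <- NaN
  img <- unmask(vals, mask, fill = 0)
  if (!is.null(reference)) {
    ref <- RNifti::asNifti(reference)
    if (!all(dim(ref)[1:3] == dim(mask)))
      stop("reference geometry does not match mask grid", call. = FALSE)
    img <- RNifti::asNifti(img, reference = ref)
  } else {
    img <- RNifti::asNifti(img)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
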