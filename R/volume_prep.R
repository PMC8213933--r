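#' Temporally normalize a subject's 4D series voxel-wise
#'
#' For every voxel, over the retained (non-censored) volumes only, the mean
#' is subtracted and the result divided by the temporal standard deviation.
#' Censored volumes are excluded both from the statistics and from the
#' output. Voxels with zero temporal variance are set to 0 and flagged.
#'
#' @param data 4D numeric array (x, y, z, t), BOLD in arbitrary units.
#' @param censor logical vector of length t; `TRUE` marks a volume to drop.
#' @param sd_denom `"sample"` (n - 1, the default) or `"population"` (n)
#'   denominator for the temporal SD.
#' @return a list with `data` (4D array over retained volumes only),
#'   `zero_variance` (3D logical flags), and `retained` (indices of kept
#'   volumes in the original series).
#' @export
temporal_normalize <- function(data, censor = NULL,
                               sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  d <- dim(data)
  if (length(d) != 4L) stop("'data' must be a 4D array", call. = FALSE)
  if (is.null(censor)) censor <- rep(FALSE, d[4])
  if (length(censor) != d[4])
    stop("'censor' length must equal the number of volumes", call. = FALSE)
  keep <- which(!censor)
  if (length(keep) < 2L)
    stop("fewer than 2 volumes retained after censoring", call. = FALSE)
  if (!all(is.finite(data)))
    stop("non-finite values in input series", call. = FALSE)
  V <- prod(d[1:3])
  m <- matrix(data, nrow = V, ncol = d[4])[, keep, drop = FALSE]
  mu <- rowMeans(m)
  n <- length(keep)
  ss <- rowSums((m - mu)^2)
  denom <- if (sd_denom == "sample") n - 1L else n
  sdv <- sqrt(ss / denom)
  zero_var <- sdv == 0
  sdv[zero_var] <- 1          # value is 0 after centering anyway
  out <- (m - mu) / sdv
  out[zero_var, ] <- 0
  list(data = array(out, c(d[1:3], n)),
       zero_variance = array(zero_var, d[1:3]),
       retained = keep)
}

#' Mask normalized subject series and stack them into a volume matrix
#'
#' Builds the clustering substrate: an N x V matrix whose rows are retained
#' volumes (all subjects, subject order as given, time order within
#' subject) and whose columns are the in-mask voxels in x-fastest
#' (column-major) linearization — the order of `which(mask)`.
#'
#' @param series named list, one element per subject, each a list with
#'   `data` (4D normalized array), optionally `retained` (original volume
#'   indices, as returned by [temporal_normalize()]) and `group`.
#' @param mask 3D logical array; `V = sum(mask)` voxels are kept.
#' @param groups optional named vector of group labels per subject;
#'   overrides any `group` element in `series`.
#' @return an object of class `volume_matrix`: a list with `values` (N x V
#'   matrix), `provenance` (data.frame subject, volume, group), `mask`, and
#'   `flat_order = "x-fastest"`.
#' @export
apply_mask_and_stack <- function(series, mask, groups = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array", call. = FALSE)
  mask <- mask != 0
  vox <- which(mask)
  if (length(vox) == 0L) stop("mask is empty", call. = FALSE)
  if (is.null(names(series)))
    names(series) <- sprintf("sub%02d", seq_along(series))
  blocks <- vector("list", length(series))
  prov <- vector("list", length(series))
  for (i in seq_along(series)) {
    id <- names(series)[i]
    s <- series[[i]]
    dat <- if (is.list(s)) s$data else s
    d <- dim(dat)
    if (length(d) != 4L || !all(d[1:3] == dim(mask)))
      stop(sprintf("subject '%s': series grid %s does not match mask %s",
                   id, paste(d[1:3], collapse = "x"),
                   paste(dim(mask), collapse = "x")), call. = FALSE)
    m <- matrix(dat, nrow = prod(d[1:3]))[vox, , drop = FALSE]
    blocks[[i]] <- t(m)
    volume <- if (is.list(s) && !is.null(s$retained)) s$retained
              else seq_len(d[4])
    grp <- if (!is.null(groups)) unname(groups[id])
           else if (is.list(s) && !is.null(s$group)) s$group else NA_character_
    prov[[i]] <- data.frame(subject = id, volume = volume,
                            group = grp, stringsAsFactors = FALSE)
  }
  structure(list(values = do.call(rbind, blocks),
                 provenance = do.call(rbind, prov),
                 mask = mask,
                 flat_order = "x-fastest"),
            class = "volume_matrix")
}

#' Prepare a synthetic dataset for clustering
#'
#' Convenience wrapper: temporally normalizes every subject's series over
#' its retained volumes and stacks the in-mask voxels into a
#' `volume_matrix`.
#'
#' @param dataset a `synth_dataset`.
#' @param sd_denom passed to [temporal_normalize()].
#' @return a `volume_matrix`.
#' @export
prepare_volume_matrix <- function(dataset, sd_denom = "sample") {
  series <- lapply(names(dataset$series), function(id) {
    norm <- temporal_normalize(dataset$series[[id]],
                               dataset$censor_masks[[id]],
                               sd_denom = sd_denom)
    list(data = norm$data, retained = norm$retained)
  })
  names(series) <- names(dataset$series)
  apply_mask_and_stack(series, dataset$mask, groups = dataset$group_labels)
}

#' @export
print.volume_matrix <- function(x, ...) {
  cat(sprintf("volume_matrix: %d volumes x %d in-mask voxels (%d subjects)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$provenance$subject))))
  invisible(x)
}
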