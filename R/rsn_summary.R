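#' Assign every in-mask voxel to exactly one network
#'
#' Overlapping network maps are resolved by assigning each voxel to the
#' network with the highest absolute z-statistic there; ties go to the
#' lowest network index (the tie count is recorded), and voxels where every
#' map is zero stay unassigned.
#'
#' @param zmaps K network z-maps: a 4D array (grid x K) or list of 3D
#'   arrays.
#' @param mask 3D logical analysis mask.
#' @param names optional character vector of network names.
#' @return an object of class `rsn_atlas`: list with `assignment` (integer
#'   V-vector over `which(mask)`, NA = unassigned), `network_names`, `K`,
#'   `mask`, `n_ties`, and `network_sizes`.
#' @export
assign_voxels <- function(zmaps, mask, names = NULL) {
  mask <- mask != 0
  if (is.list(zmaps)) zmaps <- simplify2array(zmaps)
  d <- dim(zmaps)
  if (length(d) != 4L || !all(d[1:3] == dim(mask)))
    stop("network maps must share the mask grid", call. = FALSE)
  K <- d[4]
  vox <- which(mask)
  flat <- abs(matrix(zmaps, nrow = prod(d[1:3]), ncol = K)[vox, , drop = FALSE])
  best <- max.col(flat, ties.method = "first")
  mx <- flat[cbind(seq_along(vox), best)]
  n_ties <- sum(rowSums(flat == mx) > 1L & mx > 0)
  best[mx == 0] <- NA_integer_
  if (is.null(names)) names <- sprintf("net%02d", seq_len(K))
  sizes <- tabulate(best, nbins = K)
  names(sizes) <- names
  structure(list(assignment = best, network_names = names, K = K,
                 mask = mask, n_ties = n_ties, network_sizes = sizes),
            class = "rsn_atlas")
}

#' @export
print.rsn_atlas <- function(x, ...) {
  cat(sprintf("rsn_atlas: %d networks over %d in-mask voxels (%d unassigned, %d ties)\n",
              x$K, length(x$assignment), sum(is.na(x$assignment)), x$n_ties))
  invisible(x)
}

#' Networks x CAPs matrix of mean voxel z-scores
#'
#' Entry (k, c) is the mean of CAP c's z-statistic over the voxels assigned
#' to network k, excluding flagged (undefined) voxels. Networks with no
#' assigned voxels yield NA.
#'
#' @param zmaps named list of `cap_zmap` objects.
#' @param atlas an `rsn_atlas` on the same voxel set.
#' @return K x C numeric matrix (rows = networks, columns = CAPs).
#' @export
cap_rsn_mean_matrix <- function(zmaps, atlas) {
  V <- length(atlas$assignment)
  M <- matrix(NA_real_, atlas$K, length(zmaps),
              dimnames = list(atlas$network_names, names(zmaps)))
  for (j in seq_along(zmaps)) {
    zm <- zmaps[[j]]
    if (length(zm$z) != V)
      stop("z-map voxel count does not match atlas", call. = FALSE)
    ok <- !zm$undefined & !is.na(atlas$assignment)
    if (!any(ok)) next
    sums <- tapply(zm$z[ok], atlas$assignment[ok], mean)
    M[as.integer(names(sums)), j] <- sums
  }
  M
}

#' Bicluster a networks x CAPs matrix for display
#'
#' Rows and columns are independently ordered by the same cosine-distance
#' Ward clustering used for the volumes, applied to this matrix alone.
#' Zero-norm (constant-zero) rows or columns cannot enter cosine distance
#' and are moved to the end of the order.
#'
#' @param M numeric matrix with at least 2 rows and 2 columns.
#' @return list with `row_order`, `col_order` (integer permutations),
#'   `row_tree`, `col_tree` (`hclust` or NULL when fewer than 2 usable
#'   vectors remain).
#' @export
bicluster_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L || ncol(M) < 2L)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  order_one <- function(X) {
    ok <- which(rowSums(X^2, na.rm = TRUE) > 0 &
                  apply(X, 1, function(r) all(is.finite(r))))
    dropped <- setdiff(seq_len(nrow(X)), ok)
    if (length(dropped))
      message(length(dropped), " zero-norm/non-finite vector(s) moved to the end")
    if (length(ok) < 2L)
      return(list(order = c(ok, dropped), tree = NULL))
    tr <- ward_linkage(cosine_distance_matrix(X[ok, , drop = FALSE]))
    list(order = c(ok[tr$order], dropped), tree = tr)
  }
  ro <- order_one(M)
  co <- order_one(t(M))
  list(row_order = ro$order, col_order = co$order,
       row_tree = ro$tree, col_tree = co$tree)
}

#' Percent-significant-voxel matrices, decile highlighting, and ranked report
#'
#' For each CAP x direction significance mask, computes the percentage of
#' every network's voxels that are significant; highlights entries at or
#' above the 90th percentile of all nonzero percentages (pooled over both
#' directions); and builds a ranked report of CAP x direction cells by
#' total significant voxel count, with per-network "x% (a/b)" strings and
#' the number of 26-connected significant components.
#'
#' @param masks named list of logical V-vectors; names formatted
#'   `"<cap>|<direction>"` as produced by [run_group_contrast()].
#' @param atlas an `rsn_atlas` on the same voxel set.
#' @param top number of report rows to keep (default 20).
#' @param connectivity connectivity for the component count (default 26).
#' @return list with `pct` (named list of K x C percentage matrices, one
#'   per direction), `decile_mask` (same shape, logical), `decile_cutoff`,
#'   and `report` (data.frame `cap`, `direction`, `voxels`, `clusters`,
#'   `areas`).
#' @export
significant_fractions <- function(masks, atlas, top = 20L,
                                  connectivity = 26L) {
  V <- length(atlas$assignment)
  keys <- strsplit(names(masks), "|", fixed = TRUE)
  caps <- vapply(keys, `[`, character(1), 1)
  dirs <- vapply(keys, `[`, character(1), 2)
  dir_names <- unique(dirs)
  cap_names <- unique(caps)
  sizes <- atlas$network_sizes
  pct <- lapply(dir_names, function(d) {
    m <- matrix(0, atlas$K, length(cap_names),
                dimnames = list(atlas$network_names, cap_names))
    m
  })
  names(pct) <- dir_names
  counts <- pct   # significant voxel counts per network
  for (i in seq_along(masks)) {
    msk <- masks[[i]]
    if (length(msk) != V)
      stop("mask length does not match atlas voxel count", call. = FALSE)
    cnt <- tabulate(atlas$assignment[msk & !is.na(atlas$assignment)],
                    nbins = atlas$K)
    counts[[dirs[i]]][, caps[i]] <- cnt
    pct[[dirs[i]]][, caps[i]] <- ifelse(sizes > 0, 100 * cnt / sizes, 0)
  }
  nonzero <- unlist(pct)[unlist(pct) > 0]
  cutoff <- if (length(nonzero)) quantile(nonzero, 0.9, names = FALSE) else Inf
  decile <- lapply(pct, function(m) m >= cutoff & m > 0)
  # ranked Table-1-style report
  rows <- lapply(seq_along(masks), function(i) {
    msk <- masks[[i]]
    total <- sum(msk)
    img <- unmask(as.numeric(msk), atlas$mask, fill = 0)
    lab <- cpp_label_components(as.numeric(img), as.integer(dim(img)),
                                0.5, as.integer(connectivity))
    cnt <- counts[[dirs[i]]][, caps[i]]
    ord <- order(-cnt / pmax(sizes, 1))
    areas <- paste(sprintf("%s, %d%% (%d/%d)", atlas$network_names[ord],
                           pct_round(cnt[ord] / pmax(sizes[ord], 1)),
                           cnt[ord], sizes[ord]), collapse = "; ")
    data.frame(cap = caps[i], direction = dirs[i], voxels = total,
               clusters = attr(lab, "n_components"), areas = areas,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[order(-report$voxels), , drop = FALSE]
  report <- utils::head(report, top)
  rownames(report) <- NULL
  list(pct = pct, decile_mask = decile, decile_cutoff = cutoff,
       report = report)
}
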