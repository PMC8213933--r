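#' Pairwise cosine distance between volumes
#'
#' `d(i, j) = 1 - x_i . x_j / (||x_i|| ||x_j||)`, in \[0, 2\]. Cosine
#' distance is invariant to positive rescaling of any volume, so volumes
#' sharing a spatial pattern at different signal amplitudes stay close,
#' while anticorrelated patterns are maximally distant. Computed in row
#' blocks so the transient beyond the N x N result stays bounded.
#'
#' @param x a `volume_matrix` or a plain numeric matrix (rows = volumes).
#' @param block_size rows per block of the pairwise product.
#' @return an N x N symmetric matrix with zero diagonal.
#' @export
cosine_distance_matrix <- function(x, block_size = 1024L) {
  vm <- NULL
  if (inherits(x, "volume_matrix")) { vm <- x; x <- x$values }
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    who <- if (!is.null(vm))
      paste(sprintf("%s[vol %d]", vm$provenance$subject[bad],
                    vm$provenance$volume[bad]), collapse = ", ")
    else paste(bad, collapse = ", ")
    stop("zero-norm volume rows cannot enter cosine distance: ", who,
         call. = FALSE)
  }
  xn <- x / nrm
  n <- nrow(xn)
  d <- matrix(0, n, n)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n)
    d[idx, ] <- 1 - tcrossprod(xn[idx, , drop = FALSE], xn)
  }
  d <- (d + t(d)) / 2              # enforce exact symmetry
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Ward (ward.D2) agglomeration of a distance matrix
#'
#' Minimum-variance agglomerative clustering in the Murtagh-Legendre
#' ward.D2 sense: Lance-Williams updates applied to squared dissimilarities
#' with merge heights reported on the original scale. Heights are
#' nondecreasing.
#'
#' @param d an N x N symmetric distance matrix or a `dist` object.
#' @return an object of class `hclust` (merge, height, order).
#' @export
ward_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop("'d' must be a symmetric square matrix or dist", call. = FALSE)
    d <- as.dist(d)
  }
  if (attr(d, "Size") < 2L)
    stop("need at least 2 items to cluster", call. = FALSE)
  if (any(!is.finite(d)))
    stop("non-finite distances", call. = FALSE)
  stats::hclust(d, method = "ward.D2")
}

#' Integer percentages of a vector of branch counts
#'
#' The percentage formatting shared by all occupancy reports: each count is
#' divided by the total and rounded half-up to the nearest integer percent
#' (e.g. counts 4658 and 7272 of 11930 give 39 and 61).
#'
#' @param counts nonnegative numeric vector.
#' @return integer vector of percentages.
#' @export
split_percentages <- function(counts) {
  counts <- as.numeric(counts)
  pct_round(counts / sum(counts))
}

#' Cut the merge tree at every level and enumerate nested CAPs
#'
#' Cuts the tree into exactly L clusters for each L in
#' `level_min..level_max`. Within a level, clusters receive ordinal numbers
#' by order of first member appearance along the dendrogram leaf order, and
#' the label `"LL-OO"` (level-ordinal, zero-padded). Because consecutive
#' cuts of a binary tree differ by a single split, identical member-sets
#' recur across levels; the registry deduplicates them, naming each unique
#' CAP by its label at first appearance, so that levels `a..b` yield
#' `2 + 2 (b - a)` unique CAPs (58 for the standard 2..30 range).
#'
#' @param tree an `hclust` object from [ward_linkage()].
#' @param level_min,level_max inclusive cut range (defaults 2 and 30).
#' @return an object of class `cap_labeling`: a list with `levels`,
#'   `assignments` (N x n_levels integer matrix of within-level ordinals),
#'   `table` (one row per level-ordinal: `level`, `ordinal`, `label`,
#'   `unique_label`, `parent_label`, `n_members`, `new`), `members` (named
#'   list: unique CAP label -> member row indices), and `n_unique`.
#' @export
cut_levels <- function(tree, level_min = 2L, level_max = 30L) {
  if (!inherits(tree, "hclust"))
    stop("'tree' must be an hclust object", call. = FALSE)
  n <- length(tree$order)
  level_min <- stopifnot_scalar_count(level_min, "level_min", min = 2L)
  level_max <- stopifnot_scalar_count(level_max, "level_max", min = level_min)
  if (level_max > n)
    stop(sprintf("level_max (%d) exceeds the number of volumes (%d): level_max <= N required",
                 level_max, n), call. = FALSE)
  levels <- level_min:level_max
  assignments <- matrix(0L, n, length(levels),
                        dimnames = list(NULL, sprintf("L%02d", levels)))
  registry <- new.env(parent = emptyenv())   # member-set key -> unique label
  members <- list()
  rows <- list()
  prev_raw <- NULL; prev_level_labels <- NULL
  for (j in seq_along(levels)) {
    L <- levels[j]
    raw <- stats::cutree(tree, k = L)
    # ordinals by first appearance along the dendrogram leaf order
    leaf_first <- unique(raw[tree$order])
    ord_of <- integer(L); ord_of[leaf_first] <- seq_len(L)
    ords <- ord_of[raw]
    assignments[, j] <- ords
    lev_labels <- character(L)
    for (o in seq_len(L)) {
      mem <- which(ords == o)
      key <- paste(mem, collapse = ",")
      label <- sprintf("%02d-%02d", L, o)
      is_new <- !exists(key, envir = registry, inherits = FALSE)
      if (is_new) {
        assign(key, label, envir = registry)
        members[[label]] <- mem
      }
      ulabel <- get(key, envir = registry)
      lev_labels[o] <- ulabel
      parent <- NA_character_
      if (!is.null(prev_raw)) {
        parent <- prev_level_labels[prev_raw[mem[1]]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = L, ordinal = o, label = label, unique_label = ulabel,
        parent_label = parent, n_members = length(mem), new = is_new,
        stringsAsFactors = FALSE)
    }
    prev_raw <- ords
    prev_level_labels <- lev_labels
  }
  tab <- do.call(rbind, rows)
  structure(list(levels = levels, n = n, assignments = assignments,
                 table = tab, members = members,
                 n_unique = length(members)),
            class = "cap_labeling")
}

#' @export
print.cap_labeling <- function(x, ...) {
  cat(sprintf("cap_labeling: %d volumes, levels %d..%d, %d unique CAPs\n",
              x$n, min(x$levels), max(x$levels), x$n_unique))
  invisible(x)
}

#' Member rows of one CAP
#'
#' @param labeling a `cap_labeling`.
#' @param cap a unique CAP label such as `"02-01"`.
#' @return integer vector of member row indices.
#' @export
cap_members <- function(labeling, cap) {
  m <- labeling$members[[cap]]
  if (is.null(m)) stop(sprintf("unknown CAP '%s'", cap), call. = FALSE)
  m
}

#' Volume counts and fractions of the CAPs at one level
#'
#' @param labeling a `cap_labeling`.
#' @param level cut level in the labeling's range.
#' @return a data.frame with `label`, `unique_label`, `count`, `fraction`,
#'   and `pct` (integer percentage, half-up rounding). Counts sum to N and
#'   fractions to 1.
#' @export
occupancy_split <- function(labeling, level) {
  j <- match(level, labeling$levels)
  if (is.na(j)) stop("level outside the labeling's range", call. = FALSE)
  tab <- labeling$table[labeling$table$level == level, , drop = FALSE]
  counts <- tab$n_members
  data.frame(label = tab$label,
             unique_label = tab$unique_label,
             count = counts,
             fraction = counts / sum(counts),
             pct = split_percentages(counts),
             stringsAsFactors = FALSE)
}
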