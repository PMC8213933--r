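#' Per-subject CAP occupancy counts
#'
#' Counts how many of each subject's retained volumes fall in every unique
#' CAP. Within any single level, each subject's counts over that level's
#' CAPs sum to the subject's retained volume total (the cuts partition all
#' volumes).
#'
#' @param labeling a `cap_labeling`.
#' @param provenance data.frame with one row per volume-matrix row,
#'   containing at least `subject` (and optionally `group`); typically
#'   `vm$provenance`.
#' @param groups optional named vector of group labels per subject;
#'   defaults to the `group` column of `provenance`.
#' @return an object of class `occupancy_table`: list with `counts`
#'   (subjects x unique CAPs integer matrix), `groups` (named vector),
#'   `retained_total` (named vector), and `cap_table` (the labeling's
#'   level-ordinal table).
#' @export
occupancy_table <- function(labeling, provenance, groups = NULL) {
  if (nrow(provenance) != labeling$n)
    stop("provenance must cover every volume row", call. = FALSE)
  subjects <- unique(provenance$subject)
  if (is.null(groups)) {
    if (is.null(provenance$group))
      stop("no group labels in provenance and none supplied", call. = FALSE)
    groups <- vapply(subjects, function(s)
      as.character(provenance$group[provenance$subject == s][1]),
      character(1))
    names(groups) <- subjects
  }
  missing <- setdiff(subjects, names(groups))
  if (length(missing))
    stop("unknown subject(s) in provenance: ",
         paste(missing, collapse = ", "), call. = FALSE)
  caps <- names(labeling$members)
  subj_idx <- match(provenance$subject, subjects)
  counts <- matrix(0L, length(subjects), length(caps),
                   dimnames = list(subjects, caps))
  for (j in seq_along(caps)) {
    t <- tabulate(subj_idx[labeling$members[[caps[j]]]],
                  nbins = length(subjects))
    counts[, j] <- t
  }
  retained <- tabulate(subj_idx, nbins = length(subjects))
  names(retained) <- subjects
  structure(list(counts = counts, groups = groups[subjects],
                 retained_total = retained,
                 cap_table = labeling$table),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy_table: %d subjects x %d CAPs\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Group medians of one CAP's occupancy with bootstrap confidence intervals
#'
#' Percentile bootstrap of the within-group median, resampling subjects
#' with replacement inside each group.
#'
#' @param x numeric vector of per-subject counts for one CAP.
#' @param groups group label per subject (two or more levels allowed).
#' @param n_boot bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame with one row per group: `group`, `n`, `median`,
#'   `ci_lower`, `ci_upper`.
#' @export
group_median_ci <- function(x, groups, n_boot = 10000L, level = 0.95,
                            seed = 1L) {
  gl <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  if (length(x) != length(groups))
    stop("'x' and 'groups' lengths differ", call. = FALSE)
  if (any(tabulate(factor(groups, gl), nbins = length(gl)) == 0L))
    stop("every group must be nonempty", call. = FALSE)
  alpha <- (1 - level) / 2
  with_seed(seed, {
    out <- lapply(gl, function(g) {
      xs <- x[groups == g]
      boots <- vapply(seq_len(n_boot), function(i)
        median(xs[sample.int(length(xs), replace = TRUE)]), numeric(1))
      ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
      data.frame(group = g, n = length(xs), median = median(xs),
                 ci_lower = ci[1], ci_upper = ci[2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Mann-Whitney group tests across CAPs with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the per-subject
#' occupancy counts between the two groups, for every CAP; the exact null
#' distribution is used when both groups have at most 8 subjects and the
#' data are tie-free, otherwise the normal approximation with tie and
#' continuity correction. Raw p-values are adjusted with the
#' Benjamini-Hochberg procedure across all tested CAPs.
#'
#' @param occ an `occupancy_table` (must contain exactly two groups).
#' @param caps unique CAP labels to test (default: all columns).
#' @param q FDR level for the `significant` flag (default 0.05).
#' @param exact_max largest per-group size for which the exact test is
#'   attempted (default 8).
#' @return data.frame with `cap`, `p`, `p_adj`, `significant`.
#' @export
mannwhitney_fdr <- function(occ, caps = colnames(occ$counts), q = 0.05,
                            exact_max = 8L) {
  gl <- unique(occ$groups)
  if (length(gl) != 2L)
    stop("exactly two groups required", call. = FALSE)
  a <- occ$groups == gl[1]
  b <- occ$groups == gl[2]
  if (sum(a) < 2L || sum(b) < 2L)
    stop("each group needs at least 2 subjects", call. = FALSE)
  p <- vapply(caps, function(cl) {
    xa <- occ$counts[a, cl]; xb <- occ$counts[b, cl]
    if (length(unique(c(xa, xb))) == 1L) {
      warning(sprintf("CAP %s: constant occupancy in both groups, p = 1", cl),
              call. = FALSE)
      return(1)
    }
    exact <- sum(a) <= exact_max && sum(b) <= exact_max
    suppressWarnings(
      wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                  correct = TRUE)$p.value)
  }, numeric(1))
  p_adj <- p.adjust(p, method = "BH")
  data.frame(cap = caps, p = unname(p), p_adj = unname(p_adj),
             significant = unname(p_adj <= q),
             stringsAsFactors = FALSE, row.names = NULL)
}
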