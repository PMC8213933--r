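#' Build the CAP-by-group design matrix for one hierarchy level
#'
#' One row per volume, one column per CAP x group cell at the given level
#' (2L columns for two groups); every row is one-hot. CAPs to which one
#' group contributes no volumes are excluded from the contrast list with a
#' warning, since a two-sample comparison is undefined there.
#'
#' @param labeling a `cap_labeling`.
#' @param level hierarchy level to build the design for.
#' @param provenance per-row data.frame with `subject` (and `group` unless
#'   `groups` is given); typically `vm$provenance`.
#' @param groups optional named vector subject -> group label.
#' @return an object of class `cap_design`: list with `matrix` (N x 2L 0/1),
#'   `level`, `caps` (level labels), `group_names`, `contrasts` (data.frame
#'   `cap`, `testable`), and `row_group` / `row_cap` vectors.
#' @export
build_design <- function(labeling, level, provenance, groups = NULL) {
  j <- match(level, labeling$levels)
  if (is.na(j)) stop("level outside the labeling's range", call. = FALSE)
  if (nrow(provenance) != labeling$n)
    stop("provenance must cover every volume row", call. = FALSE)
  if (is.null(groups)) {
    row_group <- as.character(provenance$group)
  } else {
    row_group <- as.character(groups[provenance$subject])
  }
  if (anyNA(row_group)) stop("missing group labels", call. = FALSE)
  gl <- sort(unique(row_group))
  ords <- labeling$assignments[, j]
  tab <- labeling$table[labeling$table$level == level, , drop = FALSE]
  caps <- tab$unique_label[order(tab$ordinal)]
  row_cap <- caps[ords]
  cells <- paste(row_cap, row_group, sep = ":")
  all_cells <- as.vector(outer(caps, gl, paste, sep = ":"))
  m <- matrix(0L, labeling$n, length(all_cells),
              dimnames = list(NULL, all_cells))
  m[cbind(seq_len(labeling$n), match(cells, all_cells))] <- 1L
  testable <- vapply(caps, function(cl)
    all(vapply(gl, function(g) any(row_cap == cl & row_group == g),
               logical(1))), logical(1))
  if (any(!testable))
    warning("CAP(s) with no volumes from one group skipped: ",
            paste(caps[!testable], collapse = ", "), call. = FALSE)
  structure(list(matrix = m, level = level, caps = caps, group_names = gl,
                 contrasts = data.frame(cap = caps, testable = testable,
                                        stringsAsFactors = FALSE),
                 row_group = row_group, row_cap = row_cap),
            class = "cap_design")
}

# pooled-variance two-sample t per voxel from per-subject sufficient stats
.t_from_assignment <- function(sub_sums, sub_n, ss_total, is_a) {
  nA <- sum(sub_n[is_a]); nB <- sum(sub_n[!is_a])
  if (nA < 1 || nB < 1) return(NULL)
  sumA <- colSums(sub_sums[is_a, , drop = FALSE])
  sumB <- colSums(sub_sums[!is_a, , drop = FALSE])
  mA <- sumA / nA; mB <- sumB / nB
  ssw <- ss_total - nA * mA^2 - nB * mB^2
  ssw[ssw < 0] <- 0
  se <- sqrt(ssw / (nA + nB - 2) * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0] <- 0
  t
}

#' Subject-block permutation t-test for one CAP
#'
#' Voxel-wise two-sample t statistic (pooled variance, volumes as
#' observations) contrasting group A against group B over the member
#' volumes of one CAP. The null distribution is built by permuting group
#' labels at the subject level — all volumes of a subject travel together,
#' the subject being the exchangeability block — so inference is valid
#' despite the within-subject correlation the per-volume t ignores. When
#' the number of distinct subject-label assignments is at most `n_perm`
#' they are enumerated exhaustively and p-values are exact; otherwise
#' `n_perm` distinct random assignments are drawn without replacement,
#' excluding the observed labeling, and `p = (1 + #[perm >= obs]) /
#' (1 + n_perm)` — the observed labeling stands in for the identity, so p
#' never returns 0 and the minimum attainable value is `1 / (n_perm + 1)`. With `tfce = TRUE` each direction's t-map is enhanced
#' (positive part) and the permuted TFCE value at each voxel forms that
#' voxel's null, yielding TFCE-based uncorrected p-maps.
#'
#' @param vm a `volume_matrix` with group labels in its provenance (or
#'   supplied via `groups`).
#' @param members integer row indices of the CAP's member volumes.
#' @param groups optional named vector subject -> group label.
#' @param n_perm maximum number of permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @param tfce logical; also compute TFCE-based p-maps.
#' @param E,H,connectivity TFCE parameters (defaults 0.5, 2, 26).
#' @param dh TFCE threshold step; `NULL` uses max/100 per map.
#' @return an object of class `cap_contrast`: list with `t` (V-vector,
#'   A minus B), `n_perm_used`, `exhaustive`, `group_names`, and per
#'   direction (`"A>B"`, `"B>A"` in terms of the sorted group labels)
#'   `p` and, when enabled, `tfce` and `p_tfce`.
#' @export
permutation_ttest <- function(vm, members, groups = NULL, n_perm = 10000L,
                              seed = 1L, tfce = FALSE, E = 0.5, H = 2,
                              dh = NULL, connectivity = 26L) {
  if (!inherits(vm, "volume_matrix"))
    stop("'vm' must be a volume_matrix", call. = FALSE)
  x <- vm$values
  prov <- vm$provenance
  members <- as.integer(members)
  if (is.null(groups)) {
    groups <- tapply(as.character(prov$group), prov$subject, `[`, 1)
    groups <- groups[unique(prov$subject)]
  }
  gl <- sort(unique(as.character(groups)))
  if (length(gl) != 2L) stop("exactly two groups required", call. = FALSE)
  subjects <- names(groups)
  # per-subject sufficient statistics within the CAP
  subj_of_row <- match(prov$subject[members], subjects)
  xm <- x[members, , drop = FALSE]
  V <- ncol(xm)
  sub_n <- tabulate(subj_of_row, nbins = length(subjects))
  sub_sums <- matrix(0, length(subjects), V)
  nz <- which(sub_n > 0)
  for (s in nz)
    sub_sums[s, ] <- colSums(xm[subj_of_row == s, , drop = FALSE])
  ss_total <- colSums(xm^2)
  obs_a <- groups == gl[1]
  n_contrib <- c(sum(sub_n[obs_a] > 0), sum(sub_n[!obs_a] > 0))
  if (any(n_contrib < 2L))
    stop(sprintf("both groups must contribute >= 2 subjects to the CAP (got %d %s, %d %s)",
                 n_contrib[1], gl[1], n_contrib[2], gl[2]), call. = FALSE)
  t_obs <- .t_from_assignment(sub_sums, sub_n, ss_total, obs_a)

  S <- length(subjects)
  SA <- sum(obs_a)
  n_distinct <- choose(S, SA)
  if (n_distinct < 2)
    stop("fewer than 2 distinct subject-label permutations", call. = FALSE)
  exhaustive <- n_distinct <= n_perm
  assignments <- if (exhaustive) {
    combn(S, SA, simplify = FALSE)
  } else {
    # distinct random assignments, excluding the observed labeling, which
    # the +1 in the p-value already represents
    with_seed(seed, {
      obs_key <- paste(sort(which(obs_a)), collapse = ",")
      seen <- new.env(parent = emptyenv())
      out <- vector("list", n_perm)
      got <- 0L
      while (got < n_perm) {
        a <- sort(sample.int(S, SA))
        key <- paste(a, collapse = ",")
        if (key == obs_key ||
            !is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- a
      }
      out
    })
  }
  n_used <- length(assignments)

  if (tfce) {
    dims <- dim(vm$mask)
    inmask <- which(vm$mask)
    tfce_of <- function(tvec, sign) {
      img <- array(0, dims)
      img[inmask] <- if (sign > 0) pmax(tvec, 0) else pmax(-tvec, 0)
      enh <- cpp_tfce(as.numeric(img), as.integer(dims), E, H,
                      if (is.null(dh)) -1 else dh, as.integer(connectivity))
      enh[inmask]
    }
    obs_pos <- tfce_of(t_obs, 1)
    obs_neg <- tfce_of(t_obs, -1)
    cnt_pos_t <- numeric(V); cnt_neg_t <- numeric(V)
  }
  cnt_pos <- numeric(V); cnt_neg <- numeric(V)
  eps <- 1e-10
  for (a in assignments) {
    is_a <- logical(S); is_a[a] <- TRUE
    t_p <- .t_from_assignment(sub_sums, sub_n, ss_total, is_a)
    if (is.null(t_p)) {
      # a group lost all its volumes: count as extreme (conservative)
      cnt_pos <- cnt_pos + 1; cnt_neg <- cnt_neg + 1
      if (tfce) { cnt_pos_t <- cnt_pos_t + 1; cnt_neg_t <- cnt_neg_t + 1 }
      next
    }
    cnt_pos <- cnt_pos + (t_p >= t_obs - eps)
    cnt_neg <- cnt_neg + (-t_p >= -t_obs - eps)
    if (tfce) {
      cnt_pos_t <- cnt_pos_t + (tfce_of(t_p, 1) >= obs_pos - eps)
      cnt_neg_t <- cnt_neg_t + (tfce_of(t_p, -1) >= obs_neg - eps)
    }
  }
  p_of <- function(cnt) {
    if (exhaustive) cnt / n_used else (1 + cnt) / (1 + n_used)
  }
  dirs <- list()
  dirs[[paste0(gl[1], ">", gl[2])]] <- c(
    list(p = p_of(cnt_pos)),
    if (tfce) list(tfce = obs_pos, p_tfce = p_of(cnt_pos_t)))
  dirs[[paste0(gl[2], ">", gl[1])]] <- c(
    list(p = p_of(cnt_neg)),
    if (tfce) list(tfce = obs_neg, p_tfce = p_of(cnt_neg_t)))
  structure(list(t = t_obs, n_perm_used = n_used, exhaustive = exhaustive,
                 group_names = gl, directions = dirs, tfce_enabled = tfce),
            class = "cap_contrast")
}

#' Threshold-free cluster enhancement of a 3D statistic map
#'
#' `TFCE(v) = sum_h extent(v, h)^E * h^H * dh` over thresholds
#' `h = dh, 2 dh, ..., max`, where `extent(v, h)` is the voxel count of the
#' connected component containing v at threshold h. Only the positive part
#' is enhanced; each contrast direction supplies its own map.
#'
#' @param stat 3D numeric array.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` (default) uses max/100.
#' @param connectivity 6 or 26 (default 26).
#' @return 3D numeric array of enhanced values.
#' @export
tfce <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26L) {
  if (!is.array(stat) || length(dim(stat)) != 3L)
    stop("'stat' must be a 3D array", call. = FALSE)
  if (any(!is.finite(stat))) stop("non-finite values in map", call. = FALSE)
  out <- cpp_tfce(as.numeric(stat), as.integer(dim(stat)), E, H,
                  if (is.null(dh)) -1 else dh, as.integer(connectivity))
  array(out, dim(stat))
}

#' Benjamini-Hochberg FDR pooled across all contrasts
#'
#' Pools the uncorrected p-values of every contrast (all CAPs, both
#' directions, all levels) into one family and applies the
#' Benjamini-Hochberg step-up rule at level q: the cutoff is the largest
#' p(i) with p(i) <= i q / m. Because each direction of a two-sample
#' comparison is a one-tailed test, two-tailed reporting halves the pooled
#' cutoff per direction; significance masks use the per-tail threshold.
#'
#' @param p_maps named list of numeric p-value vectors (one per contrast
#'   direction).
#' @param q FDR level (default 0.05).
#' @param two_tailed also report the halved per-tail cutoff (default TRUE).
#' @param mask_threshold which cutoff the significance masks use:
#'   `"pooled"` (the BH cutoff over the pooled family, the default — the
#'   family already contains both directions of every contrast, and
#'   opposite directions can never both fall under it) or `"per_tail"`
#'   (the halved two-tailed reporting threshold, a stricter convention).
#' @return list with `fdr_threshold` (pooled BH cutoff), `per_tail_threshold`,
#'   `q`, `m` (family size), and `masks` (named list of logical vectors).
#' @export
pooled_fdr <- function(p_maps, q = 0.05, two_tailed = TRUE,
                       mask_threshold = c("pooled", "per_tail")) {
  mask_threshold <- match.arg(mask_threshold)
  if (!length(p_maps)) stop("empty p-value pool", call. = FALSE)
  if (is.numeric(p_maps)) p_maps <- list(pooled = p_maps)
  pool <- unlist(p_maps, use.names = FALSE)
  if (!length(pool)) stop("empty p-value pool", call. = FALSE)
  m <- length(pool)
  ps <- sort(pool)
  ok <- which(ps <= seq_len(m) * q / m)
  cutoff <- if (length(ok)) ps[max(ok)] else 0
  per_tail <- if (two_tailed) cutoff / 2 else cutoff
  thr <- if (mask_threshold == "pooled") cutoff else per_tail
  masks <- lapply(p_maps, function(p) p <= thr & cutoff > 0)
  list(fdr_threshold = cutoff, per_tail_threshold = per_tail, q = q, m = m,
       masks = masks)
}

#' Run all group contrasts for a set of hierarchy levels
#'
#' For every testable CAP at each requested level, runs the subject-block
#' permutation t-test in both directions (with TFCE by default) and pools
#' the resulting uncorrected p-maps across all contrasts for
#' Benjamini-Hochberg FDR control, mirroring a merged-then-corrected
#' randomise workflow.
#'
#' @param vm a `volume_matrix`.
#' @param labeling a `cap_labeling`.
#' @param levels levels to test (default: all in the labeling).
#' @param n_perm permutations per contrast (default 10000).
#' @param seed integer seed.
#' @param tfce use TFCE-based p-maps for the FDR pool (default TRUE).
#' @param q FDR level (default 0.05).
#' @param ... further arguments passed to [permutation_ttest()].
#' @return an object of class `contrast_result`: list with `contrasts`
#'   (named list of `cap_contrast`, one per tested CAP), `fdr` (the
#'   [pooled_fdr()] result), `masks` (named list, one logical V-vector per
#'   CAP x direction), `levels`, `q`, `tfce`.
#' @export
run_group_contrast <- function(vm, labeling, levels = labeling$levels,
                               n_perm = 10000L, seed = 1L, tfce = TRUE,
                               q = 0.05, ...) {
  tested <- character(0)
  contrasts <- list()
  for (L in levels) {
    des <- suppressWarnings(build_design(labeling, L, vm$provenance))
    for (cl in des$contrasts$cap[des$contrasts$testable]) {
      if (cl %in% names(contrasts)) next   # same member-set seen at an
      mem <- cap_members(labeling, cl)     # earlier level: identical test
      res <- tryCatch(
        permutation_ttest(vm, mem, n_perm = n_perm,
                          seed = seed + length(contrasts), tfce = tfce, ...),
        error = function(e) NULL)          # < 2 subjects in a group
      if (!is.null(res)) contrasts[[cl]] <- res
    }
  }
  if (!length(contrasts)) stop("no testable contrasts", call. = FALSE)
  p_maps <- list()
  for (cl in names(contrasts)) {
    for (d in names(contrasts[[cl]]$directions)) {
      dir <- contrasts[[cl]]$directions[[d]]
      p_maps[[paste(cl, d, sep = "|")]] <-
        if (tfce) dir$p_tfce else dir$p
    }
  }
  fdr <- pooled_fdr(p_maps, q = q, two_tailed = TRUE)
  structure(list(contrasts = contrasts, fdr = fdr, masks = fdr$masks,
                 levels = levels, q = q, tfce = tfce),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  nsig <- sum(vapply(x$masks, sum, numeric(1)))
  cat(sprintf(
    "contrast_result: %d CAP contrasts, pooled BH cutoff %.4g (per tail %.4g), %d significant voxel entries\n",
    length(x$contrasts), x$fdr$fdr_threshold, x$fdr$per_tail_threshold,
    nsig))
  invisible(x)
}
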