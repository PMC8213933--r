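# Shared fixtures and independent oracles, built in code at test time.

# small dataset reused across test files (built once per run)
.tiny_cache <- new.env(parent = emptyenv())
tiny_dataset <- function() {
  if (is.null(.tiny_cache$ds))
    .tiny_cache$ds <- generate_dataset(
      synth_config(seed = 7, n_subjects_per_group = 3L, n_volumes = 40L))
  .tiny_cache$ds
}
tiny_vm <- function() {
  if (is.null(.tiny_cache$vm))
    .tiny_cache$vm <- prepare_volume_matrix(tiny_dataset())
  .tiny_cache$vm
}
tiny_labeling <- function() {
  if (is.null(.tiny_cache$lab))
    .tiny_cache$lab <- cut_levels(
      ward_linkage(cosine_distance_matrix(tiny_vm())), 2, 30)
  .tiny_cache$lab
}

# Brute-force Ward oracle: greedy merging of the pair minimizing the
# explicit increase in within-cluster sum of squares, computed from raw
# coordinates; reported height is sqrt(2 * delta-ESS), the ward.D2 height
# for Euclidean input.
ward_oracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        muA <- colMeans(X[A, , drop = FALSE])
        muB <- colMeans(X[B, , drop = FALSE])
        delta <- length(A) * length(B) / (length(A) + length(B)) *
          sum((muA - muB)^2)
        if (delta < best) { best <- delta; bi <- i; bj <- j }
      }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights[step] <- sqrt(2 * best)
    sets[[step]] <- merged
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  list(heights = heights, sets = sets)
}

# member set created by each merge step of an hclust tree
hclust_merge_sets <- function(tree) {
  n <- length(tree$order)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    ch <- tree$merge[i, ]
    mem <- unlist(lapply(ch, function(x)
      if (x < 0) -x else out[[x]]))
    out[[i]] <- sort(mem)
  }
  out
}

# full null-condition run (generate + prepare + cluster), cached because
# several calibration checks share it
null_run <- function(seed = 1L) {
  key <- paste0("null", seed)
  if (is.null(.tiny_cache[[key]])) {
    ds <- generate_dataset(synth_preset("null", seed = seed))
    vm <- prepare_volume_matrix(ds)
    lab <- cut_levels(ward_linkage(cosine_distance_matrix(vm)), 2, 30)
    .tiny_cache[[key]] <- list(ds = ds, vm = vm, lab = lab)
  }
  .tiny_cache[[key]]
}

# ground-truth macro label of every retained volume, in volume-matrix row
# order (subjects in dataset order, time within subject)
retained_macro_labels <- function(dataset) {
  unlist(lapply(dataset$state_labels, function(st)
    st$macro[!st$censored]), use.names = FALSE)
}
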