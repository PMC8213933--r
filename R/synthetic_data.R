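#' Configuration for the synthetic brain-state generator
#'
#' Defines a multi-subject resting-state dataset in which every fMRI volume
#' is a noisy mixture of K network spatial maps whose signed amplitudes are
#' governed by a latent two-macro-state Markov chain (a "DMN-positive" and a
#' "DMN-negative / task-positive" regime), with optional sub-states inside
#' each macro-state, a group amplitude effect confined to selected networks,
#' and random volume censoring.
#'
#' The defaults describe the validation-scale conditions used throughout the
#' package: 6 subjects per group, 100 volumes per subject on a 16 x 16 x 12
#' grid with 8 networks, unit noise standard deviation matched to the unit
#' peak signal amplitude, and a 13.2% expected censoring rate. Pass
#' `n_subjects_per_group = c(27, 28)`, `n_volumes = 250` and
#' `n_networks = 14` for a full study-scale dataset.
#'
#' @param seed integer; master seed for all randomness in the dataset.
#' @param n_subjects_per_group integer of length 1 or 2; subjects in groups
#'   A and B (a single value is used for both).
#' @param n_volumes integer; volumes per subject before censoring.
#' @param grid_shape integer vector of length 3; voxels per axis.
#' @param n_networks integer K; number of network maps.
#' @param macro_transition_prob probability in (0, 1) of switching
#'   macro-state at each volume (stay probability is its complement).
#' @param substates_per_macro integer; sub-states nested in each macro-state.
#' @param amplitude_table K x (2 * substates_per_macro) matrix of signed
#'   network amplitudes, columns ordered macro 1 sub-states then macro 2
#'   sub-states; `NULL` uses [default_amplitude_table()].
#' @param noise_sd standard deviation of i.i.d. additive Gaussian voxel noise.
#' @param group_effect_delta signed amplitude offset added for group B in
#'   `affected_networks` whenever `affected_macro` is active.
#' @param affected_networks integer indices of networks carrying the group
#'   effect.
#' @param affected_macro macro-state (1 or 2) during which the group effect
#'   applies.
#' @param macro_switch_probs optional numeric of length 2: per-volume
#'   probability of leaving macro-state 1 and 2 respectively, overriding
#'   the symmetric `macro_transition_prob`; an asymmetric pair tilts the
#'   stationary occupancy (e.g. `c(0.078, 0.122)` gives the 61/39
#'   DMN-positive/negative split).
#' @param censor_fraction probability in \[0, 1) that a volume is censored.
#' @param blob_sigma Gaussian width (voxels) of the network blobs.
#' @param mask_threshold map value at or above which a voxel counts as
#'   network support; the analysis mask is the union of supports.
#' @return an object of class `synth_config`.
#' @seealso [generate_dataset()], [default_amplitude_table()]
#' @export
synth_config <- function(seed = 1L,
                         n_subjects_per_group = 6L,
                         n_volumes = 100L,
                         grid_shape = c(16L, 16L, 12L),
                         n_networks = 8L,
                         macro_transition_prob = 0.1,
                         macro_switch_probs = NULL,
                         substates_per_macro = 2L,
                         amplitude_table = NULL,
                         noise_sd = 1,
                         group_effect_delta = 0,
                         affected_networks = integer(0),
                         affected_macro = 1L,
                         censor_fraction = 0.132,
                         blob_sigma = 2,
                         mask_threshold = 0.1) {
  stopifnot_scalar_count(seed, "seed", min = 0L)
  if (!length(n_subjects_per_group) %in% 1:2)
    stop("'n_subjects_per_group' must have length 1 or 2", call. = FALSE)
  for (n in n_subjects_per_group)
    stopifnot_scalar_count(n, "n_subjects_per_group")
  if (length(n_subjects_per_group) == 1L)
    n_subjects_per_group <- rep(n_subjects_per_group, 2L)
  stopifnot_scalar_count(n_volumes, "n_volumes")
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("'grid_shape' must be 3 positive integers", call. = FALSE)
  stopifnot_scalar_count(n_networks, "n_networks")
  stopifnot_prob_open(macro_transition_prob, "macro_transition_prob")
  if (!is.null(macro_switch_probs)) {
    if (length(macro_switch_probs) != 2L)
      stop("'macro_switch_probs' must have length 2", call. = FALSE)
    for (p in macro_switch_probs) stopifnot_prob_open(p, "macro_switch_probs")
  }
  stopifnot_scalar_count(substates_per_macro, "substates_per_macro")
  if (length(censor_fraction) != 1L || censor_fraction < 0 ||
      censor_fraction >= 1)
    stop("'censor_fraction' must lie in [0, 1)", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be a finite nonnegative number", call. = FALSE)
  if (!is.finite(group_effect_delta))
    stop("'group_effect_delta' must be finite", call. = FALSE)
  if (!affected_macro %in% 1:2)
    stop("'affected_macro' must be 1 or 2", call. = FALSE)
  if (length(affected_networks) &&
      (any(affected_networks < 1) || any(affected_networks > n_networks)))
    stop("'affected_networks' must index networks in 1..K", call. = FALSE)
  if (is.null(amplitude_table))
    amplitude_table <- default_amplitude_table(n_networks,
                                               substates_per_macro)
  amplitude_table <- as.matrix(amplitude_table)
  if (!all(is.finite(amplitude_table)))
    stop("'amplitude_table' must be finite", call. = FALSE)
  if (nrow(amplitude_table) != n_networks ||
      ncol(amplitude_table) != 2L * substates_per_macro)
    stop(sprintf(
      "'amplitude_table' must be %d x %d (networks x sub-states), got %d x %d",
      n_networks, 2L * substates_per_macro,
      nrow(amplitude_table), ncol(amplitude_table)), call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_volumes = as.integer(n_volumes),
    grid_shape = as.integer(grid_shape),
    n_networks = as.integer(n_networks),
    macro_transition_prob = macro_transition_prob,
    macro_switch_probs = macro_switch_probs,
    substates_per_macro = as.integer(substates_per_macro),
    amplitude_table = amplitude_table,
    noise_sd = noise_sd,
    group_effect_delta = group_effect_delta,
    affected_networks = as.integer(affected_networks),
    affected_macro = as.integer(affected_macro),
    censor_fraction = censor_fraction,
    blob_sigma = blob_sigma,
    mask_threshold = mask_threshold
  ), class = "synth_config")
}

#' Default signed amplitude table
#'
#' The first ceiling(K/2) networks form a default-mode-like module, the rest
#' a task-positive module. In macro-state 1 the default-mode module is
#' active (+1) and the task module deactivated (-0.8); macro-state 2
#' reverses the signs. Sub-states beyond the first perturb the amplitudes
#' with a deterministic +/-35% alternating pattern so that sub-states differ
#' in direction, not merely in scale (cosine distance is scale-invariant).
#'
#' @param K number of networks.
#' @param substates_per_macro sub-states per macro-state.
#' @return a K x (2 * substates_per_macro) matrix.
#' @export
default_amplitude_table <- function(K, substates_per_macro = 2L) {
  dmn <- seq_len(ceiling(K / 2))
  base1 <- rep(-0.8, K); base1[dmn] <- 1      # macro 1: DMN-positive
  base2 <- rep(1, K);    base2[dmn] <- -0.8   # macro 2: task-positive
  cols <- lapply(1:2, function(m) {
    base <- if (m == 1L) base1 else base2
    vapply(seq_len(substates_per_macro), function(s) {
      if (s == 1L) return(base)
      tweak <- ifelse((seq_len(K) + s) %% 2 == 0, 0.35, -0.35)
      base * (1 + tweak)
    }, numeric(K))
  })
  tab <- cbind(cols[[1]], cols[[2]])
  rownames(tab) <- sprintf("net%02d", seq_len(K))
  colnames(tab) <- as.vector(outer(seq_len(substates_per_macro), 1:2,
                                   function(s, m) sprintf("m%d_s%d", m, s)))
  tab
}

#' Generate K smooth network blob maps on a voxel grid
#'
#' Places K blob centers by rejection sampling with a minimum pairwise
#' separation, then evaluates an isotropic Gaussian of width `sigma` around
#' each center, normalized to peak 1. The nearest-center voxel ownership is
#' recorded as the ground-truth atlas; because the blobs are identical and
#' isotropic, the max-value voxel assignment coincides with ownership up to
#' distance ties.
#'
#' @param grid_shape integer vector of length 3.
#' @param K number of maps.
#' @param seed integer seed for center placement.
#' @param sigma Gaussian width in voxels.
#' @param min_separation minimum pairwise center distance in voxels (>= 2).
#' @param margin voxels kept free of centers at each grid edge.
#' @return a list with `maps` (4D array, grid x K, each peak 1), `centers`
#'   (K x 3), and `ownership` (3D integer array, nearest center per voxel).
#' @export
make_network_maps <- function(grid_shape, K, seed = 1L, sigma = 2,
                              min_separation = 4, margin = 2) {
  grid_shape <- as.integer(grid_shape)
  K <- stopifnot_scalar_count(K, "K")
  inner <- pmax(grid_shape - 2L * margin, 0L)
  if (prod(inner) < K)
    stop(sprintf(
      paste("grid %s too small for K = %d blob centers with margin %d:",
            "need at least K placeable interior voxels"),
      paste(grid_shape, collapse = "x"), K, margin), call. = FALSE)
  centers <- with_seed(seed, {
    acc <- matrix(numeric(0), ncol = 3)
    tries <- 0L
    while (nrow(acc) < K) {
      tries <- tries + 1L
      if (tries > 5000L * K)
        stop(sprintf(
          paste("could not place %d blob centers with pairwise separation",
                ">= %g in grid %s: grid too small for K"),
          K, min_separation, paste(grid_shape, collapse = "x")),
          call. = FALSE)
      cand <- margin + runif(3) * (grid_shape - 2 * margin)
      if (nrow(acc) == 0L ||
          min(sqrt(rowSums(sweep(acc, 2, cand)^2))) >= min_separation)
        acc <- rbind(acc, cand)
    }
    acc
  })
  dimnames(centers) <- NULL
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  # squared distance of every voxel to every center
  d2 <- outer(rowSums(coords^2), rep(1, K)) -
    2 * coords %*% t(centers) +
    outer(rep(1, nrow(coords)), rowSums(centers^2))
  maps <- exp(-d2 / (2 * sigma^2))
  # centers are continuous; renormalize so each map peaks at exactly 1
  maps <- sweep(maps, 2, apply(maps, 2, max), "/")
  ownership <- max.col(-d2, ties.method = "first")
  list(maps = array(maps, c(grid_shape, K)),
       centers = centers,
       ownership = array(as.integer(ownership), grid_shape))
}

#' Simulate the latent (macro, sub) brain-state sequence
#'
#' First-order symmetric two-state Markov chain over the macro-states with
#' stay probability `1 - macro_transition_prob`; a sub-state is drawn
#' uniformly at each dwell onset and held until the next macro switch.
#'
#' @param n_volumes sequence length (>= 1).
#' @param macro_transition_prob per-volume switch probability in (0, 1).
#' @param substates_per_macro number of sub-states per macro-state.
#' @param seed integer seed.
#' @param start optional forced initial macro-state (1 or 2); by default the
#'   chain starts from its uniform stationary distribution.
#' @return a data.frame with integer columns `macro` and `sub`.
#' @export
simulate_state_sequence <- function(n_volumes, macro_transition_prob,
                                    substates_per_macro = 1L, seed = 1L,
                                    start = NULL) {
  n_volumes <- stopifnot_scalar_count(n_volumes, "n_volumes")
  stopifnot_prob_open(macro_transition_prob, "macro_transition_prob")
  S <- stopifnot_scalar_count(substates_per_macro, "substates_per_macro")
  with_seed(seed, {
    macro <- integer(n_volumes)
    sub <- integer(n_volumes)
    macro[1] <- if (is.null(start)) sample(1:2, 1L) else as.integer(start)
    sub[1] <- sample.int(S, 1L)
    if (n_volumes > 1L) {
      switches <- runif(n_volumes - 1L) < macro_transition_prob
      for (t in 2:n_volumes) {
        if (switches[t - 1L]) {
          macro[t] <- 3L - macro[t - 1L]
          sub[t] <- sample.int(S, 1L)   # new dwell onset
        } else {
          macro[t] <- macro[t - 1L]
          sub[t] <- sub[t - 1L]
        }
      }
    }
    data.frame(macro = macro, sub = sub)
  })
}

#' Generate a full synthetic multi-subject dataset
#'
#' Each retained or censored volume of subject s is the mixture
#' `sum_k a_k(state, group) * map_k + noise`, where the amplitude vector is
#' the column of the amplitude table selected by the volume's (macro, sub)
#' state; for subjects in group B the amplitudes of `affected_networks` are
#' shifted by `group_effect_delta` whenever `affected_macro` is active.
#' Censored volumes are flagged but kept in the series so that downstream
#' censoring is exercised. All randomness derives from `config$seed`.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `synth_dataset`: a list with `series` (named
#'   list of 4D arrays), `mask` (3D logical), `network_maps` (4D array),
#'   `ownership` (3D integer), `centers`, `state_labels` (named list of
#'   per-volume data.frames with `volume`, `macro`, `sub`, `censored`),
#'   `group_labels` (named character vector in A/B), `censor_masks` (named
#'   list of logical vectors), and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("'config' must be a synth_config object", call. = FALSE)
  nets <- make_network_maps(config$grid_shape, config$n_networks,
                            seed = config$seed, sigma = config$blob_sigma)
  mask <- apply(nets$maps, 1:3, max) >= config$mask_threshold
  V_grid <- prod(config$grid_shape)
  maps_flat <- matrix(nets$maps, nrow = V_grid, ncol = config$n_networks)
  S <- config$substates_per_macro
  nA <- config$n_subjects_per_group[1]
  nB <- config$n_subjects_per_group[2]
  n_sub <- nA + nB
  ids <- sprintf("sub%02d", seq_len(n_sub))
  groups <- c(rep("A", nA), rep("B", nB))
  names(groups) <- ids

  series <- vector("list", n_sub); names(series) <- ids
  state_labels <- vector("list", n_sub); names(state_labels) <- ids
  censor_masks <- vector("list", n_sub); names(censor_masks) <- ids

  with_seed(config$seed, {
    for (i in seq_len(n_sub)) {
      states <- local({
        # draw the chain inline so it shares the master stream
        leave <- if (is.null(config$macro_switch_probs))
          rep(config$macro_transition_prob, 2)
        else config$macro_switch_probs
        # start from the stationary distribution of the chain
        p1 <- leave[2] / sum(leave)
        macro <- integer(config$n_volumes); sub <- integer(config$n_volumes)
        macro[1] <- if (runif(1) < p1) 1L else 2L
        sub[1] <- sample.int(S, 1L)
        if (config$n_volumes > 1L)
          for (t in 2:config$n_volumes) {
            if (runif(1) < leave[macro[t - 1L]]) {
              macro[t] <- 3L - macro[t - 1L]; sub[t] <- sample.int(S, 1L)
            } else {
              macro[t] <- macro[t - 1L]; sub[t] <- sub[t - 1L]
            }
          }
        data.frame(macro = macro, sub = sub)
      })
      amp <- config$amplitude_table[, (states$macro - 1L) * S + states$sub,
                                    drop = FALSE]
      if (groups[i] == "B" && length(config$affected_networks) &&
          config$group_effect_delta != 0) {
        hit <- states$macro == config$affected_macro
        amp[config$affected_networks, hit] <-
          amp[config$affected_networks, hit] + config$group_effect_delta
      }
      dat <- maps_flat %*% amp            # V_grid x n_volumes
      if (config$noise_sd > 0)
        dat <- dat + rnorm(length(dat), sd = config$noise_sd)
      censored <- if (config$censor_fraction > 0)
        runif(config$n_volumes) < config$censor_fraction
      else rep(FALSE, config$n_volumes)
      # guarantee >= 2 retained volumes for normalization
      if (sum(!censored) < 2L)
        censored[seq_len(min(2L, config$n_volumes))] <- FALSE
      series[[i]] <- array(dat, c(config$grid_shape, config$n_volumes))
      state_labels[[i]] <- data.frame(volume = seq_len(config$n_volumes),
                                      macro = states$macro,
                                      sub = states$sub,
                                      censored = censored)
      censor_masks[[i]] <- censored
    }
  })
  structure(list(series = series, mask = mask, network_maps = nets$maps,
                 ownership = nets$ownership, centers = nets$centers,
                 state_labels = state_labels, group_labels = groups,
                 censor_masks = censor_masks, config = config),
            class = "synth_dataset")
}

#' Named synthetic study conditions
#'
#' Fixed presets used throughout the validation suite:
#' \describe{
#'   \item{`"null"`}{the default validation scale (6 + 6 subjects, 100
#'     volumes, 8 networks) with no group effect — for calibration checks.}
#'   \item{`"effect"`}{the same scale with the default injected group
#'     effect: amplitude offset of +1 (one noise SD) for group B in
#'     networks 1 and 2 during macro-state 2, i.e. reduced deactivation of
#'     two default-mode-module networks.}
#'   \item{`"study"`}{full study scale: 27 + 28 subjects, 250 volumes, 14
#'     networks on a 24 x 24 x 18 grid, with asymmetric macro dwell
#'     probabilities giving a 61/39 DMN-positive/negative occupancy.}
#' }
#'
#' @param preset one of `"null"`, `"effect"`, `"study"`.
#' @param seed master seed.
#' @return a [synth_config()].
#' @export
synth_preset <- function(preset = c("null", "effect", "study"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    null = synth_config(seed = seed),
    effect = synth_config(seed = seed, group_effect_delta = 1,
                          affected_networks = c(1L, 2L),
                          affected_macro = 2L),
    study = synth_config(seed = seed, n_subjects_per_group = c(27L, 28L),
                         n_volumes = 250L, grid_shape = c(24L, 24L, 18L),
                         n_networks = 14L,
                         macro_switch_probs = c(0.078, 0.122)))
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "synth_dataset: %d subjects (%d A / %d B), %d volumes each, grid %s\n",
    length(x$series), cfg$n_subjects_per_group[1],
    cfg$n_subjects_per_group[2], cfg$n_volumes,
    paste(cfg$grid_shape, collapse = "x")))
  cat(sprintf("  %d networks, %d in-mask voxels, %.1f%% volumes censored\n",
              cfg$n_networks, sum(x$mask),
              100 * mean(unlist(x$censor_masks))))
  invisible(x)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Per-subject 4D NIfTI series, the 3D mask, the K-map atlas stack, a
#' ground-truth state table and a subject table (both TSV).
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(dataset$series)) {
    p <- file.path(dir, paste0(id, "_bold.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(dataset$series[[id]]), p,
                       datatype = "double")
    paths[paste0("series_", id)] <- p
  }
  p <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dataset$mask + 0), p,
                     datatype = "uint8")
  paths["mask"] <- p
  p <- file.path(dir, "atlas_maps.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dataset$network_maps), p,
                     datatype = "double")
  paths["atlas"] <- p
  truth <- do.call(rbind, lapply(names(dataset$state_labels), function(id)
    cbind(subject = id, dataset$state_labels[[id]])))
  p <- file.path(dir, "ground_truth.tsv")
  write_tsv(truth, p)
  paths["ground_truth"] <- p
  subjects <- data.frame(subject = names(dataset$group_labels),
                         group = unname(dataset$group_labels))
  p <- file.path(dir, "subjects.tsv")
  write_tsv(subjects, p)
  paths["subjects"] <- p
  invisible(paths)
}
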