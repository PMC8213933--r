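test_that("config validation rejects malformed settings", {
  expect_error(synth_config(macro_transition_prob = 0), "open interval")
  expect_error(synth_config(censor_fraction = 1), "\\[0, 1\\)")
  expect_error(synth_config(n_volumes = 0), "integer >= 1")
  expect_error(synth_config(amplitude_table = matrix(1, 3, 4),
                            n_networks = 8), "8 x 4")
  expect_error(synth_config(affected_networks = 9, n_networks = 8),
               "1..K")
})

test_that("network maps are peak-1 blobs with disjoint argmax voxels", {
  one <- make_network_maps(c(10, 10, 8), K = 1, seed = 2)
  expect_equal(max(one$maps), 1, tolerance = 1e-12)
  expect_true(all(one$maps >= 0))

  two <- make_network_maps(c(16, 16, 16), K = 2, seed = 5)
  am <- apply(matrix(two$maps, ncol = 2), 2, which.max)
  expect_length(unique(am), 2L)

  expect_error(make_network_maps(c(3, 3, 3), K = 14, seed = 1),
               "too small")
})

test_that("max-value voxel assignment reproduces blob ownership", {
  nets <- make_network_maps(c(24, 24, 18), K = 14, seed = 7)
  mask <- apply(nets$maps, 1:3, max) >= 0.1
  atlas <- assign_voxels(nets$maps, mask)
  own <- nets$ownership[mask]
  expect_gte(mean(own == atlas$assignment, na.rm = TRUE), 0.95)
})

test_that("macro chain is symmetric, Markov, and respects the forced start", {
  s1 <- simulate_state_sequence(1, 0.5, seed = 3)
  expect_true(s1$macro %in% 1:2 && nrow(s1) == 1)

  long <- simulate_state_sequence(10000, 0.2, substates_per_macro = 2,
                                  seed = 11)
  occ1 <- mean(long$macro == 1)
  expect_gte(occ1, 0.45); expect_lte(occ1, 0.55)
  # sub-state constant within a dwell
  dwell_breaks <- which(diff(long$macro) != 0)
  same <- diff(long$sub) != 0 & diff(long$macro) == 0
  expect_false(any(same))

  frozen <- simulate_state_sequence(5000, 1e-9, seed = 4, start = 1)
  expect_true(all(frozen$macro == 1L))
})

test_that("identical configs generate identical datasets", {
  cfg <- synth_config(seed = 21, n_subjects_per_group = 2, n_volumes = 12,
                      grid_shape = c(10, 10, 8), n_networks = 3)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$series, d2$series)
  expect_identical(d1$state_labels, d2$state_labels)
})

test_that("noiseless volumes are exact map mixtures, identical per sub-state", {
  cfg <- synth_config(seed = 9, n_subjects_per_group = 1, n_volumes = 30,
                      noise_sd = 0, censor_fraction = 0)
  ds <- generate_dataset(cfg)
  st <- ds$state_labels[[1]]
  key <- paste(st$macro, st$sub)
  dup <- which(duplicated(key))
  expect_gt(length(dup), 0)
  flat <- matrix(ds$series[[1]], ncol = cfg$n_volumes)
  for (i in dup) {
    first <- match(key[i], key)
    expect_identical(flat[, i], flat[, first])
  }
  # exact linear combination of the network maps
  mf <- matrix(ds$network_maps, ncol = cfg$n_networks)
  S <- cfg$substates_per_macro
  a <- cfg$amplitude_table[, (st$macro[1] - 1) * S + st$sub[1]]
  expect_equal(flat[, 1], as.numeric(mf %*% a), tolerance = 1e-12)
})

test_that("same-substate volumes are cosine-identical, cross-substate not", {
  cfg <- synth_config(seed = 13, n_subjects_per_group = 1, n_volumes = 40,
                      noise_sd = 0, censor_fraction = 0)
  ds <- generate_dataset(cfg)
  st <- ds$state_labels[[1]]
  flat <- t(matrix(ds$series[[1]], ncol = cfg$n_volumes))[, which(ds$mask)]
  d <- cosine_distance_matrix(flat)
  key <- paste(st$macro, st$sub)
  same <- outer(key, key, "==")
  off <- upper.tri(d)
  expect_lt(max(d[off & same]), 1e-10)
  expect_gt(min(d[off & !same]), 1e-6)
})

test_that("group effect is confined to affected networks (noiseless)", {
  cfg <- synth_config(seed = 17, n_subjects_per_group = 2, n_volumes = 40,
                      noise_sd = 0, censor_fraction = 0,
                      group_effect_delta = 0.5,
                      affected_networks = c(1, 2), affected_macro = 2)
  ds <- generate_dataset(cfg)
  mf <- matrix(ds$network_maps, ncol = cfg$n_networks)
  # mean volume during the affected macro-state, per group
  gmean <- function(g) {
    vols <- list()
    for (id in names(ds$series)[ds$group_labels == g]) {
      st <- ds$state_labels[[id]]
      hit <- which(st$macro == cfg$affected_macro & st$sub == 1)
      flat <- matrix(ds$series[[id]], ncol = cfg$n_volumes)
      vols[[id]] <- rowMeans(flat[, hit, drop = FALSE])
    }
    Reduce(`+`, vols) / length(vols)
  }
  diffv <- gmean("B") - gmean("A")
  affected_support <- rowSums(mf[, c(1, 2), drop = FALSE]) > 1e-3
  expect_gt(min(abs(diffv[affected_support & mf[, 1] > 0.5])), 0.2)
  expect_lt(max(abs(diffv[!affected_support])), 0.5 * 2e-3)
})

test_that("realized censoring matches the configured 13.2% rate", {
  cfg <- synth_config(seed = 31, n_subjects_per_group = c(27, 28),
                      n_volumes = 250, grid_shape = c(8, 8, 6),
                      n_networks = 2, noise_sd = 0,
                      censor_fraction = 0.132)
  ds <- generate_dataset(cfg)
  frac <- mean(vapply(ds$censor_masks, mean, numeric(1)))
  expect_lt(abs(frac - 0.132), 0.01)
})

test_that("dataset round-trips to NIfTI and TSV on disk", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  paths <- write_synth_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[["series_sub01"]])
  expect_equal(as.array(back), ds$series[[1]], ignore_attr = TRUE)
  truth <- read_tsv(paths[["ground_truth"]])
  expect_equal(nrow(truth), length(ds$series) * ds$config$n_volumes)
  subj <- read_tsv(paths[["subjects"]])
  expect_equal(subj$group, unname(ds$group_labels))
})
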