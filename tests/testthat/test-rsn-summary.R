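make_atlas <- function() {
  # two 2x2x1 networks side by side on a 4x2x1 grid
  mask <- array(TRUE, c(4, 2, 1))
  z1 <- array(0, c(4, 2, 1)); z1[1:2, , 1] <- 3
  z2 <- array(0, c(4, 2, 1)); z2[3:4, , 1] <- 2
  assign_voxels(list(z1, z2), mask, names = c("n1", "n2"))
}

test_that("voxels go to the network with the highest absolute z", {
  mask <- array(TRUE, c(3, 1, 1))
  z <- list(array(c(2, 0, 1), c(3, 1, 1)),
            array(c(-5, 0, 1), c(3, 1, 1)),
            array(c(1, 0, 1), c(3, 1, 1)))
  atlas <- assign_voxels(z, mask)
  expect_equal(atlas$assignment[1], 2L)           # |-5| wins
  expect_true(is.na(atlas$assignment[2]))         # all-zero voxel
  expect_equal(atlas$assignment[3], 1L)           # tie -> lowest index
  expect_equal(atlas$n_ties, 1L)
  expect_error(assign_voxels(z, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("synthetic atlas assignment recovers blob ownership", {
  ds <- tiny_dataset()
  atlas <- assign_voxels(ds$network_maps, ds$mask)
  own <- ds$ownership[ds$mask]
  expect_gte(mean(own == atlas$assignment, na.rm = TRUE), 0.95)
})

test_that("network x CAP mean-z entries average the assigned voxels", {
  atlas <- make_atlas()
  zconst <- structure(list(z = rep(3, 8), undefined = rep(FALSE, 8),
                           n_members = 10), class = "cap_zmap")
  # n1 owns voxels 1,2,5,6 and n2 owns 3,4,7,8 (x-fastest order):
  # give each network two +2 and two -2 voxels so both average to zero
  zsplit <- structure(list(z = c(2, 2, -2, -2, -2, -2, 2, 2),
                           undefined = rep(FALSE, 8), n_members = 10),
                      class = "cap_zmap")
  M <- cap_rsn_mean_matrix(list(c1 = zconst, c2 = zsplit), atlas)
  expect_equal(M["n1", "c1"], 3)
  expect_equal(M["n2", "c1"], 3)
  expect_equal(M["n1", "c2"], 0)    # +2, +2, -2, -2 average to zero
  expect_equal(M["n2", "c2"], 0)
})

test_that("mean-z sign pattern follows the amplitude table (noiseless)", {
  cfg <- synth_config(seed = 29, n_subjects_per_group = 2, n_volumes = 60,
                      noise_sd = 0)
  ds <- generate_dataset(cfg)
  vm <- prepare_volume_matrix(ds)
  lab <- cut_levels(ward_linkage(cosine_distance_matrix(vm)), 2, 2)
  macro <- retained_macro_labels(ds)
  atlas <- assign_voxels(ds$network_maps, ds$mask)
  zl <- compute_all_zmaps(vm, lab)
  M <- cap_rsn_mean_matrix(zl, atlas)
  cap1 <- names(which.max(vapply(lab$members, function(m)
    mean(macro[m] == 1), numeric(1))))
  cap2 <- setdiff(colnames(M), cap1)
  dmn <- seq_len(ceiling(cfg$n_networks / 2))
  expect_true(all(M[dmn, cap1] > 0))
  expect_true(all(M[-dmn, cap1] < 0))
  expect_true(all(M[dmn, cap2] < 0))
  expect_true(all(M[-dmn, cap2] > 0))
})

test_that("biclustering orders duplicates together and is equivariant", {
  set.seed(15)
  M <- matrix(rnorm(5 * 6), 5, 6)
  Mdup <- M; Mdup[, 4] <- Mdup[, 2]           # identical columns
  bic <- bicluster_matrix(Mdup)
  pos <- match(c(2, 4), bic$col_order)
  expect_equal(abs(diff(pos)), 1L)
  expect_setequal(bic$row_order, 1:5)
  expect_setequal(bic$col_order, 1:6)

  # permuting input columns gives the same clustering up to relabeling:
  # identical merge heights and identical co-membership at every cut
  bic0 <- bicluster_matrix(M)
  perm <- c(3, 1, 6, 2, 5, 4)
  bic2 <- bicluster_matrix(M[, perm])
  expect_equal(bic2$col_tree$height, bic0$col_tree$height,
               tolerance = 1e-10)
  for (k in 2:5) {
    c0 <- cutree(bic0$col_tree, k)[perm]   # in permuted column space
    c2 <- cutree(bic2$col_tree, k)
    expect_equal(outer(c0, c0, "=="), outer(c2, c2, "=="))
  }
  expect_equal(bic2$row_tree$height, bic0$row_tree$height,
               tolerance = 1e-10)

  tiny <- matrix(c(1, 2, 3, 4), 2, 2)
  b3 <- bicluster_matrix(tiny)
  expect_setequal(b3$row_order, 1:2)
  expect_setequal(b3$col_order, 1:2)

  Mz <- rbind(M, 0)
  expect_message(b4 <- bicluster_matrix(Mz), "zero-norm")
  expect_equal(b4$row_order[6], 6L)
})

test_that("significant fractions, decile mask, and report are consistent", {
  atlas <- make_atlas()   # n1 = 4 voxels, n2 = 4 voxels
  m1 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  m2 <- rep(FALSE, 8)
  masks <- list("c1|A>B" = m1, "c1|B>A" = m2)
  sf <- significant_fractions(masks, atlas)
  # grid is x-fastest: network 1 owns voxels 1,2,5,6; mask hits 1,2 of it
  expect_equal(sf$pct[["A>B"]]["n1", "c1"], 50)
  expect_equal(sf$pct[["A>B"]]["n2", "c1"], 25)
  expect_true(all(sf$pct[["B>A"]] == 0))
  # partition property: network counts sum to the total in-atlas count
  expect_equal(sum(sf$pct[["A>B"]][, "c1"] / 100 * atlas$network_sizes),
               sum(m1))
  expect_equal(sf$report$voxels[1], 3L)
  expect_match(sf$report$areas[1], "n1, 50% \\(2/4\\)")
  expect_true(all(unlist(sf$decile_mask[["B>A"]]) == FALSE))

  sf0 <- significant_fractions(list("c1|A>B" = m2), atlas)
  expect_true(all(sf0$pct[["A>B"]] == 0))
  expect_false(any(unlist(sf0$decile_mask)))
})

test_that("injected effect peaks in the affected networks' rows", {
  cfg <- synth_config(seed = 59, n_subjects_per_group = 4, n_volumes = 60,
                      group_effect_delta = 1.5,
                      affected_networks = c(1, 2), affected_macro = 2)
  ds <- generate_dataset(cfg)
  vm <- prepare_volume_matrix(ds)
  lab <- cut_levels(ward_linkage(cosine_distance_matrix(vm)), 2, 2)
  contrast <- run_group_contrast(vm, lab, levels = 2, n_perm = 200,
                                 seed = 4, tfce = TRUE)
  atlas <- assign_voxels(ds$network_maps, ds$mask)
  sf <- significant_fractions(contrast$masks, atlas)
  macro <- retained_macro_labels(ds)
  cap_eff <- names(which.max(vapply(lab$members, function(m)
    mean(macro[m] == 2), numeric(1))))
  pct_col <- sf$pct[["B>A"]][, cap_eff]
  expect_true(which.max(pct_col) %in% c(1, 2))
})
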