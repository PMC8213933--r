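test_that("design matrix is one-hot with exact cell membership", {
  vm <- tiny_vm()
  lab <- tiny_labeling()
  des <- build_design(lab, 2, vm$provenance)
  expect_equal(ncol(des$matrix), 4L)
  expect_true(all(rowSums(des$matrix) == 1L))
  # column sums equal the occupancy cross-tabulation
  occ <- occupancy_table(lab, vm$provenance)
  for (cl in des$caps) {
    for (g in des$group_names) {
      expect_equal(sum(des$matrix[, paste(cl, g, sep = ":")]),
                   sum(occ$counts[occ$groups == g, cl]))
    }
  }
})

test_that("full enumeration yields exact p-values on the 1/20 grid", {
  # 3 + 3 subjects: C(6,3) = 20 label assignments
  cfg <- synth_config(seed = 37, n_subjects_per_group = 3, n_volumes = 20,
                      grid_shape = c(8, 8, 6), n_networks = 2,
                      censor_fraction = 0)
  ds <- generate_dataset(cfg)
  vm <- prepare_volume_matrix(ds)
  res <- permutation_ttest(vm, seq_len(nrow(vm$values)), n_perm = 1000)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, 20L)
  for (d in res$directions) {
    mult <- d$p * 20
    expect_equal(mult, round(mult), tolerance = 1e-9)
    expect_true(all(d$p > 0 & d$p <= 1))
  }
})

test_that("perfectly separated groups reach the minimum attainable p", {
  cfg <- synth_config(seed = 41, n_subjects_per_group = 3, n_volumes = 60,
                      grid_shape = c(10, 10, 8), n_networks = 2,
                      noise_sd = 0, censor_fraction = 0,
                      group_effect_delta = 5,
                      affected_networks = 1, affected_macro = 2)
  ds <- generate_dataset(cfg)
  vm <- prepare_volume_matrix(ds)
  macro <- retained_macro_labels(ds)
  members <- which(macro == 2)
  # every subject must dwell in macro-state 2 for the minimum p to be 1/20
  expect_equal(length(unique(vm$provenance$subject[members])), 6L)
  res <- permutation_ttest(vm, members)
  mf <- matrix(ds$network_maps, ncol = cfg$n_networks)
  core <- which(mf[which(ds$mask), 1] > 0.7)
  dirBA <- res$directions[["B>A"]]
  expect_true(all(dirBA$p[core] == 1 / res$n_perm_used))
})

test_that("directional p-values are complementary and masks disjoint", {
  vm <- tiny_vm()
  lab <- tiny_labeling()
  res <- permutation_ttest(vm, cap_members(lab, "02-01"), n_perm = 200,
                           seed = 2)
  pA <- res$directions[[1]]$p
  pB <- res$directions[[2]]$p
  expect_true(all(pA + pB >= 1))      # both tails can never be small
  fdr <- pooled_fdr(list(a = pA, b = pB), q = 0.05)
  expect_equal(sum(fdr$masks$a & fdr$masks$b), 0L)
})

test_that("TFCE matches the closed form and the cubic scaling law", {
  g <- array(0, c(9, 9, 9))
  h0 <- 2.7
  g[5, 5, 5] <- h0
  # isolated voxel: integral of 1^E * h^2 dh from 0 to h0 = h0^3 / 3
  enh <- tfce(g, dh = h0 / 1000)
  expect_lt(abs(enh[5, 5, 5] - h0^3 / 3) / (h0^3 / 3), 0.005)

  set.seed(3)
  m <- array(pmax(rnorm(10 * 10 * 8), 0), c(10, 10, 8))
  e1 <- tfce(m)
  e2 <- tfce(2.5 * m)
  expect_equal(e2, 2.5^3 * e1, tolerance = 1e-6)

  expect_equal(tfce(array(0, c(4, 4, 4))), array(0, c(4, 4, 4)))
  expect_error(tfce(matrix(0, 3, 3)), "3D")
})

test_that("TFCE preserves ranking within a single connected component", {
  g <- array(0, c(12, 6, 6))
  g[3:9, 3, 3] <- c(1, 2, 3, 5, 3, 2, 1)   # one ridge-shaped component
  enh <- tfce(g, dh = 0.01)
  v <- g[g > 0]; e <- enh[g > 0]
  expect_equal(order(e), order(v))
})

test_that("connected components are counted with 26- vs 6-connectivity", {
  img <- array(0, c(4, 4, 4))
  img[1, 1, 1] <- 1
  img[2, 2, 2] <- 1    # diagonal touch: one 26-component, two 6-components
  lab26 <- hicap:::cpp_label_components(as.numeric(img), dim(img), 0.5, 26L)
  lab6 <- hicap:::cpp_label_components(as.numeric(img), dim(img), 0.5, 6L)
  expect_equal(attr(lab26, "n_components"), 1L)
  expect_equal(attr(lab6, "n_components"), 2L)
})

test_that("pooled BH cutoff and the two-tailed halving rule are exact", {
  pool <- c(0.001, 0.02, 0.03, 0.04)
  res <- pooled_fdr(pool, q = 0.05, two_tailed = FALSE)
  expect_equal(res$fdr_threshold, 0.04)
  expect_true(all(res$masks$pooled))

  # a pool whose realized cutoff is .004 reports a per-tail .002
  pool2 <- c(0.001, 0.004, rep(0.9, 23))
  res2 <- pooled_fdr(pool2, q = 0.05, two_tailed = TRUE)
  expect_equal(res2$fdr_threshold, 0.004)
  expect_equal(res2$per_tail_threshold, 0.002)

  none <- pooled_fdr(rep(1, 50))
  expect_equal(none$fdr_threshold, 0)
  expect_false(any(none$masks[[1]]))
  expect_error(pooled_fdr(list()), "empty")
})

test_that("permutation p-values are valid under the null", {
  cfg <- synth_config(seed = 53, n_subjects_per_group = 4, n_volumes = 40,
                      grid_shape = c(10, 10, 8), n_networks = 4)
  ds <- generate_dataset(cfg)
  vm <- prepare_volume_matrix(ds)
  res <- permutation_ttest(vm, seq_len(nrow(vm$values)), n_perm = 200,
                           seed = 3)
  for (alpha in c(0.01, 0.05)) {
    for (d in res$directions)
      expect_lte(mean(d$p <= alpha), alpha + 0.02)
  }
})
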