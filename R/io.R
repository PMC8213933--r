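#' Write a data.frame as TSV
#'
#' Tab-separated, no quoting, no row names: the portable table format used
#' for every tabular artifact.
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' @param output_dir directory for all artifacts.
#' @param level_min,level_max hierarchy cut range (defaults 2, 30).
#' @param n_perm permutations per contrast (default 10000; the synthetic
#'   presets use 500).
#' @param q FDR level (default 0.05).
#' @param seed master seed.
#' @param tfce enable TFCE in the contrasts (default TRUE).
#' @param occupancy_fractions report occupancy as per-subject fractions of
#'   retained volumes instead of raw counts (default FALSE).
#' @param synth a [synth_config()] for the simulate stage (optional).
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir, level_min = 2L, level_max = 30L,
                       n_perm = 10000L, q = 0.05, seed = 1L, tfce = TRUE,
                       occupancy_fractions = FALSE, synth = NULL) {
  stopifnot_scalar_count(level_min, "level_min", min = 2L)
  stopifnot_scalar_count(level_max, "level_max", min = level_min)
  stopifnot_prob_open(q, "q")
  structure(list(output_dir = output_dir, level_min = as.integer(level_min),
                 level_max = as.integer(level_max),
                 n_perm = as.integer(n_perm), q = q,
                 seed = as.integer(seed), tfce = isTRUE(tfce),
                 occupancy_fractions = isTRUE(occupancy_fractions),
                 synth = synth),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Top-level keys mirror the [run_config()] arguments; an optional `synth`
#' block mirrors [synth_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  synth <- NULL
  if (!is.null(raw$synth)) {
    sargs <- raw$synth
    if (!is.null(sargs$amplitude_table))
      sargs$amplitude_table <- matrix(unlist(sargs$amplitude_table),
                                      nrow = sargs$n_networks, byrow = TRUE)
    synth <- do.call(synth_config, sargs)
  }
  args <- raw[setdiff(names(raw), "synth")]
  args$synth <- synth
  do.call(run_config, args)
}

#' Run the full CAP pipeline on a synthetic dataset
#'
#' simulate -> prepare -> cluster -> z-maps -> occupancy -> contrasts ->
#' network summary, writing every artifact (NIfTI images, TSV tables, a PNG
#' heatmap) under `config$output_dir` together with a JSON manifest listing
#' the seed, the configuration, the realized pooled BH cutoff, and every
#' file written.
#'
#' @param config a [run_config()] whose `synth` field is set.
#' @param dataset optionally, an already generated `synth_dataset` (skips
#'   the simulate stage).
#' @return invisibly, a list with the in-memory results (`dataset`, `vm`,
#'   `labeling`, `zmaps`, `occupancy`, `contrast`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  if (is.null(dataset)) {
    if (is.null(config$synth))
      stop("config$synth must be set when no dataset is supplied",
           call. = FALSE)
    dataset <- generate_dataset(config$synth)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- write_synth_dataset(dataset, file.path(config$output_dir,
                                                      "data"))
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[%s] %s (%.1f s elapsed)",
                    format(Sys.time(), "%H:%M:%S"), stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  log_stage("prepare")
  vm <- prepare_volume_matrix(dataset)
  log_stage("cluster")
  d <- cosine_distance_matrix(vm)
  tree <- ward_linkage(d)
  level_max <- min(config$level_max, nrow(vm$values))
  labeling <- cut_levels(tree, config$level_min, level_max)
  sizes <- integer(nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    ch <- tree$merge[i, ]
    sizes[i] <- sum(ifelse(ch < 0, 1L, sizes[pmax(ch, 1)]))
  }
  linkage_tab <- data.frame(child1 = tree$merge[, 1],
                            child2 = tree$merge[, 2],
                            height = tree$height,
                            size = sizes)
  p <- file.path(config$output_dir, "linkage.tsv")
  write_tsv(linkage_tab, p); artifacts["linkage"] <- p
  p <- file.path(config$output_dir, "cap_registry.tsv")
  write_tsv(labeling$table, p); artifacts["cap_registry"] <- p

  log_stage("z-maps")
  zmaps <- compute_all_zmaps(vm, labeling)
  zdir <- file.path(config$output_dir, "zmaps")
  dir.create(zdir, showWarnings = FALSE)
  for (cl in names(zmaps)) {
    p <- file.path(zdir, sprintf("cap_%s_z.nii.gz", gsub("-", "_", cl)))
    export_zmap(zmaps[[cl]], vm$mask, p)
    artifacts[paste0("zmap_", cl)] <- p
  }

  log_stage("occupancy")
  occ <- occupancy_table(labeling, vm$provenance)
  occ_out <- as.data.frame(occ$counts)
  if (config$occupancy_fractions)
    occ_out <- occ_out / occ$retained_total
  occ_out <- cbind(subject = rownames(occ$counts),
                   group = unname(occ$groups),
                   retained = unname(occ$retained_total), occ_out)
  p <- file.path(config$output_dir, "occupancy.tsv")
  write_tsv(occ_out, p); artifacts["occupancy"] <- p
  mw <- mannwhitney_fdr(occ, q = config$q)
  p <- file.path(config$output_dir, "occupancy_tests.tsv")
  write_tsv(mw, p); artifacts["occupancy_tests"] <- p

  log_stage("contrasts")
  contrast <- run_group_contrast(vm, labeling,
                                 levels = config$level_min:level_max,
                                 n_perm = config$n_perm, seed = config$seed,
                                 tfce = config$tfce, q = config$q)
  message(sprintf("  pooled BH cutoff: %.5f (per tail %.5f)",
                  contrast$fdr$fdr_threshold,
                  contrast$fdr$per_tail_threshold))
  cdir <- file.path(config$output_dir, "contrasts")
  dir.create(cdir, showWarnings = FALSE)
  for (key in names(contrast$masks)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", key)
    p <- file.path(cdir, sprintf("sig_%s.nii.gz", safe))
    img <- RNifti::asNifti(unmask(as.numeric(contrast$masks[[key]]),
                                  vm$mask, fill = 0))
    RNifti::writeNifti(img, p, datatype = "uint8")
    artifacts[paste0("sig_", key)] <- p
  }

  log_stage("summarize")
  atlas <- assign_voxels(dataset$network_maps, dataset$mask)
  mean_z <- cap_rsn_mean_matrix(zmaps, atlas)
  bic <- bicluster_matrix(mean_z)
  sf <- significant_fractions(contrast$masks, atlas)
  p <- file.path(config$output_dir, "rsn_cap_mean_z.tsv")
  write_tsv(cbind(network = rownames(mean_z), as.data.frame(mean_z)), p)
  artifacts["rsn_cap_mean_z"] <- p
  for (d2 in names(sf$pct)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", d2)
    p <- file.path(config$output_dir, sprintf("pct_sig_%s.tsv", safe))
    write_tsv(cbind(network = rownames(sf$pct[[d2]]),
                    as.data.frame(sf$pct[[d2]])), p)
    artifacts[paste0("pct_sig_", d2)] <- p
  }
  p <- file.path(config$output_dir, "table1_report.tsv")
  write_tsv(sf$report, p); artifacts["table1_report"] <- p
  p <- file.path(config$output_dir, "rsn_cap_heatmap.png")
  plot_cap_rsn_heatmap(mean_z, bic, sf, p)
  artifacts["heatmap"] <- p

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("hicap")),
                   r_version = R.version.string,
                   n_volumes = nrow(vm$values),
                   n_voxels = ncol(vm$values),
                   levels = c(config$level_min, level_max),
                   n_unique_caps = labeling$n_unique,
                   fdr_threshold = contrast$fdr$fdr_threshold,
                   per_tail_threshold = contrast$fdr$per_tail_threshold,
                   artifacts = as.list(artifacts))
  p <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  log_stage("done")
  invisible(list(dataset = dataset, vm = vm, labeling = labeling,
                 zmaps = zmaps, occupancy = occ, contrast = contrast,
                 summary = list(atlas = atlas, mean_z = mean_z,
                                bicluster = bic, fractions = sf),
                 manifest = manifest))
}

#' PNG heatmap of the networks x CAPs mean-z matrix
#'
#' Rows and columns follow the biclustering display orders; cells flagged
#' in the decile masks are marked "T"/"A"-style with the direction's
#' initial. Display color range is clipped to \[-limit, limit\].
#'
#' @param mean_z K x C matrix.
#' @param bic result of [bicluster_matrix()] (optional).
#' @param sf result of [significant_fractions()] (optional).
#' @param path output PNG path.
#' @param limit color saturation limit (default: max absolute value).
#' @return invisibly, the path.
#' @export
plot_cap_rsn_heatmap <- function(mean_z, bic = NULL, sf = NULL, path,
                                 limit = NULL) {
  ro <- if (!is.null(bic)) bic$row_order else seq_len(nrow(mean_z))
  co <- if (!is.null(bic)) bic$col_order else seq_len(ncol(mean_z))
  M <- mean_z[ro, co, drop = FALSE]
  M[!is.finite(M)] <- 0
  if (is.null(limit)) limit <- max(abs(M), 1e-9)
  M[M > limit] <- limit; M[M < -limit] <- -limit
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  grDevices::png(path, width = 200 + 28 * ncol(M), height = 200 + 28 * nrow(M))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(7, 8, 2, 1))
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M),
                  zlim = c(-limit, limit), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(M)), colnames(M), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(M)), rownames(M), las = 2, cex.axis = 0.8)
  if (!is.null(sf)) {
    for (d in names(sf$decile_mask)) {
      # contrasted CAPs may be a subset of the displayed columns
      dm_full <- matrix(FALSE, nrow(mean_z), ncol(mean_z),
                        dimnames = dimnames(mean_z))
      dm <- sf$decile_mask[[d]]
      dm_full[rownames(dm), intersect(colnames(dm), colnames(dm_full))] <-
        dm[, intersect(colnames(dm), colnames(dm_full)), drop = FALSE]
      dm <- dm_full[ro, co, drop = FALSE]
      idx <- which(dm, arr.ind = TRUE)
      if (nrow(idx))
        graphics::text(idx[, 2], idx[, 1], substr(d, 1, 1), cex = 0.9,
                       font = 2)
    }
  }
  invisible(path)
}
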