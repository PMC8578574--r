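#' Default run configuration
#'
#' All thresholds default to the standard settings of the analysis flow:
#' QC (sample missingness 0.1, call rate 0.95, MAF 0.05, HWE 0.001),
#' LD pruning (500 kb window, r-squared 0.5), informative-locus threshold
#' 0.20, AMOVA with 1023 permutations, sweep threshold 0.25 with a 1 Mb
#' flank, and the LD-decay Ne settings.
#'
#' @param ped,map input PLINK text paths
#' @param metadata optional path to a CSV keyed by `id` or `pop` with the
#'   hierarchy columns (`geography`, `body_size`, `dairy_level`)
#' @param genes,qtls optional feature-track paths (BED/GFF3)
#' @param overrides named list of settings to override
#' @return a `run_config` list
#' @export
run_config <- function(ped, map, metadata = NULL, genes = NULL,
                       qtls = NULL, overrides = list()) {
  cfg <- list(
    ped = ped, map = map, metadata = metadata,
    genes = genes, qtls = qtls,
    mind = 0.1, cr = 0.95, maf = 0.05, hwe = 0.001,
    prune_window_bp = 5e5, prune_r2 = 0.5,
    informative_threshold = 0.20,
    k_range = 2:7, runs_per_k = 3,
    amova_group_col = NULL, amova_perms = 1023,
    ne_alpha = 2.2, ne_phased = FALSE, ne_bins = 20,
    ne_min_dist_bp = 5e4, ne_max_dist_bp = 4e6,
    scan_threshold = 0.25, scan_flank_bp = 1e6,
    scan_perms = 0, scan_alpha = 1e-4,
    seed = 1L)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with at least `ped` and `map` entries
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$ped), !is.null(y$map))
  run_config(y$ped, y$map, metadata = y$metadata, genes = y$genes,
             qtls = y$qtls,
             overrides = y[setdiff(names(y),
                                   c("ped", "map", "metadata",
                                     "genes", "qtls"))])
}

#' Run the full analysis pipeline
#'
#' Stages in order: QC (sample missingness, then the SNP cascade) ->
#' LD pruning -> diversity (per-breed summaries, pairwise F_ST and Nei
#' distance, differentiation indices) -> informative-locus selection ->
#' structure (IBS/MDS, admixture over a K range) -> AMOVA and hierarchical
#' F-statistics (when a group column is configured) -> per-breed Ne
#' trajectories -> pairwise selection scans with optional annotation.
#' Tables are written as CSV into `out_dir` together with a JSON manifest
#' recording the seed, every effective threshold and the stage-by-stage
#' marker/sample counts. A single global seed is fanned out to the stages
#' through one `sample.int()` draw, so each stage is individually
#' reproducible.
#'
#' @param config a `run_config` (or path to a YAML file)
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage_fail <- function(stage, e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  set.seed(config$seed)
  stage_seed <- stats::setNames(
    as.list(sample.int(.Machine$integer.max %/% 2, 4)),
    c("structure", "amova", "scan", "misc"))

  log("reading %s / %s", config$ped, config$map)
  co <- tryCatch(read_ped_map(config$ped, config$map),
                 error = function(e) stage_fail("input", e))
  if (!is.null(config$metadata))
    co <- attach_metadata(co, utils::read.csv(config$metadata,
                                              stringsAsFactors = FALSE))

  # --- QC ---
  fs <- filter_samples(co, config$mind)
  fq <- filter_snps(fs$cohort, config$cr, config$maf, config$hwe)
  qc <- bind_qc_reports(fs$report, fq$report)
  co <- fq$cohort
  utils::write.csv(qc, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  log("QC done: %d samples x %d markers", nrow(co$samples),
      nrow(co$variants))
  dos <- to_dosage(co, "minor")

  # --- pruning ---
  kept <- ld_prune(dos, window_bp = config$prune_window_bp,
                   r2_max = config$prune_r2)
  dosp <- dos[, kept, drop = FALSE]
  attr(dosp, "variants") <- co$variants[kept, ]
  attr(dosp, "pops") <- co$samples$pop
  log("pruning kept %d of %d markers", length(kept), ncol(dos))

  # --- diversity ---
  div <- per_population_summary(dosp)
  comp <- wc_fst_per_locus(dosp)
  fst_mat <- pairwise_fst(dosp)
  nei_mat <- pairwise_nei(dosp)
  idx <- differentiation_indices(dosp)
  utils::write.csv(div, file.path(out_dir, "diversity_per_breed.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(attr(dosp, "variants")[c("chrom", "pos", "name")],
                         comp),
                   file.path(out_dir, "fst_per_locus.csv"),
                   row.names = FALSE)
  utils::write.csv(fst_mat, file.path(out_dir, "pairwise_fst.csv"))
  utils::write.csv(nei_mat, file.path(out_dir, "pairwise_nei.csv"))

  # --- informative loci ---
  inf <- select_informative_loci(comp$theta, config$informative_threshold)
  log("informative loci (theta >= %.2f): %d",
      config$informative_threshold, length(inf))
  dosi <- if (length(inf) >= 2) {
    di <- dosp[, inf, drop = FALSE]
    attr(di, "variants") <- attr(dosp, "variants")[inf, ]
    attr(di, "pops") <- attr(dosp, "pops")
    di
  } else dosp

  # --- structure ---
  ibs <- ibs_matrix(dosp)
  mds <- mds_projection(ibs, 3)
  utils::write.csv(data.frame(id = co$samples$id, pop = co$samples$pop,
                              mds$points),
                   file.path(out_dir, "mds.csv"), row.names = FALSE)
  ks <- tryCatch(
    choose_k(dosi, config$k_range, config$runs_per_k,
             seed = stage_seed$structure),
    error = function(e) stage_fail("structure", e))
  utils::write.csv(ks$table, file.path(out_dir, "k_selection.csv"),
                   row.names = FALSE)
  best <- ks$fits[[paste0("K", ks$selected_k)]]
  memb <- membership_table(best, co$samples$pop)
  utils::write.csv(memb, file.path(out_dir, "membership.csv"))

  # --- AMOVA / hierarchical F ---
  am <- hf <- NULL
  if (!is.null(config$amova_group_col)) {
    gcol <- co$samples[[config$amova_group_col]]
    if (is.null(gcol) || anyNA(gcol))
      stage_fail("amova", simpleError(sprintf(
        "invalid design column '%s'", config$amova_group_col)))
    am <- amova(dosp, co$samples$pop, gcol,
                n_perm = config$amova_perms, seed = stage_seed$amova)
    utils::write.csv(am$table, file.path(out_dir, "amova.csv"),
                     row.names = FALSE)
    lv <- co$samples[intersect(c("geography", "body_size", "dairy_level"),
                               names(co$samples))]
    lv <- lv[colSums(is.na(lv)) == 0]
    if (ncol(lv)) {
      hf <- hierarchical_fstats(dosp, lv)
      utils::write.csv(hf$F, file.path(out_dir, "hier_fstats.csv"))
    }
  }

  # --- Ne (per breed, on pre-pruning post-QC genotypes) ---
  ne_list <- list()
  for (b in unique(co$samples$pop)) {
    db <- dos[co$samples$pop == b, , drop = FALSE]
    attr(db, "variants") <- co$variants
    bins <- ld_decay_bins(db, n_bins = config$ne_bins,
                          min_dist_bp = config$ne_min_dist_bp,
                          max_dist_bp = config$ne_max_dist_bp)
    if (!nrow(bins)) next
    tr <- ne_trajectory(bins, n = sum(co$samples$pop == b),
                        alpha = config$ne_alpha,
                        phased = config$ne_phased)
    ne_list[[b]] <- tr
    utils::write.csv(tr, file.path(out_dir, sprintf("ne_%s.csv", b)),
                     row.names = FALSE)
  }

  # --- selection scans ---
  genes <- if (!is.null(config$genes)) read_features(config$genes)
  qtls <- if (!is.null(config$qtls)) read_features(config$qtls)
  breeds <- unique(co$samples$pop)
  scans <- list()
  for (i in seq_along(breeds)[-length(breeds)])
    for (j in seq((i + 1), length(breeds))) {
      sc <- pairwise_scan(dosp, breed_a = breeds[i], breed_b = breeds[j])
      rg <- call_sweeps(sc, config$scan_threshold, config$scan_flank_bp,
                        perms = config$scan_perms,
                        alpha = config$scan_alpha,
                        seed = stage_seed$scan, dos = dosp,
                        pops = attr(dosp, "pops"))
      rg <- annotate_regions(rg, genes, qtls)
      if (nrow(rg)) {
        rg$pair <- paste(breeds[i], breeds[j], sep = "/")
        scans[[length(scans) + 1]] <- rg
      }
    }
  sig <- if (length(scans)) do.call(rbind, scans) else empty_regions()
  sig_out <- sig
  sig_out$genes <- vapply(sig_out$genes,
                          function(g) paste(g, collapse = ";"), "")
  utils::write.csv(sig_out, file.path(out_dir, "signatures.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    stage_seeds = stage_seed,
    settings = config[setdiff(names(config),
                              c("ped", "map", "metadata",
                                "genes", "qtls"))],
    package_version = as.character(utils::packageVersion("zebupop")),
    counts = list(
      samples_in = qc$n_in[1], samples_out = qc$n_out[1],
      markers_post_qc = nrow(co$variants),
      markers_post_prune = length(kept),
      informative_loci = length(inf),
      selected_k = ks$selected_k,
      signature_regions = nrow(sig)),
    qc = lapply(seq_len(nrow(qc)), function(i) as.list(qc[i, ])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("pipeline complete")
  invisible(list(cohort = co, qc = qc, diversity = div,
                 fst = comp, pairwise_fst = fst_mat, nei = nei_mat,
                 indices = idx, mds = mds, k_selection = ks,
                 membership = memb, amova = am, hier_fstats = hf,
                 ne = ne_list, signatures = sig, manifest = manifest))
}
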