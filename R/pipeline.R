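# End-to-end orchestration: simulate -> duplex screen -> composition ->
# GO -> binding fits, with deterministic seeding and a JSON-lines manifest.
# All file traffic goes through the formats layer.

#' Default pipeline configuration
#'
#' A flat list of stage parameters; any entry can be overridden by the
#' `...` arguments of [run_pipeline()]. The single `seed` drives every
#' stochastic stage (sub-seeds are derived deterministically from it).
#'
#' @param seed master integer seed.
#' @return named list of pipeline defaults.
#' @export
pipeline_config <- function(seed) {
  list(
    seed = as.integer(seed),
    bee_length = 100000L,
    viral_lengths = c(vdv1 = 10000L),
    n_fragments = 2000L,
    duplex_pairs = 30L,
    n_go_terms = 200L,
    min_overlap = 25L,
    max_overhang = 100L,
    min_fraction = 0.01,
    alpha = 0.05,
    mst_phases = data.frame(kd = c(4e-9, 3e-7, 25e-6), amplitude = 1),
    noise_sd = 0.01
  )
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> duplex screen -> composition/enrichment -> GO ->
#' binding fit in order, writing all artifacts under `out_dir` through the
#' formats layer and recording them in a JSON-lines `manifest.jsonl`.
#' Re-running with the same seed reproduces every output byte-identically.
#' Existing outputs are only overwritten with `force = TRUE`.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param force overwrite an existing non-empty output directory.
#' @param ... overrides for [pipeline_config()] entries.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(out_dir, seed, force = FALSE, ...) {
  cfg <- utils::modifyList(pipeline_config(seed), list(...))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(stage, path, n) {
    manifest[[length(manifest) + 1L]] <<-
      list(stage = stage, path = basename(path), n = n)
    path
  }

  # --- simulate ---------------------------------------------------------
  ref <- make_reference(cfg$seed, bee_length = cfg$bee_length,
                        viral_lengths = cfg$viral_lengths, dir = out_dir)
  emit("simulate", file.path(out_dir, "reference.fasta"),
       length(ref$sequences))
  emit("simulate", file.path(out_dir, "annotation.gff3"),
       nrow(ref$features))
  # plant duplexes in the first few sufficiently long genes
  long_genes <- ref$features$gene_id[
    ref$features$end - ref$features$start >= 400]
  loci <- utils::head(long_genes, 3)
  dl <- data.frame(locus = loci,
                   n_pairs = rep(ceiling(cfg$duplex_pairs / length(loci)),
                                 length(loci)))
  scfg <- sim_config(seed = cfg$seed + 1L, n_fragments = cfg$n_fragments,
                     duplex_loci = dl,
                     min_overlap = cfg$min_overlap,
                     max_overhang = cfg$max_overhang)
  reads <- simulate_fragments(ref, scfg, dir = out_dir)
  log_stage("simulate", nrow(reads), " reads, ",
            nrow(attr(reads, "truth")), " planted duplex pairs")
  emit("simulate", file.path(out_dir, "duplex_truth.tsv"),
       nrow(attr(reads, "truth")))

  # --- duplex screen ----------------------------------------------------
  params <- screen_params(cfg$min_overlap, cfg$max_overhang)
  bee_reads <- reads[ref$species_of[reads$reference] == "apis", ,
                     drop = FALSE]
  cand <- call_duplexes(bee_reads, params)
  uq <- dedupe_and_classify(cand, ref)
  write_bed(cand, emit("screen", file.path(out_dir, "candidates.bed"),
                       nrow(cand)))
  hist <- length_distribution(uq)
  utils::write.table(hist,
                     emit("screen", file.path(out_dir,
                                              "length_histogram.tsv"),
                          nrow(hist)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dup_counts <- count_duplexes_per_gene(uq,
                                        samples = scfg$samples$sample_id)
  write_counts_tsv(dup_counts,
                   emit("screen", file.path(out_dir,
                                            "duplex_gene_counts.tsv"),
                        nrow(dup_counts)))
  log_stage("screen", nrow(cand), " candidates -> ", nrow(uq),
            " unique duplexes on ", nrow(dup_counts), " genes")

  # --- composition ------------------------------------------------------
  comp_counts <- composition_counts(reads, ref)
  grp <- stats::setNames(scfg$samples$group, scfg$samples$sample_id)
  comp <- summarize_composition(comp_counts,
                                min_fraction = cfg$min_fraction,
                                group_of_sample = grp)
  write_counts_tsv(comp$normalized,
                   emit("composition",
                        file.path(out_dir, "composition_normalized.tsv"),
                        nrow(comp$normalized)))
  enr <- enrichment_report(comp, "apis", "vdv1", alpha = cfg$alpha)
  utils::write.table(enr,
                     emit("composition",
                          file.path(out_dir, "enrichment_report.tsv"),
                          nrow(enr)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vref <- names(cfg$viral_lengths)[1]
  cov <- strand_coverage(merge_mates(reads), vref,
                         cfg$viral_lengths[[1]])
  write_bedgraph(cov$plus,
                 vref, emit("composition",
                            file.path(out_dir, "coverage_plus.bedgraph"),
                            sum(cov$plus > 0)))
  write_bedgraph(cov$minus,
                 vref, emit("composition",
                            file.path(out_dir, "coverage_minus.bedgraph"),
                            sum(cov$minus > 0)))
  log_stage("composition", nrow(comp$fractions),
            " groups reported; viral enrichment tested")

  # --- GO ---------------------------------------------------------------
  gene_counts <- assign_reads_to_genes(bee_reads, ref)
  universe <- build_universe(gene_counts)
  interest <- rownames(dup_counts)[rownames(dup_counts) %in% universe]
  g2g <- make_go_universe(ref, n_terms = cfg$n_go_terms,
                          seed = cfg$seed + 2L,
                          interest_set = interest,
                          path = file.path(out_dir, "gene2go.tsv"))
  emit("go", file.path(out_dir, "gene2go.tsv"), nrow(g2g))
  lens <- stats::setNames(ref$features$mean_tx_length,
                          ref$features$gene_id)
  go_res <- run_go(interest, universe, g2g, lens)
  utils::write.table(go_res,
                     emit("go", file.path(out_dir, "go_results.tsv"),
                          nrow(go_res)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("go", length(universe), " universe genes, ",
            sum(go_res$flag_overrepresented), " term(s) flagged")

  # --- binding ----------------------------------------------------------
  tcfg <- titration_sim_config(phases = cfg$mst_phases,
                               noise_sd = cfg$noise_sd,
                               seed = cfg$seed + 3L)
  curve <- simulate_titration(tcfg)
  utils::write.csv(curve,
                   emit("binding", file.path(out_dir, "titration.csv"),
                        nrow(curve)),
                   row.names = FALSE)
  fit <- fit_multiphase(curve, nrow(cfg$mst_phases))
  fit_df <- data.frame(phase = seq_len(nrow(fit$model$phases)),
                       kd = fit$model$phases$kd,
                       amplitude = fit$model$phases$amplitude,
                       baseline = fit$model$baseline,
                       rss = fit$rss, bic = fit$bic,
                       converged = fit$converged)
  utils::write.table(fit_df,
                     emit("binding", file.path(out_dir, "binding_fit.tsv"),
                          nrow(fit_df)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("binding", "fitted ", nrow(fit$model$phases),
            " phase(s), rss = ", signif(fit$rss, 3))

  # --- manifest ---------------------------------------------------------
  man_df <- do.call(rbind, lapply(manifest, as.data.frame))
  con <- file(file.path(out_dir, "manifest.jsonl"), "w")
  for (m in manifest)
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE), con)
  close(con)

  invisible(list(reference = ref, reads = reads, candidates = cand,
                 unique_duplexes = uq, duplex_counts = dup_counts,
                 composition = comp, enrichment = enr, go = go_res,
                 binding_fit = fit, manifest = man_df))
}
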