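# Species/biotype composition summaries: strand-aware gene-level fragment
# assignment, mean-ratio library-size normalization, Welch enrichment tests
# and strand-specific coverage.

#' Assign fragments to genes (strand-aware, gene level)
#'
#' Paired reads are mate-merged to fragments whose sense strand follows the
#' stranded protocol (dUTP by default). A fragment is assigned to a gene
#' iff its interval overlaps the gene span and its sense strand equals the
#' gene strand; fragments overlapping two or more eligible genes are
#' ambiguous and dropped (tallied); fragments overlapping no gene are
#' tallied as unannotated (`"Other"`).
#'
#' @param reads aligned-read table (or pre-merged fragments with a `strand`
#'   sense column, passed via `fragments`).
#' @param annotation gene feature table or `annotated_reference`.
#' @param stranded_protocol `"dutp"` or `"fr"`.
#' @param samples sample ids fixing column order (default observed).
#' @return gene-by-sample count matrix including all annotated genes;
#'   attributes `other` and `ambiguous` hold per-sample tallies, and
#'   `fragment_gene` maps each assigned fragment to its gene.
#' @export
assign_reads_to_genes <- function(reads, annotation,
                                  stranded_protocol = c("dutp", "fr"),
                                  samples = NULL) {
  stranded_protocol <- match.arg(stranded_protocol)
  if (methods::is(annotation, "annotated_reference"))
    annotation <- annotation$features
  fr <- merge_mates(reads, stranded_protocol)
  if (is.null(samples)) samples <- sort(unique(fr$sample))
  genes <- annotation$gene_id
  counts <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  other <- stats::setNames(integer(length(samples)), samples)
  ambiguous <- stats::setNames(integer(length(samples)), samples)
  assigned_map <- NULL
  if (nrow(fr) > 0 && nrow(annotation) > 0) {
    lv <- unique(c(fr$reference, annotation$reference))
    hits <- GenomicRanges::findOverlaps(
      as_granges0(fr$reference, fr$start, fr$end, fr$strand,
                  seqlevels = lv),
      as_granges0(annotation$reference, annotation$start, annotation$end,
                  annotation$strand, seqlevels = lv))
    n_hits <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(fr))
    uniq <- n_hits == 1L
    one <- hits[uniq[S4Vectors::queryHits(hits)]]
    qi <- S4Vectors::queryHits(one)
    gi <- S4Vectors::subjectHits(one)
    tab <- table(gene = genes[gi], sample = fr$sample[qi])
    counts[rownames(tab), colnames(tab)] <-
      counts[rownames(tab), colnames(tab)] + unclass(tab)
    none <- n_hits == 0L
    ot <- table(fr$sample[none])
    other[names(ot)] <- as.integer(ot)
    amb <- table(fr$sample[n_hits >= 2L])
    ambiguous[names(amb)] <- as.integer(amb)
    assigned_map <- data.frame(fragment_id = fr$fragment_id[qi],
                               sample = fr$sample[qi],
                               gene_id = genes[gi],
                               stringsAsFactors = FALSE)
  } else if (nrow(fr) > 0) {
    ot <- table(fr$sample)
    other[names(ot)] <- as.integer(ot)
  }
  attr(counts, "other") <- other
  attr(counts, "ambiguous") <- ambiguous
  attr(counts, "fragment_gene") <- assigned_map
  counts
}

#' Mean-ratio library size factors
#'
#' The factor of a sample is its total mapped count divided by the mean
#' total across samples; factors therefore average to 1. Normalized counts
#' are counts divided by the factor.
#'
#' @param counts count matrix (rows x samples) or a named vector of
#'   per-sample totals.
#' @return named numeric size factors.
#' @export
size_factors_mean_ratio <- function(counts) {
  totals <- if (is.matrix(counts)) colSums(counts) else counts
  if (any(totals <= 0)) stop("zero total mapped count in sample(s): ",
                             paste(names(totals)[totals <= 0],
                                   collapse = ", "))
  totals / mean(totals)
}

#' Species / biotype composition counts
#'
#' Builds the grouped count matrix the composition report works on: one
#' row per (species, biotype) group. Bee fragments are grouped by the
#' biotype of their uniquely assigned gene, with unannotated fragments as
#' `apis/Other` (ambiguous fragments are dropped); fragments on a viral
#' reference count toward that species regardless of annotation.
#'
#' @param reads aligned-read table.
#' @param reference an `annotated_reference`.
#' @param stranded_protocol `"dutp"` or `"fr"`.
#' @return group-by-sample count matrix with rownames `species/biotype`.
#' @export
composition_counts <- function(reads, reference,
                               stranded_protocol = c("dutp", "fr")) {
  stranded_protocol <- match.arg(stranded_protocol)
  fr <- merge_mates(reads, stranded_protocol)
  samples <- sort(unique(fr$sample))
  species <- reference$species_of[fr$reference]
  is_bee <- species == "apis"
  groups <- character(nrow(fr))
  groups[!is_bee] <- paste0(species[!is_bee], "/NA")

  bee_counts <- assign_reads_to_genes(
    reads[reads$reference %in%
            names(reference$species_of)[reference$species_of == "apis"], ,
          drop = FALSE],
    reference, stranded_protocol, samples = samples)
  bt <- reference$features$biotype[match(rownames(bee_counts),
                                         reference$features$gene_id)]
  out <- rowsum(bee_counts, paste0("apis/", bt))
  out <- rbind(out, `apis/Other` = attr(bee_counts, "other")[samples])
  viral <- fr[!is_bee, , drop = FALSE]
  if (nrow(viral) > 0) {
    vt <- table(paste0(reference$species_of[viral$reference], "/NA"),
                factor(viral$sample, levels = samples))
    out <- rbind(out, unclass(vt))
  }
  out
}

#' Summarize composition with normalization and low-fraction filtering
#'
#' Normalizes grouped counts by mean-ratio size factors, computes
#' per-sample fractions, and reports only groups reaching `min_fraction`
#' in at least one sample (the full table is kept as an attribute). Group
#' means per sample-group (e.g. replicate means) are included when a
#' group assignment is given.
#'
#' @param group_counts group-by-sample count matrix, e.g. from
#'   [composition_counts()].
#' @param min_fraction report threshold on the per-sample fraction
#'   (default 0.01, i.e. groups below 1 percent everywhere are collapsed
#'   out of the report).
#' @param group_of_sample optional named vector mapping sample to fraction
#'   group (`total_rj` / `mrjp3_bound`).
#' @return list of class `composition_table`: `normalized`, `fractions`
#'   (filtered), `size_factors`, `group_of_sample`; attribute
#'   `full_fractions` retains all groups.
#' @export
summarize_composition <- function(group_counts, min_fraction = 0.01,
                                  group_of_sample = NULL) {
  sf <- size_factors_mean_ratio(group_counts)
  norm <- sweep(group_counts, 2, sf, "/")
  frac <- sweep(group_counts, 2, colSums(group_counts), "/")
  keep <- apply(frac, 1, max) >= min_fraction
  out <- structure(
    list(normalized = norm, fractions = frac[keep, , drop = FALSE],
         size_factors = sf, group_of_sample = group_of_sample),
    class = "composition_table")
  attr(out, "full_fractions") <- frac
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition_table:", nrow(attr(x, "full_fractions")), "group(s),",
      ncol(x$fractions), "sample(s);", nrow(x$fractions),
      "group(s) above the report threshold\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Two-sided Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided Student-t p value.
#'
#' @param x,y numeric vectors (at least 2 values each).
#' @return list `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = Inf, p = 1))
    stop("both groups have zero variance; Welch test degenerate")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Species-enrichment report
#'
#' For each sample-group (fraction), tests whether per-sample normalized
#' counts differ between two species using the two-sided Welch test;
#' sample counts are summed over the species' groups first.
#'
#' @param composition a `composition_table` with `group_of_sample` set.
#' @param species_a,species_b species labels as used in the group
#'   rownames (`species/biotype`).
#' @param alpha significance level for the flag.
#' @param use `"normalized"` (default) or `"fractions"` values.
#' @return data frame, one row per fraction group: `t`, `df`, `p`,
#'   `significant` (groups with fewer than 2 replicates are skipped with a
#'   warning).
#' @export
enrichment_report <- function(composition, species_a, species_b,
                              alpha = 0.05,
                              use = c("normalized", "fractions")) {
  use <- match.arg(use)
  stopifnot(!is.null(composition$group_of_sample))
  vals <- if (use == "normalized") composition$normalized else
    attr(composition, "full_fractions")
  sp <- sub("/.*$", "", rownames(vals))
  a <- colSums(vals[sp == species_a, , drop = FALSE])
  b <- colSums(vals[sp == species_b, , drop = FALSE])
  grp <- composition$group_of_sample[colnames(vals)]
  rows <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) {
      warning("fraction '", g, "' has < 2 replicates; test skipped")
      next
    }
    wt <- welch_t_test(a[idx], b[idx])
    rows[[g]] <- data.frame(fraction = g, t = wt$t, df = wt$df, p = wt$p,
                            significant = wt$p < alpha)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Strand-specific per-base coverage
#'
#' Depth per base and strand for one reference, optionally log10(x+1)
#' transformed (reads may be fragments; any interval table with
#' `reference`, `start`, `end`, `strand` works).
#'
#' @param reads interval table.
#' @param reference reference name.
#' @param reference_length reference length in nt.
#' @param transform `"raw"` or `"log10p1"`.
#' @return list with numeric vectors `plus` and `minus` of
#'   `reference_length` per-base values (0-based positions).
#' @export
strand_coverage <- function(reads, reference, reference_length,
                            transform = c("raw", "log10p1")) {
  transform <- match.arg(transform)
  out <- list()
  for (s in c("+", "-")) {
    sub <- reads[reads$reference == reference & reads$strand == s, ,
                 drop = FALSE]
    cov <- as.numeric(IRanges::coverage(
      IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      width = reference_length))
    if (transform == "log10p1") cov <- log10(cov + 1)
    out[[if (s == "+") "plus" else "minus"]] <- cov
  }
  out
}
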