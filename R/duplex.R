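# Strand-specific putative-dsRNA screen: pairwise opposite-strand read
# overlaps under the minimum-overlap / maximum-overhang rule, deduplication
# by interval key, gene classification, per-gene quantification, and
# median-of-ratios size factors.

#' Screen parameters
#'
#' @param min_overlap minimum duplexed overlap in nt (default 25).
#' @param max_overhang maximum single-stranded overhang on either side in
#'   nt (default 100).
#' @param exclude_mates exclude read pairs from the same fragment (two
#'   mates are one molecule, not two).
#' @param unit operate on `"read"` intervals (default) or mate-merged
#'   `"fragment"` intervals.
#' @return a `screen_params` list.
#' @export
screen_params <- function(min_overlap = 25L, max_overhang = 100L,
                          exclude_mates = TRUE,
                          unit = c("read", "fragment")) {
  stopifnot(min_overlap >= 1, max_overhang >= 0)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overhang = as.integer(max_overhang),
                 exclude_mates = isTRUE(exclude_mates),
                 unit = match.arg(unit)),
            class = "screen_params")
}

empty_candidates <- function() {
  data.frame(reference = character(), fwd_read = character(),
             rev_read = character(), fwd_fragment = character(),
             rev_fragment = character(),
             overlap_start = integer(), overlap_end = integer(),
             union_start = integer(), union_end = integer(),
             overlap_len = integer(), left_overhang = integer(),
             right_overhang = integer(), sample = character(),
             stringsAsFactors = FALSE)
}

#' Call putative dsRNA candidates from opposite-strand read overlaps
#'
#' Within each sample and reference, every (forward read, reverse read)
#' pair is a candidate duplex when the overlap
#' `min(ends) - max(starts)` is at least `min_overlap` and both overhangs
#' (`max(starts) - min(starts)` on the left, `max(ends) - min(ends)` on the
#' right) are at most `max_overhang`. With `exclude_mates`, the two reads
#' must come from distinct fragments (distinct molecules). The candidate
#' join uses an interval-overlap index rather than the all-pairs product;
#' the two are equivalent (property-tested).
#'
#' @param reads aligned-read table; with `unit = "fragment"` in the
#'   parameters, mate-merged fragments (all reads must be paired).
#' @param params a [screen_params()].
#' @return candidate table sorted by (reference, overlap_start); every row
#'   re-validated against the rule before being returned.
#' @export
call_duplexes <- function(reads, params = screen_params()) {
  if (params$unit == "fragment") {
    n_mates <- table(paste(reads$sample, reads$fragment_id))
    if (any(n_mates != 2))
      stop("unit = 'fragment' requires paired reads; merge mates first ",
           "(see merge_mates)")
    fr <- merge_mates(reads)
    reads <- data.frame(read_id = fr$fragment_id,
                        fragment_id = fr$fragment_id, mate = 1L,
                        reference = fr$reference, start = fr$start,
                        end = fr$end, strand = fr$strand,
                        sample = fr$sample)
  }
  out <- list()
  for (sid in unique(reads$sample)) {
    sub <- reads[reads$sample == sid, , drop = FALSE]
    fwd <- sub[sub$strand == "+", , drop = FALSE]
    rev <- sub[sub$strand == "-", , drop = FALSE]
    if (nrow(fwd) == 0 || nrow(rev) == 0) next
    lv <- unique(c(fwd$reference, rev$reference))
    hits <- GenomicRanges::findOverlaps(
      as_granges0(fwd$reference, fwd$start, fwd$end, seqlevels = lv),
      as_granges0(rev$reference, rev$start, rev$end, seqlevels = lv),
      minoverlap = params$min_overlap)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    f_start <- fwd$start[qi]; f_end <- fwd$end[qi]
    r_start <- rev$start[si]; r_end <- rev$end[si]
    left_oh <- pmax(f_start, r_start) - pmin(f_start, r_start)
    right_oh <- pmax(f_end, r_end) - pmin(f_end, r_end)
    keep <- left_oh <= params$max_overhang &
      right_oh <= params$max_overhang
    if (params$exclude_mates)
      keep <- keep & fwd$fragment_id[qi] != rev$fragment_id[si]
    if (!any(keep)) next
    qi <- qi[keep]; si <- si[keep]
    cand <- data.frame(
      reference = fwd$reference[qi],
      fwd_read = fwd$read_id[qi], rev_read = rev$read_id[si],
      fwd_fragment = fwd$fragment_id[qi],
      rev_fragment = rev$fragment_id[si],
      overlap_start = pmax(fwd$start[qi], rev$start[si]),
      overlap_end = pmin(fwd$end[qi], rev$end[si]),
      union_start = pmin(fwd$start[qi], rev$start[si]),
      union_end = pmax(fwd$end[qi], rev$end[si]),
      overlap_len = NA_integer_,
      left_overhang = left_oh[keep], right_overhang = right_oh[keep],
      sample = sid, stringsAsFactors = FALSE)
    cand$overlap_len <- cand$overlap_end - cand$overlap_start
    out[[sid]] <- cand
  }
  cand <- if (length(out)) do.call(rbind, out) else empty_candidates()
  cand <- cand[order(cand$reference, cand$overlap_start), , drop = FALSE]
  rownames(cand) <- NULL
  validate_candidates(cand, params)
  cand
}

# defensive validator: emitted candidates must satisfy their own invariants
validate_candidates <- function(cand, params) {
  stopifnot(
    all(cand$overlap_len == cand$overlap_end - cand$overlap_start),
    all(cand$overlap_len >= params$min_overlap),
    all(cand$left_overhang <= params$max_overhang),
    all(cand$right_overhang <= params$max_overhang),
    !params$exclude_mates || all(cand$fwd_fragment != cand$rev_fragment)
  )
  invisible(cand)
}

#' Deduplicate candidates and classify their loci
#'
#' Candidates sharing a duplicate key — the overlap interval by default, or
#' the union interval with `key = "union"` — collapse into one unique
#' duplex whose `support` counts the collapsed candidates and whose
#' `samples` lists the samples it occurs in. Each unique duplex is assigned
#' to every gene whose span intersects the overlap interval (any positional
#' overlap, strand-agnostic — a duplex involves both strands);
#' `biotype_class` is the comma-joined set of assigned biotypes, or
#' `"unannotated"` when no gene intersects. Duplex `length` is the overlap
#' length.
#'
#' @param candidates from [call_duplexes()].
#' @param annotation gene feature table (or an `annotated_reference`).
#' @param key `"overlap"` (default) or `"union"` duplicate key.
#' @return data frame of unique duplexes with list-columns
#'   `assigned_genes` and `samples`.
#' @export
dedupe_and_classify <- function(candidates, annotation,
                                key = c("overlap", "union")) {
  key <- match.arg(key)
  if (methods::is(annotation, "annotated_reference"))
    annotation <- annotation$features
  if (nrow(candidates) == 0)
    return(data.frame(reference = character(), key_start = integer(),
                      key_end = integer(), length = integer(),
                      biotype_class = character(), support = integer(),
                      assigned_genes = I(list()), samples = I(list())))
  ks <- if (key == "overlap") candidates$overlap_start else
    candidates$union_start
  ke <- if (key == "overlap") candidates$overlap_end else
    candidates$union_end
  gid <- paste(candidates$reference, ks, ke, sep = "\r")
  first <- !duplicated(gid)
  uq <- data.frame(reference = candidates$reference[first],
                   key_start = ks[first], key_end = ke[first],
                   length = candidates$overlap_len[first],
                   stringsAsFactors = FALSE)
  idx <- match(gid, gid[first])
  uq$support <- as.integer(tabulate(idx, nbins = nrow(uq)))
  uq$samples <- I(unname(split(candidates$sample, idx)))
  uq$samples <- I(lapply(uq$samples, unique))
  # gene assignment on the overlap interval (the duplexed region)
  ov_s <- candidates$overlap_start[first]
  ov_e <- candidates$overlap_end[first]
  uq$assigned_genes <- I(vector("list", nrow(uq)))
  uq$biotype_class <- "unannotated"
  if (nrow(annotation) > 0) {
    lv <- unique(c(uq$reference, annotation$reference))
    hits <- GenomicRanges::findOverlaps(
      as_granges0(uq$reference, ov_s, ov_e, seqlevels = lv),
      as_granges0(annotation$reference, annotation$start, annotation$end,
                  seqlevels = lv))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      gl <- split(annotation$gene_id[sh], qh)
      bl <- split(annotation$biotype[sh], qh)
      ii <- as.integer(names(gl))
      uq$assigned_genes[ii] <- gl
      uq$biotype_class[ii] <- vapply(
        bl, function(b) paste(sort(unique(b)), collapse = ","),
        character(1))
    }
  }
  uq <- uq[order(uq$reference, uq$key_start), , drop = FALSE]
  rownames(uq) <- NULL
  uq
}

#' Length distribution of unique duplexes
#'
#' @param unique_duplexes from [dedupe_and_classify()].
#' @param bin_width histogram bin width in nt (>= 1).
#' @return data frame `bin_start`, `bin_end`, `count` for non-empty bins.
#' @export
length_distribution <- function(unique_duplexes, bin_width = 10L) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  bin_width <- as.integer(bin_width)
  if (nrow(unique_duplexes) == 0)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  b <- floor(unique_duplexes$length / bin_width)
  tab <- table(b)
  data.frame(bin_start = as.integer(names(tab)) * bin_width,
             bin_end = (as.integer(names(tab)) + 1L) * bin_width,
             count = as.integer(tab))
}

#' Count unique duplexes per gene and sample
#'
#' Each unique duplex increments, in every sample it occurs in, the row of
#' every gene it was assigned to (a duplex intersecting k genes counts once
#' per gene). Genes with no duplex anywhere are absent.
#'
#' @param unique_duplexes from [dedupe_and_classify()].
#' @param samples sample ids defining the column order (default: observed).
#' @return count matrix (genes x samples).
#' @export
count_duplexes_per_gene <- function(unique_duplexes, samples = NULL) {
  if (is.null(samples))
    samples <- sort(unique(unlist(unique_duplexes$samples)))
  genes <- sort(unique(unlist(unique_duplexes$assigned_genes)))
  counts <- matrix(0L, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (i in seq_len(nrow(unique_duplexes))) {
    g <- unique_duplexes$assigned_genes[[i]]
    s <- unique_duplexes$samples[[i]]
    if (length(g) && length(s))
      counts[g, s] <- counts[g, s] + 1L
  }
  counts
}

#' Median-of-ratios size factors
#'
#' The classical count normalization: per sample, the factor is the median
#' over genes (restricted to genes with a positive geometric mean across
#' samples) of the ratio of the sample's count to the gene's geometric
#' mean.
#'
#' @param counts count matrix (genes x samples), at least 2 samples.
#' @return named numeric vector of positive size factors; normalized counts
#'   are `sweep(counts, 2, factors, "/")`.
#' @export
size_factors_median_ratio <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  logc <- log(counts)
  finite <- rowSums(is.finite(logc)) == ncol(counts)
  if (!any(finite))
    stop("no gene has positive counts in all samples; consider the ",
         "mean-ratio size factors (size_factors_mean_ratio)")
  loggeo <- rowMeans(logc[finite, , drop = FALSE])
  factors <- apply(logc[finite, , drop = FALSE], 2,
                   function(x) exp(stats::median(x - loggeo)))
  stats::setNames(factors, colnames(counts))
}
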