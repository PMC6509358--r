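# Shared fixtures built in code.

# small annotated reference with a known gene layout on one bee chromosome
toy_reference <- function() {
  feats <- gene_features(
    gene_id = c("pc1", "trna1", "mir1", "pc2"),
    reference = "bee1",
    start = c(100L, 1500L, 2000L, 2500L),
    end = c(1100L, 1580L, 2100L, 4000L),
    strand = c("+", "-", "+", "-"),
    biotype = c("protein_coding", "tRNA", "pre_miRNA", "protein_coding"),
    transcript_lengths = list(c(800, 1000), 80, 95, c(1200, 1500, 900))
  )
  set.seed(99)
  seqs <- c(
    bee1 = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                 collapse = ""),
    vdv1 = paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                 collapse = "")
  )
  annotated_reference(seqs, feats, c(bee1 = "apis", vdv1 = "vdv1"))
}

# single-end style read rows (each its own fragment) for interval tests
interval_reads <- function(start, end, strand, reference = "bee1",
                           sample = "s1", fragment = NULL) {
  n <- length(start)
  if (is.null(fragment)) fragment <- sprintf("frag%03d", seq_len(n))
  aligned_reads(
    read_id = sprintf("%s/1", fragment), fragment_id = fragment,
    mate = rep(1L, n), reference = rep(reference, length.out = n),
    start = start, end = end, strand = strand,
    sample = rep(sample, length.out = n)
  )
}

# all-pairs brute-force oracle for the duplex caller
brute_force_duplexes <- function(reads, params) {
  rows <- list()
  for (s in unique(reads$sample)) {
    sub <- reads[reads$sample == s, ]
    fwd <- sub[sub$strand == "+", ]
    rev <- sub[sub$strand == "-", ]
    for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
      if (fwd$reference[i] != rev$reference[j]) next
      ov <- min(fwd$end[i], rev$end[j]) - max(fwd$start[i], rev$start[j])
      lo <- abs(fwd$start[i] - rev$start[j])
      ro <- abs(fwd$end[i] - rev$end[j])
      if (ov < params$min_overlap || lo > params$max_overhang ||
          ro > params$max_overhang) next
      if (params$exclude_mates &&
          fwd$fragment_id[i] == rev$fragment_id[j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        reference = fwd$reference[i], fwd_read = fwd$read_id[i],
        rev_read = rev$read_id[j],
        overlap_start = max(fwd$start[i], rev$start[j]),
        overlap_end = min(fwd$end[i], rev$end[j]),
        sample = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(reference = character(), fwd_read = character(),
                      rev_read = character(), overlap_start = integer(),
                      overlap_end = integer(), sample = character()))
  do.call(rbind, rows)
}

# canonical sortable key for comparing candidate sets
candidate_key <- function(df) {
  sort(paste(df$sample, df$reference, df$fwd_read, df$rev_read,
             df$overlap_start, df$overlap_end))
}

# exact Wallenius upper tail by enumeration of ordered draw sequences
# (independent of the package's dynamic program)
wallenius_tail_enum <- function(m1, m2, n, x_min, odds) {
  total_p <- 0
  recurse <- function(w_left, b_left, draws_left, whites, p) {
    if (draws_left == 0) {
      if (whites >= x_min) total_p <<- total_p + p
      return(invisible())
    }
    tot <- w_left * odds + b_left
    if (w_left > 0)
      recurse(w_left - 1, b_left, draws_left - 1, whites + 1,
              p * w_left * odds / tot)
    if (b_left > 0)
      recurse(w_left, b_left - 1, draws_left - 1, whites,
              p * b_left / tot)
  }
  recurse(m1, m2, n, 0, 1)
  total_p
}
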