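# Synthetic-data generation: toy bee + virus references, stranded paired-end
# fragment simulation with planted opposite-strand duplexes, gene->GO
# annotations with controllable length bias, and noisy multi-phase MST-style
# titrations. Every generator is a pure function of (config, seed).

#' Simulation configuration for stranded read generation
#'
#' Defaults mirror the study design the pipeline targets: 100 bp paired-end
#' stranded (dUTP) libraries, three total-jelly samples and two
#' protein-bound samples, with the viral species enriched in the bound
#' fraction. Fragment lengths are Normal(250, 40) truncated to
#' `[read_length, 600]` (typical stranded total-RNA inserts).
#'
#' @param seed integer seed (mandatory; generators take no implicit entropy).
#' @param read_length read length in nt.
#' @param n_fragments background fragments per sample (planted duplex
#'   molecules are additional).
#' @param species_mix named list, one entry per sample group, each a named
#'   proportion vector over species (must sum to 1).
#' @param biotype_mix named proportion vector over bee biotypes; the key
#'   `unannotated` places fragments in annotation gaps.
#' @param duplex_loci data frame with columns `locus` (a `gene_id` or
#'   `"ref:start-end"` interval) and `n_pairs`; planted per sample.
#' @param fragment_length_mean,fragment_length_sd insert-size parameters.
#' @param samples data frame with `sample_id` and `group` (one of
#'   `total_rj`, `mrjp3_bound`).
#' @param min_overlap,max_overhang construction bounds for planted duplexes.
#' @param viral_sense_fraction fraction of viral fragments on the sense
#'   (genome) strand; the remainder are antisense.
#' @param placement `"uniform"` (fragments may overlap, as in real
#'   libraries) or `"disjoint"` (all molecule footprints disjoint except the
#'   planted duplex pairs, so the planted pairs are provably the only
#'   qualifying opposite-strand overlaps).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       read_length = 100L,
                       n_fragments = 2000L,
                       species_mix = list(
                         total_rj = c(apis = 0.95, vdv1 = 0.05),
                         mrjp3_bound = c(apis = 0.55, vdv1 = 0.45)
                       ),
                       biotype_mix = c(protein_coding = 0.70, tRNA = 0.15,
                                       pre_miRNA = 0.10, unannotated = 0.05),
                       duplex_loci = data.frame(locus = character(),
                                                n_pairs = integer()),
                       fragment_length_mean = 250,
                       fragment_length_sd = 40,
                       samples = data.frame(
                         sample_id = c("RJ_1", "RJ_2", "RJ_3",
                                       "MRJP3_1", "MRJP3_2"),
                         group = c("total_rj", "total_rj", "total_rj",
                                   "mrjp3_bound", "mrjp3_bound")
                       ),
                       min_overlap = 25L,
                       max_overhang = 100L,
                       placement = c("uniform", "disjoint")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  for (mix in species_mix)
    stopifnot(abs(sum(mix) - 1) < 1e-8)
  stopifnot(abs(sum(biotype_mix) - 1) < 1e-8)
  structure(
    list(seed = as.integer(seed), read_length = as.integer(read_length),
         n_fragments = as.integer(n_fragments), species_mix = species_mix,
         biotype_mix = biotype_mix, duplex_loci = duplex_loci,
         fragment_length_mean = fragment_length_mean,
         fragment_length_sd = fragment_length_sd, samples = samples,
         min_overlap = as.integer(min_overlap),
         max_overhang = as.integer(max_overhang),
         placement = match.arg(placement)),
    class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy annotated reference
#'
#' Builds one bee chromosome tiled with genes separated by unannotated gaps,
#' plus zero or more viral genomes. Each gene receives a biotype
#' (protein-coding genes are kilobase-scale; tRNA and pre-miRNA genes are
#' short) and one to three transcript lengths. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param bee_length bee chromosome length (nt).
#' @param viral_lengths named integer vector of viral genome lengths; names
#'   are used as both reference and species label. Default one 10 kb
#'   VDV-1-like genome; pass an empty vector for none.
#' @param biotype_probs probabilities for a new gene's biotype.
#' @param gap_mean mean intergenic gap (nt).
#' @param dir optional directory; when given, `reference.fasta` and
#'   `annotation.gff3` are written there.
#' @return an [annotated_reference()].
#' @export
make_reference <- function(seed,
                           bee_length = 100000L,
                           viral_lengths = c(vdv1 = 10000L),
                           biotype_probs = c(protein_coding = 0.8,
                                             tRNA = 0.1, pre_miRNA = 0.1),
                           gap_mean = 200,
                           dir = NULL) {
  set.seed(seed)
  stopifnot(bee_length >= 2000)
  pos <- 0L
  rows <- list()
  i <- 0L
  repeat {
    gap <- 1L + stats::rgeom(1, 1 / gap_mean)
    bt <- sample(names(biotype_probs), 1, prob = biotype_probs)
    len <- switch(bt,
      protein_coding = round(stats::runif(1, 400, 2500)),
      tRNA = round(stats::runif(1, 70, 90)),
      pre_miRNA = round(stats::runif(1, 70, 130)),
      round(stats::runif(1, 200, 600)))
    start <- pos + gap
    if (start + len > bee_length) break
    i <- i + 1L
    n_tx <- sample(1:3, 1)
    txl <- round(stats::runif(n_tx, 0.5, 1) * len)
    rows[[i]] <- data.frame(gene_id = sprintf("gene%04d", i),
                            start = start, end = start + len,
                            strand = sample(c("+", "-"), 1),
                            biotype = bt,
                            txl = I(list(txl)))
    pos <- start + len
  }
  g <- do.call(rbind, rows)
  feats <- gene_features(g$gene_id, rep("bee1", nrow(g)), g$start, g$end,
                         g$strand, g$biotype, g$txl)
  seqs <- c(bee1 = random_dna(bee_length))
  species <- c(bee1 = "apis")
  for (v in names(viral_lengths)) {
    seqs[[v]] <- random_dna(viral_lengths[[v]])
    species[[v]] <- v
  }
  ref <- annotated_reference(seqs, feats, species)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(ref$sequences, file.path(dir, "reference.fasta"))
    write_gff3(ref$features, file.path(dir, "annotation.gff3"))
  }
  ref
}

trunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(round(x), lo), hi)
}

# locus spec "gene_id" or "ref:start-end" -> list(reference, start, end)
resolve_locus <- function(locus, reference) {
  if (grepl(":", locus)) {
    ref <- sub(":.*$", "", locus)
    se <- as.integer(strsplit(sub("^[^:]*:", "", locus), "-")[[1]])
    list(reference = ref, start = se[1], end = se[2])
  } else {
    f <- reference$features[reference$features$gene_id == locus, ]
    if (nrow(f) != 1) stop("unknown duplex locus: ", locus)
    list(reference = f$reference, start = f$start, end = f$end)
  }
}

# mates of a fragment [s, e) with sense strand sigma (dUTP):
# mate 2 carries the sense strand and starts at the fragment's 5' end.
fragment_mates <- function(fragment_id, reference, s, e, sigma, sample,
                           read_length) {
  r <- pmin(read_length, e - s)
  m2_start <- ifelse(sigma == "+", s, e - r)
  m1_start <- ifelse(sigma == "+", e - r, s)
  aligned_reads(
    read_id = c(paste0(fragment_id, "/1"), paste0(fragment_id, "/2")),
    fragment_id = rep(fragment_id, 2L),
    mate = rep(c(1L, 2L), each = length(fragment_id)),
    reference = rep(reference, 2L),
    start = c(m1_start, m2_start),
    end = c(m1_start + r, m2_start + r),
    strand = c(ifelse(sigma == "+", "-", "+"), sigma),
    sample = rep(sample, 2L)
  )
}

#' Simulate stranded paired-end fragments with planted duplexes
#'
#' Background fragments are drawn per sample from the configured species and
#' biotype mixes: bee fragments come from a gene of the chosen biotype on
#' the gene's sense strand (or from an annotation gap for `unannotated`);
#' viral fragments come from both strands at the configured sense fraction.
#' Each fragment yields two mates of at most `read_length` nt (truncated at
#' feature ends); under the dUTP chemistry mate 2 maps to the fragment's
#' sense strand.
#'
#' For every planted duplex pair, two distinct molecules — one per strand —
#' are placed at the locus with an overlap of at least `min_overlap` nt and
#' overhangs of at most `max_overhang` nt by construction; a ground-truth
#' table of the planted overlaps is attached as attribute `"truth"` (and
#' validated against its own constraints before being returned).
#'
#' @param reference an [annotated_reference()].
#' @param config a [sim_config()].
#' @param dir optional output directory; per-sample minimal SAM and FASTQ
#'   plus `duplex_truth.tsv` are written when given.
#' @return an aligned-read table with attributes `truth` (planted duplex
#'   ground truth) and `fragments` (one row per simulated molecule).
#' @export
simulate_fragments <- function(reference, config, dir = NULL) {
  set.seed(config$seed)
  R <- config$read_length
  feats <- reference$features
  reflen <- reference_lengths(reference)
  bee_refs <- names(reference$species_of)[reference$species_of == "apis"]
  gaps <- annotation_gaps(reference)

  all_reads <- list()
  all_frags <- list()
  truth <- list()

  for (si in seq_len(nrow(config$samples))) {
    sample_id <- config$samples$sample_id[si]
    group <- config$samples$group[si]
    mix <- config$species_mix[[group]]
    if (is.null(mix)) mix <- config$species_mix[[1]]

    occ <- new.env()  # per-reference occupancy for disjoint placement
    place <- function(ref, lo, hi, len) {
      # sample a start for [start, start+len) within [lo, hi)
      if (hi - lo < len) return(NA_integer_)
      for (try in 1:50) {
        s <- lo + sample.int(hi - lo - len + 1L, 1L) - 1L
        if (config$placement == "uniform") return(s)
        iv <- get0(ref, envir = occ, ifnotfound = NULL)
        if (is.null(iv) ||
            !any(s < iv$end & iv$start < s + len)) {
          assign(ref, list(start = c(iv$start, s), end = c(iv$end, s + len)),
                 envir = occ)
          return(s)
        }
      }
      NA_integer_
    }

    frag_rows <- list()
    k <- 0L
    add_frag <- function(ref, s, e, sigma, origin) {
      k <<- k + 1L
      frag_rows[[k]] <<- data.frame(
        fragment_id = sprintf("%s_f%05d", sample_id, k),
        reference = ref, start = s, end = e, strand = sigma,
        origin = origin, stringsAsFactors = FALSE)
      frag_rows[[k]]$fragment_id
    }

    # -- planted duplex pairs (molecule length == read length, so each
    #    molecule's two mates cover one interval on both strands) ----------
    for (di in seq_len(nrow(config$duplex_loci))) {
      loc <- resolve_locus(config$duplex_loci$locus[di], reference)
      n_pairs <- config$duplex_loci$n_pairs[di]
      for (p in seq_len(n_pairs)) {
        d_max <- R - config$min_overlap
        a <- NA_integer_
        for (attempt in 1:200) {
          d <- sample(seq(-d_max, d_max), 1L)
          span <- R + abs(d)
          a <- place(loc$reference, loc$start, loc$end, span)
          if (!is.na(a)) break
        }
        if (is.na(a))
          stop("cannot place ", n_pairs, " duplex pair(s) at locus '",
               config$duplex_loci$locus[di],
               "'; locus too short or too crowded")
        fwd_s <- if (d >= 0) a else a - d
        rev_s <- fwd_s + d
        id_f <- add_frag(loc$reference, fwd_s, fwd_s + R, "+", "duplex")
        id_r <- add_frag(loc$reference, rev_s, rev_s + R, "-", "duplex")
        truth[[length(truth) + 1L]] <- data.frame(
          sample = sample_id, reference = loc$reference,
          fwd_fragment = id_f, rev_fragment = id_r,
          fwd_start = fwd_s, fwd_end = fwd_s + R,
          rev_start = rev_s, rev_end = rev_s + R,
          overlap_start = max(fwd_s, rev_s),
          overlap_end = min(fwd_s, rev_s) + R,
          overlap_len = R - abs(d),
          locus = config$duplex_loci$locus[di],
          stringsAsFactors = FALSE)
      }
    }

    # -- background fragments --------------------------------------------
    n_resampled <- 0L
    for (b in seq_len(config$n_fragments)) {
      sp <- sample(names(mix), 1L, prob = mix)
      placed <- FALSE
      while (!placed) {
        if (sp == "apis") {
          bt <- sample(names(config$biotype_mix), 1L,
                       prob = config$biotype_mix)
          if (bt == "unannotated") {
            gi <- sample.int(nrow(gaps), 1L,
                             prob = gaps$end - gaps$start)
            lo <- gaps$start[gi]; hi <- gaps$end[gi]
            ref <- gaps$reference[gi]
            sigma <- sample(c("+", "-"), 1L)
          } else {
            cand <- which(feats$biotype == bt &
                            feats$reference %in% bee_refs)
            if (length(cand) == 0) { n_resampled <- n_resampled + 1L; next }
            fi <- cand[sample.int(length(cand), 1L)]
            lo <- feats$start[fi]; hi <- feats$end[fi]
            ref <- feats$reference[fi]
            sigma <- feats$strand[fi]
          }
        } else {
          ref <- names(reference$species_of)[reference$species_of == sp][1]
          lo <- 0L; hi <- reflen[[ref]]
          sigma <- if (stats::runif(1) < 0.75) "+" else "-"
        }
        len <- trunc_norm(1, config$fragment_length_mean,
                          config$fragment_length_sd, R, 600)
        len <- min(len, hi - lo)
        s <- place(ref, lo, hi, len)
        if (is.na(s)) { n_resampled <- n_resampled + 1L
          if (n_resampled > 50L * config$n_fragments)
            stop("placement failed; reference too crowded for config")
          next }
        add_frag(ref, s, s + len, sigma, "background")
        placed <- TRUE
      }
    }
    if (n_resampled > 0)
      message("simulate_fragments[", sample_id, "]: resampled ",
              n_resampled, " fragment placement(s)")

    frags <- do.call(rbind, frag_rows)
    reads <- fragment_mates(frags$fragment_id, frags$reference, frags$start,
                            frags$end, frags$strand, sample_id, R)
    frags$sample <- sample_id
    all_frags[[si]] <- frags
    all_reads[[si]] <- reads
  }

  reads <- do.call(rbind, all_reads)
  class(reads) <- c("aligned_reads", "data.frame")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), reference = character(),
               fwd_fragment = character(), rev_fragment = character(),
               fwd_start = integer(), fwd_end = integer(),
               rev_start = integer(), rev_end = integer(),
               overlap_start = integer(), overlap_end = integer(),
               overlap_len = integer(), locus = character())
  # planted truth must satisfy its own stated constraints
  stopifnot(all(truth$overlap_len >= config$min_overlap),
            all(truth$overlap_len ==
                  truth$overlap_end - truth$overlap_start),
            all(abs(truth$fwd_start - truth$rev_start) <=
                  config$max_overhang))
  attr(reads, "truth") <- truth
  attr(reads, "fragments") <- do.call(rbind, all_frags)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in unique(reads$sample)) {
      sub <- reads[reads$sample == sid, ]
      write_sam_minimal(sub, reference_lengths(reference),
                        file.path(dir, paste0(sid, ".sam")))
      write_fastq(sub, reference,
                  file.path(dir, paste0(sid, "_R1.fastq")),
                  file.path(dir, paste0(sid, "_R2.fastq")))
    }
    utils::write.table(truth, file.path(dir, "duplex_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  reads
}

# unannotated intervals (gaps between gene spans) per bee reference
annotation_gaps <- function(reference) {
  out <- list()
  for (ref in names(reference$sequences)) {
    if (reference$species_of[[ref]] != "apis") next
    L <- nchar(reference$sequences[[ref]])
    f <- reference$features[reference$features$reference == ref, ]
    if (nrow(f) == 0) {
      out[[ref]] <- data.frame(reference = ref, start = 0L, end = L)
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
    gap <- IRanges::gaps(ir, start = 1L, end = L)
    out[[ref]] <- data.frame(reference = ref,
                             start = IRanges::start(gap) - 1L,
                             end = IRanges::end(gap))
  }
  do.call(rbind, out)
}

#' Simulate a gene-to-GO annotation table
#'
#' Assigns `n_terms` GO-like terms to the reference's genes. With
#' `bias = "length"` the per-gene annotation probability increases with the
#' gene's mean transcript length (logistic in centred log-length), emulating
#' the length bias that motivates Wallenius-based enrichment testing. One
#' term can be planted as truly enriched in `interest_set`: its members are
#' drawn preferentially (odds `planted_odds`) from that set.
#'
#' @param reference an [annotated_reference()] with at least 50 genes.
#' @param n_terms number of terms.
#' @param seed integer seed.
#' @param bias `"none"` or `"length"`.
#' @param bias_strength logistic slope on centred log mean transcript
#'   length.
#' @param mean_term_size expected genes per term.
#' @param interest_set gene ids in which to plant an enriched term
#'   (`NULL` disables planting).
#' @param planted_odds enrichment odds of the planted term for interest
#'   genes.
#' @param path optional TSV output (`gene_id<TAB>term_id`).
#' @return data frame `gene_id`, `term_id`; attribute `"truth"` records the
#'   planted term and the bias setting.
#' @export
make_go_universe <- function(reference, n_terms = 200L, seed,
                             bias = c("none", "length"),
                             bias_strength = 1.0,
                             mean_term_size = 15,
                             interest_set = NULL,
                             planted_odds = 8,
                             path = NULL) {
  bias <- match.arg(bias)
  set.seed(seed)
  genes <- reference$features$gene_id
  stopifnot(length(genes) >= 50)
  if (n_terms == 0) {
    out <- data.frame(gene_id = character(), term_id = character())
    attr(out, "truth") <- list(planted_term = NA_character_, bias = bias)
    return(out)
  }
  loglen <- log(reference$features$mean_tx_length)
  z <- loglen - mean(loglen)
  base_p <- mean_term_size / length(genes)
  w <- if (bias == "length") stats::plogis(stats::qlogis(base_p) +
                                             bias_strength * z)
       else rep(base_p, length(genes))

  rows <- list()
  planted_term <- NA_character_
  for (t in seq_len(n_terms)) {
    tid <- sprintf("GO:%07d", t)
    p <- w
    if (t == 1L && !is.null(interest_set)) {
      planted_term <- tid
      odds <- p / (1 - p)
      odds[genes %in% interest_set] <- odds[genes %in% interest_set] *
        planted_odds
      p <- odds / (1 + odds)
    }
    members <- genes[stats::runif(length(genes)) < p]
    if (length(members))
      rows[[t]] <- data.frame(gene_id = members, term_id = tid,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(planted_term = planted_term, bias = bias,
                             interest_set = interest_set)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Titration simulation configuration
#'
#' Mirrors an MST experiment: a 16-step two-fold dilution series of the
#' unlabeled protein is mixed 1:1 (equal volumes, halving both
#' concentrations) with the fluorescently labeled RNA, in triplicate. The
#' signal is a baseline plus a sum of independent binding phases under the
#' ligand-depletion isotherm, with i.i.d. Gaussian noise scaled to the total
#' amplitude (dynamic range).
#'
#' @param phases data frame with `kd` (molar, strictly increasing) and
#'   `amplitude` (signal units) — one row per binding phase.
#' @param labeled_conc prepared labeled-RNA concentration (molar) before
#'   1:1 mixing.
#' @param protein_concs 16 prepared protein concentrations (molar),
#'   strictly increasing.
#' @param baseline signal at zero protein.
#' @param noise_sd noise standard deviation relative to the dynamic range.
#' @param replicates number of replicate curves.
#' @param seed integer seed.
#' @return a `titration_sim_config` list.
#' @export
titration_sim_config <- function(phases,
                                 labeled_conc = 1e-8,
                                 protein_concs = 160e-6 / 2^(15:0),
                                 baseline = 0,
                                 noise_sd = 0.01,
                                 replicates = 3L,
                                 seed) {
  stopifnot(length(protein_concs) == 16L,
            all(diff(protein_concs) > 0),
            all(phases$kd > 0),
            !is.unsorted(phases$kd, strictly = TRUE),
            is.numeric(seed))
  structure(list(phases = phases, labeled_conc = labeled_conc,
                 protein_concs = protein_concs, baseline = baseline,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "titration_sim_config")
}

#' Simulate a multiphasic MST titration
#'
#' Applies the 1:1 equal-volume mixing (both the protein series and the
#' labeled RNA are halved), evaluates the multi-phase ligand-depletion
#' model, and adds Gaussian noise proportional to the dynamic range (sum of
#' absolute phase amplitudes). Deterministic given the config seed.
#'
#' @param config a [titration_sim_config()].
#' @return data frame `conc` (capillary protein concentration, molar),
#'   `signal`, `replicate`; attribute `labeled_conc` is the capillary
#'   labeled concentration.
#' @export
simulate_titration <- function(config) {
  set.seed(config$seed)
  P <- config$protein_concs / 2
  L <- config$labeled_conc / 2
  mu <- predict_binding(
    binding_model(baseline = config$baseline, kd = config$phases$kd,
                  amplitude = config$phases$amplitude, labeled_conc = L),
    P)
  dyn <- sum(abs(config$phases$amplitude))
  out <- do.call(rbind, lapply(seq_len(config$replicates), function(r) {
    data.frame(conc = P,
               signal = mu + stats::rnorm(length(P), 0,
                                          config$noise_sd * dyn),
               replicate = r)
  }))
  attr(out, "labeled_conc") <- L
  out
}

#' Simulate a self-association titration
#'
#' Signal follows a Hill curve `s0 + delta_s * C^h / (kd_app^h + C^h)` in
#' the added (unlabeled) protein concentration, with Gaussian noise relative
#' to `delta_s`.
#'
#' @param kd_app apparent dissociation constant (molar).
#' @param concs added-protein concentrations (molar).
#' @param s0,delta_s baseline and amplitude (signal units).
#' @param hill Hill coefficient.
#' @param noise_sd relative noise level.
#' @param replicates replicate curves.
#' @param seed integer seed.
#' @return data frame `conc`, `signal`, `replicate`.
#' @export
simulate_self_association <- function(kd_app = 3.5e-6,
                                      concs = 160e-6 / 2^(15:0) / 2,
                                      s0 = 0, delta_s = 1, hill = 1,
                                      noise_sd = 0.02, replicates = 3L,
                                      seed) {
  set.seed(seed)
  mu <- s0 + delta_s * concs^hill / (kd_app^hill + concs^hill)
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(conc = concs,
               signal = mu + stats::rnorm(length(concs), 0,
                                          noise_sd * abs(delta_s)),
               replicate = r)
  }))
}
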