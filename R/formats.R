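# Readers/writers for every on-disk format the pipeline touches, plus the
# domain containers all other modules speak in.
#
# Coordinate convention: internal coordinates are ALWAYS 0-based half-open
# [start, end). GFF3 is 1-based closed at the file boundary; BED/bedGraph are
# 0-based half-open. Conversion happens here and nowhere else.

#' Construct a gene feature table
#'
#' Gene features carry strand-aware spans with a biotype label and the
#' lengths of the gene's transcripts (their mean is the gene length used by
#' the length-bias-aware enrichment test). Coordinates are 0-based half-open.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param reference reference (chromosome) name per gene.
#' @param start,end 0-based half-open span per gene (`start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @param biotype one of `"protein_coding"`, `"tRNA"`, `"pre_miRNA"`,
#'   `"other"`.
#' @param transcript_lengths list of positive numeric vectors, one per gene;
#'   defaults to the span length.
#' @return a `data.frame` with one row per gene and a `mean_tx_length`
#'   column.
#' @export
gene_features <- function(gene_id, reference, start, end, strand, biotype,
                          transcript_lengths = NULL) {
  biotypes <- c("protein_coding", "tRNA", "pre_miRNA", "other")
  stopifnot(
    !anyDuplicated(gene_id),
    all(start < end),
    all(strand %in% c("+", "-")),
    all(biotype %in% biotypes)
  )
  if (is.null(transcript_lengths))
    transcript_lengths <- as.list(end - start)
  stopifnot(length(transcript_lengths) == length(gene_id),
            all(vapply(transcript_lengths, function(x) mean(x) > 0, logical(1))))
  df <- data.frame(
    gene_id = as.character(gene_id),
    reference = as.character(reference),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  df$transcript_lengths <- transcript_lengths
  df$mean_tx_length <- vapply(transcript_lengths, mean, numeric(1))
  df[order(df$reference, df$start), , drop = FALSE]
}

#' Construct an annotated reference
#'
#' Bundles reference sequences, gene features, and a reference-to-species
#' map (e.g. `"apis"` for bee chromosomes, `"vdv1"` for a viral genome).
#' This is the universe every read and duplex maps to.
#'
#' @param sequences named character vector (or `DNAStringSet`) of nucleotide
#'   sequences; names are reference names.
#' @param features a data frame from [gene_features()] (may have zero rows).
#' @param species_of named character vector mapping reference name to a
#'   species label.
#' @return an object of class `annotated_reference`.
#' @export
annotated_reference <- function(sequences, features, species_of) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  stopifnot(
    !is.null(names(sequences)), !anyDuplicated(names(sequences)),
    all(features$reference %in% names(sequences)),
    all(names(sequences) %in% names(species_of))
  )
  seqlen <- nchar(sequences)
  if (nrow(features) > 0) {
    stopifnot(all(features$start >= 0),
              all(features$end <= seqlen[features$reference]))
  }
  structure(
    list(sequences = toupper(sequences),
         features = features,
         species_of = species_of[names(sequences)]),
    class = "annotated_reference"
  )
}

#' @export
print.annotated_reference <- function(x, ...) {
  cat("annotated_reference:", length(x$sequences), "sequence(s),",
      nrow(x$features), "gene feature(s)\n")
  cat("  species:", paste(unique(x$species_of), collapse = ", "), "\n")
  invisible(x)
}

reference_lengths <- function(ref) nchar(ref$sequences)

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(stats::setNames(as.character(seqs), names(seqs)))
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Consumes `gene` rows carrying `ID` and (optionally) `biotype` attributes.
#' 1-based closed file coordinates become 0-based half-open; a missing
#' biotype defaults to `"other"`. A `transcript_lengths` attribute
#' (comma-separated) is honoured when present.
#'
#' @param path GFF3 file.
#' @param reference optional `annotated_reference` sequences (named character
#'   vector) used to validate that features lie within bounds.
#' @return a gene feature data frame sorted by (reference, start).
#' @export
read_gff3 <- function(path, reference = NULL) {
  stopifnot(file.exists(path))
  g <- rtracklayer::readGFF(path,
                            filter = list(type = "gene"),
                            columns = c("seqid", "start", "end", "strand", "type"))
  if (nrow(g) == 0) {
    return(gene_features(character(), character(), integer(), integer(),
                         character(), character(), list()))
  }
  biotype <- if ("biotype" %in% names(g)) as.character(g$biotype) else
    rep(NA_character_, nrow(g))
  biotype[is.na(biotype)] <- "other"
  txl <- if ("transcript_lengths" %in% names(g)) {
    # readGFF splits comma-separated attribute values into a list column
    raw <- as.list(g$transcript_lengths)
    lapply(raw, function(s) as.numeric(unlist(strsplit(as.character(s), ","))))
  } else NULL
  feats <- gene_features(
    gene_id = as.character(g$ID),
    reference = as.character(g$seqid),
    start = as.integer(g$start) - 1L,  # 1-based closed -> 0-based half-open
    end = as.integer(g$end),
    strand = as.character(g$strand),
    biotype = biotype,
    transcript_lengths = txl
  )
  if (!is.null(reference)) {
    if (methods::is(reference, "annotated_reference"))
      reference <- reference$sequences
    bad <- !(feats$reference %in% names(reference)) |
      feats$end > nchar(reference)[match(feats$reference, names(reference))]
    if (any(bad))
      stop("feature(s) beyond sequence bounds: ",
           paste(feats$gene_id[bad], collapse = ", "))
  }
  feats
}

#' Write gene features to GFF3
#'
#' Inverse of [read_gff3()] on the domain model: internal 0-based half-open
#' spans are emitted as 1-based closed `gene` rows with `ID`, `biotype` and
#' `transcript_lengths` attributes.
#'
#' @param features gene feature data frame.
#' @param path output file.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0) {
    features <- features[order(features$reference, features$start), ]
    txl <- vapply(features$transcript_lengths,
                  function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                                    collapse = ","),
                  character(1))
    lines <- sprintf("%s\tapisrna\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s;transcript_lengths=%s",
                     features$reference, features$start + 1L, features$end,
                     features$strand, features$gene_id, features$biotype, txl)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Construct an aligned-read table
#'
#' One row per mapped read: 0-based half-open interval, mapped strand, mate
#' index and the fragment (molecule) it came from. The duplex screen and all
#' counting operate on this table.
#'
#' @param read_id,fragment_id,mate,reference,start,end,strand,sample
#'   per-read vectors; `mate` in `{1,2}`, `strand` in `{+,-}`.
#' @return a `data.frame` of class `c("aligned_reads","data.frame")`.
#' @export
aligned_reads <- function(read_id, fragment_id, mate, reference, start, end,
                          strand, sample) {
  stopifnot(all(start < end), all(strand %in% c("+", "-")),
            all(mate %in% c(1L, 2L)))
  df <- data.frame(
    read_id = as.character(read_id),
    fragment_id = as.character(fragment_id),
    mate = as.integer(mate),
    reference = as.character(reference),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    sample = as.character(sample),
    stringsAsFactors = FALSE
  )
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Read stranded alignments (minimal SAM or fragment BED)
#'
#' The minimal SAM dialect supports `@SQ` headers, the FLAG bits for
#' paired/strand/mate, `POS` and CIGARs consisting of a single `M` run;
#' spliced or clipped CIGARs raise an error because the downstream screen
#' operates on plain intervals. Unmapped records are skipped (count
#' reported via message). The fragment-BED dialect is BED6 with
#' `name = fragment_id/mate`.
#'
#' @param path input file.
#' @param dialect `"sam"` or `"bed"`.
#' @param sample sample label attached to every read (default: file stem).
#' @return an aligned-read table ([aligned_reads()]).
#' @export
read_alignments <- function(path, dialect = c("sam", "bed"),
                            sample = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (is.null(sample))
    sample <- sub("\\.(sam|bed)$", "", basename(path))
  if (dialect == "sam") read_sam_minimal(path, sample) else
    read_fragment_bed(path, sample)
}

read_sam_minimal <- function(path, sample) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  ga <- as.data.frame(Rsamtools::scanBam(bam, param = param)[[1]])
  n_unmapped <- sum(bitwAnd(ga$flag, 4L) != 0L)
  if (n_unmapped > 0)
    message("read_alignments: skipped ", n_unmapped, " unmapped record(s)")
  ga <- ga[bitwAnd(ga$flag, 4L) == 0L, , drop = FALSE]
  if (nrow(ga) == 0)
    return(aligned_reads(character(), character(), integer(), character(),
                         integer(), integer(), character(), character()))
  bad <- !grepl("^[0-9]+M$", ga$cigar)
  if (any(bad))
    stop("unsupported CIGAR (minimal dialect accepts a single M run): ",
         ga$cigar[which(bad)[1]])
  len <- as.integer(sub("M$", "", ga$cigar))
  paired <- bitwAnd(ga$flag, 1L) != 0L
  mate <- ifelse(!paired, 1L, ifelse(bitwAnd(ga$flag, 64L) != 0L, 1L, 2L))
  strand <- ifelse(bitwAnd(ga$flag, 16L) != 0L, "-", "+")
  aligned_reads(
    read_id = paste0(ga$qname, "/", mate),
    fragment_id = ga$qname,
    mate = mate,
    reference = as.character(ga$rname),
    start = ga$pos - 1L,
    end = ga$pos - 1L + len,
    strand = strand,
    sample = sample
  )
}

read_fragment_bed <- function(path, sample) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character"))
  frag <- sub("/[12]$", "", bed$name)
  mate <- ifelse(grepl("/2$", bed$name), 2L, 1L)
  aligned_reads(
    read_id = bed$name, fragment_id = frag, mate = mate,
    reference = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand, sample = sample
  )
}

#' Write a minimal SAM file
#'
#' Emits `@SQ` headers and one line per read with FLAG bits for
#' paired/strand/mate and a pure-`M` CIGAR; the inverse of the minimal SAM
#' reader. Sequence and qualities are written as `*`.
#'
#' @param reads aligned-read table.
#' @param reference_lengths named integer vector of reference lengths.
#' @param path output file.
#' @export
write_sam_minimal <- function(reads, reference_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                     as.integer(reference_lengths)), con)
  if (nrow(reads) > 0) {
    paired <- ave(seq_len(nrow(reads)), reads$fragment_id,
                  FUN = length) == 2
    flag <- ifelse(paired, 1L + 2L, 0L) +
      ifelse(reads$strand == "-", 16L, 0L) +
      ifelse(paired & reads$mate == 1L, 64L, 0L) +
      ifelse(paired & reads$mate == 2L, 128L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     reads$fragment_id, flag, reads$reference,
                     reads$start + 1L, reads$end - reads$start)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write intervals as BED6
#'
#' For duplex candidates the score column is the overlap length and the
#' emitted interval is the overlapped (duplexed) region; any table with
#' `reference`, `start`, `end`, `strand` columns is accepted otherwise.
#' Output is sorted by (reference, start).
#'
#' @param x duplex-candidate table or generic interval table.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (all(c("overlap_start", "overlap_end", "overlap_len") %in% names(x))) {
    df <- data.frame(chrom = x$reference, start = x$overlap_start,
                     end = x$overlap_end,
                     name = paste0(x$fwd_read, "|", x$rev_read),
                     score = x$overlap_len, strand = "+")
  } else {
    nm <- if ("name" %in% names(x)) x$name else
      if ("gene_id" %in% names(x)) x$gene_id else
        sprintf("item%d", seq_len(nrow(x)))
    sc <- if ("score" %in% names(x)) x$score else 0L
    df <- data.frame(chrom = x$reference, start = x$start, end = x$end,
                     name = nm, score = sc, strand = x$strand)
  }
  df <- df[order(df$chrom, df$start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write paired reads to FASTQ (constant quality)
#'
#' Read sequences are extracted from the reference (reverse-complemented for
#' minus-strand reads); qualities are constant Q37.
#'
#' @param reads aligned-read table.
#' @param reference an `annotated_reference`.
#' @param path_r1,path_r2 output FASTQ files for mate 1 and mate 2.
#' @export
write_fastq <- function(reads, reference, path_r1, path_r2) {
  for (m in 1:2) {
    sub <- reads[reads$mate == m, , drop = FALSE]
    seqs <- substring(reference$sequences[sub$reference],
                      sub$start + 1L, sub$end)
    neg <- sub$strand == "-"
    if (any(neg))
      seqs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[neg])))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sub$fragment_id
    qual <- Biostrings::BStringSet(strrep("F", nchar(seqs)))  # Q37
    path <- if (m == 1) path_r1 else path_r2
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = qual)
  }
  invisible(c(path_r1, path_r2))
}

#' Read/write a count matrix as TSV
#'
#' Row identifiers in the first column (`id`), one column per sample.
#'
#' @param path TSV file.
#' @return numeric matrix with row and column names.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_counts_tsv
#' @param counts numeric matrix (rows = genes/groups, columns = samples).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal-depth runs are merged, zero runs skipped.
#'
#' @param coverage numeric per-base vector (0-based positions).
#' @param reference reference name.
#' @param path output file.
#' @export
write_bedgraph <- function(coverage, reference, path) {
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = reference, start = starts[keep], end = ends[keep],
                   value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Fragment sense strand under a stranded protocol. TruSeq stranded total RNA
# is dUTP chemistry: the fragment's sense strand is the strand of mate 2;
# "fr" libraries use mate 1.
sense_mate <- function(stranded_protocol = c("dutp", "fr")) {
  switch(match.arg(stranded_protocol), dutp = 2L, fr = 1L)
}

#' Merge read mates into fragments
#'
#' Groups reads by `fragment_id` within each sample and emits one interval
#' per fragment (union of its mates) with the fragment's sense strand
#' inferred from the stranded protocol (dUTP: mate 2 carries the sense
#' strand). Unpaired reads become single-read fragments whose strand is
#' taken as-is when they are mate `sense_mate` or flipped otherwise.
#'
#' @param reads aligned-read table.
#' @param stranded_protocol `"dutp"` (default) or `"fr"`.
#' @return data frame with `fragment_id`, `reference`, `start`, `end`,
#'   `strand` (fragment sense), `sample`.
#' @export
merge_mates <- function(reads, stranded_protocol = c("dutp", "fr")) {
  sm <- sense_mate(stranded_protocol)
  if (nrow(reads) == 0)
    return(data.frame(fragment_id = character(), reference = character(),
                      start = integer(), end = integer(),
                      strand = character(), sample = character()))
  key <- paste(reads$sample, reads$fragment_id, sep = "\r")
  start <- tapply(reads$start, key, min)
  end <- tapply(reads$end, key, max)
  first <- reads[!duplicated(key), ]
  ord <- match(paste(first$sample, first$fragment_id, sep = "\r"),
               names(start))
  # sense strand: strand of the sense mate; if absent, flip the other mate
  sense <- ifelse(reads$mate == sm, reads$strand,
                  ifelse(reads$strand == "+", "-", "+"))
  sense_by_key <- tapply(sense, key, function(s) s[1])
  data.frame(
    fragment_id = first$fragment_id,
    reference = first$reference,
    start = as.integer(start[ord]),
    end = as.integer(end[ord]),
    strand = as.character(sense_by_key[ord]),
    sample = first$sample,
    stringsAsFactors = FALSE
  )
}

# GRanges helper: 0-based half-open domain intervals -> GRanges (1-based).
# An explicit seqlevels universe lets two tables with disjoint references
# be compared without seqlevel mismatch warnings.
as_granges0 <- function(reference, start, end, strand = "*",
                        seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(reference)
  GenomicRanges::GRanges(
    seqnames = factor(reference, levels = seqlevels),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}
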