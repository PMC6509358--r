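# Gene-length-bias-aware GO overrepresentation: expressed-gene universe,
# term-size filter, per-gene membership weights from binned means with
# isotonic smoothing, and Wallenius noncentral hypergeometric upper-tail
# p values. GO is treated as a flat gene -> term table (no DAG).

#' GO analysis configuration
#'
#' @param min_expressed_count a gene is expressed with at least this count
#'   in at least one sample (default 2).
#' @param min_term_size terms annotated to fewer universe genes are
#'   dropped (default 5).
#' @param alpha raw-p significance level for the overrepresentation flag
#'   (default 0.05; no multiple-testing correction by default).
#' @param bias `"length"` (Wallenius with length-derived odds) or
#'   `"none"` (odds 1, i.e. the central hypergeometric).
#' @param adjust apply Benjamini-Hochberg correction to the flag
#'   (off by default).
#' @return a `go_config` list.
#' @export
go_config <- function(min_expressed_count = 2L, min_term_size = 5L,
                      alpha = 0.05, bias = c("length", "none"),
                      adjust = FALSE) {
  stopifnot(min_expressed_count > 0, min_term_size > 0, alpha > 0)
  structure(list(min_expressed_count = as.integer(min_expressed_count),
                 min_term_size = as.integer(min_term_size), alpha = alpha,
                 bias = match.arg(bias), adjust = isTRUE(adjust)),
            class = "go_config")
}

#' Expressed-gene universe
#'
#' Genes with a count of at least `min_expressed_count` in at least one
#' sample.
#'
#' @param counts gene-by-sample count matrix.
#' @param config a [go_config()].
#' @return character vector of gene ids.
#' @export
build_universe <- function(counts, config = go_config()) {
  u <- rownames(counts)[apply(counts, 1, max) >= config$min_expressed_count]
  if (length(u) == 0) stop("empty expressed-gene universe")
  u
}

#' Length-bias membership weights
#'
#' Estimates P(gene in interest set | gene length) as a monotone
#' nondecreasing function of length: genes are grouped into
#' equal-occupancy length bins, per-bin membership means are smoothed by
#' isotonic regression (weighted by bin size) against bin mean length, and
#' the fitted value is mapped back to each gene, clipped to
#' `(eps, 1 - eps)`.
#'
#' @param universe gene ids.
#' @param interest_set gene ids of the differentially-represented set.
#' @param gene_lengths named numeric vector (mean transcript length per
#'   gene), covering the universe.
#' @param n_bins number of length bins.
#' @param eps clipping margin.
#' @return named weight vector over the universe, values in (0, 1).
#' @export
length_bias_weights <- function(universe, interest_set, gene_lengths,
                                n_bins = 10L, eps = 1e-4) {
  stopifnot(all(universe %in% names(gene_lengths)))
  len <- gene_lengths[universe]
  stopifnot(all(len > 0))
  member <- as.numeric(universe %in% interest_set)
  if (all(member == 1) || all(member == 0)) {
    warning("interest set covers all or none of the universe; ",
            "uniform weights returned")
    return(stats::setNames(rep(pmin(pmax(mean(member), eps), 1 - eps),
                               length(universe)), universe))
  }
  n_bins <- max(2L, min(n_bins, floor(length(universe) / 5)))
  br <- unique(stats::quantile(len, probs = seq(0, 1, length.out =
                                                  n_bins + 1L)))
  bin <- cut(len, breaks = br, include.lowest = TRUE)
  bin_mean <- tapply(member, bin, mean)
  bin_len <- tapply(len, bin, mean)
  bin_n <- as.numeric(table(bin))
  keep <- !is.na(bin_mean)
  o <- order(bin_len[keep])
  # weighted isotonic (nondecreasing in length) via pool-adjacent-violators
  fit <- pava(bin_mean[keep][o], bin_n[keep][o])
  w_bin <- stats::setNames(numeric(sum(keep)), names(bin_mean)[keep][o])
  w_bin[] <- fit
  w <- w_bin[as.character(bin)]
  stats::setNames(pmin(pmax(unname(w), eps), 1 - eps), universe)
}

# pool-adjacent-violators: weighted isotonic (nondecreasing) fit
pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) /
        (wt[m - 1L] + wt[m])
      wt[m - 1L] <- wt[m - 1L] + wt[m]
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], size[seq_len(m)])
}

#' Wallenius noncentral hypergeometric probabilities
#'
#' Exact dynamic program over the distribution's defining sequential-draw
#' process: `n_set` items are drawn one at a time without replacement from
#' an urn of `n_annotated` white (in-term) and `n_universe - n_annotated`
#' black items, each draw picking an item with probability proportional to
#' its weight (white items have relative weight `odds`). The state after
#' `i` draws is fully described by the number of whites drawn, giving an
#' O(n_set^2) recurrence for the pmf.
#'
#' `wallenius_pvalue` returns the upper tail `P(X >= n_hit)`.
#'
#' @param n_annotated white (term-annotated) items in the universe.
#' @param n_universe universe size.
#' @param n_set number of draws (interest-set size).
#' @param n_hit observed white draws.
#' @param odds weight of white relative to black items (> 0).
#' @return upper-tail probability in (0, 1].
#' @export
wallenius_pvalue <- function(n_annotated, n_universe, n_set, n_hit,
                             odds = 1) {
  pmf <- wallenius_pmf(n_annotated, n_universe, n_set, odds)
  p <- sum(pmf[seq.int(n_hit + 1L, length(pmf))])
  min(max(p, .Machine$double.xmin), 1)
}

#' @rdname wallenius_pvalue
#' @return `wallenius_pmf`: numeric vector of `P(X = x)` for
#'   `x = 0..n_set`.
#' @export
wallenius_pmf <- function(n_annotated, n_universe, n_set, odds = 1) {
  stopifnot(odds > 0, n_annotated >= 0, n_set >= 0,
            n_annotated <= n_universe, n_set <= n_universe)
  m1 <- n_annotated
  m2 <- n_universe - n_annotated
  # prob[x + 1] = P(x whites after i draws)
  prob <- c(1, numeric(n_set))
  if (n_set == 0) return(prob)
  for (i in seq_len(n_set)) {
    new <- numeric(n_set + 1L)
    xs <- 0:(i - 1L)
    for (x in xs) {
      p <- prob[x + 1L]
      if (p == 0) next
      ww <- (m1 - x) * odds          # total weight of remaining whites
      wb <- m2 - (i - 1L - x)        # remaining blacks (weight 1 each)
      tot <- ww + wb
      if (tot <= 0) next
      if (ww > 0) new[x + 2L] <- new[x + 2L] + p * ww / tot
      if (wb > 0) new[x + 1L] <- new[x + 1L] + p * wb / tot
    }
    prob <- new
  }
  prob
}

# odds ratio from membership weights: mean weight inside the term vs out
term_odds <- function(weights, in_term) {
  wi <- mean(weights[in_term])
  wo <- mean(weights[!in_term])
  (wi / (1 - wi)) / (wo / (1 - wo))
}

#' Run the GO overrepresentation analysis
#'
#' Restricts the annotation to the universe, drops terms with fewer than
#' `min_term_size` annotated universe genes, and tests each remaining term
#' for overrepresentation in the interest set with the Wallenius
#' noncentral hypergeometric upper tail. With `bias = "length"` the term
#' odds derive from the length-bias weights ([length_bias_weights()]);
#' with `bias = "none"` all odds are 1 (central hypergeometric). A term is
#' flagged overrepresented when its (raw, by default) p value is below
#' `alpha`.
#'
#' @param interest_set gene ids of interest (subset of the universe; genes
#'   outside the universe are ignored).
#' @param universe expressed gene ids.
#' @param gene2go data frame `gene_id`, `term_id`.
#' @param gene_lengths named mean-transcript-length vector.
#' @param config a [go_config()].
#' @return data frame of term results sorted by p value: `term_id`,
#'   `n_annotated`, `n_in_set`, `expected`, `odds`, `p_over`,
#'   `flag_overrepresented`.
#' @export
run_go <- function(interest_set, universe, gene2go, gene_lengths,
                   config = go_config()) {
  interest_set <- intersect(interest_set, universe)
  g2g <- gene2go[gene2go$gene_id %in% universe, , drop = FALSE]
  sizes <- table(g2g$term_id)
  terms <- names(sizes)[sizes >= config$min_term_size]
  if (length(terms) == 0)
    return(data.frame(term_id = character(), n_annotated = integer(),
                      n_in_set = integer(), expected = numeric(),
                      odds = numeric(), p_over = numeric(),
                      flag_overrepresented = logical()))
  weights <- if (config$bias == "length")
    length_bias_weights(universe, interest_set, gene_lengths)
  else stats::setNames(rep(0.5, length(universe)), universe)
  n_u <- length(universe)
  n_s <- length(interest_set)
  res <- lapply(terms, function(tid) {
    ann <- unique(g2g$gene_id[g2g$term_id == tid])
    in_term <- universe %in% ann
    odds <- if (config$bias == "length") term_odds(weights, in_term) else 1
    n_hit <- sum(ann %in% interest_set)
    p <- wallenius_pvalue(length(ann), n_u, n_s, n_hit, odds)
    data.frame(term_id = tid, n_annotated = length(ann),
               n_in_set = n_hit,
               expected = n_s * length(ann) / n_u,
               odds = odds, p_over = p)
  })
  res <- do.call(rbind, res)
  p_for_flag <- if (config$adjust) stats::p.adjust(res$p_over, "BH") else
    res$p_over
  res$flag_overrepresented <- p_for_flag < config$alpha
  res <- res[order(res$p_over), , drop = FALSE]
  rownames(res) <- NULL
  res
}
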