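# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own code paths.

# Exact hypergeometric upper tail P(X >= q) by direct log-binomial summation.
oracle_hyper_p <- function(q, m, n, k) {
  hi <- min(k, m)
  if (q > hi) return(0)
  j <- max(q, max(0, k - n)):hi
  sum(exp(lchoose(m, j) + lchoose(n, k - j) - lchoose(m + n, k)))
}

# Mutual best hit by literal predicate scan over all (a, b) pairs.
oracle_mbh <- function(fwd, rev) {
  out <- list()
  for (a in unique(fwd$query_id)) {
    fa <- fwd[fwd$query_id == a, ]
    top <- fa[fa$score == max(fa$score), ]
    if (nrow(top) != 1) next
    b <- top$target_id
    rb <- rev[rev$query_id == b, ]
    if (nrow(rb) == 0) next
    rtop <- rb[rb$score == max(rb$score), ]
    if (nrow(rtop) == 1 && rtop$target_id == a) {
      out[[length(out) + 1]] <- c(a, b)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(gene_a = m[, 1], gene_b = m[, 2]) |>
    dplyr::arrange(gene_a)
}

# Exhaustive Hamming scan: does any leader k-mer match any window at <= d?
oracle_sl_match <- function(seq, leaders, k = 25, max_mismatch = 3) {
  sv <- strsplit(seq, "")[[1]]
  for (li in seq_len(nrow(leaders))) {
    lv <- strsplit(leaders$sequence[li], "")[[1]]
    for (kk in seq_len(max(0, length(lv) - k + 1))) {
      kmer <- lv[kk:(kk + k - 1)]
      for (w in seq_len(max(0, length(sv) - k + 1))) {
        if (sum(sv[w:(w + k - 1)] != kmer) <= max_mismatch) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Exhaustive maximum-weight matching over within-family pairs.
oracle_max_matching_score <- function(df) {
  best <- 0
  recurse <- function(i, used, total) {
    if (i > nrow(df)) {
      best <<- max(best, total)
      return(invisible())
    }
    if (!(df$gene1[i] %in% used) && !(df$gene2[i] %in% used)) {
      recurse(i + 1, c(used, df$gene1[i], df$gene2[i]), total + df$score[i])
    }
    recurse(i + 1, used, total)
  }
  recurse(1L, character(0), 0)
  best
}

# Exhaustive minimal Dollo event count for one presence pattern: enumerate all
# internal-node labelings, keep those with exactly one gain (counting a gain
# on the pre-root branch when the root is labelled present), minimise losses.
oracle_dollo_min_losses <- function(tree, present_tips) {
  edges <- tree$edge
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n_nodes <- ntip + nnode
  tip_state <- rep(0L, ntip)
  tip_state[match(present_tips, tree$tip.label)] <- 1L
  best <- Inf
  for (code in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(code))[seq_len(nnode)]
    state <- c(tip_state, internal)
    gains <- state[ntip + 1] # pre-root gain when root present
    losses <- 0
    for (e in seq_len(nrow(edges))) {
      p <- state[edges[e, 1]]; ch <- state[edges[e, 2]]
      if (p == 0 && ch == 1) gains <- gains + 1
      if (p == 1 && ch == 0) losses <- losses + 1
    }
    if (gains == 1) best <- min(best, losses)
  }
  best
}

# Small three-chromosome annotation with deterministic coordinates.
fixture_annotation <- function(n_per_chrom = 10, gap = 5000, len = 1000,
                               chroms = c("chr1", "chr2", "chr3")) {
  dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
    start <- (seq_len(n_per_chrom) - 1) * (gap + len)
    tibble::tibble(
      gene_id = sprintf("%s_g%02d", chroms[ci], seq_len(n_per_chrom)),
      chrom = chroms[ci], start = start, end = start + len,
      strand = rep(c("+", "-"), length.out = n_per_chrom),
      exon_count = 3L + (seq_len(n_per_chrom) %% 4L)
    )
  }))
}

fixture_leaders <- function(seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      name = c("SL1", "SL2", "SL3"),
      sequence = vapply(1:3, function(i) {
        paste(sample(c("A", "C", "G", "T"), 28, replace = TRUE),
              collapse = "")
      }, character(1))
    )
  })
}

# Substitute exactly n mismatches at distinct positions of a sequence.
with_mismatches <- function(seq, positions) {
  other <- c(A = "C", C = "A", G = "T", T = "G")
  v <- strsplit(seq, "")[[1]]
  v[positions] <- other[v[positions]]
  paste(v, collapse = "")
}

fixture_tree8 <- function() {
  ape::read.tree(text = "((A,B),(C,(D,(E,(F,(G,H))))));")
}
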