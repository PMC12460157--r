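# Splice-leader detection, trans-spliced gene classification, operon calling,
# cell QC, expression specificity, and regulatory complexity comparison.

#' Detect a splice leader in a read 5' window
#'
#' A read matches when any `k`-mer of any leader aligns to any `k`-wide
#' window of the stored 5' sequence with Hamming distance at most
#' `max_mismatch`. Ambiguous bases count as mismatches. The best match
#' (lowest distance, then earliest window position, then leader order) is
#' returned. Vectorised over reads.
#'
#' @param five_prime_seq Character vector of read 5' windows (>= `k` nt).
#' @param leaders Splice-leader tibble (`name`, `sequence`).
#' @param k Match seed length.
#' @param max_mismatch Inclusive Hamming distance threshold.
#' @return Character vector of matched leader names (`NA` when no match).
#' @export
detect_splice_leader <- function(five_prime_seq, leaders, k = 25,
                                 max_mismatch = 3) {
  if (any(nchar(five_prime_seq) < k)) {
    stop("all 5' sequences must be at least k nt long")
  }
  best_name <- rep(NA_character_, length(five_prime_seq))
  best_dist <- rep(Inf, length(five_prime_seq))
  best_pos <- rep(Inf, length(five_prime_seq))
  seq_mat <- seq_to_int_matrix(five_prime_seq)
  max_w <- max(nchar(five_prime_seq)) - k + 1
  for (li in seq_len(nrow(leaders))) {
    lv <- utf8ToInt(leaders$sequence[li])
    n_kmer <- length(lv) - k + 1
    if (n_kmer < 1) next
    for (kk in seq_len(n_kmer)) {
      kmer <- lv[kk:(kk + k - 1)]
      for (w in seq_len(max_w)) {
        wnd <- seq_mat[, w:(w + k - 1), drop = FALSE]
        d <- rowSums(wnd != rep(kmer, each = nrow(wnd)))
        hit <- d <= max_mismatch &
          (d < best_dist | (d == best_dist & w < best_pos))
        best_name[hit] <- leaders$name[li]
        best_dist[hit] <- d[hit]
        best_pos[hit] <- w
      }
    }
  }
  best_name
}

# Character sequences (equal length assumed padded) -> integer code matrix;
# positions beyond a sequence's length are coded 0 (mismatch to everything).
seq_to_int_matrix <- function(seqs) {
  n <- length(seqs)
  width <- max(nchar(seqs))
  mat <- matrix(0L, n, width)
  for (i in seq_len(n)) {
    v <- utf8ToInt(seqs[i])
    mat[i, seq_along(v)] <- v
  }
  mat
}

#' Classify trans-spliced genes from splice-leader read counts
#'
#' Counts, per gene, the reads carrying a detected splice leader; a gene is
#' trans-spliced when its total reaches `min_reads`. The per-leader
#' breakdown is retained in long form.
#'
#' @param reads Read tibble (`read_id`, `gene_id`, `five_prime_seq`).
#' @param leaders Splice-leader tibble (`name`, `sequence`).
#' @param min_reads Inclusive threshold of leader-bearing reads.
#' @param gene_ids Optional vector of genes to report (zero counts included).
#' @param k,max_mismatch Passed to [detect_splice_leader].
#' @return List with `genes` (tibble `gene_id`, `total_sl_reads`,
#'   `trans_spliced`) and `leader_counts` (tibble `gene_id`, `leader`, `n`).
#' @export
classify_trans_spliced <- function(reads, leaders, min_reads = 5,
                                   gene_ids = NULL, k = 25, max_mismatch = 3) {
  hit <- detect_splice_leader(reads$five_prime_seq, leaders, k, max_mismatch)
  gene_ids <- gene_ids %||% sort(unique(reads$gene_id))
  leader_counts <- tibble::tibble(gene_id = reads$gene_id, leader = hit) |>
    dplyr::filter(!is.na(.data$leader)) |>
    dplyr::count(.data$gene_id, .data$leader)
  totals <- leader_counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(total_sl_reads = sum(.data$n), .groups = "drop")
  genes <- tibble::tibble(gene_id = gene_ids) |>
    dplyr::left_join(totals, by = "gene_id") |>
    dplyr::mutate(
      total_sl_reads = dplyr::coalesce(.data$total_sl_reads, 0L),
      trans_spliced = .data$total_sl_reads >= min_reads
    )
  list(genes = genes, leader_counts = leader_counts)
}

#' Call candidate and validated operons
#'
#' Chains consecutive genes of a chromosome (and strand, unless
#' `require_same_strand = FALSE`) whenever the intergenic gap
#' `next start - previous end` is strictly below `max_gap` (0-based
#' half-open coordinates: abutting genes have gap 0; overlapping genes have a
#' negative gap and are chained with a warning). Chains of two or more genes
#' are candidate operons; a candidate is validated when at least one member
#' is trans-spliced. Every gene belongs to at most one operon and the output
#' is invariant to input row order.
#'
#' @param annot Gene tibble.
#' @param sl Trans-spliced classification: tibble with `gene_id`,
#'   `trans_spliced` (e.g. `classify_trans_spliced(...)$genes`).
#' @param max_gap Strict chaining threshold in bp.
#' @param require_same_strand Break chains at strand switches.
#' @return Tibble of operons: `operon_id`, `chrom`, `strand`, `n_genes`,
#'   `genes` (list-column of ordered gene ids), `candidate`, `validated`.
#' @export
call_operons <- function(annot, sl, max_gap = 250,
                         require_same_strand = TRUE) {
  ts <- setNames(sl$trans_spliced, sl$gene_id)
  genes <- dplyr::arrange(annot, .data$chrom, .data$start, .data$gene_id)
  gap <- c(NA, genes$start[-1] - genes$end[-nrow(genes)])
  new_chrom <- c(TRUE, genes$chrom[-1] != genes$chrom[-nrow(genes)])
  strand_break <- if (require_same_strand) {
    c(FALSE, genes$strand[-1] != genes$strand[-nrow(genes)])
  } else rep(FALSE, nrow(genes))
  breaks <- new_chrom | strand_break | is.na(gap) | gap >= max_gap
  if (any(gap[!breaks] < 0, na.rm = TRUE)) {
    warning("overlapping genes (negative gap) chained into operons")
  }
  chain <- cumsum(breaks)
  genes$chain <- chain
  operons <- genes |>
    dplyr::group_by(.data$chain) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      strand = if (length(unique(.data$strand)) == 1) .data$strand[1] else "*",
      n_genes = dplyr::n(),
      genes = list(.data$gene_id),
      validated = any(ts[.data$gene_id], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      operon_id = sprintf("operon_%04d", dplyr::row_number()),
      candidate = TRUE
    ) |>
    dplyr::select("operon_id", "chrom", "strand", "n_genes", "genes",
                  "candidate", "validated")
  operons
}

#' Filter cells on UMI, gene and mitochondrial thresholds
#'
#' Keeps a cell iff `min_umi <= UMIs <= max_umi`, detected genes
#' `>= min_genes`, and mitochondrial fraction `<= max_mito`: thresholds
#' phrased as "fewer than" / "more than" / "higher than" are strict
#' removals, so boundary values are kept.
#'
#' @param counts Cell x gene count matrix (rows are cells).
#' @param mito_frac Per-cell mitochondrial fraction in `[0, 1]`.
#' @param min_umi,max_umi,min_genes,max_mito QC thresholds.
#' @return List with `counts` (filtered matrix) and `cells` (tibble `cell`,
#'   `umis`, `n_genes`, `mito_frac`, `keep`).
#' @export
qc_filter_cells <- function(counts, mito_frac, min_umi = 500,
                            max_umi = 20000, min_genes = 200,
                            max_mito = 0.20) {
  stopifnot(nrow(counts) == length(mito_frac),
            all(mito_frac >= 0 & mito_frac <= 1))
  umis <- rowSums(counts)
  n_genes <- rowSums(counts > 0)
  keep <- umis >= min_umi & umis <= max_umi & n_genes >= min_genes &
    mito_frac <= max_mito
  cells <- tibble::tibble(
    cell = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    umis = unname(umis), n_genes = unname(n_genes),
    mito_frac = unname(mito_frac), keep = unname(keep)
  )
  list(counts = counts[keep, , drop = FALSE], cells = cells)
}

#' Expression specificity: tau and coefficient of variation
#'
#' From cell-type-averaged expression: `cv = sd / mean` over cell types, and
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`. Tau is 0 for uniform non-zero
#' profiles and 1 for single-cell-type expression; both indices are invariant
#' to scaling a profile by a positive constant. All-zero genes are flagged
#' with undefined scores.
#'
#' @param celltype_means Cell-type x gene matrix of mean expression.
#' @return Tibble: `gene_id`, `mean_expr`, `cv`, `tau`, `defined`.
#' @export
expression_specificity <- function(celltype_means) {
  if (nrow(celltype_means) < 2) stop("need at least 2 cell types")
  m <- unname(colMeans(celltype_means))
  s <- unname(apply(celltype_means, 2, sd))
  mx <- unname(apply(celltype_means, 2, max))
  n <- nrow(celltype_means)
  tau <- unname(colSums(
    1 - sweep(celltype_means, 2, ifelse(mx > 0, mx, 1), "/")
  )) / (n - 1)
  defined <- m > 0
  tibble::tibble(
    gene_id = colnames(celltype_means) %||%
      as.character(seq_len(ncol(celltype_means))),
    mean_expr = unname(m),
    cv = ifelse(defined, unname(s / m), NA_real_),
    tau = ifelse(defined, unname(tau), NA_real_),
    defined = unname(defined)
  )
}

#' Open-chromatin peak counts per gene category
#'
#' Assigns each peak to the gene with the nearest transcription start site
#' (strand-aware: `start` for `+` genes, `end` for `-` genes) within
#' `max_dist`; ties go to the earlier gene in coordinate order. Per-gene
#' counts are summarised per category and categories are compared pairwise
#' with two-sided Mann-Whitney tests.
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`).
#' @param annot Gene tibble.
#' @param gene_categories Tibble `gene_id`, `category` (e.g. operonic /
#'   trans_spliced / other).
#' @param max_dist Maximal peak-to-TSS distance for assignment (bp).
#' @return List: `counts` (tibble `gene_id`, `category`, `n_peaks`),
#'   `tests` (tibble `category_a`, `category_b`, `p`).
#' @export
regulatory_complexity <- function(peaks, annot, gene_categories,
                                  max_dist = 10000) {
  genes <- annot |>
    dplyr::mutate(tss = ifelse(.data$strand == "-", .data$end, .data$start)) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
  assigned <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) { assigned[i] <- NA_character_; next }
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    d <- abs(g$tss - mid)
    j <- which(d == min(d))[1] # ties: earlier gene in coordinate order
    assigned[i] <- if (d[j] <= max_dist) g$gene_id[j] else NA_character_
  }
  counts <- gene_categories |>
    dplyr::left_join(
      tibble::tibble(gene_id = assigned[!is.na(assigned)]) |>
        dplyr::count(.data$gene_id, name = "n_peaks"),
      by = "gene_id"
    ) |>
    dplyr::mutate(n_peaks = dplyr::coalesce(.data$n_peaks, 0L))
  cats <- sort(unique(counts$category))
  if (length(cats) < 2) {
    return(list(counts = counts,
                tests = tibble::tibble(category_a = character(),
                                       category_b = character(),
                                       p = numeric())))
  }
  tests <- purrr::map_dfr(utils::combn(cats, 2, simplify = FALSE), function(pr) {
    a <- counts$n_peaks[counts$category == pr[1]]
    b <- counts$n_peaks[counts$category == pr[2]]
    p <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
    tibble::tibble(category_a = pr[1], category_b = pr[2], p = p)
  })
  list(counts = counts, tests = tests)
}
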