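# Splice-leader detection, trans-spliced classification, operon chaining,
# cell QC, specificity indices, and regulatory complexity.

test_that("splice-leader matching respects the Hamming threshold exactly", {
  leaders <- fixture_leaders()
  base <- paste0(substr(leaders$sequence[1], 1, 25), "CGTAC")
  expect_equal(detect_splice_leader(base, leaders), "SL1")
  m3 <- with_mismatches(base, c(2, 9, 17))
  expect_equal(detect_splice_leader(m3, leaders), "SL1")
  m4 <- with_mismatches(base, c(2, 9, 17, 21))
  expect_true(is.na(detect_splice_leader(m4, leaders)))
  expect_error(detect_splice_leader("ACGT", leaders), "at least k")
})

test_that("detection equals the exhaustive Hamming scan on random reads", {
  leaders <- fixture_leaders()
  withr::with_seed(8, {
    seqs <- vapply(seq_len(1000), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
      if (i %% 3 == 0) {
        # plant a leader fragment with 0-4 mismatches at a random offset
        li <- sample(3, 1)
        frag <- substr(leaders$sequence[li], 1, 26)
        frag <- with_mismatches(frag, sample(26, sample(0:4, 1)))
        s <- substr(paste0(frag, s), 1, 30)
      }
      s
    }, character(1))
    got <- !is.na(detect_splice_leader(seqs, leaders))
    want <- vapply(seqs, oracle_sl_match, logical(1), leaders = leaders)
    expect_equal(unname(got), unname(want))
  })
})

test_that("the five-read threshold for trans-splicing is inclusive", {
  leaders <- fixture_leaders()
  sl_seq <- substr(paste0(leaders$sequence[1], "ACGTACGTAC"), 1, 30)
  plain <- strrep("AC", 15)
  mk_reads <- function(n_sl, gene) {
    tibble::tibble(
      read_id = sprintf("%s_r%d", gene, seq_len(n_sl + 3)),
      gene_id = gene,
      five_prime_seq = c(rep(sl_seq, n_sl), rep(plain, 3))
    )
  }
  reads <- dplyr::bind_rows(mk_reads(5, "g5"), mk_reads(4, "g4"),
                            mk_reads(0, "g0"))
  cls <- classify_trans_spliced(reads, leaders)
  got <- setNames(cls$genes$trans_spliced, cls$genes$gene_id)
  expect_true(got[["g5"]])
  expect_false(got[["g4"]])
  expect_false(got[["g0"]])
  expect_equal(cls$genes$total_sl_reads[cls$genes$gene_id == "g0"], 0L)
})

test_that("operon chaining uses a strict gap bound in half-open coordinates", {
  sl <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       trans_spliced = c(FALSE, TRUE, FALSE))
  annot249 <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", start = c(0, 349),
    end = c(100, 400), strand = "+", exon_count = 1L
  )
  ops <- call_operons(annot249, sl)
  expect_equal(nrow(ops), 1) # gap 249 < 250 chains

  annot250 <- annot249
  annot250$start[2] <- 350
  expect_equal(nrow(call_operons(annot250, sl)), 0) # gap 250 breaks

  # three genes with gaps 100, 100, middle one trans-spliced -> validated
  annot3 <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(0, 200, 400), end = c(100, 300, 500), strand = "+",
    exon_count = 1L
  )
  ops3 <- call_operons(annot3, sl)
  expect_equal(ops3$n_genes, 3)
  expect_true(ops3$validated)
  expect_equal(ops3$genes[[1]], c("g1", "g2", "g3"))
})

test_that("strand handling and overlap warnings behave as documented", {
  sl <- tibble::tibble(gene_id = c("g1", "g2"), trans_spliced = TRUE)
  annot <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", start = c(0, 150),
    end = c(100, 250), strand = c("+", "-"), exon_count = 1L
  )
  expect_equal(nrow(call_operons(annot, sl)), 0)
  expect_equal(nrow(call_operons(annot, sl, require_same_strand = FALSE)), 1)

  overlapping <- annot
  overlapping$strand <- "+"
  overlapping$start[2] <- 50
  expect_warning(call_operons(overlapping, sl), "negative gap")
})

test_that("operon calling partitions genes and is order-invariant and monotone", {
  withr::with_seed(14, {
    n <- 60
    start <- cumsum(sample(c(100, 200, 400, 5000), n, replace = TRUE)) +
      (0:(n - 1)) * 800
    annot <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n), chrom = rep(c("c1", "c2"), each = 30),
      start = start, end = start + 700,
      strand = sample(c("+", "-"), n, replace = TRUE), exon_count = 1L
    )
    sl <- tibble::tibble(gene_id = annot$gene_id,
                         trans_spliced = runif(n) < 0.5)
    ops <- call_operons(annot, sl)
    all_genes <- unlist(ops$genes)
    expect_equal(anyDuplicated(all_genes), 0) # partition refinement
    shuffled <- call_operons(annot[sample(n), ], sl)
    expect_equal(ops, shuffled)
    for (gap in c(100, 250, 500, 1000)) {
      lo <- sum(call_operons(annot, sl, max_gap = gap)$n_genes)
      hi <- sum(call_operons(annot, sl, max_gap = gap * 2)$n_genes)
      expect_lte(lo, hi) # raising max_gap never removes genes from operons
    }
  })
})

test_that("classification recovers planted trans-splicing at high accuracy", {
  annot <- fixture_annotation(n_per_chrom = 25)
  leaders <- fixture_leaders()
  operons <- list(c("chr1_g01", "chr1_g02"), c("chr2_g05", "chr2_g06"))
  lib <- simulate_sl_library(annot, operons, leaders, reads_per_gene = 20,
                             sl_fraction = 0.6, error_rate = 0.01, seed = 19)
  cls <- classify_trans_spliced(lib$reads, leaders,
                                gene_ids = annot$gene_id)
  truth <- tidy(lib$truth)
  joined <- dplyr::inner_join(cls$genes, truth, by = "gene_id",
                              suffix = c("_called", "_true"))
  tp <- sum(joined$trans_spliced_called & joined$trans_spliced_true)
  recall <- tp / sum(joined$trans_spliced_true)
  precision <- tp / sum(joined$trans_spliced_called)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("cell QC boundaries are kept and violations removed", {
  genes <- 300
  mk_cell <- function(umis, n_genes) {
    v <- numeric(genes)
    if (n_genes > 0) {
      v[seq_len(n_genes)] <- c(umis - n_genes + 1, rep(1, n_genes - 1))
    }
    v
  }
  counts <- rbind(
    ok = mk_cell(500, 200),      # both at boundary: kept
    low_umi = mk_cell(499, 200), # fewer than 500 UMIs: removed
    high_umi = mk_cell(20001, 250),
    few_genes = mk_cell(600, 199),
    high_mito = mk_cell(600, 250),
    at_mito = mk_cell(20000, 250) # 20% mito and 20000 UMIs: kept
  )
  mito <- c(0.10, 0.10, 0.10, 0.10, 0.25, 0.20)
  res <- qc_filter_cells(counts, mito)
  expect_equal(res$cells$keep,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(rownames(res$counts), c("ok", "at_mito"))
})

test_that("tau and cv follow their formulas and are scale invariant", {
  m <- rbind(c(1, 2, 4), c(0, 2, 2), c(0, 2, 2), c(0, 2, 0))
  colnames(m) <- c("single", "uniform", "mixed")
  res <- expression_specificity(m)
  expect_equal(res$tau[res$gene_id == "single"], 1)
  expect_equal(res$tau[res$gene_id == "uniform"], 0)
  expect_equal(res$cv[res$gene_id == "uniform"], 0)
  # hand evaluation for [4, 2, 2, 0]: tau = (0.5 + 0.5 + 1) / 3
  expect_equal(res$tau[res$gene_id == "mixed"], 2 / 3)
  expect_equal(res$cv[res$gene_id == "mixed"],
               sd(c(4, 2, 2, 0)) / mean(c(4, 2, 2, 0)))

  scaled <- expression_specificity(m * 13)
  expect_equal(res$tau, scaled$tau)
  expect_equal(res$cv, scaled$cv)

  zero <- expression_specificity(cbind(m, allzero = 0))
  expect_false(zero$defined[zero$gene_id == "allzero"])
  expect_true(is.na(zero$tau[zero$gene_id == "allzero"]))
})

test_that("peak assignment ties go to the earlier gene and counts compare", {
  annot <- tibble::tibble(
    gene_id = c("early", "late"), chrom = "chr1",
    start = c(1000, 3000), end = c(1500, 3500), strand = "+",
    exon_count = 1L
  )
  # peak midpoint 2000: equidistant from both TSSs (1000 and 3000)
  peaks <- tibble::tibble(chrom = "chr1", start = 1900, end = 2100)
  cats <- tibble::tibble(gene_id = c("early", "late"), category = "other")
  res <- regulatory_complexity(peaks, annot, cats)
  expect_equal(res$counts$n_peaks[res$counts$gene_id == "early"], 1L)
  expect_equal(res$counts$n_peaks[res$counts$gene_id == "late"], 0L)

  none <- regulatory_complexity(peaks[0, ], annot, cats)
  expect_true(all(none$counts$n_peaks == 0))
})

test_that("planted peak asymmetry separates categories", {
  withr::with_seed(27, {
    n <- 60
    start <- (0:(n - 1)) * 50000
    annot <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
      start = start, end = start + 2000, strand = "+", exon_count = 1L
    )
    cats <- tibble::tibble(
      gene_id = annot$gene_id,
      category = rep(c("trans_spliced", "other"), each = n / 2)
    )
    n_peaks <- ifelse(cats$category == "other", rpois(n, 6), rpois(n, 2))
    peaks <- dplyr::bind_rows(purrr::map2(
      annot$start, n_peaks,
      function(s, k) {
        if (k == 0) return(NULL)
        tibble::tibble(chrom = "chr1",
                       start = s + seq_len(k) * 100,
                       end = s + seq_len(k) * 100 + 50)
      }
    ))
    res <- regulatory_complexity(peaks, annot, cats)
    med <- tapply(res$counts$n_peaks, res$counts$category, median)
    expect_gt(med[["other"]], med[["trans_spliced"]])
    expect_lt(res$tests$p, 0.01)
  })
})
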