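# Mutual best hits, Oxford grids, Fisher enrichment, linkage-group
# assignment and fusion classification.

test_that("mutual best hits follow the reciprocal-top-score predicate", {
  fwd <- tibble::tibble(
    query_id = c("a1", "a1", "a2"),
    target_id = c("b1", "b2", "b2"),
    score = c(100, 80, 90)
  )
  rev <- tibble::tibble(
    query_id = c("b1", "b2", "b2"),
    target_id = c("a1", "a1", "a2"),
    score = c(95, 60, 70)
  )
  expect_equal(
    mutual_best_hits(fwd, rev),
    tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  )
})

test_that("tied best hits drop the gene", {
  fwd <- tibble::tibble(query_id = c("a1", "a1"),
                        target_id = c("b1", "b2"), score = c(100, 100))
  rev <- tibble::tibble(query_id = c("b1", "b2"),
                        target_id = c("a1", "a1"), score = c(50, 40))
  expect_equal(nrow(mutual_best_hits(fwd, rev)), 0)
})

test_that("empty and malformed similarity tables are handled", {
  empty <- tibble::tibble(query_id = character(), target_id = character(),
                          score = numeric())
  expect_equal(nrow(mutual_best_hits(empty, empty)), 0)
  dup <- tibble::tibble(query_id = c("a", "a"), target_id = c("b", "b"),
                        score = c(1, 2))
  expect_error(mutual_best_hits(dup, empty), "duplicated")
})

test_that("MBH matches a brute-force predicate scan on random score tables", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      genes_a <- sprintf("a%02d", 1:20)
      genes_b <- sprintf("b%02d", 1:20)
      fwd <- tidyr::expand_grid(query_id = genes_a, target_id = genes_b) |>
        dplyr::mutate(score = sample(50, dplyr::n(), replace = TRUE))
      rev <- tidyr::expand_grid(query_id = genes_b, target_id = genes_a) |>
        dplyr::mutate(score = sample(50, dplyr::n(), replace = TRUE))
      expect_equal(mutual_best_hits(fwd, rev), oracle_mbh(fwd, rev))
    }
  })
})

test_that("Oxford grid counts pairs and applies the chromosome filter", {
  annot_a <- fixture_annotation(chroms = c("chr1", "chrX"))
  annot_b <- fixture_annotation(chroms = c("c1", "cX"))
  pairs <- tibble::tibble(
    gene_a = c("chr1_g01", "chr1_g02", "chr1_g03"),
    gene_b = c("cX_g01", "cX_g02", "cX_g03")
  )
  grid <- build_oxford_grid(annot_a, annot_b, pairs, min_genes = 1)
  expect_equal(grid$total, 3)
  expect_equal(unname(grid$counts["chr1", "cX"]), 3)

  # below min_genes the chromosome is dropped entirely
  grid5 <- build_oxford_grid(annot_a, annot_b, pairs, min_genes = 5)
  expect_equal(grid5$total, 0)

  empty <- build_oxford_grid(annot_a, annot_b, pairs[0, ])
  expect_equal(empty$total, 0)
  expect_error(
    build_oxford_grid(annot_a, annot_b,
                      tibble::tibble(gene_a = "nope", gene_b = "cX_g01")),
    "nope"
  )
})

test_that("enrichment p-values are exact one-sided hypergeometric tails", {
  # [30, 5; 5, 30]: q = 30, margins 35/35, N = 70
  p_pkg <- hyper_enrichment_p(30, 35, 35, 70)
  p_oracle <- oracle_hyper_p(30, 35, 70 - 35, 35)
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)

  # zero count with positive margins: P(X >= 0) = 1
  expect_equal(hyper_enrichment_p(0, 10, 10, 30), 1)
})

test_that("zero-margin cells are skipped with p = 1", {
  counts <- matrix(c(5, 0, 0, 0), 2, 2,
                   dimnames = list(chrom_a = c("r1", "r2"),
                                   chrom_b = c("c1", "c2")))
  grid <- karyoburst:::new_oxford_grid(counts)
  enr <- test_chromosome_enrichment(grid)
  empty_rows <- enr[enr$chrom_a == "r2" | enr$chrom_b == "c2", ]
  expect_true(all(empty_rows$p == 1))
})

test_that("diagonal simulations give clean assignment and no fusions", {
  sim <- simulate_ortholog_genomes(
    setNames(rep(30L, 5), c("A1", "B1", "C1", "D", "E")),
    noise = 0, seed = 6
  )
  grid <- build_oxford_grid(sim$genome_a, sim$genome_b, sim$pairs)
  enr <- test_chromosome_enrichment(grid)
  diag_cells <- enr[sub("chrA_", "", enr$chrom_a) ==
                      sub("chrB_", "", enr$chrom_b), ]
  expect_true(all(diag_cells$significant))
  expect_true(all(diag_cells$q < 1e-6))
  off <- enr[sub("chrA_", "", enr$chrom_a) !=
               sub("chrB_", "", enr$chrom_b), ]
  expect_true(all(!off$significant))

  asn <- assign_linkage_groups(enr, sim$ref_labels)
  asn1 <- asn[!is.na(asn$blg), ]
  expect_equal(nrow(asn1), 5) # bijection
  expect_equal(anyDuplicated(asn1$chrom), 0)
  fus <- classify_fusions(asn, sim$genome_b, sim$pairs, sim$genome_a,
                          sim$ref_labels, n_perm = 100, seed = 1)
  expect_equal(nrow(fus), 0)
})

test_that("enrichment output is invariant to gene order and relabeling", {
  sim <- simulate_ortholog_genomes(
    c(K = 25, O2 = 25, R = 25),
    list(list(chrom = "chrB1", blgs = c("K", "O2"), mixed = TRUE)),
    noise = 0.05, seed = 9
  )
  grid1 <- build_oxford_grid(sim$genome_a, sim$genome_b, sim$pairs)
  shuffled_a <- sim$genome_a[sample(nrow(sim$genome_a)), ]
  shuffled_b <- sim$genome_b[sample(nrow(sim$genome_b)), ]
  grid2 <- build_oxford_grid(shuffled_a, shuffled_b,
                             sim$pairs[sample(nrow(sim$pairs)), ])
  e1 <- test_chromosome_enrichment(grid1) |>
    dplyr::arrange(chrom_a, chrom_b)
  e2 <- test_chromosome_enrichment(grid2) |>
    dplyr::arrange(chrom_a, chrom_b)
  expect_equal(e1, e2)

  # renaming chromosomes permutes rows but preserves all statistics
  renamed <- sim$genome_b |>
    dplyr::mutate(chrom = paste0("Z_", chrom))
  grid3 <- build_oxford_grid(sim$genome_a, renamed, sim$pairs)
  e3 <- test_chromosome_enrichment(grid3) |>
    dplyr::mutate(chrom_b = sub("^Z_", "", chrom_b)) |>
    dplyr::arrange(chrom_a, chrom_b)
  expect_equal(e1, e3)
})

test_that("unlabelled reference chromosomes in significant rows warn", {
  sim <- simulate_ortholog_genomes(c(K = 30, R = 30), noise = 0, seed = 2)
  grid <- build_oxford_grid(sim$genome_a, sim$genome_b, sim$pairs)
  enr <- test_chromosome_enrichment(grid)
  labels <- sim$ref_labels[1, ] # drop one label
  expect_warning(asn <- assign_linkage_groups(enr, labels), "unlabelled")
  expect_false("R" %in% asn$blg)
})

test_that("run-count mixing test separates blocky from interleaved layouts", {
  # two contiguous blocks over 200 genes: minimal runs, unmixed
  annot <- tibble::tibble(
    gene_id = sprintf("q%03d", 1:200), chrom = "fused",
    start = (0:199) * 2000, end = (0:199) * 2000 + 1000,
    strand = "+", exon_count = 2L
  )
  ref <- tibble::tibble(
    gene_id = sprintf("r%03d", 1:200),
    chrom = rep(c("refA", "refB"), each = 100),
    start = rep((0:99) * 2000, 2), end = rep((0:99) * 2000 + 1000, 2),
    strand = "+", exon_count = 2L
  )
  pairs_block <- tibble::tibble(gene_a = sprintf("r%03d", 1:200),
                                gene_b = sprintf("q%03d", 1:200))
  ref_labels <- tibble::tibble(chrom = c("refA", "refB"), blg = c("A", "B"))
  asn <- tibble::tibble(chrom = "fused", blg = c("A", "B"),
                        count = 100, q = 1e-10)
  call_block <- classify_fusions(asn, annot, pairs_block, ref, ref_labels,
                                 n_perm = 500, seed = 3)
  expect_equal(call_block$runs_observed, 2)
  expect_false(call_block$mixed)

  # perfectly alternating: maximal runs, mixed
  pairs_alt <- tibble::tibble(
    gene_a = sprintf("r%03d", c(rbind(1:100, 101:200))),
    gene_b = sprintf("q%03d", 1:200)
  )
  call_alt <- classify_fusions(asn, annot, pairs_alt, ref, ref_labels,
                               n_perm = 500, seed = 3)
  expect_equal(call_alt$runs_observed, 200)
  expect_true(call_alt$mixed)
})

test_that("chromosomes with too few labelled genes are indeterminate", {
  annot <- tibble::tibble(
    gene_id = sprintf("q%d", 1:6), chrom = "fused",
    start = (0:5) * 2000, end = (0:5) * 2000 + 1000,
    strand = "+", exon_count = 2L
  )
  ref <- tibble::tibble(
    gene_id = sprintf("r%d", 1:6), chrom = rep(c("refA", "refB"), 3),
    start = (0:5) * 2000, end = (0:5) * 2000 + 1000,
    strand = "+", exon_count = 2L
  )
  asn <- tibble::tibble(chrom = "fused", blg = c("A", "B"),
                        count = 3, q = 0.01)
  calls <- classify_fusions(
    asn, annot, tibble::tibble(gene_a = sprintf("r%d", 1:6),
                               gene_b = sprintf("q%d", 1:6)),
    ref, tibble::tibble(chrom = c("refA", "refB"), blg = c("A", "B")),
    n_perm = 50, seed = 1
  )
  expect_true(is.na(calls$mixed))
})

test_that("BH control holds on null ortholog placements", {
  # random placement of orthologs over two 8-chromosome genomes: the mean
  # fraction of significant cells at q < 0.05 stays below 0.05
  frac <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      chroms <- sprintf("c%d", 1:8)
      annot_a <- tibble::tibble(
        gene_id = sprintf("a%03d", 1:200),
        chrom = sample(chroms, 200, replace = TRUE),
        start = 0, end = 100, strand = "+"
      )
      annot_b <- tibble::tibble(
        gene_id = sprintf("b%03d", 1:200),
        chrom = sample(chroms, 200, replace = TRUE),
        start = 0, end = 100, strand = "+"
      )
      annot_a$start <- seq_len(200) * 1000; annot_a$end <- annot_a$start + 100
      annot_b$start <- seq_len(200) * 1000; annot_b$end <- annot_b$start + 100
      pairs <- tibble::tibble(gene_a = annot_a$gene_id,
                              gene_b = annot_b$gene_id)
      grid <- build_oxford_grid(annot_a, annot_b, pairs, min_genes = 1)
      enr <- test_chromosome_enrichment(grid)
      mean(enr$significant)
    })
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})
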