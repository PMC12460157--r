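# Two-genome ortholog simulator with planted linkage-group fusions.

#' Simulate a pair of genomes with planted linkage-group fusions
#'
#' Generates two annotated genomes sharing a 1:1 ortholog set. Genome A keeps
#' one chromosome per ancestral linkage group (the reference side, as in an
#' amphioxus-style comparison); genome B realises a fusion plan in which some
#' chromosomes carry the genes of several linkage groups, either interleaved in
#' random order (fusion-with-mixing) or as contiguous blocks. A configurable
#' fraction of genome-B orthologs is then relocated uniformly at random to
#' emulate background rearrangement noise.
#'
#' @param blg_plan Named integer vector: linkage-group label -> gene count
#'   (each at least 10).
#' @param fusion_plan List of fusion descriptors, each a list with elements
#'   `chrom` (target genome-B chromosome label), `blgs` (character vector of
#'   two or more linkage-group labels) and `mixed` (logical).
#' @param noise Fraction of genome-B genes relocated uniformly at random.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param gene_meanlog,gap_meanlog,sdlog Log-normal layout parameters for gene
#'   lengths and intergenic gaps (defaults ~2 kb genes, ~1 kb gaps).
#' @return A list with elements `genome_a`, `genome_b` (gene tibbles),
#'   `chrom_sizes_a`, `chrom_sizes_b`, `pairs` (ortholog pair tibble with
#'   columns `gene_a`, `gene_b`), `ref_labels` (genome-A chromosome -> linkage
#'   group label) and `truth` (a [sim_truth] recording each planted fusion).
#' @examples
#' sim <- simulate_ortholog_genomes(
#'   blg_plan = c(K = 20, O2 = 20, R = 20),
#'   fusion_plan = list(list(chrom = "chrB1", blgs = c("K", "O2"), mixed = TRUE)),
#'   noise = 0, seed = 1
#' )
#' table(sim$genome_b$chrom)
#' @export
simulate_ortholog_genomes <- function(blg_plan, fusion_plan = list(),
                                      noise = 0, seed = 1L,
                                      gene_meanlog = log(2000),
                                      gap_meanlog = log(1000), sdlog = 0.5) {
  stopifnot(is.numeric(blg_plan), length(blg_plan) >= 1, noise >= 0, noise <= 1)
  blgs <- names(blg_plan)
  if (is.null(blgs) || any(blgs == "")) stop("blg_plan must be a named vector")
  if (any(blg_plan < 10)) stop("each linkage group needs at least 10 genes")
  fused_blgs <- unlist(lapply(fusion_plan, `[[`, "blgs"))
  missing <- setdiff(fused_blgs, blgs)
  if (length(missing) > 0) {
    stop("fusion_plan references linkage groups absent from blg_plan: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(fused_blgs) > 0) {
    stop("each linkage group may appear in at most one fusion")
  }

  withr::with_seed(substream_seed(seed, "ortholog_genomes"), {
    gene_ids <- unlist(lapply(blgs, function(b) {
      sprintf("g_%s_%03d", b, seq_len(blg_plan[[b]]))
    }))
    gene_blg <- rep(blgs, times = blg_plan)

    # Genome A: one chromosome per linkage group, genes in id order.
    chrom_a <- paste0("chrA_", gene_blg)
    a_layout <- dplyr::bind_rows(lapply(split(seq_along(gene_ids), chrom_a), function(idx) {
      layout_genes(length(idx), gene_meanlog, gap_meanlog, sdlog) |>
        dplyr::mutate(gene_id = paste0(gene_ids[idx], "_A"), .before = 1)
    }))
    genome_a <- tibble::tibble(
      gene_id = a_layout$gene_id,
      chrom = sub("^g_(.*)_\\d+_A$", "chrA_\\1", a_layout$gene_id),
      start = a_layout$start, end = a_layout$end,
      strand = sample(c("+", "-"), nrow(a_layout), replace = TRUE),
      exon_count = rpois(nrow(a_layout), 4) + 1L
    ) |> dplyr::arrange(.data$chrom, .data$start)

    # Genome B: realise the fusion plan, then relocate a noise fraction.
    b_chrom_of <- setNames(paste0("chrB_", blgs), blgs)
    for (f in fusion_plan) b_chrom_of[f$blgs] <- f$chrom
    order_within <- lapply(split(gene_ids, b_chrom_of[gene_blg]), function(ids) ids)
    for (f in fusion_plan) {
      ids <- order_within[[f$chrom]]
      if (isTRUE(f$mixed)) {
        order_within[[f$chrom]] <- sample(ids)
      } # unmixed: keep contiguous blocks in linkage-group order
    }

    b_assign <- tibble::tibble(
      gene_id = unlist(order_within, use.names = FALSE),
      chrom = rep(names(order_within), lengths(order_within))
    )
    # Relocation noise: chosen genes move to a uniform chromosome and a
    # uniform slot within it; unmoved genes keep their relative order.
    n_move <- rbinom(1, nrow(b_assign), noise)
    key <- as.numeric(seq_len(nrow(b_assign)))
    if (n_move > 0) {
      movers <- sample(nrow(b_assign), n_move)
      chroms_b <- unique(b_assign$chrom)
      b_assign$chrom[movers] <- sample(chroms_b, n_move, replace = TRUE)
      key[movers] <- runif(n_move, 0, nrow(b_assign))
    }
    b_assign <- b_assign[order(b_assign$chrom, key), ]

    b_layout <- dplyr::bind_rows(lapply(split(b_assign, b_assign$chrom), function(df) {
      layout_genes(nrow(df), gene_meanlog, gap_meanlog, sdlog) |>
        dplyr::mutate(gene_id = paste0(df$gene_id, "_B"), chrom = df$chrom,
                      .before = 1)
    }))
    genome_b <- tibble::tibble(
      gene_id = b_layout$gene_id, chrom = b_layout$chrom,
      start = b_layout$start, end = b_layout$end,
      strand = sample(c("+", "-"), nrow(b_layout), replace = TRUE),
      exon_count = rpois(nrow(b_layout), 4) + 1L
    ) |> dplyr::arrange(.data$chrom, .data$start)

    sizes <- function(genome) {
      genome |>
        dplyr::group_by(chrom = .data$chrom) |>
        dplyr::summarise(length = max(.data$end) + 1000, .groups = "drop")
    }

    pairs <- tibble::tibble(gene_a = paste0(gene_ids, "_A"),
                            gene_b = paste0(gene_ids, "_B"))
    ref_labels <- tibble::tibble(chrom = paste0("chrA_", blgs), blg = blgs)

    events <- dplyr::bind_rows(lapply(fusion_plan, function(f) {
      tibble::tibble(kind = "fusion", chrom = f$chrom,
                     blgs = paste(sort(f$blgs), collapse = "+"),
                     mixed = isTRUE(f$mixed))
    }))
    if (nrow(events) == 0) {
      events <- tibble::tibble(kind = character(), chrom = character(),
                               blgs = character(), mixed = logical())
    }

    list(
      genome_a = genome_a, genome_b = genome_b,
      chrom_sizes_a = sizes(genome_a), chrom_sizes_b = sizes(genome_b),
      pairs = pairs, ref_labels = ref_labels,
      truth = sim_truth(
        "ortholog_genomes",
        list(blg_plan = blg_plan, fusion_plan = fusion_plan, noise = noise,
             seed = seed),
        events
      )
    )
  })
}
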