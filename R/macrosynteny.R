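# Macrosynteny: mutual-best-hit orthology, chromosome-pair enrichment,
# linkage-group assignment, and fusion/mixing classification.

#' Infer 1:1 orthologs by mutual best hit
#'
#' A pair `(a, b)` is retained iff `b` is `a`'s unique top score in the
#' forward table and `a` is `b`'s unique top score in the reverse table.
#' Genes whose best hit is tied are dropped (conservative).
#'
#' @param forward Similarity tibble A->B with columns `query_id`,
#'   `target_id`, `score` (non-negative, at most one row per pair).
#' @param reverse Similarity tibble B->A, same columns.
#' @return Tibble of ortholog pairs with columns `gene_a`, `gene_b`.
#' @examples
#' fwd <- tibble::tibble(query_id = c("a1", "a1"), target_id = c("b1", "b2"),
#'                       score = c(100, 80))
#' rev <- tibble::tibble(query_id = c("b1", "b2"), target_id = c("a1", "a1"),
#'                       score = c(95, 60))
#' mutual_best_hits(fwd, rev)
#' @export
mutual_best_hits <- function(forward, reverse) {
  for (tab in list(forward, reverse)) {
    if (nrow(tab) > 0 && anyDuplicated(tab[c("query_id", "target_id")]) > 0) {
      stop("duplicated (query, target) rows in similarity table")
    }
    if (any(!is.finite(tab$score))) stop("similarity scores must be finite")
  }
  if (nrow(forward) == 0 || nrow(reverse) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  best_fwd <- unique_best(forward)
  best_rev <- unique_best(reverse)
  dplyr::inner_join(
    best_fwd, best_rev,
    by = c(query_id = "target_id", target_id = "query_id")
  ) |>
    dplyr::transmute(gene_a = .data$query_id, gene_b = .data$target_id) |>
    dplyr::arrange(.data$gene_a)
}

# Rows holding each query's unique top score; tied queries dropped.
unique_best <- function(tab) {
  tab |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("query_id", "target_id")
}

#' Build an Oxford grid of shared-ortholog counts
#'
#' Cross-tabulates ortholog pairs by the chromosomes of their two members.
#' Chromosomes carrying fewer than `min_genes` orthologs in total are dropped
#' from the grid (scaffold-noise filter).
#'
#' @param annot_a,annot_b Gene tibbles for the two genomes.
#' @param pairs Ortholog pair tibble (`gene_a`, `gene_b`).
#' @param min_genes Minimum orthologs per retained chromosome.
#' @return An `oxford_grid` object: list with `counts` (chromA x chromB
#'   matrix), `row_margin`, `col_margin`, `total`.
#' @export
build_oxford_grid <- function(annot_a, annot_b, pairs, min_genes = 5) {
  if (nrow(pairs) == 0) {
    return(new_oxford_grid(matrix(0, 0, 0)))
  }
  chrom_a <- setNames(annot_a$chrom, annot_a$gene_id)[pairs$gene_a]
  chrom_b <- setNames(annot_b$chrom, annot_b$gene_id)[pairs$gene_b]
  if (anyNA(chrom_a)) {
    stop("pair member absent from annotation A: ",
         pairs$gene_a[which(is.na(chrom_a))[1]])
  }
  if (anyNA(chrom_b)) {
    stop("pair member absent from annotation B: ",
         pairs$gene_b[which(is.na(chrom_b))[1]])
  }
  counts <- unclass(table(chrom_a, chrom_b))
  keep_a <- rowSums(counts) >= min_genes
  keep_b <- colSums(counts) >= min_genes
  new_oxford_grid(counts[keep_a, keep_b, drop = FALSE])
}

new_oxford_grid <- function(counts) {
  structure(
    list(counts = counts, row_margin = rowSums(counts),
         col_margin = colSums(counts), total = sum(counts)),
    class = "oxford_grid"
  )
}

#' @export
print.oxford_grid <- function(x, ...) {
  cat("<oxford_grid>", nrow(x$counts), "x", ncol(x$counts),
      "chromosomes,", x$total, "ortholog pairs\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.oxford_grid <- function(x, ...) {
  if (x$total == 0 && length(x$counts) == 0) {
    return(tibble::tibble(chrom_a = character(), chrom_b = character(),
                          n = numeric()))
  }
  as.data.frame.table(x$counts, responseName = "n", stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::rename(chrom_a = "chrom_a", chrom_b = "chrom_b")
}

#' One-sided hypergeometric enrichment p-value
#'
#' Exact upper-tail probability `P(X >= q)` for the count in a 2x2 table
#' `[q, rowsum - q; colsum - q, N - rowsum - colsum + q]`, identical to a
#' one-sided (greater) Fisher exact test. Vectorised.
#'
#' @param q Observed cell count.
#' @param rowsum,colsum Margins of the cell.
#' @param total Grand total N.
#' @return p-values in `(0, 1]`.
#' @export
hyper_enrichment_p <- function(q, rowsum, colsum, total) {
  phyper(q - 1, rowsum, total - rowsum, colsum, lower.tail = FALSE)
}

#' Test chromosome-pair ortholog enrichment on an Oxford grid
#'
#' For each grid cell, computes the one-sided (greater) Fisher exact p-value
#' for enrichment of shared orthologs given the chromosome margins, applies
#' Benjamini-Hochberg correction across all cells, and flags significant and
#' reciprocal cells. Cells with a zero margin are skipped with `p = 1`.
#' Reciprocal means significant and additionally the lowest-q cell (ties
#' broken by higher odds ratio) in its row or in its column, so a chromosome
#' may legitimately host several significant partners (fused linkage groups)
#' while dominated one-off cells are excluded.
#'
#' @param grid An `oxford_grid`.
#' @param alpha BH significance level.
#' @return Enrichment tibble: `chrom_a`, `chrom_b`, `count`, `odds_ratio`,
#'   `p`, `q`, `significant`, `reciprocal`.
#' @export
test_chromosome_enrichment <- function(grid, alpha = 0.05) {
  stopifnot(inherits(grid, "oxford_grid"))
  if (grid$total == 0) stop("grid total must be positive")
  tab <- tidy(grid)
  N <- grid$total
  tab <- tab |>
    dplyr::mutate(
      rowsum = grid$row_margin[.data$chrom_a],
      colsum = grid$col_margin[.data$chrom_b],
      b = .data$rowsum - .data$n,
      c = .data$colsum - .data$n,
      d = N - .data$rowsum - .data$colsum + .data$n,
      odds_ratio = (.data$n * .data$d) / (.data$b * .data$c),
      p = dplyr::if_else(
        .data$rowsum == 0 | .data$colsum == 0,
        1,
        hyper_enrichment_p(.data$n, .data$rowsum, .data$colsum, N)
      )
    )
  tab$q <- p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < alpha
  best <- function(df) {
    sig <- df$significant
    rank <- order(df$q, -df$odds_ratio)
    seq_len(nrow(df)) == rank[1] & sig
  }
  tab <- tab |>
    dplyr::group_by(.data$chrom_a) |>
    dplyr::mutate(best_in_row = best(dplyr::pick(dplyr::everything()))) |>
    dplyr::group_by(.data$chrom_b) |>
    dplyr::mutate(best_in_col = best(dplyr::pick(dplyr::everything()))) |>
    dplyr::ungroup() |>
    dplyr::mutate(reciprocal = .data$significant &
                    (.data$best_in_row | .data$best_in_col))
  tab |>
    dplyr::transmute(.data$chrom_a, .data$chrom_b, count = .data$n,
                     odds_ratio = .data$odds_ratio, p = .data$p, q = .data$q,
                     significant = .data$significant,
                     reciprocal = .data$reciprocal)
}

#' Assign bilaterian linkage groups to query chromosomes
#'
#' Transfers linkage-group labels from a labelled reference genome: a query
#' chromosome acquires label L for every significant reciprocal enrichment
#' row against a reference chromosome labelled L. Reference chromosomes
#' missing from the label map trigger a warning and their rows are ignored.
#'
#' @param enrichment Enrichment tibble from [test_chromosome_enrichment];
#'   `chrom_a` is the reference side, `chrom_b` the query side.
#' @param ref_labels Tibble with columns `chrom` (reference chromosome) and
#'   `blg` (linkage-group label).
#' @return Assignment tibble: one row per (query chromosome, label) with the
#'   supporting enrichment row columns; query chromosomes with no label are
#'   present with `blg = NA` so undetected groups are reportable.
#' @export
assign_linkage_groups <- function(enrichment, ref_labels) {
  lab <- setNames(ref_labels$blg, ref_labels$chrom)
  hits <- dplyr::filter(enrichment, .data$reciprocal)
  unlabelled <- setdiff(unique(hits$chrom_a), names(lab))
  if (length(unlabelled) > 0) {
    warning("ignoring significant rows for unlabelled reference chromosomes: ",
            paste(unlabelled, collapse = ", "))
    hits <- dplyr::filter(hits, .data$chrom_a %in% names(lab))
  }
  assigned <- hits |>
    dplyr::transmute(chrom = .data$chrom_b,
                     blg = unname(lab[.data$chrom_a]),
                     count = .data$count, q = .data$q)
  empty <- setdiff(unique(enrichment$chrom_b), assigned$chrom)
  dplyr::bind_rows(
    assigned,
    tibble::tibble(chrom = empty, blg = NA_character_,
                   count = NA_real_, q = NA_real_)
  ) |>
    dplyr::arrange(.data$chrom, .data$blg)
}

#' Classify fusions as with or without mixing
#'
#' For every query chromosome carrying two or more assigned linkage groups,
#' orders its ortholog-bearing genes by start coordinate, labels each by the
#' linkage group of its reference partner, and counts label runs. A
#' permutation null shuffles the labels `n_perm` times; the chromosome is
#' called mixed unless the observed run count falls in the lower `alpha`
#' tail of the null (significantly blockier than random implies
#' fusion-without-mixing). Chromosomes with fewer than 10 labelled genes are
#' reported with `mixed = NA` (indeterminate).
#'
#' @param assignment Assignment tibble from [assign_linkage_groups].
#' @param annot_q Query genome gene tibble.
#' @param pairs Ortholog pair tibble (`gene_a` reference, `gene_b` query).
#' @param annot_ref Reference genome gene tibble.
#' @param ref_labels Reference chromosome -> linkage-group label tibble.
#' @param n_perm Number of label permutations.
#' @param alpha Lower-tail level below which a chromosome is called unmixed.
#' @param seed Integer seed for the permutation null.
#' @return Tibble of fusion calls: `chrom`, `component_blgs`, `n_genes`,
#'   `runs_observed`, `runs_null_mean`, `mixing_p`, `mixed`.
#' @export
classify_fusions <- function(assignment, annot_q, pairs, annot_ref,
                             ref_labels, n_perm = 1000, alpha = 0.05,
                             seed = 1L) {
  multi <- assignment |>
    dplyr::filter(!is.na(.data$blg)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(blgs = list(sort(unique(.data$blg))), .groups = "drop")
  if (nrow(multi) == 0) {
    return(tibble::tibble(chrom = character(), component_blgs = character(),
                          n_genes = integer(), runs_observed = integer(),
                          runs_null_mean = numeric(), mixing_p = numeric(),
                          mixed = logical()))
  }
  ref_chrom <- setNames(annot_ref$chrom, annot_ref$gene_id)
  blg_of_ref <- setNames(ref_labels$blg, ref_labels$chrom)
  gene_blg <- setNames(blg_of_ref[ref_chrom[pairs$gene_a]], pairs$gene_b)

  q_genes <- annot_q |>
    dplyr::mutate(blg = gene_blg[.data$gene_id]) |>
    dplyr::filter(!is.na(.data$blg)) |>
    dplyr::arrange(.data$chrom, .data$start)

  withr::with_seed(substream_seed(seed, "fusion_mixing"), {
    purrr::pmap_dfr(multi, function(chrom, blgs) {
      labels <- q_genes$blg[q_genes$chrom == chrom & q_genes$blg %in% blgs]
      obs <- length(rle(labels)$lengths)
      if (length(labels) < 10) {
        return(tibble::tibble(
          chrom = chrom, component_blgs = paste(blgs, collapse = "+"),
          n_genes = length(labels), runs_observed = obs,
          runs_null_mean = NA_real_, mixing_p = NA_real_, mixed = NA
        ))
      }
      null_runs <- vapply(seq_len(n_perm), function(i) {
        length(rle(sample(labels))$lengths)
      }, numeric(1))
      p_low <- (1 + sum(null_runs <= obs)) / (n_perm + 1)
      tibble::tibble(
        chrom = chrom, component_blgs = paste(blgs, collapse = "+"),
        n_genes = length(labels), runs_observed = obs,
        runs_null_mean = mean(null_runs), mixing_p = p_low,
        mixed = p_low > alpha
      )
    })
  })
}
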