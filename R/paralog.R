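# Duplication-burst dating: paralogue pair selection, FDTv divergence,
# chromosome-pair placement, and the intron-count retrotransposition test.

#' Select one pair per gene within each paralogue family
#'
#' Greedy maximum-score matching: within each family, repeatedly take the
#' highest-scoring pair of unused genes and mark both used, so every gene is
#' counted in at most one pair (avoiding excess weight for large families).
#' An exact maximum-weight matching is available for small families via
#' `exact = TRUE`.
#'
#' @param scores Within-family pair scores: tibble `family_id`, `gene1`,
#'   `gene2`, `score`.
#' @param members Optional family membership tibble (`family_id`, `gene_id`)
#'   used to reject singleton families.
#' @param exact Use exhaustive maximum-weight matching for families with at
#'   most `exact_limit` members.
#' @param exact_limit Family-size cap for the exact search.
#' @return Tibble of selected pairs: `family_id`, `gene1`, `gene2`, `score`.
#' @export
select_paralog_pairs <- function(scores, members = NULL, exact = FALSE,
                                 exact_limit = 12) {
  if (!is.null(members)) {
    sizes <- table(members$family_id)
    if (any(sizes < 2)) {
      stop("families of size 1 cannot form pairs: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    }
  }
  if (nrow(scores) == 0) stop("no within-family pairs supplied")
  scores |>
    dplyr::group_by(.data$family_id) |>
    dplyr::group_modify(function(df, key) {
      n_members <- length(unique(c(df$gene1, df$gene2)))
      if (exact && n_members <= exact_limit) {
        exact_matching(df)
      } else {
        greedy_matching(df)
      }
    }) |>
    dplyr::ungroup()
}

greedy_matching <- function(df) {
  df <- df[order(-df$score, df$gene1, df$gene2), ]
  used <- character(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!(df$gene1[i] %in% used) && !(df$gene2[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, df$gene1[i], df$gene2[i])
    }
  }
  df[keep, c("gene1", "gene2", "score")]
}

# Exhaustive maximum-weight matching by branch-free recursion over the pair
# list; practical for families of about a dozen genes.
exact_matching <- function(df) {
  best_score <- -Inf
  best_sel <- integer(0)
  pairs1 <- df$gene1; pairs2 <- df$gene2; sc <- df$score
  recurse <- function(i, used, sel, total) {
    if (i > nrow(df)) {
      if (total > best_score) {
        best_score <<- total; best_sel <<- sel
      }
      return(invisible())
    }
    # upper bound: all remaining scores
    if (total + sum(sc[i:nrow(df)][sc[i:nrow(df)] > 0]) <= best_score) {
      return(invisible())
    }
    if (!(pairs1[i] %in% used) && !(pairs2[i] %in% used)) {
      recurse(i + 1, c(used, pairs1[i], pairs2[i]), c(sel, i), total + sc[i])
    }
    recurse(i + 1, used, sel, total)
  }
  recurse(1L, character(0), integer(0), 0)
  df[best_sel, c("gene1", "gene2", "score")]
}

#' Count transversions at fourfold-degenerate sites
#'
#' An aligned codon column is a fourfold-degenerate (FD) site iff both codons
#' are ungapped, encode the same amino acid, share identical first two bases,
#' and that two-base prefix belongs to a fourfold box (third base free). A
#' transversion is counted when the third bases differ across the
#' purine/pyrimidine boundary. FDTv = transversions / FD sites.
#'
#' @param alignment Codon alignment tibble with character columns `codon1`,
#'   `codon2` (3-mers over `ACGT-`).
#' @return One-row tibble: `fd_sites`, `transversions`, `fdtv` (NA when no
#'   FD site), `defined`.
#' @examples
#' aln <- tibble::tibble(codon1 = c("GGA", "CCT", "AAA"),
#'                       codon2 = c("GGT", "CCG", "AAA"))
#' compute_fdtv(aln)
#' @export
compute_fdtv <- function(alignment) {
  if (nrow(alignment) == 0) stop("empty codon alignment")
  c1 <- toupper(alignment$codon1)
  c2 <- toupper(alignment$codon2)
  ungapped <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  pre1 <- substr(c1, 1, 2); pre2 <- substr(c2, 1, 2)
  fd <- ungapped & pre1 == pre2 & pre1 %in% FOURFOLD_PREFIXES &
    translate_codon(c1) == translate_codon(c2)
  fd[is.na(fd)] <- FALSE
  t1 <- substr(c1[fd], 3, 3); t2 <- substr(c2[fd], 3, 3)
  tv <- sum(t1 != t2 & xor(t1 %in% PURINES, t2 %in% PURINES))
  tibble::tibble(
    fd_sites = sum(fd), transversions = tv,
    fdtv = if (sum(fd) > 0) tv / sum(fd) else NA_real_,
    defined = sum(fd) > 0
  )
}

#' Build a codon alignment from two equal-length coding sequences
#'
#' @param cds1,cds2 In-frame coding sequences (character scalars, lengths a
#'   multiple of 3; gaps `-` allowed in codon units).
#' @return Codon alignment tibble with columns `codon1`, `codon2`.
#' @export
codon_alignment <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2) || nchar(cds1) %% 3 != 0) {
    stop("coding sequences must be aligned and a multiple of 3 long")
  }
  starts <- seq(1, nchar(cds1), by = 3)
  tibble::tibble(codon1 = substring(cds1, starts, starts + 2),
                 codon2 = substring(cds2, starts, starts + 2))
}

#' FDTv per selected paralogue pair
#'
#' Convenience wrapper: computes [compute_fdtv] for every selected pair from
#' a named vector of coding sequences.
#'
#' @param pairs Pair tibble (`gene1`, `gene2`).
#' @param cds Named character vector of aligned coding sequences.
#' @return `pairs` with `fd_sites`, `transversions`, `fdtv`, `defined`.
#' @export
pairwise_fdtv <- function(pairs, cds) {
  res <- purrr::map2_dfr(pairs$gene1, pairs$gene2, function(g1, g2) {
    compute_fdtv(codon_alignment(cds[[g1]], cds[[g2]]))
  })
  dplyr::bind_cols(pairs, res)
}

#' Kernel-density FDTv profile across copy-number strata
#'
#' Fits a Gaussian kernel density per stratum, reports modes (local maxima
#' above 10% of the global maximum), and states whether all strata share a
#' mode within tolerance -- a shared single burst places one peak at the same
#' divergence in every stratum regardless of copy number.
#'
#' @param fdtv_tbl Tibble with a numeric `fdtv` column.
#' @param strata Optional character/integer vector (one per row) assigning a
#'   copy-number stratum; a single stratum is assumed when `NULL`.
#' @param min_stratum Minimum defined FDTv values per retained stratum.
#' @param mode_floor Fraction of the global density maximum below which local
#'   maxima are ignored.
#' @param tolerance Maximal spread of per-stratum primary modes still called
#'   a shared mode.
#' @param bw Kernel bandwidth passed to [stats::density] (default "nrd0").
#' @return An `fdtv_profile` object: list with `strata` (tibble: `stratum`,
#'   `n`, `modes` list-col, `primary_mode`), `shared_mode` (logical),
#'   `densities` (long tibble for plotting).
#' @export
fdtv_profile <- function(fdtv_tbl, strata = NULL, min_stratum = 20,
                         mode_floor = 0.1, tolerance = 0.05, bw = "nrd0") {
  x <- fdtv_tbl$fdtv
  strata <- strata %||% rep("all", length(x))
  keep <- !is.na(x)
  x <- x[keep]; strata <- as.character(strata)[keep]
  counts <- table(strata)
  small <- names(counts)[counts < min_stratum]
  if (length(small) > 0) {
    warning("excluding strata below ", min_stratum, " pairs: ",
            paste(small, collapse = ", "))
  }
  use <- !(strata %in% small)
  x <- x[use]; strata <- strata[use]
  if (length(x) == 0) stop("no stratum reaches the minimum size")

  dens <- lapply(split(x, strata), function(v) {
    if (length(unique(v)) == 1) {
      # point mass: degenerate density, single mode at the value
      list(x = unique(v), y = Inf, point_mass = TRUE)
    } else {
      d <- density(v, bw = bw)
      list(x = d$x, y = d$y, point_mass = FALSE)
    }
  })
  find_modes <- function(d) {
    if (d$point_mass) return(d$x)
    y <- d$y
    locmax <- which(diff(sign(diff(y))) == -2) + 1
    if (y[1] > y[2]) locmax <- c(1, locmax)
    n <- length(y)
    if (y[n] > y[n - 1]) locmax <- c(locmax, n)
    locmax <- locmax[y[locmax] > mode_floor * max(y)]
    d$x[locmax]
  }
  strata_tbl <- tibble::tibble(
    stratum = names(dens),
    n = as.integer(counts[names(dens)]),
    modes = unname(lapply(dens, find_modes))
  )
  strata_tbl$primary_mode <- vapply(seq_along(dens), function(i) {
    m <- strata_tbl$modes[[i]]
    d <- dens[[i]]
    if (d$point_mass) return(m[1])
    m[which.max(stats::approx(d$x, d$y, xout = m)$y)]
  }, numeric(1))
  shared <- diff(range(strata_tbl$primary_mode)) <= tolerance

  densities <- dplyr::bind_rows(lapply(names(dens), function(s) {
    d <- dens[[s]]
    if (d$point_mass) return(NULL)
    tibble::tibble(stratum = s, fdtv = d$x, density = d$y)
  }))
  structure(
    list(strata = strata_tbl, shared_mode = shared, densities = densities),
    class = "fdtv_profile"
  )
}

#' @export
print.fdtv_profile <- function(x, ...) {
  cat("<fdtv_profile>", nrow(x$strata), "strata; shared mode:",
      x$shared_mode, "\n")
  print(x$strata[c("stratum", "n", "primary_mode")])
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fdtv_profile <- function(x, ...) {
  x$strata |>
    dplyr::mutate(n_modes = lengths(.data$modes)) |>
    dplyr::select("stratum", "n", "n_modes", "primary_mode")
}

#' @exportS3Method generics::glance
glance.fdtv_profile <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x$strata),
    total_modes = sum(lengths(x$strata$modes)),
    shared_mode = x$shared_mode
  )
}

#' Chromosome-pair placement of paralogue pairs
#'
#' Cross-tabulates pairs by the chromosomes of their two members (the matrix
#' is intentionally asymmetric: each pair is one observation placed at
#' (chromosome of gene1, chromosome of gene2)). The diagonal holds
#' intra-chromosomal pairs; off-diagonal cells are tested for mutual
#' enrichment with the same one-sided Fisher machinery as the macrosynteny
#' stage and BH-corrected. Intra-chromosomal separations (midpoint to
#' midpoint) are returned on the log10 bp scale. Under a whole-genome
#' duplication, homeologous chromosome pairs are mutually enriched and the
#' intra-chromosomal fraction is near zero; under a tandem burst the diagonal
#' dominates and no off-diagonal cell is enriched.
#'
#' @param pairs Pair tibble (`gene1`, `gene2`).
#' @param annot Gene tibble.
#' @param alpha BH level for off-diagonal enrichment.
#' @return List: `matrix` (chrom x chrom count matrix), `intra_fraction`,
#'   `enrichment` (off-diagonal cell tests), `wgd_enriched_pairs` (tibble of
#'   significant chromosome pairs), `separation_log10` (numeric vector).
#' @export
pair_chromosome_analysis <- function(pairs, annot, alpha = 0.05) {
  if (nrow(pairs) == 0) stop("no paralogue pairs supplied")
  chrom_of <- setNames(annot$chrom, annot$gene_id)
  mid_of <- setNames((annot$start + annot$end) / 2, annot$gene_id)
  c1 <- chrom_of[pairs$gene1]; c2 <- chrom_of[pairs$gene2]
  if (anyNA(c1) || anyNA(c2)) stop("pair member absent from annotation")
  chroms <- sort(unique(annot$chrom))
  counts <- unclass(table(factor(c1, chroms), factor(c2, chroms)))
  names(dimnames(counts)) <- c("chrom_a", "chrom_b")
  intra <- c1 == c2
  sep <- abs(mid_of[pairs$gene1] - mid_of[pairs$gene2])[intra]
  sep <- sep[sep > 0]

  grid <- new_oxford_grid(counts)
  enr <- test_chromosome_enrichment(grid, alpha = alpha) |>
    dplyr::filter(.data$chrom_a != .data$chrom_b)
  # re-correct across off-diagonal cells only
  enr$q <- p.adjust(enr$p, method = "BH")
  enr$significant <- enr$q < alpha
  wgd_pairs <- enr |>
    dplyr::filter(.data$significant) |>
    dplyr::transmute(
      .lo = pmin(.data$chrom_a, .data$chrom_b),
      .hi = pmax(.data$chrom_a, .data$chrom_b),
      q = .data$q
    ) |>
    dplyr::rename(chrom_a = ".lo", chrom_b = ".hi") |>
    dplyr::distinct(.data$chrom_a, .data$chrom_b, .keep_all = TRUE)

  list(
    matrix = counts,
    intra_fraction = mean(intra),
    enrichment = dplyr::select(enr, -"reciprocal"),
    wgd_enriched_pairs = wgd_pairs,
    separation_log10 = unname(log10(sep))
  )
}

#' Decision rule for whole-genome versus tandem duplication
#'
#' A burst is called a whole-genome duplication iff at least one chromosome
#' pair is mutually enriched in paralogue pairs and the intra-chromosomal
#' fraction is below `max_intra`; otherwise tandem.
#'
#' @param analysis Result of [pair_chromosome_analysis].
#' @param max_intra Intra-chromosomal fraction threshold.
#' @return `"wgd"` or `"tandem"`.
#' @export
classify_duplication_mode <- function(analysis, max_intra = 0.1) {
  if (nrow(analysis$wgd_enriched_pairs) > 0 &&
      analysis$intra_fraction < max_intra) "wgd" else "tandem"
}

#' Compare intron counts between duplicated and other genes
#'
#' Intron count is `exon_count - 1`. A burst of retrotransposition leaves
#' duplicated genes intronless; a tandem burst copies introns along. Groups
#' are compared with a two-sided Mann-Whitney test.
#'
#' @param duplicated_gene_ids Character vector of duplicated gene ids.
#' @param annot Gene tibble carrying `exon_count`.
#' @return One-row tibble: `median_dup`, `median_other`, `p`.
#' @export
compare_intron_counts <- function(duplicated_gene_ids, annot) {
  if (!"exon_count" %in% names(annot) || anyNA(annot$exon_count)) {
    stop("annotation must carry exon_count for every gene")
  }
  dup <- annot$gene_id %in% duplicated_gene_ids
  if (!any(dup) || all(dup)) stop("both gene groups must be non-empty")
  introns <- annot$exon_count - 1
  test <- suppressWarnings(wilcox.test(introns[dup], introns[!dup],
                                       alternative = "two.sided"))
  tibble::tibble(
    median_dup = median(introns[dup]),
    median_other = median(introns[!dup]),
    p = test$p.value
  )
}
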