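# Paralogue-family burst simulator: WGD, tandem or retrotransposition modes
# with controlled divergence at fourfold-degenerate third positions.

#' Simulate a burst of gene duplication
#'
#' Plants paralogue families under one of three duplication models and evolves
#' third positions of fourfold-degenerate codons so that every within-family
#' pair diverges at a controlled transversion rate:
#'
#' * `"wgd"`: chromosomes come in homeologous pairs (1-2, 3-4, ...) and every
#'   gene's duplicate sits on the partner chromosome, the signature a
#'   whole-genome duplication leaves on a pair-placement matrix.
#' * `"tandem"`: duplicates stay on the same chromosome at log-normal
#'   separations drawn from a two-component mixture (~10 kb and ~10 Mb scales).
#' * `"retro"`: duplicates are intronless (single-exon) copies inserted at
#'   random chromosomes, the retrotransposition signature.
#'
#' Divergence model: each copy's fourfold third base flips purine/pyrimidine
#' class with probability `c` chosen so that the between-copy transversion
#' rate is exactly `burst_tv_rate` (`2c(1-c) = rate`); transitions are added
#' independently at rate `2c` and never alter the transversion count. The
#' attainable pairwise rate is therefore below 0.5.
#'
#' @param mode One of `"wgd"`, `"tandem"`, `"retro"`.
#' @param n_families Number of paralogue families.
#' @param burst_tv_rate Planted expected transversions per fourfold site,
#'   in `[0, 0.5)`.
#' @param chrom_count Number of chromosomes (even for `"wgd"`).
#' @param seed Integer seed.
#' @param copy_number Copies per family; scalar or vector recycled over
#'   families (>= 2).
#' @param n_codons Codons per coding sequence.
#' @param n_background Additional non-duplicated genes (used by the intron
#'   test as the comparison population).
#' @param tandem_meanlog Two log-scale means for the tandem separation
#'   mixture (defaults `log(1e4)` and `log(1e7)`).
#' @return List with `annotation` (gene tibble with `exon_count`),
#'   `chrom_sizes`, `families` (tibble `family_id`, `gene_id`), `scores`
#'   (within-family pair similarity tibble), `cds` (named character vector of
#'   coding sequences), and `truth` ([sim_truth] holding mode and per-pair
#'   planted divergence).
#' @export
simulate_duplication_burst <- function(mode = c("wgd", "tandem", "retro"),
                                       n_families = 200,
                                       burst_tv_rate = 0.2,
                                       chrom_count = 8,
                                       seed = 1L,
                                       copy_number = 2L,
                                       n_codons = 300L,
                                       n_background = n_families,
                                       tandem_meanlog = c(log(1e4), log(1e7))) {
  mode <- match.arg(mode)
  if (burst_tv_rate < 0 || burst_tv_rate >= 0.5) {
    stop("burst_tv_rate must lie in [0, 0.5): pairwise class-flip divergence saturates at 0.5")
  }
  if (mode == "wgd" && chrom_count %% 2 != 0) {
    stop("wgd mode needs an even chrom_count (homeologous pairs)")
  }
  copy_number <- rep_len(as.integer(copy_number), n_families)
  if (any(copy_number < 2)) stop("copy_number must be >= 2")
  # class-flip probability giving pairwise transversion rate burst_tv_rate
  flip_p <- (1 - sqrt(1 - 2 * burst_tv_rate)) / 2

  withr::with_seed(substream_seed(seed, paste0("duplication_", mode)), {
    chroms <- sprintf("chr%02d", seq_len(chrom_count))
    chrom_len <- 5e7

    fam_ids <- sprintf("fam%04d", seq_len(n_families))
    genes <- list()
    for (i in seq_len(n_families)) {
      k <- copy_number[i]
      ids <- sprintf("%s_c%d", fam_ids[i], seq_len(k))
      exons <- rpois(1, 4) + 1L
      if (mode == "wgd") {
        c1 <- sample(seq(1, chrom_count, by = 2), 1)
        pos <- floor(runif(1, 0, chrom_len - 1e4))
        chrom <- chroms[c1 + (seq_len(k) - 1L) %% 2L]
        start <- pos + floor(runif(k, -5e3, 5e3))
        exon_count <- rep(exons, k)
      } else if (mode == "tandem") {
        chrom <- rep(sample(chroms, 1), k)
        comp <- sample(seq_along(tandem_meanlog), 1)
        sep <- rlnorm(k - 1, tandem_meanlog[comp], 0.2)
        pos <- c(0, cumsum(sep))
        anchor <- runif(1, 0, max(1, chrom_len - 1e4 - max(pos)))
        start <- floor(pmin(anchor + pos, chrom_len - 1e4))
        exon_count <- rep(exons, k)
      } else { # retro: parent keeps introns, copies are intronless
        chrom <- sample(chroms, k, replace = TRUE)
        start <- floor(runif(k, 0, chrom_len - 1e4))
        exon_count <- c(exons, rep(1L, k - 1))
      }
      genes[[i]] <- tibble::tibble(
        gene_id = ids, chrom = chrom, start = pmax(0, start),
        end = pmax(0, start) + 2000L,
        strand = sample(c("+", "-"), k, replace = TRUE),
        exon_count = exon_count, family_id = fam_ids[i]
      )
    }
    annotation <- dplyr::bind_rows(genes)
    if (n_background > 0) {
      bg_start <- floor(runif(n_background, 0, chrom_len - 1e4))
      annotation <- dplyr::bind_rows(annotation, tibble::tibble(
        gene_id = sprintf("bg%04d", seq_len(n_background)),
        chrom = sample(chroms, n_background, replace = TRUE),
        start = bg_start, end = bg_start + 2000L,
        strand = sample(c("+", "-"), n_background, replace = TRUE),
        exon_count = rpois(n_background, 4) + 1L,
        family_id = NA_character_
      ))
    }
    annotation <- dplyr::arrange(annotation, .data$chrom, .data$start)
    families <- annotation |>
      dplyr::filter(!is.na(.data$family_id)) |>
      dplyr::select("family_id", "gene_id")
    annotation$family_id <- NULL

    # Coding sequences: one random ancestor per family; each copy flips the
    # class of fourfold third bases with probability flip_p and transits
    # within class with probability 2 * flip_p.
    cds <- evolve_family_cds(families, n_codons, flip_p)

    scores <- families |>
      dplyr::group_by(.data$family_id) |>
      dplyr::reframe({
        ids <- .data$gene_id
        cmb <- utils::combn(ids, 2)
        tibble::tibble(gene1 = cmb[1, ], gene2 = cmb[2, ],
                       score = vapply(seq_len(ncol(cmb)), function(j) {
                         seq_identity(cds[[cmb[1, j]]], cds[[cmb[2, j]]])
                       }, numeric(1)))
      })

    truth_events <- scores |>
      dplyr::transmute(kind = "duplication", .data$family_id,
                       .data$gene1, .data$gene2,
                       planted_tv_rate = burst_tv_rate)

    list(
      annotation = annotation,
      chrom_sizes = tibble::tibble(chrom = chroms, length = chrom_len),
      families = families, scores = scores, cds = cds,
      truth = sim_truth(
        paste0("duplication_burst_", mode),
        list(mode = mode, n_families = n_families,
             burst_tv_rate = burst_tv_rate, chrom_count = chrom_count,
             seed = seed, copy_number = copy_number),
        truth_events
      )
    )
  })
}

# Evolve one coding sequence per family member from a shared random ancestor;
# only fourfold third positions mutate. Returns named character vector.
evolve_family_cds <- function(families, n_codons, flip_p) {
  bases <- c("A", "C", "G", "T")
  other_in_class <- c(A = "G", G = "A", C = "T", T = "C")
  cds <- character(0)
  for (fam in split(families$gene_id, families$family_id)) {
    prefixes <- sample(names(GENETIC_CODE_TABLE), n_codons, replace = TRUE)
    # avoid stop codons in the ancestor for realism
    prefixes[translate_codon(prefixes) == "*"] <- "GGA"
    anc_third <- substr(prefixes, 3, 3)
    pre2 <- substr(prefixes, 1, 2)
    fourfold <- pre2 %in% FOURFOLD_PREFIXES
    for (g in fam) {
      third <- anc_third
      idx <- which(fourfold)
      flip <- idx[runif(length(idx)) < flip_p]
      if (length(flip) > 0) {
        # cross-class substitution: purine <-> pyrimidine, uniform choice
        third[flip] <- ifelse(third[flip] %in% PURINES,
                              sample(PYRIMIDINES, length(flip), replace = TRUE),
                              sample(PURINES, length(flip), replace = TRUE))
      }
      ts <- idx[runif(length(idx)) < min(2 * flip_p, 1)]
      if (length(ts) > 0) third[ts] <- other_in_class[third[ts]]
      cds[g] <- paste0(paste0(pre2, third), collapse = "")
    }
  }
  cds
}

# Fraction of identical aligned positions between two equal-length sequences.
seq_identity <- function(s1, s2) {
  v1 <- strsplit(s1, "")[[1]]
  v2 <- strsplit(s2, "")[[1]]
  mean(v1 == v2)
}
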