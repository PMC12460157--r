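# Hi-C contact map simulator with a planted centromeric bipartition and
# centromere-enriched repeat families.

#' Simulate a binned Hi-C contact matrix with a planted centromere
#'
#' Contacts follow a Poisson model around a power-law distance decay
#' (exponent `decay_exponent`), attenuated by `attenuation` for bin pairs that
#' straddle the planted centromere bin. This is the simplest model producing
#' the two-block arm correlation structure from which correlation-eigenvector
#' centromere inference works. Repeat intervals of each family are placed with
#' a stated enrichment factor inside the centromere interval: with probability
#' `min(1, factor * p)` (where `p` is the centromere's share of the
#' chromosome) an interval is placed uniformly inside the centromere,
#' otherwise uniformly outside, so factor 1 is exactly uniform placement.
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp.
#' @param centromere_bin Planted centromere bin index (0-based, strictly
#'   inside the chromosome: `0 < centromere_bin < n_bins - 1`).
#' @param repeat_families Named list: family label -> `list(count, factor,
#'   len)` giving interval count, centromere enrichment factor and mean
#'   interval length (bp).
#' @param attenuation Multiplier in `(0, 1]` applied to cross-arm contacts;
#'   1 means no insulation (null case).
#' @param depth Expected contacts on the diagonal before decay.
#' @param decay_exponent Power-law exponent of distance decay (default -1).
#' @param chrom Chromosome label.
#' @param seed Integer seed.
#' @return List with `cm` (a [contact_matrix]), `repeats` (interval tibble
#'   `chrom`, `start`, `end`, `label`), `chrom_sizes`, `centromere`
#'   (planted interval tibble) and `truth`.
#' @export
simulate_contact_map <- function(n_bins = 100, bin_size = 250000,
                                 centromere_bin = 40,
                                 repeat_families = list(),
                                 attenuation = 0.3, depth = 5000,
                                 decay_exponent = -1,
                                 chrom = "chr1", seed = 1L) {
  if (centromere_bin <= 0 || centromere_bin >= n_bins - 1) {
    stop("centromere_bin must lie strictly inside the chromosome (no bipartition otherwise)")
  }
  stopifnot(attenuation > 0, attenuation <= 1)
  withr::with_seed(substream_seed(seed, "contact_map"), {
    d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
    lambda <- depth * (d + 1)^decay_exponent
    side <- (seq_len(n_bins) - 1) < centromere_bin
    cross <- outer(side, side, "!=")
    lambda[cross] <- lambda[cross] * attenuation
    upper <- upper.tri(lambda, diag = TRUE)
    counts <- matrix(0, n_bins, n_bins)
    counts[upper] <- rpois(sum(upper), lambda[upper])
    counts <- counts + t(counts) - diag(diag(counts))
    cm <- contact_matrix(counts, bin_size = bin_size, chrom = chrom)

    chrom_len <- n_bins * bin_size
    # planted centromere interval: the two bins flanking the arm interface
    cen_start <- (centromere_bin - 1) * bin_size
    cen_end <- (centromere_bin + 1) * bin_size
    p_cen <- (cen_end - cen_start) / chrom_len

    repeats <- dplyr::bind_rows(lapply(names(repeat_families), function(lab) {
      fam <- repeat_families[[lab]]
      fac <- fam$factor %||% 1
      n <- fam$count
      len <- pmax(1, round(rlnorm(n, log(fam$len %||% 2000), 0.3)))
      if (fac == 1) {
        # exactly uniform placement over the chromosome
        start <- floor(runif(n, 0, chrom_len - len))
      } else {
        inside <- runif(n) < min(1, fac * p_cen)
        start <- ifelse(
          inside,
          floor(runif(n, cen_start, pmax(cen_start + 1, cen_end - len))),
          floor(runif(n, 0, chrom_len - len))
        )
      }
      tibble::tibble(chrom = chrom, start = start, end = start + len,
                     label = lab)
    }))
    if (nrow(repeats) == 0) {
      repeats <- tibble::tibble(chrom = character(), start = numeric(),
                                end = numeric(), label = character())
    }

    list(
      cm = cm,
      repeats = repeats,
      chrom_sizes = tibble::tibble(chrom = chrom, length = chrom_len),
      centromere = tibble::tibble(chrom = chrom, start = cen_start,
                                  end = cen_end),
      truth = sim_truth(
        "contact_map",
        list(n_bins = n_bins, bin_size = bin_size,
             centromere_bin = centromere_bin, attenuation = attenuation,
             depth = depth, decay_exponent = decay_exponent, seed = seed,
             repeat_families = repeat_families),
        tibble::tibble(kind = "centromere", chrom = chrom,
                       bin = centromere_bin, start = cen_start, end = cen_end)
      )
    )
  })
}
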