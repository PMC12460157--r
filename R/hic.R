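# Hi-C architecture: map resolution, correlation eigenvectors, centromere
# calling, repeat permutation tests, insulation/boundaries, compartment saddle.

#' Construct a binned contact matrix
#'
#' @param matrix Symmetric non-negative numeric matrix of binned contacts;
#'   bin `i` (0-based) covers `[i * bin_size, (i + 1) * bin_size)`.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome label.
#' @param tol Symmetry tolerance.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(matrix, bin_size, chrom = "chr1", tol = 1e-9) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (any(matrix < 0)) stop("contact matrix must be non-negative")
  if (max(abs(matrix - t(matrix))) > tol * max(1, max(abs(matrix)))) {
    stop("contact matrix must be symmetric")
  }
  structure(
    list(chrom = chrom, bin_size = bin_size, matrix = matrix,
         n_bins = nrow(matrix)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix>", x$chrom, ":", x$n_bins, "bins of", x$bin_size,
      "bp;", format(sum(x$matrix) / 2, big.mark = ","), "contacts\n")
  invisible(x)
}

#' Usable map resolution of a bin-size ladder
#'
#' Reports the smallest bin size at which more than `min_fraction` of bins
#' have strictly more than `min_contacts` contacts (row sums of the raw
#' count matrix).
#'
#' @param matrices List of [contact_matrix] objects at different bin sizes.
#' @param min_contacts Contacts a bin must exceed (strict).
#' @param min_fraction Fraction of passing bins a resolution must exceed
#'   (strict).
#' @return The chosen bin size in bp, or `NA` when every size fails.
#' @export
estimate_map_resolution <- function(matrices, min_contacts = 1000,
                                    min_fraction = 0.80) {
  if (length(matrices) == 0) stop("empty bin-size ladder")
  sizes <- vapply(matrices, function(m) m$bin_size, numeric(1))
  frac <- vapply(matrices, function(m) {
    mean(rowSums(m$matrix) > min_contacts)
  }, numeric(1))
  passing <- sizes[frac > min_fraction]
  if (length(passing) == 0) NA_real_ else min(passing)
}

#' Correlation eigenvectors of a distance-normalised contact matrix
#'
#' Normalises by expected contacts per diagonal (observed/expected), computes
#' the Pearson correlation matrix of its columns, and eigendecomposes it.
#' All-zero bins are masked before correlation and carry `NA` in the returned
#' profiles. The decomposition is invariant under uniform scaling of the
#' input.
#'
#' @param cm A [contact_matrix].
#' @param n_eigs Number of leading eigenvectors (by `|eigenvalue|`).
#' @return An `eigen_profiles` object: list with `values` (bins x n_eigs
#'   matrix, unit-norm columns, `NA` at masked bins), `eigenvalues`, `mask`,
#'   `chrom`, `bin_size`; or a zero-column object when the correlation is
#'   degenerate (e.g. constant matrix).
#' @export
correlation_eigenvectors <- function(cm, n_eigs = 5) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$matrix
  informative <- rowSums(m) > 0
  if (sum(informative) < 20) {
    stop("need at least 20 informative bins")
  }
  mm <- m[informative, informative, drop = FALSE]
  oe <- observed_over_expected(mm)
  suppressWarnings(cc <- cor(oe))
  if (anyNA(cc) || max(abs(cc - cc[1, 1])) < 1e-12) {
    return(new_eigen_profiles(
      matrix(numeric(0), nrow = cm$n_bins, ncol = 0), numeric(0),
      informative, cm
    ))
  }
  cc[is.na(cc)] <- 0
  dec <- eigen(cc, symmetric = TRUE)
  ord <- order(-abs(dec$values))[seq_len(min(n_eigs, length(dec$values)))]
  vals <- matrix(NA_real_, nrow = cm$n_bins, ncol = length(ord))
  for (j in seq_along(ord)) {
    v <- dec$vectors[, ord[j]]
    vals[informative, j] <- v / sqrt(sum(v^2))
  }
  new_eigen_profiles(vals, dec$values[ord], informative, cm)
}

new_eigen_profiles <- function(values, eigenvalues, mask, cm) {
  structure(
    list(values = values, eigenvalues = eigenvalues, mask = mask,
         chrom = cm$chrom, bin_size = cm$bin_size),
    class = "eigen_profiles"
  )
}

#' @export
print.eigen_profiles <- function(x, ...) {
  cat("<eigen_profiles>", x$chrom, ":", ncol(x$values), "eigenvectors over",
      nrow(x$values), "bins\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eigen_profiles <- function(x, ...) {
  if (ncol(x$values) == 0) {
    return(tibble::tibble(bin = integer(), eigen_rank = integer(),
                          value = numeric(), eigenvalue = numeric()))
  }
  purrr::map_dfr(seq_len(ncol(x$values)), function(j) {
    tibble::tibble(bin = seq_len(nrow(x$values)) - 1L, eigen_rank = j,
                   value = x$values[, j], eigenvalue = x$eigenvalues[j])
  })
}

# Observed/expected normalisation: divide each diagonal by its mean.
observed_over_expected <- function(m) {
  n <- nrow(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- vapply(0:(n - 1), function(k) mean(m[d == k]), numeric(1))
  oe <- m / expected[d + 1]
  oe[!is.finite(oe)] <- 0
  oe
}

#' Call the centromere from correlation eigenvectors
#'
#' Automates eigenvector selection: among the leading eigenvectors, the one
#' whose sign pattern is closest to a two-block bipartition (fewest sign
#' changes along the chromosome, at least one; ties resolved toward higher
#' `|eigenvalue|`) is used. The centromere interface is the adjacent-bin pair
#' with the largest `|dEV|`; the reported interval spans the two flanking
#' bins. When no eigenvector changes sign the chromosome is returned as a
#' no-call (acrocentric or undetectable).
#'
#' @param profiles An `eigen_profiles` object.
#' @param cm The matching [contact_matrix].
#' @param eigen_rank Optional manual override of the eigenvector rank to use
#'   (replacing the automatic selection).
#' @return One-row tibble: `chrom`, `called`, `eigen_rank`, `interface_bin`
#'   (0-based index of the bin right of the interface), `start`, `end`
#'   (bp interval of the two flanking bins), `differential`.
#' @export
call_centromere <- function(profiles, cm, eigen_rank = NULL) {
  stopifnot(inherits(profiles, "eigen_profiles"))
  no_call <- tibble::tibble(
    chrom = cm$chrom, called = FALSE, eigen_rank = NA_integer_,
    interface_bin = NA_integer_, start = NA_real_, end = NA_real_,
    differential = NA_real_
  )
  if (ncol(profiles$values) == 0) return(no_call)
  sign_changes <- function(v) {
    v <- v[!is.na(v)]
    s <- sign(v)
    s <- s[s != 0]
    sum(diff(s) != 0)
  }
  if (is.null(eigen_rank)) {
    nsc <- apply(profiles$values, 2, sign_changes)
    candidates <- which(nsc >= 1)
    if (length(candidates) == 0) return(no_call)
    ord <- candidates[order(nsc[candidates],
                            -abs(profiles$eigenvalues[candidates]))]
    eigen_rank <- ord[1]
  }
  v <- profiles$values[, eigen_rank]
  dv <- abs(diff(v))
  if (all(is.na(dv))) return(no_call)
  i <- which.max(dv) # interface between bins i-1 and i (0-based)
  bs <- profiles$bin_size
  tibble::tibble(
    chrom = cm$chrom, called = TRUE, eigen_rank = as.integer(eigen_rank),
    interface_bin = as.integer(i),
    start = (i - 1) * bs, end = (i + 1) * bs,
    differential = dv[i]
  )
}

#' Permutation test for repeat enrichment at centromeres
#'
#' For each repeat family overlapping at least one called centromere,
#' computes the observed bp overlap with the centromere interval per
#' chromosome, then relocates every interval of the family uniformly at
#' random along the chromosome (lengths preserved, overlaps permitted)
#' `n_perm` times and reports the add-one empirical p-value
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param calls Centromere call tibble (from [call_centromere]) with columns
#'   `chrom`, `called`, `start`, `end`.
#' @param repeats Interval tibble `chrom`, `start`, `end`, `label`.
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param n_perm Number of randomisations.
#' @param seed Integer seed; results are bit-reproducible given
#'   `(seed, n_perm)`.
#' @param require_overlap Keep only families whose observed overlap is
#'   positive (the stated precondition); disable for null calibration.
#' @return Tibble: `label`, `chrom`, `observed_overlap`, `null_mean`,
#'   `empirical_p`, `n_perm`, `seed`.
#' @export
repeat_permutation_test <- function(calls, repeats, chrom_sizes,
                                    n_perm = 1000, seed = 1L,
                                    require_overlap = TRUE) {
  calls <- dplyr::filter(calls, .data$called)
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  if (any(calls$end > sizes[calls$chrom])) {
    stop("centromere interval exceeds chromosome length")
  }
  combos <- dplyr::inner_join(
    dplyr::distinct(repeats, .data$chrom, .data$label),
    calls[c("chrom", "start", "end")], by = "chrom"
  )
  withr::with_seed(substream_seed(seed, "repeat_permutation"), {
    res <- purrr::pmap_dfr(combos, function(chrom, label, start, end) {
      ivs <- repeats[repeats$chrom == chrom & repeats$label == label, ]
      lens <- ivs$end - ivs$start
      L <- sizes[[chrom]]
      obs <- sum(interval_overlap(ivs$start, ivs$end, start, end))
      null <- vapply(seq_len(n_perm), function(i) {
        s <- floor(runif(length(lens), 0, pmax(1, L - lens)))
        sum(interval_overlap(s, s + lens, start, end))
      }, numeric(1))
      tibble::tibble(
        label = label, chrom = chrom, observed_overlap = obs,
        null_mean = mean(null),
        empirical_p = (1 + sum(null >= obs)) / (n_perm + 1),
        n_perm = n_perm, seed = seed
      )
    })
  })
  if (require_overlap) res <- dplyr::filter(res, .data$observed_overlap > 0)
  res
}

# bp overlap of intervals [s, e) with a single interval [a, b)
interval_overlap <- function(s, e, a, b) {
  pmax(0, pmin(e, b) - pmax(s, a))
}

#' Insulation scores and domain boundaries
#'
#' The insulation score at bin `i` is the log2 of the mean contact count in
#' the `w x w` diamond upstream x downstream of `i` (with `w = window /
#' bin_size`), normalised by the chromosome-wide mean diamond score.
#' Boundaries are local insulation minima; boundary strength is the smaller
#' of the rises to the nearest flanking local maxima, and only boundaries
#' with strength strictly above `min_strength` are retained.
#'
#' @param cm A [contact_matrix].
#' @param window Diamond window in bp (at least `2 * bin_size`).
#' @param min_strength Strict retention threshold for boundary strength.
#' @return List: `insulation` (tibble `bin`, `score`), `boundaries` (tibble
#'   `bin`, `score`, `strength`).
#' @export
insulation_and_boundaries <- function(cm, window = 250000,
                                      min_strength = 0.5) {
  if (window < 2 * cm$bin_size) stop("window must be at least 2 bins wide")
  w <- floor(window / cm$bin_size)
  n <- cm$n_bins
  if (n < 2 * w + 1) {
    warning("chromosome shorter than two windows; no insulation scores")
    return(list(
      insulation = tibble::tibble(bin = integer(), score = numeric()),
      boundaries = tibble::tibble(bin = integer(), score = numeric(),
                                  strength = numeric())
    ))
  }
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    raw[i] <- mean(cm$matrix[(i - w):(i - 1), (i + 1):(i + w)])
  }
  score <- log2(raw / mean(raw, na.rm = TRUE))
  score[!is.finite(score)] <- NA_real_
  insulation <- tibble::tibble(bin = seq_len(n) - 1L, score = score)

  ok <- which(!is.na(score))
  minima <- ok[ok > min(ok) & ok < max(ok)]
  minima <- minima[vapply(minima, function(i) {
    score[i] < score[i - 1] && score[i] <= score[i + 1]
  }, logical(1))]
  boundary_strength <- function(i) {
    left <- right <- NA_real_
    j <- i - 1
    while (j > min(ok)) {
      if (!is.na(score[j - 1]) && score[j] >= score[j - 1] &&
          score[j] > score[i]) { left <- score[j]; break }
      j <- j - 1
    }
    if (is.na(left)) left <- max(score[min(ok):(i - 1)], na.rm = TRUE)
    j <- i + 1
    while (j < max(ok)) {
      if (!is.na(score[j + 1]) && score[j] >= score[j + 1] &&
          score[j] > score[i]) { right <- score[j]; break }
      j <- j + 1
    }
    if (is.na(right)) right <- max(score[(i + 1):max(ok)], na.rm = TRUE)
    min(left - score[i], right - score[i])
  }
  strengths <- vapply(minima, boundary_strength, numeric(1))
  keep <- strengths > min_strength
  list(
    insulation = insulation,
    boundaries = tibble::tibble(bin = as.integer(minima[keep]) - 1L,
                                score = score[minima[keep]],
                                strength = strengths[keep])
  )
}

#' Compartment saddle summary
#'
#' Orients an eigenvector so that bins with above-median open-chromatin peak
#' counts have positive mean value (active regions positive), ranks bins into
#' `n_categories` quantile classes of the oriented eigenvector, and averages
#' observed/expected contacts between classes. Corner cells then quantify
#' active-active and inactive-inactive contact preference.
#'
#' @param profile Numeric eigenvector (one value per bin, `NA` for masked).
#' @param cm The matching [contact_matrix].
#' @param peaks Interval tibble (`chrom`, `start`, `end`) of open-chromatin
#'   peaks on the same chromosome.
#' @param n_categories Number of eigenvector quantile classes.
#' @return List: `profile` (oriented eigenvector), `saddle` (n_categories
#'   square matrix), `flipped`, `oriented` (FALSE when no peaks on the
#'   chromosome, in which case the profile is returned unoriented).
#' @export
compartment_saddle <- function(profile, cm, peaks, n_categories = 50) {
  stopifnot(length(profile) == cm$n_bins)
  peaks <- peaks[peaks$chrom == cm$chrom, , drop = FALSE]
  oriented <- nrow(peaks) > 0
  flipped <- FALSE
  if (oriented) {
    bin_idx <- pmin(cm$n_bins - 1, floor((peaks$start + peaks$end) / 2 / cm$bin_size))
    peak_count <- tabulate(bin_idx + 1, nbins = cm$n_bins)
    active <- peak_count > median(peak_count)
    if (any(active) && mean(profile[active], na.rm = TRUE) < 0) {
      profile <- -profile
      flipped <- TRUE
    }
  }
  ok <- which(!is.na(profile))
  classes <- rep(NA_integer_, cm$n_bins)
  classes[ok] <- as.integer(cut(rank(profile[ok], ties.method = "first"),
                                breaks = n_categories, labels = FALSE))
  oe <- matrix(NA_real_, cm$n_bins, cm$n_bins)
  oe[ok, ok] <- observed_over_expected(cm$matrix[ok, ok, drop = FALSE])
  saddle <- matrix(NA_real_, n_categories, n_categories)
  for (a in seq_len(n_categories)) {
    for (b in a:n_categories) {
      cells <- oe[classes == a & !is.na(classes),
                  classes == b & !is.na(classes), drop = FALSE]
      saddle[a, b] <- saddle[b, a] <- mean(cells, na.rm = TRUE)
    }
  }
  list(profile = profile, saddle = saddle, flipped = flipped,
       oriented = oriented)
}
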