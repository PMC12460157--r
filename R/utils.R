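# Shared internal helpers: seeded sub-streams, input validation, truth records.

#' Derive a deterministic sub-stream seed
#'
#' All generators draw from sub-streams derived from one root seed and a task
#' label, so adding a generator call to a scenario never perturbs the draws of
#' unrelated sub-tasks. The derivation is a Lehmer-style mix of the root seed
#' with a polynomial hash of the label, reduced modulo 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param label Character scalar naming the sub-task.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(label))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  as.integer(((s + h) %% (m - 1)) + 1)
}

#' Validate a gene annotation table
#'
#' A genome annotation is a tibble with one row per gene model and columns
#' `gene_id`, `chrom`, `start`, `end`, `strand` and optionally `exon_count`.
#' Coordinates are 0-based half-open.
#'
#' @param genes Gene table.
#' @param chrom_sizes Optional tibble with columns `chrom`, `length` used to
#'   check that no gene exceeds its chromosome.
#' @return `genes`, invisibly, after validation.
#' @export
validate_annotation <- function(genes, chrom_sizes = NULL) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id) > 0) stop("gene_id values must be unique")
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    stop("gene coordinates must satisfy 0 <= start < end (0-based half-open)")
  }
  if (!is.null(chrom_sizes)) {
    sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    bad <- genes$end > sizes[genes$chrom]
    if (any(is.na(bad)) || any(bad)) {
      stop("gene intervals exceed chromosome length or lie on unknown chromosomes")
    }
  }
  invisible(genes)
}

#' Construct a simulation truth record
#'
#' Generators attach a `sim_truth` object recording the scenario, the exact
#' parameters of the call, and every planted event, so downstream stages can be
#' scored without re-reading generator internals.
#'
#' @param scenario Scenario label.
#' @param parameters Named list echoing the generator call.
#' @param events Tibble of planted events.
#' @return A `sim_truth` object.
#' @export
sim_truth <- function(scenario, parameters, events) {
  structure(
    list(scenario = scenario, parameters = parameters, events = events),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> scenario:", x$scenario, "\n")
  cat("  parameters:", paste(names(x$parameters), collapse = ", "), "\n")
  cat("  planted events:", nrow(x$events), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sim_truth <- function(x, ...) x$events

# Draw gene coordinates along a chromosome: log-normal gene lengths and
# intergenic gaps (defaults emulate a compact invertebrate genome: ~2 kb genes,
# ~1 kb gaps). Returns a tibble with start/end and the implied chromosome size.
layout_genes <- function(n, gene_meanlog = log(2000), gap_meanlog = log(1000),
                         sdlog = 0.5) {
  lens <- ceiling(rlnorm(n, gene_meanlog, sdlog))
  gaps <- ceiling(rlnorm(n, gap_meanlog, sdlog))
  start <- cumsum(gaps) + cumsum(c(0, lens[-n]))
  tibble::tibble(start = start, end = start + lens)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
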