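# Splice-leader read library simulator over a planted operon structure.

#' Simulate an RNA-seq read table with splice-leader prefixes
#'
#' Assigns `reads_per_gene` reads to every gene of an annotation. Genes that
#' are trans-spliced in truth (all members of the planted operons plus a
#' random fraction `ts_extra_fraction` of the remaining genes) receive a
#' splice-leader prefix on a fraction `sl_fraction` of their reads: the stored
#' 5' window is the leader sequence followed by the gene's transcript start,
#' truncated to `window` nt, with independent per-base substitution errors at
#' `error_rate`. Reads of non-trans-spliced genes (and the non-SL reads of
#' trans-spliced ones) carry plain transcript sequence.
#'
#' @param annotation Gene tibble (see [validate_annotation]).
#' @param operon_truth List of character vectors, each an ordered run of gene
#'   ids forming a planted operon (all present in `annotation`).
#' @param leaders Splice-leader tibble with columns `name`, `sequence`
#'   (each sequence >= 25 nt over ACGT).
#' @param reads_per_gene Reads simulated per gene.
#' @param sl_fraction Probability that a read of a trans-spliced gene carries
#'   a leader.
#' @param error_rate Per-base substitution probability in the stored window.
#' @param ts_extra_fraction Fraction of non-operonic genes that are
#'   trans-spliced (monocistronic trans-splicing).
#' @param window Stored 5' window length (nt).
#' @param seed Integer seed.
#' @return List with `reads` (tibble `read_id`, `gene_id`, `five_prime_seq`)
#'   and `truth` (per-gene trans-spliced status and operon membership).
#' @export
simulate_sl_library <- function(annotation, operon_truth, leaders,
                                reads_per_gene = 20, sl_fraction = 0.6,
                                error_rate = 0.01, ts_extra_fraction = 0.2,
                                window = 30L, seed = 1L) {
  stopifnot(sl_fraction >= 0, sl_fraction <= 1)
  if (sl_fraction > 0 && nrow(leaders) == 0) {
    stop("empty splice-leader set with sl_fraction > 0")
  }
  if (nrow(leaders) > 0 && any(nchar(leaders$sequence) < 25)) {
    stop("splice-leader sequences must be at least 25 nt")
  }
  operonic <- unlist(operon_truth)
  missing <- setdiff(operonic, annotation$gene_id)
  if (length(missing) > 0) {
    stop("operon_truth genes absent from annotation: ",
         paste(missing, collapse = ", "))
  }

  withr::with_seed(substream_seed(seed, "sl_library"), {
    genes <- annotation$gene_id
    non_operonic <- setdiff(genes, operonic)
    extra_ts <- non_operonic[runif(length(non_operonic)) < ts_extra_fraction]
    ts_genes <- union(operonic, extra_ts)

    transcript5 <- setNames(
      vapply(genes, function(g) random_dna(window), character(1)), genes
    )

    n_reads <- length(genes) * reads_per_gene
    gene_of <- rep(genes, each = reads_per_gene)
    is_ts <- gene_of %in% ts_genes
    has_sl <- is_ts & runif(n_reads) < sl_fraction

    five_prime <- substr(transcript5[gene_of], 1, window)
    if (any(has_sl)) {
      leader_idx <- sample(nrow(leaders), sum(has_sl), replace = TRUE)
      five_prime[has_sl] <- substr(
        paste0(leaders$sequence[leader_idx], five_prime[has_sl]), 1, window
      )
    }
    if (error_rate > 0) {
      five_prime <- mutate_bases(five_prime, error_rate)
    }

    operon_id <- rep(NA_character_, length(genes))
    names(operon_id) <- genes
    for (i in seq_along(operon_truth)) {
      operon_id[operon_truth[[i]]] <- sprintf("true_operon_%03d", i)
    }

    list(
      reads = tibble::tibble(
        read_id = sprintf("r%06d", seq_len(n_reads)),
        gene_id = gene_of,
        five_prime_seq = unname(five_prime)
      ),
      truth = sim_truth(
        "sl_library",
        list(reads_per_gene = reads_per_gene, sl_fraction = sl_fraction,
             error_rate = error_rate, ts_extra_fraction = ts_extra_fraction,
             seed = seed),
        tibble::tibble(kind = "gene_status", gene_id = genes,
                       trans_spliced = genes %in% ts_genes,
                       operon_id = unname(operon_id))
      )
    )
  })
}

# Apply independent per-base substitutions (to one of the three other bases)
# at the given rate to a character vector of equal-length sequences.
mutate_bases <- function(seqs, rate) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  hit <- matrix(runif(length(mat)) < rate, nrow(mat))
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(mat[hit], function(b) sample(setdiff(bases, b), 1),
                   character(1))
    mat[hit] <- repl
  }
  apply(mat, 1, paste, collapse = "")
}
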