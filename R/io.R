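# Readers and writers for the standard interchange formats. Gene tables use
# 0-based half-open coordinates internally; GFF3/GRanges conversions shift
# accordingly.

#' Write a gene annotation as GFF3
#'
#' @param genes Gene tibble (see [validate_annotation]).
#' @param path Output file.
#' @param source Value of the GFF3 source column.
#' @export
write_gene_gff3 <- function(genes, path, source = "karyoburst") {
  validate_annotation(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  if ("exon_count" %in% names(genes)) gr$exon_count <- genes$exon_count
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports `gene`-type records and returns the package's 0-based half-open
#' gene tibble; an `exon_count` attribute is carried through when present.
#'
#' @param path GFF3 file.
#' @return Gene tibble.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  out <- tibble::tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (!is.null(gr$exon_count)) out$exon_count <- as.integer(gr$exon_count)
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble `chrom`, `start`, `end` and optional `label`
#'   (written to the BED name column).
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1,
                              end = intervals$end)
  )
  if ("label" %in% names(intervals)) names(gr) <- intervals$label
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED interval track
#'
#' @param path BED file.
#' @return Tibble `chrom`, `start`, `end`, `label` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    label = if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  )
}

#' Write coding sequences as FASTA
#'
#' @param cds Named character vector of sequences.
#' @param path Output file.
#' @export
write_cds_fasta <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a contact matrix as dense TSV
#'
#' First line is a `#chrom=<label> bin_size=<bp>` header, followed by the
#' dense tab-separated matrix.
#'
#' @param cm A [contact_matrix].
#' @param path Output file.
#' @export
write_contact_matrix <- function(cm, path) {
  header <- sprintf("#chrom=%s bin_size=%d", cm$chrom, as.integer(cm$bin_size))
  body <- apply(cm$matrix, 1, paste, collapse = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a dense TSV contact matrix
#'
#' @param path File written by [write_contact_matrix] (or any dense matrix
#'   TSV; `chrom`/`bin_size` fall back to `"chr1"` / 1 without a header).
#' @return A [contact_matrix].
#' @export
read_contact_matrix <- function(path) {
  lines <- readr::read_lines(path)
  chrom <- "chr1"; bin_size <- 1
  if (startsWith(lines[1], "#")) {
    m <- regmatches(lines[1],
                    regexec("#chrom=(\\S+) bin_size=(\\d+)", lines[1]))[[1]]
    if (length(m) == 3) { chrom <- m[2]; bin_size <- as.numeric(m[3]) }
    lines <- lines[-1]
  }
  mat <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
  contact_matrix(mat, bin_size = bin_size, chrom = chrom)
}

#' Write the simplified read table
#'
#' @param reads Tibble `read_id`, `gene_id`, `five_prime_seq`.
#' @param path Output TSV.
#' @export
write_read_table <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' Read the simplified read table
#' @param path TSV with columns `read_id`, `gene_id`, `five_prime_seq`.
#' @return Read tibble.
#' @export
read_read_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' Write a presence/absence matrix as TSV
#' @param pam Tibble `family_id` + 0/1 species columns.
#' @param path Output TSV.
#' @export
write_presence_absence <- function(pam, path) {
  readr::write_tsv(pam, path)
  invisible(path)
}

#' Read a presence/absence matrix from TSV
#' @param path TSV with `family_id` + 0/1 species columns.
#' @return Presence/absence tibble.
#' @export
read_presence_absence <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    family_id = "c", .default = "i"
  ))
}

#' Write a similarity table
#' @param tab Tibble `query_id`, `target_id`, `score`.
#' @param path Output TSV (query, target, score; no header).
#' @export
write_similarity_table <- function(tab, path) {
  readr::write_tsv(tab[c("query_id", "target_id", "score")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a similarity table
#' @param path TSV `query<TAB>target<TAB>score`, no header.
#' @return Tibble `query_id`, `target_id`, `score`.
#' @export
read_similarity_table <- function(path) {
  readr::read_tsv(path, col_names = c("query_id", "target_id", "score"),
                  col_types = "ccd")
}
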