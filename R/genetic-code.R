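# Standard genetic code tables used by the FDTv machinery.

# Codon -> amino acid (standard code, "*" for stop).
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  setNames(aas, codons)
})

# The eight fourfold-degenerate codon boxes: 2-base prefixes whose four codons
# all encode the same amino acid (third base free).
FOURFOLD_PREFIXES <- local({
  prefixes <- unique(substr(names(GENETIC_CODE_TABLE), 1, 2))
  keep <- vapply(prefixes, function(p) {
    aa <- GENETIC_CODE_TABLE[paste0(p, c("T", "C", "A", "G"))]
    length(unique(aa)) == 1
  }, logical(1))
  prefixes[keep]
})

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_purine <- function(base) base %in% PURINES

# TRUE when two bases differ across the purine/pyrimidine boundary.
is_transversion <- function(b1, b2) xor(b1 %in% PURINES, b2 %in% PURINES)

translate_codon <- function(codon) {
  unname(GENETIC_CODE_TABLE[codon])
}
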