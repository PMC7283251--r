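# Genetic-code tables and translation helpers (loaded first).

CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
})

codon_aa <- function(codon) {
  aa <- CODON_TABLE[codon]
  aa[is.na(aa)] <- "X" # ambiguous (N-containing) codons
  unname(aa)
}

# translate a CDS string up to (not including) the first stop codon;
# returns list(aa = string, n_aa = integer, hit_stop = logical)
translate_to_stop <- function(cds) {
  n <- nchar(cds) %/% 3
  if (n == 0) return(list(aa = "", n_aa = 0L, hit_stop = FALSE))
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- codon_aa(codons)
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    k <- stop_at[1] - 1L
    list(aa = chars_seq(aa[seq_len(k)]), n_aa = k, hit_stop = TRUE)
  } else {
    list(aa = chars_seq(aa), n_aa = n, hit_stop = FALSE)
  }
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

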