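# Shared low-level sequence helpers. All sequences are plain upper-case
# character scalars internally; Biostrings is used at the file boundary.

seq_sub <- function(s, start1, end1) substr(s, start1, end1)

seq_len_bp <- function(s) nchar(s)

revcomp <- function(s) revcomp_cpp(s)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

# VCF-style left alignment of an anchored indel. `pos1` is the 1-based
# position of the shared anchor base; exactly one of ref/alt is longer.
left_normalize_indel <- function(ref_seq, pos1, ref, alt) {
  longer <- if (nchar(ref) > nchar(alt)) ref else alt
  v <- substr(longer, 2, nchar(longer)) # the inserted/deleted run
  L <- nchar(v)
  while (pos1 > 1 && substr(ref_seq, pos1, pos1) == substr(v, L, L)) {
    v <- paste0(substr(ref_seq, pos1, pos1), substr(v, 1, L - 1))
    pos1 <- pos1 - 1L
  }
  anchor <- substr(ref_seq, pos1, pos1)
  if (nchar(ref) > nchar(alt)) {
    list(pos1 = pos1, ref = paste0(anchor, v), alt = anchor)
  } else {
    list(pos1 = pos1, ref = anchor, alt = paste0(anchor, v))
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
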