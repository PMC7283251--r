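#' Annotated SDR haplotypes
#'
#' An annotated haplotype bundles one phased SDR sequence with its gene
#' models, sex class (`M`, `F` or `H`) and species/accession tags. It is the
#' atomic input of every cross-haplotype comparison in the package.
#'
#' @param accession unique haplotype identifier (FASTA record id).
#' @param species species tag.
#' @param sex_class one of `"M"`, `"F"`, `"H"`.
#' @param seq DNA sequence (character scalar, alphabet `ACGTN`).
#' @param genes tibble of gene models as built by the package readers
#'   (columns `gene_id`, `start`, `end`, `strand`, `partial`, `cds`).
#' @return an object of class `sdr_haplotype`.
#' @export
annotated_haplotype <- function(accession, species, sex_class, seq,
                                genes = NULL) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) abort("sequence alphabet must be ACGTN")
  if (!sex_class %in% c("M", "F", "H")) {
    abort(sprintf("unknown sex class '%s' for %s", sex_class, accession))
  }
  if (is.null(genes)) {
    genes <- tibble(gene_id = character(), start = integer(),
                    end = integer(), strand = character(),
                    partial = logical(), cds = list())
  }
  genes <- dplyr::arrange(as_tibble(genes), .data$start)
  bad <- genes$start < 1 | genes$end > nchar(seq)
  if (any(bad)) {
    abort(sprintf("gene(s) %s outside sequence bounds of %s",
                  paste(genes$gene_id[bad], collapse = ", "), accession))
  }
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[[i]]
    if (nrow(cds) && (min(cds$start) < genes$start[i] ||
                      max(cds$end) > genes$end[i])) {
      abort(sprintf("CDS outside gene body for %s", genes$gene_id[i]))
    }
  }
  structure(list(accession = accession, species = species,
                 sex_class = sex_class, seq = seq, genes = genes),
            class = "sdr_haplotype")
}

#' @export
print.sdr_haplotype <- function(x, ...) {
  cat(sprintf("<sdr_haplotype> %s (%s, sex class %s): %s bp, %d genes\n",
              x$accession, x$species, x$sex_class,
              format(nchar(x$seq), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' @export
print.sdr_haplotype_set <- function(x, ...) {
  tab <- table(vapply(x, `[[`, "", "sex_class"))
  cat(sprintf("<sdr_haplotype_set> %d haplotypes (%s)\n", length(x),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

new_haplotype_set <- function(haps) {
  names(haps) <- vapply(haps, `[[`, "", "accession")
  structure(haps, class = "sdr_haplotype_set")
}

# extract the spliced CDS of a gene (transcript orientation)
gene_cds_seq <- function(hap, gene_id) {
  g <- hap$genes[hap$genes$gene_id == gene_id, ]
  if (nrow(g) == 0) abort(sprintf("gene %s not found in %s", gene_id,
                                  hap$accession))
  cds <- g$cds[[1]][order(g$cds[[1]]$start), ]
  s <- paste(mapply(seq_sub, cds$start, cds$end,
                    MoreArgs = list(s = hap$seq)), collapse = "")
  if (g$strand == "-") s <- revcomp(s)
  s
}

#' Summarise a haplotype set as a tibble
#'
#' @param set an `sdr_haplotype_set`.
#' @return a tibble with one row per haplotype: accession, species,
#'   sex class, sequence length and gene count.
#' @export
haplotype_table <- function(set) {
  purrr::map_dfr(set, function(h) {
    tibble(accession = h$accession, species = h$species,
           sex_class = h$sex_class, length_bp = nchar(h$seq),
           n_genes = nrow(h$genes))
  })
}

sex_label_table <- function(set) {
  purrr::map_dfr(set, function(h) {
    tibble(accession = h$accession, sex_class = h$sex_class)
  })
}
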