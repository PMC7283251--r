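#' Annotate coding consequences of variants
#'
#' Classifies each variant against the reference haplotype's gene models:
#' `synonymous`, `nonsynonymous` (with a `stop_lost` flag when a reference
#' stop codon is destroyed), `nonsense` (a SNP or in-frame change creating a
#' premature stop), `frameshift` (coding indel of length not divisible by
#' 3), `inframe_indel`, `intronic`, `promoter` (within `promoter_bp`
#' upstream of the transcription start, strand-aware), `intergenic`, or
#' `complex` for events straddling a CDS boundary (no translation
#' attempted). For coding changes, the mutant CDS is rebuilt, translated to
#' the first stop, and its protein length reported; variants downstream of
#' a created stop do not change the first-stop length.
#'
#' @param variants tibble of calls (columns `pos`, `ref`, `alt`) on this
#'   haplotype's coordinates.
#' @param haplotype an `sdr_haplotype` providing sequence and gene models.
#' @param promoter_bp promoter window upstream of the TSS (default 3000).
#' @return tibble: `pos`, `ref`, `alt`, `gene_id`, `consequence`,
#'   `ref_protein_length`, `mutant_protein_length`, `no_stop`, `stop_lost`.
#' @export
annotate_effect <- function(variants, haplotype, promoter_bp = 3000) {
  stopifnot(inherits(haplotype, "sdr_haplotype"))
  genes <- haplotype$genes
  hv <- seq_chars(haplotype$seq)
  purrr::pmap_dfr(variants[, c("pos", "ref", "alt")],
                  function(pos, ref, alt) {
    annotate_one(pos, ref, alt, haplotype, genes, promoter_bp, hv)
  })
}

annotate_one <- function(pos, ref, alt, hap, genes, promoter_bp, hv) {
  base <- tibble(pos = pos, ref = ref, alt = alt, gene_id = NA_character_,
                 consequence = "intergenic",
                 ref_protein_length = NA_integer_,
                 mutant_protein_length = NA_integer_,
                 no_stop = FALSE, stop_lost = FALSE)
  lr <- nchar(ref); la <- nchar(alt)
  is_snp <- lr == 1 && la == 1
  # affected reference footprint (indels are anchored: run starts at pos+1)
  foot_lo <- if (is_snp) pos else pos + 1L
  foot_hi <- pos + max(lr - 1L, if (is_snp) 0L else 1L) # ins touches pos+1
  if (la > lr) foot_hi <- max(foot_hi, pos + 1L)

  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    cds <- g$cds[[1]]
    in_cds <- any(cds$start <= foot_hi & cds$end >= foot_lo)
    in_body <- g$start <= foot_hi & g$end >= foot_lo
    if (!in_cds && !in_body) next
    base$gene_id <- g$gene_id
    if (!in_cds) { base$consequence <- "intronic"; return(base) }

    # genomic positions of CDS bases in transcript orientation
    gpos <- unlist(lapply(seq_len(nrow(cds)), function(j) {
      cds$start[j]:cds$end[j]
    }))
    if (g$strand == "-") gpos <- rev(gpos)
    cds_seq <- chars_seq(if (g$strand == "+") hv[gpos] else hv[rev(gpos)])
    if (g$strand == "-") cds_seq <- revcomp(cds_seq)
    ref_tr <- translate_to_stop(cds_seq)

    if (is_snp) {
      off <- match(pos, gpos)
      if (is.na(off)) { base$consequence <- "intronic"; return(base) }
      ch <- seq_chars(cds_seq)
      ch[off] <- if (g$strand == "+") alt else revcomp(alt)
      mut_seq <- chars_seq(ch)
      codon_i <- (off - 1L) %/% 3L + 1L
      ref_codon <- substr(cds_seq, 3 * codon_i - 2, 3 * codon_i)
      mut_codon <- substr(mut_seq, 3 * codon_i - 2, 3 * codon_i)
      mut_tr <- translate_to_stop(mut_seq)
      cons <-
        if (codon_aa(mut_codon) == codon_aa(ref_codon)) "synonymous"
        else if (is_stop_codon(mut_codon) && !is_stop_codon(ref_codon)) "nonsense"
        else "nonsynonymous"
      base$consequence <- cons
      base$stop_lost <- is_stop_codon(ref_codon) && !is_stop_codon(mut_codon)
      base$ref_protein_length <- ref_tr$n_aa
      base$mutant_protein_length <- mut_tr$n_aa
      base$no_stop <- !mut_tr$hit_stop
      return(base)
    }

    # indel: the changed run must lie fully inside the CDS, else complex
    run_lo <- pos + 1L
    run_hi <- pos + max(lr, la) - 1L
    covered <- all(run_lo:run_hi %in% gpos) ||
      (la > lr && all(c(pos, pos + 1L) %in% gpos)) # pure insertion point
    del_inside <- lr == 1 || all((pos + 1L):(pos + lr - 1L) %in% gpos)
    if (!covered || !del_inside) { base$consequence <- "complex"; return(base) }

    # rebuild mutant CDS by editing at transcript offsets
    ins <- substr(alt, 2, la)
    del_n <- lr - 1L
    if (g$strand == "+") {
      anchor_off <- match(pos, gpos)
      if (is.na(anchor_off)) { base$consequence <- "complex"; return(base) }
      mut_seq <- paste0(substr(cds_seq, 1, anchor_off), ins,
                        substr(cds_seq, anchor_off + del_n + 1L,
                               nchar(cds_seq)))
    } else {
      # on - strand the genomic run sits downstream in transcript coords
      last_off <- match(pos + 1L, gpos) # transcript offset of run end
      if (is.na(last_off)) { base$consequence <- "complex"; return(base) }
      mut_seq <- paste0(substr(cds_seq, 1, last_off - del_n - 1L),
                        revcomp(ins),
                        substr(cds_seq, last_off, nchar(cds_seq)))
    }
    indel_len <- abs(la - lr)
    mut_tr <- translate_to_stop(mut_seq)
    base$ref_protein_length <- ref_tr$n_aa
    base$mutant_protein_length <- mut_tr$n_aa
    base$no_stop <- !mut_tr$hit_stop
    # an in-frame change is nonsense only if it stops before the mutant
    # CDS's own terminal codon (a premature stop, not the shifted terminus)
    expected_full <- nchar(mut_seq) %/% 3 - 1L
    base$consequence <- if (indel_len %% 3 != 0) "frameshift"
      else if (mut_tr$hit_stop && mut_tr$n_aa < expected_full) "nonsense"
      else "inframe_indel"
    return(base)
  }

  # not in any gene: promoter?
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    win <- if (g$strand == "+") {
      c(max(1L, g$start - promoter_bp), g$start - 1L)
    } else {
      c(g$end + 1L, min(nchar(hap$seq), g$end + promoter_bp))
    }
    if (win[2] >= win[1] && foot_lo <= win[2] && foot_hi >= win[1]) {
      base$gene_id <- g$gene_id
      base$consequence <- "promoter"
      return(base)
    }
  }
  base
}

primer_sites <- function(template, primer, max_mismatch, three_prime_exact,
                         reverse = FALSE) {
  # for a reverse primer the template carries revcomp(primer); the primer's
  # 3' end maps to the LEFT end of that site
  pat <- if (reverse) revcomp(primer) else primer
  w <- nchar(pat)
  n <- nchar(template)
  if (n < w) return(integer(0))
  tv <- seq_chars(template)
  pv <- seq_chars(pat)
  mism <- integer(n - w + 1)
  for (j in seq_len(w)) {
    mism <- mism + (tv[j:(n - w + j)] != pv[j])
  }
  cand <- which(mism <= max_mismatch)
  if (!length(cand) || three_prime_exact <= 0) return(cand)
  keep <- vapply(cand, function(s) {
    idx <- if (reverse) seq_len(three_prime_exact)
           else (w - three_prime_exact + 1L):w
    all(tv[s + idx - 1L] == pv[idx])
  }, TRUE)
  cand[keep]
}

#' In-silico PCR
#'
#' Predicts amplicons for forward/reverse primer pairs on a template. A
#' primer binds where it matches with at most `max_mismatch` internal
#' mismatches and a perfect match over its final `three_prime_exact` 3'
#' bases (mimicking allele-specific PCR selectivity); products up to
#' `max_product` bp are reported. Amplicon length is `end - start + 1`
#' (1-based inclusive).
#'
#' @param template DNA string or `sdr_haplotype`.
#' @param forward named character vector of forward primers (>= 15 bp).
#' @param reverse named character vector of reverse primers.
#' @param max_product maximum product size in bp.
#' @param max_mismatch internal mismatches tolerated per primer.
#' @param three_prime_exact 3'-terminal bases requiring a perfect match.
#' @return tibble: `forward_id`, `reverse_id`, `start`, `end`, `length`.
#'   No product gives an empty tibble.
#' @export
insilico_pcr <- function(template, forward, reverse, max_product = 5000,
                         max_mismatch = 1, three_prime_exact = 3) {
  seq <- if (inherits(template, "sdr_haplotype")) template$seq else toupper(template)
  if (is.null(names(forward))) names(forward) <- paste0("F", seq_along(forward))
  if (is.null(names(reverse))) names(reverse) <- paste0("R", seq_along(reverse))
  if (any(nchar(c(forward, reverse)) < 15)) abort("primers must be >= 15 bp")
  out <- list()
  for (fi in names(forward)) {
    fs <- primer_sites(seq, forward[[fi]], max_mismatch, three_prime_exact)
    if (!length(fs)) next
    for (ri in names(reverse)) {
      rsites <- primer_sites(seq, reverse[[ri]], max_mismatch,
                             three_prime_exact, reverse = TRUE)
      if (!length(rsites)) next
      rend <- rsites + nchar(reverse[[ri]]) - 1L
      for (f in fs) {
        ok <- which(rsites > f + nchar(forward[[fi]]) - 1L &
                    rend - f + 1L <= max_product)
        if (length(ok)) {
          out[[length(out) + 1]] <- tibble(
            forward_id = fi, reverse_id = ri, start = as.integer(f),
            end = as.integer(rend[ok]),
            length = as.integer(rend[ok] - f + 1L))
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(forward_id = character(), reverse_id = character(),
                  start = integer(), end = integer(), length = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Genotype individuals by allele-specific marker products
#'
#' Runs [insilico_pcr()] on the two haplotype templates of each individual
#' and reports which allele-specific products amplify; individuals with
#' both products are heterozygous carriers.
#'
#' @param f1_templates tibble: `individual`, `allele1`, `allele2` (DNA
#'   template strings, one per haplotype).
#' @param forward named character vector of allele-specific forward
#'   primers; @param reverse shared reverse primer(s).
#' @param ... passed to [insilico_pcr()].
#' @return tibble: `individual`, one logical presence column per forward
#'   primer, and `genotype_class` (`heterozygous`, `homozygous_<id>`, or
#'   `no_product`).
#' @export
genotype_by_marker <- function(f1_templates, forward, reverse, ...) {
  purrr::pmap_dfr(f1_templates, function(individual, allele1, allele2, ...) {
    amp <- dplyr::bind_rows(insilico_pcr(allele1, forward, reverse),
                            insilico_pcr(allele2, forward, reverse))
    present <- stats::setNames(names(forward) %in% amp$forward_id,
                               names(forward))
    cls <- if (sum(present) >= 2) "heterozygous"
           else if (sum(present) == 1) paste0("homozygous_", names(which(present)))
           else "no_product"
    dplyr::bind_cols(tibble(individual = individual),
                     as_tibble(as.list(present)),
                     tibble(genotype_class = cls))
  })
}
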