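# Shared fixtures: a reduced simulation (fast) and hand-built haplotypes.

small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, length = 60000, n_genes = 6, cds_codons = 120,
             n_m = 2, n_f = 3, n_h = 2, breakpoint_index = 2,
             frameshift_gene = 4,
             sv_spec = list(
               list(type = "insertion", length = 300, class = "M",
                    region = "5p"),
               list(type = "deletion", length = 400, class = "F",
                    region = "3p")),
             ...)
}

panel_labels <- function(set) {
  tibble::tibble(accession = names(set),
                 sex_class = vapply(set, function(h) h$sex_class, ""))
}

# a single-gene haplotype around a given CDS string (must start ATG and
# end in a stop); flank bp of fixed A's on either side
one_gene_hap <- function(cds, flank = 50, accession = "hap1",
                         sex_class = "H", strand = "+") {
  seq <- paste0(strrep("A", flank), cds, strrep("A", flank))
  g <- gene_model("g1", flank + 1L, flank + nchar(cds), strand,
                  tibble::tibble(start = flank + 1L,
                                 end = flank + nchar(cds), phase = 0L))
  annotated_haplotype(accession, "testus", sex_class, seq, g)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random CDS: ATG + sense codons + stop
rand_cds <- function(n_codons) {
  sense <- setdiff(names(sdrscan:::CODON_TABLE), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# linked-set comparison against simulator truth; returns precision/recall
linkage_vs_truth <- function(sim, link) {
  tr <- sim$truth
  truth_small <- dplyr::bind_rows(
    tr$linked_snvs[, c("pos", "ref", "alt", "linked_class")],
    tr$linked_indel[, c("pos", "ref", "alt", "linked_class")])
  called_small <- link[link$linked_class != "none" &
                       !startsWith(link$var_class, "SV_"),
                       c("pos", "ref", "alt", "linked_class")]
  fp <- nrow(dplyr::anti_join(called_small, truth_small,
                              by = names(truth_small)))
  fn <- nrow(dplyr::anti_join(truth_small, called_small,
                              by = names(truth_small)))
  csv <- link[startsWith(link$var_class, "SV_") &
              link$linked_class != "none", ]
  sv_match <- vapply(seq_len(nrow(tr$linked_svs)), function(i) {
    x <- tr$linked_svs[i, ]
    any(csv$var_class == x$var_class & csv$linked_class == x$linked_class &
        pmin(csv$end, x$end) - pmax(csv$pos, x$pos) >=
          0.8 * pmax(csv$end - csv$pos, x$end - x$pos))
  }, TRUE)
  list(fp_small = fp, fn_small = fn, n_truth_small = nrow(truth_small),
       n_called_small = nrow(called_small),
       sv_recovered = sum(sv_match), sv_truth = nrow(tr$linked_svs),
       sv_called = nrow(csv))
}

# run align + call + classify for a simulated panel
classify_sim_panel <- function(sim, k = 21) {
  set <- sim$haplotypes
  ref <- set[[sim$truth$reference]]
  aligned <- lapply(set[setdiff(names(set), ref$accession)], function(q) {
    align_pair(ref, q, k = k)
  })
  calls <- dplyr::bind_rows(lapply(aligned, call_variants))
  classify_sex_linked(calls, panel_labels(set),
                      lapply(aligned, function(a) a$coverage))
}
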