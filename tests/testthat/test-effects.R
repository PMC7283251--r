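test_that("frameshift deletion truncates translation at the first new stop", {
  # CDS ATG AAA CTA AGG GCC TGA encodes MKLRA (5 aa); deleting the C at CDS
  # position 7 shifts the frame so translation stops in codon 3
  hap <- one_gene_hap("ATGAAACTAAGGGCCTGA", flank = 20)
  v <- tibble::tibble(pos = 26L, ref = "AC", alt = "A")
  e <- annotate_effect(v, hap)
  expect_equal(e$consequence, "frameshift")
  expect_equal(e$ref_protein_length, 5L)
  expect_equal(e$mutant_protein_length, 2L)
})

test_that("SNP consequences follow the code table", {
  # CTA (Leu): third-position changes CTA->CTG are synonymous (4-fold Leu)
  hap <- one_gene_hap("ATGAAACTAAGGGCCTGA", flank = 20)
  syn <- annotate_effect(tibble::tibble(pos = 29L, ref = "A", alt = "G"), hap)
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$mutant_protein_length, syn$ref_protein_length)

  # AAA -> TAA creates a premature stop
  non <- annotate_effect(tibble::tibble(pos = 24L, ref = "A", alt = "T"), hap)
  expect_equal(non$consequence, "nonsense")
  expect_equal(non$mutant_protein_length, 1L)

  # destroy the stop codon -> stop_lost, flagged nonsynonymous
  sl <- annotate_effect(tibble::tibble(pos = 36L, ref = "T", alt = "C"), hap)
  expect_true(sl$stop_lost)
  expect_equal(sl$consequence, "nonsynonymous")
  expect_true(sl$no_stop)
})

test_that("in-frame deletion shortens the protein by one residue", {
  hap <- one_gene_hap("ATGAAACTAAGGGCCTGA", flank = 20)
  # delete CDS positions 7-9 (codon CTA)
  v <- tibble::tibble(pos = 26L, ref = "ACTA", alt = "A")
  e <- annotate_effect(v, hap)
  expect_equal(e$consequence, "inframe_indel")
  expect_equal(e$mutant_protein_length, e$ref_protein_length - 1L)
})

test_that("frameshift parity is exhaustive over indel lengths 1..12", {
  set.seed(30)
  cds <- rand_cds(60)
  hap <- one_gene_hap(cds, flank = 30)
  for (len in 1:12) {
    pos <- 30L + 12L # anchor inside CDS, run within CDS
    del <- tibble::tibble(pos = pos,
                          ref = substr(hap$seq, pos, pos + len), alt = substr(hap$seq, pos, pos))
    e <- annotate_effect(del, hap)
    ins <- tibble::tibble(pos = pos, ref = substr(hap$seq, pos, pos),
                          alt = paste0(substr(hap$seq, pos, pos),
                                       rand_dna(len)))
    e2 <- annotate_effect(ins, hap)
    if (len %% 3 == 0) {
      expect_false(e$consequence == "frameshift")
      expect_false(e2$consequence == "frameshift")
    } else {
      expect_equal(e$consequence, "frameshift")
      expect_equal(e2$consequence, "frameshift")
    }
  }
})

test_that("null variant reproduces the reference annotation", {
  cds <- rand_cds(80)
  hap <- one_gene_hap(cds, flank = 25)
  v <- tibble::tibble(pos = 40L, ref = substr(hap$seq, 40, 40),
                      alt = substr(hap$seq, 40, 40))
  e <- annotate_effect(v, hap)
  expect_equal(e$mutant_protein_length, e$ref_protein_length)
})

test_that("region classification covers promoter, intronic, complex, intergenic", {
  cds <- rand_cds(40)
  seq <- paste0(rand_dna(4000), cds, rand_dna(1000))
  g <- gene_model("g1", 4001L, 4000L + nchar(cds), "+",
                  tibble::tibble(start = 4001L, end = 4000L + nchar(cds),
                                 phase = 0L))
  hap <- annotated_haplotype("h", "sp", "H", seq, g)
  e <- annotate_effect(tibble::tibble(
    pos = c(3500L, 500L, 4000L),
    ref = c("A", "A", substr(seq, 4000, 4010)),
    alt = c("G", "G", substr(seq, 4000, 4000))), hap)
  expect_equal(e$consequence[1], "promoter")
  expect_equal(e$consequence[2], "intergenic")
  expect_equal(e$consequence[3], "complex") # deletion straddles CDS start

  # minus-strand promoter sits downstream of the gene end
  gm <- gene_model("g2", 4001L, 4000L + nchar(cds), "-",
                   tibble::tibble(start = 4001L, end = 4000L + nchar(cds),
                                  phase = 0L))
  hap2 <- annotated_haplotype("h2", "sp", "H", seq, gm)
  e2 <- annotate_effect(tibble::tibble(pos = 4000L + nchar(cds) + 500L,
                                       ref = "A", alt = "G"), hap2)
  expect_equal(e2$consequence, "promoter")
})

test_that("mutant protein lengths match an independent translation oracle", {
  set.seed(31)
  cds <- rand_cds(120)
  hap <- one_gene_hap(cds, flank = 40)
  cds_start <- 41L
  for (i in 1:100) {
    kind <- sample(c("snp", "del", "ins"), 1)
    p <- sample(seq(cds_start + 3L, cds_start + nchar(cds) - 20L), 1)
    v <- switch(kind,
      snp = tibble::tibble(pos = p,
                           ref = substr(hap$seq, p, p),
                           alt = sample(setdiff(c("A", "C", "G", "T"),
                                                substr(hap$seq, p, p)), 1)),
      del = { len <- sample(1:10, 1)
              tibble::tibble(pos = p, ref = substr(hap$seq, p, p + len),
                             alt = substr(hap$seq, p, p)) },
      ins = { len <- sample(1:10, 1)
              tibble::tibble(pos = p, ref = substr(hap$seq, p, p),
                             alt = paste0(substr(hap$seq, p, p),
                                          rand_dna(len))) })
    e <- annotate_effect(v, hap)
    # oracle: apply the edit to the CDS string, translate straight to stop
    mut_genome <- sdrscan:::apply_variants(hap$seq, v)
    mut_cds <- substr(mut_genome, cds_start,
                      cds_start + nchar(cds) - 1L +
                        (nchar(v$alt) - nchar(v$ref)))
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(substr(mut_cds, 1,
                                   3 * (nchar(mut_cds) %/% 3))),
      if.fuzzy.codon = "X")))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    oracle_len <- if (stop_at > 0) as.integer(stop_at) - 1L else nchar(aa)
    expect_equal(e$mutant_protein_length, oracle_len)
  }
})

test_that("in-silico PCR computes product coordinates and lengths", {
  set.seed(32)
  tpl <- rand_dna(1000)
  fw <- substr(tpl, 100, 120)
  rvsite <- substr(tpl, 688, 708)
  rv <- revcomp_str(rvsite)
  amp <- insilico_pcr(tpl, c(f = fw), c(r = rv))
  expect_equal(amp$start, 100L)
  expect_equal(amp$end, 708L)
  expect_equal(amp$length, 609L) # 708 - 100 + 1

  # template lacking the forward site
  expect_equal(nrow(insilico_pcr(strrep("AT", 500), c(f = fw), c(r = rv))), 0)

  # 3' terminal mismatch abolishes binding even within the mismatch budget
  fw_bad <- paste0(substr(fw, 1, 20),
                   setdiff(c("A", "C", "G", "T"), substr(fw, 21, 21))[1])
  expect_equal(nrow(insilico_pcr(tpl, c(f = fw_bad), c(r = rv))), 0)
  # one internal mismatch is tolerated
  fw_int <- fw
  substr(fw_int, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                  substr(fw, 5, 5))[1]
  expect_equal(nrow(insilico_pcr(tpl, c(f = fw_int), c(r = rv))), 1)
})

test_that("allele-specific products track a planted deletion", {
  set.seed(33)
  base <- rand_dna(1200)
  # functional allele = base; deletion allele lacks 8 bp at 600
  del <- paste0(substr(base, 1, 599), substr(base, 608, 1200))
  fw_fun <- substr(base, 592, 612) # spans the 8 bp -> functional-specific
  fw_del <- substr(del, 592, 612)  # spans the new junction -> deletion-specific
  rv <- revcomp_str(substr(base, 1000, 1020))
  fset <- c(fun = fw_fun, del = fw_del)
  expect_setequal(insilico_pcr(base, fset, c(r = rv))$forward_id, "fun")
  expect_setequal(insilico_pcr(del, fset, c(r = rv))$forward_id, "del")

  f1 <- tibble::tibble(individual = c("FF1", "MF1"),
                       allele1 = c(del, base), allele2 = c(del, del))
  gt <- genotype_by_marker(f1, fset, c(r = rv))
  expect_equal(gt$genotype_class,
               c("homozygous_del", "heterozygous"))
})
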