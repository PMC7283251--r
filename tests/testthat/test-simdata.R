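test_that("simulation is deterministic given the seed", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_trio(cfg)
  b <- simulate_trio(cfg)
  expect_identical(lapply(a$haplotypes, `[[`, "seq"),
                   lapply(b$haplotypes, `[[`, "seq"))
  expect_identical(a$truth$linked_snvs, b$truth$linked_snvs)
  expect_identical(a$gene_alignments, b$gene_alignments)
  expect_identical(simulate_f1(cfg), simulate_f1(cfg))
  expect_identical(simulate_expression(cfg)$counts,
                   simulate_expression(cfg)$counts)
  expect_identical(simulate_genotype_matrix(cfg)$dosage,
                   simulate_genotype_matrix(cfg)$dosage)
})

test_that("degenerate rates give identical within-class haplotypes", {
  cfg <- small_sim_config(seed = 3, ds_target = 0, diversity_rate = 0,
                          min_syn_per_gene = 0, nonsyn_per_gene = 0,
                          intergenic_rate_factor = 0)
  sim <- simulate_trio(cfg)
  seqs <- lapply(sim$haplotypes, `[[`, "seq")
  expect_identical(seqs$M01, seqs$M02)
  expect_identical(seqs$F01, seqs$F02)
  expect_identical(seqs$H01, seqs$H02)
  # M vs F differ only by planted events (frameshift + SVs), no SNVs
  expect_equal(nrow(sim$truth$linked_snvs), 0)
  al <- align_pair(sim$haplotypes$F01, sim$haplotypes$M01)
  v <- call_variants(al)
  expect_true(all(v$var_class != "SNP"))
})

test_that("infeasible dS target errors with the required minimum", {
  expect_error(simulate_trio(small_sim_config(seed = 1, ds_target = 3)),
               "infeasible")
})

test_that("truth coordinates are valid and consistent with emitted files", {
  sim <- simulate_trio(small_sim_config(seed = 2))
  ref <- sim$haplotypes[[sim$truth$reference]]
  L <- nchar(ref$seq)
  expect_true(all(sim$truth$linked_snvs$pos >= 1 &
                  sim$truth$linked_snvs$pos <= L))
  # truth ref alleles match the reference sequence
  snv <- sim$truth$linked_snvs
  at <- substring(ref$seq, snv$pos, snv$pos)
  expect_identical(at, snv$ref)
  # breakpoint lies between the flanking genes on the reference
  bp <- sim$truth$breakpoint
  g <- ref$genes
  expect_true(bp$ref_pos > g$end[g$gene_id == bp$left_gene])
  expect_true(bp$ref_pos < g$start[g$gene_id == bp$right_gene])
})

test_that("F1 cross simulation matches its design", {
  cfg <- small_sim_config(seed = 1,
                          f1 = list(n_offspring = 200, sterile_fraction = 0))
  f1 <- simulate_f1(cfg)
  expect_equal(nrow(f1), 200)
  expect_setequal(unique(f1$genotype), c("MF", "FF"))
  expect_equal(cosegregation_report(f1)$concordance, 1)

  cfg0 <- small_sim_config(seed = 1, f1 = list(n_offspring = 0))
  expect_equal(nrow(simulate_f1(cfg0)), 0)

  cfg2 <- small_sim_config(seed = 8,
                           f1 = list(n_offspring = 1000, sterile_fraction = 0,
                                     mislabel_rate = 0.05))
  rep <- cosegregation_report(simulate_f1(cfg2))
  # binomial check: 0.95 +/- 3 sd
  expect_lt(abs(rep$concordance - 0.95), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("genotype matrix r2 follows the block structure", {
  cfg <- small_sim_config(seed = 4,
                          genotypes = list(copy_prob = 1, n_samples = 40,
                                           n_snps = 30, block_snps = 30,
                                           region_length = 40000))
  g <- simulate_genotype_matrix(cfg)
  ld <- ld_track(g, window_bp = 40000, maf_min = 0)
  expect_true(all(abs(ld$median_r2[!is.na(ld$median_r2)] - 1) < 1e-12))

  cfg2 <- small_sim_config(seed = 4,
                           genotypes = list(copy_prob = 0, n_samples = 500,
                                            n_snps = 100, block_snps = 10,
                                            region_length = 20000))
  g2 <- simulate_genotype_matrix(cfg2)
  ld2 <- ld_track(g2, window_bp = 20000, maf_min = 0.05)
  expect_lt(max(ld2$median_r2, na.rm = TRUE), 0.05)
})

test_that("MAF filter removes rare variants from the LD input", {
  dos <- cbind(rep(c(0L, 2L), 10), c(2L, rep(0L, 19)))
  ld <- ld_track(list(pos = c(100L, 200L), dosage = dos), window_bp = 1000,
                 maf_min = 0.05)
  expect_equal(ld$n_snps, 1) # the rare column is gone
})

test_that("all-zero genes are reported untestable", {
  ex <- simulate_expression(small_sim_config(seed = 2))
  counts <- rbind(ex$counts, zero_gene = 0L)
  pc <- sex_pattern_classify(counts, ex$design)
  expect_true(all(pc$pattern[pc$gene == "zero_gene"] == "untestable"))
})

test_that("realized dS matches the target within stochastic tolerance", {
  sim <- simulate_trio(sim_config(seed = 31))
  aln <- sim$gene_alignments
  genes <- setdiff(names(aln), sim$truth$frameshift$gene)
  accs <- names(aln[[1]])
  concat <- vapply(accs, function(a) {
    paste(vapply(genes, function(g) aln[[g]][[a]], ""), collapse = "")
  }, "")
  cls <- vapply(sim$haplotypes, `[[`, "", "sex_class")
  pr <- ds_pairs(concat[names(cls)[cls == "M"]][1:2],
                 concat[names(cls)[cls == "F"]][1:3])
  expect_lt(abs(mean(pr$dS) - 0.0275) / 0.0275, 0.2)
})
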