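test_that("distance models match closed forms and an independent library", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAAAAAAAAA")
  D <- pairwise_distance(aln, "p")
  expect_true(all(D == 0))

  # protein pair with p = 0.1 -> Poisson distance -ln(0.9)
  prot <- c(x = strrep("M", 10), y = paste0(strrep("M", 9), "K"),
            z = strrep("M", 10))
  P <- pairwise_distance(prot, "poisson")
  expect_equal(P["x", "y"], -log(0.9), tolerance = 1e-6)
  expect_equal(P["x", "y"], 0.10536, tolerance = 1e-4)

  # TN93 cross-check against ape on random alignments
  set.seed(41)
  for (rep in 1:3) {
    seqs <- vapply(1:4, function(i) rand_dna(600), "")
    base <- seqs[1]
    seqs <- vapply(seqs, function(s) {
      idx <- sample(600, 40)
      ch <- strsplit(base, "")[[1]]
      for (p in idx) ch[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(ch, collapse = "")
    }, "")
    names(seqs) <- paste0("s", 1:4)
    D1 <- pairwise_distance(seqs, "tn93")
    bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
    for (i in 1:3) for (j in (i + 1):4) {
      # per-pair call so ape estimates frequencies from the same pair
      d_ape <- as.numeric(ape::dist.dna(bin[c(i, j), ], model = "TN93"))
      expect_equal(D1[i, j], d_ape, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("low-coverage columns are eliminated before distances", {
  aln <- c(a = "AC--------", b = "AC--------", c = "AT--------",
           d = "A---------")
  # columns 3..10 have coverage 0 (< 5%) and are dropped; column 2 kept
  D <- pairwise_distance(aln, "p")
  expect_equal(attr(D, "n_sites"), 2L)
  expect_equal(D["a", "c"], 0.5)
  # with a 95% requirement column 2 is dropped too (coverage 3/4)
  D2 <- pairwise_distance(aln, "p", site_coverage = 0.95)
  expect_equal(attr(D2, "n_sites"), 1L)
})

test_that("neighbor joining is exact on additive matrices", {
  # 3 taxa: unique solution of the three-point equations
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D3)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)

  # AB|CD with exact branch lengths
  labs <- c("A", "B", "C", "D")
  D4 <- matrix(3.5, 4, 4, dimnames = list(labs, labs))
  D4["A", "B"] <- D4["B", "A"] <- 2
  D4["C", "D"] <- D4["D", "C"] <- 3
  diag(D4) <- 0
  t4 <- neighbor_joining(D4)
  expect_equal(max(abs(ape::cophenetic.phylo(t4)[labs, labs] - D4)), 0,
               tolerance = 1e-12)

  # random additive trees: topology and branch lengths to 1e-9
  set.seed(42)
  for (n in c(6, 9, 12)) {
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- tr0$edge.length + 0.05
    D <- ape::cophenetic.phylo(tr0)
    rec <- neighbor_joining(D)
    expect_equal(ape::dist.topo(rec, tr0), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)] -
                      D)), 1e-9)
    # independent implementation agrees on the bipartitions
    expect_equal(ape::dist.topo(rec, ape::nj(D)), 0, ignore_attr = TRUE)
  }
})

test_that("NJ is invariant to label order and rejects saturated input", {
  set.seed(43)
  tr0 <- ape::rtree(8, rooted = FALSE)
  D <- ape::cophenetic.phylo(tr0)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)

  aln <- c(a = "ACGT", b = "TGCA", c = "ACGT") # a vs b fully diverged
  D2 <- pairwise_distance(aln, "poisson")
  expect_error(neighbor_joining(D2), "saturated")
})

test_that("bootstrap supports behave at the edges and split deep groups", {
  aln1 <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  bt <- bootstrap_support(aln1, n_reps = 1, seed = 1)
  expect_true(all(bt$node.label %in% c("", "0", "1")))

  set.seed(44)
  g1 <- rand_dna(500)
  g2 <- local({ # ~120 substitutions away
    ch <- strsplit(g1, "")[[1]]
    for (p in sample(500, 120)) ch[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  })
  jitter <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(500, k)) ch[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }
  aln <- c(a1 = jitter(g1, 3), a2 = jitter(g1, 3), a3 = jitter(g1, 3),
           b1 = jitter(g2, 3), b2 = jitter(g2, 3), b3 = jitter(g2, 3))
  bt2 <- bootstrap_support(aln, model = "p", n_reps = 100, seed = 2)
  lab <- tibble::tibble(accession = names(aln),
                        sex_class = c("M", "M", "M", "F", "F", "F"))
  res <- sex_clade_test(bt2, lab)
  expect_gte(res$support, 0.99)
})

test_that("sex-monophyly verdicts follow exclusive bipartitions", {
  tr <- ape::read.tree(text = "((M1:1,M2:1):1,(F1:1,(F2:1,H1:1):1):1);")
  labs <- tibble::tibble(accession = c("M1", "M2", "F1", "F2", "H1"),
                         sex_class = c("M", "M", "F", "F", "H"))
  expect_equal(sex_clade_test(tr, labs)$verdict, "M_separated")

  tr2 <- ape::read.tree(text = "((M1:1,F1:1):1,(M2:1,F2:1):1);")
  labs2 <- tibble::tibble(accession = c("M1", "M2", "F1", "F2"),
                          sex_class = c("M", "M", "F", "F"))
  expect_equal(sex_clade_test(tr2, labs2)$verdict, "none")
  expect_error(sex_clade_test(tr, labs[1:3, ]), "label")
})

test_that("breakpoint changepoint minimises mismatches over all cuts", {
  pat <- function(v) tibble::tibble(gene_id = sprintf("g%02d", seq_along(v)),
                                    verdict = v)
  b1 <- locate_breakpoint(pat(c(rep("M_separated", 4),
                                rep("F_separated", 6))))
  expect_equal(b1$cut_index, 4L)
  expect_equal(b1$mismatches, 0)
  expect_false(b1$ambiguous)

  v2 <- c("M_separated", "M_separated", "none", "M_separated",
          "F_separated", "F_separated")
  b2 <- locate_breakpoint(pat(v2))
  # independent brute force over all 7 cuts
  cost <- vapply(0:6, function(cut) {
    lhs <- sum(c(F_separated = 1, none = 0.5,
                 M_separated = 0)[v2[seq_len(cut)]], na.rm = TRUE)
    rhs <- if (cut < 6) sum(c(F_separated = 0, none = 0.5,
                              M_separated = 1)[v2[(cut + 1):6]]) else 0
    lhs + rhs
  }, 0)
  expect_equal(b2$cut_index, which(cost == min(cost)) - 1L)
  expect_equal(unique(b2$mismatches), 0.5)
  expect_equal(b2$cut_index, 4L)

  b3 <- locate_breakpoint(pat(rep("F_separated", 5)))
  expect_equal(b3$cut_index, 0L)
  expect_true(is.na(b3$left_gene))
  expect_error(locate_breakpoint(pat("M_separated")), ">= 2")
})

test_that("per-gene patterns on a simulated panel match the planted truth", {
  sim <- simulate_trio(small_sim_config(seed = 9))
  pat <- clade_patterns(sim$gene_alignments, panel_labels(sim$haplotypes))
  expect_equal(pat$verdict, sim$truth$clade_pattern$verdict)
  bp <- locate_breakpoint(pat)
  expect_equal(bp$left_gene[1], sim$truth$breakpoint$left_gene)
  expect_equal(bp$right_gene[1], sim$truth$breakpoint$right_gene)
})
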