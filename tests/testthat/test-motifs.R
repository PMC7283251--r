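mk_pfm <- function(consensus, id = "m1") {
  W <- nchar(consensus)
  m <- matrix(0, 4, W, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(W)) m[substr(consensus, j, j), j] <- 10
  attr(m, "motif_id") <- id
  m
}

test_that("promoter windows are strand-aware and clipped at sequence ends", {
  seq <- rand_dna(8000)
  g <- dplyr::bind_rows(
    gene_model("gp", 5000L, 5600L, "+",
               tibble::tibble(start = 5000L, end = 5599L, phase = 0L),
               partial = TRUE),
    gene_model("gn", 2000L, 2600L, "-",
               tibble::tibble(start = 2000L, end = 2599L, phase = 0L),
               partial = TRUE),
    gene_model("gedge", 1000L, 1500L, "+",
               tibble::tibble(start = 1000L, end = 1499L, phase = 0L),
               partial = TRUE))
  hap <- annotated_haplotype("h", "sp", "H", seq, g)
  prom <- extract_promoters(hap, window = 3000)
  pp <- prom[prom$gene_id == "gp", ]
  expect_equal(c(pp$start, pp$end), c(2000L, 4999L))
  expect_equal(pp$sequence, substr(seq, 2000, 4999))
  pe <- prom[prom$gene_id == "gedge", ]
  expect_equal(c(pe$start, pe$end), c(1L, 999L)) # truncated at the start
  pn <- prom[prom$gene_id == "gn", ]
  expect_equal(c(pn$start, pn$end), c(2601L, 5600L))
  expect_equal(pn$sequence, revcomp_str(substr(seq, 2601, 5600)))
})

test_that("PWM scanning scores the consensus at exactly 1", {
  set.seed(81)
  pwm <- pwm_from_pfm(mk_pfm("ACGTAT"))
  expect_gt(attr(pwm, "max_score"), attr(pwm, "min_score"))
  prom <- paste0(strrep("G", 30), "ACGTAT", strrep("G", 30))
  hits <- scan_pwm(prom, pwm, threshold = 0.99)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 31L)
  expect_equal(hits$rel_score, 1)
  expect_equal(hits$strand, "+")

  # threshold 1 plus one mismatch from consensus: no hit
  prom2 <- paste0(strrep("G", 30), "ACGAAT", strrep("G", 30))
  expect_equal(nrow(scan_pwm(prom2, pwm, threshold = 1)), 0)

  # planted on the minus strand
  prom3 <- paste0(strrep("G", 20), revcomp_str("ACGTAT"), strrep("G", 24))
  h3 <- scan_pwm(prom3, pwm, threshold = 0.99)
  expect_equal(h3$strand, "-")
  expect_equal(c(h3$start, h3$end), c(21L, 26L))
})

test_that("scanning the reverse complement mirrors hits exactly", {
  set.seed(82)
  pwm <- pwm_from_pfm(mk_pfm("ACGTGA"))
  prom <- rand_dna(500)
  fwd <- scan_pwm(prom, pwm, threshold = 0.8)
  rev <- scan_pwm(revcomp_str(prom), pwm, threshold = 0.8)
  L <- nchar(prom)
  mirrored <- tibble::tibble(start = L - rev$end + 1L, end = L - rev$start + 1L,
                             strand = ifelse(rev$strand == "+", "-", "+"),
                             rel_score = rev$rel_score)
  expect_equal(dplyr::arrange(fwd[, c("start", "end", "strand", "rel_score")],
                              start, strand),
               dplyr::arrange(mirrored, start, strand))
  expect_true(all(fwd$rel_score >= 0.8 & fwd$rel_score <= 1))
})

test_that("hit counts on random sequence match the analytic exceedance rate", {
  set.seed(83)
  pwm <- pwm_from_pfm(mk_pfm("ACGTA"))
  # exact per-window exceedance probability by enumerating all 4^5 windows
  W <- 5
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), W), stringsAsFactors = FALSE)
  lo <- unclass(pwm)
  scores <- rowSums(mapply(function(j) {
    lo[cbind(match(grid[[j]], rownames(lo)), j)]
  }, seq_len(W)))
  rel <- (scores - attr(pwm, "min_score")) /
    (attr(pwm, "max_score") - attr(pwm, "min_score"))
  p_hit <- mean(rel >= 0.85)
  n <- 20000
  hits <- scan_pwm(rand_dna(n), pwm, threshold = 0.85)
  expected <- 2 * (n - W + 1) * p_hit # both strands
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected))
})

test_that("motif presence/absence follows the strict linkage rule", {
  labs <- tibble::tibble(accession = c("M1", "M2", "F1", "F2", "H1"),
                         sex_class = c("M", "M", "F", "F", "H"))
  hits <- tibble::tibble(accession = c("M1", "M2", "H1"),
                         gene_id = "g1", motif_id = "m1")
  res <- sex_linked_motifs(hits, labs)
  expect_equal(res$linkage, "absent_in_F")

  hits2 <- tibble::tibble(accession = "M1", gene_id = "g1", motif_id = "m1")
  expect_equal(sex_linked_motifs(hits2, labs)$linkage, "none")

  hits3 <- tibble::tibble(accession = c("M1", "M2"), gene_id = "g1",
                          motif_id = "m1")
  expect_equal(sex_linked_motifs(hits3, labs)$linkage, "present_in_M")
})

test_that("planted class-specific promoter motifs are recovered exactly", {
  # build a mini panel: same promoter backbone, motif planted in M+H only
  set.seed(84)
  backbone <- rand_dna(600)
  plant <- function(s, motif, at) {
    paste0(substr(s, 1, at - 1), motif, substr(s, at + nchar(motif), nchar(s)))
  }
  cds <- rand_cds(40)
  mk <- function(acc, cls, with_motif) {
    prom <- if (with_motif) plant(backbone, "TTACGTAA", 300) else backbone
    seq <- paste0(prom, cds, strrep("A", 50))
    g <- gene_model("g1", 601L, 600L + nchar(cds), "+",
                    tibble::tibble(start = 601L, end = 600L + nchar(cds),
                                   phase = 0L))
    annotated_haplotype(acc, "sp", cls, seq, g)
  }
  panel <- list(mk("M1", "M", TRUE), mk("M2", "M", TRUE),
                mk("F1", "F", FALSE), mk("F2", "F", FALSE),
                mk("H1", "H", TRUE))
  labs <- tibble::tibble(accession = c("M1", "M2", "F1", "F2", "H1"),
                         sex_class = c("M", "M", "F", "F", "H"))
  pwm <- pwm_from_pfm(mk_pfm("TTACGTAA"))
  hits <- purrr::map_dfr(panel, function(h) {
    prom <- extract_promoters(h, window = 600)
    dplyr::mutate(scan_pwm(prom$sequence[1], pwm, threshold = 0.95),
                  accession = h$accession, gene_id = "g1")
  })
  res <- sex_linked_motifs(hits, labs)
  expect_equal(res$linkage, "absent_in_F")
})
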