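test_that("identity alignment yields one full-length anchor and no calls", {
  set.seed(10)
  s <- rand_dna(20000)
  al <- align_pair(s, s)
  expect_equal(nrow(al$chain), 1)
  expect_equal(al$chain$ref_start, 1)
  expect_equal(al$chain$ref_end, 20000)
  expect_equal(nrow(call_variants(al)), 0)
  expect_equal(al$coverage$start, 1)
  expect_equal(al$coverage$end, 20000)
})

test_that("a single substitution produces exactly one SNP at that position", {
  set.seed(11)
  s <- rand_dna(10000)
  q <- s
  substr(q, 5000, 5000) <- if (substr(s, 5000, 5000) == "A") "C" else "A"
  al <- align_pair(s, q)
  expect_equal(nrow(al$chain), 2) # two anchors flanking a 1 bp gap
  v <- call_variants(al)
  expect_equal(nrow(v), 1)
  expect_equal(v$var_class, "SNP")
  expect_equal(v$pos, 5000)
  expect_equal(v$ref, substr(s, 5000, 5000))
  expect_equal(v$alt, substr(q, 5000, 5000))
})

test_that("planted indels and SVs are called with correct class and length", {
  set.seed(12)
  s <- rand_dna(60000)
  # 8 bp deletion at 10000, large insertion at 30000
  ins <- rand_dna(22600)
  q <- paste0(substr(s, 1, 9999), substr(s, 10008, 30000), ins,
              substr(s, 30001, 60000))
  al <- align_pair(s, q)
  v <- call_variants(al)
  sm <- v[v$var_class == "small_indel", ]
  expect_equal(nrow(sm), 1)
  expect_equal(sm$length, 8L)
  expect_equal(nchar(sm$ref) - nchar(sm$alt), 8L)
  sv <- v[v$var_class == "SV_insertion", ]
  expect_equal(nrow(sv), 1)
  expect_equal(sv$sv_len, 22600L)
})

test_that("a reverse-complemented block is detected as an inversion", {
  set.seed(13)
  s <- rand_dna(40000)
  mid <- revcomp_str(substr(s, 20001, 25000))
  q <- paste0(substr(s, 1, 20000), mid, substr(s, 25001, 40000))
  al <- align_pair(s, q)
  v <- call_variants(al)
  inv <- v[v$var_class == "SV_inversion", ]
  expect_equal(nrow(inv), 1)
  expect_lt(abs(inv$pos - 20000), 50)
  expect_lt(abs(inv$sv_len - 5000), 100)
})

test_that("reconstruction: applying calls to the reference restores the query", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- rand_dna(8000)
    q <- s
    # plant substitutions and a small indel, well separated
    for (p in seq(500, 7000, by = 650)) {
      substr(q, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, p, p))[sample(3, 1)]
    }
    q <- paste0(substr(q, 1, 3200), substr(q, 3206, nchar(q))) # 5 bp del
    al <- align_pair(s, q)
    v <- call_variants(al)
    expect_identical(sdrscan:::apply_variants(s, v), q)
  }
})

test_that("insertions and deletions are symmetric under swapping", {
  set.seed(14)
  s <- rand_dna(20000)
  q <- paste0(substr(s, 1, 8000), rand_dna(900), substr(s, 8001, 20000))
  v1 <- call_variants(align_pair(s, q))
  v2 <- call_variants(align_pair(q, s))
  expect_equal(v1$var_class[v1$sv_len == 900], "SV_insertion")
  expect_equal(v2$var_class[v2$sv_len == 900], "SV_deletion")
  expect_equal(v1$sv_len[!is.na(v1$sv_len)], v2$sv_len[!is.na(v2$sv_len)])
})

test_that("SNP calls agree with a full global-alignment oracle on short pairs", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    s <- rand_dna(1500)
    q <- s
    pos <- sort(sample(50:1450, 12))
    for (p in pos) {
      substr(q, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, p, p))[sample(3, 1)]
    }
    v <- call_variants(align_pair(s, q, k = 15))
    # oracle: Needleman-Wunsch via Biostrings on the whole pair
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(s), type = "global")
    mt <- Biostrings::mismatchTable(al)
    expect_setequal(v$pos[v$var_class == "SNP"], mt$SubjectStart)
    expect_equal(nrow(v), nrow(mt))
  }
})

test_that("runs of N are left unaligned and excluded from coverage", {
  set.seed(15)
  s <- rand_dna(20000)
  q <- s
  substr(q, 9990, 10010) <- strrep("N", 21)
  al <- align_pair(s, q)
  expect_true(any(al$events$kind == "unaligned"))
  expect_false(any(al$coverage$start <= 10000 & al$coverage$end >= 10000))
})

test_that("marker localization reports intervals and identities", {
  set.seed(16)
  s <- rand_dna(60000)
  m1 <- substr(s, 1001, 1021)
  m2 <- substr(s, 50001, 50021)
  m3 <- m2
  substr(m3, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(m3, 11, 11))[1]
  hits <- locate_markers(s, tibble::tibble(id = c("a", "b", "c"),
                                           sequence = c(m1, m2, m3)))
  expect_equal(hits$start[1], 1001)
  expect_equal(hits$end[1], 1021)
  expect_equal(hits$identity[1], 100)
  expect_equal(hits$identity[3], 100 * 20 / 21, tolerance = 1e-6)

  # random marker absent from the sequence
  rnd <- tibble::tibble(id = "r", sequence = rand_dna(21))
  h <- locate_markers(strrep("AC", 5000), rnd)
  expect_true(is.na(h$start))

  # flanking-marker region
  reg <- region_by_flanking_markers(hits[1:2, ])
  expect_equal(reg$start, 1001)
  expect_equal(reg$end, 50021)
  expect_error(region_by_flanking_markers(hits[1, , drop = FALSE]), ">= 2")
  reg2 <- region_by_flanking_markers(hits[1:2, ], pad = 5000,
                                     seq_length = 52000)
  expect_equal(reg2$start, 1)
  expect_equal(reg2$end, 52000)
  expect_error(locate_markers(s, tibble::tibble(id = "x", sequence = "ACGT")),
               ">= 15")
})
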