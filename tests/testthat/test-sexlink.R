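mk_calls <- function(acc, pos, ref = "A", alt = "G", class = "SNP",
                     sv_len = NA_integer_) {
  tibble::tibble(accession = acc, pos = pos, ref = ref, alt = alt,
                 var_class = class, length = 1L, sv_len = sv_len)
}

panel <- tibble::tibble(
  accession = c("M1", "M2", "M3", paste0("F", 1:4), paste0("H", 1:2)),
  sex_class = c(rep("M", 3), rep("F", 4), rep("H", 2)))

test_that("strict fixation rule is definitional", {
  calls <- mk_calls(c("M1", "M2", "M3"), 100L)
  res <- classify_sex_linked(calls, panel)
  expect_equal(res$linked_class, "M")
  expect_true(res$callable)

  # present additionally in one H -> none
  calls2 <- mk_calls(c("M1", "M2", "M3", "H1"), 100L)
  expect_equal(classify_sex_linked(calls2, panel)$linked_class, "none")

  # missing one M carrier -> none
  calls3 <- mk_calls(c("M1", "M2"), 100L)
  expect_equal(classify_sex_linked(calls3, panel)$linked_class, "none")

  expect_error(classify_sex_linked(
    calls, tibble::tibble(accession = "X1", sex_class = "Z")), "unknown sex")
})

test_that("uncovered sites are uncallable and never linked", {
  calls <- mk_calls(c("M1", "M2", "M3"), 100L)
  cov <- list(F1 = tibble::tibble(start = 500L, end = 900L))
  res <- classify_sex_linked(calls, panel, coverage = cov)
  expect_false(res$callable)
  expect_equal(res$linked_class, "none")
})

test_that("multi-allelic sites classify each alt independently", {
  calls <- dplyr::bind_rows(mk_calls(c("M1", "M2", "M3"), 100L, alt = "G"),
                            mk_calls(c("F1", "F2", "F3", "F4"), 100L,
                                     alt = "T"))
  res <- classify_sex_linked(calls, panel)
  expect_setequal(res$linked_class, c("M", "F"))
})

test_that("adding haplotypes can only shrink or preserve the linked set", {
  set.seed(21)
  for (rep in 1:20) {
    accs <- panel$accession
    calls <- purrr::map_dfr(1:15, function(i) {
      mk_calls(sample(accs, sample(9, 1)), i * 10L)
    })
    base <- classify_sex_linked(calls, panel)
    linked0 <- base$pos[base$linked_class != "none"]
    # add one more haplotype (possibly carrying some variants)
    panel2 <- dplyr::bind_rows(panel, tibble::tibble(accession = "X9",
                                                     sex_class = "F"))
    extra <- mk_calls("X9", sample(seq(10, 150, 10), 5))
    after <- classify_sex_linked(dplyr::bind_rows(calls, extra), panel2)
    linked1 <- after$pos[after$linked_class != "none"]
    expect_true(all(linked1 %in% linked0))
    # no variant is ever both M- and F-linked
    key <- paste(after$pos, after$ref, after$alt)
    expect_false(any(duplicated(key[after$linked_class != "none"])))
  }
})

test_that("label permutation destroys linkage on diverged panels", {
  sim <- simulate_trio(small_sim_config(seed = 6))
  link <- classify_sim_panel(sim)
  n_true <- sum(link$linked_class != "none")
  expect_gt(n_true, 50)
  set.seed(99)
  labs <- panel_labels(sim$haplotypes)
  perm <- labs
  perm$sex_class <- sample(perm$sex_class)
  # reuse the same calls/coverage by rebuilding them once
  set <- sim$haplotypes
  ref <- set[[sim$truth$reference]]
  aligned <- lapply(set[setdiff(names(set), ref$accession)],
                    function(q) align_pair(ref, q))
  calls <- dplyr::bind_rows(lapply(aligned, call_variants))
  cov <- lapply(aligned, function(a) a$coverage)
  n_perm <- mean(replicate(5, {
    perm$sex_class <- sample(perm$sex_class)
    sum(classify_sex_linked(calls, perm, cov)$linked_class != "none")
  }))
  expect_lt(n_perm, 0.05 * n_true)
})

test_that("density tracks count classified SNPs per window", {
  calls <- classify_sex_linked(
    mk_calls(rep(c("M1", "M2", "M3"), 10), rep(1:10 * 10L, each = 3)),
    panel)
  # all 30 carrier rows collapse to 10 distinct M-linked SNPs in window 1
  tr <- density_track(calls, region = c(1L, 3000L), window_bp = 1000)
  m <- tr[tr$linked_class == "M", ]
  expect_equal(m$n[1], 10)
  expect_equal(m$per_kbp[1], 10)
  expect_true(all(m$n[-1] == 0))
  expect_equal(sum(tr$n), sum(calls$linked_class %in% c("M", "F")))

  empty <- density_track(calls[0, ], region = c(1L, 5000L), window_bp = 1000)
  expect_true(all(empty$n == 0))
  expect_error(density_track(calls, region = c(1L, 100L), window_bp = 0),
               "window")
})

test_that("SV sharing follows reciprocal overlap and the strict rule", {
  svs <- tibble::tibble(
    accession = c("F1", "F2", "F3", "F4"),
    pos = c(1000L, 1010L, 1000L, 1005L),
    ref = "N", alt = "N", var_class = "SV_deletion", length = 3000L,
    sv_len = c(3000L, 2990L, 3000L, 3001L))
  tab <- sv_sharing_table(svs, panel)
  expect_equal(nrow(tab), 1) # one cluster (reciprocal overlap ~0.99)
  expect_equal(tab$linked_class, "F")
  expect_equal(tab$n_F, 4)

  # two deletions with ~0.9 reciprocal overlap form one cluster
  svs2 <- tibble::tibble(accession = c("F1", "F2"),
                         pos = c(1000L, 1300L), ref = "N", alt = "N",
                         var_class = "SV_deletion", length = 3000L,
                         sv_len = 3000L)
  expect_equal(nrow(sv_sharing_table(svs2, panel)), 1)
  # disjoint deletions stay separate
  svs3 <- dplyr::mutate(svs2, pos = c(1000L, 9000L))
  expect_equal(nrow(sv_sharing_table(svs3, panel)), 2)

  # composition tag from a repeat annotation
  tab2 <- sv_sharing_table(svs, panel,
                           repeats = tibble::tibble(start = 900L,
                                                    end = 4100L))
  expect_equal(tab2$composition, "repeat")
})
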