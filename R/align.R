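#' Pairwise whole-haplotype alignment
#'
#' Aligns a query haplotype to a reference with a seed-and-chain strategy:
#' k-mers unique in both sequences are merged into maximal exact-match
#' anchors (mirroring unique-match seeding), the maximal-scoring colinear
#' chain is selected by weighted longest-increasing-subsequence chaining,
#' and inter-anchor gaps are resolved at base level with affine-gap global
#' alignment. Gaps too large for base-level alignment are deferred to
#' structural-variant calling; reverse-orientation anchor blocks are used to
#' detect inversions. Windows containing `N` in either haplotype are left
#' unaligned and reported as uncallable.
#'
#' @param reference,query `sdr_haplotype` objects (or plain sequences).
#' @param k anchor k-mer size (>= 15; default 21).
#' @param gap_max largest inter-anchor gap aligned at base level (bp).
#' @param scores match/mismatch/gap-open/gap-extend scores for gap
#'   alignment.
#' @return an `sdr_alignment` object with the anchor chain, base-aligned
#'   differences, structural events and the callable-coverage intervals on
#'   the reference.
#' @export
align_pair <- function(reference, query, k = 21, gap_max = 20000,
                       scores = c(match = 1, mismatch = -2,
                                  gap_open = -5, gap_ext = -1)) {
  if (k < 15) abort("k must be >= 15")
  ref_id <- if (inherits(reference, "sdr_haplotype")) reference$accession else "ref"
  qry_id <- if (inherits(query, "sdr_haplotype")) query$accession else "qry"
  rs <- if (inherits(reference, "sdr_haplotype")) reference$seq else toupper(reference)
  qs <- if (inherits(query, "sdr_haplotype")) query$seq else toupper(query)
  if (!nzchar(rs) || !nzchar(qs)) abort("empty sequence")

  fwd <- find_anchors_cpp(rs, qs, k)
  rev <- find_anchors_cpp(rs, revcomp_cpp(qs), k)
  out <- structure(list(ref_id = ref_id, qry_id = qry_id,
                        ref_seq = rs, qry_seq = qs, k = k,
                        unalignable = FALSE),
                   class = "sdr_alignment")
  if (nrow(fwd) == 0) {
    out$unalignable <- TRUE
    out$chain <- tibble(ref_start = integer(), ref_end = integer(),
                        qry_start = integer(), qry_end = integer())
    out$variants_raw <- tibble(pos = integer(), ref = character(),
                               alt = character())
    out$events <- tibble(ref_start = integer(), ref_end = integer(),
                         qry_start = integer(), qry_end = integer(),
                         kind = character())
    out$coverage <- tibble(start = integer(), end = integer())
    return(out)
  }
  idx <- chain_anchors_cpp(fwd$ref_start, fwd$qry_start, fwd$length)
  ch <- fwd[idx, , drop = FALSE]
  # trim small overlaps left by junction-ambiguous anchors
  if (nrow(ch) > 1) {
    for (i in 2:nrow(ch)) {
      ov <- max(ch$ref_start[i - 1] + ch$length[i - 1] - ch$ref_start[i],
                ch$qry_start[i - 1] + ch$length[i - 1] - ch$qry_start[i], 0L)
      if (ov > 0) {
        ch$ref_start[i] <- ch$ref_start[i] + ov
        ch$qry_start[i] <- ch$qry_start[i] + ov
        ch$length[i] <- ch$length[i] - ov
      }
    }
    ch <- ch[ch$length > 0, , drop = FALSE]
  }
  # 1-based inclusive anchor intervals
  chain <- tibble(ref_start = ch$ref_start + 1L,
                  ref_end = ch$ref_start + ch$length,
                  qry_start = ch$qry_start + 1L,
                  qry_end = ch$qry_start + ch$length)

  qlen <- nchar(qs); rlen <- nchar(rs)
  # rev anchors mapped back to original query coordinates (1-based)
  rev_tbl <- tibble(ref_start = rev$ref_start + 1L,
                    ref_end = rev$ref_start + rev$length,
                    qry_start = qlen - (rev$qry_start + rev$length) + 1L,
                    qry_end = qlen - rev$qry_start,
                    length = rev$length)

  n <- nrow(chain)
  gaps <- tibble(
    ref_start = c(1L, chain$ref_end + 1L),
    ref_end = c(chain$ref_start - 1L, rlen),
    qry_start = c(1L, chain$qry_end + 1L),
    qry_end = c(chain$qry_start - 1L, qlen))

  snps <- list(); indels <- list(); events <- list()
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    rl <- g$ref_end - g$ref_start + 1L
    ql <- g$qry_end - g$qry_start + 1L
    if (rl <= 0 && ql <= 0) next
    rg <- if (rl > 0) seq_sub(rs, g$ref_start, g$ref_end) else ""
    qg <- if (ql > 0) seq_sub(qs, g$qry_start, g$qry_end) else ""
    if (grepl("N", rg, fixed = TRUE) || grepl("N", qg, fixed = TRUE)) {
      events[[length(events) + 1]] <- dplyr::mutate(g, kind = "unaligned")
      next
    }
    diff <- ql - rl
    # reverse-orientation blocks take precedence over base-level alignment
    inverted <- FALSE
    if (rl > 50 && ql > 50) {
      hit <- rev_tbl[rev_tbl$ref_start >= g$ref_start &
                     rev_tbl$ref_end <= g$ref_end &
                     rev_tbl$qry_start >= g$qry_start &
                     rev_tbl$qry_end <= g$qry_end, ]
      inverted <- nrow(hit) > 0 && sum(hit$length) / min(rl, ql) >= 0.5
    }
    if (inverted) {
      events[[length(events) + 1]] <- dplyr::mutate(g, kind = "sv_inversion")
    } else if (rl <= 0 || ql <= 0) {
      indels[[length(indels) + 1]] <-
        list(pos0 = g$ref_start - 2L, rseq = rg, qseq = qg)
    } else if (abs(diff) <= 50 && max(rl, ql) <= gap_max &&
               as.double(rl) * ql <= 2.5e7) {
      aln <- nw_align_cpp(rg, qg, scores[["match"]], scores[["mismatch"]],
                          scores[["gap_open"]], scores[["gap_ext"]])
      d <- collect_diffs_cpp(aln$a, aln$b, g$ref_start - 1L, g$qry_start - 1L)
      if (nrow(d$snp)) snps[[length(snps) + 1]] <- d$snp
      di <- d$indel
      for (j in seq_along(di$pos0)) {
        indels[[length(indels) + 1]] <-
          list(pos0 = di$pos0[j], rseq = di$rseq[j], qseq = di$qseq[j])
      }
    } else if (diff > 50 && rl <= 50) {
      events[[length(events) + 1]] <- dplyr::mutate(g, kind = "sv_insertion")
    } else if (-diff > 50 && ql <= 50) {
      events[[length(events) + 1]] <- dplyr::mutate(g, kind = "sv_deletion")
    } else {
      kind <- if (abs(diff) > 50) "sv_complex" else "unaligned"
      events[[length(events) + 1]] <- dplyr::mutate(g, kind = kind)
    }
  }

  raw_snp <- if (length(snps)) dplyr::bind_rows(snps) else
    tibble(pos0 = integer(), ref = character(), alt = character())
  vr <- tibble(pos = raw_snp$pos0 + 1L, ref = raw_snp$ref, alt = raw_snp$alt)
  if (length(indels)) {
    ind <- purrr::map_dfr(indels, function(x) {
      pos1 <- x$pos0 + 1L
      if (pos1 >= 1) {
        anchor <- seq_sub(rs, pos1, pos1)
        tibble(pos = pos1, ref = paste0(anchor, x$rseq),
               alt = paste0(anchor, x$qseq))
      } else {
        # event at the very start: right-anchor on the following ref base
        nxt <- nchar(x$rseq) + 1L
        anchor <- seq_sub(rs, nxt, nxt)
        tibble(pos = 1L, ref = paste0(x$rseq, anchor),
               alt = paste0(x$qseq, anchor))
      }
    })
    vr <- dplyr::bind_rows(vr, ind)
  }
  out$chain <- chain
  out$variants_raw <- dplyr::arrange(vr, .data$pos)
  out$events <- if (length(events)) dplyr::bind_rows(events) else
    tibble(ref_start = integer(), ref_end = integer(),
           qry_start = integer(), qry_end = integer(), kind = character())
  cov <- dplyr::bind_rows(
    tibble(start = chain$ref_start, end = chain$ref_end),
    { ag <- gaps[, c("ref_start", "ref_end")]
      names(ag) <- c("start", "end"); ag[ag$end >= ag$start, ] },
    tibble(start = integer(), end = integer()))
  # unaligned events are not callable
  una <- out$events[out$events$kind == "unaligned", ]
  out$coverage <- subtract_intervals(merge_intervals(cov),
                                     una[, c("ref_start", "ref_end")])
  out
}

#' @export
print.sdr_alignment <- function(x, ...) {
  cat(sprintf("<sdr_alignment> %s vs %s: %d chained anchors, %d raw diffs, %d events%s\n",
              x$qry_id, x$ref_id, nrow(x$chain), nrow(x$variants_raw),
              nrow(x$events), if (x$unalignable) " [UNALIGNABLE]" else ""))
  invisible(x)
}

merge_intervals <- function(x) {
  x <- x[order(x$start), , drop = FALSE]
  if (nrow(x) < 2) return(as_tibble(x))
  start <- x$start[1]; end <- x$end[1]
  os <- integer(0); oe <- integer(0)
  for (i in 2:nrow(x)) {
    if (x$start[i] <= end + 1L) end <- max(end, x$end[i])
    else { os <- c(os, start); oe <- c(oe, end); start <- x$start[i]; end <- x$end[i] }
  }
  tibble(start = c(os, start), end = c(oe, end))
}

subtract_intervals <- function(x, drop) {
  if (!nrow(drop) || !nrow(x)) return(x)
  names(drop) <- c("start", "end")
  for (i in seq_len(nrow(drop))) {
    keep <- list()
    for (j in seq_len(nrow(x))) {
      s <- x$start[j]; e <- x$end[j]
      ds <- drop$start[i]; de <- drop$end[i]
      if (de < s || ds > e) { keep[[length(keep) + 1]] <- tibble(start = s, end = e); next }
      if (ds > s) keep[[length(keep) + 1]] <- tibble(start = s, end = ds - 1L)
      if (de < e) keep[[length(keep) + 1]] <- tibble(start = de + 1L, end = e)
    }
    x <- if (length(keep)) dplyr::bind_rows(keep) else
      tibble(start = integer(), end = integer())
  }
  x
}

in_intervals <- function(pos, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(iv$start <= p & iv$end >= p), TRUE)
}

#' Extract variant calls from a pairwise alignment
#'
#' Mismatches within 1-to-1 aligned blocks become SNPs; alignment gaps of up
#' to 50 bp become small INDELs (left-aligned against the reference);
#' larger events become structural variants (insertion, deletion, inversion
#' or complex). Exactly-50 bp events are classed as small INDELs.
#'
#' @param alignment an `sdr_alignment` from [align_pair()].
#' @return a tibble with columns `accession`, `pos` (1-based on the
#'   reference), `ref`, `alt`, `var_class`, `length` and `sv_len`.
#' @export
call_variants <- function(alignment) {
  stopifnot(inherits(alignment, "sdr_alignment"))
  rs <- alignment$ref_seq; qs <- alignment$qry_seq
  v <- alignment$variants_raw
  rows <- list()
  if (nrow(v)) {
    lr <- nchar(v$ref); la <- nchar(v$alt)
    snp <- lr == 1 & la == 1
    if (any(snp)) {
      rows[[length(rows) + 1]] <- tibble(
        pos = v$pos[snp], ref = v$ref[snp], alt = v$alt[snp],
        var_class = "SNP", length = 1L, sv_len = NA_integer_)
    }
    if (any(!snp)) {
      ind <- v[!snp, ]
      norm <- purrr::pmap_dfr(ind, function(pos, ref, alt) {
        nz <- left_normalize_indel(rs, pos, ref, alt)
        tibble(pos = nz$pos1, ref = nz$ref, alt = nz$alt)
      })
      diff <- abs(nchar(norm$ref) - nchar(norm$alt))
      rows[[length(rows) + 1]] <- tibble(
        pos = norm$pos, ref = norm$ref, alt = norm$alt,
        var_class = ifelse(diff <= 50, "small_indel",
                           ifelse(nchar(norm$alt) > nchar(norm$ref),
                                  "SV_insertion", "SV_deletion")),
        length = as.integer(diff),
        sv_len = ifelse(diff <= 50, NA_integer_, as.integer(diff)))
    }
  }
  ev <- alignment$events
  ev <- ev[ev$kind != "unaligned", , drop = FALSE]
  if (nrow(ev)) {
    rows[[length(rows) + 1]] <- purrr::pmap_dfr(ev, function(ref_start,
        ref_end, qry_start, qry_end, kind) {
      pos1 <- max(ref_start - 1L, 1L)
      anchor <- seq_sub(rs, pos1, pos1)
      rseq <- if (ref_end >= ref_start) seq_sub(rs, ref_start, ref_end) else ""
      qseq <- if (qry_end >= qry_start) seq_sub(qs, qry_start, qry_end) else ""
      cls <- c(sv_insertion = "SV_insertion", sv_deletion = "SV_deletion",
               sv_inversion = "SV_inversion", sv_complex = "SV_complex")[kind]
      svl <- switch(kind,
        sv_insertion = nchar(qseq) - nchar(rseq),
        sv_deletion = nchar(rseq) - nchar(qseq),
        nchar(rseq))
      tibble(pos = pos1, ref = paste0(anchor, rseq), alt = paste0(anchor, qseq),
             var_class = unname(cls), length = as.integer(svl),
             sv_len = as.integer(svl))
    })
  }
  res <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(pos = integer(), ref = character(), alt = character(),
           var_class = character(), length = integer(), sv_len = integer())
  dplyr::arrange(dplyr::mutate(res, accession = alignment$qry_id,
                               .before = 1), .data$pos)
}

# apply a call set back onto the reference (used by the reconstruction
# property tests); variants must be non-overlapping on the reference.
apply_variants <- function(ref_seq, variants) {
  v <- variants[order(variants$pos, decreasing = TRUE), , drop = FALSE]
  s <- ref_seq
  for (i in seq_len(nrow(v))) {
    pre <- if (v$pos[i] > 1) seq_sub(s, 1, v$pos[i] - 1) else ""
    post_from <- v$pos[i] + nchar(v$ref[i])
    post <- if (post_from <= nchar(s)) seq_sub(s, post_from, nchar(s)) else ""
    s <- paste0(pre, v$alt[i], post)
  }
  s
}

#' Locate short markers on a haplotype
#'
#' Best local alignment per marker (match +1, mismatch -2, gap open -5,
#' extend -1) on both strands; identity is the fraction of matching marker
#' bases. Markers with no hit at or above `min_identity` are reported
#' absent.
#'
#' @param reference an `sdr_haplotype` (or sequence).
#' @param markers tibble with columns `id` and `sequence` (each >= 15 bp).
#' @param min_identity minimum identity (default 0.8).
#' @return tibble: `id`, `seq_id`, `start`, `end`, `strand`, `identity`
#'   (percent); absent markers have NA coordinates.
#' @export
locate_markers <- function(reference, markers, min_identity = 0.8) {
  seq <- if (inherits(reference, "sdr_haplotype")) reference$seq else toupper(reference)
  seq_id <- if (inherits(reference, "sdr_haplotype")) reference$accession else "ref"
  if (any(nchar(markers$sequence) < 15)) abort("markers must be >= 15 bp")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  subject <- Biostrings::DNAString(gsub("N", "A", seq)) # baseOnly matrix
  purrr::pmap_dfr(markers, function(id, sequence, ...) {
    best <- NULL; best_strand <- "+"
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sequence else revcomp(sequence)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pat), subject, type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 1)
      if (is.null(best) || Biostrings::score(al) > Biostrings::score(best)) {
        best <- al; best_strand <- strand
      }
    }
    ident <- Biostrings::nmatch(best) / nchar(sequence)
    if (ident < min_identity) {
      tibble(id = id, seq_id = seq_id, start = NA_integer_, end = NA_integer_,
             strand = NA_character_, identity = NA_real_)
    } else {
      rng <- best@subject@range
      tibble(id = id, seq_id = seq_id, start = as.integer(rng@start),
             end = as.integer(rng@start + rng@width - 1L),
             strand = best_strand, identity = 100 * ident)
    }
  })
}

#' Region spanned by flanking markers
#'
#' @param hits tibble from [locate_markers()] (>= 2 located hits on the
#'   same sequence).
#' @param pad flank padding in bp.
#' @param seq_length optional sequence length used to clip the padding.
#' @return a one-row interval tibble covering all hits, padded.
#' @export
region_by_flanking_markers <- function(hits, pad = 0, seq_length = NULL) {
  hits <- hits[!is.na(hits$start), , drop = FALSE]
  if (nrow(hits) < 2) abort("need >= 2 located marker hits")
  if (length(unique(hits$seq_id)) != 1) abort("markers on different sequences")
  start <- max(1L, min(hits$start) - as.integer(pad))
  end <- max(hits$end) + as.integer(pad)
  if (!is.null(seq_length)) end <- min(end, as.integer(seq_length))
  genomic_interval(hits$seq_id[1], start, end)
}
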