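#' Extract promoter windows
#'
#' Strand-aware upstream windows of up to `window` bp from each gene's
#' transcription start, truncated at the sequence ends but not by
#' neighbouring genes. Minus-strand promoters are returned
#' reverse-complemented (promoter orientation).
#'
#' @param haplotype an `sdr_haplotype`.
#' @param window maximum promoter length (default 3000).
#' @return tibble: `gene_id`, `start`, `end` (genomic, 1-based), `strand`,
#'   `sequence`.
#' @export
extract_promoters <- function(haplotype, window = 3000) {
  L <- nchar(haplotype$seq)
  purrr::pmap_dfr(haplotype$genes[, c("gene_id", "start", "end", "strand")],
                  function(gene_id, start, end, strand) {
    if (strand == "+") {
      ws <- max(1L, start - as.integer(window)); we <- start - 1L
    } else {
      ws <- end + 1L; we <- min(L, end + as.integer(window))
    }
    if (we < ws) {
      return(tibble(gene_id = gene_id, start = NA_integer_,
                    end = NA_integer_, strand = strand, sequence = ""))
    }
    s <- seq_sub(haplotype$seq, ws, we)
    if (strand == "-") s <- revcomp(s)
    tibble(gene_id = gene_id, start = ws, end = we, strand = strand,
           sequence = s)
  })
}

#' Position weight matrix from a count matrix
#'
#' Counts are converted to probabilities with a pseudocount distributed by
#' the background frequencies, then to log2 odds against the background.
#'
#' @param pfm 4 x W count matrix (rows `A`, `C`, `G`, `T`), e.g. from
#'   [read_jaspar_pfm()].
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background base frequencies (default uniform 0.25).
#' @return a 4 x W log-odds matrix of class `sdr_pwm` with attributes
#'   `min_score`, `max_score`, `motif_id`.
#' @export
pwm_from_pfm <- function(pfm, pseudocount = 0.8,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(nrow(pfm) == 4, ncol(pfm) >= 1)
  background <- background / sum(background)
  probs <- sweep(pfm + pseudocount * background, 2,
                 colSums(pfm) + pseudocount, "/")
  lo <- log2(probs / background)
  rownames(lo) <- c("A", "C", "G", "T")
  structure(lo, class = c("sdr_pwm", class(lo)),
            min_score = sum(apply(lo, 2, min)),
            max_score = sum(apply(lo, 2, max)),
            motif_id = attr(pfm, "motif_id") %||% "motif")
}

pwm_scan_strand <- function(chars, lo) {
  W <- ncol(lo); n <- length(chars)
  if (n < W) return(numeric(0))
  idx <- match(chars, c("A", "C", "G", "T"))
  sc <- numeric(n - W + 1)
  valid <- !logical(n - W + 1)
  for (j in seq_len(W)) {
    ij <- idx[j:(n - W + j)]
    bad <- is.na(ij)
    ij[bad] <- 1L
    sc <- sc + lo[cbind(ij, j)]
    valid <- valid & !bad
  }
  sc[!valid] <- -Inf # windows containing N never score
  sc
}

#' Scan a promoter with a position weight matrix
#'
#' Both strands are scanned; scores are reported on the relative scale
#' `(score - min) / (max - min)` in [0, 1] (the consensus sequence scores
#' exactly 1). Overlapping hits are all kept.
#'
#' @param promoter DNA string (length >= motif width).
#' @param pwm an `sdr_pwm` (or a raw 4 x W count matrix, converted with
#'   defaults).
#' @param threshold minimum relative score (default 0.85).
#' @return tibble: `motif_id`, `start`, `end` (1-based within the
#'   promoter), `strand`, `rel_score`.
#' @export
scan_pwm <- function(promoter, pwm, threshold = 0.85) {
  if (!inherits(pwm, "sdr_pwm")) pwm <- pwm_from_pfm(pwm)
  W <- ncol(pwm)
  promoter <- toupper(promoter)
  n <- nchar(promoter)
  if (n < W) abort("promoter shorter than motif width")
  lo <- unclass(pwm)
  rng <- attr(pwm, "max_score") - attr(pwm, "min_score")
  hits <- list()
  fchars <- seq_chars(promoter)
  for (strand in c("+", "-")) {
    chars <- if (strand == "+") fchars else seq_chars(revcomp(promoter))
    sc <- pwm_scan_strand(chars, lo)
    rel <- (sc - attr(pwm, "min_score")) / rng
    ok <- which(rel >= threshold)
    if (!length(ok)) next
    start <- if (strand == "+") ok else n - (ok + W - 1L) + 1L
    hits[[length(hits) + 1]] <- tibble(
      motif_id = attr(pwm, "motif_id"), start = as.integer(start),
      end = as.integer(start + W - 1L), strand = strand,
      rel_score = rel[ok])
  }
  if (!length(hits)) {
    return(tibble(motif_id = character(), start = integer(), end = integer(),
                  strand = character(), rel_score = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), .data$start)
}

#' Sex-linked presence/absence of promoter motifs
#'
#' A motif is present-in-class when it hits the gene's promoter in every
#' haplotype of that class. Sex linkage follows the same strict rule as
#' variant classification: present in all haplotypes of one class and
#' absent from all haplotypes of the other two (`present_in_<class>`), or
#' the mirrored absent-in-one-class pattern (`absent_in_<class>`).
#'
#' @param hits tibble of per-haplotype motif hits with columns `accession`,
#'   `gene_id`, `motif_id` (one row per hit; as from [scan_pwm()] applied
#'   to each promoter). Every (gene, motif) combination must have been
#'   scanned in every haplotype.
#' @param sex_labels tibble (`accession`, `sex_class`).
#' @return tibble: `gene_id`, `motif_id`, per-class carrier counts,
#'   `linkage` (`present_in_M`, `absent_in_F`, ..., or `none`).
#' @export
sex_linked_motifs <- function(hits, sex_labels) {
  sex_labels <- as_tibble(sex_labels)
  totals <- table(factor(sex_labels$sex_class, c("M", "F", "H")))
  combos <- unique(hits[, c("gene_id", "motif_id")])
  purrr::pmap_dfr(combos, function(gene_id, motif_id) {
    sub <- hits[hits$gene_id == gene_id & hits$motif_id == motif_id, ]
    carriers <- unique(sub$accession)
    cls <- sex_labels$sex_class[match(carriers, sex_labels$accession)]
    nM <- sum(cls == "M"); nF <- sum(cls == "F"); nH <- sum(cls == "H")
    full <- c(M = nM == totals[["M"]], F = nF == totals[["F"]],
              H = nH == totals[["H"]])
    empty <- c(M = nM == 0, F = nF == 0, H = nH == 0)
    linkage <- "none"
    for (k in c("M", "F", "H")) {
      oth <- setdiff(c("M", "F", "H"), k)
      if (full[[k]] && all(empty[oth])) linkage <- paste0("present_in_", k)
      if (empty[[k]] && all(full[oth])) linkage <- paste0("absent_in_", k)
    }
    tibble(gene_id = gene_id, motif_id = motif_id,
           n_M = nM, n_F = nF, n_H = nH,
           total_M = as.integer(totals[["M"]]),
           total_F = as.integer(totals[["F"]]),
           total_H = as.integer(totals[["H"]]), linkage = linkage)
  })
}
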