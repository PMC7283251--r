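#' Genomic intervals
#'
#' Intervals are carried as tibbles with columns `seq_id`, `start`, `end`,
#' `strand`. All user-facing coordinates are 1-based inclusive; internal
#' computation uses 0-based half-open coordinates. The two helpers below
#' convert losslessly between the conventions.
#'
#' @param x a tibble with `start`/`end` columns (1-based inclusive for
#'   [interval_to_0based()], 0-based half-open for [interval_to_1based()]).
#' @return the same tibble in the other convention.
#' @examples
#' gi <- genomic_interval("chr1", 100, 150)
#' identical(interval_to_1based(interval_to_0based(gi)), gi)
#' @export
interval_to_0based <- function(x) {
  stopifnot(all(x$start >= 1), all(x$end >= x$start))
  dplyr::mutate(x, start = .data$start - 1L)
}

#' @rdname interval_to_0based
#' @export
interval_to_1based <- function(x) {
  stopifnot(all(x$start >= 0), all(x$end > x$start))
  dplyr::mutate(x, start = .data$start + 1L)
}

#' @param seq_id sequence identifier.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @rdname interval_to_0based
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  if (any(start < 1) || any(end < start)) {
    abort("invalid interval: need 1 <= start <= end")
  }
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  tibble(seq_id = seq_id, start = as.integer(start), end = as.integer(end),
         strand = strand)
}

#' Gene model constructor
#'
#' One row of the gene-model table carried by an [annotated_haplotype()]:
#' the gene body interval plus its CDS segments (non-overlapping, ordered
#' 5' to 3' in transcript orientation, phases in 0..2). The concatenated
#' CDS length must be divisible by 3 unless the model is flagged partial.
#'
#' @param gene_id gene identifier.
#' @param start,end 1-based inclusive gene body bounds.
#' @param strand `"+"` or `"-"`.
#' @param cds tibble with columns `start`, `end`, `phase`.
#' @param partial logical; `TRUE` for truncated/broken models.
#' @return a one-row tibble with a `cds` list-column.
#' @export
gene_model <- function(gene_id, start, end, strand, cds, partial = FALSE) {
  cds <- as_tibble(cds)
  stopifnot(all(c("start", "end", "phase") %in% names(cds)))
  if (nrow(cds) > 1) {
    o <- order(cds$start)
    if (any(cds$end[o][-nrow(cds)] >= cds$start[o][-1])) {
      abort(sprintf("gene %s: overlapping CDS segments", gene_id))
    }
  }
  if (!all(cds$phase %in% 0:2)) abort("CDS phase must be 0, 1 or 2")
  len <- sum(cds$end - cds$start + 1)
  if (!partial && len %% 3 != 0) {
    abort(sprintf("gene %s: CDS length %d not divisible by 3 (not flagged partial)",
                  gene_id, len))
  }
  tibble(gene_id = gene_id, start = as.integer(start), end = as.integer(end),
         strand = strand, partial = partial, cds = list(cds))
}
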