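#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (with nonzero
#' counts in every sample) of the ratio between the sample's count and the
#' gene's geometric mean across samples.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return named numeric vector of per-sample factors (> 0).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    abort(paste("no gene has nonzero counts in all samples;",
                "consider a pseudo-reference normalization"))
  }
  logg <- rowMeans(log(counts[ok, , drop = FALSE]))
  f <- apply(counts[ok, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logg))
  })
  stats::setNames(f, colnames(counts))
}

welch_t_vec <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- 1 # zero variance, zero difference
  list(t = t, p = p, delta = m1 - m2)
}

#' Classify sex-specific expression patterns
#'
#' Normalizes counts by median-of-ratios size factors, log2(x+1)
#' transforms them, and tests, per gene, stage and sex class, the two
#' one-vs-other-sex Welch contrasts. A pattern (`<sex>-high` /
#' `<sex>-low`) is assigned iff BOTH contrasts are significant after
#' Benjamini-Hochberg adjustment (within each contrast-by-stage stratum)
#' with the SAME sign. Genes with all-zero counts are reported untestable.
#'
#' An externally computed differential-expression table can be supplied to
#' bypass the built-in Welch stand-in: the pattern rule is then applied to
#' the provided adjusted p-values and fold-changes instead.
#'
#' @param counts genes x samples count matrix.
#' @param design tibble: `sample`, `sex` (`M`/`F`/`H`), `stage`,
#'   `replicate` (>= 2 replicates per sex/stage cell).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param external_de optional tibble bypassing the built-in test:
#'   columns `gene`, `stage`, `contrast` (`"M_vs_F"`, `"M_vs_H"`,
#'   `"F_vs_H"`), `log2fc` (first class over second), `padj`.
#' @return tibble: `gene`, `stage`, `pattern`, `sex`, `direction`,
#'   `p_adj_1`, `p_adj_2` (the two contrast adjusted p-values).
#' @export
sex_pattern_classify <- function(counts, design, alpha = 0.05,
                                 external_de = NULL) {
  if (!is.null(external_de)) {
    return(pattern_rule_external(external_de, alpha))
  }
  counts <- as.matrix(counts)
  design <- as_tibble(design)
  stopifnot(all(design$sample %in% colnames(counts)))
  counts <- counts[, design$sample, drop = FALSE]
  untestable <- rowSums(counts) == 0
  sf <- size_factors(counts[!untestable, , drop = FALSE])
  lx <- log2(sweep(counts, 2, sf, "/") + 1)
  sexes <- c("M", "F", "H")
  out <- list()
  for (st in unique(design$stage)) {
    cells <- lapply(sexes, function(s) {
      design$sample[design$sex == s & design$stage == st]
    })
    names(cells) <- sexes
    if (any(lengths(cells) < 2)) {
      warn(sprintf("stage %s skipped: fewer than 2 replicates in a cell", st))
      next
    }
    stat <- lapply(cells, function(sm) {
      x <- lx[, sm, drop = FALSE]
      list(m = rowMeans(x), v = apply(x, 1, stats::var), n = length(sm))
    })
    # the three pairwise contrasts, BH-adjusted across genes per contrast
    pairs <- list(c("M", "F"), c("M", "H"), c("F", "H"))
    tests <- lapply(pairs, function(pr) {
      a <- stat[[pr[1]]]; b <- stat[[pr[2]]]
      w <- welch_t_vec(a$m, a$v, a$n, b$m, b$v, b$n)
      w$padj <- rep(NA_real_, length(w$p))
      w$padj[!untestable] <- stats::p.adjust(w$p[!untestable], "BH")
      w
    })
    names(tests) <- vapply(pairs, paste, "", collapse = "")
    get_contrast <- function(s, o) {
      key_fwd <- paste0(s, o); key_rev <- paste0(o, s)
      if (key_fwd %in% names(tests)) {
        t <- tests[[key_fwd]]; list(padj = t$padj, delta = t$delta)
      } else {
        t <- tests[[key_rev]]; list(padj = t$padj, delta = -t$delta)
      }
    }
    for (g in seq_len(nrow(lx))) {
      gene <- rownames(lx)[g]
      if (untestable[g]) {
        out[[length(out) + 1]] <- tibble(gene = gene, stage = st,
                                         pattern = "untestable",
                                         sex = NA_character_,
                                         direction = NA_real_,
                                         p_adj_1 = NA_real_, p_adj_2 = NA_real_)
        next
      }
      hits <- list()
      for (s in sexes) {
        others <- setdiff(sexes, s)
        c1 <- get_contrast(s, others[1]); c2 <- get_contrast(s, others[2])
        sig <- !is.na(c1$padj[g]) && !is.na(c2$padj[g]) &&
          c1$padj[g] <= alpha && c2$padj[g] <= alpha &&
          sign(c1$delta[g]) == sign(c2$delta[g]) && c1$delta[g] != 0
        if (sig) {
          hits[[length(hits) + 1]] <- tibble(
            gene = gene, stage = st,
            pattern = sprintf("%s-%s", s,
                              if (c1$delta[g] > 0) "high" else "low"),
            sex = s, direction = sign(c1$delta[g]),
            p_adj_1 = c1$padj[g], p_adj_2 = c2$padj[g])
        }
      }
      out[[length(out) + 1]] <- if (length(hits)) {
        h <- dplyr::bind_rows(hits)
        h[which.min(pmax(h$p_adj_1, h$p_adj_2)), ]
      } else {
        tibble(gene = gene, stage = st, pattern = "none",
               sex = NA_character_, direction = NA_real_,
               p_adj_1 = NA_real_, p_adj_2 = NA_real_)
      }
    }
  }
  dplyr::bind_rows(out)
}

# apply the one-vs-both-other-sexes pattern rule to an external DE table
pattern_rule_external <- function(de, alpha) {
  de <- as_tibble(de)
  need <- c("gene", "stage", "contrast", "log2fc", "padj")
  stopifnot(all(need %in% names(de)))
  sexes <- c("M", "F", "H")
  lookup <- function(sub, s, o) {
    fwd <- sub[sub$contrast == sprintf("%s_vs_%s", s, o), ]
    if (nrow(fwd)) return(list(padj = fwd$padj[1], delta = fwd$log2fc[1]))
    rev <- sub[sub$contrast == sprintf("%s_vs_%s", o, s), ]
    if (nrow(rev)) return(list(padj = rev$padj[1], delta = -rev$log2fc[1]))
    list(padj = NA_real_, delta = NA_real_)
  }
  combos <- unique(de[, c("gene", "stage")])
  purrr::pmap_dfr(combos, function(gene, stage) {
    sub <- de[de$gene == gene & de$stage == stage, ]
    hits <- list()
    for (s in sexes) {
      oth <- setdiff(sexes, s)
      c1 <- lookup(sub, s, oth[1]); c2 <- lookup(sub, s, oth[2])
      sig <- !is.na(c1$padj) && !is.na(c2$padj) &&
        c1$padj <= alpha && c2$padj <= alpha &&
        sign(c1$delta) == sign(c2$delta) && c1$delta != 0
      if (sig) {
        hits[[length(hits) + 1]] <- tibble(
          gene = gene, stage = stage,
          pattern = sprintf("%s-%s", s, if (c1$delta > 0) "high" else "low"),
          sex = s, direction = sign(c1$delta),
          p_adj_1 = c1$padj, p_adj_2 = c2$padj)
      }
    }
    if (length(hits)) {
      h <- dplyr::bind_rows(hits)
      h[which.min(pmax(h$p_adj_1, h$p_adj_2)), ]
    } else {
      tibble(gene = gene, stage = stage, pattern = "none",
             sex = NA_character_, direction = NA_real_,
             p_adj_1 = NA_real_, p_adj_2 = NA_real_)
    }
  })
}

#' Z-score matrix for expression heatmaps
#'
#' Normalized counts are centred and scaled per gene across samples.
#' Constant genes yield all-zero rows (flagged in the `constant`
#' attribute).
#'
#' @param counts genes x samples count matrix.
#' @param design design tibble (columns order the samples).
#' @param gene_set non-empty character vector of genes to include.
#' @return a genes x samples matrix of class `sdr_zscore`.
#' @export
zscore_table <- function(counts, design, gene_set) {
  if (!length(gene_set)) abort("gene_set must be non-empty")
  counts <- as.matrix(counts)
  sf <- size_factors(counts[, design$sample, drop = FALSE])
  counts <- counts[gene_set, design$sample, drop = FALSE]
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  sdv <- apply(norm, 1, stats::sd)
  constant <- sdv == 0
  z <- (norm - mu) / ifelse(sdv == 0, 1, sdv)
  z[constant, ] <- 0
  structure(z, class = c("sdr_zscore", class(z)), constant = constant,
            design = design)
}
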