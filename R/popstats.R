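#' Windowed linkage-disequilibrium track
#'
#' Removes SNPs at or below the minor-allele-frequency cutoff, computes
#' r-squared as the squared Pearson correlation of allele dosages for every
#' SNP pair whose two positions fall inside the same fixed window (pairs
#' spanning window boundaries are dropped), and reports the median per
#' window. Windows left with fewer than two SNPs are reported missing.
#'
#' @param genotypes a list with `pos` (SNP positions) and `dosage`
#'   (samples x SNPs matrix of 0/1/2), as returned by
#'   [simulate_genotype_matrix()], or a VCF path (read with `vcfR`).
#' @param region `c(start, end)`; default spans the SNPs.
#' @param window_bp window width (default 20000).
#' @param maf_min SNPs with MAF <= `maf_min` are removed (default 0.05).
#' @return tibble of class `sdr_ld_track`: `window_start`, `window_end`,
#'   `n_snps`, `n_pairs`, `median_r2`.
#' @export
ld_track <- function(genotypes, region = NULL, window_bp = 20000,
                     maf_min = 0.05) {
  if (window_bp <= 0) abort("window_bp must be > 0")
  if (is.character(genotypes)) genotypes <- read_genotype_vcf(genotypes)
  pos <- genotypes$pos
  dos <- genotypes$dosage
  p <- colMeans(dos) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_min
  pos <- pos[keep]; dos <- dos[, keep, drop = FALSE]
  if (is.null(region)) region <- c(1L, max(pos, 1L))
  starts <- seq.int(region[1], region[2], by = window_bp)
  res <- purrr::map_dfr(starts, function(ws) {
    we <- min(ws + window_bp - 1L, region[2])
    idx <- which(pos >= ws & pos <= we)
    if (length(idx) < 2) {
      return(tibble(window_start = ws, window_end = we,
                    n_snps = length(idx), n_pairs = 0L,
                    median_r2 = NA_real_))
    }
    r2 <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE]))^2
    vals <- r2[upper.tri(r2)]
    vals <- vals[!is.na(vals)]
    tibble(window_start = ws, window_end = we, n_snps = length(idx),
           n_pairs = length(vals),
           median_r2 = if (length(vals)) stats::median(vals) else NA_real_)
  })
  structure(res, class = c("sdr_ld_track", class(res)),
            window_bp = window_bp, maf_min = maf_min)
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF genotypes requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dosage <- t(apply(gt, 1, function(x) {
    vapply(strsplit(x, "[|/]"), function(a) sum(as.integer(a)), 0L)
  }))
  list(pos = as.integer(vcfR::getPOS(v)), dosage = t(dosage),
       samples = colnames(gt))
}

#' Goodness-of-fit test for F1 segregation ratios
#'
#' Pearson chi-square test of observed class counts against an expected
#' ratio (default 1:1), without continuity correction.
#'
#' @param n1,n2 observed counts (>= 0, not both zero).
#' @param ratio expected ratio as `c(a, b)`.
#' @return an object of class `sdr_segregation`; `tidy()`/`glance()` give
#'   tabular access.
#' @export
segregation_chi2 <- function(n1, n2, ratio = c(1, 1)) {
  if (n1 < 0 || n2 < 0 || n1 + n2 == 0) abort("need non-negative counts, not both zero")
  obs <- c(n1, n2)
  exp <- sum(obs) * ratio / sum(ratio)
  chi2 <- sum((obs - exp)^2 / exp)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(n1 = n1, n2 = n2, ratio = ratio, chi2 = chi2, df = 1L,
                 p = p), class = "sdr_segregation")
}

#' @export
print.sdr_segregation <- function(x, ...) {
  cat(sprintf("Segregation %d:%d vs %s -> chi2 = %.2f, d.f. = %d, P = %.3f\n",
              x$n1, x$n2, paste(x$ratio, collapse = ":"), x$chi2, x$df, x$p))
  invisible(x)
}

#' Tidiers for segregation tests
#'
#' @param x an `sdr_segregation`.
#' @param ... unused.
#' @method tidy sdr_segregation
#' @export
tidy.sdr_segregation <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' @rdname tidy.sdr_segregation
#' @method glance sdr_segregation
#' @export
glance.sdr_segregation <- function(x, ...) {
  tibble(n1 = x$n1, n2 = x$n2, ratio = paste(x$ratio, collapse = ":"),
         statistic = x$chi2, df = x$df, p.value = x$p)
}

#' Marker-phenotype cosegregation report
#'
#' Counts genotype/phenotype concordance in an F1 table (male <-> `MF`
#' carrier, female <-> `FF`), names discordant individuals, and reports
#' individuals without phenotype (no inflorescence) as excluded.
#'
#' @param f1_table tibble as from [simulate_f1()]: `individual`,
#'   `genotype`, `phenotype`.
#' @return one-row tibble: `n_concordant`, `n_discordant`, `n_excluded`,
#'   `concordance`, plus a `discordant` list-column of individual ids.
#' @export
cosegregation_report <- function(f1_table) {
  excluded <- is.na(f1_table$phenotype)
  t2 <- f1_table[!excluded, , drop = FALSE]
  expected <- ifelse(t2$genotype == "MF", "male", "female")
  disc <- t2$individual[t2$phenotype != expected]
  tibble(n_concordant = sum(t2$phenotype == expected),
         n_discordant = length(disc),
         n_excluded = sum(excluded),
         concordance = if (nrow(t2)) mean(t2$phenotype == expected) else NA_real_,
         discordant = list(disc))
}
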