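# Nei-Gojobori (1986) synonymous/nonsynonymous distances with Jukes-Cantor
# correction, plus molecular-clock conversion of mean dS to divergence time.

BASES <- c("T", "C", "A", "G")

# fraction of the three possible changes at each codon position that are
# synonymous; changes creating stop codons count as nonsynonymous.
ng86_syn_sites_codon <- function(codon) {
  aa <- codon_aa(codon)
  if (aa == "*") return(NA_real_)
  s <- 0
  for (p in 1:3) {
    for (b in BASES) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      if (!is_stop_codon(mut) && codon_aa(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

SYN_SITES <- local({
  codons <- names(CODON_TABLE)
  stats::setNames(vapply(codons, ng86_syn_sites_codon, 0), codons)
})

# enumerate minimal mutational pathways between two codons; returns
# c(syn, nonsyn) counts averaged over pathways with equal weights.
# Pathways passing through stop codons are excluded (unless all are).
ng86_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, non = 0))
  perms <- if (nd == 1) list(pos) else {
    if (nd == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
  }
  walk <- function(order) {
    cur <- c1; syn <- 0; non <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop_codon(nxt) && nxt != c2) return(NULL) # blocked pathway
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn = syn, non = non)
  }
  res <- lapply(perms, walk)
  ok <- res[!vapply(res, is.null, TRUE)]
  if (!length(ok)) ok <- lapply(perms, function(o) { # all blocked: use all
    cur <- c1; syn <- 0; non <- 0
    for (p in o) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn = syn, non = non)
  })
  Reduce(`+`, ok) / length(ok)
}

jc_correct <- function(p) {
  arg <- 1 - 4 * p / 3
  ifelse(arg <= 0, NA_real_, -0.75 * log(arg))
}

#' Nei-Gojobori pairwise synonymous and nonsynonymous distances
#'
#' Counts fractional synonymous/nonsynonymous sites per codon (averaged over
#' both sequences), averages multi-difference codons over all minimal
#' mutational pathways with equal weights (pathways through stop codons
#' excluded), and applies the Jukes-Cantor correction:
#' \eqn{dS = -\frac{3}{4}\ln(1 - \frac{4}{3} pS)} (likewise dN). Codons
#' containing gaps, `N`, or stops in either sequence are skipped pairwise.
#'
#' @param cds_i,cds_j aligned CDS strings of equal length divisible by 3.
#' @return a one-row tibble: `S`, `N` (site counts), `Sd`, `Nd` (difference
#'   counts), `pS`, `pN`, `dS`, `dN`, `saturated`.
#' @export
ng86_pairwise <- function(cds_i, cds_j) {
  cds_i <- toupper(cds_i); cds_j <- toupper(cds_j)
  if (nchar(cds_i) != nchar(cds_j)) abort("aligned CDSs must have equal length")
  if (nchar(cds_i) %% 3 != 0) abort("CDS length must be divisible by 3")
  nc <- nchar(cds_i) %/% 3
  ci <- substring(cds_i, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cj <- substring(cds_j, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  valid <- grepl("^[ACGT]{3}$", ci) & grepl("^[ACGT]{3}$", cj) &
    !is_stop_codon(ci) & !is_stop_codon(cj)
  ci <- ci[valid]; cj <- cj[valid]
  S <- sum((SYN_SITES[ci] + SYN_SITES[cj]) / 2)
  N <- 3 * length(ci) - S
  Sd <- 0; Nd <- 0
  for (idx in which(ci != cj)) {
    ct <- ng86_path_counts(ci[idx], cj[idx])
    Sd <- Sd + ct[["syn"]]; Nd <- Nd + ct[["non"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  tibble(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         dS = dS, dN = dN, saturated = is.na(dS) || is.na(dN))
}

#' All cross-class pairwise dS values
#'
#' Computes [ng86_pairwise()] for every pair of sequences drawn from two
#' groups (typically all M x F allele pairs of one gene).
#'
#' @param seqs_a,seqs_b named character vectors of aligned CDSs.
#' @return tibble with one row per cross pair (`acc_a`, `acc_b` plus the
#'   [ng86_pairwise()] columns).
#' @export
ds_pairs <- function(seqs_a, seqs_b) {
  grid <- expand.grid(a = seq_along(seqs_a), b = seq_along(seqs_b))
  purrr::pmap_dfr(grid, function(a, b) {
    dplyr::mutate(ng86_pairwise(seqs_a[[a]], seqs_b[[b]]),
                  acc_a = names(seqs_a)[a] %||% as.character(a),
                  acc_b = names(seqs_b)[b] %||% as.character(b),
                  .before = 1)
  })
}

#' Summarise a dS distribution
#'
#' Mean pairwise dS with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 sd/sqrt(n)) and a Shapiro-Wilk normality check. A
#' significant Shapiro result produces a warning, not an error.
#'
#' @param ds numeric vector of pairwise dS values (or a tibble from
#'   [ds_pairs()] with a `dS` column), length >= 3.
#' @return one-row tibble: `mean_ds`, `ci_low`, `ci_high`, `n`,
#'   `shapiro_w`, `shapiro_p`.
#' @export
ds_summary <- function(ds) {
  if (is.data.frame(ds)) ds <- ds$dS
  ds <- ds[!is.na(ds)]
  if (length(ds) < 3) abort("need >= 3 dS values")
  m <- mean(ds); s <- stats::sd(ds); n <- length(ds)
  if (s == 0) {
    sw <- c(W = NA_real_); swp <- NA_real_
  } else {
    st <- stats::shapiro.test(ds)
    sw <- st$statistic; swp <- st$p.value
    if (!is.na(swp) && swp < 0.05) {
      warn(sprintf("dS distribution departs from normality (Shapiro p = %.3g)",
                   swp))
    }
  }
  tibble(mean_ds = m, ci_low = m - 1.96 * s / sqrt(n),
         ci_high = m + 1.96 * s / sqrt(n), n = n,
         shapiro_w = unname(sw), shapiro_p = swp)
}

#' Molecular-clock conversion of dS to divergence time
#'
#' Divergence in generations is `dS / (2 mu)`; multiplied by the generation
#' time this gives years. The default treats the substitution rate as
#' per-generation, which reproduces the standard worked arithmetic for
#' grape (dS 0.0275, mu 2.5e-9, 3-year generations -> 16.5 Myr);
#' `rate_units = "per_year"` interprets mu per year instead.
#'
#' @param mean_ds mean pairwise synonymous distance.
#' @param ci_low,ci_high optional CI bounds on dS, transformed identically.
#' @param mu substitution rate (> 0).
#' @param gen_time generation time in years (> 0).
#' @param rate_units `"per_generation"` (default) or `"per_year"`.
#' @return an object of class `sdr_divergence`; see [tidy.sdr_divergence()].
#' @export
divergence_time <- function(mean_ds, ci_low = NA_real_, ci_high = NA_real_,
                            mu = 2.5e-9, gen_time = 3,
                            rate_units = c("per_generation", "per_year")) {
  rate_units <- match.arg(rate_units)
  if (mu <= 0) abort("mu must be > 0")
  if (gen_time <= 0) abort("gen_time must be > 0")
  to_years <- function(ds) {
    if (is.na(ds)) return(NA_real_)
    gens <- ds / (2 * mu)
    if (rate_units == "per_generation") gens * gen_time else gens
  }
  structure(list(mean_ds = mean_ds, ci_low = ci_low, ci_high = ci_high,
                 mu = mu, gen_time = gen_time, rate_units = rate_units,
                 t_years = to_years(mean_ds),
                 t_years_low = to_years(ci_low),
                 t_years_high = to_years(ci_high)),
            class = "sdr_divergence")
}

#' @export
print.sdr_divergence <- function(x, ...) {
  cat(sprintf("M/F divergence: %.1f Myr", x$t_years / 1e6))
  if (!is.na(x$t_years_low)) {
    cat(sprintf(" (95%% CI %.1f-%.1f)", x$t_years_low / 1e6,
                x$t_years_high / 1e6))
  }
  cat(sprintf(" [dS = %.4g, mu = %.3g %s, generation %.3g yr]\n",
              x$mean_ds, x$mu, x$rate_units, x$gen_time))
  invisible(x)
}

#' Tidiers for divergence estimates
#'
#' @param x an `sdr_divergence` object.
#' @param ... unused.
#' @return `tidy()`: one row per reported quantity; `glance()`: a one-row
#'   tibble with the estimate, CI (years and Myr) and clock parameters.
#' @method tidy sdr_divergence
#' @export
tidy.sdr_divergence <- function(x, ...) {
  tibble(term = c("mean_ds", "t_myr", "t_myr_low", "t_myr_high"),
         estimate = c(x$mean_ds, x$t_years / 1e6, x$t_years_low / 1e6,
                      x$t_years_high / 1e6))
}

#' @rdname tidy.sdr_divergence
#' @method glance sdr_divergence
#' @export
glance.sdr_divergence <- function(x, ...) {
  tibble(mean_ds = x$mean_ds, t_years = x$t_years, t_myr = x$t_years / 1e6,
         t_myr_low = x$t_years_low / 1e6, t_myr_high = x$t_years_high / 1e6,
         mu = x$mu, gen_time = x$gen_time, rate_units = x$rate_units)
}
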