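#' Pipeline configuration
#'
#' Bundles the input mode (simulate inline, or files on disk) with every
#' per-stage scientific parameter. Exactly one input mode must be set.
#'
#' @param simulate an [sim_config()] for inline simulation, or `NULL`.
#' @param files `list(fasta =, gff3 =, labels =)` paths, or `NULL`.
#' @param reference accession of the reference haplotype (default: the
#'   first H haplotype).
#' @param params named list overriding stage parameters: `k`,
#'   `density_window`, `ld_window`, `maf_min`, `alpha`, `mu`, `gen_time`,
#'   `rate_units`, `promoter_bp`, `pwm_threshold`, `pfm_path`, `n_boot`,
#'   `tree_model`.
#' @return a `sdr_pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, files = NULL, reference = NULL,
                            params = list()) {
  defaults <- list(k = 21, density_window = 1000, ld_window = 20000,
                   maf_min = 0.05, alpha = 0.05, mu = 2.5e-9, gen_time = 3,
                   rate_units = "per_generation", promoter_bp = 3000,
                   pwm_threshold = 0.85, pfm_path = NULL, n_boot = 0,
                   tree_model = "p")
  structure(list(simulate = simulate, files = files, reference = reference,
                 params = utils::modifyList(defaults, params)),
            class = "sdr_pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every cross-field constraint before any stage runs.
#'
#' @param config an `sdr_pipeline_config`.
#' @return `character(0)` when valid, else a character vector of errors.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  has_sim <- !is.null(config$simulate)
  has_files <- !is.null(config$files)
  if (has_sim && has_files) errs <- c(errs, "set either simulate or files, not both")
  if (!has_sim && !has_files) errs <- c(errs, "one of simulate or files is required")
  if (has_sim && !inherits(config$simulate, "sdr_sim_config")) {
    errs <- c(errs, "simulate must be an sdr_sim_config")
  }
  if (has_files) {
    need <- c("fasta", "gff3", "labels")
    miss <- setdiff(need, names(config$files))
    if (length(miss)) {
      errs <- c(errs, sprintf("files needs %s", paste(miss, collapse = ", ")))
    } else {
      absent <- !vapply(config$files[need], file.exists, TRUE)
      if (any(absent)) {
        errs <- c(errs, sprintf("missing file(s): %s",
                                paste(unlist(config$files[need])[absent],
                                      collapse = ", ")))
      }
    }
  }
  p <- config$params
  if (p$mu <= 0) errs <- c(errs, "mu must be > 0")
  if (p$gen_time <= 0) errs <- c(errs, "gen_time must be > 0")
  if (p$density_window <= 0) errs <- c(errs, "density_window must be > 0")
  if (p$ld_window <= 0) errs <- c(errs, "ld_window must be > 0")
  if (p$alpha <= 0 || p$alpha > 1) errs <- c(errs, "alpha must be in (0, 1]")
  if (p$k < 15) errs <- c(errs, "k must be >= 15")
  errs
}

#' Run the full SDR comparison pipeline
#'
#' Executes, in dependency order: data loading or simulation, pairwise
#' alignment of every haplotype to the reference, variant calling, strict
#' sex-linkage classification, density tracks, coding-effect annotation of
#' linked variants, per-gene trees with the sex-monophyly test, breakpoint
#' localization, dS dating of the M/F split, F1 segregation, windowed LD
#' and expression-pattern classification (the last three from the
#' simulator's companion generators in simulate mode). Promoter motif
#' scanning runs when `params$pfm_path` is provided. Rerunning with an
#' identical configuration reproduces an identical report hash.
#'
#' @param config an `sdr_pipeline_config`.
#' @param out_dir optional output directory for `report.json`.
#' @return a list of class `sdr_report`: `report` (the summary list),
#'   `details` (per-stage tibbles), `hash` (md5 of the canonical report
#'   JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  errs <- validate_config(config)
  if (length(errs)) {
    abort(paste0("invalid pipeline config:\n", paste("-", errs, collapse = "\n")))
  }
  p <- config$params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  sim <- NULL
  set <- stage("data", {
    if (!is.null(config$simulate)) {
      sim <- simulate_trio(config$simulate)
      sim$haplotypes
    } else {
      read_haplotype_set(config$files$fasta, config$files$gff3,
                         config$files$labels)
    }
  })
  if (!is.null(config$simulate)) sim <- attr(set, "sim") %||% sim
  labels <- sex_label_table(set)
  ref_acc <- config$reference %||%
    labels$accession[labels$sex_class == "H"][1]
  if (is.na(ref_acc)) ref_acc <- labels$accession[1]
  ref <- set[[ref_acc]]

  aligned <- stage("align", {
    lapply(set[setdiff(names(set), ref_acc)], function(q) {
      align_pair(ref, q, k = p$k)
    })
  })
  calls <- stage("call", dplyr::bind_rows(lapply(aligned, call_variants)))
  coverage <- lapply(aligned, `[[`, "coverage")
  linkage <- stage("classify",
                   classify_sex_linked(calls, labels, coverage))
  dens <- stage("density", {
    density_track(linkage[linkage$var_class == "SNP", ],
                  region = c(1L, nchar(ref$seq)),
                  window_bp = p$density_window)
  })
  linked <- linkage[linkage$linked_class != "none", ]
  effects <- stage("effects", annotate_effect(linked, ref, p$promoter_bp))

  gene_aln <- stage("gene_alignments", {
    if (!is.null(sim)) sim$gene_alignments else panel_gene_alignments(set)
  })
  patterns <- stage("phylo", {
    clade_patterns(gene_aln, labels, model = p$tree_model,
                   n_boot = p$n_boot)
  })
  bp_call <- stage("breakpoint", locate_breakpoint(patterns))

  dating <- stage("dating", {
    fs_gene <- if (!is.null(sim)) sim$truth$frameshift$gene else NULL
    cds_genes <- setdiff(names(gene_aln), fs_gene)
    concat <- if (length(cds_genes)) {
      vapply(names(gene_aln[[cds_genes[1]]]), function(acc) {
        paste(vapply(cds_genes, function(g) gene_aln[[g]][[acc]], ""),
              collapse = "")
      }, "")
    } else character(0)
    m_acc <- labels$accession[labels$sex_class == "M"]
    f_acc <- labels$accession[labels$sex_class == "F"]
    if (length(m_acc) && length(f_acc) && length(concat)) {
      pairs <- ds_pairs(concat[m_acc], concat[f_acc])
      summ <- ds_summary(pairs)
      list(pairs = pairs, summary = summ,
           estimate = divergence_time(summ$mean_ds, summ$ci_low,
                                      summ$ci_high, mu = p$mu,
                                      gen_time = p$gen_time,
                                      rate_units = p$rate_units))
    } else NULL
  })

  f1_block <- NULL; ld <- NULL; expr_block <- NULL
  if (!is.null(config$simulate)) {
    f1_block <- stage("segregate", {
      f1 <- simulate_f1(config$simulate)
      sexed <- f1[!is.na(f1$phenotype), ]
      seg <- segregation_chi2(sum(sexed$phenotype == "male"),
                              sum(sexed$phenotype == "female"))
      list(f1 = f1, segregation = seg, coseg = cosegregation_report(f1))
    })
    ld <- stage("ld", {
      ld_track(simulate_genotype_matrix(config$simulate),
               window_bp = p$ld_window, maf_min = p$maf_min)
    })
    expr_block <- stage("express", {
      ex <- simulate_expression(config$simulate)
      calls <- sex_pattern_classify(ex$counts, ex$design, alpha = p$alpha)
      list(calls = calls, truth = ex$truth)
    })
  }

  motif_block <- NULL
  if (!is.null(p$pfm_path)) {
    motif_block <- stage("motifs", {
      pfms <- read_jaspar_pfm(p$pfm_path)
      hits <- purrr::map_dfr(set, function(h) {
        prom <- extract_promoters(h, p$promoter_bp)
        purrr::pmap_dfr(prom, function(gene_id, sequence, ...) {
          if (!nzchar(sequence)) return(NULL)
          purrr::map_dfr(pfms, function(m) {
            dplyr::mutate(scan_pwm(sequence, pwm_from_pfm(m),
                                   p$pwm_threshold),
                          gene_id = gene_id, accession = h$accession)
          })
        })
      })
      list(hits = hits,
           linked = if (nrow(hits)) sex_linked_motifs(hits, labels) else NULL)
    })
  }

  report <- list(
    reference = ref_acc,
    n_haplotypes = length(set),
    linked_counts = list(
      M_snps = sum(linkage$linked_class == "M" & linkage$var_class == "SNP"),
      F_snps = sum(linkage$linked_class == "F" & linkage$var_class == "SNP"),
      M_indels = sum(linkage$linked_class == "M" &
                     linkage$var_class == "small_indel"),
      F_indels = sum(linkage$linked_class == "F" &
                     linkage$var_class == "small_indel"),
      M_svs = sum(linkage$linked_class == "M" &
                  startsWith(linkage$var_class, "SV_")),
      F_svs = sum(linkage$linked_class == "F" &
                  startsWith(linkage$var_class, "SV_"))),
    frameshift_effects = sum(effects$consequence == "frameshift"),
    breakpoint = list(left_gene = bp_call$left_gene[1],
                      right_gene = bp_call$right_gene[1],
                      mismatches = bp_call$mismatches[1],
                      ambiguous = bp_call$ambiguous[1]),
    dating = if (!is.null(dating)) {
      as.list(glance(dating$estimate)[1, c("mean_ds", "t_myr", "t_myr_low",
                                           "t_myr_high")])
    },
    segregation = if (!is.null(f1_block)) {
      list(chi2 = round(f1_block$segregation$chi2, 2),
           df = f1_block$segregation$df, p = f1_block$segregation$p,
           concordance = f1_block$coseg$concordance)
    },
    ld_median_r2 = if (!is.null(ld)) stats::median(ld$median_r2, na.rm = TRUE),
    expression_patterns = if (!is.null(expr_block)) {
      sum(!expr_block$calls$pattern %in% c("none", "untestable"))
    },
    linked_motifs = if (!is.null(motif_block) &&
                        !is.null(motif_block$linked)) {
      sum(motif_block$linked$linkage != "none")
    },
    params = p[!vapply(p, is.null, TRUE)])

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null")
  hash <- as.character(tools::md5sum(local({
    tf <- tempfile(); writeLines(json, tf); tf
  })))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(json, file.path(out_dir, "report.json"))
  }
  structure(list(report = report, hash = unname(hash),
                 details = list(linkage = linkage, density = dens,
                                effects = effects, patterns = patterns,
                                breakpoint = bp_call, dating = dating,
                                f1 = f1_block, ld = ld,
                                expression = expr_block,
                                motifs = motif_block)),
            class = "sdr_report")
}

# per-gene "alignments" for file-mode panels: CDSs of equal length across
# the panel (genes with length differences are skipped with a warning)
panel_gene_alignments <- function(set) {
  gene_ids <- unique(unlist(lapply(set, function(h) h$genes$gene_id)))
  out <- list()
  for (g in gene_ids) {
    seqs <- vapply(set, function(h) {
      if (g %in% h$genes$gene_id) gene_cds_seq(h, g) else NA_character_
    }, "")
    seqs <- seqs[!is.na(seqs)]
    if (length(unique(nchar(seqs))) != 1 || length(seqs) < 3) {
      warn(sprintf("gene %s skipped: unequal CDS lengths across the panel", g))
      next
    }
    out[[g]] <- seqs
  }
  out
}

#' @export
print.sdr_report <- function(x, ...) {
  r <- x$report
  cat("<sdr_report>\n")
  cat(sprintf("  reference: %s (%d haplotypes)\n", r$reference,
              r$n_haplotypes))
  cat(sprintf("  linked SNPs: %d M / %d F; linked SVs: %d M / %d F\n",
              r$linked_counts$M_snps, r$linked_counts$F_snps,
              r$linked_counts$M_svs, r$linked_counts$F_svs))
  cat(sprintf("  breakpoint: %s | %s (mismatches %.1f)\n",
              r$breakpoint$left_gene, r$breakpoint$right_gene,
              r$breakpoint$mismatches))
  if (!is.null(r$dating)) {
    cat(sprintf("  divergence: %.1f Myr (dS %.4f)\n", r$dating$t_myr,
                r$dating$mean_ds))
  }
  cat(sprintf("  report hash: %s\n", x$hash))
  invisible(x)
}
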