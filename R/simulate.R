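#' Simulation configuration for a synthetic SDR panel
#'
#' Defines the study conditions the synthetic generator emulates: a panel of
#' male (M), female (F) and hermaphrodite (H) SDR haplotypes descended from
#' one ancestral region, with M/F lineages diverged to a target mean dS, an
#' F-linked frameshift deletion in one gene, class-specific structural
#' variants, and H haplotypes formed by a single F(5')+M(3') recombination
#' at a known breakpoint between two genes.
#'
#' @param seed integer RNG seed. Each generator draws from an independent
#'   stream derived from `seed` plus a fixed per-family offset.
#' @param length ancestral region length in bp.
#' @param n_genes number of intronless genes.
#' @param n_m,n_f,n_h haplotype counts per sex class.
#' @param ds_target target mean synonymous distance between M and F alleles.
#' @param diversity_rate within-class private substitution rate per bp.
#' @param intergenic_rate_factor intergenic fixed-difference rate as a
#'   fraction of the synonymous rate.
#' @param breakpoint_index H recombination breakpoint lies between genes
#'   `breakpoint_index` and `breakpoint_index + 1`.
#' @param frameshift_gene index of the gene carrying the F-linked frameshift
#'   deletion (must be 3' of the breakpoint so that H and M stay intact).
#' @param frameshift_len deletion length in bp (not a multiple of 3).
#' @param min_syn_per_gene minimum planted synonymous fixed differences per
#'   gene per lineage (keeps every gene tree informative).
#' @param nonsyn_per_gene planted nonsynonymous fixed differences per gene
#'   per lineage.
#' @param cds_codons codons per gene (including start and stop).
#' @param sv_spec list of structural variants; each element is
#'   `list(type = "insertion"|"deletion", length, class = "M"|"F",
#'   region = "5p"|"3p")`.
#' @param mu,gen_time substitution rate and generation time implied by the
#'   target dS (used for the truth divergence time).
#' @param expression,f1,genotypes sub-lists configuring the expression,
#'   F1-cross and genotype-matrix generators; see the vignette.
#' @return a validated `sdr_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       length = 200000,
                       n_genes = 14,
                       n_m = 3, n_f = 12, n_h = 5,
                       ds_target = 0.0275,
                       diversity_rate = 1e-4,
                       intergenic_rate_factor = 0.25,
                       breakpoint_index = 4,
                       frameshift_gene = 9,
                       frameshift_len = 8,
                       min_syn_per_gene = 2,
                       nonsyn_per_gene = 1,
                       cds_codons = 333,
                       sv_spec = list(
                         list(type = "insertion", length = 2000, class = "M", region = "5p"),
                         list(type = "insertion", length = 5000, class = "M", region = "3p"),
                         list(type = "deletion", length = 3000, class = "F", region = "3p"),
                         list(type = "deletion", length = 1500, class = "F", region = "3p")),
                       mu = 2.5e-9, gen_time = 3,
                       expression = list(),
                       f1 = list(),
                       genotypes = list()) {
  cfg <- list(seed = as.integer(seed), length = as.integer(length),
              n_genes = n_genes, n_m = n_m, n_f = n_f, n_h = n_h,
              ds_target = ds_target, diversity_rate = diversity_rate,
              intergenic_rate_factor = intergenic_rate_factor,
              breakpoint_index = breakpoint_index,
              frameshift_gene = frameshift_gene,
              frameshift_len = frameshift_len,
              min_syn_per_gene = min_syn_per_gene,
              nonsyn_per_gene = nonsyn_per_gene,
              cds_codons = cds_codons, sv_spec = sv_spec,
              mu = mu, gen_time = gen_time)
  cfg$expression <- utils::modifyList(list(
    stages = c("stage1", "stage2", "stage3"), replicates = 3,
    dispersion = 0.05, n_background = 30, baseline_meanlog = 5,
    baseline_sdlog = 1, depth_sdlog = 0.25, l2fc = 3,
    patterns = NULL), expression)
  cfg$f1 <- utils::modifyList(list(
    n_offspring = 218, sterile_fraction = 16 / 218, mislabel_rate = 0),
    f1)
  cfg$genotypes <- utils::modifyList(list(
    n_samples = 50, n_snps = 400, block_snps = 20, copy_prob = 0.9,
    region_length = 350000, maf_range = c(0.1, 0.5)), genotypes)
  validate_sim_config(cfg)
  structure(cfg, class = "sdr_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (ds_target < 0 || diversity_rate < 0 || intergenic_rate_factor < 0)
      abort("rates must be >= 0")
    if (breakpoint_index < 1 || breakpoint_index >= n_genes)
      abort("breakpoint must lie strictly between two gene bodies")
    if (frameshift_len %% 3 == 0)
      abort("frameshift deletion length must not be a multiple of 3")
    if (frameshift_gene <= breakpoint_index)
      abort("frameshift gene must be 3' of the breakpoint (F-linked vs H reference)")
    if (frameshift_gene > n_genes) abort("frameshift gene index out of range")
    if (length < n_genes * (3 * cds_codons + 4000))
      abort("region too short for the requested gene count")
  })
  invisible(cfg)
}

# coordinate mapping through an indel edit list (ancestral -> haplotype).
# indels: tibble(pos, len, type) where type "ins" inserts len bases AFTER
# ancestral position pos, and "del" removes ancestral [pos, pos+len-1].
map_anc_pos <- function(p, indels) {
  vapply(p, function(x) {
    off <- 0L
    for (i in seq_len(nrow(indels))) {
      if (indels$type[i] == "ins") {
        if (indels$pos[i] < x) off <- off + indels$len[i]
      } else {
        s <- indels$pos[i]; e <- s + indels$len[i] - 1L
        if (e < x) off <- off - indels$len[i]
        else if (s <= x) return(NA_integer_) # deleted
      }
    }
    as.integer(x + off)
  }, 1L)
}

build_hap_seq <- function(anc_chars, subs, indels, ins_seqs) {
  ch <- anc_chars
  if (nrow(subs)) ch[subs$pos] <- subs$to
  s <- chars_seq(ch)
  if (nrow(indels)) {
    o <- order(indels$pos, decreasing = TRUE)
    for (i in o) {
      if (indels$type[i] == "ins") {
        s <- paste0(seq_sub(s, 1, indels$pos[i]), ins_seqs[[indels$seq_id[i]]],
                    seq_sub(s, indels$pos[i] + 1L, nchar(s)))
      } else {
        s <- paste0(seq_sub(s, 1, indels$pos[i] - 1L),
                    seq_sub(s, indels$pos[i] + indels$len[i], nchar(s)))
      }
    }
  }
  s
}

#' Simulate an SDR haplotype panel with known truth
#'
#' Generates the full panel described by a [sim_config()]: an ancestral
#' region with intronless genes, M and F founder lineages carrying planted
#' synonymous/nonsynonymous/intergenic fixed differences (calibrated so the
#' realized M-F synonymous distance matches the target dS), the F-linked
#' frameshift deletion, class-specific structural variants, H founders
#' recombined from the F (5') and M (3') founders at the planted breakpoint,
#' and per-haplotype private diversity. Deterministic given the seed.
#'
#' @param config an `sdr_sim_config`.
#' @param out_dir optional directory; when given, FASTA/GFF3/labels and the
#'   truth JSON are written there.
#' @return a list of class `sdr_sim` with elements `haplotypes`
#'   (an `sdr_haplotype_set`; the first H haplotype is the conventional
#'   reference), `truth` (breakpoint, expected linked variants, expected
#'   per-gene clade patterns, implied divergence time) and
#'   `gene_alignments` (per-gene aligned CDS matrices across the panel).
#' @export
simulate_trio <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sdr_sim_config"))
  set.seed(config$seed)
  L <- config$length; ng <- config$n_genes
  cds_len <- 3L * config$cds_codons

  # --- gene layout ------------------------------------------------------
  spacing <- L %/% (ng + 1L)
  gene_start <- as.integer(seq_len(ng) * spacing)
  gene_end <- gene_start + cds_len - 1L
  gene_ids <- sprintf("gene%02d", seq_len(ng))

  # --- ancestral sequence ----------------------------------------------
  anc_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  sense <- setdiff(names(CODON_TABLE), c("TAA", "TAG", "TGA"))
  for (i in seq_len(ng)) {
    body <- c("ATG",
              sample(sense, config$cds_codons - 2L, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
    anc_chars[gene_start[i]:gene_end[i]] <- strsplit(paste(body, collapse = ""),
                                                     "")[[1]]
  }
  anc <- chars_seq(anc_chars)

  bp <- as.integer((gene_end[config$breakpoint_index] +
                    gene_start[config$breakpoint_index + 1L]) %/% 2L)

  codon_starts <- lapply(seq_len(ng), function(i) {
    seq(gene_start[i] + 3L, gene_end[i] - 3L, by = 3L) # internal codons
  })

  # --- frameshift deletion (F lineage) ---------------------------------
  fs_gene <- config$frameshift_gene
  fs_start <- gene_start[fs_gene] + 99L # inside CDS, codon boundary shifted
  fs <- tibble(pos = fs_start, len = config$frameshift_len, type = "del",
               seq_id = NA_character_, class = "F", sv = FALSE)

  # --- structural variants ---------------------------------------------
  clearance <- 1000L
  forbidden <- tibble(start = pmax(gene_start - 3500L, 1L),
                      end = pmin(gene_end + 500L, L))
  forbidden <- dplyr::bind_rows(forbidden,
                                tibble(start = bp - clearance, end = bp + clearance))
  ins_seqs <- list()
  sv_rows <- list()
  for (i in seq_along(config$sv_spec)) {
    sv <- config$sv_spec[[i]]
    lo <- if (identical(sv$region, "5p")) 1L else bp + clearance
    hi <- if (identical(sv$region, "5p")) bp - clearance else L
    need <- if (sv$type == "deletion") sv$length + 2L * clearance else 2L * clearance
    ok <- FALSE
    for (try in 1:200) {
      pos <- as.integer(sample(seq(lo + clearance, hi - need), 1))
      span <- tibble(start = pos - clearance,
                     end = pos + (if (sv$type == "deletion") sv$length else 0L) +
                       clearance)
      if (!any(forbidden$start <= span$end & forbidden$end >= span$start)) {
        ok <- TRUE; break
      }
    }
    if (!ok) abort("could not place structural variant; region too crowded")
    forbidden <- dplyr::bind_rows(forbidden, span)
    sid <- sprintf("sv%02d", i)
    if (sv$type == "insertion") ins_seqs[[sid]] <- random_dna(sv$length)
    sv_rows[[i]] <- tibble(pos = pos, len = as.integer(sv$length),
                           type = if (sv$type == "insertion") "ins" else "del",
                           seq_id = sid, class = sv$class, sv = TRUE)
  }
  sv_tbl <- dplyr::bind_rows(sv_rows, fs)

  # positions never available for substitutions: deleted spans + a buffer
  # around every indel boundary (keeps planted substitutions from merging
  # into SV alignment gaps), stop and start codons
  buffer <- 100L
  blocked <- dplyr::bind_rows(
    purrr::pmap_dfr(sv_tbl, function(pos, len, type, ...) {
      if (type == "del") tibble(start = pos - buffer, end = pos + len + buffer)
      else tibble(start = pos - buffer, end = pos + buffer)
    }),
    tibble(start = gene_start, end = gene_start + 2L),
    tibble(start = gene_end - 2L, end = gene_end))
  blocked_mask <- rep(FALSE, L)
  for (i in seq_len(nrow(blocked))) {
    blocked_mask[max(1L, blocked$start[i]):min(L, blocked$end[i])] <- TRUE
  }

  # --- planted fixed differences ---------------------------------------
  used_codon <- rep(FALSE, L) # marks whole codons already mutated
  fixed <- list()
  add_fixed <- function(pos, lineage, type, gene) {
    from <- anc_chars[pos]
    to <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
    fixed[[length(fixed) + 1]] <<- tibble(pos = pos, lineage = lineage,
                                          from = from, to = to, type = type,
                                          gene = gene)
    to
  }

  # synonymous: 4-fold degenerate third positions, calibrated to ds_target
  fourfold <- lapply(seq_len(ng), function(i) {
    cs <- codon_starts[[i]]
    keep <- vapply(cs, function(s) {
      if (any(blocked_mask[s:(s + 2L)])) return(FALSE)
      codon <- chars_seq(anc_chars[s:(s + 2L)])
      aa <- codon_aa(codon)
      alts <- vapply(c("A", "C", "G", "T"), function(b) {
        codon_aa(paste0(substr(codon, 1, 2), b))
      }, "")
      all(alts == aa)
    }, TRUE)
    cs[keep]
  })
  S_total <- 0
  for (i in seq_len(ng)) {
    cds <- seq_sub(anc, gene_start[i], gene_end[i])
    nc <- nchar(cds) %/% 3
    cods <- substring(cds, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
    cods <- cods[!is_stop_codon(cods)]
    S_total <- S_total + sum(SYN_SITES[cods])
  }
  pS <- 0.75 * (1 - exp(-4 * config$ds_target / 3))
  n_syn <- round(pS * S_total)
  if (n_syn > sum(lengths(fourfold))) {
    abort(sprintf(paste0("dS target %.4g infeasible: needs %d synonymous ",
                         "differences but only %d four-fold codons available; ",
                         "increase CDS length to >= %d codons total"),
                  config$ds_target, n_syn, sum(lengths(fourfold)),
                  ceiling(n_syn / 0.15)))
  }
  # allocation: round-robin minimum per (gene, lineage), remainder random
  cells <- expand.grid(gene = seq_len(ng), lineage = c("M", "F"),
                       stringsAsFactors = FALSE)
  alloc <- rep(0L, nrow(cells))
  base_total <- min(n_syn, config$min_syn_per_gene * nrow(cells))
  if (base_total > 0) {
    reps <- rep(seq_len(nrow(cells)), length.out = base_total)
    alloc <- alloc + tabulate(reps, nbins = nrow(cells))
  }
  rem <- n_syn - sum(alloc)
  if (rem > 0) {
    extra <- sample(seq_len(nrow(cells)), rem, replace = TRUE)
    alloc <- alloc + tabulate(extra, nbins = nrow(cells))
  }
  for (ci in seq_len(nrow(cells))) {
    g <- cells$gene[ci]; lin <- cells$lineage[ci]
    avail <- fourfold[[g]][!used_codon[fourfold[[g]]]]
    k <- min(alloc[ci], length(avail))
    if (k == 0) next
    chosen <- if (length(avail) == 1) avail else sample(avail, k)
    for (s in chosen) {
      used_codon[s] <- TRUE
      p <- s + 2L # third position
      from <- anc_chars[p]
      to <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
      fixed[[length(fixed) + 1]] <- tibble(pos = p, lineage = lin,
                                           from = from, to = to,
                                           type = "syn", gene = gene_ids[g])
    }
  }

  # nonsynonymous: first/second codon positions, never creating stops
  for (g in seq_len(ng)) {
    for (lin in c("M", "F")) {
      placed <- 0
      guard <- 0
      while (placed < config$nonsyn_per_gene && guard < 500) {
        guard <- guard + 1
        s <- sample(codon_starts[[g]], 1)
        if (used_codon[s] || any(blocked_mask[s:(s + 2L)])) next
        codon <- anc_chars[s:(s + 2L)]
        ppos <- sample(1:2, 1)
        from <- codon[ppos]
        for (to in sample(setdiff(c("A", "C", "G", "T"), from))) {
          mut <- codon; mut[ppos] <- to
          mc <- chars_seq(mut)
          if (!is_stop_codon(mc) && codon_aa(mc) != codon_aa(chars_seq(codon))) {
            used_codon[s] <- TRUE
            fixed[[length(fixed) + 1]] <- tibble(pos = s + ppos - 1L,
                                                 lineage = lin, from = from,
                                                 to = to, type = "nonsyn",
                                                 gene = gene_ids[g])
            placed <- placed + 1
            break
          }
        }
      }
    }
  }

  # intergenic fixed differences at a fraction of the synonymous rate
  in_gene <- rep(FALSE, L)
  for (i in seq_len(ng)) in_gene[gene_start[i]:gene_end[i]] <- TRUE
  nc_pool <- which(!in_gene & !blocked_mask)
  p_nc <- config$intergenic_rate_factor * pS
  n_nc <- stats::rbinom(1, length(nc_pool), p_nc)
  if (n_nc > 0) {
    for (p in sample(nc_pool, n_nc)) {
      add_fixed(p, sample(c("M", "F"), 1), "intergenic", NA_character_)
    }
  }
  fixed <- if (length(fixed)) dplyr::bind_rows(fixed) else
    tibble(pos = integer(), lineage = character(), from = character(),
           to = character(), type = character(), gene = character())
  fixed <- dplyr::arrange(fixed, .data$pos)

  # --- founder edit lists ----------------------------------------------
  founder_subs <- function(class) {
    if (class == "H") {
      dplyr::bind_rows(fixed[fixed$lineage == "F" & fixed$pos <= bp, ],
                       fixed[fixed$lineage == "M" & fixed$pos > bp, ])
    } else fixed[fixed$lineage == class, ]
  }
  founder_indels <- function(class) {
    if (class == "H") {
      dplyr::bind_rows(sv_tbl[sv_tbl$class == "F" & sv_tbl$pos <= bp, ],
                       sv_tbl[sv_tbl$class == "M" & sv_tbl$pos > bp, ])
    } else sv_tbl[sv_tbl$class == class, ]
  }

  # --- private diversity ------------------------------------------------
  classes <- c(rep("M", config$n_m), rep("F", config$n_f), rep("H", config$n_h))
  accs <- c(sprintf("M%02d", seq_len(config$n_m)),
            sprintf("F%02d", seq_len(config$n_f)),
            sprintf("H%02d", seq_len(config$n_h)))
  taken <- rep(FALSE, L)
  taken[fixed$pos] <- TRUE
  priv_pool <- which(!blocked_mask & !taken)
  private <- lapply(seq_along(accs), function(i) {
    k <- stats::rbinom(1, L, config$diversity_rate)
    if (k == 0 || !length(priv_pool)) {
      return(tibble(pos = integer(), to = character()))
    }
    cand <- sample(priv_pool, min(2L * k + 10L, length(priv_pool)))
    picks <- integer(0); tos <- character(0)
    for (p in cand) {
      if (length(picks) >= k) break
      if (in_gene[p]) { # avoid creating stops in the coding frame
        gidx <- which(gene_start <= p & gene_end >= p)
        off <- (p - gene_start[gidx]) %% 3L
        s <- p - off
        codon <- anc_chars[s:(s + 2L)]
        alts <- setdiff(c("A", "C", "G", "T"), anc_chars[p])
        safe <- alts[vapply(alts, function(b) {
          mut <- codon; mut[off + 1L] <- b
          !is_stop_codon(chars_seq(mut))
        }, TRUE)]
        if (!length(safe)) next
        picks <- c(picks, p); tos <- c(tos, sample(safe, 1))
      } else {
        picks <- c(picks, p)
        tos <- c(tos, sample(setdiff(c("A", "C", "G", "T"), anc_chars[p]), 1))
      }
    }
    priv_pool <<- priv_pool[!priv_pool %in% picks]
    tibble(pos = as.integer(picks), to = tos)
  })

  # --- build haplotypes -------------------------------------------------
  species_of <- c(M = "Vitis_sim_male", F = "Vitis_sim_female",
                  H = "Vitis_sim_herm")
  haps <- vector("list", length(accs))
  for (i in seq_along(accs)) {
    cls <- classes[i]
    subs <- founder_subs(cls)[, c("pos", "to")]
    ind <- founder_indels(cls)
    pv <- private[[i]]
    if (nrow(pv)) {
      keep <- !is.na(map_anc_pos(pv$pos, ind))
      pv <- pv[keep, , drop = FALSE]
      subs <- dplyr::bind_rows(subs, pv)
    }
    seqi <- build_hap_seq(anc_chars, subs, ind, ins_seqs)
    genes <- purrr::map_dfr(seq_len(ng), function(g) {
      gs <- map_anc_pos(gene_start[g], ind)
      ge <- map_anc_pos(gene_end[g], ind)
      partial <- FALSE
      if (cls == "F" && g == fs_gene) { partial <- TRUE }
      gene_model(gene_ids[g], gs, ge, "+",
                 tibble(start = gs, end = ge, phase = 0L), partial = partial)
    })
    haps[[i]] <- annotated_haplotype(accs[i], unname(species_of[cls]), cls,
                                     seqi, genes)
  }
  set <- new_haplotype_set(haps)
  ref <- set[[which(classes == "H")[1]]]

  # --- truth: expected calls against the H reference -------------------
  ref_ind <- founder_indels("H")
  ref_chars <- seq_chars(ref$seq)
  truth_snvs <- local({
    five <- fixed$pos <= bp
    rp <- map_anc_pos(fixed$pos, ref_ind)
    h_has_mut <- (five & fixed$lineage == "F") | (!five & fixed$lineage == "M")
    keep <- !is.na(rp)
    tibble(pos = rp, ref = ifelse(h_has_mut, fixed$to, fixed$from),
           alt = ifelse(h_has_mut, fixed$from, fixed$to),
           var_class = "SNP", linked_class = ifelse(five, "M", "F"),
           length = 1L, planted_type = fixed$type, gene = fixed$gene)[keep, ]
  })
  # expected SV calls vs reference: carried by H iff class matches the
  # H side of the breakpoint; otherwise seen in the carrier class itself
  truth_svs <- purrr::pmap_dfr(sv_tbl[sv_tbl$sv, ], function(pos, len, type,
                                                             seq_id, class, sv) {
    five <- pos <= bp
    h_carries <- (five && class == "F") || (!five && class == "M")
    rp <- map_anc_pos(pos, ref_ind)
    if (h_carries) {
      # reference carries the event; the OTHER diverged class shows the
      # mirror call, linked to that class
      linked <- if (class == "M") "F" else "M"
      if (type == "ins") {
        tibble(pos = rp, end = rp + len, var_class = "SV_deletion",
               sv_len = len, linked_class = linked)
      } else {
        tibble(pos = rp, end = rp + len, var_class = "SV_insertion",
               sv_len = len, linked_class = linked)
      }
    } else {
      # projected interval [pos, pos + len] for either type, matching the
      # classifier's reciprocal-overlap convention
      tibble(pos = rp, end = rp + len,
             var_class = if (type == "ins") "SV_insertion" else "SV_deletion",
             sv_len = len, linked_class = class)
    }
  })
  # the F frameshift deletion: H/M intact, all F deleted -> F-linked indel,
  # left-normalized exactly as the caller reports it
  fs_rp <- map_anc_pos(fs_start, ref_ind)
  fs_ref_allele <- chars_seq(ref_chars[(fs_rp - 1L):(fs_rp + config$frameshift_len - 1L)])
  fs_norm <- left_normalize_indel(ref$seq, fs_rp - 1L, fs_ref_allele,
                                  substr(fs_ref_allele, 1, 1))
  truth_fs <- tibble(pos = fs_norm$pos1, ref = fs_norm$ref, alt = fs_norm$alt,
                     var_class = "small_indel", linked_class = "F",
                     length = config$frameshift_len,
                     planted_type = "frameshift", gene = gene_ids[fs_gene])

  clade_truth <- tibble(
    gene_id = gene_ids,
    verdict = ifelse(seq_len(ng) <= config$breakpoint_index,
                     "M_separated", "F_separated"))

  truth <- list(
    reference = ref$accession,
    breakpoint = list(anc_pos = bp,
                      ref_pos = map_anc_pos(bp, ref_ind),
                      left_gene = gene_ids[config$breakpoint_index],
                      right_gene = gene_ids[config$breakpoint_index + 1L]),
    linked_snvs = truth_snvs,
    linked_indel = truth_fs,
    linked_svs = truth_svs,
    clade_pattern = clade_truth,
    frameshift = list(gene = gene_ids[fs_gene], len = config$frameshift_len,
                      cds_offset = fs_start - gene_start[fs_gene] + 1L),
    ds_target = config$ds_target,
    true_time_years = config$ds_target / (2 * config$mu) * config$gen_time,
    gene_layout = tibble(gene_id = gene_ids, start = gene_start,
                         end = gene_end))

  # --- per-gene aligned ortholog CDSs ----------------------------------
  fs_cds_off <- fs_start - gene_start[fs_gene] + 1L
  gene_aln <- lapply(seq_len(ng), function(g) {
    out <- vapply(seq_along(accs), function(i) {
      s <- gene_cds_seq(set[[i]], gene_ids[g])
      if (g == fs_gene && classes[i] == "F") {
        s <- paste0(substr(s, 1, fs_cds_off - 1L),
                    strrep("-", config$frameshift_len),
                    substr(s, fs_cds_off, nchar(s)))
      }
      s
    }, "")
    stats::setNames(out, accs)
  })
  names(gene_aln) <- gene_ids

  res <- structure(list(haplotypes = set, truth = truth,
                        gene_alignments = gene_aln, config = config),
                   class = "sdr_sim")
  if (!is.null(out_dir)) {
    write_haplotype_set(set, out_dir)
    jsonlite::write_json(
      truth, file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    for (g in gene_ids) {
      writeLines(paste0(">", names(gene_aln[[g]]), "\n", gene_aln[[g]]),
                 file.path(out_dir, sprintf("aln_%s.fasta", g)))
    }
  }
  res
}

#' @export
print.sdr_sim <- function(x, ...) {
  cat(sprintf("<sdr_sim> %d haplotypes, %d genes, breakpoint %s|%s (ref pos %s)\n",
              length(x$haplotypes), x$config$n_genes,
              x$truth$breakpoint$left_gene, x$truth$breakpoint$right_gene,
              format(x$truth$breakpoint$ref_pos, big.mark = ",")))
  invisible(x)
}

#' Simulate an F1 mapping population from an FF x MF cross
#'
#' Offspring genotypes are drawn 1:1 between M-carrier (`MF`) and
#' F-homozygote (`FF`); sex phenotype equals the genotype class (perfect
#' cosegregation) unless a mislabel rate is configured. A configurable
#' fraction never flowers and is flagged without phenotype.
#'
#' @param config an `sdr_sim_config` (uses the `f1` block).
#' @return tibble: `individual`, `genotype` (`MF`/`FF`), `phenotype`
#'   (`male`/`female`/`NA`), `inflorescence` (logical).
#' @export
simulate_f1 <- function(config) {
  stopifnot(inherits(config, "sdr_sim_config"))
  set.seed(config$seed + 1003L)
  n <- config$f1$n_offspring
  if (n == 0) {
    return(tibble(individual = character(), genotype = character(),
                  phenotype = character(), inflorescence = logical()))
  }
  genotype <- sample(c("MF", "FF"), n, replace = TRUE)
  phenotype <- ifelse(genotype == "MF", "male", "female")
  flip <- stats::runif(n) < config$f1$mislabel_rate
  phenotype[flip] <- ifelse(phenotype[flip] == "male", "female", "male")
  sterile <- stats::runif(n) < config$f1$sterile_fraction
  phenotype[sterile] <- NA_character_
  tibble(individual = sprintf("F1_%04d", seq_len(n)),
         genotype = genotype, phenotype = phenotype,
         inflorescence = !sterile)
}

#' Simulate an expression count matrix with planted sex patterns
#'
#' Negative-binomial counts around log-normal gene baselines with
#' per-sample depth factors; planted genes are shifted by a log2
#' fold-change in one sex class at designated stages.
#'
#' @param config an `sdr_sim_config` (uses the `expression` block). The
#'   `patterns` element is a tibble (`gene`, `stage`, `sex`, `direction`)
#'   or `NULL` for the default six planted patterns on SDR genes.
#' @return list: `counts` (genes x samples integer matrix), `design`
#'   (tibble: `sample`, `sex`, `stage`, `replicate`), `truth` (planted
#'   pattern tibble).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sdr_sim_config"))
  set.seed(config$seed + 2003L)
  ex <- config$expression
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  bg_ids <- if (ex$n_background > 0) sprintf("bg%03d", seq_len(ex$n_background))
            else character(0)
  genes <- c(gene_ids, bg_ids)
  patterns <- ex$patterns
  if (is.null(patterns)) {
    # default planted patterns on four genes spread across the region:
    # one female-high at two stages, one male-high at two stages, one
    # male-high and one female-low at single stages
    stages <- ex$stages
    pick <- function(frac) gene_ids[max(1L, round(frac * config$n_genes))]
    patterns <- tibble(
      gene = c(pick(0.64), pick(0.64), pick(0.5), pick(0.5), pick(0.79),
               pick(0.86)),
      stage = c(stages[1], stages[3], stages[1], stages[2], stages[2],
                stages[3]),
      sex = c("F", "F", "M", "M", "M", "F"),
      direction = c(1, 1, 1, 1, 1, -1))
    patterns <- patterns[!duplicated(patterns[, c("gene", "stage")]), ]
  }
  missing <- setdiff(patterns$gene, c(gene_ids, bg_ids))
  if (length(missing)) {
    abort(sprintf("planted pattern gene(s) not simulated: %s",
                  paste(missing, collapse = ", ")))
  }
  design <- tidyr::expand_grid(sex = c("M", "F", "H"), stage = ex$stages,
                               replicate = seq_len(ex$replicates))
  design$sample <- sprintf("%s_%s_r%d", design$sex, design$stage,
                           design$replicate)
  design <- design[, c("sample", "sex", "stage", "replicate")]
  base <- stats::rlnorm(length(genes), ex$baseline_meanlog, ex$baseline_sdlog)
  depth <- stats::rlnorm(nrow(design), 0, ex$depth_sdlog)
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(design),
                   dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- base * depth[j]
    hit <- patterns$stage == design$stage[j] & patterns$sex == design$sex[j]
    if (any(hit)) {
      idx <- match(patterns$gene[hit], genes)
      mu[idx] <- mu[idx] * 2^(ex$l2fc * patterns$direction[hit])
    }
    counts[, j] <- stats::rnbinom(length(genes), mu = mu,
                                  size = 1 / ex$dispersion)
  }
  list(counts = counts, design = design, truth = patterns)
}

#' @importFrom stats rlnorm
NULL

#' Simulate a phased genotype matrix with LD blocks
#'
#' Haplotype alleles within a block copy a per-sample founder allele with a
#' configurable probability, giving within-block correlation that decays
#' with the copy probability; blocks are mutually independent.
#'
#' @param config an `sdr_sim_config` (uses the `genotypes` block).
#' @param vcf_path optional path; when given, a phased VCF is written.
#' @return list: `pos` (SNP positions), `dosage` (samples x SNPs matrix of
#'   0/1/2), `samples`, and `block` (block index per SNP).
#' @export
simulate_genotype_matrix <- function(config, vcf_path = NULL) {
  stopifnot(inherits(config, "sdr_sim_config"))
  set.seed(config$seed + 3003L)
  gt <- config$genotypes
  pos <- sort(sample(seq_len(gt$region_length), gt$n_snps))
  block <- ((seq_len(gt$n_snps) - 1L) %/% gt$block_snps) + 1L
  samples <- sprintf("acc%03d", seq_len(gt$n_samples))
  hap <- function() {
    h <- integer(gt$n_snps)
    for (b in unique(block)) {
      idx <- which(block == b)
      p <- stats::runif(1, gt$maf_range[1], gt$maf_range[2])
      founder <- stats::rbinom(1, 1, p)
      copy <- stats::runif(length(idx)) < gt$copy_prob
      h[idx] <- ifelse(copy, founder, stats::rbinom(length(idx), 1, p))
    }
    h
  }
  h1 <- t(vapply(samples, function(s) hap(), integer(gt$n_snps)))
  h2 <- t(vapply(samples, function(s) hap(), integer(gt$n_snps)))
  dosage <- h1 + h2
  rownames(dosage) <- samples
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=sim_sdr>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    gts <- vapply(seq_len(gt$n_snps), function(i) {
      paste(sprintf("%d|%d", h1[, i], h2[, i]), collapse = "\t")
    }, "")
    rows <- sprintf("sim_sdr\t%d\tsnp%04d\tA\tG\t.\t.\t.\tGT\t%s",
                    pos, seq_len(gt$n_snps), gts)
    writeLines(c(hdr, rows), vcf_path)
  }
  list(pos = pos, dosage = dosage, samples = samples, block = block)
}
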