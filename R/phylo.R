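#' Pairwise evolutionary distances from an alignment
#'
#' Columns with residue coverage below `site_coverage` are removed first;
#' remaining gaps are handled by pairwise deletion. Models: `"p"`
#' (mismatch fraction), `"poisson"` (d = -ln(1 - p), for proteins), and
#' `"tn93"` (Tamura-Nei 1993 for DNA, with base frequencies observed from
#' each pair). Saturated pairs (p >= 1 or a non-positive log argument) are
#' flagged rather than silently dropped.
#'
#' @param aligned_seqs named character vector of equal-length aligned
#'   sequences (>= 3).
#' @param model `"p"`, `"poisson"` or `"tn93"`.
#' @param site_coverage minimum fraction of sequences with a residue for a
#'   column to be kept. The default (0.05) removes only near-empty
#'   columns; use 0.95 for partial-deletion behaviour.
#' @return a symmetric distance matrix of class `sdr_dist` with attributes
#'   `model`, `saturated` (logical matrix) and `n_sites`.
#' @export
pairwise_distance <- function(aligned_seqs, model = c("p", "poisson", "tn93"),
                              site_coverage = 0.05) {
  model <- match.arg(model)
  n <- length(aligned_seqs)
  if (n < 3) abort("need >= 3 sequences")
  if (length(unique(nchar(aligned_seqs))) != 1) {
    abort("aligned sequences must have equal length")
  }
  labs <- names(aligned_seqs) %||% as.character(seq_len(n))
  m <- do.call(rbind, strsplit(toupper(aligned_seqs), ""))
  missing_chars <- c("-", ".", "?", "N", "X")
  resid <- !(m %in% missing_chars)
  dim(resid) <- dim(m)
  keep <- colMeans(resid) >= site_coverage
  m <- m[, keep, drop = FALSE]
  resid <- resid[, keep, drop = FALSE]
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- resid[i, ] & resid[j, ]
      xi <- m[i, use]; xj <- m[j, use]
      L <- length(xi)
      if (L == 0) { D[i, j] <- D[j, i] <- NA; sat[i, j] <- sat[j, i] <- TRUE; next }
      if (model %in% c("p", "poisson")) {
        p <- mean(xi != xj)
        d <- if (model == "p") p else if (p < 1) -log(1 - p) else NA_real_
      } else {
        d <- tn93_distance(xi, xj)
      }
      if (is.na(d)) sat[i, j] <- sat[j, i] <- TRUE
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(D, class = c("sdr_dist", "matrix", "array"), model = model,
            saturated = sat, n_sites = ncol(m))
}

tn93_distance <- function(xi, xj) {
  L <- length(xi)
  fr <- (table(factor(xi, c("A", "C", "G", "T"))) +
         table(factor(xj, c("A", "C", "G", "T")))) / (2 * L)
  gA <- fr[["A"]]; gC <- fr[["C"]]; gG <- fr[["G"]]; gT <- fr[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diffs <- xi != xj
  P1 <- mean((xi == "A" & xj == "G") | (xi == "G" & xj == "A"))
  P2 <- mean((xi == "C" & xj == "T") | (xi == "T" & xj == "C"))
  Q <- mean(diffs) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (anyNA(c(w1, w2, w3)) || w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Neighbor-joining tree construction
#'
#' Standard Saitou-Nei agglomeration on a distance matrix: at each step the
#' pair minimising the Q criterion is joined; ties are broken by the
#' smallest label-pair index; negative branch lengths are clamped to zero.
#' The result is unrooted (trifurcating root node).
#'
#' @param D a symmetric distance matrix (an `sdr_dist` or plain matrix,
#'   >= 3 labels, finite entries).
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "sdr_dist")) {
    sat <- attr(D, "saturated")
    if (any(sat)) {
      idx <- which(sat & upper.tri(sat), arr.ind = TRUE)
      pairs <- apply(idx, 1, function(k) {
        paste(rownames(sat)[k[1]], colnames(sat)[k[2]], sep = "/")
      })
      abort(sprintf("saturated distances for pair(s): %s",
                    paste(pairs, collapse = ", ")))
    }
  }
  d <- unclass(D)
  attr(d, "model") <- NULL; attr(d, "saturated") <- NULL
  attr(d, "n_sites") <- NULL
  n <- nrow(d)
  if (n < 3) abort("need >= 3 taxa")
  if (any(!is.finite(d))) abort("distances must be finite")
  labs <- rownames(d) %||% as.character(seq_len(n))
  reps <- labs # newick fragment per active cluster
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (q[i, j] < best) { best <- q[i, j]; bi <- i; bj <- j }
      }
    }
    vi <- 0.5 * d[bi, bj] + (r[bi] - r[bj]) / (2 * (n - 2))
    vj <- d[bi, bj] - vi
    new_rep <- sprintf("(%s:%s,%s:%s)", reps[bi], fmt(vi), reps[bj], fmt(vj))
    keep <- setdiff(seq_len(n), c(bi, bj))
    nd <- 0.5 * (d[bi, keep] + d[bj, keep] - d[bi, bj])
    d2 <- matrix(0, n - 1, n - 1)
    d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
    d2[n - 1, seq_along(keep)] <- nd
    d2[seq_along(keep), n - 1] <- nd
    d <- d2
    reps <- c(reps[keep], new_rep)
    n <- n - 1
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", reps[1], fmt(v1), reps[2], fmt(v2),
                 reps[3], fmt(v3))
  ape::read.tree(text = txt)
}

# non-trivial bipartitions of an unrooted tree as canonical keys; the side
# not containing the first tip (alphabetically) is reported
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  out <- list()
  if (tree$Nnode < 2) return(out)
  for (node in (nt + 2):(nt + tree$Nnode)) { # skip the root
    tips <- tree$tip.label[phangorn_descendants(tree, node)]
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) >= 2 && length(side) <= nt - 2) {
      out[[length(out) + 1]] <- list(node = node, key = paste(sort(side),
                                                              collapse = "|"))
    }
  }
  out
}

# tip indices descending from an internal node (iterative postorder)
phangorn_descendants <- function(tree, node) {
  nt <- length(tree$tip.label)
  todo <- node; tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= nt])
    todo <- c(todo, kids[kids > nt])
  }
  tips
}

#' Bootstrap support for distance trees
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance + neighbor-joining tree per replicate, and reports for each
#' internal bipartition of the original tree the fraction of replicate
#' trees containing it. Deterministic given the seed. Replicates with
#' saturated distances are skipped (counted in the denominator).
#'
#' @inheritParams pairwise_distance
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return the original [ape::phylo] tree with supports (0..1) stored as
#'   internal `node.label`s.
#' @export
bootstrap_support <- function(aligned_seqs, model = "p", n_reps = 1000,
                              seed = 1, site_coverage = 0.05) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  tree <- neighbor_joining(pairwise_distance(aligned_seqs, model,
                                             site_coverage))
  splits <- tree_splits(tree)
  counts <- stats::setNames(numeric(length(splits)),
                            vapply(splits, `[[`, "", "key"))
  L <- nchar(aligned_seqs[[1]])
  chars <- strsplit(aligned_seqs, "")
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rs <- vapply(chars, function(x) paste(x[idx], collapse = ""), "")
    names(rs) <- names(aligned_seqs)
    bt <- tryCatch(neighbor_joining(pairwise_distance(rs, model,
                                                      site_coverage)),
                   error = function(e) NULL)
    if (is.null(bt)) next
    keys <- vapply(tree_splits(bt), `[[`, "", "key")
    hit <- names(counts) %in% keys
    counts[hit] <- counts[hit] + 1
  }
  supports <- counts / n_reps
  nt <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  for (s in splits) {
    labs[s$node - nt] <- format(supports[[s$key]], digits = 4)
  }
  tree$node.label <- labs
  tree
}

#' Sex-monophyly (exclusive clade) test
#'
#' Scans the unrooted tree's bipartitions for one isolating exactly the M
#' leaves, and one isolating exactly the F leaves. When both exist (possible
#' when H leaves fall outside both groups), the verdict is resolved by
#' bootstrap support if present, else by the length of the separating edge.
#'
#' @param tree an [ape::phylo]; node labels, if present, are read as
#'   bootstrap supports.
#' @param sex_labels tibble (`accession`, `sex_class`) or named vector
#'   covering every leaf.
#' @return one-row tibble: `verdict` (`M_separated`, `F_separated`,
#'   `none`), `support`, plus per-class detail columns.
#' @export
sex_clade_test <- function(tree, sex_labels) {
  if (is.data.frame(sex_labels)) {
    sex_labels <- stats::setNames(sex_labels$sex_class, sex_labels$accession)
  }
  if (!all(tree$tip.label %in% names(sex_labels))) {
    abort("every leaf needs a sex label")
  }
  cls <- sex_labels[tree$tip.label]
  nt <- length(tree$tip.label)
  find_side <- function(target) {
    tgt <- sort(tree$tip.label[cls == target])
    if (!length(tgt)) return(NULL)
    if (length(tgt) == 1) { # pendant edge isolates a singleton trivially
      tip <- match(tgt, tree$tip.label)
      eidx <- which(tree$edge[, 2] == tip)
      return(list(support = NA_real_,
                  edge_len = tree$edge.length[eidx] %||% NA_real_))
    }
    key <- paste(tgt, collapse = "|")
    for (s in tree_splits(tree)) {
      tips <- sort(tree$tip.label[phangorn_descendants(tree, s$node)])
      comp <- sort(setdiff(tree$tip.label, tips))
      if (identical(tips, tgt) || identical(comp, tgt)) {
        sup <- if (!is.null(tree$node.label)) {
          suppressWarnings(as.numeric(tree$node.label[s$node - nt]))
        } else NA_real_
        eidx <- which(tree$edge[, 2] == s$node)
        return(list(support = sup,
                    edge_len = if (length(eidx)) tree$edge.length[eidx]
                               else NA_real_))
      }
    }
    NULL
  }
  msep <- find_side("M"); fsep <- find_side("F")
  verdict <- "none"; support <- NA_real_
  if (!is.null(msep) && is.null(fsep)) { verdict <- "M_separated"; support <- msep$support }
  if (is.null(msep) && !is.null(fsep)) { verdict <- "F_separated"; support <- fsep$support }
  if (!is.null(msep) && !is.null(fsep)) {
    pick_m <- if (!is.na(msep$support) && !is.na(fsep$support)) {
      msep$support >= fsep$support
    } else if (!is.na(msep$edge_len) && !is.na(fsep$edge_len)) {
      msep$edge_len >= fsep$edge_len
    } else TRUE
    verdict <- if (pick_m) "M_separated" else "F_separated"
    support <- if (pick_m) msep$support else fsep$support
  }
  tibble(verdict = verdict, support = support,
         m_separated = !is.null(msep), f_separated = !is.null(fsep),
         m_support = msep$support %||% NA_real_,
         f_support = fsep$support %||% NA_real_)
}

#' Locate the recombination breakpoint from ordered clade patterns
#'
#' Brute-forces all n+1 cut positions of the gene-ordered pattern vector
#' under the model "M-separated left of the cut, F-separated right of it";
#' `none` verdicts cost half a mismatch on either side. All minimal cuts
#' are reported; more than one is flagged ambiguous.
#'
#' @param patterns tibble with `gene_id` and `verdict` ordered by reference
#'   coordinate (as from [sex_clade_test()] applied per gene).
#' @return tibble of minimal-mismatch cuts: `cut_index` (0..n), `left_gene`,
#'   `right_gene`, `mismatches`, `ambiguous`.
#' @export
locate_breakpoint <- function(patterns) {
  v <- patterns$verdict
  n <- length(v)
  if (n < 2) abort("need >= 2 genes")
  cost_left <- c(M_separated = 0, none = 0.5, F_separated = 1)
  cost_right <- c(M_separated = 1, none = 0.5, F_separated = 0)
  mm <- vapply(0:n, function(cut) {
    lhs <- if (cut >= 1) sum(cost_left[v[seq_len(cut)]]) else 0
    rhs <- if (cut < n) sum(cost_right[v[(cut + 1):n]]) else 0
    lhs + rhs
  }, 0)
  best <- which(mm == min(mm)) - 1L
  tibble(cut_index = best,
         left_gene = ifelse(best >= 1, patterns$gene_id[pmax(best, 1)],
                            NA_character_),
         right_gene = ifelse(best < n, patterns$gene_id[pmin(best + 1L, n)],
                             NA_character_),
         mismatches = mm[best + 1L],
         ambiguous = length(best) > 1)
}

#' Per-gene clade patterns across a panel
#'
#' Builds a distance tree per gene alignment, applies the sex-monophyly
#' test, and returns the gene-ordered pattern vector ready for
#' [locate_breakpoint()].
#'
#' @param gene_alignments named list of per-gene aligned sequence vectors
#'   (genes in reference coordinate order).
#' @param sex_labels as in [sex_clade_test()].
#' @param model distance model (default `"p"`; DNA alignments).
#' @param n_boot bootstrap replicates per gene (0 = none).
#' @param seed seed for bootstrap resampling.
#' @return a tibble of class `sdr_clade_patterns`: `gene_id`, `verdict`,
#'   `support` and the detail columns of [sex_clade_test()].
#' @export
clade_patterns <- function(gene_alignments, sex_labels, model = "p",
                           n_boot = 0, seed = 1) {
  res <- purrr::imap_dfr(gene_alignments, function(aln, gid) {
    tree <- if (n_boot > 0) {
      bootstrap_support(aln, model = model, n_reps = n_boot, seed = seed)
    } else {
      neighbor_joining(pairwise_distance(aln, model))
    }
    dplyr::mutate(sex_clade_test(tree, sex_labels), gene_id = gid,
                  .before = 1)
  })
  structure(res, class = c("sdr_clade_patterns", class(res)))
}
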