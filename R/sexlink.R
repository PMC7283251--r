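#' Strict sex-linkage classification of variants
#'
#' A variant is M-linked iff it is present in every M haplotype and absent
#' from every F and H haplotype (symmetrically for F). H haplotypes always
#' sit in the "other" pool; no H-linked class is emitted. Absence is only
#' asserted where the haplotype's alignment covers the site: sites uncovered
#' in at least one haplotype are flagged uncallable and never linked. SNPs
#' and small INDELs are matched by exact (pos, ref, alt) identity; SVs by
#' class plus reciprocal overlap. Each alternate allele of a multi-allelic
#' site is classified independently.
#'
#' @param variants tibble of calls from [call_variants()] across all query
#'   haplotypes (column `accession` identifies the query), all against the
#'   same reference, left-normalized.
#' @param sex_labels tibble (`accession`, `sex_class`) for the full panel
#'   including the reference haplotype.
#' @param coverage optional named list of per-accession callable intervals
#'   (tibbles with `start`, `end`, as in `align_pair()$coverage`); missing
#'   entries are treated as fully covered.
#' @param ro_min reciprocal-overlap threshold for SV identity (default 0.8).
#' @return tibble with one row per distinct variant / SV cluster: position,
#'   alleles, class, `linked_class` (`M`/`F`/`none`), `callable`, carrier
#'   counts per sex class and the carrier accession list.
#' @export
classify_sex_linked <- function(variants, sex_labels, coverage = NULL,
                                ro_min = 0.8) {
  sex_labels <- as_tibble(sex_labels)
  bad <- !sex_labels$sex_class %in% c("M", "F", "H")
  if (any(bad)) {
    abort(sprintf("unknown sex label '%s'",
                  paste(unique(sex_labels$sex_class[bad]), collapse = "', '")))
  }
  panel <- split(sex_labels$accession, sex_labels$sex_class)
  panel <- lapply(c(M = "M", F = "F", H = "H"), function(k) panel[[k]] %||% character(0))
  covered_at <- function(acc, lo, hi) {
    iv <- coverage[[acc]]
    if (is.null(iv)) return(TRUE)
    any(iv$start <= lo & iv$end >= hi)
  }
  decide <- function(carriers, lo, hi) {
    others <- setdiff(sex_labels$accession, carriers)
    unc <- others[!vapply(others, covered_at, TRUE, lo = lo, hi = hi)]
    callable <- length(unc) == 0
    cls <- vapply(carriers, function(a) {
      sex_labels$sex_class[match(a, sex_labels$accession)]
    }, "")
    linked <- "none"
    if (callable) {
      if (length(panel$M) && setequal(carriers, panel$M)) linked <- "M"
      else if (length(panel$F) && setequal(carriers, panel$F)) linked <- "F"
    }
    list(linked = linked, callable = callable,
         n_M = sum(cls == "M"), n_F = sum(cls == "F"), n_H = sum(cls == "H"))
  }

  v <- as_tibble(variants)
  small <- v[!startsWith(v$var_class, "SV_"), , drop = FALSE]
  svs <- v[startsWith(v$var_class, "SV_"), , drop = FALSE]

  out <- list()
  if (nrow(small)) {
    key <- paste(small$pos, small$ref, small$alt, sep = "\r")
    first <- !duplicated(key)
    uk <- key[first]
    u <- small[first, , drop = FALSE]
    u_end <- u$pos + nchar(u$ref) - 1L
    # carrier matrix: haplotype x variant
    acc_all <- sex_labels$accession
    carry <- matrix(FALSE, length(acc_all), length(uk),
                    dimnames = list(acc_all, NULL))
    carry[cbind(match(small$accession, acc_all), match(key, uk))] <- TRUE
    # coverage matrix via sorted-interval lookup per haplotype
    cov_ok <- matrix(TRUE, length(acc_all), length(uk))
    if (!is.null(coverage)) {
      for (ai in seq_along(acc_all)) {
        iv <- coverage[[acc_all[ai]]]
        if (is.null(iv)) next
        iv <- iv[order(iv$start), , drop = FALSE]
        j <- findInterval(u$pos, iv$start)
        cov_ok[ai, ] <- j >= 1 & iv$end[pmax(j, 1)] >= u_end
      }
    }
    n_by_class <- function(cls) {
      rows <- sex_labels$sex_class == cls
      if (!any(rows)) integer(ncol(carry)) else
        colSums(carry[rows, , drop = FALSE])
    }
    nM <- n_by_class("M"); nF <- n_by_class("F"); nH <- n_by_class("H")
    tM <- sum(sex_labels$sex_class == "M")
    tF <- sum(sex_labels$sex_class == "F")
    # a site is callable iff every non-carrier haplotype is covered there
    callable <- colSums(!carry & !cov_ok) == 0
    linked <- rep("none", length(uk))
    linked[callable & tM > 0 & nM == tM & nF == 0 & nH == 0] <- "M"
    linked[callable & tF > 0 & nF == tF & nM == 0 & nH == 0] <- "F"
    out[[1]] <- tibble(pos = u$pos, end = u_end, ref = u$ref, alt = u$alt,
                       var_class = u$var_class, linked_class = linked,
                       callable = callable, n_M = as.integer(nM),
                       n_F = as.integer(nF), n_H = as.integer(nH),
                       carriers = lapply(seq_along(uk), function(j) {
                         acc_all[carry[, j]]
                       }))
  }
  if (nrow(svs)) {
    out[[2]] <- purrr::map_dfr(split(svs, svs$var_class), function(g) {
      cl <- cluster_svs(g, ro_min)
      purrr::map_dfr(split(seq_len(nrow(g)), cl), function(idx) {
        rows <- g[idx, ]
        carriers <- unique(rows$accession)
        lo <- min(rows$pos); hi <- max(sv_interval_end(rows))
        d <- decide(carriers, lo, hi)
        tibble(pos = lo, end = hi, ref = rows$ref[1], alt = rows$alt[1],
               var_class = rows$var_class[1], linked_class = d$linked,
               callable = d$callable, n_M = d$n_M, n_F = d$n_F, n_H = d$n_H,
               carriers = list(carriers))
      })
    })
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(pos = integer(), end = integer(), ref = character(),
           alt = character(), var_class = character(),
           linked_class = character(), callable = logical(),
           n_M = integer(), n_F = integer(), n_H = integer(),
           carriers = list())
  dplyr::arrange(res, .data$pos)
}

# effective interval for reciprocal-overlap identity: the event length
# projected onto the reference ([pos, pos + sv_len]; for insertions this is
# the inserted length, for the other classes the affected reference span)
sv_interval_end <- function(x) x$pos + x$sv_len

cluster_svs <- function(g, ro_min) {
  s <- g$pos
  e <- sv_interval_end(g)
  n <- nrow(g)
  cl <- integer(n)
  reps <- list() # cluster representative intervals
  for (i in order(s)) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      ov <- min(e[i], reps[[k]][2]) - max(s[i], reps[[k]][1]) + 1
      if (ov > 0 &&
          ov / (e[i] - s[i] + 1) >= ro_min &&
          ov / (reps[[k]][2] - reps[[k]][1] + 1) >= ro_min) {
        cl[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1]] <- c(s[i], e[i])
      cl[i] <- length(reps)
    }
  }
  cl
}

#' Windowed density track of classified variants
#'
#' Counts classified variants per fixed-width window, normalized to
#' variants per kbp. Uncallable sites are excluded (reported separately via
#' the `callable` column of the input).
#'
#' @param calls tibble from [classify_sex_linked()].
#' @param region `c(start, end)` on the reference (default: span of calls).
#' @param window_bp window width in bp (> 0).
#' @param classes linkage classes to track.
#' @param callable_only drop uncallable calls first (default TRUE).
#' @return a tibble of class `sdr_density_track`: `window_start`,
#'   `window_end`, `linked_class`, `n`, `per_kbp`.
#' @export
density_track <- function(calls, region = NULL, window_bp = 1000,
                          classes = c("M", "F"), callable_only = TRUE) {
  if (window_bp <= 0) abort("window_bp must be > 0")
  if (is.null(region)) region <- c(1L, max(calls$pos, 1L))
  if (region[1] < 1 || region[2] < region[1]) abort("invalid region")
  if (callable_only) calls <- calls[calls$callable, , drop = FALSE]
  starts <- seq.int(region[1], region[2], by = window_bp)
  ends <- pmin(starts + window_bp - 1L, region[2])
  grid <- tidyr::expand_grid(linked_class = classes,
                             wi = seq_along(starts))
  res <- dplyr::mutate(grid,
    window_start = starts[.data$wi], window_end = ends[.data$wi])
  res$n <- vapply(seq_len(nrow(res)), function(i) {
    sum(calls$linked_class == res$linked_class[i] &
        calls$pos >= res$window_start[i] & calls$pos <= res$window_end[i])
  }, 0L)
  res <- dplyr::select(res, -"wi")
  res$per_kbp <- res$n * 1000 / window_bp
  structure(res, class = c("sdr_density_track", class(res)),
            window_bp = window_bp, region = region)
}

#' SV sharing table across sex classes
#'
#' Groups structural variants by class and reciprocal overlap and reports,
#' per cluster, the presence pattern across sex classes, the mean event
#' length, the linked class under the strict fixation rule, and an optional
#' repeat-composition tag.
#'
#' @param sv_calls tibble of SV calls (rows of [call_variants()] with an
#'   `SV_` class) across the panel.
#' @param sex_labels tibble (`accession`, `sex_class`) for the full panel.
#' @param coverage,ro_min as in [classify_sex_linked()].
#' @param repeats optional tibble of repeat intervals (`start`, `end`);
#'   clusters with > 50% overlap are tagged `"repeat"`, else `"unique"`.
#' @return tibble: cluster position/span, `var_class`, `n_M`, `n_F`,
#'   `n_H`, class totals, `mean_length`, `linked_class`, `composition`.
#' @export
sv_sharing_table <- function(sv_calls, sex_labels, coverage = NULL,
                             ro_min = 0.8, repeats = NULL) {
  calls <- classify_sex_linked(sv_calls, sex_labels, coverage, ro_min)
  totals <- table(factor(sex_labels$sex_class, c("M", "F", "H")))
  lens <- vapply(seq_len(nrow(calls)), function(i) {
    mean(abs(sv_calls$sv_len[sv_calls$pos >= calls$pos[i] - 1 &
                             sv_calls$var_class == calls$var_class[i] &
                             sv_calls$pos <= calls$end[i]]), na.rm = TRUE)
  }, 0)
  comp <- rep(NA_character_, nrow(calls))
  if (!is.null(repeats)) {
    comp <- vapply(seq_len(nrow(calls)), function(i) {
      ov <- sum(pmax(0, pmin(calls$end[i], repeats$end) -
                        pmax(calls$pos[i], repeats$start) + 1))
      if (ov / (calls$end[i] - calls$pos[i] + 1) > 0.5) "repeat" else "unique"
    }, "")
  }
  dplyr::mutate(calls, total_M = as.integer(totals[["M"]]),
                total_F = as.integer(totals[["F"]]),
                total_H = as.integer(totals[["H"]]),
                mean_length = lens, composition = comp)
}
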