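#' Read a labelled haplotype panel
#'
#' Reads a multi-record FASTA, a GFF3 annotation and a labels table into a
#' set of annotated haplotypes. FASTA record ids must match GFF3 seqids and
#' the `accession` column of the labels table; every record needs a label.
#'
#' @param fasta_path multi-record FASTA of haplotype sequences.
#' @param gff3_path GFF3 with `gene` and `CDS` features per haplotype
#'   (seqid = accession). GFF3 is the only annotation dialect accepted.
#' @param labels a TSV path or tibble with columns `accession`,
#'   `sex_class` (`M`/`F`/`H`) and `species`.
#' @return an `sdr_haplotype_set` (list of [annotated_haplotype()] objects,
#'   genes sorted by start).
#' @export
read_haplotype_set <- function(fasta_path, gff3_path, labels) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (is.character(labels)) {
    labels <- as_tibble(read.delim(labels, stringsAsFactors = FALSE))
  }
  labels <- as_tibble(labels)
  missing <- setdiff(ids, labels$accession)
  if (length(missing)) {
    abort(sprintf("no label for haplotype(s): %s",
                  paste(missing, collapse = ", ")))
  }
  orphan <- setdiff(labels$accession, ids)
  if (length(orphan)) {
    abort(sprintf("label without sequence: %s", paste(orphan, collapse = ", ")))
  }
  gff <- read_gff3(gff3_path)
  haps <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    lab <- labels[labels$accession == id, ][1, ]
    genes <- gff_to_genes(gff[gff$seqid == id, , drop = FALSE])
    h <- annotated_haplotype(id, lab$species, lab$sex_class,
                             as.character(seqs[[i]]), genes)
    bad <- which(vapply(h$genes$cds, function(cd) {
      nrow(cd) > 0 && max(cd$end) > nchar(h$seq)
    }, TRUE))
    if (length(bad)) abort(sprintf("CDS beyond sequence end in %s", id))
    h
  })
  new_haplotype_set(haps)
}

# minimal GFF3 reader (9 tab-separated columns, '#' comments)
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), phase = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) abort("malformed GFF3: expected 9 columns")
  f <- do.call(rbind, f)
  data.frame(seqid = f[, 1], type = f[, 3],
             start = as.integer(f[, 4]), end = as.integer(f[, 5]),
             strand = f[, 7], phase = f[, 8], attributes = f[, 9],
             stringsAsFactors = FALSE)
}

gff_attr <- function(attributes, key) {
  m <- regmatches(attributes,
                  regexec(paste0("(?:^|;)", key, "=([^;]+)"), attributes))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

gff_to_genes <- function(gff) {
  genes <- gff[gff$type == "gene", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(genes) == 0) return(NULL)
  ids <- gff_attr(genes$attributes, "ID")
  parents <- gff_attr(cds$attributes, "Parent")
  partial <- tolower(gff_attr(genes$attributes, "partial")) %in% "true"
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ci <- cds[!is.na(parents) & parents == ids[i], , drop = FALSE]
    cd <- tibble(start = ci$start, end = ci$end,
                 phase = ifelse(ci$phase == ".", 0L, as.integer(ci$phase)))
    gene_model(ids[i], genes$start[i], genes$end[i], genes$strand[i],
               cd[order(cd$start), ], partial = partial[i])
  })
  dplyr::bind_rows(rows)
}

#' Write a haplotype panel to FASTA + GFF3 + labels TSV
#'
#' @param set an `sdr_haplotype_set`.
#' @param dir output directory (created if absent). Writes
#'   `haplotypes.fasta`, `haplotypes.gff3` and `labels.tsv`.
#' @return invisibly, the three file paths.
#' @export
write_haplotype_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "haplotypes.fasta")
  gf <- file.path(dir, "haplotypes.gff3")
  lb <- file.path(dir, "labels.tsv")
  seqs <- Biostrings::DNAStringSet(vapply(set, `[[`, "", "seq"))
  names(seqs) <- names(set)
  Biostrings::writeXStringSet(seqs, fa, width = 80)
  lines <- "##gff-version 3"
  for (h in set) {
    for (i in seq_len(nrow(h$genes))) {
      g <- h$genes[i, ]
      attrs <- sprintf("ID=%s%s", g$gene_id,
                       if (g$partial) ";partial=true" else "")
      lines <- c(lines, paste(h$accession, "sdrscan", "gene", g$start, g$end,
                              ".", g$strand, ".", attrs, sep = "\t"))
      cd <- g$cds[[1]]
      for (j in seq_len(nrow(cd))) {
        lines <- c(lines, paste(h$accession, "sdrscan", "CDS", cd$start[j],
                                cd$end[j], ".", g$strand, cd$phase[j],
                                sprintf("ID=%s.cds%d;Parent=%s", g$gene_id, j,
                                        g$gene_id), sep = "\t"))
      }
    }
  }
  writeLines(lines, gf)
  labs <- purrr::map_dfr(set, function(h) {
    tibble(accession = h$accession, sex_class = h$sex_class,
           species = h$species)
  })
  write.table(labs, lb, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gf, labels = lb))
}

#' Write variant calls as VCF 4.2
#'
#' SNPs and small INDELs are written with explicit alleles (INDELs
#' left-anchored on a shared leading base); structural variants use symbolic
#' ALT alleles with `END`/`SVLEN`/`SVTYPE` INFO keys. Coordinates are
#' 1-based. Unsorted input is sorted, never rejected.
#'
#' @param variants tibble with columns `pos`, `ref`, `alt`, `var_class`
#'   (and `sv_len` for SVs) as produced by [call_variants()].
#' @param reference_id the reference haplotype id (CHROM column).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_variants_vcf <- function(variants, reference_id, path) {
  v <- dplyr::arrange(as_tibble(variants), .data$pos)
  ok <- grepl("^[ACGTN]+$", v$ref) & grepl("^[ACGTN]+$", v$alt)
  if (any(!ok)) abort("invalid alleles (must be non-empty ACGTN strings)")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", reference_id),
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(v)) {
    is_sv <- startsWith(v$var_class, "SV_")
    alt <- v$alt
    info <- rep(".", nrow(v))
    svtype <- c(SV_insertion = "INS", SV_deletion = "DEL",
                SV_inversion = "INV", SV_complex = "CPX")
    if (any(is_sv)) {
      alt[is_sv] <- sprintf("<%s>", svtype[v$var_class[is_sv]])
      end <- v$pos + nchar(v$ref) - 1L
      slen <- ifelse(v$var_class == "SV_deletion", -v$sv_len, v$sv_len)
      info[is_sv] <- sprintf("END=%d;SVLEN=%d;SVTYPE=%s", end[is_sv],
                             slen[is_sv], svtype[v$var_class[is_sv]])
      # symbolic records keep only the padding base as REF
      vref <- v$ref
      vref[is_sv] <- substr(vref[is_sv], 1, 1)
      v$ref <- vref
    }
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                    reference_id, v$pos, v$ref, alt, info)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read JASPAR position frequency matrices
#'
#' Parses JASPAR 4-row PFM text (one or more records, `A`/`C`/`G`/`T` rows,
#' counts optionally bracketed).
#'
#' @param path JASPAR PFM file.
#' @return a list of 4 x W count matrices (rows `A`, `C`, `G`, `T`), each
#'   with attributes `motif_id` and `motif_name`.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) abort("no JASPAR records found (missing '>' header)")
  out <- lapply(seq_along(starts), function(i) {
    from <- starts[i] + 1
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) != 4) abort("each JASPAR record needs 4 base rows")
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]]
    rows <- lapply(block, function(l) {
      body <- gsub("[\\[\\]]", " ", sub("^[ACGTacgt]", "", l))
      as.numeric(regmatches(body, gregexpr("-?[0-9.]+", body))[[1]])
    })
    if (length(unique(lengths(rows))) != 1 || lengths(rows)[1] < 1) {
      abort("JASPAR rows have unequal width")
    }
    m <- do.call(rbind, rows)
    if (any(m < 0)) abort("negative counts in PFM")
    bases <- toupper(substr(block, 1, 1))
    rownames(m) <- if (all(sort(bases) == c("A", "C", "G", "T"))) bases
                   else c("A", "C", "G", "T")
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    attr(m, "motif_id") <- hdr[1]
    attr(m, "motif_name") <- if (length(hdr) > 1) hdr[2] else hdr[1]
    m
  })
  names(out) <- vapply(out, attr, "", "motif_id")
  out
}

#' Write a phylogenetic tree as newick
#'
#' Thin wrapper over [ape::write.tree()] that rejects duplicate leaf labels.
#' Bootstrap supports stored as node labels are preserved.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file; if `NULL`, the newick string is returned.
#' @return the newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels")
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
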