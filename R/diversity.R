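#' Multiple alignment of conspecific mitogenome variants
#'
#' Builds a center-star multiple alignment from global pairwise
#' alignments of every variant against the longest one (match +1,
#' mismatch -1, gap -2 by default — a linear gap penalty). Conspecific
#' variants are near-identical, for which center-star alignment is
#' essentially exact. Pre-aligned input (all sequences the same length)
#' is accepted verbatim. Inputs whose pairwise identity to the center
#' falls below `min_identity` are refused: they are probably not
#' conspecific variants.
#'
#' @param sequences named character vector (or `DNAStringSet`, or list)
#'   of >= 2 nucleotide sequences; `N` marks missing data.
#' @param match,mismatch,gap alignment scores (defaults +1, -1, -2).
#' @param min_identity refusal threshold on pairwise identity
#'   (default 0.70).
#' @return object of class `VariantAlignment`: `ids`, `matrix`
#'   (character matrix, variants x columns), `reference` (id of the
#'   first input, the coordinate system for SNP positions).
#' @export
align_variants <- function(sequences, match = 1, mismatch = -1, gap = 2,
                           min_identity = 0.70) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  sequences <- unlist(as.list(sequences))
  if (length(sequences) < 2L) stop("need at least 2 variant sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("variant", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  ids <- names(sequences)
  lens <- nchar(sequences)

  if (length(unique(lens)) == 1L) {          # pre-aligned (or gap-free)
    mat <- t(vapply(sequences, function(s) seq_chars(s),
                    character(lens[1])))
    rownames(mat) <- ids
    return(structure(list(ids = ids, matrix = mat, reference = ids[1]),
                     class = "VariantAlignment"))
  }

  center <- which.max(lens)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  n_center <- lens[center]
  slot_counts <- vector("list", length(sequences))
  aligned_other <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    if (i == center) {
      slot_counts[[i]] <- integer(n_center + 1L)
      aligned_other[[i]] <- seq_chars(sequences[[i]])
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sequences[[i]]),
      Biostrings::DNAString(sequences[[center]]),
      substitutionMatrix = submat, gapOpening = 0, gapExtension = abs(gap),
      type = "global")
    ac0 <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    ao0 <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    both <- ac0 %in% c("A", "C", "G", "T") & ao0 %in% c("A", "C", "G", "T")
    idy <- if (any(both)) mean(ac0[both] == ao0[both]) else 0
    if (idy < min_identity) {
      stop("pairwise identity of '", ids[i], "' to '", ids[center],
           "' is ", sprintf("%.1f%%", 100 * idy), " (< ",
           sprintf("%.0f%%", 100 * min_identity),
           "): inputs are probably not conspecific variants")
    }
    ac <- ac0
    ao <- ao0
    # per-slot gap counts of the aligned center: slot k = gaps between
    # center residue k and k+1 (slot 0 before the first residue)
    slots <- integer(n_center + 1L)
    k <- 0L
    for (pos in seq_along(ac)) {
      if (ac[pos] == "-") slots[k + 1L] <- slots[k + 1L] + 1L
      else k <- k + 1L
    }
    slot_counts[[i]] <- slots
    aligned_other[[i]] <- list(ac = ac, ao = ao)
  }
  master <- do.call(pmax, slot_counts)

  center_chars <- seq_chars(sequences[[center]])
  build_row <- function(i) {
    if (i == center) {
      # center row (or verbatim row): insert master gaps between residues
      out <- character(0)
      for (k in 0:n_center) {
        out <- c(out, rep("-", master[k + 1L]),
                 if (k < n_center) center_chars[k + 1L])
      }
      return(out)
    }
    al <- aligned_other[[i]]
    out <- character(0)
    pos <- 1L
    for (k in 0:n_center) {
      seg <- character(0)
      while (pos <= length(al$ac) && al$ac[pos] == "-") {
        seg <- c(seg, al$ao[pos]); pos <- pos + 1L
      }
      seg <- c(seg, rep("-", master[k + 1L] - length(seg)))
      out <- c(out, seg)
      if (k < n_center) {
        out <- c(out, al$ao[pos]); pos <- pos + 1L
      }
    }
    out
  }
  rows <- lapply(seq_along(sequences), build_row)
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  structure(list(ids = ids, matrix = mat, reference = ids[1]),
            class = "VariantAlignment")
}

#' @export
print.VariantAlignment <- function(x, ...) {
  cat("VariantAlignment:", length(x$ids), "variants x", ncol(x$matrix),
      "columns (reference:", x$reference, ")\n")
  invisible(x)
}

# map alignment columns to 1-based coordinates on the reference row
# (NA at columns where the reference has a gap)
reference_positions <- function(aln) {
  ref_row <- aln$matrix[aln$reference, ]
  pos <- cumsum(ref_row != "-")
  pos[ref_row == "-"] <- NA_integer_
  pos
}

#' Call SNPs across aligned conspecific variants
#'
#' A column is a SNP iff at least two distinct characters among
#' `{A,C,G,T}` occur in it; gaps and `N` are missing data, never
#' alleles. Positions are reported on the reference variant's (the
#' first input's) ungapped coordinate system. When an annotation is
#' supplied each SNP is assigned to the gene whose interval contains it,
#' or `"intergenic"`.
#'
#' @param alignment a [align_variants()] result, or a character matrix
#'   (variants x columns, rownames as ids).
#' @param annotation optional [mito_genome()] or annotation data.frame
#'   (`symbol`, `start`, `end`) on the reference coordinate system.
#' @return data.frame of class `SnpTable`: `position`, `gene`,
#'   `n_alleles`, then one allele column per variant (`NA` = missing
#'   call). Attribute `reference` holds the reference variant id.
#' @export
call_snps <- function(alignment, annotation = NULL) {
  if (is.matrix(alignment)) {
    ids <- rownames(alignment) %||% paste0("variant", seq_len(nrow(alignment)))
    alignment <- structure(list(ids = ids, matrix = alignment,
                                reference = ids[1]),
                           class = "VariantAlignment")
  }
  mat <- alignment$matrix
  if (ncol(mat) < 1L) stop("alignment has no columns")
  acgt <- c("A", "C", "G", "T")
  n_distinct <- apply(mat, 2L, function(col) length(unique(col[col %in% acgt])))
  snp_cols <- which(n_distinct >= 2L)
  pos <- reference_positions(alignment)
  ann <- annotation
  if (inherits(ann, "MitoGenome")) ann <- ann$annotations
  gene_at <- function(p) {
    if (is.na(p) || is.null(ann)) return(if (is.null(ann)) NA_character_
                                          else "intergenic")
    hit <- which((!ann$start > ann$end & ann$start <= p & p <= ann$end) |
                   (ann$start > ann$end & (p >= ann$start | p <= ann$end)))
    if (length(hit)) ann$symbol[hit[1]] else "intergenic"
  }
  out <- data.frame(position = pos[snp_cols],
                    gene = vapply(pos[snp_cols], gene_at, ""),
                    n_alleles = n_distinct[snp_cols],
                    stringsAsFactors = FALSE)
  alleles <- t(mat[, snp_cols, drop = FALSE])
  alleles[!alleles %in% acgt] <- NA_character_
  colnames(alleles) <- alignment$ids
  out <- cbind(out, as.data.frame(alleles, stringsAsFactors = FALSE))
  o <- order(out$position)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- alignment$reference
  class(out) <- c("SnpTable", "data.frame")
  out
}

# pi over a set of alignment columns: mean over all distinct sequence
# pairs of per-site differences, missing (gap/N) columns excluded
# pairwise; NA when no pair has comparable sites
nucleotide_diversity <- function(mat) {
  n <- nrow(mat)
  acgt <- c("A", "C", "G", "T")
  if (n < 2L || ncol(mat) == 0L) return(NA_real_)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] %in% acgt & mat[j, ] %in% acgt
      if (!any(ok)) next
      vals <- c(vals, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Per-gene SNP tallies and nucleotide diversity
#'
#' Summarizes a SNP table per protein-coding gene: SNP count, ungapped
#' reference gene length, SNP density and nucleotide diversity
#' \eqn{\pi} (mean pairwise proportion of differing sites, missing data
#' excluded pairwise; every sequence in the alignment counts, so a
#' duplicated variant does affect \eqn{\pi} — the convention is
#' documented and tested). Totals are sums over the summarized genes;
#' total \eqn{\pi} is computed over the concatenated gene columns.
#'
#' @param snp_table a [call_snps()] table.
#' @param annotation a [mito_genome()] or annotation data.frame;
#'   must cover `genes`.
#' @param alignment the [align_variants()] alignment the SNPs came from.
#' @param genes gene symbols to summarize (default: all annotated PCGs).
#' @return object of class `DiversityReport`: `per_gene` data.frame
#'   (`gene`, `length`, `snp_count`, `snp_density`, `pi`),
#'   `total_length`, `total_snps`, `snp_density`, `pi`, `n_variants`.
#' @export
diversity_report <- function(snp_table, annotation, alignment,
                             genes = NULL) {
  ann <- if (inherits(annotation, "MitoGenome")) annotation$annotations
         else as.data.frame(annotation)
  if (is.null(ann$class)) ann$class <- feature_class_of(ann$symbol)
  if (is.null(genes)) genes <- ann$symbol[ann$class == "PCG"]
  missing_genes <- setdiff(genes, ann$symbol)
  if (length(missing_genes)) {
    stop("gene(s) absent from annotation: ",
         paste(missing_genes, collapse = ", "))
  }
  pos <- reference_positions(alignment)
  mat <- alignment$matrix
  rows <- list(); all_cols <- integer(0)
  for (g in genes) {
    a <- ann[ann$symbol == g, ][1, ]
    if (a$start <= a$end) {
      cols <- which(!is.na(pos) & pos >= a$start & pos <= a$end)
      glen <- a$end - a$start + 1L
    } else {                                 # wrapped gene
      cols <- which(!is.na(pos) & (pos >= a$start | pos <= a$end))
      glen <- max(pos, na.rm = TRUE) - a$start + 1L + a$end
    }
    all_cols <- c(all_cols, cols)
    snps <- sum(snp_table$gene == g, na.rm = TRUE)
    rows[[g]] <- data.frame(
      gene = g, length = glen, snp_count = snps,
      snp_density = if (glen > 0) snps / glen else NA_real_,
      pi = nucleotide_diversity(mat[, cols, drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows); rownames(per_gene) <- NULL
  total_length <- sum(per_gene$length)
  total_snps <- sum(per_gene$snp_count)
  structure(list(per_gene = per_gene,
                 total_length = total_length, total_snps = total_snps,
                 snp_density = if (total_length > 0)
                   total_snps / total_length else NA_real_,
                 pi = nucleotide_diversity(mat[, all_cols, drop = FALSE]),
                 n_variants = nrow(mat)),
            class = "DiversityReport")
}

#' @export
print.DiversityReport <- function(x, ...) {
  cat(sprintf(
    "DiversityReport: %d variants | %d genes | %d SNPs / %d nt (density %.3g) | pi %.3g\n",
    x$n_variants, nrow(x$per_gene), x$total_snps, x$total_length,
    x$snp_density, x$pi))
  invisible(x)
}

#' Fold difference in diversity between two variant sets
#'
#' Reports both defined ratios — SNP density and \eqn{\pi} — of set `b`
#' relative to set `a`. No single "the" fold difference is asserted:
#' different summary statistics yield different ratios, so both are
#' returned, labelled.
#'
#' @param report_a,report_b [diversity_report()] objects (or lists with
#'   `snp_density` and `pi`).
#' @return list: `density_ratio`, `pi_ratio`, `infinite` flag (set when
#'   a denominator is zero; the ratio is then `Inf`).
#' @examples
#' a <- list(snp_density = 1e-3, pi = 1e-3)
#' b <- list(snp_density = 2e-2, pi = 2e-2)
#' fold_difference(a, b)$density_ratio  # 20
#' @export
fold_difference <- function(report_a, report_b) {
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) return(Inf)
    num / den
  }
  dr <- ratio(report_b$snp_density, report_a$snp_density)
  pr <- ratio(report_b$pi, report_a$pi)
  list(density_ratio = dr, pi_ratio = pr,
       infinite = (!is.na(dr) && is.infinite(dr)) ||
                  (!is.na(pr) && is.infinite(pr)))
}

#' Expand a sparse SNP matrix into a full-width alignment
#'
#' Published intraspecific SNP matrices list only the variable columns.
#' To re-analyse one with [call_snps()] / [diversity_report()] it is
#' expanded into a gap-free alignment of the stated genome length:
#' every unlisted column is filled with an identical (hence
#' monomorphic, analytically inert) filler base, listed columns carry
#' the transcribed alleles, and missing calls become `N`.
#'
#' @param snp_matrix a [read_snp_matrix()] result.
#' @param length genome length (must exceed `max(positions)`).
#' @param filler filler base (default `"A"`).
#' @return a `VariantAlignment`.
#' @export
expand_snp_matrix <- function(snp_matrix, length, filler = "A") {
  stopifnot(length >= max(snp_matrix$positions))
  ids <- rownames(snp_matrix$alleles)
  mat <- matrix(filler, nrow = length(ids), ncol = length,
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    al <- snp_matrix$alleles[i, ]
    al[is.na(al)] <- "N"
    mat[i, snp_matrix$positions] <- al
  }
  structure(list(ids = ids, matrix = mat,
                 reference = snp_matrix$reference),
            class = "VariantAlignment")
}

#' Write a SNP table in the printed-matrix dialect
#'
#' Rows are variants, columns SNP positions; the reference row is fully
#' filled, cells identical to the reference are left blank, and missing
#' calls are written as `.` — the dialect of published intraspecific
#' SNP matrices. [read_snp_matrix()] reads it back.
#'
#' @param snp_table a [call_snps()] table.
#' @param path output TSV.
#' @export
write_snp_matrix <- function(snp_table, path) {
  ref <- attr(snp_table, "reference")
  meta <- c("position", "gene", "n_alleles")
  ids <- setdiff(colnames(snp_table), meta)
  m <- t(as.matrix(snp_table[, ids, drop = FALSE]))
  colnames(m) <- snp_table$position
  out <- m
  for (id in ids) {
    if (id == ref) next
    same <- !is.na(m[id, ]) & m[id, ] == m[ref, ]
    out[id, same] <- ""
    out[id, is.na(m[id, ])] <- "."
  }
  df <- data.frame(variant = ids, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_matrix
#' @param reference id of the reference row (default: first row).
#' @return `read_snp_matrix()`: list `positions`, `alleles` (character
#'   matrix variants x positions, `NA` for missing calls), `reference`.
#' @export
read_snp_matrix <- function(path, reference = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  positions <- as.integer(colnames(m))
  reference <- reference %||% ids[1]
  for (id in ids) {
    blank <- m[id, ] == ""
    m[id, blank] <- m[reference, blank]
    m[id, m[id, ] == "."] <- NA_character_
  }
  list(positions = positions, alleles = m, reference = reference)
}
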