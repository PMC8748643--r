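#' Annotated mitochondrial genome
#'
#' Container for one mitochondrial sequence with named gene features.
#' Coordinates are 1-based inclusive on the major strand, matching GenBank
#' convention. A feature whose `start > end` on a circular genome wraps
#' the origin and is flagged `wrapped`.
#'
#' @param id text identifier (accession or fixture name).
#' @param sequence nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @param annotations data.frame with columns `symbol`, `start`, `end`,
#'   `strand` and optionally `class` (recomputed from the symbol when
#'   absent).
#' @param taxon taxon label, defaults to `id`.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param assembly_gap optional length-2 integer vector, the interval of
#'   an unresolved assembly gap (for unclosed genomes).
#' @param unclassified optional data.frame of features that could not be
#'   mapped to a canonical symbol (kept for reporting, never analysed).
#' @return object of class `MitoGenome`.
#' @export
mito_genome <- function(id, sequence, annotations, taxon = id,
                        topology = c("circular", "linear"),
                        assembly_gap = NULL, unclassified = NULL) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence may only contain A, C, G, T, N")
  }
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("symbol", "start", "end", "strand")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns: ", paste(need, collapse = ", "))
  }
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  if (nrow(ann) > 0) {
    if (any(ann$start < 1L | ann$start > L | ann$end < 1L | ann$end > L)) {
      stop("annotation coordinates outside [1, ", L, "]")
    }
    if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    dup <- duplicated(ann$symbol)
    if (any(dup)) {
      stop("duplicate annotation for symbol(s): ",
           paste(unique(ann$symbol[dup]), collapse = ", "))
    }
    ann$class <- feature_class_of(ann$symbol)
    ann$wrapped <- ann$start > ann$end
    if (topology == "linear" && any(ann$wrapped)) {
      stop("wrapped annotations are impossible on a linear genome")
    }
  } else {
    ann$class <- character(0); ann$wrapped <- logical(0)
  }
  rownames(ann) <- NULL
  structure(list(id = id, taxon = taxon, sequence = sequence,
                 topology = topology, annotations = ann,
                 assembly_gap = assembly_gap,
                 unclassified = unclassified),
            class = "MitoGenome")
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat("MitoGenome ", x$id, " (", x$taxon, "): ", nchar(x$sequence), " bp, ",
      x$topology, ", ", nrow(x$annotations), " annotated features\n",
      sep = "")
  if (!is.null(x$unclassified) && nrow(x$unclassified) > 0) {
    cat("  +", nrow(x$unclassified), "unclassified feature(s)\n")
  }
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

# length of a feature taking circular wrap into account
feature_length <- function(genome, i) {
  a <- genome$annotations[i, ]
  if (a$wrapped) nchar(genome$sequence) - a$start + 1L + a$end
  else a$end - a$start + 1L
}

#' Extract the coding-strand sequence of an annotated gene
#'
#' Returns the gene sequence read 5'→3' on its coding strand: the
#' major-strand slice for `+` features, its reverse complement for `-`
#' features. Features wrapping the circular origin are concatenated
#' across the origin.
#'
#' @param genome a [mito_genome()].
#' @param symbol canonical gene symbol annotated in `genome`.
#' @return nucleotide string.
#' @export
extract_gene_sequence <- function(genome, symbol) {
  i <- match(symbol, genome$annotations$symbol)
  if (is.na(i)) stop("symbol '", symbol, "' is not annotated in ", genome$id)
  a <- genome$annotations[i, ]
  s <- circular_slice(genome$sequence, a$start, a$end)
  if (a$strand == "-") revcomp(s) else s
}

#' Read off the gene order of an annotated genome
#'
#' Elements are sorted by start position around the circle; ties broken
#' deterministically by `(end, symbol)`. Strands are preserved; the
#' control region is included only when `include_cr`.
#'
#' @param genome a [mito_genome()] with at least 2 annotations.
#' @param include_cr include the `CR` element if annotated.
#' @return a [gene_order()].
#' @export
extract_gene_order <- function(genome, include_cr = TRUE) {
  ann <- genome$annotations
  if (!include_cr) ann <- ann[ann$symbol != "CR", , drop = FALSE]
  if (nrow(ann) < 2L) stop("need at least 2 annotations to define an order")
  o <- order(ann$start, ann$end, ann$symbol)
  ann <- ann[o, , drop = FALSE]
  gene_order(taxon = genome$taxon, symbols = ann$symbol,
             strands = ann$strand, topology = genome$topology,
             includes_cr = include_cr && "CR" %in% ann$symbol)
}

#' Read / write a mitogenome as FASTA plus a feature table
#'
#' The feature table is a TSV with header
#' `symbol<TAB>start<TAB>end<TAB>strand<TAB>class`, coordinates 1-based
#' inclusive; a row with `start > end` denotes a feature wrapping the
#' circular origin. This pair of files round-trips a [mito_genome()]
#' exactly.
#'
#' @param fasta_path FASTA file with a single record.
#' @param table_path feature-table TSV.
#' @param topology genome topology (a FASTA record does not carry one).
#' @param taxon optional taxon label, default: the FASTA record name.
#' @return a [mito_genome()].
#' @export
read_fasta_with_table <- function(fasta_path, table_path,
                                  topology = "circular", taxon = NULL) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) != 1L) stop("expected exactly one FASTA record, got ",
                              length(dss))
  id <- strsplit(names(dss)[1], "\\s+")[[1]][1]
  seqs <- as.character(dss[[1]])
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("symbol", "start", "end", "strand")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  L <- nchar(seqs)
  if (any(tab$start < 1L | tab$end < 1L | tab$start > L | tab$end > L)) {
    stop("feature table coordinate outside [1, ", L, "] in ", table_path)
  }
  if (topology == "linear" && any(tab$start > tab$end)) {
    stop("wrapped feature (start > end) impossible on a linear genome")
  }
  mito_genome(id = id, sequence = seqs, annotations = tab,
              taxon = taxon %||% names(dss)[1], topology = topology)
}

#' @rdname read_fasta_with_table
#' @param genome the [mito_genome()] to write.
#' @export
write_fasta_with_table <- function(genome, fasta_path, table_path) {
  dss <- Biostrings::DNAStringSet(genome$sequence)
  names(dss) <- genome$id
  Biostrings::writeXStringSet(dss, fasta_path, width = 70L)
  ann <- genome$annotations[, c("symbol", "start", "end", "strand", "class")]
  utils::write.table(ann, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, table = table_path))
}
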