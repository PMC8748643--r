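#' Classify start and stop codons of annotated protein-coding genes
#'
#' For each PCG the first in-frame codon and the trailing terminal are
#' reported. Mitochondrial PCGs frequently end on a bare `T` or `TA`
#' completed to `TAA` by 3' polyadenylation of the mRNA; such genes
#' (CDS length mod 3 equal to 1 or 2) are classed `incomplete_polyA`.
#' Starts outside the canonical set are flagged `noncanonical` but never
#' rejected (e.g. an annotated CAA start).
#'
#' @param genome a [mito_genome()] with at least one PCG annotation.
#' @param canonical_starts character vector of canonical start codons;
#'   `ATN` entries expand over A,C,G,T.
#' @param genetic_code NCBI translation table id (default 5,
#'   invertebrate mitochondrial).
#' @return data.frame of class `TerminalReport`: `gene`, `start_codon`,
#'   `start_class` (`canonical`/`noncanonical`), `stop_codon` (`TAA`,
#'   `TAG`, `T`, `TA`, or the observed triplet), `stop_class`
#'   (`complete`/`incomplete_polyA`/`noncanonical`).
#' @export
classify_terminals <- function(genome,
                               canonical_starts = c("ATN", "GTG", "TTG",
                                                    "GTT"),
                               genetic_code = 5) {
  ann <- genome$annotations
  pcgs <- ann$symbol[ann$class == "PCG"]
  if (!length(pcgs)) stop("genome has no PCG annotation")
  starts <- unique(unlist(lapply(canonical_starts, function(cs) {
    if (grepl("N", cs)) {
      vapply(c("A", "C", "G", "T"),
             function(b) gsub("N", b, cs), "")
    } else cs
  })))
  code <- genetic_code_table(genetic_code)
  stops <- names(code)[code == "*"]
  rows <- lapply(pcgs, function(sym) {
    cds <- extract_gene_sequence(genome, sym)
    if (nchar(cds) < 6L) stop("PCG ", sym, " shorter than 6 nt")
    start_codon <- substr(cds, 1L, 3L)
    rem <- nchar(cds) %% 3L
    if (rem == 0L) {
      stop_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
      stop_class <- if (stop_codon %in% stops) "complete" else "noncanonical"
    } else {
      stop_codon <- substr(cds, nchar(cds) - rem + 1L, nchar(cds))
      stop_class <- if (stop_codon %in% c("T", "TA")) "incomplete_polyA"
                    else "noncanonical"
    }
    data.frame(gene = sym, start_codon = start_codon,
               start_class = if (start_codon %in% starts) "canonical"
                             else "noncanonical",
               stop_codon = stop_codon, stop_class = stop_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TerminalReport", "data.frame")
  out
}

#' Relative synonymous codon usage (RSCU)
#'
#' For each sense codon \eqn{c} of a synonymous family of degeneracy
#' \eqn{d}, \eqn{RSCU_c = d \cdot n_c / \sum_{c'} n_{c'}}: the observed
#' count divided by the count expected under uniform usage within the
#' family. Within every observed family the values sum to \eqn{d} (mean
#' 1); codons of unobserved families are reported `NA`.
#'
#' Stop codons are excluded from families. CDSs whose length is not a
#' multiple of 3 are assumed to carry an incomplete polyadenylated stop:
#' the trailing 1-2 nt are dropped and only complete in-frame codons are
#' counted. The terminal codon of each CDS is excluded when it is a stop.
#'
#' @param cds_collection character vector (or list) of in-frame CDS
#'   nucleotide strings, or a [mito_genome()] (all annotated PCGs are
#'   pooled).
#' @param genetic_code NCBI translation table id (default 5). Table 2
#'   (vertebrate mitochondrial) reassigns AGA/AGG from serine to stop.
#' @param warn_internal_stops emit a warning when internal stop codons
#'   are encountered (they are excluded from counting; diagnosis belongs
#'   to [detect_internal_stops()]).
#' @return data.frame of class `RSCUTable`: `codon`, `amino_acid`,
#'   `count`, `degeneracy`, `rscu`.
#' @examples
#' rscu(c("ATGTTTTTTTAA"))  # all Phe as TTT: rscu(TTT)=2, rscu(TTC)=0
#' @export
rscu <- function(cds_collection, genetic_code = 5,
                 warn_internal_stops = TRUE) {
  if (inherits(cds_collection, "MitoGenome")) {
    g <- cds_collection
    pcgs <- g$annotations$symbol[g$annotations$class == "PCG"]
    cds_collection <- vapply(pcgs, extract_gene_sequence, "", genome = g)
  }
  cds_collection <- toupper(unlist(cds_collection, use.names = FALSE))
  code <- genetic_code_table(genetic_code)
  stops <- names(code)[code == "*"]
  counts <- stats::setNames(integer(length(code)), names(code))
  n_internal <- 0L
  for (cds in cds_collection) {
    cod <- codons_of(cds)
    if (!length(cod)) next
    # drop a terminal stop codon (complete stop); incomplete trailing nts
    # were already dropped by codons_of()
    if (nchar(cds) %% 3L == 0L && cod[length(cod)] %in% stops) {
      cod <- cod[-length(cod)]
    }
    internal <- cod %in% stops
    n_internal <- n_internal + sum(internal)
    cod <- cod[!internal & !grepl("[^ACGT]", cod)]
    if (length(cod)) {
      tab <- table(cod)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  if (warn_internal_stops && n_internal > 0L) {
    warning(n_internal, " internal stop codon(s) excluded from RSCU ",
            "counting; run detect_internal_stops() on the affected genes")
  }
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  fam_size <- table(aa)
  fam_total <- tapply(counts[sense], aa, sum)
  d <- as.integer(fam_size[aa])
  tot <- as.numeric(fam_total[aa])
  val <- ifelse(tot > 0, counts[sense] * d / tot, NA_real_)
  out <- data.frame(codon = sense, amino_acid = unname(aa),
                    count = unname(counts[sense]), degeneracy = d,
                    rscu = unname(val), stringsAsFactors = FALSE)
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("RSCUTable", "data.frame")
  out
}
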