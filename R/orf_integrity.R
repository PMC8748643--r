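#' Detect internal stop codons in a coding sequence
#'
#' Scans the annotated reading frame of a CDS for premature stop codons.
#' The terminal codon is never listed: when the CDS length is a multiple
#' of 3 the last complete codon is the terminal; otherwise the trailing
#' 1-2 nt are an (incomplete, polyadenylated) terminal and every complete
#' codon counts as internal. Codons containing ambiguity characters are
#' never called stops.
#'
#' @param cds in-frame nucleotide string, length >= 6.
#' @param genetic_code NCBI translation table id (default 5).
#' @return data.frame with columns `codon_index` (1-based) and `triplet`.
#' @examples
#' detect_internal_stops("ATGTAAAAATAA")  # stop at codon 2
#' @export
detect_internal_stops <- function(cds, genetic_code = 5) {
  cds <- toupper(cds)
  if (nchar(cds) < 6L) stop("cds must be at least 6 nt")
  code <- genetic_code_table(genetic_code)
  stops <- names(code)[code == "*"]
  cod <- codons_of(cds)
  internal <- seq_along(cod)
  if (nchar(cds) %% 3L == 0L) internal <- internal[-length(internal)]
  hit <- internal[cod[internal] %in% stops]
  data.frame(codon_index = hit, triplet = cod[hit],
             stringsAsFactors = FALSE)
}

# no internal stop codon under the definition of detect_internal_stops();
# sequences shorter than 6 nt are vacuously open
orf_is_open <- function(s, stops) {
  cod <- codons_of(s)
  if (!length(cod)) return(TRUE)
  internal <- seq_along(cod)
  if (nchar(s) %% 3L == 0L) internal <- internal[-length(internal)]
  !any(cod[internal] %in% stops)
}

# translate complete codons, dropping a terminal stop; ambiguous codons
# become X
translate_cds <- function(s, genetic_code = 5) {
  code <- genetic_code_table(genetic_code)
  cod <- codons_of(s)
  if (!length(cod)) return("")
  aa <- unname(code[cod])
  aa[is.na(aa)] <- "X"
  if (nchar(s) %% 3L == 0L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Single-nucleotide frameshift hypotheses for a broken reading frame
#'
#' Given a CDS with internal stop codons, evaluates whether a single
#' nucleotide deletion (or, symmetrically, insertion) in the gene could
#' explain them while the remainder of the gene still constitutes an
#' open reading frame. For the deletion hypothesis the candidate set is
#' every position `p` (1..length+1) at which re-inserting some
#' nucleotide yields a stop-free reading frame from the start through
#' the gene terminus; the insertion hypothesis deletes one nucleotide at
#' `p` (1..length) instead. Only +/-1 events are considered.
#'
#' Without a homolog the candidate set is reported as a set/interval,
#' never a point: neighbouring positions (e.g. within a homopolymer run)
#' are often equivalent, and a unique position is only identifiable by
#' comparison against a full-length ortholog — see
#' [refine_with_homolog()].
#'
#' @param cds in-frame nucleotide string.
#' @param genetic_code NCBI translation table id (default 5).
#' @param gene optional gene symbol recorded in the report.
#' @return object of class `OrfIntegrityReport`: `gene`, `cds_length`,
#'   `internal_stops` (as [detect_internal_stops()]),
#'   `truncated_product_length` (aa count before the first internal
#'   stop), `hypotheses` — a list of hypotheses each with `type`
#'   (`"deletion"`/`"insertion"`), `candidate_positions`,
#'   `candidate_interval` (`c(min, max)`), `downstream_open`,
#'   `refined_position` (`NA` until refined), and `ambiguous_positions`
#'   (positions with non-ACGT characters, skipped during evaluation).
#'   Hypotheses with an empty candidate set are omitted.
#' @export
frameshift_hypotheses <- function(cds, genetic_code = 5, gene = NA_character_) {
  cds <- toupper(cds)
  L <- nchar(cds)
  internal <- detect_internal_stops(cds, genetic_code)
  code <- genetic_code_table(genetic_code)
  stops <- names(code)[code == "*"]
  ch <- seq_chars(cds)
  ambiguous <- which(!ch %in% c("A", "C", "G", "T"))

  report <- structure(list(
    gene = gene, cds_length = L, internal_stops = internal,
    truncated_product_length = if (nrow(internal)) internal$codon_index[1] - 1L
                               else NA_integer_,
    hypotheses = list(), genetic_code = genetic_code,
    ambiguous_positions = ambiguous, refine_warning = FALSE
  ), class = "OrfIntegrityReport")
  if (nrow(internal) == 0L) return(report)

  # stop flag for the triplet starting at q (1..L-2); ambiguous never stop
  is_stop_at <- function(q) {
    substr(cds, q, q + 2L) %in% stops
  }
  all_q <- seq_len(max(L - 2L, 0L))
  stop3 <- logical(L)
  trip <- substring(cds, all_q, all_q + 2L)
  stop3[all_q] <- trip %in% stops

  # first stop among frame-0 complete codons (codon index)
  f0_starts <- seq.int(1L, by = 3L, length.out = L %/% 3L)
  f0_stop <- which(stop3[f0_starts])
  first_stop0 <- if (length(f0_stop)) f0_stop[1] else Inf

  last_stop_in <- function(starts, exclude = integer(0)) {
    starts <- setdiff(starts, exclude)
    hit <- starts[stop3[starts]]
    if (length(hit)) max(hit) else -Inf
  }

  # ---- deletion hypothesis: re-insert one nucleotide at p in 1..L+1 ----
  # repaired codon k = ceiling(p/3) contains the free nucleotide, so it is
  # always satisfiable; downstream codons read original starts q = 3k,
  # 3k+3, ... (frame shifted +1)
  q0 <- seq.int(3L, L - 2L, by = 3L)
  excl0 <- if ((L + 1L) %% 3L == 0L) L - 2L else integer(0)
  last0 <- last_stop_in(q0[q0 >= 3L], exclude = excl0)
  p_del <- seq_len(L + 1L)
  k_del <- (p_del + 2L) %/% 3L
  ok_del <- (k_del <= first_stop0) & (3L * k_del > last0)
  del_pos <- p_del[ok_del]

  # ---- insertion hypothesis: delete the nucleotide at p in 1..L ----
  # bridge codon k is built purely from retained characters and must not
  # be a stop; downstream codons read original starts q = 3k+2, 3k+5, ...
  q2 <- seq.int(2L, L - 2L, by = 3L)
  excl2 <- if ((L - 1L) %% 3L == 0L) L - 2L else integer(0)
  last2 <- last_stop_in(q2, exclude = excl2)
  p_ins <- seq_len(L)
  k_ins <- (p_ins + 2L) %/% 3L
  # prefix codons 1..k-1 must be stop-free, except that codon k-1 is the
  # repaired *terminal* (stop allowed) when it ends the repaired sequence
  prefix_ok <- (k_ins <= first_stop0) |
    ((L - 1L) %% 3L == 0L & (k_ins - 1L) == (L - 1L) %/% 3L &
       first_stop0 >= k_ins - 1L)
  pre_ok <- prefix_ok & (3L * k_ins + 2L > last2)
  ins_pos <- integer(0)
  for (p in p_ins[pre_ok]) {
    k <- (p + 2L) %/% 3L
    idx <- setdiff(seq.int(3L * k - 2L, 3L * k + 1L), p)
    idx <- idx[idx >= 1L & idx <= L][1:3]
    if (anyNA(idx)) { ins_pos <- c(ins_pos, p); next }   # incomplete terminal
    bridge <- paste(ch[idx], collapse = "")
    bridge_is_terminal <- (L - 1L) %% 3L == 0L && 3L * k == L - 1L
    if (bridge_is_terminal || !(bridge %in% stops)) ins_pos <- c(ins_pos, p)
  }

  add_hypothesis <- function(type, pos) {
    if (!length(pos)) return(NULL)
    list(type = type, candidate_positions = pos,
         candidate_interval = range(pos), downstream_open = TRUE,
         refined_position = NA_integer_)
  }
  hyp <- Filter(Negate(is.null),
                list(add_hypothesis("deletion", del_pos),
                     add_hypothesis("insertion", ins_pos)))
  report$hypotheses <- hyp
  report
}

#' @export
print.OrfIntegrityReport <- function(x, ...) {
  cat("OrfIntegrityReport", if (!is.na(x$gene)) paste0("[", x$gene, "]"),
      ": ", nrow(x$internal_stops), " internal stop(s)\n", sep = "")
  if (nrow(x$internal_stops)) {
    cat("  first internal stop at codon", x$internal_stops$codon_index[1],
        "-> truncated product", x$truncated_product_length, "aa\n")
  }
  for (h in x$hypotheses) {
    cat("  ", h$type, " hypothesis: ", length(h$candidate_positions),
        " candidate position(s) in [", h$candidate_interval[1], ", ",
        h$candidate_interval[2], "]",
        if (!is.na(h$refined_position))
          paste0(", refined to ", h$refined_position) else "",
        "\n", sep = "")
  }
  invisible(x)
}

# all repaired sequences for hypothesis h at position p (4 insertions or
# 1 deletion), as character vector
repaired_sequences <- function(cds, type, p) {
  if (type == "deletion") {
    pre <- substr(cds, 1L, p - 1L); post <- substr(cds, p, nchar(cds))
    paste0(pre, c("A", "C", "G", "T"), post)
  } else {
    paste0(substr(cds, 1L, p - 1L), substr(cds, p + 1L, nchar(cds)))
  }
}

#' Refine a frameshift hypothesis against a full-length homolog
#'
#' Narrows the candidate interval of each hypothesis to the positions
#' whose repaired translation attains the best global amino-acid
#' alignment score against a full-length ortholog protein (e.g. the same
#' gene from a congener). When a unique best position exists it is
#' recorded as `refined_position`; ties (equivalent positions producing
#' the same protein) retain the narrowed interval. If even the best
#' alignment is poor — normalized score below `score_floor` of the
#' homolog self-alignment — the report is returned unchanged with
#' `refine_warning = TRUE`.
#'
#' @param report an [frameshift_hypotheses()] report.
#' @param cds the CDS the report was computed from.
#' @param homolog_protein amino-acid string of a full-length ortholog.
#' @param substitution_matrix name of a published substitution matrix
#'   (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension linear gap penalty (defaults 10, 1).
#' @param score_floor minimum best score as a fraction of the homolog
#'   self-alignment score (default 0.3).
#' @return the refined `OrfIntegrityReport`.
#' @export
refine_with_homolog <- function(report, cds, homolog_protein,
                                substitution_matrix = "BLOSUM62",
                                gap_opening = 10, gap_extension = 1,
                                score_floor = 0.3) {
  stopifnot(inherits(report, "OrfIntegrityReport"))
  cds <- toupper(cds)
  homolog_protein <- toupper(gsub("\\*", "", homolog_protein))
  if (!nzchar(homolog_protein)) stop("homolog_protein is empty")
  code_id <- report$genetic_code
  stops <- names(genetic_code_table(code_id))[genetic_code_table(code_id) == "*"]
  align_score <- function(aa) {
    aa <- gsub("\\*", "X", aa)
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa), Biostrings::AAString(homolog_protein),
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension,
      type = "global"))
  }
  self_score <- align_score(homolog_protein)
  best_overall <- -Inf
  refined <- report
  for (i in seq_along(report$hypotheses)) {
    h <- report$hypotheses[[i]]
    scores <- vapply(h$candidate_positions, function(p) {
      reps <- repaired_sequences(cds, h$type, p)
      reps <- reps[vapply(reps, orf_is_open, TRUE, stops = stops)]
      if (!length(reps)) return(-Inf)
      max(vapply(reps, function(r) align_score(translate_cds(r, code_id)),
                 0))
    }, 0)
    best <- max(scores)
    best_overall <- max(best_overall, best)
    keep <- h$candidate_positions[scores == best]
    h$candidate_positions <- keep
    h$candidate_interval <- range(keep)
    if (length(keep) == 1L) h$refined_position <- keep
    refined$hypotheses[[i]] <- h
  }
  if (!length(report$hypotheses) ||
      best_overall < score_floor * self_score) {
    report$refine_warning <- TRUE
    warning("homolog alignment score below floor; report returned unchanged")
    return(report)
  }
  refined
}
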