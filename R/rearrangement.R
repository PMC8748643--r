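# Signed circular gene-order comparison.
#
# The unit of counting is the moved gene: the retained backbone is a
# maximum-length common subsequence (same symbol AND same strand) of the
# two circular orders, maximized over rotations; every shared gene outside
# the backbone is an event. A block of k genes moved together therefore
# counts as k transpositions, which is the convention used when comparing
# insect mitogenomes against the ancestral arrangement.

# restrict a GeneOrder's elements to a symbol set, preserving order
restrict_elements <- function(order, symbols) {
  el <- order$elements
  el[el$symbol %in% symbols, , drop = FALSE]
}

# linear LCS of two signed element frames; match = same symbol and
# (strand agreement, optionally waived for symbols in `ignore_strand`).
# Returns list(size, idx_a) with a deterministic traceback (prefers the
# diagonal, then skipping b, then skipping a).
signed_lcs <- function(ea, eb, ignore_strand = character(0)) {
  n <- nrow(ea); m <- nrow(eb)
  D <- matrix(0L, n + 1L, m + 1L)
  match_ok <- function(i, j) {
    ea$symbol[i] == eb$symbol[j] &&
      (ea$strand[i] == eb$strand[j] || ea$symbol[i] %in% ignore_strand)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(D[i, j + 1L], D[i + 1L, j])
      if (match_ok(i, j)) best <- max(best, D[i, j] + 1L)
      D[i + 1L, j + 1L] <- best
    }
  }
  # traceback
  idx <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (match_ok(i, j) && D[i + 1L, j + 1L] == D[i, j] + 1L) {
      idx <- c(i, idx); i <- i - 1L; j <- j - 1L
    } else if (D[i, j + 1L] >= D[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(size = D[n + 1L, m + 1L], idx_a = idx)
}

# maximum common signed subsequence of two (possibly circular) orders
# restricted to their shared symbols; circular query is rotated
# exhaustively (fixing the reference linearization is exact because any
# cyclic common subsequence can be read off starting at the first
# retained element after the reference's cut). No reflection.
backbone_of <- function(reference, query, ignore_strand = character(0)) {
  shared <- intersect(reference$elements$symbol, query$elements$symbol)
  if (length(shared) < 2L) stop("need at least 2 shared symbols")
  ea <- restrict_elements(reference, shared)
  eb <- restrict_elements(query, shared)
  rotations <- if (query$topology == "circular") seq_len(nrow(eb)) else 1L
  best <- NULL
  for (k in rotations) {
    res <- signed_lcs(ea, rotate_order_elements(eb, k), ignore_strand)
    cand <- ea[res$idx_a, , drop = FALSE]
    if (is.null(best) || res$size > best$size) {
      best <- list(size = res$size, backbone = cand)
    } else if (res$size == best$size) {
      # deterministic tie-break: prefer a backbone containing cox1, then
      # the lexicographically smallest symbol string
      old <- best$backbone; new <- cand
      old_cox <- "cox1" %in% old$symbol; new_cox <- "cox1" %in% new$symbol
      replace <- (new_cox && !old_cox) ||
        (new_cox == old_cox &&
           paste(new$symbol, collapse = " ") <
           paste(old$symbol, collapse = " "))
      if (replace) best <- list(size = res$size, backbone = new)
    }
  }
  rownames(best$backbone) <- NULL
  best$backbone
}

#' Align two circular signed gene orders
#'
#' Returns the retained common backbone: a maximum-length common
#' subsequence of the two orders restricted to their shared symbols,
#' where a match requires the same symbol and the same strand, maximized
#' over all rotations of the circular query (never a reflection —
#' chromosome orientation is fixed by the major strand). Ties are broken
#' deterministically by preferring the backbone containing `cox1`, then
#' the lexicographically smallest one.
#'
#' @param reference,query [gene_order()] objects sharing >= 2 symbols.
#' @return data.frame (`symbol`, `strand`) of backbone elements in
#'   reference order.
#' @export
align_circular_orders <- function(reference, query) {
  backbone_of(reference, query)
}

#' Classify per-gene rearrangement events against a reference order
#'
#' Every shared gene outside the common backbone is an event: same
#' strand in both orders — a transposition; opposite strand but
#' matchable in place (it joins the backbone once its strand mismatch is
#' waived) — an inversion; opposite strand and relocated — an inverse
#' transposition. The control region may anchor rotation but is never
#' counted as an event. Genes present in only one order (partial
#' genomes) are excluded from the comparison and listed.
#'
#' @param reference,query [gene_order()] objects sharing >= 2 symbols.
#' @return object of class `RearrangementReport`: `reference`, `query`
#'   (taxon labels), `shared_genes`, `excluded_genes`, `backbone`,
#'   `moved_genes` (transposed or inverse-transposed genes),
#'   `events` (named character vector gene -> event class),
#'   `n_transpositions`, `n_inversions`, `n_inverse_transpositions`.
#' @examples
#' ref <- ancestral_insect_order()
#' identical_report <- classify_events(ref, ref)
#' identical_report$n_transpositions  # 0
#' @export
classify_events <- function(reference, query) {
  shared <- intersect(reference$elements$symbol, query$elements$symbol)
  excluded <- setdiff(union(reference$elements$symbol,
                            query$elements$symbol), shared)
  bb <- backbone_of(reference, query)
  er <- restrict_elements(reference, shared)
  eq <- restrict_elements(query, shared)
  strand_r <- stats::setNames(er$strand, er$symbol)
  strand_q <- stats::setNames(eq$strand, eq$symbol)
  outside <- setdiff(shared, bb$symbol)
  outside <- setdiff(outside, "CR")   # CR never counts as an event
  events <- stats::setNames(character(0), character(0))
  for (g in outside) {
    if (strand_r[[g]] == strand_q[[g]]) {
      events[g] <- "transposition"
    } else {
      # in place if waiving the strand mismatch of g alone lets it join
      # the backbone
      bb2 <- backbone_of(reference, query, ignore_strand = g)
      events[g] <- if (g %in% bb2$symbol && nrow(bb2) == nrow(bb) + 1L)
        "inversion" else "inverse_transposition"
    }
  }
  moved <- names(events)[events %in% c("transposition",
                                       "inverse_transposition")]
  structure(list(
    reference = reference$taxon, query = query$taxon,
    shared_genes = shared, excluded_genes = excluded,
    backbone = bb, moved_genes = moved, events = events,
    n_transpositions = sum(events == "transposition"),
    n_inversions = sum(events == "inversion"),
    n_inverse_transpositions = sum(events == "inverse_transposition")
  ), class = "RearrangementReport")
}

#' @export
print.RearrangementReport <- function(x, ...) {
  cat("RearrangementReport:", x$query, "vs", x$reference, "\n")
  cat("  shared", length(x$shared_genes), "| backbone", nrow(x$backbone),
      "| transpositions", x$n_transpositions,
      "| inversions", x$n_inversions,
      "| inverse transpositions", x$n_inverse_transpositions, "\n")
  if (length(x$events)) {
    cat("  events:", paste(names(x$events), x$events, sep = ":",
                           collapse = ", "), "\n")
  }
  if (length(x$excluded_genes)) {
    cat("  excluded (absent in one order):",
        paste(x$excluded_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exhaustive minimal gene-removal oracle
#'
#' Finds, by exhaustive enumeration, the minimal number of shared genes
#' whose removal makes the two circular signed orders identical up to
#' rotation. Serves as an independent oracle for [classify_events()]:
#' the minimum equals the number of moved genes plus in-place
#' inversions. Restricted to instances with at most 12 shared symbols.
#'
#' @param reference,query [gene_order()] objects.
#' @return integer, the minimal removal count.
#' @export
brute_force_min_removal <- function(reference, query) {
  shared <- intersect(reference$elements$symbol, query$elements$symbol)
  if (length(shared) > 12L) stop("brute force limited to <= 12 shared symbols")
  er <- restrict_elements(reference, shared)
  eq <- restrict_elements(query, shared)
  sig <- function(el) paste(el$symbol, el$strand, sep = "")
  equal_up_to_rotation <- function(a, b) {
    n <- length(a)
    if (n != length(b)) return(FALSE)
    if (n == 0L) return(TRUE)
    for (k in seq_len(n)) {
      if (all(a == b[((seq_len(n) + k - 2L) %% n) + 1L])) return(TRUE)
    }
    FALSE
  }
  for (r in 0:length(shared)) {
    removals <- utils::combn(shared, r, simplify = FALSE)
    for (rm in removals) {
      keep <- setdiff(shared, rm)
      a <- sig(er[er$symbol %in% keep, , drop = FALSE])
      b <- sig(eq[eq$symbol %in% keep, , drop = FALSE])
      if (equal_up_to_rotation(a, b)) return(r)
    }
  }
  length(shared)
}

#' Cross-taxon shared rearrangement matrix
#'
#' Runs [classify_events()] for each query against a common reference
#' and tabulates, per (taxon, gene), the event class of that gene (empty
#' string when the gene kept its ancestral placement). Mirrors the
#' cross-species comparison used to identify rearrangements shared
#' between taxa.
#'
#' @param reference a [gene_order()].
#' @param queries a non-empty list of [gene_order()] objects.
#' @return object of class `SharedEventMatrix`: `taxa`, `genes`,
#'   `events` (character matrix taxa x genes), `indicator` (logical
#'   matrix: gene affected by any event), `reports` (the per-taxon
#'   [classify_events()] reports).
#' @export
shared_event_matrix <- function(reference, queries) {
  if (!length(queries)) stop("need at least one query order")
  taxa <- vapply(queries, function(q) q$taxon, "")
  genes <- setdiff(reference$elements$symbol, "CR")
  ev <- matrix("", nrow = length(queries), ncol = length(genes),
               dimnames = list(taxa, genes))
  reports <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    rep_i <- classify_events(reference, queries[[i]])
    reports[[i]] <- rep_i
    for (g in names(rep_i$events)) ev[i, g] <- rep_i$events[[g]]
  }
  structure(list(taxa = taxa, genes = genes, events = ev,
                 indicator = ev != "", reports = reports),
            class = "SharedEventMatrix")
}

#' @export
print.SharedEventMatrix <- function(x, ...) {
  cat("SharedEventMatrix:", length(x$taxa), "taxa x", length(x$genes),
      "genes;", sum(x$indicator), "events\n")
  affected <- colSums(x$indicator)
  affected <- affected[affected > 0]
  if (length(affected)) {
    cat("  affected genes:",
        paste(names(affected), affected, sep = "x", collapse = ", "), "\n")
  }
  invisible(x)
}
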