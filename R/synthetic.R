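# Seeded synthetic mitogenome generator with ground-truth manifests.
#
# The generator states a world resembling the study system: a circular
# ~16 kb AT-rich genome carrying the 37 genes + control region in the
# ancestral insect order, onto which single-gene rearrangements, sparse
# SNPs across conspecific variants and a single-nucleotide frameshift
# deletion are planted with every event recorded in a manifest.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) saved <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cheap order-sensitive checksum for coordinate-bookkeeping checks
gene_checksum <- function(s) {
  paste0(nchar(s), ":", sum(utf8ToInt(s) * seq_len(nchar(s))) %% 999999937)
}

#' Default per-gene length profile of the synthetic template
#'
#' Lengths copied from typical insect mitogenomes (e.g. nad5 ~1.7 kb,
#' cox1 ~1.5 kb, tRNAs ~65 bp); PCG lengths are multiples of 3. The
#' control region absorbs the remainder of the genome length.
#'
#' @return named integer vector over the 37 gene symbols.
#' @export
default_gene_lengths <- function() {
  pcg <- c(atp6 = 675L, atp8 = 156L, cob = 1134L, cox1 = 1536L,
           cox2 = 684L, cox3 = 786L, nad1 = 939L, nad2 = 1023L,
           nad3 = 351L, nad4 = 1338L, nad4L = 294L, nad5 = 1719L,
           nad6 = 522L)
  trna <- stats::setNames(rep(65L, 22L), trna_symbols())
  rrna <- c(rrnL = 1325L, rrnS = 789L)
  c(pcg, trna, rrna)
}

# sample `n` bases iid with AT bias `at` (P(A)=P(T)=at/2)
sample_bases <- function(n, at) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

# a stop-free in-frame CDS: canonical start, non-stop body codons with
# AT bias, complete TAA stop
sample_cds <- function(len, at, stops) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_body <- len / 3L - 2L
  body <- character(n_body)
  i <- 1L
  while (i <= n_body) {
    cod <- paste(sample_bases(3L, at), collapse = "")
    if (!cod %in% stops) { body[i] <- cod; i <- i + 1L }
  }
  paste0(sample(c("ATA", "ATT", "ATG"), 1L),
         paste(body, collapse = ""), "TAA")
}

#' Generate a synthetic ancestral-order mitogenome
#'
#' A circular genome in the ancestral insect arrangement: 37 genes laid
#' out contiguously from `trnI`, the control region (all remaining
#' length) between `rrnS` and `trnI`. PCGs are stop-free in frame with
#' a canonical start and a complete TAA stop; minus-strand genes are
#' reverse-complemented onto the major strand. The realized AT fraction
#' is checked to be within 0.02 of the target.
#'
#' @param length total genome length in bp (10000-20000; default 16255,
#'   a typical strepsipteran mitogenome length).
#' @param at_fraction target AT fraction (0.5-0.9; default 0.84, the
#'   AT bias of strepsipteran mitogenomes; fruit-fly-like genomes use
#'   ~0.72).
#' @param gene_length_profile named lengths for the 37 genes.
#' @param seed integer seed (mandatory for a reproducible manifest).
#' @param id,taxon genome labels.
#' @return list `genome` (a [mito_genome()]) and `manifest` (the truth
#'   manifest: seed, template parameters, per-gene checksums).
#' @export
generate_template <- function(length = 16255L, at_fraction = 0.84,
                              gene_length_profile = default_gene_lengths(),
                              seed = 1L, id = "synthetic_template",
                              taxon = id) {
  length <- as.integer(length)
  if (length < 10000L || length > 20000L) {
    stop("length must be within [10000, 20000]")
  }
  if (at_fraction < 0.5 || at_fraction > 0.9) {
    stop("at_fraction must be within [0.5, 0.9]")
  }
  glen <- gene_length_profile
  ord <- ancestral_insect_order(include_cr = FALSE)
  if (!all(ord$elements$symbol %in% names(glen))) {
    stop("gene_length_profile must cover all 37 genes")
  }
  cr_len <- length - sum(glen[ord$elements$symbol])
  if (cr_len < 50L) stop("gene_length_profile exceeds genome length")
  stops <- names(genetic_code_table(5))[genetic_code_table(5) == "*"]

  with_seed(seed, {
    blocks <- list()
    for (i in seq_len(nrow(ord$elements))) {
      sym <- ord$elements$symbol[i]
      strand <- ord$elements$strand[i]
      len_i <- glen[[sym]]
      coding <- if (sym %in% pcg_symbols()) {
        sample_cds(len_i, at_fraction, stops)
      } else paste(sample_bases(len_i, at_fraction), collapse = "")
      major <- if (strand == "-") revcomp(coding) else coding
      blocks[[sym]] <- list(symbol = sym, strand = strand, major = major)
    }
    blocks[["CR"]] <- list(symbol = "CR", strand = "+",
                           major = paste(sample_bases(cr_len, at_fraction),
                                         collapse = ""))
    genome <- assemble_blocks(blocks, id = id, taxon = taxon)
    realized_at <- composition_stats(genome)$at_content
    if (abs(realized_at - at_fraction) > 0.02) {
      stop("realized AT fraction ", round(realized_at, 3),
           " misses target by more than 0.02")
    }
    manifest <- list(
      seed = seed,
      template = list(length = length, at_fraction = at_fraction,
                      realized_at = realized_at,
                      gene_lengths = as.list(glen), cr_length = cr_len),
      gene_checksums = gene_checksums_of(genome),
      events = list(), snps = list(), frameshift = NULL)
    list(genome = genome, manifest = manifest)
  })
}

# contiguous block list -> MitoGenome
assemble_blocks <- function(blocks, id, taxon) {
  seqs <- vapply(blocks, function(b) b$major, "")
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  ann <- data.frame(symbol = vapply(blocks, function(b) b$symbol, ""),
                    start = starts, end = ends,
                    strand = vapply(blocks, function(b) b$strand, ""),
                    stringsAsFactors = FALSE)
  mito_genome(id = id, sequence = paste(seqs, collapse = ""),
              annotations = ann, taxon = taxon, topology = "circular")
}

gene_checksums_of <- function(genome) {
  syms <- genome$annotations$symbol
  stats::setNames(lapply(syms, function(s)
    gene_checksum(extract_gene_sequence(genome, s))), syms)
}

# genome -> ordered block list (requires contiguous, non-wrapped features)
genome_blocks <- function(genome) {
  ann <- genome$annotations
  ann <- ann[order(ann$start), ]
  if (any(ann$wrapped)) stop("block editing requires non-wrapped features")
  blocks <- lapply(seq_len(nrow(ann)), function(i) {
    list(symbol = ann$symbol[i], strand = ann$strand[i],
         major = substr(genome$sequence, ann$start[i], ann$end[i]))
  })
  stats::setNames(blocks, ann$symbol)
}

#' Plant gene rearrangements into a synthetic genome
#'
#' Applies single-gene events: a `transposition` relocates the gene's
#' full feature (sequence and annotation) to an intergenic junction at
#' least 2 genes away that does not recreate an original adjacency (so
#' every planted move is detectable); an `inversion` reverse-complements
#' the gene in place and flips its strand; an `inverse_transposition`
#' does both. No gene may appear twice.
#'
#' @param genome a contiguous synthetic [mito_genome()].
#' @param events data.frame with columns `gene`, `type` and optionally
#'   `after` (symbol of the gene after which to insert; `NA` = random
#'   admissible junction).
#' @param seed integer seed for random destinations.
#' @return list `genome` (rearranged) and `manifest` fragment `events`
#'   (one record per applied event, including the realized junction).
#' @export
apply_rearrangements <- function(genome, events, seed = 1L) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (!all(c("gene", "type") %in% names(events))) {
    stop("events need columns gene, type")
  }
  if (!"after" %in% names(events)) {
    events$after <- rep(NA_character_, nrow(events))
  }
  if (anyDuplicated(events$gene)) stop("no gene may appear in two events")
  bad <- setdiff(events$gene, genome$annotations$symbol)
  if (length(bad)) stop("events reference unannotated gene(s): ",
                        paste(bad, collapse = ", "))
  if (!all(events$type %in% c("transposition", "inversion",
                              "inverse_transposition"))) {
    stop("event type must be transposition, inversion or ",
         "inverse_transposition")
  }
  with_seed(seed, {
    blocks0 <- genome_blocks(genome)
    original_order <- names(blocks0)

    attempt_events <- function() {
      blocks <- blocks0
      applied <- list()
      for (r in seq_len(nrow(events))) {
        g <- events$gene[r]; type <- events$type[r]
        syms <- names(blocks)
        i <- match(g, syms)
        n <- length(syms)
        left0 <- syms[((i - 2L) %% n) + 1L]
        right0 <- syms[(i %% n) + 1L]
        if (type %in% c("inversion", "inverse_transposition")) {
          blocks[[g]]$major <- revcomp(blocks[[g]]$major)
          blocks[[g]]$strand <- if (blocks[[g]]$strand == "+") "-" else "+"
        }
        dest <- NA_character_
        if (type %in% c("transposition", "inverse_transposition")) {
          rest <- blocks[-i]
          rsyms <- names(rest)
          m <- length(rsyms)
          # junction after rsyms[j]; forbid recreating either original
          # adjacency and require >= 2 genes distance from the origin
          pos_orig <- match(left0, rsyms)   # g originally after left0
          cand <- seq_len(m)
          ok <- vapply(cand, function(j) {
            after <- rsyms[j]; before <- rsyms[(j %% m) + 1L]
            circ_dist <- min((j - pos_orig) %% m, (pos_orig - j) %% m)
            after != left0 && before != right0 && circ_dist >= 2L
          }, TRUE)
          if (!is.na(events$after[r])) {
            j <- match(events$after[r], rsyms)
            if (is.na(j)) stop("destination gene '", events$after[r],
                               "' not available")
            if (!ok[j]) stop("destination after '", events$after[r],
                             "' recreates an original adjacency or is ",
                             "too close for gene ", g)
          } else {
            if (!any(ok)) stop("no admissible destination for gene ", g)
            j <- sample(cand[ok], 1L)
          }
          dest <- rsyms[j]
          moved <- blocks[[i]]
          blocks <- append(rest, list(moved), after = j)
          names(blocks)[j + 1L] <- g
        }
        applied[[length(applied) + 1L]] <- list(
          gene = g, type = type,
          after = if (!is.na(dest)) dest else NA_character_)
      }
      list(blocks = blocks, applied = applied)
    }

    # planted events must be exactly recoverable; with several moves a
    # random destination can occasionally create a tie in which the
    # backbone swaps a planted gene for a bystander, so random layouts
    # are re-drawn until the event set round-trips
    recovers_exactly <- function(out) {
      if (nrow(events) == 0L) return(TRUE)
      rep1 <- classify_events(extract_gene_order(genome),
                              extract_gene_order(out))
      setequal(names(rep1$events), events$gene) &&
        all(rep1$events[events$gene] == events$type)
    }
    randomized <- any(is.na(events$after)) && nrow(events) > 0L
    for (try in seq_len(if (randomized) 30L else 1L)) {
      att <- attempt_events()
      out <- assemble_blocks(att$blocks, id = genome$id,
                             taxon = genome$taxon)
      if (!randomized || recovers_exactly(out)) {
        return(list(genome = out,
                    manifest = list(seed = seed,
                                    original_order = original_order,
                                    events = att$applied,
                                    gene_checksums = gene_checksums_of(out))))
      }
    }
    stop("could not place the requested events detectably")
  })
}

#' Plant SNPs across synthetic conspecific variants
#'
#' Emits `n_variants` copies of the genome; the first is the unchanged
#' reference. Substitutions only, transition-biased 2:1 by default.
#' Each SNP is carried by a random non-empty subset of the non-reference
#' variants; when a `missing_pattern` masks part of one variant
#' (emulating a low-coverage sample), every SNP is guaranteed at least
#' one unmasked carrier, so the SNP count is unaffected by masking.
#'
#' @param genome a [mito_genome()].
#' @param n_variants number of variants (>= 2; default 6, a typical
#'   intraspecific variant panel).
#' @param n_snps number of SNPs to plant (ignored when `positions`
#'   given).
#' @param positions optional explicit SNP positions (1-based).
#' @param within_classes restrict random positions to features of these
#'   classes (e.g. `"PCG"`); `NULL` = anywhere.
#' @param missing_pattern optional list `variant` (index or id) and
#'   `fraction` (0-1): a contiguous block of that fraction of the
#'   genome is masked to `N` in that variant.
#' @param transition_bias odds of a transition vs either transversion
#'   (default 2).
#' @param seed integer seed.
#' @return list `variants` (named character vector of sequences) and
#'   `manifest` with the planted alleles (`position`, `ref`, `alt`,
#'   `carriers`).
#' @export
make_variants <- function(genome, n_variants = 6L, n_snps = 10L,
                          positions = NULL, within_classes = NULL,
                          missing_pattern = NULL, transition_bias = 2,
                          seed = 1L) {
  if (n_variants < 2L) stop("need n_variants >= 2")
  L <- genome_length(genome)
  if (is.null(positions) && n_snps > L) stop("n_snps exceeds genome length")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  with_seed(seed, {
    pool <- seq_len(L)
    if (!is.null(within_classes)) {
      ann <- genome$annotations
      ann <- ann[ann$class %in% within_classes, , drop = FALSE]
      pool <- unlist(lapply(seq_len(nrow(ann)), function(i) {
        if (ann$start[i] <= ann$end[i]) ann$start[i]:ann$end[i]
        else c(ann$start[i]:L, 1:ann$end[i])
      }))
    }
    if (is.null(positions)) {
      positions <- sort(sample(pool, n_snps))
    } else {
      positions <- sort(unique(as.integer(positions)))
      if (any(positions < 1L | positions > L)) {
        stop("explicit SNP positions outside the genome")
      }
    }
    mask_idx <- integer(0); mask_variant <- NA_integer_
    if (!is.null(missing_pattern)) {
      mv <- missing_pattern$variant
      mask_variant <- if (is.character(mv)) NA_integer_ else as.integer(mv)
      frac <- missing_pattern$fraction
      span <- max(1L, floor(frac * L))
      start <- sample(L, 1L)
      mask_idx <- ((start - 1L + seq_len(span) - 1L) %% L) + 1L
    }
    ref_chars <- seq_chars(genome$sequence)
    var_chars <- lapply(seq_len(n_variants), function(i) ref_chars)
    snps <- list()
    for (p in positions) {
      ref <- ref_chars[p]
      if (!ref %in% c("A", "C", "G", "T")) next
      alt <- if (stats::runif(1) < transition_bias / (transition_bias + 1)) {
        transition[[ref]]
      } else sample(tv[[ref]], 1L)
      repeat {
        carriers <- which(stats::runif(n_variants - 1L) < 0.4) + 1L
        if (!length(carriers)) next
        unmasked <- if (!is.na(mask_variant) && p %in% mask_idx) {
          setdiff(carriers, mask_variant)
        } else carriers
        if (length(unmasked)) break
      }
      for (v in carriers) var_chars[[v]][p] <- alt
      snps[[length(snps) + 1L]] <- list(position = p, ref = ref, alt = alt,
                                        carriers = carriers)
    }
    if (length(mask_idx) && !is.na(mask_variant)) {
      var_chars[[mask_variant]][mask_idx] <- "N"
    }
    ids <- c(paste0(genome$id, "_ref"),
             paste0(genome$id, "_v", seq_len(n_variants - 1L)))
    variants <- stats::setNames(
      vapply(var_chars, paste, "", collapse = ""), ids)
    list(variants = variants,
         manifest = list(seed = seed, n_variants = n_variants,
                         positions = vapply(snps, `[[`, 0, "position"),
                         snps = snps,
                         masked_variant = if (is.na(mask_variant)) NULL
                                          else ids[mask_variant],
                         masked_n = length(mask_idx)))
  })
}

#' Plant a single-nucleotide frameshift deletion in a PCG
#'
#' Deletes one nucleotide at the given CDS position (1-based on the
#' coding strand), emulating a -1 frameshift: the annotated frame gains
#' a premature internal stop while the shifted downstream frame remains
#' open to the terminus, so the deletion hypothesis of
#' [frameshift_hypotheses()] is valid by construction. If the deletion
#' happens not to introduce an internal stop, downstream codons of the
#' source gene are resampled (seeded) until it does. All downstream
#' feature coordinates shift by -1.
#'
#' @param genome a [mito_genome()] whose PCGs are stop-free in frame.
#' @param gene PCG symbol (default `"nad5"`, the classic case).
#' @param position CDS position to delete (default 291); must not fall
#'   in the terminal codon.
#' @param seed integer seed (used only if resampling is needed).
#' @return list `genome` (edited), `manifest` (`gene`, `position`,
#'   `deleted_base`, `major_position`, `original_cds` — the pre-deletion
#'   CDS, i.e. the ground-truth full-length gene).
#' @export
plant_frameshift <- function(genome, gene = "nad5", position = 291L,
                             seed = 1L) {
  ann <- genome$annotations
  i <- match(gene, ann$symbol)
  if (is.na(i) || ann$class[i] != "PCG") stop("gene must be an annotated PCG")
  cds <- extract_gene_sequence(genome, gene)
  L0 <- nchar(cds)
  position <- as.integer(position)
  if (position < 1L || position > L0 - 3L) {
    stop("position must lie inside the CDS and outside the terminal codon")
  }
  stops <- names(genetic_code_table(5))[genetic_code_table(5) == "*"]
  with_seed(seed, {
    cds_new <- cds
    guard <- 0L
    repeat {
      deleted <- paste0(substr(cds_new, 1L, position - 1L),
                        substr(cds_new, position + 1L, L0))
      if (nrow(detect_internal_stops(deleted, 5)) > 0L) break
      guard <- guard + 1L
      if (guard > 200L) stop("could not induce an internal stop")
      # resample one downstream body codon (original frame, non-stop)
      ci <- sample(((position + 2L) %/% 3L + 1L):(L0 %/% 3L - 1L), 1L)
      repeat {
        cod <- paste(sample_bases(3L, 0.8), collapse = "")
        if (!cod %in% stops) break
      }
      substr(cds_new, 3L * ci - 2L, 3L * ci) <- cod
    }
    a <- ann[i, ]
    major_pos <- if (a$strand == "+") a$start + position - 1L
                 else a$end - position + 1L
    deleted_base <- substr(genome$sequence, major_pos, major_pos)
    new_seq <- paste0(substr(genome$sequence, 1L, major_pos - 1L),
                      substr(genome$sequence, major_pos + 1L,
                             nchar(genome$sequence)))
    # re-write the (possibly resampled) gene body, then delete
    if (!identical(cds_new, cds)) {
      major_gene <- if (a$strand == "-") revcomp(cds_new) else cds_new
      tmp <- genome$sequence
      substr(tmp, a$start, a$end) <- major_gene
      new_seq <- paste0(substr(tmp, 1L, major_pos - 1L),
                        substr(tmp, major_pos + 1L, nchar(tmp)))
      deleted_base <- substr(tmp, major_pos, major_pos)
    }
    ann2 <- ann
    ann2$end[ann2$end >= major_pos] <- ann2$end[ann2$end >= major_pos] - 1L
    ann2$start[ann2$start > major_pos] <-
      ann2$start[ann2$start > major_pos] - 1L
    out <- mito_genome(id = genome$id, sequence = new_seq,
                       annotations = ann2[, c("symbol", "start", "end",
                                              "strand")],
                       taxon = genome$taxon, topology = genome$topology)
    list(genome = out,
         manifest = list(seed = seed, gene = gene, position = position,
                         major_position = major_pos,
                         deleted_base = deleted_base,
                         original_cds = cds_new))
  })
}
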