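#' Read an annotated mitogenome from a GenBank flat file
#'
#' A light-weight parser for the subset of the GenBank flat-file format
#' mitogenome records use: `LOCUS` (length, topology), `ACCESSION`,
#' `ORGANISM`, the `FEATURES` table (`CDS`, `tRNA`, `rRNA`, `D-loop`,
#' `misc_feature` keys; `complement()`, `join()` across the origin and
#' partial-end markers `<`/`>` are understood) and the `ORIGIN` sequence
#' block. Feature names are taken from `/gene`, then `/product`, then
#' `/note`, and mapped with [canonicalize_symbol()]; features lacking a
#' mappable name — and second copies of an already-seen symbol — are kept
#' in the `unclassified` slot and reported via a message, never analysed.
#' Partial records (fewer than 37 genes) load without error.
#'
#' @param path GenBank flat file.
#' @param extra_synonyms optional named character vector passed to
#'   [canonicalize_symbol()] to extend the symbol table.
#' @return a [mito_genome()].
#' @export
read_genbank <- function(path, extra_synonyms = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  topology <- if (grepl("\\bcircular\\b", lines[1])) "circular" else "linear"
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION", lines, value = TRUE)[1])
  if (is.na(acc)) acc <- strsplit(lines[1], "\\s+")[[1]][2]
  org <- grep("^\\s{2,}ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^\\s*ORGANISM\\s+", "", org[1])) else acc

  # ---- sequence ----
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank record has no ORIGIN sequence block")
  seq_lines <- lines[(oi[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence in GenBank record")

  # ---- features ----
  fi <- grep("^FEATURES", lines)
  if (!length(fi)) stop("GenBank record has no FEATURES table")
  feat_lines <- lines[(fi[1] + 1L):(oi[1] - 1L)]
  keys_wanted <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature",
                   "rep_origin")
  feats <- list()
  cur <- NULL
  for (ln in feat_lines) {
    if (grepl("^\\s{5}\\S", ln)) {                       # new feature
      key <- sub("^\\s{5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^\\s{5}\\S+\\s*", "", ln))
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      cur <- list(key = key, loc = loc, quals = character(0),
                  in_loc = !grepl("[)0-9]$", loc) || grepl(",$", loc))
    } else if (!is.null(cur)) {
      body <- trimws(ln)
      if (startsWith(body, "/")) {
        cur$quals <- c(cur$quals, body)
        cur$in_loc <- FALSE
      } else if (isTRUE(cur$in_loc)) {                   # continued location
        cur$loc <- paste0(cur$loc, body)
        cur$in_loc <- grepl(",$", body)
      } else if (length(cur$quals)) {                    # continued qualifier
        cur$quals[length(cur$quals)] <-
          paste(cur$quals[length(cur$quals)], body)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats <- Filter(function(f) f$key %in% keys_wanted, feats)
  if (!length(feats)) stop("GenBank record has no usable features")

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  rows <- list(); uncls <- list()
  for (f in feats) {
    loc <- parse_genbank_location(f$loc)
    label <- qual_value(f$quals, "gene")
    if (is.na(label)) label <- qual_value(f$quals, "product")
    if (is.na(label)) label <- qual_value(f$quals, "note")
    if (f$key == "D-loop" && is.na(label)) label <- "control region"
    sym <- if (is.na(label)) NA_character_ else
      tryCatch(canonicalize_symbol(label, extra = extra_synonyms),
               error = function(e) NA_character_)
    if (is.na(sym)) {
      uncls[[length(uncls) + 1L]] <-
        data.frame(key = f$key, label = label %||% NA_character_,
                   start = loc$start, end = loc$end, strand = loc$strand,
                   reason = "unmappable label", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(symbol = sym, start = loc$start, end = loc$end,
                   strand = loc$strand, stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(symbol = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  # tRNA/rRNA features are sometimes doubled by a parent `gene` feature or
  # a re-annotation; keep the first occurrence, report the rest
  dup <- duplicated(ann$symbol)
  if (any(dup)) {
    d <- ann[dup, , drop = FALSE]
    uncls[[length(uncls) + 1L]] <-
      data.frame(key = "duplicate", label = d$symbol, start = d$start,
                 end = d$end, strand = d$strand, reason = "duplicate symbol",
                 stringsAsFactors = FALSE)
    ann <- ann[!dup, , drop = FALSE]
  }
  if (nrow(ann) == 0L) stop("no mappable features in GenBank record")
  unclassified <- if (length(uncls)) do.call(rbind, uncls) else NULL
  if (!is.null(unclassified)) {
    message(acc, ": ", nrow(unclassified),
            " feature(s) retained unclassified (unmappable or duplicate)")
  }
  mito_genome(id = acc, sequence = sequence, annotations = ann,
              taxon = taxon, topology = topology,
              unclassified = unclassified)
}

# "123..456", "complement(123..456)", "join(15000..16255,1..100)",
# "complement(join(...))", partial markers < and > -> list(start, end, strand)
parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", loc)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  bounds <- lapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  })
  if (length(bounds) == 1L) {
    list(start = bounds[[1]][1], end = bounds[[1]][2], strand = strand)
  } else {
    # join across the origin: start of the first arc, end of the last
    list(start = bounds[[1]][1], end = bounds[[length(bounds)]][2],
         strand = strand)
  }
}

#' Write a minimal GenBank flat file
#'
#' Emits the subset of the format [read_genbank()] understands (LOCUS,
#' ACCESSION, ORGANISM, FEATURES with gene qualifiers, ORIGIN). Intended
#' for fixtures and round-trip checks, not for submission-grade records.
#'
#' @param genome a [mito_genome()].
#' @param path output file.
#' @export
write_genbank <- function(genome, path) {
  L <- nchar(genome$sequence)
  con <- file(path, "w"); on.exit(close(con))
  top <- if (genome$topology == "circular") "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     genome$id, L, top), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", genome$taxon), con)
  writeLines(sprintf("ACCESSION   %s", genome$id), con)
  writeLines("SOURCE      mitochondrion", con)
  writeLines(sprintf("  ORGANISM  %s", genome$taxon), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  for (i in seq_len(nrow(genome$annotations))) {
    a <- genome$annotations[i, ]
    span <- if (a$wrapped) {
      sprintf("join(%d..%d,1..%d)", a$start, L, a$end)
    } else sprintf("%d..%d", a$start, a$end)
    if (a$strand == "-") span <- sprintf("complement(%s)", span)
    writeLines(sprintf("     %-16s%s", key_of[[a$class]], span), con)
    writeLines(sprintf("                     /gene=\"%s\"", a$symbol), con)
  }
  writeLines("ORIGIN", con)
  starts <- seq.int(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(genome$sequence, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}
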