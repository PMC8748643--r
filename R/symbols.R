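#' Canonical mitochondrial gene nomenclature
#'
#' The 38-symbol vocabulary used throughout the package: 13 protein-coding
#' genes (PCGs), 22 tRNA genes, 2 rRNA genes and `CR` for the control
#' (AT-rich) region. Annotation dialects (GenBank products, MITOS labels,
#' abbreviations such as `COI` or `12S`) are mapped onto this vocabulary by
#' [canonicalize_symbol()].
#'
#' The leucine and serine tRNA paralogs follow the invertebrate
#' mitochondrial convention: `trnL1` carries anticodon UAG (CUN codons),
#' `trnL2` UAA (UUR); `trnS1` UCU/GCU (AGN), `trnS2` UGA (UCN).
#'
#' @format A character vector of 38 canonical symbols.
#' @export
canonical_symbols <- function() {
  c(pcg_symbols(), trna_symbols(), rrna_symbols(), "CR")
}

#' @rdname canonical_symbols
#' @export
pcg_symbols <- function() {
  c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
}

#' @rdname canonical_symbols
#' @export
trna_symbols <- function() {
  c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
    "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
    "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
}

#' @rdname canonical_symbols
#' @export
rrna_symbols <- function() {
  c("rrnL", "rrnS")
}

#' Feature class of a canonical symbol
#'
#' @param symbol character vector of canonical symbols.
#' @return character vector over `PCG`, `tRNA`, `rRNA`, `CR`.
#' @export
feature_class_of <- function(symbol) {
  out <- rep(NA_character_, length(symbol))
  out[symbol %in% pcg_symbols()] <- "PCG"
  out[symbol %in% trna_symbols()] <- "tRNA"
  out[symbol %in% rrna_symbols()] <- "rRNA"
  out[symbol == "CR"] <- "CR"
  if (anyNA(out)) {
    stop("not canonical gene symbols: ",
         paste(unique(symbol[is.na(out)]), collapse = ", "))
  }
  out
}

# one-letter amino-acid code for each tRNA symbol, used when parsing
# "tRNA-Leu" style labels
.trna_aa <- c(
  trnA = "Ala", trnC = "Cys", trnD = "Asp", trnE = "Glu", trnF = "Phe",
  trnG = "Gly", trnH = "His", trnI = "Ile", trnK = "Lys", trnM = "Met",
  trnN = "Asn", trnP = "Pro", trnQ = "Gln", trnR = "Arg", trnT = "Thr",
  trnV = "Val", trnW = "Trp", trnY = "Tyr"
)

# static synonym table; lower-cased keys.  User-extensible through the
# `extra` argument of canonicalize_symbol().
.symbol_synonyms <- local({
  syn <- c(
    # protein-coding genes
    "cox1" = "cox1", "coi" = "cox1", "co1" = "cox1", "coxi" = "cox1",
    "cytochrome c oxidase subunit 1" = "cox1",
    "cytochrome c oxidase subunit i" = "cox1",
    "cox2" = "cox2", "coii" = "cox2", "co2" = "cox2", "coxii" = "cox2",
    "cytochrome c oxidase subunit 2" = "cox2",
    "cytochrome c oxidase subunit ii" = "cox2",
    "cox3" = "cox3", "coiii" = "cox3", "co3" = "cox3", "coxiii" = "cox3",
    "cytochrome c oxidase subunit 3" = "cox3",
    "cytochrome c oxidase subunit iii" = "cox3",
    "cob" = "cob", "cytb" = "cob", "cyt b" = "cob", "cytochrome b" = "cob",
    "atp6" = "atp6", "atpase6" = "atp6", "atpase 6" = "atp6",
    "atp synthase f0 subunit 6" = "atp6",
    "atp8" = "atp8", "atpase8" = "atp8", "atpase 8" = "atp8",
    "atp synthase f0 subunit 8" = "atp8",
    "nad1" = "nad1", "nd1" = "nad1", "nadh dehydrogenase subunit 1" = "nad1",
    "nad2" = "nad2", "nd2" = "nad2", "nadh dehydrogenase subunit 2" = "nad2",
    "nad3" = "nad3", "nd3" = "nad3", "nadh dehydrogenase subunit 3" = "nad3",
    "nad4" = "nad4", "nd4" = "nad4", "nadh dehydrogenase subunit 4" = "nad4",
    "nad4l" = "nad4L", "nd4l" = "nad4L",
    "nadh dehydrogenase subunit 4l" = "nad4L",
    "nad5" = "nad5", "nd5" = "nad5", "nadh dehydrogenase subunit 5" = "nad5",
    "nad6" = "nad6", "nd6" = "nad6", "nadh dehydrogenase subunit 6" = "nad6",
    # rRNAs
    "rrnl" = "rrnL", "16s" = "rrnL", "l-rrna" = "rrnL", "lrrna" = "rrnL",
    "16s rrna" = "rrnL", "16s ribosomal rna" = "rrnL",
    "large subunit ribosomal rna" = "rrnL",
    "rrns" = "rrnS", "12s" = "rrnS", "s-rrna" = "rrnS", "srrna" = "rrnS",
    "12s rrna" = "rrnS", "12s ribosomal rna" = "rrnS",
    "small subunit ribosomal rna" = "rrnS",
    # control region
    "cr" = "CR", "at-rich region" = "CR", "at rich region" = "CR",
    "control region" = "CR", "d-loop" = "CR", "oh" = "CR"
  )
  # unambiguous tRNAs: trnA, "tRNA-Ala", trna(ala)
  for (sym in names(.trna_aa)) {
    aa3 <- .trna_aa[[sym]]
    syn[tolower(sym)] <- sym
    syn[tolower(paste0("trna-", aa3))] <- sym
    syn[tolower(paste0("trna_", aa3))] <- sym
    syn[tolower(paste0("trna ", aa3))] <- sym
  }
  # explicit paralog suffixes
  for (p in c("trnL1", "trnL2", "trnS1", "trnS2")) syn[tolower(p)] <- p
  syn["trna-leu1"] <- "trnL1"; syn["trna-leu2"] <- "trnL2"
  syn["trna-ser1"] <- "trnS1"; syn["trna-ser2"] <- "trnS2"
  syn
})

# anticodon-based disambiguation for Leu/Ser paralogs (invertebrate
# convention, RNA or DNA alphabet accepted)
.paralog_by_anticodon <- c(
  "leu.taa" = "trnL2", "leu.uaa" = "trnL2",
  "leu.tag" = "trnL1", "leu.uag" = "trnL1",
  "ser.tga" = "trnS2", "ser.uga" = "trnS2",
  "ser.tct" = "trnS1", "ser.ucu" = "trnS1",
  "ser.gct" = "trnS1", "ser.gcu" = "trnS1"
)

#' Map an annotation label onto the canonical gene symbol vocabulary
#'
#' Understands common GenBank and MITOS dialects, e.g. `"COI"`, `"ND4L"`,
#' `"tRNA-Met"`, `"trnL2(taa)"`, `"12S ribosomal RNA"`. Leucine and serine
#' tRNA paralogs are disambiguated by an explicit `1`/`2` suffix or by an
#' anticodon given in parentheses; a bare `"tRNA-Leu"` is ambiguous and
#' raises an error.
#'
#' @param raw_label a non-empty character scalar.
#' @param extra optional named character vector of additional synonyms
#'   (names are labels, values canonical symbols), checked first.
#' @return one canonical symbol (see [canonical_symbols()]).
#' @examples
#' canonicalize_symbol("COI")
#' canonicalize_symbol("trnL(taa)")
#' canonicalize_symbol("12S ribosomal RNA")
#' @export
canonicalize_symbol <- function(raw_label, extra = NULL) {
  if (!is.character(raw_label) || length(raw_label) != 1L ||
      is.na(raw_label) || !nzchar(trimws(raw_label))) {
    stop("raw_label must be a non-empty character scalar")
  }
  lab <- trimws(raw_label)
  if (!is.null(extra)) {
    hit <- extra[match(tolower(lab), tolower(names(extra)))]
    if (!is.na(hit)) return(unname(hit))
  }
  key <- tolower(lab)

  # anticodon in parentheses or after a dash: trnL(taa), trnL-uaa,
  # "tRNA-Ser(UCU)", mitos "trnS1(gcu)"
  m <- regmatches(key, regexec("^(trna[-_ ]?|trn)([a-z0-9]+)[-_(]+([acgut]{3})\\)?$", key))[[1]]
  if (length(m) == 4L) {
    body <- m[3]; anticodon <- m[4]
    aa <- .resolve_trna_body(body)
    if (!is.na(aa)) {
      if (aa %in% c("leu", "ser")) {
        hit <- .paralog_by_anticodon[paste(aa, anticodon, sep = ".")]
        if (!is.na(hit)) return(unname(hit))
        stop("anticodon '", anticodon, "' does not identify a ", aa,
             " tRNA paralog in label '", raw_label, "'")
      }
      # anticodon redundant for the other amino acids
      plain <- .symbol_synonyms[paste0("trna-", tolower(body))]
      if (!is.na(plain)) return(unname(plain))
      hit2 <- .symbol_synonyms[paste0("trn", substr(body, 1, 2))]
      sym <- names(.trna_aa)[tolower(.trna_aa) == aa]
      if (length(sym) == 1L) return(sym)
    }
  }

  key2 <- gsub("\\s+", " ", key)
  hit <- .symbol_synonyms[key2]
  if (!is.na(hit)) return(unname(hit))

  if (key2 %in% c("trnl", "trna-leu", "trna leu", "trns", "trna-ser",
                  "trna ser")) {
    stop("ambiguous label '", raw_label,
         "': leucine/serine tRNA paralog requires a 1/2 suffix or anticodon")
  }
  stop("cannot map label '", raw_label, "' onto a canonical gene symbol")
}

# "Leu", "L", "ser2", "S1" -> lower-case amino-acid keyword (paralog digit
# stripped), NA when unrecognised
.resolve_trna_body <- function(body) {
  body <- sub("[12]$", "", body)
  aa3 <- tolower(.trna_aa)
  one <- c(a = "ala", c = "cys", d = "asp", e = "glu", f = "phe", g = "gly",
           h = "his", i = "ile", k = "lys", l = "leu", m = "met", n = "asn",
           p = "pro", q = "gln", r = "arg", s = "ser", t = "thr", v = "val",
           w = "trp", y = "tyr")
  if (body %in% c(aa3, "leu", "ser")) return(body)
  if (body %in% names(one)) return(unname(one[body]))
  NA_character_
}

#' The ancestral insect (holometabolan) mitochondrial gene order
#'
#' The packaged 37-gene + control-region arrangement against which
#' rearrangements are counted. The control region sits between `rrnS` and
#' `trnI`, its conserved insect location.
#'
#' @param include_cr include the control region element (default `TRUE`).
#' @return a [gene_order()] object, circular, taxon `"ancestral_insect"`.
#' @examples
#' ord <- ancestral_insect_order()
#' head(ord$elements, 3)  # the I-Q-M start
#' @export
ancestral_insect_order <- function(include_cr = TRUE) {
  sym <- c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY", "cox1",
           "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3", "trnG",
           "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF", "nad5",
           "trnH", "nad4", "nad4L", "trnT", "trnP", "nad6", "cob", "trnS2",
           "nad1", "trnL1", "rrnL", "trnV", "rrnS", "CR")
  str <- c("+", "-", "+", "+", "+", "-", "-", "+",
           "+", "+", "+", "+", "+", "+", "+", "+",
           "+", "+", "+", "+", "+", "+", "-", "-",
           "-", "-", "-", "+", "-", "+", "+", "+",
           "-", "-", "-", "-", "-", "+")
  keep <- if (include_cr) rep(TRUE, 38L) else sym != "CR"
  gene_order(taxon = "ancestral_insect", symbols = sym[keep],
             strands = str[keep], topology = "circular",
             includes_cr = include_cr)
}
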