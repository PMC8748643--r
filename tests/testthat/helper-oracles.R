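# independent oracles and small fixture builders used across the suite

mito_stops <- function(code = 5) {
  tab <- Biostrings::getGeneticCode(as.character(code))
  names(tab)[tab == "*"]
}

# openness by direct translation: no internal stop (terminal codon of an
# exact-multiple length is exempt)
naive_open <- function(s, code = 5) {
  stops <- mito_stops(code)
  n <- nchar(s); nc <- n %/% 3
  if (nc == 0) return(TRUE)
  starts <- seq(1, by = 3, length.out = nc)
  cods <- substring(s, starts, starts + 2)
  internal <- seq_len(nc)
  if (n %% 3 == 0) internal <- internal[-nc]
  !any(cods[internal] %in% stops)
}

# exhaustive frameshift oracles: brute-force string surgery
oracle_deletion_candidates <- function(s, code = 5) {
  L <- nchar(s)
  keep <- vapply(seq_len(L + 1), function(p) {
    any(vapply(c("A", "C", "G", "T"), function(x) {
      naive_open(paste0(substr(s, 1, p - 1), x, substr(s, p, L)), code)
    }, TRUE))
  }, TRUE)
  seq_len(L + 1)[keep]
}

oracle_insertion_candidates <- function(s, code = 5) {
  L <- nchar(s)
  keep <- vapply(seq_len(L), function(p) {
    naive_open(paste0(substr(s, 1, p - 1), substr(s, p + 1, L)), code)
  }, TRUE)
  seq_len(L)[keep]
}

# random AT-biased sequence
random_seq <- function(n, at = 0.7) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# random signed gene order over a sample of canonical symbols
random_signed_order <- function(n, taxon = "rand") {
  syms <- sample(setdiff(canonical_symbols(), "CR"), n)
  gene_order(taxon, syms, sample(c("+", "-"), n, replace = TRUE))
}

# tiny 60 bp circular toy genome with a wrapped minus-strand gene
toy_wrapped_genome <- function() {
  s <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  ann <- data.frame(
    symbol = c("trnI", "trnM", "cox1"),
    start = c(5L, 20L, 55L), end = c(12L, 30L, 6L),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  mito_genome("toy", s, ann, topology = "circular")
}
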