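# low-level nucleotide helpers shared across modules

# reverse complement of an ACGTN character scalar (keeps case upper)
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# genetic code table by NCBI id ("5" invertebrate mito default, "2"
# vertebrate mito, "1" standard); named character vector codon -> aa
genetic_code_table <- function(id = 5) {
  Biostrings::getGeneticCode(as.character(id))
}

# split an in-frame nucleotide string into complete codons (trailing 1-2 nt
# dropped); returns character vector of 3-mers
codons_of <- function(s) {
  n <- nchar(s)
  nc <- n %/% 3L
  if (nc == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = nc)
  substring(s, starts, starts + 2L)
}

# 1-based circular slice of sequence string; start may exceed end (wrap)
circular_slice <- function(s, start, end) {
  L <- nchar(s)
  stopifnot(start >= 1L, start <= L, end >= 1L, end <= L)
  if (start <= end) substr(s, start, end)
  else paste0(substr(s, start, L), substr(s, 1L, end))
}
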