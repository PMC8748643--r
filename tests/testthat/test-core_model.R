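test_that("canonicalize_symbol maps common dialects and rejects garbage", {
  cases <- list(
    c("COI", "cox1"), c("cox1", "cox1"), c("CO2", "cox2"),
    c("CYTB", "cob"), c("cytochrome b", "cob"),
    c("ND4L", "nad4L"), c("NADH dehydrogenase subunit 5", "nad5"),
    c("ATPase6", "atp6"), c("ATP synthase F0 subunit 8", "atp8"),
    c("12S ribosomal RNA", "rrnS"), c("16S", "rrnL"), c("l-rRNA", "rrnL"),
    c("tRNA-Met", "trnM"), c("trnW", "trnW"),
    c("trnL(taa)", "trnL2"), c("trnL(tag)", "trnL1"),
    c("tRNA-Leu(UAA)", "trnL2"), c("trnS(gct)", "trnS1"),
    c("trnS2(tga)", "trnS2"), c("tRNA-Ser1", "trnS1"),
    c("control region", "CR"), c("D-loop", "CR"))
  for (cs in cases) expect_identical(canonicalize_symbol(cs[1]), cs[2])
  expect_error(canonicalize_symbol("tRNA-Leu"), "ambiguous")
  expect_error(canonicalize_symbol("made-up gene"), "made-up gene")
  expect_error(canonicalize_symbol(""), "non-empty")
  # user-extensible synonym table
  expect_identical(canonicalize_symbol("weird", extra = c(weird = "nad2")),
                   "nad2")
})

test_that("ancestral order has the documented structure", {
  ord <- ancestral_insect_order()
  el <- ord$elements
  expect_identical(el$symbol[1:3], c("trnI", "trnQ", "trnM"))
  cls <- feature_class_of(el$symbol)
  expect_identical(as.integer(table(cls)[c("PCG", "tRNA", "rRNA", "CR")]),
                   c(13L, 22L, 2L, 1L))
  # CR between rrnS and trnI (its conserved insect location)
  i <- match("CR", el$symbol)
  expect_identical(el$symbol[i - 1L], "rrnS")
  expect_identical(el$symbol[(i %% nrow(el)) + 1L], "trnI")
  expect_false("CR" %in% ancestral_insect_order(FALSE)$elements$symbol)
})

test_that("extract_gene_sequence is strand-aware and handles wrap", {
  g <- toy_wrapped_genome()
  # plus strand: plain slice
  expect_identical(extract_gene_sequence(g, "trnI"),
                   substr(g$sequence, 5, 12))
  # wrapped minus-strand gene: manual concatenation of the two arcs,
  # then reverse complement (independent arithmetic)
  arcs <- paste0(substr(g$sequence, 55, 60), substr(g$sequence, 1, 6))
  expect_identical(extract_gene_sequence(g, "cox1"),
                   paste(rev(strsplit(chartr("ACGT", "TGCA", arcs),
                                      "")[[1]]), collapse = ""))
  expect_true(g$annotations$wrapped[g$annotations$symbol == "cox1"])
  expect_error(extract_gene_sequence(g, "nad3"), "not annotated")
})

test_that("MitoGenome invariants are enforced", {
  s <- strrep("ACGT", 20)
  ann <- data.frame(symbol = "trnI", start = 1, end = 10, strand = "+")
  expect_silent(mito_genome("x", s, ann))
  expect_error(mito_genome("x", "", ann), "non-empty")
  expect_error(mito_genome("x", s, transform(ann, end = 999)), "outside")
  expect_error(
    mito_genome("x", s, rbind(ann, ann)), "duplicate")
  wrap <- data.frame(symbol = "trnI", start = 70, end = 5, strand = "+")
  expect_error(mito_genome("x", s, wrap, topology = "linear"), "wrapped")
  expect_silent(mito_genome("x", s, wrap, topology = "circular"))
})

test_that("extract_gene_order sorts by start with deterministic tie-break", {
  s <- strrep("ACGT", 30)
  ann <- data.frame(symbol = c("trnM", "trnI", "trnQ"),
                    start = c(50, 10, 50), end = c(80, 20, 60),
                    strand = "+")
  ord <- extract_gene_order(mito_genome("x", s, ann))
  # equal starts: shorter feature (smaller end) first
  expect_identical(ord$elements$symbol, c("trnI", "trnQ", "trnM"))
  expect_error(
    extract_gene_order(mito_genome("x", s, ann[1, , drop = FALSE])),
    "at least 2")
})

test_that("gene order text serialization is bit-exact", {
  ord <- ancestral_insect_order()
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_order(ord, path)
  back <- read_gene_order(path, taxon = ord$taxon)
  expect_identical(back$elements, ord$elements)
  expect_identical(format_gene_order(back), format_gene_order(ord))
  expect_match(format_gene_order(ord), "^trnI \\+ , trnQ - ,")
  expect_error(parse_gene_order("trnI + , garbage"), "malformed")
})

test_that("FASTA + feature table round-trips exactly", {
  set.seed(31)
  tpl <- generate_template(seed = 31, length = 15200)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tb <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_with_table(tpl$genome, fa, tb)
  back <- read_fasta_with_table(fa, tb)
  expect_identical(back$sequence, tpl$genome$sequence)
  expect_identical(back$annotations[, c("symbol", "start", "end", "strand")],
                   tpl$genome$annotations[, c("symbol", "start", "end",
                                              "strand")])
  # coordinate out of range on a linear genome
  bad <- utils::read.delim(tb)
  bad$end[1] <- nchar(tpl$genome$sequence) + 5L
  tb2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, tb2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fasta_with_table(fa, tb2, topology = "linear"),
               "outside|coordinate")
})

test_that("GenBank reader round-trips and tolerates partial records", {
  tpl <- generate_template(seed = 8, length = 15100)
  g <- tpl$genome
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, gb)
  back <- read_genbank(gb)
  expect_identical(back$sequence, g$sequence)
  expect_identical(back$topology, "circular")
  expect_setequal(back$annotations$symbol, g$annotations$symbol)
  m <- match(g$annotations$symbol, back$annotations$symbol)
  expect_identical(back$annotations$start[m], g$annotations$start)
  expect_identical(back$annotations$strand[m], g$annotations$strand)
  # partial record: drop half the features -> loads with < 37 genes
  g2 <- g
  g2$annotations <- g$annotations[seq(1, 38, by = 2), ]
  gb2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g2, gb2)
  expect_lt(nrow(read_genbank(gb2)$annotations), 37L)
  # a record with no usable features errors
  lines <- readLines(gb)
  feat <- grep("^     (CDS|tRNA|rRNA|D-loop)|^                     /gene",
               lines)
  writeLines(lines[-feat], gb2)
  expect_error(read_genbank(gb2), "features")
})

test_that("orientation and rotation contracts hold", {
  tpl <- generate_template(seed = 13, length = 15050)
  g <- tpl$genome
  L <- nchar(g$sequence)
  # reverse-complementing the genome leaves every coding sequence intact
  rc <- mito_genome(
    id = g$id,
    sequence = paste(rev(strsplit(chartr("ACGTN", "TGCAN", g$sequence),
                                  "")[[1]]), collapse = ""),
    annotations = data.frame(
      symbol = g$annotations$symbol,
      start = L - g$annotations$end + 1L,
      end = L - g$annotations$start + 1L,
      strand = ifelse(g$annotations$strand == "+", "-", "+")),
    topology = "circular")
  for (sym in c("cox1", "nad5", "trnQ", "rrnS")) {
    expect_identical(extract_gene_sequence(rc, sym),
                     extract_gene_sequence(g, sym))
  }
  # rotating the circular sequence yields an equal GeneOrder
  k <- 4321L
  rot <- mito_genome(
    id = g$id,
    sequence = paste0(substr(g$sequence, k + 1L, L),
                      substr(g$sequence, 1L, k)),
    annotations = data.frame(
      symbol = g$annotations$symbol,
      start = ((g$annotations$start - k - 1L) %% L) + 1L,
      end = ((g$annotations$end - k - 1L) %% L) + 1L,
      strand = g$annotations$strand),
    topology = "circular")
  expect_true(order_equal(extract_gene_order(rot), extract_gene_order(g)))
})
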