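test_that("generate_template states its world and is bit-reproducible", {
  tpl <- generate_template(seed = 1)
  g <- tpl$genome
  expect_identical(nchar(g$sequence), 16255L)
  expect_identical(nrow(g$annotations), 38L)
  expect_true(order_equal(extract_gene_order(g), ancestral_insect_order()))
  at <- composition_stats(g)$at_content
  expect_lt(abs(at - 0.84), 0.02)
  # PCGs stop-free in frame with canonical terminals
  for (sym in pcg_symbols()) {
    cds <- extract_gene_sequence(g, sym)
    expect_identical(nrow(detect_internal_stops(cds)), 0L)
    expect_true(substr(cds, 1, 3) %in% c("ATA", "ATT", "ATG"))
    expect_identical(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")
  }
  # determinism: same seed -> identical FASTA bytes
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  tb <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_with_table(g, fa1, tb)
  write_fasta_with_table(generate_template(seed = 1)$genome, fa2, tb)
  expect_identical(readLines(fa1), readLines(fa2))
  # different seed -> different sequence
  expect_false(identical(generate_template(seed = 2)$genome$sequence,
                         g$sequence))
  # a neutral AT target is realized too
  at50 <- composition_stats(generate_template(seed = 3,
                                              at_fraction = 0.5)$genome)
  expect_lt(abs(at50$at_content - 0.5), 0.02)
  expect_error(generate_template(length = 5000), "within")
  expect_error(generate_template(at_fraction = 0.95), "within")
})

test_that("apply_rearrangements plants detectable events with bookkeeping", {
  tpl <- generate_template(seed = 21, length = 15800)
  ref <- ancestral_insect_order()
  # zero events: genome unchanged
  rea0 <- apply_rearrangements(tpl$genome,
                               data.frame(gene = character(0),
                                          type = character(0)), seed = 1)
  expect_identical(rea0$genome$sequence, tpl$genome$sequence)

  ev <- data.frame(gene = c("trnA", "trnS1", "trnF", "trnS2", "trnL1",
                            "rrnS"),
                   type = "transposition")
  rea <- apply_rearrangements(tpl$genome, ev, seed = 22)
  rep1 <- classify_events(ref, extract_gene_order(rea$genome))
  expect_identical(rep1$n_transpositions, 6L)
  expect_setequal(rep1$moved_genes, ev$gene)
  # coordinate bookkeeping: every gene still excises its sequence
  expect_identical(rea$manifest$gene_checksums[order(names(rea$manifest$gene_checksums))],
                   tpl$manifest$gene_checksums[order(names(tpl$manifest$gene_checksums))])

  inv <- apply_rearrangements(tpl$genome,
                              data.frame(gene = "trnG", type = "inversion"),
                              seed = 23)
  rep2 <- classify_events(ref, extract_gene_order(inv$genome))
  expect_identical(rep2$n_inversions, 1L)
  expect_identical(rep2$n_transpositions, 0L)
  # inversion preserves the coding sequence (revcomp + strand flip)
  expect_identical(extract_gene_sequence(inv$genome, "trnG"),
                   extract_gene_sequence(tpl$genome, "trnG"))

  expect_error(apply_rearrangements(tpl$genome,
                                    data.frame(gene = c("trnA", "trnA"),
                                               type = "transposition"),
                                    seed = 1),
               "two events")
  expect_error(apply_rearrangements(tpl$genome,
                                    data.frame(gene = "trnA",
                                               type = "transposition",
                                               after = "trnR"),
                                    seed = 1),
               "adjacency|close")
})

test_that("make_variants plants exactly the manifest SNPs", {
  tpl <- generate_template(seed = 31, length = 15200)
  mv <- make_variants(tpl$genome, n_variants = 6, n_snps = 10,
                      within_classes = "PCG", seed = 32)
  aln <- align_variants(mv$variants)
  snps <- call_snps(aln, annotation = tpl$genome)
  expect_identical(sort(snps$position),
                   sort(as.integer(mv$manifest$positions)))
  expect_true(all(snps$gene %in% pcg_symbols()))
  # alleles match the manifest
  for (rec in mv$manifest$snps) {
    row <- snps[snps$position == rec$position, ]
    expect_identical(row[[1, names(mv$variants)[1]]], rec$ref)
    expect_identical(row[[1, names(mv$variants)[rec$carriers[1]]]], rec$alt)
  }
  # zero SNPs -> identical variants, empty table
  mv0 <- make_variants(tpl$genome, n_variants = 3, n_snps = 0, seed = 33)
  expect_identical(length(unique(mv0$variants)), 1L)
  expect_identical(nrow(call_snps(align_variants(mv0$variants))), 0L)
  # masking half a variant leaves the SNP count unchanged
  mvm <- make_variants(tpl$genome, n_variants = 6, n_snps = 10,
                       within_classes = "PCG",
                       missing_pattern = list(variant = 6, fraction = 0.5),
                       seed = 32)
  snpsm <- call_snps(align_variants(mvm$variants), annotation = tpl$genome)
  expect_identical(nrow(snpsm), 10L)
  masked_id <- mvm$manifest$masked_variant
  expect_gt(sum(is.na(snpsm[[masked_id]])), 0L)
  expect_error(make_variants(tpl$genome, n_variants = 1), "n_variants")
})

test_that("plant_frameshift constructs a valid -1 deletion scenario", {
  tpl <- generate_template(seed = 41, length = 15700)
  fs <- plant_frameshift(tpl$genome, gene = "nad5", position = 291,
                         seed = 42)
  expect_identical(nchar(fs$genome$sequence),
                   nchar(tpl$genome$sequence) - 1L)
  cds <- extract_gene_sequence(fs$genome, "nad5")
  expect_identical(nchar(cds), nchar(fs$manifest$original_cds) - 1L)
  rep1 <- frameshift_hypotheses(cds, gene = "nad5")
  expect_gt(nrow(rep1$internal_stops), 0L)
  del <- Filter(function(h) h$type == "deletion", rep1$hypotheses)
  expect_length(del, 1L)
  expect_true(291 %in% del[[1]]$candidate_positions)
  # truncation bookkeeping: translation stops at the first internal stop
  expect_identical(rep1$truncated_product_length,
                   rep1$internal_stops$codon_index[1] - 1L)
  # downstream features shifted by -1, upstream untouched
  a0 <- tpl$genome$annotations; a1 <- fs$genome$annotations
  pos <- fs$manifest$major_position
  expect_identical(a1$start[a0$start > pos], a0$start[a0$start > pos] - 1L)
  expect_identical(a1$start[a0$end < pos], a0$start[a0$end < pos])
  # every other gene still excises the same sequence
  for (sym in setdiff(a0$symbol, "nad5")) {
    expect_identical(extract_gene_sequence(fs$genome, sym),
                     extract_gene_sequence(tpl$genome, sym))
  }
  expect_error(plant_frameshift(tpl$genome, "nad5",
                                nchar(extract_gene_sequence(tpl$genome,
                                                            "nad5"))),
               "terminal")
  expect_error(plant_frameshift(tpl$genome, "trnA", 10), "PCG")
})
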