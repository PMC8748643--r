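test_that("detect_internal_stops finds premature stops, never the terminal", {
  expect_identical(nrow(detect_internal_stops("ATGAAATTTTAA")), 0L)
  hit <- detect_internal_stops("ATGTAAAAATAA")
  expect_identical(hit$codon_index, 2L)
  expect_identical(hit$triplet, "TAA")
  # trailing incomplete terminal: complete codons all internal
  hit2 <- detect_internal_stops("ATGTAGAAAT")
  expect_identical(hit2$codon_index, 2L)
  # TGA is tryptophan, not a stop, in the mito codes
  expect_identical(nrow(detect_internal_stops("ATGTGAAAATAA")), 0L)
  # but AGA is a stop under the vertebrate mito code
  expect_identical(nrow(detect_internal_stops("ATGAGAAAATAA",
                                              genetic_code = 2)), 1L)
  expect_error(detect_internal_stops("ATG"), "at least 6")
})

test_that("frameshift candidate sets equal the exhaustive oracle", {
  set.seed(99)
  n_checked <- 0
  while (n_checked < 40) {
    s <- random_seq(sample(30:180, 1), at = 0.72)
    rep1 <- frameshift_hypotheses(s)
    if (nrow(rep1$internal_stops) == 0) next
    n_checked <- n_checked + 1
    got <- list(deletion = integer(0), insertion = integer(0))
    for (h in rep1$hypotheses) got[[h$type]] <- h$candidate_positions
    expect_identical(as.integer(got$deletion),
                     as.integer(oracle_deletion_candidates(s)))
    expect_identical(as.integer(got$insertion),
                     as.integer(oracle_insertion_candidates(s)))
    # soundness checked directly: some re-insertion at every reported
    # position provably restores an open frame
    for (p in got$deletion) {
      expect_true(any(vapply(c("A", "C", "G", "T"), function(x)
        naive_open(paste0(substr(s, 1, p - 1), x,
                          substr(s, p, nchar(s)))), TRUE)))
    }
    # invariants
    expect_identical(rep1$truncated_product_length,
                     rep1$internal_stops$codon_index[1] - 1L)
    for (h in rep1$hypotheses) {
      expect_true(h$downstream_open)
      expect_true(all(h$candidate_positions >= h$candidate_interval[1] &
                        h$candidate_positions <= h$candidate_interval[2]))
    }
  }
})

test_that("irreparable frames (stops in every shifted frame) admit no hypothesis", {
  # search (seeded, via the oracle) for sequences with internal stops
  # that no single +/-1 indel can repair, then check the scanner agrees
  set.seed(404)
  found <- 0L
  while (found < 5L) {
    s <- random_seq(sample(40:90, 1), at = 0.8)
    rep1 <- frameshift_hypotheses(s)
    if (nrow(rep1$internal_stops) == 0L) next
    if (length(oracle_deletion_candidates(s)) > 0L ||
        length(oracle_insertion_candidates(s)) > 0L) next
    found <- found + 1L
    expect_length(rep1$hypotheses, 0L)
  }
  # and the scanner never invents hypotheses for a clean frame
  clean <- frameshift_hypotheses("ATGAAATTTCATTAA")
  expect_identical(nrow(clean$internal_stops), 0L)
  expect_length(clean$hypotheses, 0L)
})

test_that("planted deletions are always recovered (property)", {
  set.seed(123)
  stops <- mito_stops(5)
  hits <- 0L; total <- 0L
  for (i in 1:100) {
    # stop-free 300-900 nt CDS, then delete one nucleotide
    n_cod <- sample(100:300, 1)
    body <- character(n_cod)
    for (j in seq_len(n_cod)) {
      repeat {
        cod <- random_seq(3, at = 0.75)
        if (!cod %in% stops) break
      }
      body[j] <- cod
    }
    full <- paste0("ATG", paste(body, collapse = ""), "TAA")
    q <- sample(nchar(full) - 3L, 1)
    broken <- paste0(substr(full, 1, q - 1),
                     substr(full, q + 1, nchar(full)))
    rep1 <- frameshift_hypotheses(broken)
    if (nrow(rep1$internal_stops) == 0) next   # deletion left frame open
    total <- total + 1L
    del <- Filter(function(h) h$type == "deletion", rep1$hypotheses)
    if (length(del) && q %in% del[[1]]$candidate_positions) hits <- hits + 1L
  }
  expect_gt(total, 50)
  expect_identical(hits, total)  # 100% recovery
})

test_that("homolog refinement recovers the planted position", {
  tpl <- generate_template(seed = 17, length = 15300)
  fs <- plant_frameshift(tpl$genome, gene = "cox3", position = 200,
                         seed = 18)
  cds <- extract_gene_sequence(fs$genome, "cox3")
  rep1 <- frameshift_hypotheses(cds, gene = "cox3")
  del <- Filter(function(h) h$type == "deletion", rep1$hypotheses)[[1]]
  expect_true(200 %in% del$candidate_positions)
  # self-homolog: translation of the pre-deletion gene
  truth <- mitocomp:::translate_cds(fs$manifest$original_cds)
  ref <- refine_with_homolog(rep1, cds, truth)
  del2 <- Filter(function(h) h$type == "deletion", ref$hypotheses)[[1]]
  expect_true(200 %in% del2$candidate_positions)
  expect_false(ref$refine_warning)
  # the refined repair reconstructs the ground-truth protein exactly
  p <- if (!is.na(del2$refined_position)) del2$refined_position
       else del2$candidate_positions[1]
  repairs <- mitocomp:::repaired_sequences(cds, "deletion", p)
  expect_true(any(vapply(repairs, function(r)
    identical(mitocomp:::translate_cds(r), truth), TRUE)))
  # an unrelated homolog trips the score floor: unchanged + warning
  junk <- paste(rep("W", 260), collapse = "")
  expect_warning(ref2 <- refine_with_homolog(rep1, cds, junk), "floor")
  expect_true(ref2$refine_warning)
  expect_identical(ref2$hypotheses[[1]]$candidate_positions,
                   rep1$hypotheses[[1]]$candidate_positions)
})
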