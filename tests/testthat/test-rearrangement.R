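test_that("backbone alignment: identity, I-Q-M, exhaustive maximum", {
  ref <- ancestral_insect_order()
  bb <- align_circular_orders(ref, ref)
  expect_identical(bb$symbol, ref$elements$symbol)

  # the I-Q-M -> M-I-Q rearrangement keeps {I, Q}, moves M
  a <- gene_order("anc", c("trnI", "trnQ", "trnM", "cox1"),
                  c("+", "-", "+", "+"))
  b <- gene_order("qry", c("trnM", "trnI", "trnQ", "cox1"),
                  c("+", "+", "-", "+"))
  bb2 <- align_circular_orders(a, b)
  expect_setequal(bb2$symbol, c("trnI", "trnQ", "cox1"))
  rep1 <- classify_events(a, b)
  expect_identical(unname(rep1$events["trnM"]), "transposition")
  expect_identical(rep1$n_transpositions, 1L)

  expect_error(
    align_circular_orders(gene_order("a", "cox1", "+"),
                          gene_order("b", "cox2", "+")),
    "shared")
})

test_that("event classes are assigned by strand and placement", {
  ref <- ancestral_insect_order()
  el <- ref$elements
  # strand flip in place -> 1 inversion, 0 transpositions
  el2 <- el
  i <- match("trnD", el2$symbol)
  el2$strand[i] <- "-"
  q <- gene_order("flip", el2$symbol, el2$strand)
  rep1 <- classify_events(ref, q)
  expect_identical(rep1$n_inversions, 1L)
  expect_identical(rep1$n_transpositions, 0L)
  expect_identical(unname(rep1$events["trnD"]), "inversion")
  expect_false("trnD" %in% rep1$moved_genes)  # flipped in place, not moved

  # relocate + flip -> inverse transposition
  el3 <- el[-i, ]
  moved <- el[i, ]; moved$strand <- "-"
  el3 <- rbind(el3[1:25, ], moved, el3[26:nrow(el3), ])
  q2 <- gene_order("invtrans", el3$symbol, el3$strand)
  rep2 <- classify_events(ref, q2)
  expect_identical(rep2$n_inverse_transpositions, 1L)
  expect_identical(unname(rep2$events["trnD"]), "inverse_transposition")
  expect_true("trnD" %in% rep2$moved_genes)

  # identical orders: all counts zero, moved/backbone partition intact
  rep3 <- classify_events(ref, ref)
  expect_identical(rep3$n_transpositions + rep3$n_inversions +
                     rep3$n_inverse_transpositions, 0L)
  expect_length(intersect(rep3$moved_genes, rep3$backbone$symbol), 0L)
})

test_that("classify_events matches the brute-force oracle (property)", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:9, 1)
    ref <- random_signed_order(n, "ref")
    q <- gene_order("q", sample(ref$elements$symbol),
                    sample(c("+", "-"), n, replace = TRUE))
    rep1 <- classify_events(ref, q)
    expect_identical(length(rep1$moved_genes) + rep1$n_inversions,
                     brute_force_min_removal(ref, q))
    # symmetry of the moved-gene count
    rep_rev <- classify_events(q, ref)
    expect_identical(length(rep_rev$moved_genes) + rep_rev$n_inversions,
                     length(rep1$moved_genes) + rep1$n_inversions)
  }
})

test_that("reports are rotation-invariant", {
  set.seed(55)
  ref <- ancestral_insect_order()
  tpl <- generate_template(seed = 55, length = 15400)
  rea <- apply_rearrangements(
    tpl$genome,
    data.frame(gene = c("trnA", "nad3", "trnV"), type = "transposition"),
    seed = 56)
  q <- extract_gene_order(rea$genome)
  rep0 <- classify_events(ref, q)
  for (k in c(5L, 17L, 30L)) {
    el <- mitocomp:::rotate_order_elements(q$elements, k)
    qr <- gene_order(q$taxon, el$symbol, el$strand)
    repk <- classify_events(ref, qr)
    expect_identical(sort(names(repk$events)), sort(names(rep0$events)))
    expect_identical(repk$n_transpositions, rep0$n_transpositions)
  }
})

test_that("k planted transpositions yield exactly k events, k <= 6", {
  movable <- c("trnA", "trnS1", "trnF", "trnS2", "trnL1", "rrnS")
  ref <- ancestral_insect_order()
  for (k in 1:6) {
    tpl <- generate_template(seed = 60 + k, length = 15600)
    rea <- apply_rearrangements(
      tpl$genome,
      data.frame(gene = movable[1:k], type = "transposition"),
      seed = 70 + k)
    rep1 <- classify_events(ref, extract_gene_order(rea$genome))
    expect_identical(rep1$n_transpositions, k)
    expect_setequal(rep1$moved_genes, movable[1:k])
  }
})

test_that("shared_event_matrix tabulates cross-taxon moved genes", {
  ref <- ancestral_insect_order()
  tpl <- generate_template(seed = 91, length = 15500)
  mk <- function(genes, seed) {
    rea <- apply_rearrangements(
      tpl$genome, data.frame(gene = genes, type = "transposition"),
      seed = seed)
    o <- extract_gene_order(rea$genome); o$taxon <- paste0("t", seed)
    o
  }
  # trnS1 moved in all three taxa, trnA in two, trnF in one
  qs <- list(mk(c("trnS1", "trnA", "trnF"), 101),
             mk(c("trnS1", "trnA"), 102),
             mk("trnS1", 103))
  mtx <- shared_event_matrix(ref, qs)
  expect_identical(unname(colSums(mtx$indicator)[c("trnS1", "trnA",
                                                   "trnF")]),
                   c(3, 2, 1))
  expect_identical(unname(rowSums(mtx$indicator)),
                   vapply(mtx$reports, function(r) length(r$events), 0))
  # a query identical to the reference gives an all-zero row
  mtx2 <- shared_event_matrix(ref, list(ref))
  expect_identical(sum(mtx2$indicator), 0L)
  expect_error(shared_event_matrix(ref, list()), "at least one")
})

test_that("partial genomes are compared on shared genes only", {
  ref <- ancestral_insect_order()
  el <- ref$elements[ref$elements$symbol != "CR", ]
  keep <- el[-match(c("trnK", "nad6", "rrnL"), el$symbol), ]
  q <- gene_order("partial", keep$symbol, keep$strand)
  rep1 <- classify_events(ref, q)
  expect_setequal(rep1$excluded_genes, c("trnK", "nad6", "rrnL", "CR"))
  expect_identical(rep1$n_transpositions, 0L)
})
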