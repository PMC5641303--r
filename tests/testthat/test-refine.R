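test_that("the built-in engine reaches the brute-force pairing maximum", {
  res <- foldSingle(nussinovEngine(), "GGGAAACCC")
  expect_equal(sum(res$pairTable > 0) / 2, 3)
  expect_equal(res$pairTable,
               pairTable(parseDotBracket("(((...)))")))
  # brute force over all nested structures confirms optimality on 8-mers
  set.seed(51)
  for (k in 1:15) {
    s <- random_rna(8)
    got <- sum(foldSingle(nussinovEngine(), s)$pairTable > 0) / 2
    expect_equal(got, oracle_max_pairing(s), info = s)
  }
  # no canonical partners -> no pairs
  expect_equal(sum(foldSingle(nussinovEngine(), "AAAAAAA")$pairTable), 0)
})

test_that("the built-in duplex engine pairs complementary strands fully", {
  res <- foldDuplex(nussinovEngine(), "GGGG", "CCCC")
  expect_equal(nrow(res$pairs), 4L)
  # antiparallel: ascending 5' positions pair descending 3' positions
  expect_equal(res$pairs[, 1], 1:4)
  expect_equal(res$pairs[, 2], 4:1)
  expect_equal(nrow(foldDuplex(nussinovEngine(), "AAAA", "GGGG")$pairs), 0L)
})

test_that("refining an inconsistent hairpin folds its span de novo", {
  gen <- generateStructure("GGGAAACCA", "GGGAAACCC", "(((...)))")
  # the hairpin is 2/9 ~ 22% inconsistent (> 20%) -> refolded;
  # the built-in engine's maximum pairing on GGGAAACCA has 2 pairs
  expect_equal(gen@elementLabels, "inconsistent")
  expect_equal(nrow(basePairs(finalStructure(gen))),
               oracle_max_pairing("GGGAAACCA"))
  expect_equal(toDotBracket(finalStructure(gen)), "((....)).")
  expect_true(all(provenance(gen) == "de-novo"))
})

test_that("assembly keeps consistent elements verbatim", {
  set.seed(53)
  for (k in 1:25) {
    fx <- homologFixture(length = sample(40:100, 1), subRate = 0.2,
                         compensatory = 0.9)
    gen <- generateStructure(fx$query, fx$template, fx$structure)
    im <- gen@intermediate
    d <- gen@decomposition
    labs <- gen@elementLabels
    els <- c(hairpins(d), stems(d))
    out_pt <- pairTable(finalStructure(gen))
    im_pt <- pairTable(im)
    for (i in which(labs == "consistent")) {
      own <- els[[i]]@owned
      expect_equal(out_pt[own], im_pt[own])
      expect_true(all(provenance(gen)[own] == "template-transfer"))
    }
    for (i in which(labs == "inconsistent"))
      expect_true(all(provenance(gen)[els[[i]]@owned] == "de-novo"))
    # unassigned positions stay unpaired
    expect_true(all(out_pt[is.na(elementAssignment(d))] == 0L))
    # result is a valid nested pair table
    expect_silent(toDotBracket(finalStructure(gen)))
  }
})

test_that("identity inputs return the template structure exactly", {
  set.seed(57)
  for (k in 1:25) {
    s <- randomNestedStructure(sample(20:120, 1))
    seq <- makeTemplateSequence(s)
    gen <- generateStructure(seq, seq, s)
    expect_equal(basePairs(finalStructure(gen)), basePairs(s))
    expect_true(all(provenance(gen) != "de-novo"))
  }
})

test_that("unrelated sequences still yield a valid structure", {
  set.seed(59)
  s <- randomNestedStructure(60)
  tmpl <- makeTemplateSequence(s)
  rnd <- random_rna(60)
  gen <- generateStructure(rnd, tmpl, s)
  expect_s4_class(finalStructure(gen), "SecondaryStructure")
  expect_silent(toDotBracket(finalStructure(gen)))
})

test_that("assembleStructure demands a refined structure per bad element", {
  aln <- alignSequences("GGGAAACCA", "GGGAAACCC")
  im <- buildIntermediate("(((...)))", aln, "GGGAAACCA")
  d <- decomposeStructure(im)
  labels <- classifyElements(d, im)
  expect_error(
    assembleStructure(im, d, labels, list(NULL), "GGGAAACCA"),
    "missing")
  refined <- list(refineElement(hairpins(d)[[1]], "GGGAAACCA",
                                nussinovEngine()))
  gen <- assembleStructure(im, d, labels, refined, "GGGAAACCA")
  expect_equal(toDotBracket(finalStructure(gen)), "((....)).")
})

test_that("stem refinement folds strand subsequences as a duplex", {
  db <- "((((((...))((...))))))"
  st <- findStems(db)[[1]]
  expect_equal(st@strand5, c(1L, 4L))
  expect_equal(st@strand3, c(19L, 22L))
  # query whose stem strands are GGGG / CCCC: full antiparallel duplex,
  # re-indexed into global coordinates
  query <- paste0("GGGG", "GGAAACCGGAAACC", "CCCC")
  p <- refineElement(st, query, nussinovEngine())
  expect_equal(unname(p[, 1]), 1:4)
  expect_equal(unname(p[, 2]), 22:19)
})
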