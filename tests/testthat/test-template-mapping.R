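test_that("canonical pairs are Watson-Crick plus wobble, never N", {
  expect_true(all(isCanonicalPair(c("G", "C", "A", "U", "G", "U"),
                                  c("C", "G", "U", "A", "U", "G"))))
  expect_false(any(isCanonicalPair(c("A", "C", "N", "G"),
                                   c("G", "U", "N", "G"))))
  expect_error(isCanonicalPair("X", "A"), "residues")
})

test_that("perfect conservation transfers the template verbatim", {
  aln <- alignSequences("GGGAAACCC", "GGGAAACCC")
  im <- buildIntermediate("(((...)))", aln, "GGGAAACCC")
  expect_equal(toDotBracket(im), "(((...)))")
  expect_equal(caseLabels(im), c(4L, 4L, 4L, 2L, 2L, 2L, 4L, 4L, 4L))
  expect_true(all(consistentPositions(im)))
})

test_that("a non-canonical substitution marks both pair ends case 3", {
  aln <- alignSequences("GGGAAACCA", "GGGAAACCC")
  im <- buildIntermediate("(((...)))", aln, "GGGAAACCA")
  expect_equal(toDotBracket(im), ".((...)).")
  expect_equal(caseLabels(im), c(3L, 4L, 4L, 2L, 2L, 2L, 4L, 4L, 3L))
  expect_equal(consistentPositions(im),
               caseLabels(im) %in% c(2L, 4L))
})

test_that("a deletion orphans the partner as case 3 via the gap rule", {
  aln <- alignmentFromGapped("GG-AAACCC", "GGGAAACCC")
  im <- buildIntermediate("(((...)))", aln, "GGAAACCC")
  # template pair 3-7 loses its opening side; query position of template 7
  # (query position 6) is orphaned
  expect_equal(toDotBracket(im), "((....))")
  expect_equal(caseLabels(im), c(4L, 4L, 2L, 2L, 2L, 3L, 4L, 4L))
  # every case-3 position has a gapped or non-canonical mate
  expect_true(all(caseLabels(im) %in% c(2L, 3L, 4L)))
})

test_that("intermediate structures agree with a naive case-table oracle", {
  set.seed(31)
  for (k in 1:60) {
    fx <- homologFixture(length = sample(30:90, 1),
                         subRate = runif(1, 0, 0.4),
                         indelRate = runif(1, 0, 0.08),
                         compensatory = runif(1))
    aln <- alignSequences(fx$query, fx$template)
    im <- buildIntermediate(fx$structure, aln, fx$query)
    orc <- oracle_four_cases(toDotBracket(fx$structure), alignedQuery(aln),
                             alignedTemplate(aln), fx$query)
    expect_equal(caseLabels(im), orc$case)
    expect_equal(pairTable(im), orc$pt)
  }
})

test_that("identity transfer holds for arbitrary fixtures", {
  set.seed(13)
  for (k in 1:20) {
    s <- randomNestedStructure(sample(20:100, 1))
    seq <- makeTemplateSequence(s)
    aln <- alignSequences(seq, seq)
    im <- buildIntermediate(s, aln, seq)
    expect_equal(basePairs(im), basePairs(s))
    expect_true(all(consistentPositions(im)))
  }
})

test_that("no pair is invented: intermediate pairs are template images", {
  set.seed(17)
  for (k in 1:20) {
    fx <- homologFixture(length = 60, subRate = 0.3, compensatory = 0.3)
    aln <- alignSequences(fx$query, fx$template)
    im <- buildIntermediate(fx$structure, aln, fx$query)
    tm <- templateMap(aln)
    imaged <- basePairs(fx$structure)
    imaged <- cbind(tm[imaged[, 1]], tm[imaged[, 2]])
    imaged <- imaged[!is.na(imaged[, 1]) & !is.na(imaged[, 2]), ,
                     drop = FALSE]
    imaged <- cbind(pmin(imaged[, 1], imaged[, 2]),
                    pmax(imaged[, 1], imaged[, 2]))
    key <- paste(imaged[, 1], imaged[, 2])
    got <- basePairs(im)
    expect_true(all(paste(got[, 1], got[, 2]) %in% key))
  }
})

test_that("extra mutations at paired sites never add case-4 positions", {
  set.seed(19)
  s <- randomNestedStructure(80)
  tmpl <- makeTemplateSequence(s)
  pt <- pairTable(s)
  paired <- which(pt > 0)
  ch <- strsplit(tmpl, "")[[1]]
  count4 <- function(q) {
    aln <- alignSequences(q, tmpl)
    sum(caseLabels(buildIntermediate(s, aln, q)) == 4L)
  }
  prev <- count4(tmpl)
  mutated <- ch
  for (p in sample(paired, min(10, length(paired)))) {
    mutated[p] <- setdiff(c("A", "C", "G", "U"), mutated[p])[1]
    now <- count4(paste(mutated, collapse = ""))
    expect_lte(now, prev)
    prev <- now
  }
})

test_that("intermediate report prints sequence, structure and cases", {
  aln <- alignSequences("GGGAAACCC", "GGGAAACCC")
  im <- buildIntermediate("(((...)))", aln, "GGGAAACCC")
  lines <- capture.output(out <- intermediateReport(im, "GGGAAACCC"))
  expect_equal(lines, c("GGGAAACCC", "(((...)))", "444222444"))
})
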