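test_that("template sequences realize their structure with canonical pairs", {
  set.seed(121)
  for (k in 1:30) {
    s <- randomNestedStructure(sample(10:80, 1))
    seq <- makeTemplateSequence(s)
    ch <- strsplit(seq, "")[[1]]
    bp <- basePairs(s)
    if (nrow(bp))
      expect_true(all(isCanonicalPair(ch[bp[, 1]], ch[bp[, 2]])))
  }
  # fixed seed reproduces the draw
  expect_identical(makeTemplateSequence("(((...)))", seed = 4),
                   makeTemplateSequence("(((...)))", seed = 4))
})

test_that("zero divergence returns the template unchanged", {
  s <- randomNestedStructure(50, seed = 6)
  tmpl <- makeTemplateSequence(s, seed = 6)
  expect_identical(mutateHomolog(tmpl, s, subRate = 0, indelRate = 0,
                                 seed = 1), tmpl)
})

test_that("fully compensatory substitution keeps every pair canonical", {
  set.seed(123)
  for (k in 1:15) {
    s <- randomNestedStructure(60)
    tmpl <- makeTemplateSequence(s)
    q <- mutateHomolog(tmpl, s, subRate = 1, indelRate = 0,
                       compensatory = 1)
    ch <- strsplit(q, "")[[1]]
    bp <- basePairs(s)
    expect_true(all(isCanonicalPair(ch[bp[, 1]], ch[bp[, 2]])))
    # template transfer under the identity alignment keeps all pairs
    aln <- alignmentFromGapped(q, tmpl)
    im <- buildIntermediate(s, aln, q)
    expect_equal(basePairs(im), basePairs(s))
  }
})

test_that("non-compensatory substitution breaks pairs at the expected rate", {
  # a fully mutated pair survives only if the random new bases happen to be
  # canonical; estimate the survival rate by simulation and compare to the
  # observed case-3 fraction
  set.seed(125)
  s <- parseDotBracket(paste0(strrep("(", 30), strrep(".", 5),
                              strrep(")", 30)))
  tmpl <- makeTemplateSequence(s)
  surv <- replicate(60, {
    q <- mutateHomolog(tmpl, s, subRate = 1, indelRate = 0,
                       compensatory = 0)
    aln <- alignmentFromGapped(q, tmpl)
    sum(caseLabels(buildIntermediate(s, aln, q)) == 4L) / 60
  })
  # Monte-Carlo estimate of the chance that two independent substitutions
  # of a canonical pair land on a canonical pair again
  pairs0 <- matrix(c("G", "C"), 1e4, 2, byrow = TRUE)
  draw <- function(b) vapply(b, function(x)
    sample(setdiff(c("A", "C", "G", "U"), x), 1), character(1))
  est <- mean(isCanonicalPair(draw(pairs0[, 1]), draw(pairs0[, 2])))
  expect_lt(abs(mean(surv) - est), 0.1)
})

test_that("divergence increases inconsistency monotonically in the mean", {
  set.seed(127)
  s <- randomNestedStructure(80)
  tmpl <- makeTemplateSequence(s)
  mean_bad <- function(rate) {
    mean(replicate(25, {
      q <- mutateHomolog(tmpl, s, subRate = rate, indelRate = 0,
                         compensatory = 0)
      aln <- alignmentFromGapped(q, tmpl)
      sum(!consistentPositions(buildIntermediate(s, aln, q)))
    }))
  }
  bad <- vapply(c(0.05, 0.2, 0.5), mean_bad, numeric(1))
  expect_true(all(diff(bad) > 0))
})

test_that("indels exercise the gap cases of template mapping", {
  set.seed(129)
  fx <- homologFixture(length = 80, subRate = 0, indelRate = 0.1,
                       compensatory = 1)
  aln <- alignSequences(fx$query, fx$template)
  im <- buildIntermediate(fx$structure, aln, fx$query)
  expect_true(any(caseLabels(im) %in% c(1L, 3L)) ||
                nchar(fx$query) == nchar(fx$template))
})

test_that("fixture pairs are reproducible under a fixed seed", {
  a <- homologFixture(length = 60, seed = 14)
  b <- homologFixture(length = 60, seed = 14)
  expect_identical(a$template, b$template)
  expect_identical(a$query, b$query)
  expect_identical(toDotBracket(a$structure), toDotBracket(b$structure))
})
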