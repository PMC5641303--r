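test_that("a lone stem-loop is a single hairpin with no stems", {
  d <- decomposeStructure("(((...)))")
  expect_length(hairpins(d), 1L)
  expect_length(stems(d), 0L)
  h <- hairpins(d)[[1]]
  expect_equal(h@strand5, c(1L, 9L))
  expect_equal(nrow(h@memberPairs), 3L)
  expect_true(all(!is.na(elementAssignment(d))))
})

test_that("an unpaired run between two hairpins is split, not shared", {
  d <- decomposeStructure("((...))...((...))")
  expect_length(hairpins(d), 2L)
  own1 <- hairpins(d)[[1]]@owned
  own2 <- hairpins(d)[[2]]@owned
  # 3-nt run at 8..10: two positions to the upstream hairpin (midpoint,
  # middle position included), one to the downstream
  expect_equal(own1, 1:9)
  expect_equal(own2, 10:17)
  expect_length(intersect(own1, own2), 0L)
})

test_that("a two-hairpin multiloop closed by a stem decomposes as derived", {
  d <- decomposeStructure("((..((...))..((...))..))")
  expect_length(hairpins(d), 2L)
  expect_length(stems(d), 1L)
  st <- stems(d)[[1]]
  expect_equal(st@strand5, c(1L, 2L))
  expect_equal(st@strand3, c(23L, 24L))
  expect_equal(nrow(st@memberPairs), 2L)
  # junction runs attach to the hairpins, never to the stem
  expect_equal(hairpins(d)[[1]]@owned, 3:12)
  expect_equal(hairpins(d)[[2]]@owned, 13:22)
})

test_that("all-unpaired structures decompose to nothing", {
  d <- decomposeStructure("....")
  expect_length(hairpins(d), 0L)
  expect_length(stems(d), 0L)
  expect_true(all(is.na(elementAssignment(d))))
})

test_that("dangling ends adjacent to stems stay unassigned", {
  # outer pairs enclose two hairpins -> stem; leading/trailing dots touch
  # the stem only and multiloop cores between stems stay single strand
  d <- decomposeStructure("..((((...))((...))))..")
  expect_length(stems(d), 1L)
  asg <- elementAssignment(d)
  expect_true(all(is.na(asg[c(1, 2, 21, 22)])))
})

test_that("every paired position is owned by exactly one element", {
  set.seed(71)
  for (k in 1:300) {
    s <- randomNestedStructure(sample(10:120, 1))
    pt <- pairTable(s)
    d <- decomposeStructure(s)
    els <- c(hairpins(d), stems(d))
    owned <- unlist(lapply(els, function(e) e@owned))
    expect_equal(anyDuplicated(owned), 0L)
    paired <- which(pt > 0)
    expect_true(all(paired %in% owned))
    # assignment table agrees with the element owned sets
    asg <- elementAssignment(d)
    for (i in seq_along(els))
      expect_equal(which(asg == i), els[[i]]@owned)
    # member pairs partition the structure's pairs
    expect_equal(sum(vapply(els, function(e) nrow(e@memberPairs),
                            integer(1))), nrow(basePairs(s)))
  }
})

test_that("both strands of every element pair the same number of bases", {
  set.seed(72)
  for (k in 1:100) {
    s <- randomNestedStructure(sample(20:120, 1))
    d <- decomposeStructure(s)
    for (e in c(hairpins(d), stems(d))) {
      bp <- e@memberPairs
      if (e@type == "stem") {
        expect_true(all(bp[, 1] >= e@strand5[1] & bp[, 1] <= e@strand5[2]))
        expect_true(all(bp[, 2] >= e@strand3[1] & bp[, 2] <= e@strand3[2]))
        expect_true(e@strand5[2] < e@strand3[1])
      }
      # one pairing nucleotide per strand per pair, by construction;
      # opening and closing counts match
      expect_equal(length(unique(bp[, 1])), length(unique(bp[, 2])))
    }
  }
})

test_that("decomposition depends only on the pair table, not the sequence", {
  s <- randomNestedStructure(60, seed = 3)
  d1 <- decomposeStructure(s)
  d2 <- decomposeStructure(parseDotBracket(toDotBracket(s)))
  expect_equal(elementAssignment(d1), elementAssignment(d2))
})

test_that("findHairpins/findStems expose the same elements as decompose", {
  db <- "((..((...))..((...))..))"
  hp <- findHairpins(db)
  st <- findStems(db, hp)
  d <- decomposeStructure(db)
  expect_equal(lapply(hp, function(h) h@owned),
               lapply(hairpins(d), function(h) h@owned))
  expect_equal(lapply(st, function(s) s@memberPairs),
               lapply(stems(d), function(s) s@memberPairs))
})

test_that("element summaries tabulate spans and inconsistency fractions", {
  aln <- alignSequences("GGGAAACCA", "GGGAAACCC")
  im <- buildIntermediate("(((...)))", aln, "GGGAAACCA")
  d <- decomposeStructure(im)
  df <- elementSummary(d, im)
  expect_equal(nrow(df), 1L)
  expect_equal(df$type, "hairpin")
  expect_equal(df$inconsistentFraction, 2 / 9, tolerance = 1e-12)
})
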