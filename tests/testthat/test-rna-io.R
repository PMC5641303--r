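test_that("dot-bracket parsing matches brackets per tier and flags errors", {
  s <- parseDotBracket("(((...)))")
  expect_equal(length(s), 9L)
  expect_equal(unname(basePairs(s)),
               matrix(c(1L, 2L, 3L, 9L, 8L, 7L), ncol = 2))
  expect_equal(nrow(basePairs(parseDotBracket("........."))), 0L)
  # pseudoknot tiers
  pk <- parseDotBracket("((..[[..))..]]")
  expect_equal(nrow(basePairs(pk)), 4L)
  expect_error(parseDotBracket("(()"), "unclosed '\\(' at position 1")
  expect_error(parseDotBracket("())"), "unbalanced '\\)' at position 3")
  expect_error(parseDotBracket("(x)"), "invalid character")
})

test_that("serialization inverts parsing and rejects pseudoknots", {
  expect_equal(toDotBracket(parseDotBracket("((..(...)))")), "((..(...)))")
  expect_equal(toDotBracket(parseDotBracket("....")), "....")
  crossing <- new("SecondaryStructure", length = 4L,
                  basePairs = matrix(c(1L, 2L, 3L, 4L), ncol = 2,
                                     dimnames = list(NULL, c("i", "j"))))
  expect_error(toDotBracket(crossing), "removePseudoknots")
})

test_that("round-trip holds for random nested structures", {
  set.seed(42)
  for (k in 1:1000) {
    db <- toDotBracket(randomNestedStructure(sample(1:120, 1)))
    expect_identical(toDotBracket(parseDotBracket(db)), db)
  }
})

test_that("pseudoknot removal keeps a maximum crossing-free subset", {
  # already-nested input is unchanged
  s <- parseDotBracket("(((...)))")
  expect_equal(basePairs(removePseudoknots(s)), basePairs(s))
  # minimal crossing: tie broken toward the smaller opening index
  cr <- new("SecondaryStructure", length = 4L,
            basePairs = matrix(c(1L, 2L, 3L, 4L), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))))
  expect_equal(unname(basePairs(removePseudoknots(cr))),
               matrix(c(1L, 3L), ncol = 2))
  # two crossing helices of equal size: deterministic first-opening subset
  pk <- new("SecondaryStructure", length = 13L,
            basePairs = matrix(as.integer(c(1, 11, 2, 10, 3, 13, 4, 12)),
                               ncol = 2, byrow = TRUE,
                               dimnames = list(NULL, c("i", "j"))))
  expect_equal(unname(basePairs(removePseudoknots(pk))),
               matrix(c(1L, 2L, 11L, 10L), ncol = 2))
})

test_that("pseudoknot removal cardinality equals brute force on random input", {
  set.seed(7)
  for (k in 1:60) {
    n <- sample(10:30, 1)
    # random (possibly crossing) pair table with <= 8 pairs
    pos <- sample(n, 2L * sample(2:min(8L, n %/% 2L), 1))
    pairs <- matrix(pos, ncol = 2)
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
    pairs <- matrix(as.integer(pairs), ncol = 2)
    s <- new("SecondaryStructure", length = as.integer(n),
             basePairs = matrix(as.integer(pairs), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))))
    res <- removePseudoknots(s)
    ptr <- pairTable(res)
    # output is nested and of maximum cardinality
    expect_identical(toDotBracket(res), toDotBracket(res))  # serializable
    expect_equal(nrow(basePairs(res)), oracle_max_nested(pairs))
    # input unchanged
    expect_equal(nrow(basePairs(s)), nrow(pairs))
  }
})

test_that("FASTA reading normalizes to uppercase RNA", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acGT", ">y", "GGGAAACCC"), f)
  rs <- readRnaFasta(f)
  expect_equal(as.character(rs[["x"]]), "ACGU")
  expect_equal(as.character(rs[["y"]]), "GGGAAACCC")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACXG"), f2)
  expect_error(readRnaFasta(f2), "invalid characters")
})

test_that("Vienna records parse, validate lengths, and round-trip", {
  f <- withr::local_tempfile(fileext = ".vienna")
  writeLines(c(">x", "GGGAAACCC", "(((...)))"), f)
  rec <- readVienna(f)[[1]]
  expect_equal(rec$sequence, "GGGAAACCC")
  expect_equal(nrow(basePairs(rec$structure)), 3L)
  f2 <- withr::local_tempfile(fileext = ".vienna")
  writeLines(c(">x", "GGG", "(((...)))"), f2)
  expect_error(readVienna(f2), "length")
  out <- withr::local_tempfile(fileext = ".vienna")
  writeVienna(rec, out)
  expect_equal(readVienna(out)[[1]]$sequence, rec$sequence)
  expect_equal(toDotBracket(readVienna(out)[[1]]$structure), "(((...)))")
})

test_that("CT format reading reconstructs the pair table", {
  f <- withr::local_tempfile(fileext = ".ct")
  lines <- c("9 test",
             "1 G 0 2 9 1", "2 G 1 3 8 2", "3 G 2 4 7 3",
             "4 A 3 5 0 4", "5 A 4 6 0 5", "6 A 5 7 0 6",
             "7 C 6 8 3 7", "8 C 7 9 2 8", "9 C 8 0 1 9")
  writeLines(lines, f)
  rec <- readCt(f)
  expect_equal(rec$sequence, "GGGAAACCC")
  expect_equal(toDotBracket(rec$structure), "(((...)))")
})
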