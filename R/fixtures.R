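# Synthetic template/homolog generation for hermetic testing and
# benchmarking: random nested structures, sequences realizing them, and
# controlled divergence (substitutions, compensatory changes, indels).

.PAIR_TYPES <- matrix(c("A", "U", "U", "A", "G", "C", "C", "G", "G", "U",
                        "U", "G"), ncol = 2L, byrow = TRUE)

#' Random nested secondary structure
#'
#' Samples a random nested structure by a stochastic grammar over helices:
#' an interval is either opened by a stacked helix of at least two base
#' pairs (helix length 2 plus a geometric extension, emulating the stacked
#' stems of real RNA; isolated lonely pairs are never produced), prefixed
#' by an unpaired position, or split into two independent intervals
#' (producing multiloops). Hairpin loops have at least three unpaired
#' nucleotides. With the default branching probabilities roughly half of
#' the positions end up paired, in the range typical of structured RNAs.
#'
#' @param length number of positions (>= 1).
#' @param helixProb probability of opening a helix in an interval.
#' @param splitProb probability of splitting an interval in two.
#' @param helixExtension geometric parameter for helix length beyond 2.
#' @param seed optional RNG seed.
#' @return a nested [SecondaryStructure-class].
#' @examples
#' toDotBracket(randomNestedStructure(40, seed = 1))
#' @export
randomNestedStructure <- function(length, helixProb = 0.3,
                                  splitProb = 0.2, helixExtension = 0.5,
                                  seed = NULL) {
  stopifnot(length >= 1)
  gen <- function(len) {
    if (len < 7L) return(strrep(".", len))  # too short for a 2-bp helix
    u <- stats::runif(1)
    if (u < helixProb) {
      h <- min(2L + stats::rgeom(1L, helixExtension), (len - 3L) %/% 2L)
      paste0(strrep("(", h), gen(len - 2L * h), strrep(")", h))
    } else if (u < helixProb + splitProb && len >= 14L) {
      cut <- sample(7:(len - 7L), 1L)
      paste0(gen(cut), gen(len - cut))
    } else {
      paste0(".", gen(len - 1L))
    }
  }
  db <- .with_seed(seed, gen(as.integer(length)))
  parseDotBracket(db)
}

#' Random sequence realizing a structure
#'
#' Draws a sequence whose paired positions carry canonical pairs (pair type
#' uniform over A-U/U-A/G-C/C-G/G-U/U-G) and whose unpaired positions are
#' uniform random residues, so the structure can be transferred onto the
#' sequence without inconsistency.
#'
#' @param structure a nested [SecondaryStructure-class] or dot-bracket
#'   string.
#' @param seed optional RNG seed.
#' @return uppercase RNA character string.
#' @examples
#' makeTemplateSequence("(((...)))", seed = 7)
#' @export
makeTemplateSequence <- function(structure, seed = NULL) {
  s <- .as_ss(structure)
  .with_seed(seed, {
    ch <- sample(c("A", "C", "G", "U"), s@length, replace = TRUE)
    bp <- s@basePairs
    if (nrow(bp)) {
      type <- sample.int(nrow(.PAIR_TYPES), nrow(bp), replace = TRUE)
      ch[bp[, 1L]] <- .PAIR_TYPES[type, 1L]
      ch[bp[, 2L]] <- .PAIR_TYPES[type, 2L]
    }
    paste(ch, collapse = "")
  })
}

#' Mutate a template sequence into a synthetic homolog
#'
#' Applies per-position substitutions and indels to emulate evolutionary
#' divergence. A substitution hitting a paired position is, with probability
#' `compensatory`, a compensatory change: the position and its partner are
#' rewritten together with a fresh canonical pair type, so pairing is
#' preserved. Non-compensatory substitutions draw a random different
#' residue. Deletions are single positions extended geometrically
#' (p = 0.5) and never remove both members of one base pair; insertions add
#' random residues. The defaults (15% substitution, 80% compensatory, 2%
#' indel) produce homologs of the divergence range the method is intended
#' for.
#'
#' @param template the template sequence.
#' @param structure the template's nested structure (guides compensatory
#'   changes).
#' @param subRate per-position substitution probability.
#' @param indelRate per-position indel probability.
#' @param compensatory probability that a substitution at a paired position
#'   preserves a canonical pair.
#' @param seed optional RNG seed.
#' @return RNA character string of the diverged homolog.
#' @examples
#' tmpl <- makeTemplateSequence("(((...)))", seed = 1)
#' mutateHomolog(tmpl, "(((...)))", subRate = 0.3, seed = 2)
#' @export
mutateHomolog <- function(template, structure, subRate = 0.15,
                          indelRate = 0.02, compensatory = 0.8,
                          seed = NULL) {
  t <- .as_rna(template, "template")
  s <- .as_ss(structure)
  stopifnot(s@length == nchar(t), subRate >= 0, subRate <= 1,
            indelRate >= 0, indelRate <= 1, compensatory >= 0,
            compensatory <= 1)
  pt <- pairTable(s)
  .with_seed(seed, {
    ch <- .chars(t)
    n <- length(ch)
    bases <- c("A", "C", "G", "U")
    # substitutions (a compensatory hit rewrites both partners at once)
    hit <- which(stats::runif(n) < subRate)
    for (p in hit) {
      if (pt[p] > 0L && stats::runif(1) < compensatory) {
        type <- .PAIR_TYPES[sample.int(nrow(.PAIR_TYPES), 1L), ]
        ch[p] <- type[1L]
        ch[pt[p]] <- type[2L]
      } else {
        ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      }
    }
    # indels: geometric extension, half deletions / half insertions
    deleted <- logical(n)
    insertions <- vector("list", n + 1L)  # insertions[[p]] goes before p
    ind <- which(stats::runif(n) < indelRate)
    for (p in ind) {
      len <- 1L + stats::rgeom(1L, 0.5)
      if (stats::runif(1) < 0.5) {
        for (d in p:min(n, p + len - 1L)) {
          # never delete both members of one pair
          if (pt[d] > 0L && deleted[pt[d]]) next
          deleted[d] <- TRUE
        }
      } else {
        insertions[[p]] <- sample(bases, len, replace = TRUE)
      }
    }
    out <- character(0)
    for (p in seq_len(n)) {
      if (!is.null(insertions[[p]])) out <- c(out, insertions[[p]])
      if (!deleted[p]) out <- c(out, ch[p])
    }
    if (!is.null(insertions[[n + 1L]])) out <- c(out, insertions[[n + 1L]])
    if (!length(out)) out <- sample(bases, 1L)  # degenerate: keep length >= 1
    paste(out, collapse = "")
  })
}

#' Synthetic template/query fixture pair
#'
#' Convenience wrapper producing a full synthetic test case: a random nested
#' structure (or a supplied one), a template sequence realizing it, and a
#' diverged query.
#'
#' @param structure a nested structure or dot-bracket string; if `NULL` a
#'   random structure of `length` positions is drawn.
#' @param length structure length used when `structure` is `NULL`.
#' @param subRate,indelRate,compensatory divergence parameters, see
#'   [mutateHomolog()].
#' @param seed optional RNG seed governing all draws.
#' @return list with `structure` ([SecondaryStructure-class]), `template`
#'   and `query` (RNA strings).
#' @export
homologFixture <- function(structure = NULL, length = 80, subRate = 0.15,
                           indelRate = 0.02, compensatory = 0.8,
                           seed = NULL) {
  .with_seed(seed, {
    s <- if (is.null(structure)) randomNestedStructure(length)
         else .as_ss(structure)
    tmpl <- makeTemplateSequence(s)
    qry <- mutateHomolog(tmpl, s, subRate = subRate, indelRate = indelRate,
                         compensatory = compensatory)
    list(structure = s, template = tmpl, query = qry)
  })
}
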