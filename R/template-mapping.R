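# Mapping the template structure onto the query: the four-case table.

# 5x5 logical lookup over A,C,G,U,N: Watson-Crick + GU wobble; N never pairs
.CANON <- local({
  m <- matrix(FALSE, 5, 5, dimnames = list(c("A", "C", "G", "U", "N"),
                                           c("A", "C", "G", "U", "N")))
  m["A", "U"] <- m["U", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "U"] <- m["U", "G"] <- TRUE
  m
})

#' Is a base combination a canonical pair?
#'
#' Canonical means Watson-Crick (A-U, G-C) or the G-U wobble pair, the pair
#' set accepted by the thermodynamic folding engines downstream. `N` is
#' never canonical. Vectorized over both arguments.
#'
#' @param a,b residues (single characters from `A C G U N`).
#' @return logical vector.
#' @examples
#' isCanonicalPair(c("G", "G", "A"), c("C", "U", "G"))
#' @export
isCanonicalPair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(!a %in% rownames(.CANON)) || any(!b %in% rownames(.CANON)))
    stop("residues must be in {A, C, G, U, N}", call. = FALSE)
  .CANON[cbind(a, b)]
}

# fast path: pt_t = template pair table, qmap/tmap = position maps,
# qc = query residues (character vector)
.intermediate_core <- function(pt_t, qmap, tmap, qc) {
  nq <- length(qmap)
  case <- integer(nq)
  pt_q <- integer(nq)
  tq <- qmap                       # template image of each query position
  case[is.na(tq)] <- 1L
  mapped <- which(!is.na(tq))
  r <- pt_t[tq[mapped]]            # template partner (0 = unpaired)
  case[mapped[r == 0L]] <- 2L
  pairedq <- mapped[r > 0L]
  if (length(pairedq)) {
    qr <- tmap[r[r > 0L]]          # query image of the template partner
    bad <- is.na(qr)
    okpos <- pairedq[!bad]
    if (length(okpos)) {
      canon <- .CANON[cbind(qc[okpos], qc[qr[!bad]])]
      case[okpos[canon]] <- 4L
      pt_q[okpos[canon]] <- qr[!bad][canon]
      case[okpos[!canon]] <- 3L
    }
    case[pairedq[bad]] <- 3L
  }
  list(pt = pt_q, case = case, consistent = case %in% c(2L, 4L))
}

#' Map the template structure onto the query (intermediate structure)
#'
#' For each query position `p` with template image `A_q(p)` there are four
#' possibilities: (1) `A_q(p)` is a gap; (2) `A_q(p)` is unpaired in the
#' template; (3) `A_q(p)` is paired to a template position `r` but `A_t(r)`
#' is a gap, or the query residues at `p` and `A_t(r)` do not form a
#' canonical pair; (4) `A_q(p)` is paired to `r` and `(p, A_t(r))` is
#' canonical. Only case 4 yields a transferred pair; cases 1-3 leave `p`
#' unpaired. Cases 2 and 4 are consistent, cases 1 and 3 inconsistent. The
#' rule is applied independently per position, which makes case 3 symmetric
#' for the two ends of a failed pair automatically.
#'
#' @param templateStructure the template's [SecondaryStructure-class] (or
#'   dot-bracket string); must be nested and match the template sequence
#'   length in the alignment.
#' @param alignment a [TemplateAlignment-class] from [alignSequences()] or
#'   [alignmentFromGapped()].
#' @param query the query sequence.
#' @return an [IntermediateStructure-class].
#' @examples
#' aln <- alignSequences("GGGAAACCA", "GGGAAACCC")
#' im <- buildIntermediate("(((...)))", aln, "GGGAAACCA")
#' toDotBracket(im)
#' caseLabels(im)
#' @export
buildIntermediate <- function(templateStructure, alignment, query) {
  ts <- .as_ss(templateStructure)
  q <- .as_rna(query, "query")
  if (!is(alignment, "TemplateAlignment"))
    stop("alignment must be a TemplateAlignment", call. = FALSE)
  if (length(alignment@templateMap) != ts@length)
    stop("template structure length (", ts@length,
         ") does not match the aligned template length (",
         length(alignment@templateMap), ")", call. = FALSE)
  if (length(alignment@queryMap) != nchar(q))
    stop("query length does not match the aligned query", call. = FALSE)
  pt_t <- pairTable(ts)
  .stop_if_pseudoknotted(pt_t, "buildIntermediate")
  core <- .intermediate_core(pt_t, alignment@queryMap, alignment@templateMap,
                             .chars(q))
  bp <- matrix(as.integer(.pairs_from_pt(core$pt)), ncol = 2L,
               dimnames = list(NULL, c("i", "j")))
  new("IntermediateStructure", length = nchar(q), basePairs = bp,
      caseLabel = core$case, consistent = core$consistent)
}

#' Annotated dump of an intermediate structure
#'
#' Three-line debug rendering: sequence, dot-bracket, per-position case
#' digit.
#'
#' @param intermediate an [IntermediateStructure-class].
#' @param query the query sequence it was built on.
#' @return character vector of three lines (invisibly printed with `cat`).
#' @export
intermediateReport <- function(intermediate, query) {
  q <- .as_rna(query, "query")
  lines <- c(q, toDotBracket(intermediate),
             paste(intermediate@caseLabel, collapse = ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
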