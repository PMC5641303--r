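# Decomposition of a nested structure into elementary elements.
#
# Hairpins first: a hairpin is seeded at a loop-closing pair (only unpaired
# nucleotides between its ends) and grown outward through every enclosing
# pair that closes only that loop (so stacked runs, bulges and internal
# loops are absorbed); growth stops at a pair that would also enclose a
# different hairpin, i.e. at a multiloop junction. Unpaired runs adjacent to
# a hairpin are attached to it; a run lying between two hairpins is split at
# its midpoint, the left half (including the middle position when the run
# length is odd) going to the upstream hairpin, so no position is shared.
#
# Stems then claim the remaining pairs: maximal chains of nested pairs
# between junctions, processed outermost-first. A stem's strands are the
# position ranges of its opening and closing pair positions; unlike
# hairpins, stems take no single-strand flanks. Whatever remains (dangling
# ends, multiloop cores adjacent to stems) is unassigned single strand.

.decompose_core <- function(pt) {
  n <- length(pt)
  empty <- list(hairpins = list(), stems = list(),
                assignment = rep(NA_integer_, n))
  op <- which(pt > seq_len(n))
  if (!length(op)) return(empty)
  pr <- cbind(op, pt[op])  # pairs sorted by opening position
  np <- nrow(pr)
  isloop <- vapply(seq_len(np), function(k) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    j - i == 1L || all(pt[(i + 1L):(j - 1L)] == 0L)
  }, logical(1))
  loops <- pr[isloop, , drop = FALSE]
  encl <- vapply(seq_len(np), function(k)
    sum(loops[, 1L] >= pr[k, 1L] & loops[, 2L] <= pr[k, 2L]), integer(1))

  # ---- hairpins: pairs enclosing exactly one loop, grouped by that loop
  hpix <- which(encl == 1L)
  loopid <- vapply(hpix, function(k)
    which(loops[, 1L] >= pr[k, 1L] & loops[, 2L] <= pr[k, 2L]), integer(1))
  hairpins <- lapply(seq_len(nrow(loops)), function(l) {
    mem <- hpix[loopid == l]
    core <- c(min(pr[mem, 1L]), max(pr[mem, 2L]))
    list(type = "hairpin", pairs = pr[mem, , drop = FALSE],
         core = core, owned = seq.int(core[1L], core[2L]))
  })
  # order by 5' start
  hairpins <- hairpins[order(vapply(hairpins, function(h) h$core[1L],
                                    integer(1)))]
  incore <- logical(n)
  for (h in hairpins) incore[h$owned] <- TRUE
  corestart <- vapply(hairpins, function(h) h$core[1L], integer(1))
  coreend <- vapply(hairpins, function(h) h$core[2L], integer(1))

  # ---- attach unpaired runs adjacent to hairpins
  free <- pt == 0L & !incore
  rl <- rle(free)
  stops <- cumsum(rl$lengths)
  starts <- stops - rl$lengths + 1L
  for (r in which(rl$values)) {
    a <- starts[r]; b <- stops[r]
    leftH <- if (a > 1L) match(a - 1L, coreend) else NA_integer_
    rightH <- if (b < n) match(b + 1L, corestart) else NA_integer_
    len <- b - a + 1L
    if (!is.na(leftH) && !is.na(rightH)) {
      nleft <- as.integer(ceiling(len / 2))
      hairpins[[leftH]]$owned <- c(hairpins[[leftH]]$owned,
                                   seq.int(a, a + nleft - 1L))
      if (nleft < len)
        hairpins[[rightH]]$owned <- c(seq.int(a + nleft, b),
                                      hairpins[[rightH]]$owned)
    } else if (!is.na(leftH)) {
      hairpins[[leftH]]$owned <- c(hairpins[[leftH]]$owned, seq.int(a, b))
    } else if (!is.na(rightH)) {
      hairpins[[rightH]]$owned <- c(seq.int(a, b), hairpins[[rightH]]$owned)
    }
  }
  hairpins <- lapply(hairpins, function(h) {
    h$owned <- sort(h$owned)
    h$strand5 <- c(min(h$owned), max(h$owned))
    h$strand3 <- c(NA_integer_, NA_integer_)
    h$core <- NULL
    h
  })

  # ---- stems: chains of the remaining pairs between junctions
  stemix <- which(encl >= 2L)
  stems <- list()
  if (length(stemix)) {
    # direct parent pair of every pair, via a scan with an open-pair stack
    parent <- integer(np)
    stack <- integer(0)
    kbyopen <- integer(n)
    kbyopen[pr[, 1L]] <- seq_len(np)
    for (p in seq_len(n)) {
      q <- pt[p]
      if (q > p) {
        k <- kbyopen[p]
        parent[k] <- if (length(stack)) stack[length(stack)] else 0L
        stack <- c(stack, k)
      } else if (q > 0L && q < p) {
        stack <- stack[-length(stack)]
      }
    }
    nchildren <- tabulate(parent[parent > 0L], np)
    isstem <- logical(np)
    isstem[stemix] <- TRUE
    stemid <- integer(np)
    nextid <- 0L
    for (k in stemix) {  # ascending opening position = outermost first
      pk <- parent[k]
      if (pk == 0L || !isstem[pk] || nchildren[pk] >= 2L) {
        nextid <- nextid + 1L
        stemid[k] <- nextid
      } else {
        stemid[k] <- stemid[pk]
      }
    }
    stems <- lapply(seq_len(nextid), function(sid) {
      mem <- which(stemid == sid)
      s5 <- c(min(pr[mem, 1L]), max(pr[mem, 1L]))
      s3 <- c(min(pr[mem, 2L]), max(pr[mem, 2L]))
      list(type = "stem", pairs = pr[mem, , drop = FALSE],
           owned = c(seq.int(s5[1L], s5[2L]), seq.int(s3[1L], s3[2L])),
           strand5 = s5, strand3 = s3)
    })
  }

  assignment <- rep(NA_integer_, n)
  for (k in seq_along(hairpins)) assignment[hairpins[[k]]$owned] <- k
  nh <- length(hairpins)
  for (k in seq_along(stems)) assignment[stems[[k]]$owned] <- nh + k
  list(hairpins = hairpins, stems = stems, assignment = assignment)
}

.element_to_s4 <- function(el) {
  new("StructureElement", type = el$type,
      memberPairs = matrix(as.integer(el$pairs), ncol = 2L,
                           dimnames = list(NULL, c("i", "j"))),
      owned = as.integer(el$owned), strand5 = as.integer(el$strand5),
      strand3 = as.integer(el$strand3))
}

#' Identify the hairpins of a nested structure
#'
#' @param s a [SecondaryStructure-class] or dot-bracket string (nested).
#' @return list of [StructureElement-class] of type `"hairpin"`, ordered
#'   5' to 3'.
#' @examples
#' findHairpins("((..((...))..((...))..))")
#' @export
findHairpins <- function(s) {
  s <- .as_ss(s)
  pt <- pairTable(s)
  .stop_if_pseudoknotted(pt, "findHairpins")
  lapply(.decompose_core(pt)$hairpins, .element_to_s4)
}

#' Identify the stems of a nested structure
#'
#' Stems claim the base pairs not consumed by hairpins, processed
#' outermost-first; they take no single-strand flanks.
#'
#' @param s a [SecondaryStructure-class] or dot-bracket string (nested).
#' @param hairpins the hairpin list from [findHairpins()] (accepted for
#'   interface symmetry; the decomposition is recomputed from `s`).
#' @return list of [StructureElement-class] of type `"stem"`.
#' @export
findStems <- function(s, hairpins = findHairpins(s)) {
  s <- .as_ss(s)
  pt <- pairTable(s)
  .stop_if_pseudoknotted(pt, "findStems")
  lapply(.decompose_core(pt)$stems, .element_to_s4)
}

#' Decompose a structure into hairpins and stems
#'
#' @param s a [SecondaryStructure-class] or dot-bracket string (nested).
#' @return a [StructureDecomposition-class]. Every paired position belongs
#'   to exactly one element; unpaired positions outside hairpin
#'   neighbourhoods and stem strands are unassigned single strand.
#' @examples
#' decomposeStructure("((..((...))..((...))..))")
#' @export
decomposeStructure <- function(s) {
  s <- .as_ss(s)
  pt <- pairTable(s)
  .stop_if_pseudoknotted(pt, "decomposeStructure")
  core <- .decompose_core(pt)
  new("StructureDecomposition", length = s@length,
      hairpins = lapply(core$hairpins, .element_to_s4),
      stems = lapply(core$stems, .element_to_s4),
      assignment = core$assignment)
}

#' Per-element summary table of a decomposition
#'
#' @param d a [StructureDecomposition-class].
#' @param intermediate optionally, the [IntermediateStructure-class] the
#'   decomposition came from; adds the inconsistent-position fraction.
#' @return a `data.frame` with one row per element (type, spans, pair count,
#'   owned positions, and inconsistency fraction when available).
#' @export
elementSummary <- function(d, intermediate = NULL) {
  els <- c(d@hairpins, d@stems)
  df <- data.frame(
    element = seq_along(els),
    type = vapply(els, function(e) e@type, character(1)),
    start5 = vapply(els, function(e) e@strand5[1L], integer(1)),
    end5 = vapply(els, function(e) e@strand5[2L], integer(1)),
    start3 = vapply(els, function(e) e@strand3[1L], integer(1)),
    end3 = vapply(els, function(e) e@strand3[2L], integer(1)),
    nPairs = vapply(els, function(e) nrow(e@memberPairs), integer(1)),
    nOwned = vapply(els, function(e) length(e@owned), integer(1)))
  if (!is.null(intermediate)) {
    cons <- intermediate@consistent
    df$inconsistentFraction <- vapply(els, function(e)
      sum(!cons[e@owned]) / length(e@owned), numeric(1))
  }
  df
}
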