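# Dinucleotide-preserving sequence shuffling (Altschul-Erickson).

# one shuffle of the character vector ch, using the current RNG stream
.dinuc_shuffle_once <- function(ch) {
  L <- length(ch)
  last <- ch[L]
  verts <- unique(ch)
  # out-edge multisets of the dinucleotide (de Bruijn-like) multigraph
  edges <- split(ch[-1L], factor(ch[-L], levels = verts))
  nonterm <- setdiff(names(which(lengths(edges) > 0L)), last)
  # choose a trailing edge for every non-terminal vertex until the chosen
  # edges form an arborescence directed toward the end vertex
  repeat {
    trailing <- vapply(nonterm, function(v) {
      e <- edges[[v]]
      e[[sample.int(length(e), 1L)]]
    }, character(1))
    ok <- TRUE
    for (v in nonterm) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !cur %in% nonterm) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- trailing[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining edges; trailing edge goes last
  ordered <- edges
  for (v in names(edges)) {
    e <- edges[[v]]
    if (!length(e)) next
    if (v %in% nonterm) {
      drop1 <- match(trailing[[v]], e)
      rest <- e[-drop1]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[v]] <- c(rest, trailing[[v]])
    } else if (length(e) > 1L) {
      ordered[[v]] <- e[sample.int(length(e))]
    }
  }
  # walk the Eulerian path from the first residue
  out <- character(L)
  out[1L] <- ch[1L]
  cursor <- structure(rep(1L, length(ordered)), names = names(ordered))
  cur <- ch[1L]
  for (k in 2:L) {
    i <- cursor[[cur]]
    out[k] <- ordered[[cur]][i]
    cursor[[cur]] <- i + 1L
    cur <- out[k]
  }
  out
}

#' Dinucleotide-preserving shuffle of an RNA sequence
#'
#' Generates random sequences with exactly the dinucleotide multiset (and
#' hence length and mononucleotide composition) of the input, by sampling
#' Eulerian paths in the dinucleotide transition multigraph
#' (Altschul-Erickson). The first and last residues are preserved by
#' construction.
#'
#' @param seq sequence of length >= 2 (character or `RNAString`).
#' @param n number of shuffled sequences to draw.
#' @param seed optional seed; the caller's RNG state is restored afterwards.
#' @return character vector of `n` shuffled sequences.
#' @examples
#' dinucleotideShuffle("GCAUGCAU", n = 3, seed = 1)
#' @export
dinucleotideShuffle <- function(seq, n = 1L, seed = NULL) {
  s <- .as_rna(seq, "seq")
  if (nchar(s) < 2L)
    stop("sequence must have length >= 2", call. = FALSE)
  ch <- .chars(s)
  .with_seed(seed, vapply(seq_len(n), function(k)
    paste(.dinuc_shuffle_once(ch), collapse = ""), character(1)))
}
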