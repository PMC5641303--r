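# Tree edit distance between secondary structures.

#' Structure tree of a nested secondary structure
#'
#' Full-representation rooted ordered tree: a virtual root (`R`), one
#' internal node per base pair (`P`) whose children are the enclosed pairs
#' and unpaired positions in 5'->3' order, and one leaf per unpaired
#' position (`U`). The node count is `#pairs + #unpaired + 1` and an
#' in-order traversal reconstructs the dot-bracket string.
#'
#' @param s a [SecondaryStructure-class] or dot-bracket string (nested).
#' @return nested list; each node is `list(label, children)`.
#' @examples
#' str(structureTree("(.)"), max.level = 3)
#' @export
structureTree <- function(s) {
  s <- .as_ss(s)
  pt <- pairTable(s)
  .stop_if_pseudoknotted(pt, "structureTree")
  walk <- function(i, j) {
    children <- list()
    p <- i
    while (p <= j) {
      if (pt[p] == 0L) {
        children[[length(children) + 1L]] <- list(label = "U",
                                                  children = list())
        p <- p + 1L
      } else {
        q <- pt[p]
        children[[length(children) + 1L]] <-
          list(label = "P", children = walk(p + 1L, q - 1L))
        p <- q + 1L
      }
    }
    children
  }
  list(label = "R", children = if (s@length) walk(1L, s@length) else list())
}

#' Tree edit distance between two secondary structures
#'
#' Ordered-tree edit distance (node relabel, insert, delete; unit costs)
#' between the full-representation structure trees of `a` and `b`, computed
#' with the Zhang-Shasha algorithm. Distances are raw integers; they are not
#' normalized by structure size, so comparisons are meaningful between
#' structures of similar length. Zero means structural identity.
#'
#' @param a,b [SecondaryStructure-class] objects or dot-bracket strings
#'   (both nested).
#' @return non-negative integer.
#' @examples
#' treeEditDistance("(...)", ".....")
#' @export
treeEditDistance <- function(a, b) {
  a <- .as_ss(a)
  b <- .as_ss(b)
  pta <- pairTable(a)
  ptb <- pairTable(b)
  .stop_if_pseudoknotted(pta, "treeEditDistance")
  .stop_if_pseudoknotted(ptb, "treeEditDistance")
  .tree_edit_distance_pt(pta, ptb)
}
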