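# Scoring generated structures against references, and the pairwise
# cross-validation protocol.

#' Percent of positions with correctly predicted structural information
#'
#' A position is counted correct when its pairing status matches the
#' reference and, if paired, the partner position matches too; 100 therefore
#' holds exactly for identical structures (equivalently, tree edit distance
#' zero). Both structures must live on the same sequence (equal lengths).
#'
#' @param predicted,reference [SecondaryStructure-class] objects or
#'   dot-bracket strings of equal length.
#' @return percentage in `[0, 100]`.
#' @examples
#' percentCorrect("(...)", ".....")
#' @export
percentCorrect <- function(predicted, reference) {
  p <- .as_ss(predicted)
  r <- .as_ss(reference)
  if (p@length != r@length)
    stop("structures have different lengths (", p@length, " vs ", r@length,
         ")", call. = FALSE)
  100 * mean(pairTable(p) == pairTable(r))
}

#' Pairwise cross-validation within a family of solved structures
#'
#' For every ordered pair (template, query) of distinct family members,
#' generates the query structure from the template and scores it against the
#' query's experimentally determined structure with both metrics (tree edit
#' distance and percent of correct positions). Optionally runs the
#' reliability bootstrap per prediction.
#'
#' @param family list of members, each a list with `id`, `sequence` and
#'   `structure` (as returned by [readVienna()] or [readCt()]); at least two
#'   members.
#' @param engine a [FoldingEngine-class].
#' @param hairpinThreshold,stemThreshold element inconsistency thresholds.
#' @param bootstrapN if > 0, run [bootstrapStructure()] with this many
#'   shuffles per prediction and add `zD` and `reliable` columns.
#' @param seed optional seed for the bootstrap.
#' @return `data.frame` with one row per ordered (query, template) pair:
#'   ids, `treeEditDistance`, `percentCorrect`, and bootstrap columns when
#'   requested.
#' @export
crossValidate <- function(family, engine = nussinovEngine(),
                          hairpinThreshold = 0.2, stemThreshold = 0.1,
                          bootstrapN = 0L, seed = NULL) {
  if (length(family) < 2L) {
    warning("family has fewer than 2 members; skipped")
    return(data.frame(query = character(0), template = character(0),
                      treeEditDistance = integer(0),
                      percentCorrect = numeric(0)))
  }
  idx <- expand.grid(q = seq_along(family), t = seq_along(family))
  idx <- idx[idx$q != idx$t, , drop = FALSE]
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    qm <- family[[idx$q[r]]]
    tm <- family[[idx$t[r]]]
    gen <- generateStructure(qm$sequence, tm$sequence, tm$structure,
                             engine = engine,
                             hairpinThreshold = hairpinThreshold,
                             stemThreshold = stemThreshold)
    ref <- .as_ss(qm$structure)
    if (!.is_nested_pt(pairTable(ref))) ref <- removePseudoknots(ref)
    out <- data.frame(
      query = qm$id, template = tm$id,
      treeEditDistance = treeEditDistance(finalStructure(gen), ref),
      percentCorrect = percentCorrect(finalStructure(gen), ref))
    if (bootstrapN > 0L) {
      bs <- bootstrapStructure(qm$sequence, tm$sequence, tm$structure,
                               engine = engine, N = bootstrapN, seed = seed,
                               hairpinThreshold = hairpinThreshold,
                               stemThreshold = stemThreshold)
      out$zD <- bs@zD
      out$reliable <- bs@reliable
    }
    out
  })
  do.call(rbind, rows)
}
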