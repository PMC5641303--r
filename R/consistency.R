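# Element-level consistency calls.

.classify_core <- function(elements, consistent, hairpinThreshold,
                           stemThreshold) {
  vapply(elements, function(el) {
    stopifnot(length(el$owned) > 0L)
    frac <- sum(!consistent[el$owned]) / length(el$owned)
    th <- if (el$type == "hairpin") hairpinThreshold else stemThreshold
    if (frac > th) "inconsistent" else "consistent"
  }, character(1))
}

#' Classify structure elements as consistent or inconsistent
#'
#' An element is inconsistent when the fraction of mapping-inconsistent
#' positions among the positions it owns (paired members plus attached
#' unpaired positions) is strictly greater than the threshold for its type.
#' The default thresholds are 20% for hairpins and 10% for stems; "over" is
#' strict, so an element sitting exactly at the threshold is consistent.
#'
#' @param decomposition a [StructureDecomposition-class] computed from
#'   `intermediate`.
#' @param intermediate the [IntermediateStructure-class] carrying the
#'   per-position consistency flags.
#' @param hairpinThreshold,stemThreshold maximum tolerated inconsistent
#'   fraction per element type, in `[0, 1]`.
#' @return character vector (`"consistent"`/`"inconsistent"`), one entry per
#'   element of `c(hairpins(decomposition), stems(decomposition))`.
#' @export
classifyElements <- function(decomposition, intermediate,
                             hairpinThreshold = 0.2, stemThreshold = 0.1) {
  stopifnot(is(decomposition, "StructureDecomposition"),
            is(intermediate, "IntermediateStructure"),
            hairpinThreshold >= 0, hairpinThreshold <= 1,
            stemThreshold >= 0, stemThreshold <= 1)
  if (decomposition@length != intermediate@length)
    stop("decomposition and intermediate structure lengths differ",
         call. = FALSE)
  els <- lapply(c(decomposition@hairpins, decomposition@stems), function(e)
    list(type = e@type, owned = e@owned))
  .classify_core(els, intermediate@consistent, hairpinThreshold,
                 stemThreshold)
}
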