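#' @describeIn SecondaryStructure-class base pairs as a two-column integer
#'   matrix (1-based, i < j).
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@basePairs)

#' @describeIn SecondaryStructure-class partner lookup vector: entry `p` is
#'   the partner of position `p`, or 0 if unpaired.
#' @export
setMethod("pairTable", "SecondaryStructure",
  function(x) .pt_from_pairs(x@basePairs, x@length))

#' @describeIn SecondaryStructure-class number of positions.
#' @param x a `SecondaryStructure`.
#' @export
setMethod("length", "SecondaryStructure", function(x) x@length)

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure of length", object@length, "with",
      nrow(object@basePairs), "base pairs\n")
  if (.is_nested_pt(pairTable(object))) {
    db <- toDotBracket(object)
    if (nchar(db) > 70) db <- paste0(substr(db, 1, 67), "...")
    cat(" ", db, "\n")
  } else {
    cat("  (pseudoknotted)\n")
  }
})

setMethod("show", "IntermediateStructure", function(object) {
  callNextMethod()
  tb <- table(factor(object@caseLabel, levels = 1:4))
  cat("  mapping cases 1-4:", paste(tb, collapse = "/"),
      sprintf(" (%d/%d positions consistent)\n",
              sum(object@consistent), object@length))
})

#' @describeIn IntermediateStructure-class per-position mapping case (1-4).
#' @export
setMethod("caseLabels", "IntermediateStructure", function(x) x@caseLabel)

#' @describeIn IntermediateStructure-class per-position consistency flag.
#' @export
setMethod("consistentPositions", "IntermediateStructure",
  function(x) x@consistent)

#' @describeIn TemplateAlignment-class query -> template position map.
#' @export
setMethod("queryMap", "TemplateAlignment", function(x) x@queryMap)

#' @describeIn TemplateAlignment-class template -> query position map.
#' @export
setMethod("templateMap", "TemplateAlignment", function(x) x@templateMap)

#' @describeIn TemplateAlignment-class gapped query string.
#' @export
setMethod("alignedQuery", "TemplateAlignment", function(x) x@alignedQuery)

#' @describeIn TemplateAlignment-class gapped template string.
#' @export
setMethod("alignedTemplate", "TemplateAlignment",
  function(x) x@alignedTemplate)

setMethod("show", "TemplateAlignment", function(object) {
  cat("TemplateAlignment (", sum(!is.na(object@queryMap)), "aligned columns",
      if (!is.na(object@score)) sprintf(", score %.2f", object@score), ")\n")
  trunc <- function(s) if (nchar(s) > 70) paste0(substr(s, 1, 67), "...") else s
  cat("  query:   ", trunc(object@alignedQuery), "\n")
  cat("  template:", trunc(object@alignedTemplate), "\n")
})

#' @describeIn StructureDecomposition-class list of hairpin elements.
#' @export
setMethod("hairpins", "StructureDecomposition", function(x) x@hairpins)

#' @describeIn StructureDecomposition-class list of stem elements.
#' @export
setMethod("stems", "StructureDecomposition", function(x) x@stems)

#' @describeIn StructureDecomposition-class per-position owning element
#'   index into `c(hairpins(x), stems(x))`, NA when unassigned.
#' @export
setMethod("elementAssignment", "StructureDecomposition",
  function(x) x@assignment)

setMethod("show", "StructureDecomposition", function(object) {
  cat("StructureDecomposition:", length(object@hairpins), "hairpin(s),",
      length(object@stems), "stem(s),",
      sum(is.na(object@assignment)), "unassigned position(s)\n")
})

setMethod("show", "StructureElement", function(object) {
  if (object@type == "hairpin") {
    cat(sprintf("Hairpin [%d-%d], %d base pair(s)\n", object@strand5[1L],
                object@strand5[2L], nrow(object@memberPairs)))
  } else {
    cat(sprintf("Stem 5'[%d-%d] / 3'[%d-%d], %d base pair(s)\n",
                object@strand5[1L], object@strand5[2L], object@strand3[1L],
                object@strand3[2L], nrow(object@memberPairs)))
  }
})

#' @describeIn GeneratedStructure-class per-position provenance.
#' @export
setMethod("provenance", "GeneratedStructure", function(x) x@provenance)

#' @describeIn GeneratedStructure-class the assembled structure.
#' @export
setMethod("finalStructure", "GeneratedStructure", function(x) x@structure)

setMethod("show", "GeneratedStructure", function(object) {
  cat("GeneratedStructure on a query of length", object@structure@length,
      "\n")
  db <- toDotBracket(object@structure)
  if (nchar(db) > 70) db <- paste0(substr(db, 1, 67), "...")
  cat(" ", db, "\n")
  tb <- table(factor(object@provenance,
                     levels = c("template-transfer", "de-novo",
                                "single-strand")))
  cat(sprintf("  %d transferred / %d de novo / %d single-strand positions\n",
              tb[1L], tb[2L], tb[3L]))
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult (N =", object@N, "shuffles)\n")
  cat(sprintf("  d_gen = %g, null %.2f +/- %.2f  =>  z_d = %s\n", object@dGen,
              mean(object@dRnd), stats::sd(object@dRnd),
              format(object@zD, digits = 3)))
  cat(sprintf("  e_gen = %g, null %.2f +/- %.2f  =>  z_e = %s\n", object@eGen,
              mean(object@eRnd), stats::sd(object@eRnd),
              format(object@zE, digits = 3)))
  cat("  reliable:", object@reliable,
      if (object@degenerate) "(degenerate null)" else "", "\n")
})
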