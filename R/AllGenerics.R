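#' @rdname SecondaryStructure-class
#' @param x an object.
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname IntermediateStructure-class
#' @param x an object.
#' @export
setGeneric("caseLabels", function(x) standardGeneric("caseLabels"))

#' @rdname IntermediateStructure-class
#' @export
setGeneric("consistentPositions",
  function(x) standardGeneric("consistentPositions"))

#' @rdname TemplateAlignment-class
#' @param x an object.
#' @export
setGeneric("queryMap", function(x) standardGeneric("queryMap"))

#' @rdname TemplateAlignment-class
#' @export
setGeneric("templateMap", function(x) standardGeneric("templateMap"))

#' @rdname TemplateAlignment-class
#' @export
setGeneric("alignedQuery", function(x) standardGeneric("alignedQuery"))

#' @rdname TemplateAlignment-class
#' @export
setGeneric("alignedTemplate", function(x) standardGeneric("alignedTemplate"))

#' @rdname StructureDecomposition-class
#' @param x an object.
#' @export
setGeneric("hairpins", function(x) standardGeneric("hairpins"))

#' @rdname StructureDecomposition-class
#' @export
setGeneric("stems", function(x) standardGeneric("stems"))

#' @rdname StructureDecomposition-class
#' @export
setGeneric("elementAssignment",
  function(x) standardGeneric("elementAssignment"))

#' @rdname GeneratedStructure-class
#' @param x an object.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname GeneratedStructure-class
#' @export
setGeneric("finalStructure", function(x) standardGeneric("finalStructure"))

#' Fold a single contiguous RNA subsequence
#'
#' @param engine a [FoldingEngine-class].
#' @param seq RNA sequence (character or `RNAString`).
#' @return list with `pairTable` (integer vector, 0 = unpaired) and `energy`
#'   (kcal/mol).
#' @export
setGeneric("foldSingle", function(engine, seq) standardGeneric("foldSingle"))

#' Predict inter-strand pairs between the two strands of a stem
#'
#' @param engine a [FoldingEngine-class].
#' @param seq5,seq3 the 5' and 3' strand sequences (both 5'->3').
#' @return list with `pairs` (integer matrix: position in `seq5`, position in
#'   `seq3`) and `energy`.
#' @export
setGeneric("foldDuplex",
  function(engine, seq5, seq3) standardGeneric("foldDuplex"))

#' Evaluate the free energy of a sequence/structure pair
#'
#' @param engine a [FoldingEngine-class].
#' @param seq RNA sequence.
#' @param structure a [SecondaryStructure-class] or dot-bracket string.
#' @return numeric(1), free energy in kcal/mol.
#' @export
setGeneric("foldEnergy",
  function(engine, seq, structure) standardGeneric("foldEnergy"))
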