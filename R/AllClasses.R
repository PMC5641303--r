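#' @import methods
NULL

#' Secondary structure as a pair table
#'
#' The universal structure representation of the package: a set of base pairs
#' (i, j), i < j, 1-based, over a sequence of a given length, with every
#' position in at most one pair. Pseudoknotted (crossing) pair sets are legal
#' in this container; most downstream operations require a nested structure,
#' obtainable with [removePseudoknots()].
#'
#' @slot length integer(1), number of positions.
#' @slot basePairs integer matrix with two columns (`i`, `j`), one row per
#'   base pair, ordered by opening position.
#' @export
setClass("SecondaryStructure",
  slots = c(length = "integer", basePairs = "matrix"))

setValidity("SecondaryStructure", function(object) {
  n <- object@length
  bp <- object@basePairs
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("length must be a single non-negative integer")
  if (!is.matrix(bp) || ncol(bp) != 2L || !is.integer(bp))
    return("basePairs must be an integer matrix with 2 columns")
  if (nrow(bp) > 0L) {
    if (any(is.na(bp))) return("basePairs contains NA")
    if (any(bp < 1L) || any(bp > n)) return("base pair position out of range")
    if (any(bp[, 1L] >= bp[, 2L])) return("base pairs must have i < j")
    if (anyDuplicated(as.vector(bp)))
      return("a position participates in more than one base pair")
  }
  TRUE
})

#' Pairwise query/template alignment with position maps
#'
#' Holds a global pairwise alignment between a query and a template sequence
#' together with the two position maps derived from it: `queryMap` sends each
#' query position to its template position (NA at gap columns) and
#' `templateMap` is the reverse map. The two maps are mutually inverse
#' wherever both are defined.
#'
#' @slot alignedQuery,alignedTemplate gapped sequence strings of equal length.
#' @slot queryMap integer vector, one entry per query position.
#' @slot templateMap integer vector, one entry per template position.
#' @slot score numeric(1), alignment score (NA for user-supplied alignments).
#' @export
setClass("TemplateAlignment",
  slots = c(alignedQuery = "character", alignedTemplate = "character",
            queryMap = "integer", templateMap = "integer", score = "numeric"))

setValidity("TemplateAlignment", function(object) {
  if (nchar(object@alignedQuery) != nchar(object@alignedTemplate))
    return("aligned strings differ in length")
  qm <- object@queryMap; tm <- object@templateMap
  def <- which(!is.na(qm))
  if (any(tm[qm[def]] != def))
    return("queryMap and templateMap are not mutually inverse")
  TRUE
})

#' Template structure mapped onto the query
#'
#' A [SecondaryStructure-class] on the query sequence annotated, per position,
#' with the mapping case (1: query position aligned to a gap; 2: aligned to an
#' unpaired template position; 3: aligned to a paired template position whose
#' partner maps to a gap or yields a non-canonical pair; 4: pair transferred)
#' and the derived consistency flag (cases 2 and 4 are consistent). Only
#' case-4 positions are paired; no pair is invented at this stage.
#'
#' @slot caseLabel integer vector in 1..4, one per query position.
#' @slot consistent logical vector, one per query position.
#' @export
setClass("IntermediateStructure", contains = "SecondaryStructure",
  slots = c(caseLabel = "integer", consistent = "logical"))

setValidity("IntermediateStructure", function(object) {
  n <- object@length
  if (length(object@caseLabel) != n || length(object@consistent) != n)
    return("annotation length does not match structure length")
  if (any(!object@caseLabel %in% 1:4)) return("caseLabel outside 1..4")
  paired <- logical(n)
  paired[as.vector(object@basePairs)] <- TRUE
  if (any(paired != (object@caseLabel == 4L)))
    return("a position is paired iff its case label is 4")
  if (any(object@consistent != (object@caseLabel %in% c(2L, 4L))))
    return("consistent flag must equal caseLabel in {2,4}")
  TRUE
})

#' An elementary structure element: hairpin or stem
#'
#' Hairpins are seeded at a loop-closing pair (only unpaired nucleotides
#' between its ends) and extended outward while the enclosing pair still
#' closes only that hairpin; interior unpaired positions and adjacent
#' single-strand runs belong to the hairpin. Stems are chains of the
#' remaining pairs between multiloop junctions; their two strands contain
#' the same number of pairing nucleotides and take no single-strand flanks.
#'
#' @slot type `"hairpin"` or `"stem"`.
#' @slot memberPairs integer matrix of the element's base pairs.
#' @slot owned integer vector of all positions owned by the element.
#' @slot strand5,strand3 integer(2) position ranges of the 5' and 3' strands
#'   (for a hairpin, `strand5` is the whole span and `strand3` is `NA`).
#' @export
setClass("StructureElement",
  slots = c(type = "character", memberPairs = "matrix", owned = "integer",
            strand5 = "integer", strand3 = "integer"))

#' Decomposition of a structure into hairpins and stems
#'
#' @slot length integer(1), structure length.
#' @slot hairpins,stems lists of [StructureElement-class].
#' @slot assignment integer vector mapping each position to the owning
#'   element's index in `c(hairpins, stems)`, NA for unassigned single-strand
#'   positions.
#' @export
setClass("StructureDecomposition",
  slots = c(length = "integer", hairpins = "list", stems = "list",
            assignment = "integer"))

#' Generated (final) structure with provenance
#'
#' @slot structure the assembled [SecondaryStructure-class] on the query.
#' @slot provenance per position, one of `"template-transfer"`, `"de-novo"`,
#'   `"single-strand"`.
#' @slot query the query sequence (uppercase RNA string).
#' @slot intermediate the [IntermediateStructure-class] the assembly started
#'   from.
#' @slot decomposition the element decomposition used.
#' @slot elementLabels `"consistent"`/`"inconsistent"` per element.
#' @export
setClass("GeneratedStructure",
  slots = c(structure = "SecondaryStructure", provenance = "character",
            query = "character", intermediate = "IntermediateStructure",
            decomposition = "StructureDecomposition",
            elementLabels = "character"))

#' Bootstrap reliability result
#'
#' Null distributions of tree edit distance and free energy obtained from
#' dinucleotide-shuffled copies of the query, and the resulting z-scores.
#' The sign convention is "better than the null is positive":
#' `z = (mean(null) - observed) / sd(null)` for both metrics, so that a
#' generated structure close to the template (small distance, low energy)
#' scores high. `reliable` is `zD >= 2` on the distance metric.
#'
#' @slot dGen,eGen observed tree edit distance to the template / free energy.
#' @slot dRnd,eRnd numeric vectors of length N (the null samples).
#' @slot zD,zE z-scores (NA when the null sample is degenerate).
#' @slot reliable logical(1).
#' @slot degenerate logical(1), TRUE when a null standard deviation is zero.
#' @slot N integer(1), number of shuffles.
#' @export
setClass("BootstrapResult",
  slots = c(dGen = "numeric", dRnd = "numeric", eGen = "numeric",
            eRnd = "numeric", zD = "numeric", zE = "numeric",
            reliable = "logical", degenerate = "logical", N = "integer"))

#' Folding engine contract
#'
#' Virtual class for the de-novo folding backend used to re-predict
#' inconsistent elements: `foldSingle` folds one contiguous subsequence,
#' `foldDuplex` predicts inter-strand pairs between the two strands of a
#' stem, `foldEnergy` evaluates the free energy of a sequence/structure pair.
#' Two implementations ship with the package: [nussinovEngine()] (a
#' deterministic maximum-canonical-pairing engine, energy -1 kcal/mol per
#' pair, requiring no external software) and [viennaEngine()] (RNAfold /
#' RNAduplex / RNAeval command-line adapters).
#'
#' @export
setClass("FoldingEngine", representation("VIRTUAL"))

#' @rdname FoldingEngine-class
#' @slot minLoop integer(1), minimum hairpin loop size.
#' @export
setClass("NussinovEngine", contains = "FoldingEngine",
  slots = c(minLoop = "integer"))

#' @rdname FoldingEngine-class
#' @slot rnafold,rnaduplex,rnaeval paths to the ViennaRNA executables.
#' @export
setClass("ViennaRNAEngine", contains = "FoldingEngine",
  slots = c(rnafold = "character", rnaduplex = "character",
            rnaeval = "character"))
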