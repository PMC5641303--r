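# Pairwise query/template alignment and the two position maps derived from it.

.maps_from_gapped <- function(aq, at) {
  cq <- .chars(aq)
  ct <- .chars(at)
  if (length(cq) != length(ct))
    stop("aligned strings differ in length", call. = FALSE)
  gq <- cq == "-"
  gt <- ct == "-"
  if (any(gq & gt)) stop("column with gaps in both rows", call. = FALSE)
  qpos <- cumsum(!gq)
  tpos <- cumsum(!gt)
  queryMap <- rep(NA_integer_, sum(!gq))
  templateMap <- rep(NA_integer_, sum(!gt))
  both <- !gq & !gt
  queryMap[qpos[both]] <- tpos[both]
  templateMap[tpos[both]] <- qpos[both]
  list(queryMap = queryMap, templateMap = templateMap)
}

#' Global alignment of a query to a template sequence
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap costs. Defaults
#' follow the ClustalW2 nucleotide settings used for template transfer:
#' match 1.9, mismatch 0, gap opening 7, gap extension 0.5 (a gap of length
#' L costs `gapOpening + gapExtension * L`); `U` and `T` are equivalent
#' because input is normalized to RNA, and `N` scores 0 against everything.
#' The traceback is deterministic (diagonal preferred over a gap in the
#' template, over a gap in the query), so results are reproducible.
#'
#' @param query,template sequences (character or `RNAString`), non-empty.
#' @param gapOpening,gapExtension affine gap parameters.
#' @param match,mismatch substitution scores.
#' @return a [TemplateAlignment-class].
#' @examples
#' aln <- alignSequences("GGGAAACCC", "GGGAAACCC")
#' queryMap(aln)
#' @export
alignSequences <- function(query, template, gapOpening = 7,
                           gapExtension = 0.5, match = 1.9, mismatch = 0) {
  q <- .as_rna(query, "query")
  t <- .as_rna(template, "template")
  res <- .gotoh_align(q, t, gapOpening, gapExtension, match, mismatch)
  maps <- .maps_from_gapped(res$aligned_query, res$aligned_template)
  new("TemplateAlignment", alignedQuery = res$aligned_query,
      alignedTemplate = res$aligned_template, queryMap = maps$queryMap,
      templateMap = maps$templateMap, score = res$score)
}

#' Build a TemplateAlignment from precomputed gapped strings
#'
#' Lets users supply an alignment computed elsewhere (e.g. ClustalW2 or any
#' aligned-FASTA pair); the position maps are read off column-wise.
#'
#' @param alignedQuery,alignedTemplate equal-length gapped strings (gap
#'   character `-`); no column may be gapped in both rows.
#' @return a [TemplateAlignment-class] (score is NA).
#' @examples
#' templateMap(alignmentFromGapped("AC-GU", "ACCGU"))
#' @export
alignmentFromGapped <- function(alignedQuery, alignedTemplate) {
  aq <- toupper(chartr("tT", "UU", alignedQuery))
  at <- toupper(chartr("tT", "UU", alignedTemplate))
  .as_rna(gsub("-", "", aq), "ungapped query")
  .as_rna(gsub("-", "", at), "ungapped template")
  maps <- .maps_from_gapped(aq, at)
  new("TemplateAlignment", alignedQuery = aq, alignedTemplate = at,
      queryMap = maps$queryMap, templateMap = maps$templateMap,
      score = NA_real_)
}

#' Read a two-record aligned FASTA file as a TemplateAlignment
#'
#' The first record is taken as the query row, the second as the template
#' row.
#'
#' @param file path to an aligned FASTA file with (at least) two records.
#' @return a [TemplateAlignment-class].
#' @export
readAlignedFasta <- function(file) {
  raw <- Biostrings::readBStringSet(file)
  if (length(raw) < 2L)
    stop("aligned FASTA must contain two records", call. = FALSE)
  alignmentFromGapped(as.character(raw[[1L]]), as.character(raw[[2L]]))
}
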