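# De-novo re-prediction of inconsistent elements and assembly of the final
# structure.

# el: core element list; qc: query residues; returns global pair matrix
.refine_core <- function(el, qc, engine) {
  if (el$type == "hairpin") {
    span <- el$strand5
    sub <- paste(qc[span[1L]:span[2L]], collapse = "")
    res <- foldSingle(engine, sub)
    lp <- .pairs_from_pt(res$pairTable)
    if (nrow(lp)) lp <- lp + span[1L] - 1L
    lp
  } else {
    s5 <- paste(qc[el$strand5[1L]:el$strand5[2L]], collapse = "")
    s3 <- paste(qc[el$strand3[1L]:el$strand3[2L]], collapse = "")
    res <- foldDuplex(engine, s5, s3)
    p <- res$pairs
    if (nrow(p))
      p <- cbind(el$strand5[1L] - 1L + p[, 1L], el$strand3[1L] - 1L + p[, 2L])
    p
  }
}

.assemble_core <- function(n, elements, labels, refined) {
  pt <- integer(n)
  prov <- rep("single-strand", n)
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    if (labels[k] == "consistent") {
      prov[el$owned] <- "template-transfer"
      p <- el$pairs
    } else {
      prov[el$owned] <- "de-novo"
      p <- refined[[k]]
    }
    if (length(p) && nrow(p)) {
      if (any(pt[as.vector(p)] != 0L))
        stop("assembly conflict: refined pair overlaps a kept pair",
             call. = FALSE)
      pt[p[, 1L]] <- p[, 2L]
      pt[p[, 2L]] <- p[, 1L]
    }
  }
  if (!.is_nested_pt(pt))
    stop("assembled structure is not nested", call. = FALSE)
  list(pt = pt, prov = prov)
}

# full pipeline on plain data; aln may be a TemplateAlignment to skip the
# built-in aligner
.generate_core <- function(q, tseq, pt_t, engine, hairpinThreshold = 0.2,
                           stemThreshold = 0.1, aln = NULL, gapOpening = 7,
                           gapExtension = 0.5, match = 1.9, mismatch = 0) {
  if (is.null(aln)) {
    g <- .gotoh_align(q, tseq, gapOpening, gapExtension, match, mismatch)
    maps <- .maps_from_gapped(g$aligned_query, g$aligned_template)
  } else {
    maps <- list(queryMap = aln@queryMap, templateMap = aln@templateMap)
  }
  qc <- .chars(q)
  im <- .intermediate_core(pt_t, maps$queryMap, maps$templateMap, qc)
  dec <- .decompose_core(im$pt)
  elements <- c(dec$hairpins, dec$stems)
  labels <- .classify_core(elements, im$consistent, hairpinThreshold,
                           stemThreshold)
  refined <- vector("list", length(elements))
  for (k in which(labels == "inconsistent"))
    refined[[k]] <- .refine_core(elements[[k]], qc, engine)
  asm <- .assemble_core(length(qc), elements, labels, refined)
  list(pt = asm$pt, prov = asm$prov, im = im, dec = dec, labels = labels,
       maps = maps)
}

#' Re-predict one inconsistent element de novo
#'
#' Hairpins are folded as a single contiguous subsequence (their span,
#' including attached unpaired positions); stems are folded as a duplex of
#' their two strand subsequences. Returned pairs are in global query
#' coordinates.
#'
#' @param element a [StructureElement-class].
#' @param query the query sequence.
#' @param engine a [FoldingEngine-class].
#' @return integer matrix of base pairs (global 1-based coordinates).
#' @export
refineElement <- function(element, query, engine = nussinovEngine()) {
  q <- .as_rna(query, "query")
  el <- list(type = element@type, strand5 = element@strand5,
             strand3 = element@strand3)
  p <- tryCatch(.refine_core(el, .chars(q), engine), error = function(e)
    stop("refinement of ", element@type, " [", element@strand5[1L], "-",
         element@strand5[2L], "] failed: ", conditionMessage(e),
         call. = FALSE))
  matrix(as.integer(p), ncol = 2L, dimnames = list(NULL, c("i", "j")))
}

#' Combine consistent and re-predicted elements into the final structure
#'
#' Consistent elements keep their intermediate pairing verbatim;
#' inconsistent elements contribute their de-novo pairs; unassigned
#' single-strand positions stay unpaired.
#'
#' @param intermediate the [IntermediateStructure-class].
#' @param decomposition its [StructureDecomposition-class].
#' @param labels element labels from [classifyElements()].
#' @param refined list (parallel to the elements) of global pair matrices
#'   for the inconsistent elements, e.g. from [refineElement()].
#' @param query the query sequence.
#' @return a [GeneratedStructure-class].
#' @export
assembleStructure <- function(intermediate, decomposition, labels, refined,
                              query) {
  q <- .as_rna(query, "query")
  els <- lapply(c(decomposition@hairpins, decomposition@stems), function(e)
    list(type = e@type, pairs = e@memberPairs, owned = e@owned))
  if (length(labels) != length(els))
    stop("one label per element required", call. = FALSE)
  miss <- which(labels == "inconsistent" &
                  vapply(refined, is.null, logical(1)))
  if (length(miss))
    stop("refined structure missing for inconsistent element(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  asm <- .assemble_core(intermediate@length, els, labels, refined)
  new("GeneratedStructure", structure = .ss_from_pt(asm$pt),
      provenance = asm$prov, query = q, intermediate = intermediate,
      decomposition = decomposition, elementLabels = labels)
}

#' Generate the query structure from a homologous template
#'
#' The full pipeline: align the query to the template, map the template
#' structure through the alignment (intermediate structure), decompose into
#' hairpins and stems, classify elements by their fraction of
#' mapping-inconsistent positions (defaults: over 20% for hairpins, over 10%
#' for stems), re-predict the inconsistent elements de novo with the folding
#' engine, and splice the pieces back together. A structure is produced for
#' any input, related or not; use [bootstrapStructure()] to decide whether
#' it is reliable.
#'
#' @param query the query sequence (character or `RNAString`).
#' @param templateSeq the template sequence.
#' @param templateStruct the template [SecondaryStructure-class] or
#'   dot-bracket string; must be nested (see [removePseudoknots()]).
#' @param engine a [FoldingEngine-class]; default [nussinovEngine()].
#' @param hairpinThreshold,stemThreshold element inconsistency thresholds.
#' @param alignment optional precomputed [TemplateAlignment-class]; when
#'   supplied the built-in aligner is skipped.
#' @param gapOpening,gapExtension,match,mismatch built-in aligner
#'   parameters; see [alignSequences()].
#' @return a [GeneratedStructure-class].
#' @examples
#' gen <- generateStructure("GGGAAACCA", "GGGAAACCC", "(((...)))")
#' toDotBracket(finalStructure(gen))
#' provenance(gen)
#' @export
generateStructure <- function(query, templateSeq, templateStruct,
                              engine = nussinovEngine(),
                              hairpinThreshold = 0.2, stemThreshold = 0.1,
                              alignment = NULL, gapOpening = 7,
                              gapExtension = 0.5, match = 1.9,
                              mismatch = 0) {
  q <- .as_rna(query, "query")
  t <- .as_rna(templateSeq, "template")
  ts <- .as_ss(templateStruct)
  if (ts@length != nchar(t))
    stop("template structure length does not match template sequence",
         call. = FALSE)
  pt_t <- pairTable(ts)
  .stop_if_pseudoknotted(pt_t, "generateStructure")
  core <- .generate_core(q, t, pt_t, engine, hairpinThreshold, stemThreshold,
                         aln = alignment, gapOpening = gapOpening,
                         gapExtension = gapExtension, match = match,
                         mismatch = mismatch)
  bp <- matrix(as.integer(.pairs_from_pt(core$im$pt)), ncol = 2L,
               dimnames = list(NULL, c("i", "j")))
  im <- new("IntermediateStructure", length = nchar(q), basePairs = bp,
            caseLabel = core$im$case, consistent = core$im$consistent)
  dec <- new("StructureDecomposition", length = nchar(q),
             hairpins = lapply(core$dec$hairpins, .element_to_s4),
             stems = lapply(core$dec$stems, .element_to_s4),
             assignment = core$dec$assignment)
  new("GeneratedStructure", structure = .ss_from_pt(core$pt),
      provenance = core$prov, query = q, intermediate = im,
      decomposition = dec, elementLabels = core$labels)
}
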