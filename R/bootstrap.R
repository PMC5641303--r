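# Reliability assessment of a generated structure by a dinucleotide-shuffle
# bootstrap.

.bootstrap_core <- function(q, tseq, pt_t, engine, N, hairpinThreshold,
                            stemThreshold) {
  gen <- .generate_core(q, tseq, pt_t, engine, hairpinThreshold,
                        stemThreshold)
  dGen <- .tree_edit_distance_pt(gen$pt, pt_t)
  eGen <- foldEnergy(engine, q, .ss_from_pt(gen$pt))
  ch <- .chars(q)
  dRnd <- numeric(N)
  eRnd <- numeric(N)
  for (k in seq_len(N)) {
    sh <- paste(.dinuc_shuffle_once(ch), collapse = "")
    g <- .generate_core(sh, tseq, pt_t, engine, hairpinThreshold,
                        stemThreshold)
    dRnd[k] <- .tree_edit_distance_pt(g$pt, pt_t)
    eRnd[k] <- foldEnergy(engine, sh, .ss_from_pt(g$pt))
  }
  zscore <- function(obs, null) {
    s <- stats::sd(null)
    if (!is.finite(s) || s == 0) return(NA_real_)
    (mean(null) - obs) / s  # "better than the null" is positive
  }
  zD <- zscore(dGen, dRnd)
  zE <- zscore(eGen, eRnd)
  degenerate <- is.na(zD) || is.na(zE)
  new("BootstrapResult", dGen = as.numeric(dGen), dRnd = dRnd,
      eGen = eGen, eRnd = eRnd, zD = zD, zE = zE,
      reliable = !is.na(zD) && zD >= 2, degenerate = degenerate,
      N = as.integer(N))
}

#' Bootstrap reliability of a generated structure
#'
#' Generates structures, with the same pipeline as the query, for `N`
#' dinucleotide-shuffled copies of the query; the shuffles preserve length
#' and (di)nucleotide composition but destroy homology, so they approximate
#' the null distribution of non-homologous sequences. The tree edit distance
#' of each generated structure to the template structure (`d`) and its free
#' energy (`e`) are standardized against these null samples:
#' `z = (mean(null) - observed) / sd(null)`, so structures better than the
#' null score positive. The structure is called reliable when `zD >= 2`
#' (the distance-based score is the decision metric; the energy-based score
#' is reported alongside). A zero null standard deviation yields an NA
#' z-score, `reliable = FALSE`, and the degenerate-null flag.
#'
#' @param query the query sequence.
#' @param templateSeq,templateStruct the template sequence and its (nested)
#'   structure.
#' @param engine a [FoldingEngine-class].
#' @param N number of shuffled sequences (default 100).
#' @param seed optional RNG seed for reproducibility.
#' @param hairpinThreshold,stemThreshold element inconsistency thresholds.
#' @return a [BootstrapResult-class].
#' @examples
#' bootstrapStructure("GGGAAACCC", "GGGAAACCC", "(((...)))",
#'                    N = 20, seed = 1)
#' @export
bootstrapStructure <- function(query, templateSeq, templateStruct,
                               engine = nussinovEngine(), N = 100L,
                               seed = NULL, hairpinThreshold = 0.2,
                               stemThreshold = 0.1) {
  q <- .as_rna(query, "query")
  t <- .as_rna(templateSeq, "template")
  ts <- .as_ss(templateStruct)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (nchar(q) < 2L)
    stop("query must have length >= 2 for dinucleotide shuffling",
         call. = FALSE)
  pt_t <- pairTable(ts)
  .stop_if_pseudoknotted(pt_t, "bootstrapStructure")
  .with_seed(seed, .bootstrap_core(q, t, pt_t, engine, as.integer(N),
                                   hairpinThreshold, stemThreshold))
}

#' Repeated bootstrap for z-score variance assessment
#'
#' Runs the bootstrap `runs` times with independent shuffle sets and
#' summarizes how often the structure is called reliable, exposing the
#' run-to-run variance of the z-scores.
#'
#' @inheritParams bootstrapStructure
#' @param runs number of independent bootstrap runs.
#' @return list with `zD` and `zE` (numeric vectors of length `runs`),
#'   `fractionReliable` (share of runs with `zD >= 2`), and `results` (the
#'   individual [BootstrapResult-class] objects).
#' @export
repeatedBootstrap <- function(query, templateSeq, templateStruct,
                              engine = nussinovEngine(), N = 100L,
                              runs = 100L, seed = NULL,
                              hairpinThreshold = 0.2, stemThreshold = 0.1) {
  if (runs < 1L) stop("runs must be >= 1", call. = FALSE)
  q <- .as_rna(query, "query")
  t <- .as_rna(templateSeq, "template")
  ts <- .as_ss(templateStruct)
  pt_t <- pairTable(ts)
  .stop_if_pseudoknotted(pt_t, "repeatedBootstrap")
  results <- .with_seed(seed, lapply(seq_len(runs), function(r)
    .bootstrap_core(q, t, pt_t, engine, as.integer(N), hairpinThreshold,
                    stemThreshold)))
  zD <- vapply(results, function(x) x@zD, numeric(1))
  zE <- vapply(results, function(x) x@zE, numeric(1))
  list(zD = zD, zE = zE,
       fractionReliable = mean(!is.na(zD) & zD >= 2),
       results = results)
}
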