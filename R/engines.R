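# Folding engines: the built-in deterministic maximum-pairing engine and the
# ViennaRNA command-line adapter.

#' Built-in deterministic folding engine
#'
#' Maximum canonical base pairing (Nussinov dynamic programming) with a
#' minimum hairpin loop of `minLoop` unpaired nucleotides; duplexes are
#' maximum antiparallel non-crossing canonical matchings; the energy model
#' is -1 kcal/mol per base pair. Entirely self-contained and deterministic,
#' which makes every pipeline stage reproducible without external software.
#'
#' @param minLoop minimum hairpin loop size (default 3).
#' @return a [NussinovEngine-class].
#' @examples
#' foldSingle(nussinovEngine(), "GGGAAACCC")
#' @export
nussinovEngine <- function(minLoop = 3L)
  new("NussinovEngine", minLoop = as.integer(minLoop))

#' ViennaRNA command-line folding engine
#'
#' Adapter around the RNAfold, RNAduplex and RNAeval programs: hairpins are
#' re-predicted with RNAfold, stems with RNAduplex (the single best duplex),
#' and free energies evaluated with RNAeval.
#'
#' @param rnafold,rnaduplex,rnaeval executable names or paths.
#' @return a [ViennaRNAEngine-class].
#' @export
viennaEngine <- function(rnafold = "RNAfold", rnaduplex = "RNAduplex",
                         rnaeval = "RNAeval") {
  for (exe in c(rnafold, rnaduplex, rnaeval)) {
    if (Sys.which(exe) == "")
      stop("ViennaRNA executable not found: '", exe,
           "'; install the ViennaRNA package or use nussinovEngine()",
           call. = FALSE)
  }
  new("ViennaRNAEngine", rnafold = rnafold, rnaduplex = rnaduplex,
      rnaeval = rnaeval)
}

# ---- built-in engine ------------------------------------------------------

setMethod("foldSingle", "NussinovEngine", function(engine, seq) {
  s <- .as_rna(seq, "seq")
  pt <- .nussinov_fold(s, engine@minLoop)
  list(pairTable = pt, energy = -1.0 * sum(pt > 0L) / 2)
})

setMethod("foldDuplex", "NussinovEngine", function(engine, seq5, seq3) {
  s5 <- .as_rna(seq5, "seq5")
  s3 <- .as_rna(seq3, "seq3")
  pairs <- .duplex_fold(s5, s3)
  list(pairs = pairs, energy = -1.0 * nrow(pairs))
})

setMethod("foldEnergy", "NussinovEngine", function(engine, seq, structure) {
  s <- .as_ss(structure)
  -1.0 * nrow(s@basePairs)
})

# ---- ViennaRNA adapter ----------------------------------------------------

.vienna_run <- function(exe, args, input) {
  out <- suppressWarnings(system2(exe, args, input = input, stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop(exe, " failed with status ", status, call. = FALSE)
  out
}

.vienna_energy <- function(line) {
  m <- regmatches(line, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", line))
  if (!length(m)) stop("cannot parse energy from: ", line, call. = FALSE)
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

setMethod("foldSingle", "ViennaRNAEngine", function(engine, seq) {
  s <- .as_rna(seq, "seq")
  out <- .vienna_run(engine@rnafold, c("--noPS"), s)
  line <- out[2L]
  db <- sub("\\s.*$", "", line)
  list(pairTable = pairTable(parseDotBracket(db)),
       energy = .vienna_energy(line))
})

setMethod("foldDuplex", "ViennaRNAEngine", function(engine, seq5, seq3) {
  s5 <- .as_rna(seq5, "seq5")
  s3 <- .as_rna(seq3, "seq3")
  out <- .vienna_run(engine@rnaduplex, character(0), c(s5, s3))
  line <- out[length(out)]
  # e.g. "(((&)))   1,3   :   5,7   (-1.20)"
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  db <- parts[1L]
  halves <- strsplit(db, "&", fixed = TRUE)[[1]]
  rng5 <- as.integer(strsplit(parts[2L], ",")[[1]])
  rng3 <- as.integer(strsplit(parts[4L], ",")[[1]])
  open5 <- rng5[1L] - 1L + which(.chars(halves[1L]) == "(")
  close3 <- rng3[1L] - 1L + which(.chars(halves[2L]) == ")")
  if (length(open5) != length(close3))
    stop("unbalanced duplex structure from RNAduplex: ", db, call. = FALSE)
  pairs <- cbind(open5, rev(close3))
  list(pairs = pairs, energy = .vienna_energy(line))
})

setMethod("foldEnergy", "ViennaRNAEngine", function(engine, seq, structure) {
  s <- .as_rna(seq, "seq")
  db <- toDotBracket(.as_ss(structure))
  out <- .vienna_run(engine@rnaeval, character(0), c(s, db))
  .vienna_energy(out[length(out)])
})
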