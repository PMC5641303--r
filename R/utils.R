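# internal helpers shared across modules

# Normalize a sequence to an uppercase RNA character string.
# Accepts character(1), RNAString/DNAString/BString; T -> U; validates the
# alphabet {A,C,G,U,N} (only A/C/G/U/T/N in either case accepted on input).
.as_rna <- function(x, what = "sequence") {
  if (inherits(x, "XString") || inherits(x, "XStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string or an XString", call. = FALSE)
  s <- chartr("acgutT", "ACGUUU", x)
  bad <- gsub("[ACGUNn]", "", s)
  if (nzchar(bad))
    stop(what, " contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "), call. = FALSE)
  s <- chartr("n", "N", s)
  if (nchar(s) < 1L) stop(what, " is empty", call. = FALSE)
  s
}

# Coerce to SecondaryStructure (dot-bracket strings accepted everywhere).
.as_ss <- function(x) {
  if (is(x, "SecondaryStructure")) return(x)
  if (is.character(x) && length(x) == 1L) return(parseDotBracket(x))
  stop("expected a SecondaryStructure or a dot-bracket string", call. = FALSE)
}

# pair table (integer vector, 0 = unpaired) <-> pair matrix
.pt_from_pairs <- function(bp, n) {
  pt <- integer(n)
  if (nrow(bp)) {
    pt[bp[, 1L]] <- bp[, 2L]
    pt[bp[, 2L]] <- bp[, 1L]
  }
  pt
}

.pairs_from_pt <- function(pt) {
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
}

.new_ss <- function(bp, n) {
  bp <- matrix(as.integer(bp), ncol = 2L,
               dimnames = list(NULL, c("i", "j")))
  if (nrow(bp)) bp <- bp[order(bp[, 1L]), , drop = FALSE]
  new("SecondaryStructure", length = as.integer(n), basePairs = bp)
}

.ss_from_pt <- function(pt) .new_ss(.pairs_from_pt(pt), length(pt))

# TRUE iff the pair table has no crossing pairs
.is_nested_pt <- function(pt) {
  stack <- integer(0)
  for (p in seq_along(pt)) {
    q <- pt[p]
    if (q > p) {
      stack <- c(stack, q)
    } else if (q > 0L && q < p) {
      if (!length(stack) || stack[length(stack)] != p) return(FALSE)
      stack <- stack[-length(stack)]
    }
  }
  length(stack) == 0L
}

.stop_if_pseudoknotted <- function(pt, caller) {
  if (!.is_nested_pt(pt))
    stop(caller, ": structure contains pseudoknots; ",
         "call removePseudoknots() first", call. = FALSE)
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. With seed = NULL the current stream is used as-is.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
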