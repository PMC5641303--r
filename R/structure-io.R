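#' Parse a dot-bracket string into a secondary structure
#'
#' Matches brackets per tier: `()` for nested pairs and, for pseudoknotted
#' input, the additional tiers `[]`, `{}` and `<>`. Unpaired positions are
#' dots. Bracket tiers beyond `()` are accepted on input only; serialization
#' with [toDotBracket()] requires a nested structure.
#'
#' @param text dot-bracket string over `.()[]{}<>`.
#' @return a [SecondaryStructure-class].
#' @examples
#' basePairs(parseDotBracket("(((...)))"))
#' @export
parseDotBracket <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("text must be a single string", call. = FALSE)
  ch <- .chars(text)
  n <- length(ch)
  openers <- c("(", "[", "{", "<")
  closers <- c(")", "]", "}", ">")
  ok <- ch %in% c(".", openers, closers)
  if (any(!ok))
    stop("invalid character '", ch[which(!ok)[1L]], "' at position ",
         which(!ok)[1L], call. = FALSE)
  bp <- matrix(integer(0), ncol = 2L)
  for (tier in seq_along(openers)) {
    stack <- integer(0)
    for (p in seq_len(n)) {
      if (ch[p] == openers[tier]) {
        stack <- c(stack, p)
      } else if (ch[p] == closers[tier]) {
        if (!length(stack))
          stop("unbalanced '", closers[tier], "' at position ", p,
               call. = FALSE)
        bp <- rbind(bp, c(stack[length(stack)], p))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unclosed '", openers[tier], "' at position ", stack[1L],
           call. = FALSE)
  }
  .new_ss(bp, n)
}

#' Serialize a nested secondary structure to dot-bracket
#'
#' @param s a [SecondaryStructure-class] (must be nested) or dot-bracket
#'   string.
#' @return dot-bracket string such that [parseDotBracket()] inverts it.
#' @export
toDotBracket <- function(s) {
  s <- .as_ss(s)
  pt <- pairTable(s)
  .stop_if_pseudoknotted(pt, "toDotBracket")
  out <- rep(".", s@length)
  bp <- s@basePairs
  out[bp[, 1L]] <- "("
  out[bp[, 2L]] <- ")"
  paste(out, collapse = "")
}

#' Remove pseudoknots by maximal nested pair selection
#'
#' Returns a crossing-free subset of the input base pairs of maximum
#' cardinality, computed by a Nussinov-style dynamic program restricted to
#' the input pair set. Ties are broken deterministically by preferring pairs
#' with the smaller opening position.
#'
#' @param s a [SecondaryStructure-class] or dot-bracket string (bracket tiers
#'   allowed).
#' @return a nested [SecondaryStructure-class]; the input is unchanged.
#' @examples
#' toDotBracket(removePseudoknots(parseDotBracket("((..[[..))..]]")))
#' @export
removePseudoknots <- function(s) {
  s <- .as_ss(s)
  pt <- pairTable(s)
  if (.is_nested_pt(pt)) return(.new_ss(s@basePairs, s@length))
  n <- s@length
  # M[i, j] = max retainable pairs within [i, j]; each i has at most one
  # candidate partner pt[i], so the recurrence is O(1) per cell
  M <- matrix(0L, n + 1L, n + 1L)  # 1-shifted so that empty intervals index 0
  for (len in 2:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- M[i + 2L, j + 1L]  # i unpaired (interval [i+1, j])
      k <- pt[i]
      if (k > i && k <= j) {
        inner <- if (k - 1L >= i + 1L) M[i + 2L, k] else 0L
        rest <- if (k + 1L <= j) M[k + 2L, j + 1L] else 0L
        cand <- 1L + inner + rest
        if (cand > best) best <- cand
      }
      M[i + 1L, j + 1L] <- best
    }
  }
  keep <- matrix(integer(0), ncol = 2L)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    while (i < j) {
      k <- pt[i]
      val <- M[i + 1L, j + 1L]
      if (k > i && k <= j) {
        inner <- if (k - 1L >= i + 1L) M[i + 2L, k] else 0L
        rest <- if (k + 1L <= j) M[k + 2L, j + 1L] else 0L
        if (1L + inner + rest == val) {  # keep (i, k); ties prefer pairing
          keep <- rbind(keep, c(i, k))
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  .new_ss(keep, n)
}

#' Read RNA sequences from a FASTA file
#'
#' Sequences are normalized to uppercase RNA (`T`/`t` become `U`); characters
#' outside `A C G U T N` (either case) are rejected. `N` is accepted and
#' treated as unpairable throughout the package.
#'
#' @param file path to a (multi-record) FASTA file.
#' @return a [Biostrings::RNAStringSet].
#' @export
readRnaFasta <- function(file) {
  raw <- Biostrings::readBStringSet(file)
  if (length(raw) == 0L) stop("empty FASTA file: ", file, call. = FALSE)
  seqs <- vapply(seq_along(raw), function(i)
    .as_rna(as.character(raw[[i]]), paste0("record '", names(raw)[i], "'")),
    character(1))
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' Read Vienna-style sequence + dot-bracket records
#'
#' A Vienna record is a FASTA header line, one or more sequence lines, then
#' one or more dot-bracket lines whose total length equals the sequence
#' length. Bracket tiers `[] {} <>` are accepted (pseudoknotted input).
#'
#' @param file path to the file.
#' @return a list of records, each a list with elements `id`, `sequence`
#'   (uppercase RNA string) and `structure` ([SecondaryStructure-class]).
#' @export
readVienna <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", file, call. = FALSE)
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1L] != 1L)
    stop("not a Vienna/FASTA file (no leading '>' header): ", file,
         call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    id <- sub("^>\\s*", "", lines[starts[k]])
    body <- lines[(starts[k] + 1L):ends[k]]
    isstruct <- grepl("^[.()\\[\\]{}<>]+$", body, perl = TRUE)
    # sequence lines come first; structure lines are those made of brackets
    firststruct <- which(isstruct)[1L]
    if (is.na(firststruct))
      stop("record '", id, "': no structure line", call. = FALSE)
    seqstr <- .as_rna(paste(body[seq_len(firststruct - 1L)], collapse = ""),
                      paste0("record '", id, "'"))
    structstr <- paste(body[firststruct:length(body)], collapse = "")
    if (nchar(structstr) != nchar(seqstr))
      stop("record '", id, "': structure length (", nchar(structstr),
           ") does not match sequence length (", nchar(seqstr), ")",
           call. = FALSE)
    list(id = id, sequence = seqstr, structure = parseDotBracket(structstr))
  })
}

#' Write Vienna-style records
#'
#' @param records a list of records as returned by [readVienna()], or a
#'   single record list with `id`, `sequence`, `structure`.
#' @param file output path.
#' @export
writeVienna <- function(records, file) {
  if (!is.null(records$id)) records <- list(records)
  out <- unlist(lapply(records, function(r) {
    c(paste0(">", r$id), r$sequence, toDotBracket(r$structure))
  }))
  writeLines(out, file)
}

#' Read a CT (connect) format structure file
#'
#' The usual format for experimentally derived structures: a header line with
#' the sequence length, then one line per position with columns index, base,
#' previous, next, pairing partner (0 = unpaired), original index.
#'
#' @param file path to the CT file.
#' @return a list with `id`, `sequence` and `structure`
#'   ([SecondaryStructure-class]; may be pseudoknotted).
#' @export
readCt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file: ", file, call. = FALSE)
  head <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head[1L]))
  if (is.na(n) || n < 1L)
    stop("CT header does not start with the sequence length", call. = FALSE)
  if (length(lines) < n + 1L)
    stop("CT file truncated: expected ", n, " positions", call. = FALSE)
  fields <- strsplit(trimws(lines[2:(n + 1L)]), "\\s+")
  bases <- vapply(fields, `[`, character(1), 2L)
  partner <- as.integer(vapply(fields, `[`, character(1), 5L))
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > n))
    stop("invalid pairing column in CT file", call. = FALSE)
  pt <- partner
  # symmetrize and validate
  for (p in which(pt > 0L)) {
    if (pt[pt[p]] != p)
      stop("asymmetric pair table in CT file at position ", p, call. = FALSE)
  }
  seqstr <- .as_rna(paste(bases, collapse = ""), "CT sequence")
  list(id = paste(head[-1L], collapse = " "), sequence = seqstr,
       structure = .ss_from_pt(pt))
}
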