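# Independent oracles used to verify the package's algorithms on small
# instances. These deliberately share no code with the implementation.

# ---- forest edit distance by the definitional recursion -------------------
# A forest of structure trees corresponds exactly to a dot-bracket string
# (U leaf = ".", P node = "(children)"), so forests are represented as
# strings and the recursion memoized on the string pair. The virtual roots
# of two structure trees always match, so the tree distance equals the
# forest distance between the two dot-bracket strings.
oracle_ted <- local({
  memo <- new.env(parent = emptyenv())
  nnodes <- function(f) {
    if (!nzchar(f)) return(0L)
    ch <- strsplit(f, "")[[1]]
    sum(ch == ".") + sum(ch == "(")
  }
  # split off the last tree of forest f: returns c(rest, children, label)
  last_tree <- function(f) {
    n <- nchar(f)
    if (substr(f, n, n) == ".")
      return(list(rest = substr(f, 1, n - 1), children = "", label = "U"))
    depth <- 0L
    for (p in n:1) {
      c <- substr(f, p, p)
      if (c == ")") depth <- depth + 1L
      if (c == "(") depth <- depth - 1L
      if (depth == 0L)
        return(list(rest = substr(f, 1, p - 1),
                    children = substr(f, p + 1, n - 1), label = "P"))
    }
    stop("unbalanced forest")
  }
  fed <- function(a, b) {
    if (!nzchar(a)) return(nnodes(b))
    if (!nzchar(b)) return(nnodes(a))
    key <- paste(a, b, sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ta <- last_tree(a)
    tb <- last_tree(b)
    del <- 1L + fed(paste0(ta$rest, ta$children), b)
    ins <- 1L + fed(a, paste0(tb$rest, tb$children))
    mat <- fed(ta$rest, tb$rest) + fed(ta$children, tb$children) +
      (ta$label != tb$label)
    res <- min(del, ins, mat)
    memo[[key]] <- res
    res
  }
  fed
})

# ---- exhaustive enumeration of nested structures (min hairpin loop 3) -----
oracle_all_structures <- local({
  memo <- list()
  f <- function(n) {
    if (n == 0L) return("")
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", f(n - 1L))
    if (n >= 5L) {
      for (m in 3:(n - 2L)) {
        inner <- f(m)
        rest <- f(n - m - 2L)
        out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest,
                                      paste0)))
      }
    }
    out <- unique(out)
    memo[[key]] <<- out
    out
  }
  f
})

# ---- brute-force global affine alignment score ----------------------------
# Enumerates every global alignment of a and b; a gap of length L costs
# open + ext * L (terminal gaps included); match/mismatch as given.
oracle_align_score <- function(a, b, open = 7, ext = 0.5, match = 1.9,
                               mismatch = 0) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: last column type (0 start, 1 sub, 2 gap-in-b, 3 gap-in-a)
  rec <- function(i, j, score, last) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == "N" || b[j] == "N") 0
           else if (a[i] == b[j]) match else mismatch
      rec(i + 1L, j + 1L, score + s, 1L)
    }
    if (i <= length(a))
      rec(i + 1L, j, score - ext - if (last == 2L) 0 else open, 2L)
    if (j <= length(b))
      rec(i, j + 1L, score - ext - if (last == 3L) 0 else open, 3L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# ---- brute-force maximum crossing-free pair subset ------------------------
oracle_max_nested <- function(pairs) {
  if (!nrow(pairs)) return(0L)
  np <- nrow(pairs)
  crossing <- function(p, q) {
    (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
      (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
  }
  best <- 0L
  for (mask in 0:(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      for (x in seq_along(sel)) {
        for (y in seq_len(x - 1L)) {
          if (crossing(pairs[sel[x], ], pairs[sel[y], ])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}

# ---- naive per-position reimplementation of the four-case mapping ---------
# Works directly on the gapped alignment strings; shares no code with
# buildIntermediate.
oracle_four_cases <- function(template_db, aligned_query, aligned_template,
                              query) {
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  aq <- strsplit(aligned_query, "")[[1]]
  at <- strsplit(aligned_template, "")[[1]]
  qc <- strsplit(query, "")[[1]]
  tpt <- RNAtemplate::pairTable(RNAtemplate::parseDotBracket(template_db))
  ncol_aln <- length(aq)
  # column index of each query / template position
  qcol <- which(aq != "-")
  tcol <- which(at != "-")
  t_of_col <- integer(ncol_aln)
  t_of_col[tcol] <- seq_along(tcol)
  q_of_col <- integer(ncol_aln)
  q_of_col[qcol] <- seq_along(qcol)
  nq <- length(qcol)
  case <- integer(nq)
  partner <- integer(nq)
  for (p in seq_len(nq)) {
    col <- qcol[p]
    if (at[col] == "-") { case[p] <- 1L; next }
    tp <- t_of_col[col]
    r <- tpt[tp]
    if (r == 0L) { case[p] <- 2L; next }
    rcol <- tcol[r]
    if (aq[rcol] == "-") { case[p] <- 3L; next }
    mate <- q_of_col[rcol]
    if (paste0(qc[p], qc[mate]) %in% canonical) {
      case[p] <- 4L
      partner[p] <- mate
    } else {
      case[p] <- 3L
    }
  }
  list(case = case, pt = partner)
}

# ---- brute-force maximum canonical pairing (min loop 3) -------------------
oracle_max_pairing <- function(seq) {
  qc <- strsplit(seq, "")[[1]]
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  structs <- oracle_all_structures(length(qc))
  best <- 0L
  for (db in structs) {
    bp <- RNAtemplate::basePairs(RNAtemplate::parseDotBracket(db))
    if (!nrow(bp)) next
    ok <- all(paste0(qc[bp[, 1]], qc[bp[, 2]]) %in% canonical)
    if (ok) best <- max(best, nrow(bp))
  }
  best
}

# ---- exhaustive dinucleotide shuffle set ----------------------------------
# All permutations of the multiset of residues that keep the first and last
# residues and the dinucleotide multiset; feasible for length <= 9.
oracle_shuffle_set <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  dinucs <- function(x) sort(paste0(x[-length(x)], x[-1]))
  target <- dinucs(ch)
  interior <- ch[-c(1L, L)]
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      for (p in perms(rest)) out[[length(out) + 1L]] <- c(u, p)
    }
    out
  }
  cand <- unique(vapply(perms(interior), function(p)
    paste(c(ch[1L], p, ch[L]), collapse = ""), character(1)))
  cand[vapply(cand, function(s)
    identical(dinucs(strsplit(s, "")[[1]]), target), logical(1))]
}

# ---- misc helpers ---------------------------------------------------------
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

dinuc_multiset <- function(s) {
  ch <- strsplit(s, "")[[1]]
  sort(paste0(ch[-length(ch)], ch[-1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
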