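#' Edit (Levenshtein) distance
#'
#' Unit-cost edit distance between strings over an alphabet: the minimum
#' number of single-character substitutions, insertions and deletions
#' transforming one string into the other. This is the distance the motif
#' definition is built on. Computed by [utils::adist()]; inputs are
#' validated against the alphabet first.
#'
#' @param x,y Strings over `alphabet` (vectors recycle pairwise).
#' @param alphabet An [ems_alphabet()].
#' @return Integer vector of distances.
#' @examples
#' edit_distance("ACGT", "AGT")   # one deletion
#' @export
edit_distance <- function(x, y, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  check_sequences(x[nchar(x) > 0], alphabet, "string")
  check_sequences(y[nchar(y) > 0], alphabet, "string")
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(x[i], y[i]))
  out
}

#' Expand a compact motif into its l-mers
#'
#' A compact motif is a string over the alphabet plus the wildcard `*`; each
#' `*` stands for every alphabet symbol, so a compact motif with w wildcards
#' represents `|Sigma|^w` concrete l-mers.
#'
#' @param x A single compact motif string.
#' @param alphabet An [ems_alphabet()].
#' @return Character vector of all represented l-mers, in alphabet order.
#' @examples
#' expand_compact("*GT")
#' @export
expand_compact <- function(x, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(length(x) == 1L)
  check_compact(x, alphabet)
  ch <- strsplit(x, "")[[1]]
  pools <- lapply(ch, function(c) {
    if (c == alphabet$wildcard) alphabet$symbols else c
  })
  if (!length(pools)) return("")
  grid <- expand.grid(rev(pools), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort_lmers(out, alphabet)
}

#' Intersect two compact motifs
#'
#' Position-wise intersection of compact motifs: empty whenever some
#' position holds two distinct concrete symbols; otherwise a concrete symbol
#' wins over a wildcard and the result keeps a wildcard only where both
#' inputs do. The expansion of the result equals the intersection of the
#' two expansions.
#'
#' @param a,b Compact motifs of the same length.
#' @param alphabet An [ems_alphabet()].
#' @return A compact motif string, or `NULL` for the empty intersection.
#' @examples
#' compact_intersect("*GT", "AG*")  # "AGT"
#' @export
compact_intersect <- function(a, b, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(length(a) == 1L, length(b) == 1L)
  check_compact(a, alphabet)
  check_compact(b, alphabet)
  if (nchar(a) != nchar(b)) {
    stop("compact motifs must have the same length", call. = FALSE)
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  w <- alphabet$wildcard
  conflict <- ca != w & cb != w & ca != cb
  if (any(conflict)) return(NULL)
  res <- ifelse(ca == w, cb, ca)
  paste(res, collapse = "")
}

#' All strings one edit operation away
#'
#' The set of strings reachable from `x` by exactly one substitution (to a
#' different symbol), one deletion, or one insertion of any alphabet symbol
#' at any position. Used by the brute-force oracle that grows friendhoods
#' one edit at a time.
#'
#' @param x A string over `alphabet` (possibly empty).
#' @param alphabet An [ems_alphabet()].
#' @return Character vector (a set: no duplicates, unordered semantics).
#' @export
grow_one_edit <- function(x, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(length(x) == 1L)
  if (nchar(x) > 0) check_sequences(x, alphabet, "string")
  ch <- if (nchar(x)) strsplit(x, "")[[1]] else character()
  n <- length(ch)
  out <- character()
  for (p in seq_len(n)) {                       # deletions
    out <- c(out, paste(ch[-p], collapse = ""))
  }
  for (p in seq_len(n)) {                       # substitutions (to different)
    for (s in setdiff(alphabet$symbols, ch[p])) {
      tmp <- ch; tmp[p] <- s
      out <- c(out, paste(tmp, collapse = ""))
    }
  }
  for (p in 0:n) {                              # insertions
    for (s in alphabet$symbols) {
      out <- c(out, paste(c(ch[seq_len(p)], s, ch[seq_len(n - p) + p]),
                          collapse = ""))
    }
  }
  unique(out)
}

all_lmers <- function(l, alphabet) {
  sigma <- length(alphabet$symbols)
  if (sigma^l > 2^20) {
    stop("exhaustive l-mer enumeration is limited to |Sigma|^l <= 2^20",
         call. = FALSE)
  }
  pools <- rep(list(alphabet$symbols), l)
  grid <- expand.grid(rev(pools), stringsAsFactors = FALSE)
  sort_lmers(do.call(paste0, rev(grid)), alphabet)
}

all_substrings <- function(S, kmin, kmax) {
  m <- nchar(S)
  out <- character()
  for (k in kmin:kmax) {
    if (k > m || k < 1) next
    out <- c(out, substring(S, seq_len(m - k + 1), seq_len(m - k + 1) + k - 1))
  }
  unique(out)
}

#' Brute-force (l,d)-motifs of one string
#'
#' Reference oracle for the motif set of a single string: all l-mers within
#' edit distance at most d of some substring of length k, l-d <= k <= l+d.
#' Two independent routes are provided: `"scan"` checks every l-mer of
#' `Sigma^l` against every admissible substring with the distance DP;
#' `"grow"` grows each substring's neighborhood one edit at a time and keeps
#' the length-l strings. Both are exponential and intended for small
#' problems only; every production engine is validated against this oracle.
#'
#' @param S A string over the alphabet.
#' @param l Motif length; must satisfy `l > d`.
#' @param d Distance budget, `d >= 0`.
#' @param alphabet An [ems_alphabet()].
#' @param method `"scan"` or `"grow"`.
#' @return Character vector of motifs, sorted in alphabet order.
#' @export
oracle_motifs_one_string <- function(S, l, d, alphabet = ems_alphabet(),
                                     method = c("scan", "grow")) {
  alphabet <- as_alphabet(alphabet)
  method <- match.arg(method)
  check_params(l, d)
  check_sequences(S, alphabet, "string")
  m <- nchar(S)
  if (m < l - d) {
    stop("string shorter than l - d: no substring can be within distance d",
         call. = FALSE)
  }
  subs <- all_substrings(S, l - d, min(l + d, m))
  if (method == "scan") {
    lmers <- all_lmers(l, alphabet)
    D <- utils::adist(lmers, subs)
    mind <- do.call(pmin, as.data.frame(D))
    sort_lmers(lmers[mind <= d], alphabet)
  } else {
    out <- character()
    for (L in subs) {
      # N_{l,d}(L) = union over t = 0..d of F_{l,t}(L),
      # F_{l,t}(L) = { x in G^t(L) : |x| = l }
      cur <- L
      if (nchar(L) == l) out <- c(out, L)
      for (t in seq_len(d)) {
        cur <- unique(unlist(lapply(cur, grow_one_edit, alphabet = alphabet)))
        out <- c(out, cur[nchar(cur) == l])
      }
    }
    sort_lmers(unique(out), alphabet)
  }
}

#' Brute-force common (l,d)-motifs
#'
#' Intersection over all input strings of [oracle_motifs_one_string()]:
#' the reference answer the solver engines are tested against.
#'
#' @param sequences Character vector of strings over the alphabet.
#' @inheritParams oracle_motifs_one_string
#' @return Sorted character vector of common motifs.
#' @export
oracle_common_motifs <- function(sequences, l, d, alphabet = ems_alphabet(),
                                 method = c("scan", "grow")) {
  alphabet <- as_alphabet(alphabet)
  method <- match.arg(method)
  stopifnot(length(sequences) >= 1L)
  sets <- lapply(sequences, oracle_motifs_one_string,
                 l = l, d = d, alphabet = alphabet, method = method)
  sort_lmers(Reduce(intersect, sets), alphabet)
}

check_params <- function(l, d) {
  if (!(is.numeric(l) && is.numeric(d)) || length(l) != 1L ||
      length(d) != 1L || l != as.integer(l) || d != as.integer(d)) {
    stop("l and d must be single integers", call. = FALSE)
  }
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  if (l <= d) {
    stop("l must exceed d (for l <= d every l-mer trivially neighbors ",
         "short substrings)", call. = FALSE)
  }
  invisible(TRUE)
}
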