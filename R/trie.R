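#' Motif tries
#'
#' A motif trie stores a set of l-mers. Edges out of a node carry mutually
#' exclusive non-empty subsets of the alphabet; a non-empty trie has `l + 1`
#' levels, and the trie contains the l-mer `s1..sl` exactly when each `sj`
#' lies in the label of the level-j edge along some root-to-leaf path.
#' Compact motifs insert in one pass (a wildcard descends into every child),
#' which is what makes the trie an efficient container for the compact
#' neighborhood candidates.
#'
#' Tries have reference semantics: [trie_insert()] modifies its argument in
#' place (and also returns it invisibly). [trie_intersect()] is pure and
#' builds a new trie.
#'
#' @param l Depth (motif length).
#' @param alphabet An [ems_alphabet()] (at most 31 symbols).
#' @return `motif_trie()` returns an empty trie of class `motif_trie`.
#' @examples
#' tr <- motif_trie(3)
#' trie_insert(tr, c("*GT", "A*C"))
#' trie_enumerate(tr)
#' @export
motif_trie <- function(l, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(length(l) == 1L, l >= 1L, l == as.integer(l))
  structure(
    list(ptr = cpp_trie_new(as.integer(l), alphabet_string(alphabet)),
         l = as.integer(l), alphabet = alphabet),
    class = "motif_trie"
  )
}

#' @export
print.motif_trie <- function(x, ...) {
  cat(sprintf("<motif_trie> l = %d, alphabet = %s, %s l-mers, %d nodes\n",
              x$l, alphabet_string(x$alphabet),
              format(trie_count(x), big.mark = ","),
              cpp_trie_node_count(x$ptr)))
  invisible(x)
}

#' @describeIn motif_trie Insert compact motifs (in place): a concrete
#'   character descends into the child whose label contains it, splitting
#'   that child copy-on-write when the label is not already the singleton;
#'   a wildcard descends into every child; symbols not covered by any label
#'   get a fresh child.
#' @param trie A `motif_trie`.
#' @param motifs Character vector of compact motifs of length `l`.
#' @export
trie_insert <- function(trie, motifs) {
  stopifnot(inherits(trie, "motif_trie"))
  if (length(motifs)) {
    check_compact(motifs, trie$alphabet)
    if (any(nchar(motifs) != trie$l)) {
      stop("motif length does not match trie depth", call. = FALSE)
    }
    cpp_trie_insert(trie$ptr, motifs)
  }
  invisible(trie)
}

#' @describeIn motif_trie Pure intersection: the expansion of the result is
#'   the intersection of the two expansions. Children pair up by label
#'   intersection; branches with no surviving leaf are pruned eagerly, so
#'   emptiness is visible at the root.
#' @param t1,t2 Tries of equal depth and alphabet.
#' @export
trie_intersect <- function(t1, t2) {
  stopifnot(inherits(t1, "motif_trie"), inherits(t2, "motif_trie"))
  if (t1$l != t2$l ||
      !identical(t1$alphabet$symbols, t2$alphabet$symbols)) {
    stop("tries must share depth and alphabet", call. = FALSE)
  }
  structure(
    list(ptr = cpp_trie_intersect(t1$ptr, t2$ptr), l = t1$l,
         alphabet = t1$alphabet),
    class = "motif_trie"
  )
}

#' @describeIn motif_trie Depth-first enumeration of the stored l-mers,
#'   visiting each edge once per symbol of its label in alphabet order:
#'   the output is sorted and duplicate-free.
#' @export
trie_enumerate <- function(trie) {
  stopifnot(inherits(trie, "motif_trie"))
  cpp_trie_enumerate(trie$ptr)
}

#' @describeIn motif_trie `TRUE` when the trie stores no l-mer.
#' @export
trie_is_empty <- function(trie) {
  stopifnot(inherits(trie, "motif_trie"))
  cpp_trie_is_empty(trie$ptr)
}

#' @describeIn motif_trie Number of stored l-mers (without enumerating).
#' @export
trie_count <- function(trie) {
  stopifnot(inherits(trie, "motif_trie"))
  cpp_trie_count(trie$ptr)
}

#' @describeIn motif_trie Structural validity: labels at every node are
#'   non-empty, within the alphabet and mutually exclusive, and every path
#'   of a non-empty trie has exactly `l` edges.
#' @export
trie_validate <- function(trie) {
  stopifnot(inherits(trie, "motif_trie"))
  cpp_trie_check(trie$ptr)
}

#' Motif trie of a whole string
#'
#' Builds the trie whose expansion is the exact (l,d)-motif set of `S`, by
#' inserting every compact candidate from [gen_all()] (per-k chunks, so the
#' candidate multiset is never materialized at once).
#'
#' @inheritParams gen_all
#' @param max_candidates Abort if the compact candidate count for the
#'   string exceeds this guard.
#' @return A `motif_trie`.
#' @export
trie_from_string <- function(S, l, d, rules = TRUE,
                             alphabet = ems_alphabet(),
                             max_candidates = 5e7) {
  alphabet <- as_alphabet(alphabet)
  trie <- motif_trie(l, alphabet)
  total <- 0
  gen_all(S, l, d, rules = rules, alphabet = alphabet,
          chunk_fun = function(chunk) {
            total <<- total + length(chunk)
            if (total > max_candidates) {
              stop(sprintf(
                "per-string compact candidate count exceeds guard (%g)",
                max_candidates), call. = FALSE)
            }
            cpp_trie_insert(trie$ptr, chunk)
          })
  trie
}
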