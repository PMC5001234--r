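#' Compact radix sort with wildcard expansion
#'
#' Sorts an array of compact motifs while expanding their wildcards: one
#' stable counting-sort phase per base position, processed from the last
#' position to the first. In the phase that touches a position, a wildcard
#' there increments every symbol's bucket counter and the motif is emitted
#' as `|Sigma|` copies with that wildcard finalized, placed at the proper
#' bucket offsets; later phases therefore only ever see concrete symbols at
#' already-processed positions. The result is the fully expanded multiset,
#' sorted lexicographically in alphabet order.
#'
#' @param x Character vector of compact motifs (equal length).
#' @param alphabet An [ems_alphabet()].
#' @return Character vector of expanded l-mers, sorted (duplicates kept).
#' @examples
#' compact_radix_sort(c("*G", "CA"))
#' @export
compact_radix_sort <- function(x, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  if (!length(x)) return(character())
  check_compact(x, alphabet)
  cpp_radix_expand(x, alphabet_string(alphabet))
}

#' Remove duplicates from a sorted motif array
#'
#' Linear scan over a sorted, expanded motif array; errors if the input
#' violates the sortedness contract.
#'
#' @param x Sorted character vector.
#' @param alphabet An [ems_alphabet()].
#' @return Strictly increasing character vector with the same set of values.
#' @export
dedupe_sorted <- function(x, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  cpp_dedupe_sorted(x, alphabet_string(alphabet))
}

#' Intersect two sorted duplicate-free motif arrays
#'
#' Linear two-pointer merge scan; errors if either input is not strictly
#' increasing in alphabet order.
#'
#' @param a,b Sorted duplicate-free character vectors.
#' @param alphabet An [ems_alphabet()].
#' @return Sorted duplicate-free intersection.
#' @export
intersect_sorted <- function(a, b, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  cpp_intersect_sorted(a, b, alphabet_string(alphabet))
}

#' Union of two sorted duplicate-free motif arrays
#'
#' Linear merge used by the binary-tree combination of per-worker arrays.
#'
#' @inheritParams intersect_sorted
#' @return Sorted duplicate-free union.
#' @export
union_sorted <- function(a, b, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  cpp_union_sorted(a, b, alphabet_string(alphabet))
}
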