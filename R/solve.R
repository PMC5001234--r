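#' Solve an (l,d) edit-distance motif search problem
#'
#' Finds every l-mer within edit distance at most `d` of a substring of
#' each input sequence. Strings are processed in input order; the
#' accumulator is initialized from the first string's motif set and
#' intersected with each following string's set, with an early exit as soon
#' as it empties.
#'
#' Two interchangeable engines compute the per-string sets from the compact
#' exact-distance-d candidates:
#' * `"trie"` inserts candidates into a motif trie per string and
#'   intersects tries (sequential);
#' * `"radix"` expands and sorts candidates with the compact radix sort,
#'   deduplicates, and intersects sorted arrays. With `workers > 1` the
#'   per-string workloads (one per k-mer; `(2d+1)(m-l+1)` of them) are
#'   shuffled with the instance seed, split evenly across workers, each
#'   worker generates/sorts/dedupes its candidates and filters them against
#'   the accumulated common set, and the worker arrays are combined by a
#'   binary-tree union. The output is identical for every worker count.
#'
#' @param sequences Character vector of sequences over the alphabet (or an
#'   `ems_instance` from [generate_instance()], from which `l` and `d` are
#'   taken by default).
#' @param l Motif length (`l > d`).
#' @param d Distance budget (`d >= 0`).
#' @param engine `"trie"` or `"radix"`.
#' @param workers Number of workers for the radix engine (`>= 1`).
#' @param alphabet An [ems_alphabet()].
#' @param seed Seed for the workload shuffle (deterministic partition).
#' @param max_candidates Abort with an error if any string's compact
#'   candidate count exceeds this guard instead of exhausting memory.
#' @param verbose Report per-string candidate counts (compact and unique
#'   expanded) via [message()].
#' @return Sorted character vector of all common motifs.
#' @examples
#' ems_solve(c("ACGTACGT", "CCGTAAGT"), l = 4, d = 1)
#' @export
ems_solve <- function(sequences, l = NULL, d = NULL,
                      engine = c("trie", "radix"), workers = 1L,
                      alphabet = ems_alphabet(), seed = 1L,
                      max_candidates = 5e7, verbose = FALSE) {
  if (inherits(sequences, "ems_instance")) {
    inst <- sequences
    sequences <- inst$sequences
    if (is.null(l)) l <- inst$l
    if (is.null(d)) d <- inst$d
    alphabet <- inst$alphabet
  }
  engine <- match.arg(engine)
  alphabet <- as_alphabet(alphabet)
  check_params(l, d)
  if (!is.numeric(workers) || length(workers) != 1L || workers < 1) {
    stop("workers must be a single integer >= 1", call. = FALSE)
  }
  workers <- as.integer(workers)
  if (!length(sequences)) stop("no input sequences", call. = FALSE)
  sequences <- toupper(as.character(sequences))
  check_sequences(sequences, alphabet, "sequence")
  short <- nchar(sequences) < l - d
  if (any(short)) {
    stop(sprintf("sequence %d is shorter than l - d = %d",
                 which(short)[1L], l - d), call. = FALSE)
  }
  if (engine == "trie") {
    solve_trie(sequences, l, d, alphabet, max_candidates, verbose)
  } else {
    solve_radix(sequences, l, d, workers, alphabet, seed,
                max_candidates, verbose)
  }
}

solve_trie <- function(sequences, l, d, alphabet, max_candidates, verbose) {
  acc <- NULL
  for (i in seq_along(sequences)) {
    tri <- trie_from_string(sequences[[i]], l, d, rules = TRUE,
                            alphabet = alphabet,
                            max_candidates = max_candidates)
    acc <- if (i == 1L) tri else trie_intersect(acc, tri)
    if (verbose) {
      message(sprintf("string %d: %s unique l-mers, accumulator %s",
                      i, format(trie_count(tri), big.mark = ","),
                      format(trie_count(acc), big.mark = ",")))
    }
    if (trie_is_empty(acc)) return(character())
  }
  trie_enumerate(acc)
}

solve_radix <- function(sequences, l, d, workers, alphabet, seed,
                        max_candidates, verbose) {
  ab <- alphabet_string(alphabet)
  M <- NULL
  for (i in seq_along(sequences)) {
    S <- sequences[[i]]
    wl <- workload_table(nchar(S), l, d)
    perm <- with_seed(seed + i - 1L, sample.int(nrow(wl)))
    wl <- wl[perm, , drop = FALSE]
    parts <- split(seq_len(nrow(wl)),
                   rep_len(seq_len(workers), nrow(wl)))
    M_prev <- M
    worker_fun <- function(idx) {
      if (!length(idx)) return(character())
      cand <- cpp_gen_motifs(S, wl$j[idx], wl$k[idx],
                             as.integer(l), as.integer(d), TRUE)
      if (length(cand) > max_candidates) {
        stop(sprintf("per-string compact candidate count exceeds guard (%g)",
                     max_candidates), call. = FALSE)
      }
      u <- cpp_dedupe_sorted(cpp_radix_expand(cand, ab), ab)
      if (i > 1L) u <- cpp_intersect_sorted(u, M_prev, ab)
      u
    }
    res <- if (workers > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(parts, worker_fun, mc.cores = workers)
    } else {
      lapply(parts, worker_fun)
    }
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop(attr(res[[which(err)[1L]]], "condition"))
    M <- tree_merge(res, ab)
    if (verbose) {
      message(sprintf("string %d: accumulator %s motifs", i,
                      format(length(M), big.mark = ",")))
    }
    if (!length(M)) return(character())
  }
  M
}

# binary-tree union over ceil(log2(w)) rounds; pads with empty arrays
tree_merge <- function(arrays, ab) {
  w <- length(arrays)
  size <- 2^ceiling(log2(max(w, 1L)))
  if (size > w) arrays <- c(arrays, rep(list(character()), size - w))
  while (length(arrays) > 1L) {
    half <- length(arrays) / 2L
    arrays <- lapply(seq_len(half), function(q) {
      cpp_union_sorted(arrays[[2L * q - 1L]], arrays[[2L * q]], ab)
    })
  }
  arrays[[1L]]
}
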