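# Shared fixtures and independent oracles for the test suite.

DNA <- ems_alphabet("dna")

rand_dna <- function(m) {
  paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = "")
}

# Independent oracle: the recursive definition of unit-cost edit distance
# (memoized but otherwise literal), never the DP the package calls.
ed_recursive <- function(x, y) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == 0L) {
      j
    } else if (j == 0L) {
      i
    } else {
      cost <- if (substr(x, i, i) == substr(y, j, j)) 0L else 1L
      min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    }
    memo[[key]] <- val
    val
  }
  rec(nchar(x), nchar(y))
}

# Union of expansions of a set of compact motifs, sorted in alphabet order.
expansion_union <- function(motifs, alphabet = DNA) {
  if (!length(motifs)) return(character())
  sort_lmers(unique(unlist(lapply(motifs, expand_compact,
                                  alphabet = alphabet))), alphabet)
}

# All strings over an alphabet up to a maximum length (for exhaustive checks).
all_strings_upto <- function(symbols, max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- expand.grid(rep(list(symbols), len), stringsAsFactors = FALSE)
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# Canonical key for a tagged candidate row (provenance identity).
tag_key <- function(tagged) {
  paste(tagged$j, tagged$k, tagged$trace, sep = "|")
}
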