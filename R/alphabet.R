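#' Motif alphabets
#'
#' An alphabet fixes the ordered set of symbols candidate motifs are built
#' from, the wildcard character `*` (which stands for every symbol of the
#' alphabet at a position) and the deletion sentinel `-` (used internally to
#' mark deleted characters during neighborhood generation so that rule
#' predicates over original string positions stay evaluable). The symbol
#' order defines the lexicographic order of all motif output.
#'
#' @param x Either `"dna"` (A, C, G, T), `"protein"` (the 20 standard amino
#'   acids in alphabetical one-letter order), or a character vector of
#'   distinct single characters giving a custom alphabet.
#' @return An object of class `ems_alphabet` with components `symbols`,
#'   `wildcard` (`"*"`) and `sentinel` (`"-"`).
#' @examples
#' ems_alphabet("dna")
#' ems_alphabet(c("0", "1"))
#' @export
ems_alphabet <- function(x = "dna") {
  if (is.character(x) && length(x) == 1L && x %in% c("dna", "protein")) {
    symbols <- switch(x,
      dna = c("A", "C", "G", "T"),
      protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    )
  } else {
    symbols <- as.character(x)
  }
  if (length(symbols) < 2L) {
    stop("an alphabet needs at least two symbols", call. = FALSE)
  }
  if (any(nchar(symbols) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be distinct", call. = FALSE)
  }
  if (any(symbols %in% c("*", "-"))) {
    stop("'*' and '-' are reserved (wildcard and deletion sentinel)",
         call. = FALSE)
  }
  structure(
    list(symbols = symbols, wildcard = "*", sentinel = "-"),
    class = "ems_alphabet"
  )
}

#' @export
print.ems_alphabet <- function(x, ...) {
  cat("<ems_alphabet> ", paste(x$symbols, collapse = ""),
      " (wildcard '", x$wildcard, "', sentinel '", x$sentinel, "')\n",
      sep = "")
  invisible(x)
}

as_alphabet <- function(alphabet) {
  if (inherits(alphabet, "ems_alphabet")) alphabet else ems_alphabet(alphabet)
}

alphabet_string <- function(alphabet) {
  paste(alphabet$symbols, collapse = "")
}

# Validate that strings use only alphabet symbols (no wildcard/sentinel).
check_sequences <- function(x, alphabet, what = "sequence") {
  bad <- vapply(
    strsplit(x, ""),
    function(ch) any(!ch %in% alphabet$symbols),
    logical(1)
  )
  if (any(bad)) {
    stop(sprintf("%s %s contains characters outside the alphabet [%s]",
                 what, which(bad)[1L], alphabet_string(alphabet)),
         call. = FALSE)
  }
  invisible(x)
}

check_compact <- function(x, alphabet, what = "compact motif") {
  ok <- c(alphabet$symbols, alphabet$wildcard)
  bad <- vapply(
    strsplit(x, ""),
    function(ch) any(!ch %in% ok),
    logical(1)
  )
  if (any(bad)) {
    stop(sprintf("%s %s contains characters outside the alphabet [%s] + '*'",
                 what, which(bad)[1L], alphabet_string(alphabet)),
         call. = FALSE)
  }
  invisible(x)
}

#' Sort strings in alphabet order
#'
#' Lexicographic sort induced by the alphabet's symbol order (independent of
#' locale and of ASCII codes for custom alphabets).
#'
#' @param x Character vector of equal-length strings over the alphabet.
#' @param alphabet An [ems_alphabet()].
#' @return `x` sorted.
#' @export
sort_lmers <- function(x, alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  if (!length(x)) return(x)
  key_syms <- rawToChar(as.raw(64L + seq_along(alphabet$symbols)), multiple = TRUE)
  key <- chartr(alphabet_string(alphabet), paste(key_syms, collapse = ""), x)
  x[order(key, method = "radix")]
}

# RNG scoping: run code under a seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
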