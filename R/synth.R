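#' Random Hamming neighbor of an l-mer
#'
#' Draws a neighbor of `x` at Hamming distance exactly `d` (the default
#' used to plant motif occurrences): `d` positions chosen uniformly without
#' replacement, each changed to a uniformly chosen different symbol. With
#' `at_most = TRUE` each chosen position instead receives a uniform symbol
#' from the whole alphabet, giving Hamming distance at most `d` (a
#' sensitivity-check variant).
#'
#' @param x An l-mer over the alphabet.
#' @param d Number of positions to mutate, `0 <= d <= nchar(x)`.
#' @param alphabet An [ems_alphabet()].
#' @param at_most Draw a distance-`<= d` neighbor instead of exactly `d`.
#' @return A single l-mer.
#' @export
hamming_neighbor <- function(x, d, alphabet = ems_alphabet(),
                             at_most = FALSE) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(length(x) == 1L)
  check_sequences(x, alphabet, "string")
  l <- nchar(x)
  if (d < 0 || d > l) {
    stop("d must satisfy 0 <= d <= nchar(x)", call. = FALSE)
  }
  if (d == 0) return(x)
  ch <- strsplit(x, "")[[1]]
  pos <- sample.int(l, d)
  for (p in pos) {
    pool <- if (at_most) alphabet$symbols else setdiff(alphabet$symbols, ch[p])
    ch[p] <- pool[sample.int(length(pool), 1L)]
  }
  paste(ch, collapse = "")
}

#' Generate a random (planted) EMS instance
#'
#' The standard planted-instance model for motif-search benchmarks:
#' `n` i.i.d. uniform random strings of length `m` over the alphabet; when
#' `plant = TRUE`, a random motif `M` of length `l` is drawn and, in each
#' string independently, a fresh Hamming-distance-exactly-`d` neighbor of
#' `M` overwrites a uniformly chosen length-`l` window. Unplanted instances
#' (`plant = FALSE`) are the background model used to estimate spurious
#' motif counts.
#'
#' @param l,d Problem parameters (`l > d >= 0`).
#' @param n Number of strings (default 20).
#' @param m String length (default 600).
#' @param plant Plant a motif occurrence in every string?
#' @param alphabet An [ems_alphabet()].
#' @param seed Optional seed; a fixed seed reproduces the instance exactly.
#' @return An object of class `ems_instance`: a list with `sequences`,
#'   `l`, `d`, `alphabet`, `seed`, and (when planted) `planted$motif` plus
#'   `planted$positions` (1-based window starts).
#' @examples
#' inst <- generate_instance(l = 8, d = 1, n = 5, m = 100, seed = 7)
#' inst
#' @export
generate_instance <- function(l, d, n = 20L, m = 600L, plant = TRUE,
                              alphabet = ems_alphabet(), seed = NULL) {
  alphabet <- as_alphabet(alphabet)
  check_params(l, d)
  stopifnot(n >= 1L)
  if (m < l) stop("m must be at least l", call. = FALSE)
  syms <- alphabet$symbols
  with_seed(seed, {
    sequences <- vapply(seq_len(n), function(i) {
      paste(sample(syms, m, replace = TRUE), collapse = "")
    }, character(1))
    planted <- NULL
    if (plant) {
      motif <- paste(sample(syms, l, replace = TRUE), collapse = "")
      positions <- integer(n)
      for (i in seq_len(n)) {
        occ <- hamming_neighbor(motif, d, alphabet)
        pos <- sample.int(m - l + 1L, 1L)
        substr(sequences[i], pos, pos + l - 1L) <- occ
        positions[i] <- pos
      }
      planted <- list(motif = motif, positions = positions)
    }
    structure(
      list(sequences = sequences, l = l, d = d, alphabet = alphabet,
           planted = planted, seed = seed),
      class = "ems_instance"
    )
  })
}

#' @export
print.ems_instance <- function(x, ...) {
  cat(sprintf("<ems_instance> (%d,%d), n = %d, m = %d, alphabet %s%s\n",
              x$l, x$d, length(x$sequences), nchar(x$sequences[1]),
              alphabet_string(x$alphabet),
              if (is.null(x$planted)) ", unplanted"
              else paste0(", planted motif ", x$planted$motif)))
  invisible(x)
}

#' Duplication statistics of compact neighborhood generation
#'
#' Runs compact candidate generation over every k-mer of a string and
#' measures how often each distinct compact motif string is generated: the
#' multiset size, the distinct count, their ratio (mean multiplicity) and
#' the full multiplicity histogram. The skip rules keep the mean close to 1
#' (exactly 1 on strings whose characters are all distinct); without them
#' the same compact motif is produced by many different edit traces.
#'
#' @inheritParams gen_all
#' @return An object of class `ems_repstats`: list with `total_generated`,
#'   `distinct`, `mean_multiplicity` and `histogram` (data.frame with
#'   `multiplicity` and `count`, counts summing to `distinct`).
#' @export
repetition_stats <- function(S, l, d, rules = TRUE,
                             alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  check_params(l, d)
  check_sequences(S, alphabet, "string")
  wl <- workload_table(nchar(S), l, d)
  if (is.null(wl) || !nrow(wl)) stop("string shorter than l - d", call. = FALSE)
  st <- cpp_gen_stats(S, wl$j, wl$k, as.integer(l), as.integer(d), rules)
  structure(
    list(total_generated = st$total, distinct = st$distinct,
         mean_multiplicity = st$total / st$distinct,
         histogram = data.frame(multiplicity = st$multiplicity,
                                count = st$count)),
    class = "ems_repstats"
  )
}

#' @export
print.ems_repstats <- function(x, ...) {
  cat(sprintf(
    "<ems_repstats> %s generated / %s distinct = mean multiplicity %.3f\n",
    format(x$total_generated, big.mark = ","),
    format(x$distinct, big.mark = ","), x$mean_multiplicity))
  invisible(x)
}

#' Monte-Carlo estimate of the expected spurious motif count
#'
#' Spurious motifs are motifs reported on purely random input by chance.
#' This estimates their expected number for given `(l, d, n, m)` by
#' generating unplanted random instances and counting the motifs the exact
#' solver reports, returning the mean and its standard error over
#' replicates.
#'
#' @inheritParams generate_instance
#' @param replicates Number of independent unplanted instances (`>= 1`).
#' @param engine,workers Passed to [ems_solve()].
#' @return An object of class `ems_spurious`: list with `mean`, `se`,
#'   `counts` (per replicate) and the model parameters.
#' @export
estimate_spurious <- function(l, d, n = 20L, m = 600L, replicates = 5L,
                              alphabet = ems_alphabet(), seed = NULL,
                              engine = "radix", workers = 1L) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(replicates >= 1L)
  sub_seeds <- with_seed(seed, sample.int(2^31 - 1L, replicates))
  counts <- vapply(seq_len(replicates), function(r) {
    inst <- generate_instance(l, d, n = n, m = m, plant = FALSE,
                              alphabet = alphabet, seed = sub_seeds[r])
    length(ems_solve(inst, engine = engine, workers = workers,
                     seed = sub_seeds[r] %% 2^20))
  }, numeric(1))
  structure(
    list(mean = mean(counts),
         se = if (replicates > 1L) stats::sd(counts) / sqrt(replicates)
              else NA_real_,
         counts = counts, l = l, d = d, n = n, m = m,
         replicates = replicates),
    class = "ems_spurious"
  )
}

#' @export
print.ems_spurious <- function(x, ...) {
  cat(sprintf(
    "<ems_spurious> (%d,%d) n = %d, m = %d: %.1f +/- %.1f motifs (%d replicates)\n",
    x$l, x$d, x$n, x$m, x$mean, if (is.na(x$se)) 0 else x$se, x$replicates))
  invisible(x)
}
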