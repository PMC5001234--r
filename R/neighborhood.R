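#' Three-phase plan for exact-distance-d generation
#'
#' For a k-mer, the exact-distance-d length-l friendhood is generated by
#' applying delta deletions, then beta substitutions, then alpha insertions
#' with `delta + beta + alpha = d` and `k - delta + alpha = l`. Solving
#' those constraints with `q = k - l` gives
#' `max(0, q) <= delta <= floor((d + q) / 2)`, `alpha = delta - q`,
#' `beta = d - 2 * delta + q`. This function returns all admissible triples.
#'
#' @param k k-mer length, `l - d <= k <= l + d`.
#' @param l Motif length.
#' @param d Distance budget.
#' @return A data.frame with columns `delta`, `beta`, `alpha`, one row per
#'   admissible triple, and attributes `k` and `q`.
#' @examples
#' phase_plan(k = 8, l = 8, d = 2)
#' @export
phase_plan <- function(k, l, d) {
  check_params(l, d)
  if (k < l - d || k > l + d) {
    stop(sprintf("k = %d outside [l - d, l + d] = [%d, %d]", k, l - d, l + d),
         call. = FALSE)
  }
  k <- as.integer(k); l <- as.integer(l); d <- as.integer(d)
  q <- k - l
  delta <- seq.int(max(0L, q), (d + q) %/% 2L)
  plan <- data.frame(delta = delta, beta = d - 2L * delta + q,
                     alpha = delta - q)
  attr(plan, "k") <- k
  attr(plan, "q") <- q
  plan
}

workload_table <- function(m, l, d) {
  ks <- seq.int(l - d, min(l + d, m))
  ks <- ks[ks >= 1L]
  do.call(rbind, lapply(ks, function(k) {
    data.frame(j = seq_len(m - k + 1L), k = k)
  }))
}

#' Per-string generation workloads
#'
#' One workload is the friendhood generation task for one k-mer `(j, k)` of
#' a string. For `m >= l + d` there are exactly `(2d + 1) * (m - l + 1)`
#' workloads, the unit the parallel solver distributes across workers.
#'
#' @param m String length.
#' @param l,d Problem parameters.
#' @return A data.frame with columns `j` (1-based start) and `k` (length).
#' @export
ems_workloads <- function(m, l, d) {
  check_params(l, d)
  wl <- workload_table(m, l, d)
  if (is.null(wl) || !nrow(wl)) {
    stop("string shorter than l - d: no workloads", call. = FALSE)
  }
  wl
}

#' Compact friendhood of one k-mer
#'
#' Generates the tagged compact (l,d)-friend candidates of the k-mer
#' `S[j..j+k-1]`: every trace of exactly d edit operations (deletions, then
#' substitutions, then insertions) that turns the k-mer into a length-l
#' compact motif, where substituted and inserted positions carry the
#' wildcard `*`. With `rules = TRUE`, candidates matched by any of the nine
#' duplication-avoiding skip rules are not emitted; the union of expansions
#' is unchanged (completeness) but most duplicate compact motifs disappear.
#'
#' @param S A string over the alphabet.
#' @param j 1-based start of the k-mer.
#' @param k k-mer length, `l - d <= k <= l + d`.
#' @param l,d Problem parameters (`l > d >= 0`).
#' @param rules Apply the skip rules (default `TRUE`).
#' @param tagged If `TRUE` return a data.frame with provenance columns
#'   `j`, `k`, `trace` (e.g. `"2D,5I"`, ops sorted by position with
#'   D < R < I) and `motif`; otherwise a character vector of compact motifs.
#' @param alphabet An [ems_alphabet()].
#' @return Character vector or data.frame, in generation order.
#' @export
gen_friends <- function(S, j, k, l, d, rules = TRUE, tagged = FALSE,
                        alphabet = ems_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  check_params(l, d)
  check_sequences(S, alphabet, "string")
  if (k < l - d || k > l + d) {
    stop(sprintf("k = %d outside [l - d, l + d]", k), call. = FALSE)
  }
  if (j < 1 || j + k - 1 > nchar(S)) {
    stop("k-mer (j, k) outside the string", call. = FALSE)
  }
  if (tagged) {
    as.data.frame(cpp_gen_tagged(S, as.integer(j), as.integer(k),
                                 as.integer(l), as.integer(d), rules),
                  stringsAsFactors = FALSE)
  } else {
    cpp_gen_motifs(S, as.integer(j), as.integer(k),
                   as.integer(l), as.integer(d), rules)
  }
}

#' Compact (l,d)-motif candidates of a whole string
#'
#' Concatenation of [gen_friends()] over every k-mer of `S` with
#' `l - d <= k <= l + d`. The union of the expansions of the result equals
#' the exact motif set of `S` (the completeness guarantee the skip rules
#' preserve), with or without the rules.
#'
#' @inheritParams gen_friends
#' @param chunk_fun Optional function called once per k-mer length `k` with
#'   the character vector of compact motifs generated for that `k`; when
#'   supplied, `gen_all()` streams chunks through it and returns (invisibly)
#'   the total candidate count instead of materializing the full multiset.
#' @return Character vector of compact motifs (or a tagged data.frame), in
#'   generation order; with `chunk_fun`, the total count, invisibly.
#' @examples
#' gen_all("ACGT", l = 3, d = 1)
#' @export
gen_all <- function(S, l, d, rules = TRUE, tagged = FALSE,
                    alphabet = ems_alphabet(), chunk_fun = NULL) {
  alphabet <- as_alphabet(alphabet)
  check_params(l, d)
  check_sequences(S, alphabet, "string")
  wl <- workload_table(nchar(S), l, d)
  if (is.null(wl) || !nrow(wl)) {
    stop("string shorter than l - d", call. = FALSE)
  }
  if (!is.null(chunk_fun)) {
    stopifnot(!tagged)
    total <- 0
    for (k in unique(wl$k)) {
      idx <- wl$k == k
      chunk <- cpp_gen_motifs(S, wl$j[idx], wl$k[idx],
                              as.integer(l), as.integer(d), rules)
      total <- total + length(chunk)
      chunk_fun(chunk)
    }
    return(invisible(total))
  }
  if (tagged) {
    as.data.frame(cpp_gen_tagged(S, wl$j, wl$k, as.integer(l),
                                 as.integer(d), rules),
                  stringsAsFactors = FALSE)
  } else {
    cpp_gen_motifs(S, wl$j, wl$k, as.integer(l), as.integer(d), rules)
  }
}

#' Parse a trace string
#'
#' Converts the `trace` column emitted by tagged generation (e.g.
#' `"2D,3R,5I"`) into a data.frame of edit operations.
#'
#' @param trace A single trace string; `""` is the empty trace.
#' @return data.frame with integer `p` and character `o` (one of D, R, I).
#' @export
parse_trace <- function(trace) {
  stopifnot(length(trace) == 1L)
  if (!nzchar(trace)) {
    return(data.frame(p = integer(), o = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trace, ",", fixed = TRUE)[[1]]
  data.frame(
    p = as.integer(sub("[DRI]$", "", parts)),
    o = sub("^[0-9]+", "", parts),
    stringsAsFactors = FALSE
  )
}

#' Duplication-avoiding skip rules
#'
#' Decides whether a (partial or complete) tagged candidate is skipped by
#' one of the nine rules that prune duplicate compact motifs. A rule matches
#' on membership of edit-operation tuples `<p, o>` in the trace, together
#' with the position of the k-mer in the string. In every rule `t >= 0`.
#'
#' The rules (for the k-mer starting at `j`, length `k`, in a string of
#' length `m`):
#' 1. `j + k <= m` and the leftmost base is deleted.
#' 2. A substitution immediately follows a deleted position.
#' 3. `j + k <= m` and positions `j..j+t` are all substituted with
#'    position `j+t+1` deleted.
#' 4. An insertion at a deleted position.
#' 5. An insertion just after a deleted position.
#' 6. An insertion at a substituted position.
#' 7. `j > 1` and an insertion at the leftmost position.
#' 8. `j > 1` and positions `j..j+t` all substituted with an insertion at
#'    `j+t+1`.
#' 9. `j + k <= m` and an insertion at the right end (`p = j + k`).
#'
#' @param j,k 1-based start and length of the k-mer.
#' @param m Length of the parent string.
#' @param trace Either a trace string (see [parse_trace()]) or a data.frame
#'   with columns `p` and `o`.
#' @return A list with `skip` (logical) and `rule` (lowest matching rule id,
#'   or `NA` if none matches).
#' @export
should_skip <- function(j, k, m, trace) {
  if (is.character(trace)) trace <- parse_trace(trace)
  has <- function(p, o) any(trace$p == p & trace$o == o)
  run_then <- function(o2) {
    # exists t >= 0 with R at j..j+t and o2 at j+t+1
    t <- 0L
    while (has(j + t, "R")) {
      if (has(j + t + 1L, o2)) return(TRUE)
      t <- t + 1L
    }
    FALSE
  }
  dels <- trace$p[trace$o == "D"]
  subs <- trace$p[trace$o == "R"]
  fired <- c(
    j + k <= m && has(j, "D"),                              # 1
    any(vapply(dels, function(p) has(p + 1L, "R"), logical(1))),  # 2
    j + k <= m && run_then("D"),                            # 3
    any(vapply(dels, function(p) has(p, "I"), logical(1))),       # 4
    any(vapply(dels, function(p) has(p + 1L, "I"), logical(1))),  # 5
    any(vapply(subs, function(p) has(p, "I"), logical(1))),       # 6
    j > 1 && has(j, "I"),                                   # 7
    j > 1 && run_then("I"),                                 # 8
    j + k <= m && has(j + k, "I")                           # 9
  )
  if (any(fired)) list(skip = TRUE, rule = which(fired)[1L])
  else list(skip = FALSE, rule = NA_integer_)
}
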