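test_that("phase_plan solves the three-phase arithmetic", {
  p <- phase_plan(k = 10, l = 8, d = 2)        # k = l + d: deletions only
  expect_identical(nrow(p), 1L)
  expect_identical(unlist(p[1, ]), c(delta = 2L, beta = 0L, alpha = 0L))

  p <- phase_plan(k = 8, l = 8, d = 2)
  expect_identical(p$delta, 0:1)
  expect_identical(p$beta, c(2L, 0L))
  expect_identical(p$alpha, c(0L, 1L))

  p <- phase_plan(k = 7, l = 8, d = 1)
  expect_identical(unlist(p[1, ]), c(delta = 0L, beta = 0L, alpha = 1L))

  for (l in 3:8) {
    for (d in 0:3) {
      if (l <= d) next
      for (k in (l - d):(l + d)) {
        p <- phase_plan(k, l, d)
        expect_gt(nrow(p), 0L)
        expect_true(all(p$alpha >= 0L & p$beta >= 0L & p$delta >= 0L))
        expect_true(all(p$delta + p$beta + p$alpha == d))
        expect_true(all(k - p$delta + p$alpha == l))
      }
    }
  }
  expect_error(phase_plan(11, 8, 2), "outside")
})

test_that("gen_friends reproduces the worked per-k-mer friendhoods", {
  # rightmost 4-mer of ACGT at (3,1): all four deletions survive (rule 1
  # needs j + k <= m)
  expect_setequal(gen_friends("ACGT", 1, 4, 3, 1),
                  c("CGT", "AGT", "ACT", "ACG"))
  # interior 2-mer "CG": only the middle insertion survives (rules 7 and 9)
  expect_identical(gen_friends("ACGT", 2, 2, 3, 1), "C*G")
  # rightmost 2-mer "GT": right-end insertion allowed since j + k > m
  expect_setequal(gen_friends("ACGT", 3, 2, 3, 1), c("G*T", "GT*"))
})

test_that("gen_all emits the full compact candidate set of a string", {
  g <- gen_all("ACGT", 3, 1)
  expect_setequal(g, c("CGT", "AGT", "ACT", "ACG",
                       "*CG", "A*G", "AC*", "*GT", "C*T", "CG*",
                       "*AC", "A*C", "C*G", "G*T", "GT*"))
  expect_identical(anyDuplicated(g), 0L)

  # d = 0: exactly the m - l + 1 substrings, wildcard-free
  S <- rand_dna(12)
  expect_identical(sort(gen_all(S, 4, 0)),
                   sort(substring(S, 1:9, 4:12)))
})

test_that("every emitted trace has exactly d ops and motif length l", {
  set.seed(50)
  for (r in 1:5) {
    S <- rand_dna(sample(8:15, 1))
    l <- sample(3:5, 1)
    d <- sample(1:2, 1)
    tg <- gen_all(S, l, d, tagged = TRUE)
    expect_true(all(nchar(tg$motif) == l))
    nops <- vapply(tg$trace, function(tr) nrow(parse_trace(tr)), integer(1))
    expect_true(all(nops == d))
    # at k = l + d only deletion traces occur
    kmax <- tg$k == l + d
    if (any(kmax)) {
      expect_false(any(grepl("[RI]", tg$trace[kmax])))
    }
  }
})

test_that("generation-time rule guards equal post-hoc rule filtering", {
  set.seed(51)
  for (r in 1:5) {
    S <- rand_dna(sample(8:14, 1))
    m <- nchar(S)
    l <- sample(3:5, 1)
    d <- sample(1:2, 1)
    off <- gen_all(S, l, d, rules = FALSE, tagged = TRUE)
    on <- gen_all(S, l, d, rules = TRUE, tagged = TRUE)
    keep <- !vapply(seq_len(nrow(off)), function(i) {
      should_skip(off$j[i], off$k[i], m, off$trace[i])$skip
    }, logical(1))
    expect_identical(sort(tag_key(off[keep, ])), sort(tag_key(on)))
  }
})

test_that("should_skip implements the nine rules literally", {
  # deleting the leftmost base of a non-rightmost k-mer
  expect_identical(should_skip(1, 3, 4, "1D"), list(skip = TRUE, rule = 1L))
  # substitution just after a deletion
  expect_identical(should_skip(2, 4, 10, "3D,4R")$rule, 2L)
  # insertion at the leftmost position needs j > 1
  expect_false(should_skip(1, 3, 10, "1I")$skip)
  expect_identical(should_skip(2, 3, 10, "2I")$rule, 7L)
  # run of substitutions from j then a deletion, non-rightmost k-mer
  expect_identical(should_skip(1, 4, 10, "1R,2R,3D")$rule, 3L)
  expect_false(should_skip(1, 4, 4, "1R,2R,3D")$skip)   # rightmost: kept
  # insertions at/after a deleted position
  expect_identical(should_skip(1, 4, 4, "2D,2I")$rule, 4L)
  expect_identical(should_skip(1, 4, 4, "2D,3I")$rule, 5L)
  # insertion at a substituted position
  expect_identical(should_skip(1, 4, 4, "2R,2I")$rule, 6L)
  # run of substitutions from j then an insertion, j > 1
  expect_identical(should_skip(2, 4, 10, "2R,3I")$rule, 8L)
  # right-end insertion of a non-rightmost k-mer
  expect_identical(should_skip(1, 3, 10, "4I")$rule, 9L)
  expect_false(should_skip(1, 3, 3, "4I")$skip)
  expect_false(should_skip(1, 3, 10, "")$skip)
})

test_that("rules remove only duplicates, never coverage", {
  set.seed(52)
  for (r in 1:8) {
    S <- rand_dna(sample(10:20, 1))
    l <- sample(3:5, 1)
    d <- sample(1:2, 1)
    on <- gen_all(S, l, d, rules = TRUE)
    off <- gen_all(S, l, d, rules = FALSE)
    expect_lte(length(on), length(off))
    expect_setequal(unique(on), unique(off))
    oracle <- oracle_motifs_one_string(S, l, d)
    expect_identical(expansion_union(on), oracle)
    expect_identical(expansion_union(off), oracle)
  }
})

test_that("generation is duplication-free on all-distinct characters", {
  big <- ems_alphabet(LETTERS[1:20])
  set.seed(53)
  for (r in 1:10) {
    S <- paste(sample(LETTERS[1:20], 18), collapse = "")
    g <- gen_all(S, l = 5, d = 3, alphabet = big)
    expect_identical(anyDuplicated(g), 0L)
  }
})

test_that("gen_all streams per-k chunks through a callback", {
  chunks <- list()
  total <- gen_all("ACGTACGT", 4, 1,
                   chunk_fun = function(x) chunks[[length(chunks) + 1]] <<- x)
  expect_identical(sum(lengths(chunks)), as.integer(total))
  expect_setequal(unlist(chunks), gen_all("ACGTACGT", 4, 1))
})
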