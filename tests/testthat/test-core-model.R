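test_that("edit_distance matches the recursive definition and is a metric", {
  expect_identical(edit_distance("ACGT", "ACGT"), 0L)
  expect_identical(edit_distance("ACGT", "AGT"), 1L)
  expect_identical(edit_distance("ACGT", "TGCA"),
                   as.integer(ed_recursive("ACGT", "TGCA")))

  # exhaustive over a 2-letter alphabet, strings of length <= 3
  ab <- ems_alphabet(c("A", "C"))
  strs <- all_strings_upto(c("A", "C"), 3)
  n <- length(strs)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- edit_distance(strs[i], strs[j], ab)
      expect_identical(D[i, j], as.integer(ed_recursive(strs[i], strs[j])))
    }
  }
  expect_true(all(D == t(D)))
  expect_identical(D == 0L, outer(strs, strs, "=="))  # identity of indiscernibles
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      expect_true(all(D[i, j] <= D[i, ] + D[, j]))   # triangle inequality
    }
  }
})

test_that("edit_distance rejects characters outside the alphabet", {
  expect_error(edit_distance("ACGN", "ACG"), "outside the alphabet")
})

test_that("expand_compact enumerates exactly |Sigma|^wildcards l-mers", {
  expect_identical(expand_compact("ACG"), "ACG")
  expect_identical(expand_compact("*GT"), c("AGT", "CGT", "GGT", "TGT"))
  e <- expand_compact("**")
  expect_length(e, 16L)
  expect_identical(e, sort_lmers(unique(e)))

  set.seed(41)
  for (r in 1:20) {
    l <- sample(1:4, 1)
    a <- paste(sample(c("A", "C", "G", "T", "*"), l, TRUE), collapse = "")
    nw <- lengths(regmatches(a, gregexpr("*", a, fixed = TRUE)))
    expect_length(expand_compact(a), 4^nw)
  }
})

test_that("compact_intersect agrees with set intersection of expansions", {
  expect_identical(compact_intersect("*GT", "AG*"), "AGT")
  expect_null(compact_intersect("AC", "AG"))
  expect_identical(compact_intersect("A*", "A*"), "A*")
  expect_error(compact_intersect("AC", "ACG"), "same length")

  set.seed(42)
  for (r in 1:200) {
    l <- sample(1:4, 1)
    a <- paste(sample(c("A", "C", "G", "T", "*"), l, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "*"), l, TRUE), collapse = "")
    ab <- compact_intersect(a, b)
    want <- intersect(expand_compact(a), expand_compact(b))
    got <- if (is.null(ab)) character() else expand_compact(ab)
    expect_setequal(got, want)
  }
})

test_that("grow_one_edit is the one-edit ball minus the string itself", {
  g <- grow_one_edit("A")
  expect_setequal(g, c("", "C", "G", "T",
                       "AA", "CA", "GA", "TA", "AC", "AG", "AT"))
  expect_setequal(grow_one_edit(""), c("A", "C", "G", "T"))
  set.seed(43)
  for (r in 1:10) {
    L <- rand_dna(sample(1:5, 1))
    g <- grow_one_edit(L)
    expect_false(L %in% g)
    expect_true(all(edit_distance(g, L) == 1L))
  }
})

test_that("the two oracle variants agree and match exact substrings at d = 0", {
  expect_identical(oracle_motifs_one_string("ACGT", 3, 0), c("ACG", "CGT"))
  s11 <- oracle_motifs_one_string("AAAA", 4, 1)
  expect_true("AAAA" %in% s11)
  expect_true(all(c("CAAA", "ACAA", "AACA", "AAAC") %in% s11))

  set.seed(44)
  for (r in 1:8) {
    m <- sample(6:10, 1)
    l <- sample(3:4, 1)
    d <- sample(0:2, 1)
    if (l <= d) d <- l - 1L
    S <- rand_dna(m)
    expect_identical(
      oracle_motifs_one_string(S, l, d, method = "scan"),
      oracle_motifs_one_string(S, l, d, method = "grow")
    )
  }
})

test_that("neighborhood equals the union of exact-distance friend sets", {
  # N_{l,d}(L) = union over t of F_{l,t}(L), F_{l,t}(L) = length-l strings
  # in the t-th one-edit growth of L
  set.seed(45)
  for (r in 1:6) {
    l <- sample(3:4, 1)
    d <- sample(1:2, 1)
    L <- rand_dna(sample((l - d):(l + d), 1))
    cur <- L
    friends <- if (nchar(L) == l) L else character()
    for (t in seq_len(d)) {
      cur <- unique(unlist(lapply(cur, grow_one_edit)))
      friends <- union(friends, cur[nchar(cur) == l])
    }
    lmers <- expand_compact(paste(rep("*", l), collapse = ""))
    neigh <- lmers[vapply(lmers, function(x) {
      as.integer(utils::adist(x, L)) <= d
    }, logical(1))]
    expect_setequal(friends, neigh)
  }
})

test_that("the common-motif oracle intersects per-string motif sets", {
  s <- oracle_motifs_one_string("ACGTAC", 3, 1)
  expect_identical(oracle_common_motifs("ACGTAC", 3, 1), s)
  expect_identical(oracle_common_motifs(c("ACGTAC", "ACGTAC"), 3, 1), s)
  expect_identical(oracle_common_motifs(c("ACGT", "TTTT"), 4, 0), character())
})

test_that("parameter validation rejects l <= d and bad inputs", {
  expect_error(oracle_motifs_one_string("ACGT", 2, 2), "l must exceed d")
  expect_error(oracle_motifs_one_string("ACG", 8, 1), "shorter than l - d")
  expect_error(oracle_motifs_one_string("ACGN", 3, 1), "outside the alphabet")
})
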