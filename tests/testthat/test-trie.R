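test_that("inserting a compact motif produces subset-labelled paths", {
  tr <- motif_trie(3)
  expect_true(trie_is_empty(tr))
  trie_insert(tr, "*GT")
  # single path: edge {A,C,G,T}, then {G}, then {T}
  expect_identical(emsfinder:::cpp_trie_node_count(tr$ptr), 4L)
  expect_identical(emsfinder:::cpp_trie_root_labels(tr$ptr), "ACGT")
  expect_identical(trie_enumerate(tr), c("AGT", "CGT", "GGT", "TGT"))

  trie_insert(tr, "A*C")
  expect_setequal(trie_enumerate(tr),
                  c("AGT", "CGT", "GGT", "TGT", "AAC", "ACC", "AGC", "ATC"))
  expect_true(trie_validate(tr))

  # idempotence
  before <- trie_enumerate(tr)
  trie_insert(tr, "*GT")
  expect_identical(trie_enumerate(tr), before)
})

test_that("edge labels stay mutually exclusive under random insertions", {
  set.seed(60)
  for (r in 1:20) {
    l <- sample(2:4, 1)
    tr <- motif_trie(l)
    motifs <- replicate(sample(1:12, 1), {
      paste(sample(c("A", "C", "G", "T", "*"), l, TRUE), collapse = "")
    })
    trie_insert(tr, motifs)
    expect_true(trie_validate(tr))
    enum <- trie_enumerate(tr)
    expect_identical(enum, expansion_union(motifs))   # sorted, duplicate-free
    expect_identical(trie_count(tr), as.double(length(enum)))
  }
})

test_that("trie intersection equals set intersection of expansions", {
  t1 <- motif_trie(3); trie_insert(t1, c("*GT", "A*C"))
  t2 <- motif_trie(3); trie_insert(t2, c("AG*", "C*T"))
  expect_identical(trie_enumerate(trie_intersect(t1, t2)),
                   c("AGC", "AGT", "CGT"))

  empty <- motif_trie(3)
  expect_true(trie_is_empty(trie_intersect(t1, empty)))
  expect_identical(trie_enumerate(trie_intersect(t1, t1)),
                   trie_enumerate(t1))

  set.seed(61)
  for (r in 1:15) {
    l <- sample(2:3, 1)
    mk <- function() {
      tr <- motif_trie(l)
      trie_insert(tr, replicate(sample(1:6, 1), {
        paste(sample(c("A", "C", "G", "T", "*"), l, TRUE), collapse = "")
      }))
      tr
    }
    a <- mk(); b <- mk(); c3 <- mk()
    ab <- trie_intersect(a, b)
    expect_identical(trie_enumerate(ab),
                     sort_lmers(intersect(trie_enumerate(a),
                                          trie_enumerate(b))))
    expect_true(trie_validate(ab))
    # commutative and associative at the expansion level
    expect_identical(trie_enumerate(trie_intersect(b, a)),
                     trie_enumerate(ab))
    expect_identical(
      trie_enumerate(trie_intersect(trie_intersect(a, b), c3)),
      trie_enumerate(trie_intersect(a, trie_intersect(b, c3)))
    )
  }
})

test_that("trie_from_string expands to the exact per-string motif set", {
  tr <- trie_from_string("ACGT", 3, 0)
  expect_identical(trie_enumerate(tr), c("ACG", "CGT"))

  set.seed(62)
  for (r in 1:15) {
    S <- rand_dna(sample(10:30, 1))
    l <- sample(3:6, 1)
    d <- sample(0:2, 1)
    if (l <= d) d <- l - 1L
    tr <- trie_from_string(S, l, d)
    expect_identical(trie_enumerate(tr), oracle_motifs_one_string(S, l, d))
    expect_true(trie_validate(tr))
  }

  # strings with disjoint motif sets intersect to the empty trie
  t1 <- trie_from_string("AAAAAA", 4, 0)
  t2 <- trie_from_string("CCCCCC", 4, 0)
  expect_true(trie_is_empty(trie_intersect(t1, t2)))
})

test_that("trie operations validate lengths and alphabets", {
  tr <- motif_trie(3)
  expect_error(trie_insert(tr, "ACGT"), "length")
  expect_error(trie_insert(tr, "AC-"), "outside the alphabet")
  expect_error(trie_intersect(tr, motif_trie(4)), "depth")
})
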