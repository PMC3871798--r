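test_that("dot-bracket parsing builds validated, sorted pair sets", {
  s <- parse_vienna(c(">hp", "GGAAACC", "((...))"))
  expect_equal(unname(s$pairs), cbind(c(2L, 1L), c(6L, 7L)))
  expect_equal(s$id, "hp")

  s0 <- parse_vienna(c(">x", "ACGU", "...."))
  expect_equal(nrow(s0$pairs), 0L)

  expect_error(parse_vienna(c(">x", "ACGU", "((..")), "unbalanced '\\(' at position 1")
  expect_error(parse_vienna(c(">x", "ACGU", "))..")), "unbalanced '\\)' at position 1")
  expect_error(parse_vienna(c(">x", "ACGUA", "....")), "does not match")
  expect_error(parse_vienna(c(">x", "ACGUA", "[...]")), "unsupported structure character")
})

test_that("structure invariants are enforced", {
  expect_error(structured_rna("ACGU", cbind(1L, 5L)), "left < right")
  expect_error(structured_rna("ACGUAC", cbind(c(1L, 1L), c(4L, 6L))), "more than one")
  expect_error(structured_rna("ACGUACGU", cbind(c(1L, 3L), c(5L, 8L))), "crossing")
  expect_error(structured_rna("ACXU", NULL), "invalid nucleotide")
  expect_silent(structured_rna("ACGNU", cbind(1L, 5L)))
})

test_that("pair relations classify as nested or juxtaposed", {
  expect_equal(classify_relation(c(2, 6), c(1, 7)), "i_enclosed_by_j")
  expect_equal(classify_relation(c(1, 7), c(2, 6)), "j_enclosed_by_i")
  expect_equal(classify_relation(c(1, 4), c(5, 8)), "i_before_j")
  expect_equal(classify_relation(c(5, 8), c(1, 4)), "j_before_i")
  expect_error(classify_relation(c(1, 5), c(3, 8)), "crossing")
  expect_error(classify_relation(c(2, 6), c(2, 6)), "distinct")
})

test_that("parents and F sets follow the directly-before rule", {
  s <- parse_vienna(c(">a", "GGCCGGCC", "(())(())"))
  # pairs sorted by right endpoint: (2,3), (1,4), (6,7), (5,8)
  expect_equal(unname(s$pairs[, 2]), c(3L, 4L, 7L, 8L))
  expect_equal(s$parent, c(2L, 0L, 4L, 0L))        # (2,3) in (1,4); (6,7) in (5,8)
  expect_equal(f_set(s, 4L), 2L)                   # F((5,8)) = {(1,4)}
  expect_equal(f_set(s, 1L), integer(0))           # F((2,3)) empty

  s2 <- parse_vienna(c(">b", "GCGCGC", "()()()"))
  expect_equal(s2$f_prev, c(0L, 1L, 2L))           # only the direct predecessor

  s3 <- parse_vienna(c(">c", "GCGGCC", "()(())"))
  expect_equal(s3$parent, c(0L, 3L, 0L))           # (4,5) inside (3,6)
  expect_equal(f_set(s3, 3L), 1L)                  # F((3,6)) = {(1,2)}
  expect_equal(f_set(s3, 2L), integer(0))          # F((4,5)) empty
})

test_that("loop regions follow the 1-based inclusive conventions", {
  s <- parse_vienna(c(">hp", "GGAAACC", "((...))"))
  expect_equal(loop_region(s, "hairpin", c(2, 6)),
               c(start = 3L, end = 5L, length = 3L))
  expect_equal(loop_region(s, "left_internal", c(2, 6), c(1, 7))[["length"]], 0L)
  expect_equal(loop_region(s, "right_internal", c(2, 6), c(1, 7))[["length"]], 0L)

  s2 <- parse_vienna(c(">m", "GGCCAGGCC", "(()).(())"))
  expect_equal(loop_region(s2, "between", c(1, 4), c(6, 9)),
               c(start = 5L, end = 5L, length = 1L))
  expect_error(loop_region(s2, "between", c(6, 9), c(1, 4)), "requires")
  expect_error(loop_region(s2, "left_internal", c(1, 4), c(6, 9)), "requires")
})

test_that("serialisation round-trips sequence and dot-bracket exactly", {
  for (seed in 1:5) {
    s <- random_structure(gen_params(target_length = 60L, target_pairs = 9L,
                                     seed = seed))
    txt <- write_vienna(s)
    s2 <- parse_vienna(txt)
    expect_identical(s2$seq, s$seq)
    expect_identical(as_dotbracket(s2), as_dotbracket(s))
    expect_identical(unname(s2$pairs), unname(s$pairs))
  }
})

test_that("pairs plus loop regions partition every nucleotide", {
  for (seed in 1:8) {
    s <- random_structure(gen_params(target_length = 50L, target_pairs = 7L,
                                     seed = 100L + seed))
    # walk the pseudo-root partition: every position is in exactly one pair
    # or one loop region
    covered <- rep(0L, s$length)
    n <- nrow(s$pairs)
    for (k in seq_len(n)) covered[s$pairs[k, ]] <- covered[s$pairs[k, ]] + 1L
    # loop positions = those under no pair deeper than their innermost pair
    unpaired <- which(covered == 0L)
    expect_equal(2L * n + length(unpaired), s$length)
    expect_true(all(covered <= 1L))
    # parent consistency
    for (k in seq_len(n)) {
      p <- s$parent[k]
      if (p > 0L) {
        expect_true(s$pairs[p, 1] < s$pairs[k, 1] && s$pairs[k, 2] < s$pairs[p, 2])
      }
      f <- s$f_prev[k]
      if (f > 0L) expect_lt(s$pairs[f, 2], s$pairs[k, 1])
    }
  }
})

test_that("bpseq files read into validated structures", {
  tf <- tempfile(fileext = ".bpseq")
  writeLines(c("1 G 7", "2 G 6", "3 A 0", "4 A 0", "5 A 0", "6 C 2", "7 C 1"), tf)
  s <- read_bpseq(tf, id = "hp")
  expect_equal(s$seq, "GGAAACC")
  expect_equal(unname(s$pairs), cbind(c(2L, 1L), c(6L, 7L)))

  writeLines(c("1 G 3", "2 G 0", "3 C 2"), tf)
  expect_error(read_bpseq(tf), "inconsistent")
})

test_that("shipped example files parse and agree across formats", {
  va <- system.file("extdata", "synthetic_a.vienna", package = "opmalign")
  ba <- system.file("extdata", "synthetic_a.bpseq", package = "opmalign")
  s1 <- read_vienna(va)[[1]]
  s2 <- read_bpseq(ba)
  expect_identical(s1$seq, s2$seq)
  expect_identical(unname(s1$pairs), unname(s2$pairs))
  cfg <- system.file("extdata", "default_scoring.yaml", package = "opmalign")
  sch <- read_scoring_config(cfg)
  expect_equal(sch$R, scoring_scheme()$R)
})
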