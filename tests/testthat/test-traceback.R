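test_that("alignment objects respect column and matching invariants", {
  sch <- scoring_scheme()
  for (seed in c(2L, 12L, 31L)) {
    inst <- random_instance(seed, l_range = c(30L, 55L), max_pairs = 10L)
    a <- align_structures(inst$a, inst$b, sch)
    expect_equal(nchar(a$aligned_a), nchar(a$aligned_b))
    expect_identical(gsub("-", "", a$aligned_a, fixed = TRUE), inst$a$seq)
    expect_identical(gsub("-", "", a$aligned_b, fixed = TRUE), inst$b$seq)
    # matched pair partners occupy mutually consistent columns
    ca <- strsplit(a$aligned_a, "")[[1]]; cb <- strsplit(a$aligned_b, "")[[1]]
    cum_a <- cumsum(ca != "-"); cum_b <- cumsum(cb != "-")
    for (k in seq_len(nrow(a$matching))) {
      col_l <- which(cum_a == a$matching$left_a[k] & ca != "-")[1L]
      col_r <- which(cum_a == a$matching$right_a[k] & ca != "-")[1L]
      expect_equal(cum_b[col_l], a$matching$left_b[k])
      expect_equal(cum_b[col_r], a$matching$right_b[k])
      expect_equal(substr(a$structure_a, col_l, col_l), "(")
      expect_equal(substr(a$structure_a, col_r, col_r), ")")
    }
    # one-to-one matching and exact decomposition
    expect_false(anyDuplicated(a$matching$pair_a) > 0)
    expect_false(anyDuplicated(a$matching$pair_b) > 0)
    expect_identical(a$score_total, sparse_align(inst$a, inst$b, sch)$score)
    # broken pairs render as unpaired characters
    expect_equal(sum(strsplit(a$structure_a, "")[[1]] == "("), nrow(a$matching))
  }
})

test_that("sparse and full tracebacks recompose to the same optimum", {
  sch <- scoring_scheme()
  inst <- random_instance(44L, l_range = c(30L, 50L), max_pairs = 9L)
  af <- align_structures(inst$a, inst$b, sch, engine = "full")
  as_ <- align_structures(inst$a, inst$b, sch, engine = "sparse")
  expect_identical(af$score_total, as_$score_total)
  rec <- recompose_score(as_, inst$a, inst$b, sch)
  expect_equal(rec$total, as_$score_total)
})

test_that("recomposition rejects inconsistent matchings", {
  sch <- scoring_scheme()
  # two couples whose relations disagree across the structures
  sa <- structured_rna("GCGGCC", cbind(c(1L, 3L), c(2L, 6L)))  # (1,2) before (3,6)
  sb <- structured_rna("GGCCGC", cbind(c(2L, 5L), c(3L, 6L)))  # (2,3) inside? no: (2,3) <J (5,6)
  fake <- list(matching = tibble::tibble(
    pair_a = c(1L, 2L), pair_b = c(2L, 1L),
    left_a = c(1L, 3L), right_a = c(2L, 6L),
    left_b = c(5L, 2L), right_b = c(6L, 3L)))
  expect_error(recompose_score(fake, sa, sb, sch), "inconsistent matching")
})

test_that("empty matching recomposes to the pure sequence score", {
  sch <- scoring_scheme()
  sa <- structured_rna("ACGGUA", NULL)
  sb <- structured_rna("ACGUA", NULL)
  a <- align_structures(sa, sb, sch)
  expect_equal(nrow(a$matching), 0L)
  rec <- recompose_score(a, sa, sb, sch)
  expect_equal(rec$structure, 0)
  expect_equal(rec$total, align_loops_affine(sa$seq, sb$seq, sch))
})

test_that("sum-of-pairs score counts reproduced residue couples", {
  sch <- scoring_scheme()
  inst <- random_instance(3L, l_range = c(30L, 45L), max_pairs = 8L)
  ref <- align_structures(inst$a, inst$b, sch)
  expect_equal(sps(ref, ref), 1.0)

  # an alignment with no common residue couples: gap everything
  allgap <- ref
  allgap$aligned_a <- paste0(inst$a$seq, strrep("-", inst$b$length))
  allgap$aligned_b <- paste0(strrep("-", inst$a$length), inst$b$seq)
  expect_equal(sps(allgap, ref), 0.0)

  # half of four couples reproduced
  mk <- function(ra, rb) {
    x <- ref
    x$aligned_a <- ra; x$aligned_b <- rb
    x$seq_a <- gsub("-", "", ra, fixed = TRUE)
    x$seq_b <- gsub("-", "", rb, fixed = TRUE)
    x
  }
  r1 <- mk("ACGU", "ACGU")
  t1 <- mk("ACGU--", "AC--GU")
  expect_equal(sps(t1, r1), 0.5)
  expect_error(sps(mk("AAAA", "AAAA"), r1), "same sequences")
})

test_that("tidy and glance summarise an alignment", {
  sch <- scoring_scheme()
  inst <- random_instance(6L, l_range = c(30L, 45L), max_pairs = 8L)
  a <- align_structures(inst$a, inst$b, sch)
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(a$matching))
  expect_true(all(c("dinuc_a", "dinuc_b") %in% names(td)))
  gl <- glance(a)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$score_total, a$score_total)
  expect_equal(gl$n_matched + gl$n_broken_a, nrow(inst$a$pairs))
})

test_that("Stockholm output round-trips and marks gaps consistently", {
  sch <- scoring_scheme()
  s <- parse_vienna(c(">hp", "GGAAACC", "((...))"))
  a <- align_structures(s, s, sch)
  txt <- write_stockholm(a)
  expect_equal(txt[1], "# STOCKHOLM 1.0")
  rt <- read_stockholm(txt)
  expect_equal(unname(rt$seqs[a$id_a]), a$aligned_a)
  expect_equal(unname(rt$ss[a$id_b]), a$structure_b)
  expect_false(grepl("-", a$aligned_a, fixed = TRUE))

  fx <- insertion_fixture()
  a2 <- align_structures(fx$a, fx$b, sch)
  txt2 <- write_stockholm(a2)
  rt2 <- read_stockholm(txt2)
  row_b <- unname(rt2$seqs[a2$id_b])
  expect_equal(lengths(regmatches(row_b, gregexpr("-", row_b, fixed = TRUE))), 1L)

  # degenerate: two empty sequences give a header-only file
  e <- align_structures(structured_rna("", NULL, id = "e1"),
                        structured_rna("", NULL, id = "e2"), sch)
  expect_equal(write_stockholm(e), c("# STOCKHOLM 1.0", "//"))
})
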