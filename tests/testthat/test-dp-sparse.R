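test_that("sparsification is lossless under all option combinations", {
  sch <- scoring_scheme()
  for (seed in 1:30) {
    inst <- random_instance(seed, l_range = c(30L, 60L), max_pairs = 12L)
    ref <- full_align(inst$a, inst$b, sch)$score
    for (prune in c(TRUE, FALSE)) {
      for (gate in c(TRUE, FALSE)) {
        st <- sparse_align(inst$a, inst$b, sch, prune = prune, mh_gate = gate)
        expect_identical(st$score, ref,
                         info = sprintf("seed %d prune %s gate %s", seed, prune, gate))
      }
    }
  }
})

test_that("pairless inputs yield z = 0 and the plain sequence score", {
  sch <- scoring_scheme()
  sa <- structured_rna("ACGGUAAC", NULL)
  sb <- structured_rna("AGGUAC", NULL)
  st <- sparse_align(sa, sb, sch)
  expect_identical(st$score, align_loops_affine(sa$seq, sb$seq, sch))
  expect_equal(st$stats$z_peak, 0)
  expect_equal(st$stats$z_final, 0)
})

test_that("identical stacked helices detect stacked OPMs and prune inner ones", {
  sch <- scoring_scheme()
  inst <- helix_instance()  # five perfectly stacked identical pairs
  st <- sparse_align(inst$a, inst$b, sch, prune = TRUE)
  diag_opms <- dplyr::filter(st$opms, .data$pair_a == .data$pair_b)
  expect_equal(nrow(diag_opms), 5L)           # every self-matching detected
  expect_lt(sum(diag_opms$alive), 5L)         # inner stacked OPMs removed
  expect_gt(st$stats$opms_pruned, 0)
  # pruning did not change the optimum
  expect_identical(st$score, sparse_align(inst$a, inst$b, sch, prune = FALSE)$score)
  # perfect stacking means zero re-splitting bounds for adjacent pairs
  u <- prune_bounds(c(1L, 1L), c(2L, 2L), inst$a, inst$b, sch)
  expect_equal(unname(u), c(0, 0))
})

test_that("per-run accounting of the OPM list is consistent", {
  sch <- scoring_scheme()
  for (seed in c(2L, 7L, 13L)) {
    inst <- random_instance(seed, l_range = c(40L, 60L), max_pairs = 12L)
    st <- sparse_align(inst$a, inst$b, sch)
    expect_equal(st$stats$z_final, st$stats$z_peak - st$stats$opms_pruned)
    expect_lte(st$stats$z_peak, nrow(inst$a$pairs) * nrow(inst$b$pairs))
    expect_equal(st$stats$z_final, sum(st$opms$alive))
    expect_equal(st$stats$opms_pruned, nrow(st$prune_events))
    # OPMs are discovered in nondecreasing right-endpoint order
    ra <- inst$a$pairs[st$opms$pair_a, 2L]
    expect_true(all(diff(ra) >= 0))
  }
})

test_that("detection decisions replay from logged M and span scores", {
  sch <- scoring_scheme()
  inst <- random_instance(5L, l_range = c(30L, 50L), max_pairs = 10L)
  st <- sparse_align(inst$a, inst$b, sch)
  full <- full_align(inst$a, inst$b, sch, m_bar = TRUE)
  na <- nrow(inst$a$pairs); nb <- nrow(inst$b$pairs)
  # the sparse engine's span scores agree with the baseline's
  expect_identical(st$m_bar[-1, -1], full$m_bar[-1, -1])
  # every detected OPM satisfied the criterion; every undetected couple failed it
  detected <- matrix(FALSE, na, nb)
  detected[cbind(st$opms$pair_a, st$opms$pair_b)] <- TRUE
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      expect_equal(detected[i, j],
                   detect_opm(st$M[i + 1L, j + 1L], st$m_bar[i + 1L, j + 1L]))
    }
  }
})

test_that("boundary detection uses >= (ties are OPMs)", {
  expect_true(detect_opm(10, 10))
  expect_false(detect_opm(9, 10))
  expect_true(detect_opm(11, 10))
})

test_that("span scores dominate restricted matchings on random instances", {
  sch <- scoring_scheme()
  for (seed in c(1L, 8L)) {
    inst <- random_instance(seed + 20L, l_range = c(25L, 45L), max_pairs = 8L)
    st <- sparse_align(inst$a, inst$b, sch)
    # M_bar >= M always (the couple's matching is one span interpretation)
    expect_true(all(st$m_bar[-1, -1] >= st$M[-1, -1], na.rm = TRUE))
  }
})

test_that("identical structures detect every self-matching as an OPM", {
  sch <- scoring_scheme()
  for (seed in c(4L, 11L)) {
    s <- random_structure(gen_params(target_length = 50L, target_pairs = 8L,
                                     seed = seed))
    st <- sparse_align(s, s, sch, prune = FALSE)
    n <- nrow(s$pairs)
    detected <- dplyr::filter(st$opms, .data$pair_a == .data$pair_b)
    expect_equal(sort(detected$pair_a), seq_len(n))
  }
})

test_that("pruning removals satisfy the replayed criterion and keep all cells", {
  sch <- scoring_scheme()
  for (seed in c(3L, 9L, 21L)) {
    inst <- random_instance(seed, l_range = c(40L, 60L), max_pairs = 12L)
    on_ <- sparse_align(inst$a, inst$b, sch, prune = TRUE, mh_gate = FALSE)
    off <- sparse_align(inst$a, inst$b, sch, prune = FALSE, mh_gate = FALSE)
    # no later M cell changed by any removal
    expect_identical(on_$M, off$M)
    # each logged removal re-derives from the bound formula
    for (k in seq_len(nrow(on_$prune_events))) {
      ev <- on_$prune_events[k, ]
      u <- prune_bounds(c(ev$inner_a, ev$inner_b), c(ev$outer_a, ev$outer_b),
                        inst$a, inst$b, sch)
      expect_equal(unname(c(ev$u_left, ev$u_right)), unname(u))
      expect_gte(ev$gap, sum(u))
    }
  }
})

test_that("an enclosed OPM with large re-splitting bounds is retained", {
  sch <- scoring_scheme()
  # inner helix far from the outer pair: big gap regions, bound exceeds the
  # score difference, so the inner OPM survives
  s <- structured_rna("GAAAAGGGAAACCCAAAAC",
                      cbind(c(1L, 6L, 7L, 8L), c(19L, 14L, 13L, 12L)))
  st <- sparse_align(s, s, sch, prune = TRUE)
  inner_alive <- dplyr::filter(st$opms, .data$pair_a == .data$pair_b,
                               .data$pair_a %in% 1:3)
  expect_true(any(inner_alive$alive))
})

test_that("the hairpin gate never changes the optimum and skips work", {
  sch <- scoring_scheme()
  skipped_total <- 0
  for (seed in c(6L, 14L, 25L)) {
    inst <- random_instance(seed, l_range = c(40L, 60L), max_pairs = 12L)
    on_ <- sparse_align(inst$a, inst$b, sch, mh_gate = TRUE)
    off <- sparse_align(inst$a, inst$b, sch, mh_gate = FALSE)
    expect_identical(on_$score, off$score)
    expect_identical(on_$M, off$M)
    skipped_total <- skipped_total + on_$stats$mh_cells_skipped
    # wherever both were computed, the bound dominates Mh
    na <- nrow(inst$a$pairs); nb <- nrow(inst$b$pairs)
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        bound <- hairpin_upper_bound(inst$a$pairs[i, ], inst$b$pairs[j, ],
                                     sch, inst$a, inst$b)
        expect_gte(bound, off$Mh[i + 1L, j + 1L])
      }
    }
  }
  expect_gt(skipped_total, 0)
})

test_that("the gate decision function mirrors the engine rule", {
  sch <- scoring_scheme()
  s <- random_structure(gen_params(target_length = 40L, target_pairs = 6L, seed = 2L))
  p <- s$pairs[nrow(s$pairs), ]
  bound <- hairpin_upper_bound(p, p, sch, s, s)
  expect_equal(mh_gate(p, p, bound + 1, sch, s, s), "skip_Mh")
  expect_equal(mh_gate(p, p, bound, sch, s, s), "compute_Mh")
  expect_equal(mh_gate(p, p, NA, sch, s, s), "compute_Mh")
  expect_equal(mh_gate(p, p, -Inf, sch, s, s), "compute_Mh")
})

test_that("prune bound formula matches hand substitutions", {
  # r_max = 6, d_max = 2, g = -5, e = -1, weights 1
  D <- matrix(-1, 4, 4, dimnames = list(NUC4, NUC4)); diag(D) <- 2
  R <- matrix(0, 16, 16, dimnames = list(DINUC16, DINUC16)); diag(R) <- 6
  sch <- scoring_scheme(R = R, D = D, g = -5, e = -1, w1 = 1, w2 = 1)
  expect_equal(prune_bound_formula(1, 0, 2, 0, sch), 6 + 2 * 8)
  expect_equal(prune_bound_formula(0, 0, 0, 0, sch), 0)
  expect_equal(prune_bound_formula(0, 2, 0, 3, sch), 12 + 24)
})

test_that("prune_obsolete applies the removal criterion to an OPM list", {
  sch <- scoring_scheme()
  inst <- helix_instance()
  st <- sparse_align(inst$a, inst$b, sch, prune = FALSE)
  opms <- st$opms
  # replay the pruning pass for the outermost self-matching
  out <- prune_obsolete(opms, c(5L, 5L), inst$a, inst$b, sch)
  expect_gt(attr(out, "removed"), 0)
  expect_lt(sum(out$alive), nrow(out))
  expect_error(prune_obsolete(opms, c(99L, 99L), inst$a, inst$b, sch), "not in")
})
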