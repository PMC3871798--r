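str_payload <- function(s) {
  list(seq = encode_seq(s$seq),
       left = as.integer(s$pairs[, 1L]),
       right = as.integer(s$pairs[, 2L]))
}

scheme_payload <- function(sch) {
  list(R = sch$scaled$R, D = sch$scaled$D, g = sch$scaled$g, e = sch$scaled$e,
       r_max = sch$scaled$r_max, d_max = sch$scaled$d_max)
}

unscale <- function(m) m / 100

new_dpstate <- function(res, engine, sa, sb, sch, options = list()) {
  structure(
    list(score = res$score_raw / 100,
         M = unscale(res$M), Mh = unscale(res$Mh), Ml = unscale(res$Ml),
         M_raw = res$M,
         m_bar = if (!is.null(res$Mbar)) unscale(res$Mbar) else NULL,
         engine = engine, options = options,
         sa = sa, sb = sb, scheme = sch),
    class = "rna_dpstate"
  )
}

#' Baseline structure alignment (all base-pair combinations)
#'
#' The quartic-time reference engine: for every combination of base pairs
#' `(p_A, p_B)` (plus the pseudo-roots) it computes the optimal alignment
#' score `M[p_A, p_B]` of the enclosed regions given that the two pairs are
#' matched, as the maximum of the hairpin interpretation `Mh` (every inner
#' pair broken, interiors aligned as sequence) and the multi-loop
#' interpretation `Ml` (a chain of matched inner couples, with the loop
#' segments delimited by matched pairs aligned independently under affine
#' gaps). The total score is `M` at the pseudo-root couple. This engine
#' serves as the exactness oracle for [sparse_align].
#'
#' @param sa,sb [structured_rna] inputs (either may be pairless).
#' @param sch A [scoring_scheme].
#' @param m_bar When `TRUE`, also compute the unrestricted optimal
#'   alignment score of the one-pair spans `A[l..r] x B[l'..r']` for every
#'   real couple (the quantity the sparse engine compares against for OPM
#'   detection).
#' @return An `rna_dpstate` with `score`, tables `M`, `Mh`, `Ml` (row/col 1
#'   is the pseudo-root; `NA` marks uncomputed interpretations), and
#'   optionally `m_bar`.
#' @seealso [sparse_align], [align_structures], [trace_alignment]
#' @export
full_align <- function(sa, sb, sch = scoring_scheme(), m_bar = FALSE) {
  stopifnot(inherits(sa, "structured_rna"), inherits(sb, "structured_rna"),
            inherits(sch, "scoring_scheme"))
  res <- cpp_full_align(str_payload(sa), str_payload(sb), scheme_payload(sch), m_bar)
  new_dpstate(res, "full", sa, sb, sch)
}

#' Sparse structure alignment restricted to optimal pair matchings
#'
#' Computes the same optimum as [full_align] in expected cubic time by
#' restricting the multi-loop recursion to Optimal Pair Matchings (OPMs):
#' couples `(p_A, p_B)` whose matched score `M[p_A, p_B]` is at least the
#' unrestricted optimal alignment score of their spans. Only OPMs can
#' contribute to an optimal alignment, so chains range over the online OPM
#' list. Two further devices cut constant factors: a hairpin upper bound
#' skips the interior sequence alignment when the multi-loop value already
#' dominates it, and an online pruning rule drops an enclosed OPM once an
#' enclosing OPM dominates it by more than the largest possible gain of
#' re-splitting around it.
#'
#' @param sa,sb [structured_rna] inputs.
#' @param sch A [scoring_scheme].
#' @param prune Apply online OPM pruning (default `TRUE`).
#' @param mh_gate Apply the hairpin upper-bound gate (default `TRUE`).
#' @return An `rna_dpstate` as for [full_align], plus: `m_bar` (span scores
#'   used by detection), `opms` (tibble of detected OPMs with their `M`
#'   values and alive status), `stats` (a [sparse_stats] list), and
#'   `prune_events` (one row per pruned OPM with the two Eq.-style upper
#'   bounds and the score gap that triggered removal).
#' @export
sparse_align <- function(sa, sb, sch = scoring_scheme(), prune = TRUE,
                         mh_gate = TRUE) {
  stopifnot(inherits(sa, "structured_rna"), inherits(sb, "structured_rna"),
            inherits(sch, "scoring_scheme"))
  res <- cpp_sparse_align(str_payload(sa), str_payload(sb), scheme_payload(sch),
                          prune, mh_gate)
  st <- new_dpstate(res, "sparse", sa, sb, sch,
                    options = list(prune = prune, mh_gate = mh_gate))
  st$opms <- tibble::tibble(
    pair_a = res$opm_pairs[, 1L],
    pair_b = res$opm_pairs[, 2L],
    score = res$opm_scores / 100,
    alive = res$opm_pairs[, 3L] == 1L
  )
  st$stats <- list(
    z_final = res$z_final, z_peak = res$z_peak,
    opms_pruned = res$opms_pruned,
    mh_cells_computed = res$mh_cells_computed,
    mh_cells_skipped = res$mh_cells_skipped,
    loop_alignments_computed = res$loop_alignments_computed
  )
  pe <- res$prune_log
  st$prune_events <- tibble::tibble(
    outer_a = as.integer(pe[, 1L]), outer_b = as.integer(pe[, 2L]),
    inner_a = as.integer(pe[, 3L]), inner_b = as.integer(pe[, 4L]),
    u_left = pe[, 5L] / 100, u_right = pe[, 6L] / 100, gap = pe[, 7L] / 100
  )
  st
}

#' Run statistics of a sparse alignment
#'
#' @param state An `rna_dpstate` from [sparse_align].
#' @return A one-row tibble with `z_final`, `z_peak`, `opms_pruned`,
#'   `mh_cells_computed`, `mh_cells_skipped`, `loop_alignments_computed`.
#' @export
sparse_stats <- function(state) {
  stopifnot(inherits(state, "rna_dpstate"), state$engine == "sparse")
  tibble::as_tibble(state$stats)
}

#' @export
print.rna_dpstate <- function(x, ...) {
  cat(sprintf("rna_dpstate (%s engine): '%s' (%d bp) vs '%s' (%d bp), score %.2f\n",
              x$engine, x$sa$id, nrow(x$sa$pairs), x$sb$id, nrow(x$sb$pairs),
              x$score))
  if (x$engine == "sparse") {
    cat(sprintf("  OPMs: %d alive / %d detected, %d pruned; Mh cells skipped: %d\n",
                x$stats$z_final, x$stats$z_peak, x$stats$opms_pruned,
                x$stats$mh_cells_skipped))
  }
  invisible(x)
}

#' Precompute loop-region sequence similarities
#'
#' Builds the table of `w2`-weighted affine-gap similarity scores between
#' the loop regions the baseline recursion can request: every hairpin
#' interior of `sa` against every hairpin interior of `sb` (including the
#' whole sequences, the pseudo-root interiors). Entries equal
#' [align_loops_affine] on the corresponding regions.
#'
#' @param sa,sb [structured_rna] inputs.
#' @param sch A [scoring_scheme].
#' @return A tibble with one row per region combination: pair indices
#'   (0 = pseudo-root), region coordinates, and `score`.
#' @export
precompute_loop_similarities <- function(sa, sb, sch = scoring_scheme()) {
  regions <- function(s) {
    k <- c(0L, seq_len(nrow(s$pairs)))
    tibble::tibble(
      pair = k,
      start = c(1L, if (nrow(s$pairs)) s$pairs[, 1L] + 1L),
      end = c(s$length, if (nrow(s$pairs)) s$pairs[, 2L] - 1L)
    )
  }
  ra <- regions(sa)
  rb <- regions(sb)
  grid <- expand.grid(ia = seq_len(nrow(ra)), ib = seq_len(nrow(rb)))
  sub <- function(s, a, b) if (a > b) "" else substr(s$seq, a, b)
  tibble::tibble(
    pair_a = ra$pair[grid$ia], pair_b = rb$pair[grid$ib],
    start_a = ra$start[grid$ia], end_a = ra$end[grid$ia],
    start_b = rb$start[grid$ib], end_b = rb$end[grid$ib],
    score = vapply(seq_len(nrow(grid)), function(k) {
      align_loops_affine(sub(sa, ra$start[grid$ia[k]], ra$end[grid$ia[k]]),
                         sub(sb, rb$start[grid$ib[k]], rb$end[grid$ib[k]]), sch)
    }, numeric(1))
  )
}
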