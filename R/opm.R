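#' OPM detection criterion
#'
#' A couple `(p_A, p_B)` is an Optimal Pair Matching when its matched
#' score `M[p_A, p_B]` is at least the unrestricted optimal alignment
#' score of the one-pair spans (the couple's own matching is then one
#' optimal interpretation of the spans, so no outer cell ever needs a
#' non-OPM couple).
#'
#' @param m_value `M[p_A, p_B]`.
#' @param m_bar_value Unrestricted span score (see [compute_m_bar]).
#' @return `TRUE` iff `m_value >= m_bar_value` (ties count as OPMs).
#' @export
detect_opm <- function(m_value, m_bar_value) {
  m_value >= m_bar_value
}

#' Unrestricted span alignment score of a couple
#'
#' Computes the optimal alignment score of `A[l(p_A)..r(p_A)]` against
#' `B[l(p_B)..r(p_B)]` with no restriction on whether `p_A` matches `p_B`
#' (the comparison value for OPM detection; conceptually the `M` value of
#' one-column-extended pseudo pairs, which carry no structure score and
#' clamp at the sequence ends). Uses the baseline engine, so it is an
#' independent reference for the sparse engine's internal detection
#' values.
#'
#' @param sa,sb [structured_rna] inputs.
#' @param k_a,k_b Pair indices (rows of `sa$pairs` / `sb$pairs`).
#' @param sch A [scoring_scheme].
#' @return Numeric score.
#' @export
compute_m_bar <- function(sa, sb, k_a, k_b, sch = scoring_scheme()) {
  state <- full_align(sa, sb, sch, m_bar = TRUE)
  state$m_bar[k_a + 1L, k_b + 1L]
}

#' Upper bound on the re-splitting gain around an enclosed OPM
#'
#' The Eq.-11-style bound used by online pruning: when an OPM `o` encloses
#' an OPM `o_chi` on both structures, the advantage of re-splitting a
#' future alignment through `o_chi` instead of `o` is bounded on each side
#' by the best case of re-matching every base pair and every nucleotide of
#' the gap regions between the two pairs:
#' `U = max(m_A, m_B) * w1*r_max + max(len_A, len_B) * w2*(d_max - g - e)`,
#' where `m` counts base pairs annotated inside the gap region and `len`
#' is the region length. The left bound uses the regions strictly between
#' the left endpoints of the two pairs, the right bound those between the
#' right endpoints; for perfectly stacked pairs both regions are empty and
#' the bound is zero.
#'
#' @param o_inner,o_outer Couples as integer vectors `c(pair_a, pair_b)`
#'   of indices into `sa$pairs` / `sb$pairs`; `o_inner` must be enclosed
#'   by `o_outer` on both structures.
#' @param sa,sb The [structured_rna] inputs.
#' @param sch A [scoring_scheme].
#' @return Named numeric vector `c(u_left, u_right)`.
#' @export
prune_bounds <- function(o_inner, o_outer, sa, sb, sch) {
  pa_i <- sa$pairs[o_inner[1L], ]; pb_i <- sb$pairs[o_inner[2L], ]
  pa_o <- sa$pairs[o_outer[1L], ]; pb_o <- sb$pairs[o_outer[2L], ]
  if (classify_relation(pa_i, pa_o) != "i_enclosed_by_j" ||
      classify_relation(pb_i, pb_o) != "i_enclosed_by_j") {
    stop("o_inner must be enclosed by o_outer on both structures")
  }
  u_left <- prune_bound_formula(
    pairs_within(sa, pa_o[1L] + 1L, pa_i[1L] - 1L),
    pairs_within(sb, pb_o[1L] + 1L, pb_i[1L] - 1L),
    pa_i[1L] - pa_o[1L] - 1L, pb_i[1L] - pb_o[1L] - 1L, sch)
  u_right <- prune_bound_formula(
    pairs_within(sa, pa_i[2L] + 1L, pa_o[2L] - 1L),
    pairs_within(sb, pb_i[2L] + 1L, pb_o[2L] - 1L),
    pa_o[2L] - pa_i[2L] - 1L, pb_o[2L] - pb_i[2L] - 1L, sch)
  c(u_left = u_left, u_right = u_right)
}

#' @rdname prune_bounds
#' @param m_a,m_b Base-pair counts in the two gap regions.
#' @param len_a,len_b Gap region lengths.
#' @export
prune_bound_formula <- function(m_a, m_b, len_a, len_b, sch) {
  (max(m_a, m_b) * sch$scaled$r_max +
     max(len_a, len_b) * (sch$scaled$d_max - sch$scaled$g - sch$scaled$e)) / 100
}

#' Remove OPMs made obsolete by a newly detected enclosing OPM
#'
#' Applies the online pruning criterion: an alive OPM enclosed (on both
#' structures) by the new OPM is removed when the score gap
#' `M[o_new] - M[o_chi]` is at least the sum of the two re-splitting
#' bounds of [prune_bounds]; dominance then guarantees no later cell can
#' prefer a path through the enclosed OPM.
#'
#' The removal criterion additionally charges a freed-nucleotide guard: on
#' the alternative path through the enclosed OPM, the enclosing pair's own
#' two nucleotides realign as loop sequence, which the gap-region bounds
#' do not cover; each side therefore adds the best substitution score
#' available to the freed nucleotides (never negative).
#'
#' @param opms Tibble of OPMs (`pair_a`, `pair_b`, `score`, `alive`), as
#'   in the `opms` field of [sparse_align].
#' @param o_new Integer vector `c(pair_a, pair_b)` of the new OPM (must be
#'   present in `opms`).
#' @param sa,sb The [structured_rna] inputs.
#' @param sch A [scoring_scheme].
#' @return `opms` with pruned rows marked `alive = FALSE`; the number of
#'   removals is in `attr(, "removed")`.
#' @export
prune_obsolete <- function(opms, o_new, sa, sb, sch) {
  new_row <- which(opms$pair_a == o_new[1L] & opms$pair_b == o_new[2L])
  if (!length(new_row)) stop("o_new is not in the OPM list")
  m_new <- opms$score[new_row[1L]]
  pa_o <- sa$pairs[o_new[1L], ]; pb_o <- sb$pairs[o_new[2L], ]
  removed <- 0L
  for (i in seq_len(nrow(opms))) {
    if (!opms$alive[i] || i == new_row[1L]) next
    pa_i <- sa$pairs[opms$pair_a[i], ]; pb_i <- sb$pairs[opms$pair_b[i], ]
    enclosed <- pa_o[1L] < pa_i[1L] && pa_i[2L] < pa_o[2L] &&
      pb_o[1L] < pb_i[1L] && pb_i[2L] < pb_o[2L]
    if (!enclosed) next
    u <- prune_bounds(c(opms$pair_a[i], opms$pair_b[i]), o_new, sa, sb, sch)
    nt_guard <- function(pos_a, pos_b) {
      max(0, sch$scaled$D[substr(sa$seq, pos_a, pos_a), ],
          sch$scaled$D[substr(sb$seq, pos_b, pos_b), ]) / 100
    }
    guard <- nt_guard(pa_o[1L], pb_o[1L]) + nt_guard(pa_o[2L], pb_o[2L])
    if (m_new - opms$score[i] >= sum(u) + guard) {
      opms$alive[i] <- FALSE
      removed <- removed + 1L
    }
  }
  attr(opms, "removed") <- removed
  opms
}

#' Hairpin upper-bound gate
#'
#' Decides whether the hairpin interpretation `Mh` of a cell needs to be
#' computed: when the multi-loop value already exceeds the
#' [hairpin_upper_bound], `Ml > Mh` is certain and the interior sequence
#' alignment can be skipped without changing `M`.
#'
#' @param p_a,p_b The cell's base pairs (length-2 integer vectors).
#' @param ml_value The cell's `Ml` value (`-Inf`/`NA` when no enclosed OPM
#'   exists, in which case `Mh` must be computed).
#' @param sch A [scoring_scheme].
#' @param sa,sb The [structured_rna] inputs.
#' @return `"skip_Mh"` or `"compute_Mh"`.
#' @export
mh_gate <- function(p_a, p_b, ml_value, sch, sa, sb) {
  if (is.null(ml_value) || is.na(ml_value) || !is.finite(ml_value)) {
    return("compute_Mh")
  }
  if (ml_value > hairpin_upper_bound(p_a, p_b, sch, sa, sb)) "skip_Mh"
  else "compute_Mh"
}
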