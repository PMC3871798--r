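#' Align two fixed RNA secondary structures
#'
#' High-level interface: runs the chosen engine and recovers the full
#' alignment — the base-pair matching relation, the gapped sequence rows
#' with structure annotation, and the score decomposition into structure
#' and sequence terms.
#'
#' @param sa,sb [structured_rna] inputs.
#' @param sch A [scoring_scheme].
#' @param engine `"sparse"` (default) or `"full"`.
#' @param ... Passed to [sparse_align] (`prune`, `mh_gate`).
#' @return An `rna_alignment`; see [trace_alignment] for the fields.
#' @examples
#' s <- parse_vienna(c(">hp", "GGAAACC", "((...))"))
#' a <- align_structures(s, s)
#' a$score_total
#' @export
align_structures <- function(sa, sb, sch = scoring_scheme(),
                             engine = c("sparse", "full"), ...) {
  engine <- match.arg(engine)
  state <- if (engine == "sparse") sparse_align(sa, sb, sch, ...)
           else full_align(sa, sb, sch)
  trace_alignment(state)
}

#' Recover the alignment from a filled DP state
#'
#' Traces one optimal alignment from the `M` table of either engine. The
#' traceback is deterministic: at ties the hairpin interpretation is
#' preferred over the chain interpretation, and among equally scoring
#' chain predecessors the one with the smallest right endpoints wins.
#'
#' @param state An `rna_dpstate` from [full_align] or [sparse_align].
#' @return An `rna_alignment` with fields: `id_a`/`id_b`, the ungapped
#'   `seq_a`/`seq_b`, gapped rows `aligned_a`/`aligned_b`, per-row
#'   structure annotations `structure_a`/`structure_b` (matched pairs as
#'   brackets, broken pairs as dots, gaps as `-`), `matching` (tibble of
#'   matched pair couples with coordinates), `broken_a`/`broken_b`
#'   (indices of unmatched pairs), and the exact score decomposition
#'   `score_total = score_structure + score_sequence`.
#' @export
trace_alignment <- function(state) {
  stopifnot(inherits(state, "rna_dpstate"))
  sa <- state$sa; sb <- state$sb
  res <- cpp_traceback(str_payload(sa), str_payload(sb),
                       scheme_payload(state$scheme), state$M_raw)
  m <- res$matching
  matching <- tibble::tibble(
    pair_a = m[, 1L], pair_b = m[, 2L],
    left_a = if (nrow(m)) sa$pairs[m[, 1L], 1L] else integer(0),
    right_a = if (nrow(m)) sa$pairs[m[, 1L], 2L] else integer(0),
    left_b = if (nrow(m)) sb$pairs[m[, 2L], 1L] else integer(0),
    right_b = if (nrow(m)) sb$pairs[m[, 2L], 2L] else integer(0)
  )
  score_structure <- res$score_structure_raw / 100
  score_sequence <- res$score_sequence_raw / 100
  total <- (res$score_structure_raw + res$score_sequence_raw) / 100
  if (abs(total - state$score) > 1e-9) {
    stop(sprintf("internal error: traceback recomposition %.2f != engine score %.2f",
                 total, state$score))
  }
  out <- structure(
    list(id_a = sa$id, id_b = sb$id, seq_a = sa$seq, seq_b = sb$seq,
         aligned_a = res$aligned_a, aligned_b = res$aligned_b,
         structure_a = res$structure_a, structure_b = res$structure_b,
         matching = matching,
         broken_a = setdiff(seq_len(nrow(sa$pairs)), matching$pair_a),
         broken_b = setdiff(seq_len(nrow(sb$pairs)), matching$pair_b),
         score_total = total, score_structure = score_structure,
         score_sequence = score_sequence,
         engine = state$engine,
         stats = state$stats),
    class = "rna_alignment"
  )
  ung <- function(x) gsub("-", "", x, fixed = TRUE)
  if (ung(out$aligned_a) != sa$seq || ung(out$aligned_b) != sb$seq) {
    stop("internal error: gapped rows do not reproduce the input sequences")
  }
  out
}

#' @rdname trace_alignment
#' @export
trace_full <- function(state) {
  stopifnot(state$engine == "full")
  trace_alignment(state)
}

#' @rdname trace_alignment
#' @export
trace_sparse <- function(state) {
  stopifnot(state$engine == "sparse")
  trace_alignment(state)
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("rna_alignment (%s engine): score %.2f = structure %.2f + sequence %.2f\n",
              x$engine, x$score_total, x$score_structure, x$score_sequence))
  cat(sprintf("  %d matched base-pair couple(s); %d/%d pairs broken in %s/%s\n",
              nrow(x$matching), length(x$broken_a), length(x$broken_b),
              x$id_a, x$id_b))
  if (nchar(x$aligned_a) <= 100L) {
    cat("  ", x$structure_a, "\n  ", x$aligned_a, "\n  ", x$aligned_b, "\n  ",
        x$structure_b, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the matched base-pair couples of an alignment
#'
#' @param x An `rna_alignment`.
#' @param ... Unused.
#' @return A tibble with one row per matched couple: pair indices,
#'   coordinates in both molecules, the two dinucleotides, and the
#'   `w1`-weighted substitution score of the couple.
#' @importFrom generics tidy
#' @export
tidy.rna_alignment <- function(x, ...) {
  m <- x$matching
  dn <- function(seq, l, r) paste0(substr(seq, l, l), substr(seq, r, r))
  dplyr::mutate(
    m,
    dinuc_a = dn(x$seq_a, .data$left_a, .data$right_a),
    dinuc_b = dn(x$seq_b, .data$left_b, .data$right_b)
  )
}

#' One-row summary of an alignment
#'
#' @param x An `rna_alignment`.
#' @param ... Unused.
#' @return A one-row tibble: scores, matched/broken pair counts, alignment
#'   length, engine, and (for the sparse engine) the OPM count `z`.
#' @importFrom generics glance
#' @export
glance.rna_alignment <- function(x, ...) {
  tibble::tibble(
    score_total = x$score_total,
    score_structure = x$score_structure,
    score_sequence = x$score_sequence,
    n_matched = nrow(x$matching),
    n_broken_a = length(x$broken_a),
    n_broken_b = length(x$broken_b),
    columns = nchar(x$aligned_a),
    engine = x$engine,
    z = if (!is.null(x$stats)) x$stats$z_final else NA_real_
  )
}

#' Recompose the score of an alignment from its matching relation
#'
#' Independently recomputes the score decomposition from the base-pair
#' matching alone: the structure term sums the `w1`-weighted substitution
#' scores over matched couples; the sequence term sums the optimal
#' affine-gap similarity over the loop-region partition induced by the
#' matched pairs (broken pairs contribute their nucleotides as ordinary
#' loop sequence). For an alignment produced by either engine the result
#' equals the engine score exactly.
#'
#' @param a An `rna_alignment`.
#' @param sa,sb The aligned [structured_rna] inputs.
#' @param sch The [scoring_scheme] used.
#' @return A list with `total`, `structure` and `sequence` scores.
#' @export
recompose_score <- function(a, sa, sb, sch) {
  m <- a$matching
  k <- nrow(m)
  # order consistency: every couple pair must be nested-in-both or
  # juxtaposed-in-both, in the same direction
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        ra <- classify_relation(c(m$left_a[i], m$right_a[i]),
                                c(m$left_a[j], m$right_a[j]))
        rb <- classify_relation(c(m$left_b[i], m$right_b[i]),
                                c(m$left_b[j], m$right_b[j]))
        if (ra != rb) stop("inconsistent matching: couples ", i, " and ", j)
      }
    }
  }
  if (anyDuplicated(m$pair_a) || anyDuplicated(m$pair_b)) {
    stop("matching is not one-to-one")
  }
  dn <- function(seq, l, r) paste0(substr(seq, l, l), substr(seq, r, r))
  str_score <- 0
  if (k) {
    str_score <- sum(vapply(seq_len(k), function(i) {
      basepair_score(dn(sa$seq, m$left_a[i], m$right_a[i]),
                     dn(sb$seq, m$left_b[i], m$right_b[i]), sch)
    }, numeric(1)))
  }
  # loop partition induced by the matched pairs, walked recursively
  sub <- function(s, from, to) if (from > to) "" else substr(s$seq, from, to)
  seq_score <- 0
  walk <- function(a_lo, a_hi, b_lo, b_hi, couples) {
    # couples: indices into m, all with spans within [a_lo, a_hi] x [b_lo, b_hi]
    if (length(couples)) {
      top <- couples[vapply(couples, function(i) {
        !any(vapply(couples, function(j) {
          j != i && m$left_a[j] < m$left_a[i] && m$right_a[i] < m$right_a[j]
        }, logical(1)))
      }, logical(1))]
      top <- top[order(m$right_a[top])]
    } else {
      top <- integer(0)
    }
    ca <- a_lo; cb <- b_lo
    for (i in top) {
      seq_score <<- seq_score +
        align_loops_affine(sub(sa, ca, m$left_a[i] - 1L),
                           sub(sb, cb, m$left_b[i] - 1L), sch)
      inner <- setdiff(couples, i)
      inner <- inner[m$left_a[inner] > m$left_a[i] & m$right_a[inner] < m$right_a[i]]
      walk(m$left_a[i] + 1L, m$right_a[i] - 1L,
           m$left_b[i] + 1L, m$right_b[i] - 1L, inner)
      ca <- m$right_a[i] + 1L; cb <- m$right_b[i] + 1L
    }
    seq_score <<- seq_score + align_loops_affine(sub(sa, ca, a_hi), sub(sb, cb, b_hi), sch)
  }
  walk(1L, sa$length, 1L, sb$length, seq_len(k))
  list(total = str_score + seq_score, structure = str_score, sequence = seq_score)
}

#' Sum-of-pairs score of a test alignment against a reference
#'
#' The fraction of residue-residue couples aligned in the reference that
#' the test alignment reproduces. Gap couples are excluded, the standard
#' convention. A reference with no aligned residue couples yields `NA`.
#'
#' @param test,reference `rna_alignment` objects over the same sequences.
#' @return A fraction in `[0, 1]` (or `NA`).
#' @export
sps <- function(test, reference) {
  if (test$seq_a != reference$seq_a || test$seq_b != reference$seq_b) {
    stop("test and reference must align the same sequences")
  }
  pairs_of <- function(a) {
    ca <- strsplit(a$aligned_a, "")[[1]] != "-"
    cb <- strsplit(a$aligned_b, "")[[1]] != "-"
    ia <- cumsum(ca); ib <- cumsum(cb)
    k <- which(ca & cb)
    paste(ia[k], ib[k])
  }
  ref <- pairs_of(reference)
  if (!length(ref)) return(NA_real_)
  mean(ref %in% pairs_of(test))
}
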