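#' Structured RNA objects
#'
#' A `structured_rna` is a nucleotide sequence together with one fixed,
#' non-crossing set of base pairs. Pairs are stored 1-based, inclusive, and
#' sorted by increasing right endpoint (the partial order used by the
#' alignment recursions). The object carries two precomputed relations:
#' `parent`, the innermost enclosing pair of each pair (0 denotes the
#' pseudo-root `(0, l+1)`), and `f_prev`, the unique nearest sibling that is
#' directly before and juxtaposed to each pair (0 when there is none).
#'
#' @param seq Nucleotide string over `A`, `C`, `G`, `U`, `N` (`T` is accepted
#'   and converted to `U`).
#' @param pairs Two-column integer matrix of (left, right) positions, or
#'   `NULL`/empty for a pairless structure.
#' @param id Label for the molecule.
#' @return An object of class `structured_rna` with fields `id`, `seq`,
#'   `length`, `pairs`, `parent`, `f_prev`.
#' @examples
#' s <- structured_rna("GGAAACC", cbind(c(1, 2), c(7, 6)), id = "hp")
#' s$pairs          # sorted by right endpoint: (2,6) then (1,7)
#' @export
structured_rna <- function(seq, pairs = NULL, id = "rna") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("\\s", "", seq))
  seq <- chartr("T", "U", seq)
  bad <- gsub("[ACGUN]", "", seq)
  if (nzchar(bad)) {
    stop("invalid nucleotide character(s): ", paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  }
  l <- nchar(seq)
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  colnames(pairs) <- c("left", "right")
  s <- structure(
    list(id = id, seq = seq, length = l, pairs = pairs,
         parent = integer(nrow(pairs)), f_prev = integer(nrow(pairs))),
    class = "structured_rna"
  )
  validate_structure(s)
  build_relations(s)
}

#' Validate the base-pair set of a structure
#'
#' Checks the defining invariants: coordinates within `[1, l]` with
#' `left < right`, no position in more than one pair, and no two pairs
#' crossing (`l(p_i) < l(p_j) < r(p_i) < r(p_j)` is forbidden).
#'
#' @param s A `structured_rna` (relations need not be built yet).
#' @return `s`, invisibly; errors describe the first violated invariant.
#' @export
validate_structure <- function(s) {
  p <- s$pairs
  l <- s$length
  if (nrow(p) == 0L) return(invisible(s))
  if (any(p[, 1L] < 1L) || any(p[, 2L] > l) || any(p[, 1L] >= p[, 2L])) {
    stop("base pair coordinates must satisfy 1 <= left < right <= ", l)
  }
  pos <- c(p[, 1L], p[, 2L])
  if (anyDuplicated(pos)) {
    stop("position ", pos[anyDuplicated(pos)], " occurs in more than one base pair")
  }
  # crossing check on pairs sorted by left endpoint, via a stack
  o <- order(p[, 1L])
  stack <- integer(0)
  for (k in o) {
    while (length(stack) && p[stack[length(stack)], 2L] < p[k, 1L]) {
      stack <- stack[-length(stack)]
    }
    if (length(stack) && p[stack[length(stack)], 2L] < p[k, 2L]) {
      stop(sprintf("crossing base pairs: (%d,%d) and (%d,%d)",
                   p[stack[length(stack)], 1L], p[stack[length(stack)], 2L],
                   p[k, 1L], p[k, 2L]))
    }
    stack <- c(stack, k)
  }
  invisible(s)
}

#' Classify the relation between two base pairs
#'
#' In a non-crossing structure two distinct pairs are either nested or
#' juxtaposed. `p_i <I p_j` means `p_j` strictly encloses `p_i`;
#' `p_i <J p_j` means `p_i` ends before `p_j` starts.
#'
#' @param p_i,p_j Length-2 integer vectors `(left, right)`.
#' @return One of `"i_enclosed_by_j"`, `"j_enclosed_by_i"`, `"i_before_j"`,
#'   `"j_before_i"`. Crossing pairs raise an error (corrupted structure).
#' @examples
#' classify_relation(c(2, 6), c(1, 7))  # "i_enclosed_by_j"
#' classify_relation(c(1, 4), c(5, 8))  # "i_before_j"
#' @export
classify_relation <- function(p_i, p_j) {
  li <- p_i[1L]; ri <- p_i[2L]; lj <- p_j[1L]; rj <- p_j[2L]
  if (li == lj && ri == rj) stop("pairs must be distinct")
  if (lj < li && ri < rj) return("i_enclosed_by_j")
  if (li < lj && rj < ri) return("j_enclosed_by_i")
  if (ri < lj) return("i_before_j")
  if (rj < li) return("j_before_i")
  stop(sprintf("crossing base pairs: (%d,%d) and (%d,%d)", li, ri, lj, rj))
}

#' Build the nesting and juxtaposition relations of a structure
#'
#' Sorts pairs by right endpoint, assigns each pair its innermost enclosing
#' pair (`parent`, 0 = pseudo-root `(0, l+1)`) and its `F` predecessor:
#' the sibling `p_j` with `p_j <J p_i`, the same parent, and no sibling
#' `p_k` with `p_j <J p_k <J p_i`. In a fixed non-crossing structure that
#' predecessor is unique, so `f_prev` holds a single index (0 = none).
#'
#' @param s A validated `structured_rna`.
#' @return `s` with `pairs` sorted by right endpoint and `parent`/`f_prev`
#'   filled.
#' @export
build_relations <- function(s) {
  p <- s$pairs
  n <- nrow(p)
  if (n == 0L) {
    s$parent <- integer(0)
    s$f_prev <- integer(0)
    return(s)
  }
  o <- order(p[, 2L])
  p <- p[o, , drop = FALSE]
  colnames(p) <- c("left", "right")
  parent <- integer(n)
  for (k in seq_len(n)) {
    best <- 0L
    for (m in seq_len(n)) {
      if (m != k && p[m, 1L] < p[k, 1L] && p[k, 2L] < p[m, 2L]) {
        if (best == 0L || p[m, 2L] - p[m, 1L] < p[best, 2L] - p[best, 1L]) best <- m
      }
    }
    parent[k] <- best
  }
  f_prev <- integer(n)
  for (k in seq_len(n)) {
    sib <- which(parent == parent[k] & p[, 2L] < p[k, 1L])
    if (length(sib)) f_prev[k] <- sib[which.max(p[sib, 2L])]
  }
  s$pairs <- p
  s$parent <- parent
  s$f_prev <- f_prev
  s
}

#' F set of a base pair
#'
#' Returns the pairs that are directly before and juxtaposed to `k` within
#' its parent context (at most one pair in a fixed structure).
#'
#' @param s A `structured_rna`.
#' @param k Pair index (row of `s$pairs`).
#' @return Integer vector of pair indices (length 0 or 1).
#' @export
f_set <- function(s, k) {
  if (s$f_prev[k] == 0L) integer(0) else s$f_prev[k]
}

#' Loop regions of a structure
#'
#' Computes the unpaired-region coordinates used by the scoring model.
#' With 1-based inclusive coordinates and `p = (l, r)`:
#' hairpin `L(p) = [l+1, r-1]`; for `p_i <I p_j`, left internal
#' `Ll(p_i,p_j) = [l(p_j)+1, l(p_i)-1]` and right internal
#' `Lr(p_i,p_j) = [r(p_i)+1, r(p_j)-1]`; for `p_i <J p_j`, between
#' `L(p_i,p_j) = [r(p_i)+1, l(p_j)-1]`. A region with `start > end` is
#' empty (length 0).
#'
#' @param s A `structured_rna` (used only to check bounds).
#' @param kind One of `"hairpin"`, `"left_internal"`, `"right_internal"`,
#'   `"between"`.
#' @param p_i Length-2 integer vector; for `"hairpin"` the only pair.
#' @param p_j Second pair for the two-pair kinds.
#' @return Named integer vector `c(start, end, length)`.
#' @examples
#' s <- structured_rna("GGAAACC", cbind(c(1, 2), c(7, 6)))
#' loop_region(s, "hairpin", c(2, 6))                  # [3,5], length 3
#' loop_region(s, "left_internal", c(2, 6), c(1, 7))   # empty
#' @export
loop_region <- function(s, kind = c("hairpin", "left_internal", "right_internal", "between"),
                        p_i, p_j = NULL) {
  kind <- match.arg(kind)
  if (kind == "hairpin") {
    reg <- c(p_i[1L] + 1L, p_i[2L] - 1L)
  } else {
    if (is.null(p_j)) stop("kind '", kind, "' needs both p_i and p_j")
    rel <- classify_relation(p_i, p_j)
    if (kind == "between") {
      if (rel != "i_before_j") stop("'between' requires p_i <J p_j")
      reg <- c(p_i[2L] + 1L, p_j[1L] - 1L)
    } else {
      if (rel != "i_enclosed_by_j") stop("'", kind, "' requires p_i <I p_j")
      reg <- if (kind == "left_internal") c(p_j[1L] + 1L, p_i[1L] - 1L)
             else c(p_i[2L] + 1L, p_j[2L] - 1L)
    }
  }
  len <- max(0L, reg[2L] - reg[1L] + 1L)
  c(start = as.integer(reg[1L]), end = as.integer(reg[2L]), length = as.integer(len))
}

#' @export
print.structured_rna <- function(x, ...) {
  cat(sprintf("structured_rna '%s': %d nt, %d base pairs\n", x$id, x$length, nrow(x$pairs)))
  if (x$length <= 120L) {
    cat(x$seq, "\n", sep = "")
    cat(as_dotbracket(x), "\n", sep = "")
  }
  invisible(x)
}

#' Dot-bracket string of a structure
#' @param s A `structured_rna`.
#' @return Character scalar of the same length as the sequence.
#' @export
as_dotbracket <- function(s) {
  db <- rep(".", s$length)
  if (nrow(s$pairs)) {
    db[s$pairs[, 1L]] <- "("
    db[s$pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

# Region pair counts: number of pairs fully contained in [a, b] (used by the
# pruning bounds).
pairs_within <- function(s, a, b) {
  if (nrow(s$pairs) == 0L || a > b) return(0L)
  sum(s$pairs[, 1L] >= a & s$pairs[, 2L] <= b)
}
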