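NUC <- c("A", "C", "G", "U")
NUC_N <- c(NUC, "N")
DINUC <- as.vector(outer(NUC, NUC, paste0))
CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Default nucleotide substitution matrix
#'
#' The RIBOSUM85-60 single-nucleotide log-odds matrix (symmetric, 4x4,
#' rows/columns A, C, G, U).
#' @return Numeric 4x4 matrix.
#' @export
default_nucleotide_matrix <- function() {
  m <- matrix(c(
     2.22, -1.86, -1.46, -1.39,
    -1.86,  1.16, -2.48, -1.05,
    -1.46, -2.48,  1.03, -1.74,
    -1.39, -1.05, -1.74,  1.65
  ), nrow = 4L, byrow = TRUE, dimnames = list(NUC, NUC))
  m
}

#' Default base-pair substitution matrix
#'
#' A RIBOSUM-style 16x16 dinucleotide substitution table constructed from
#' the single-nucleotide matrix: `R[ab, cd] = D[a, c] + D[b, d] + B`, where
#' the conservation bonus `B` is +3 when both dinucleotides are canonical
#' pairs (Watson-Crick or GU wobble), -2 when exactly one is, and -4 when
#' neither is. The construction keeps the table symmetric and rewards
#' conserved canonical pairing; it is the package default and can be
#' replaced by any symmetric 16x16 table via [scoring_scheme] or a config
#' file.
#' @return Numeric 16x16 matrix with dinucleotide dimnames (`AA` ... `UU`).
#' @export
default_basepair_matrix <- function() {
  d <- default_nucleotide_matrix()
  r <- matrix(0, 16L, 16L, dimnames = list(DINUC, DINUC))
  for (x in DINUC) {
    for (y in DINUC) {
      b <- sum(c(x, y) %in% CANONICAL_PAIRS)
      bonus <- c(-4, -2, 3)[b + 1L]
      r[x, y] <- d[substr(x, 1, 1), substr(y, 1, 1)] + d[substr(x, 2, 2), substr(y, 2, 2)] + bonus
    }
  }
  r
}

#' Scoring scheme for structure alignment
#'
#' Bundles the base-pair substitution table `R` (16x16, dinucleotide
#' indexed), the nucleotide substitution table `D` (4x4), affine gap
#' penalties (`g` open, `e` extend, both negative with `g < e`; deleting a
#' whole region of length `k` costs `g + k*e`), and the structure/sequence
#' weights `w1 > w2 > 0`. The maxima `r_max` (over `R`) and `d_max` (over
#' `D`) are cached for the hairpin and pruning upper bounds.
#'
#' Scores are quantised to 0.01 of the weighted unit: the engines work on
#' `round(100 * w1 * R)` and `round(100 * w2 * D)` etc., so identical
#' optima computed along different recursion paths agree exactly.
#'
#' Unknown nucleotides (`N`) score as the minimum of the relevant matrix
#' row, a conservative convention.
#'
#' @param R,D Substitution tables (defaults: [default_basepair_matrix],
#'   [default_nucleotide_matrix]). Must be symmetric.
#' @param g,e Gap open / extend penalties, `g < e < 0`.
#' @param w1,w2 Structure and sequence weights, `w1 > w2 > 0`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(R = default_basepair_matrix(),
                           D = default_nucleotide_matrix(),
                           g = -5, e = -1, w1 = 2, w2 = 1) {
  R <- as.matrix(R); D <- as.matrix(D)
  stopifnot(identical(dim(R), c(16L, 16L)), identical(dim(D), c(4L, 4L)))
  if (is.null(dimnames(R))) dimnames(R) <- list(DINUC, DINUC)
  if (is.null(dimnames(D))) dimnames(D) <- list(NUC, NUC)
  R <- R[DINUC, DINUC]; D <- D[NUC, NUC]
  if (max(abs(R - t(R))) > 1e-9) stop("R must be symmetric")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  if (!(g < e && e < 0)) stop("gap parameters must satisfy g < e < 0")
  if (!(w1 >= w2 && w2 > 0)) stop("weights must satisfy w1 >= w2 > 0")

  # N-extended tables: min of the relevant row/column
  D5 <- matrix(0, 5L, 5L, dimnames = list(NUC_N, NUC_N))
  D5[NUC, NUC] <- D
  for (b in NUC) {
    D5["N", b] <- min(D[, b])
    D5[b, "N"] <- min(D[b, ])
  }
  D5["N", "N"] <- min(D)

  # 25x25 dinucleotide table over the N-extended alphabet
  dn25 <- as.vector(outer(NUC_N, NUC_N, paste0))
  R25 <- matrix(0, 25L, 25L, dimnames = list(dn25, dn25))
  expand <- function(dn) {
    a <- substr(dn, 1, 1); b <- substr(dn, 2, 2)
    as.vector(outer(if (a == "N") NUC else a, if (b == "N") NUC else b, paste0))
  }
  for (x in dn25) {
    ex <- expand(x)
    for (y in dn25) {
      R25[x, y] <- min(R[ex, expand(y)])
    }
  }

  scaled <- list(
    R = matrix(as.integer(round(100 * w1 * R25)), 25L, 25L, dimnames = dimnames(R25)),
    D = matrix(as.integer(round(100 * w2 * D5)), 5L, 5L, dimnames = dimnames(D5)),
    g = as.integer(round(100 * w2 * g)),
    e = as.integer(round(100 * w2 * e))
  )
  scaled$r_max <- max(scaled$R[DINUC, DINUC])
  scaled$d_max <- max(scaled$D[NUC, NUC])

  structure(
    list(R = R, D = D, g = g, e = e, w1 = w1, w2 = w2,
         r_max = max(R), d_max = max(D), scaled = scaled),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: w1=%g w2=%g g=%g e=%g r_max=%g d_max=%g\n",
              x$w1, x$w2, x$g, x$e, x$r_max, x$d_max))
  invisible(x)
}

dinuc_of <- function(s, pair) {
  paste0(substr(s$seq, pair[1L], pair[1L]), substr(s$seq, pair[2L], pair[2L]))
}

#' Structural similarity of two (possibly pseudo) base pairs
#'
#' Returns the `w1`-weighted substitution score `w1 * R[a, b]` for two real
#' dinucleotides. A pseudo pair against a pseudo pair scores 0, and any
#' deletion or insertion of a base pair scores 0: mis-predicted pairs are
#' broken for free rather than penalised.
#'
#' @param pair_a,pair_b Dinucleotide strings (e.g. `"GC"`), or the markers
#'   `"pseudo"` / `"deleted"`.
#' @param sch A [scoring_scheme].
#' @return Numeric score (quantised to 0.01).
#' @export
basepair_score <- function(pair_a, pair_b, sch) {
  special <- c("pseudo", "deleted")
  if (pair_a %in% special || pair_b %in% special) {
    if (pair_a %in% special && pair_b %in% special &&
        pair_a == "pseudo" && pair_b == "pseudo") return(0)
    return(0)  # deletion/insertion of a base pair carries no penalty
  }
  for (p in c(pair_a, pair_b)) {
    if (nchar(p) != 2L || !all(strsplit(p, "")[[1]] %in% NUC_N)) {
      stop("invalid dinucleotide: ", p)
    }
  }
  sch$scaled$R[pair_a, pair_b] / 100
}

#' Penalty for deleting a whole unpaired region
#'
#' `G(|L|) = 0` when the region is empty, otherwise the `w2`-weighted
#' affine cost `w2 * (g + |L| * e)`.
#'
#' @param length Region length, `>= 0`.
#' @param sch A [scoring_scheme].
#' @return Numeric score (quantised to 0.01).
#' @export
region_deletion_penalty <- function(length, sch) {
  if (length < 0) stop("region length must be non-negative")
  if (length == 0) return(0)
  (sch$scaled$g + length * sch$scaled$e) / 100
}

encode_seq <- function(x) {
  if (!nzchar(x)) return(integer(0))
  idx <- match(strsplit(toupper(chartr("T", "U", x)), "")[[1]], NUC_N)
  if (anyNA(idx)) stop("sequence contains characters outside A/C/G/U/N")
  idx - 1L
}

#' Affine-gap global alignment score of two loop regions
#'
#' Gotoh three-state global alignment with opening penalty `g` and
#' extension `e` per residue (a gap of length `k` costs `g + k*e`, so
#' deleting a whole region equals [region_deletion_penalty]). The score is
#' `w2`-weighted. Both regions empty scores 0.
#'
#' @param region_a,region_b Nucleotide strings (may be empty).
#' @param sch A [scoring_scheme].
#' @param traceback When `TRUE`, also return the gapped alignment rows.
#' @return Numeric score, or (with `traceback`) a list with `score`,
#'   `aligned_a`, `aligned_b`.
#' @export
align_loops_affine <- function(region_a, region_b, sch, traceback = FALSE) {
  res <- cpp_gotoh(encode_seq(region_a), encode_seq(region_b),
                   sch$scaled$D, sch$scaled$g, sch$scaled$e, traceback)
  if (!traceback) return(res$score / 100)
  list(score = res$score / 100,
       aligned_a = gapped_string(region_a, res$ops, 1L),
       aligned_b = gapped_string(region_b, res$ops, 2L))
}

# ops: integer vector of 0 = match/mismatch column, 1 = gap in b (consume a),
# 2 = gap in a (consume b)
gapped_string <- function(x, ops, which) {
  chars <- strsplit(x, "")[[1]]
  out <- character(length(ops))
  i <- 0L
  consume <- if (which == 1L) c(0L, 1L) else c(0L, 2L)
  for (k in seq_along(ops)) {
    if (ops[k] %in% consume) {
      i <- i + 1L
      out[k] <- chars[i]
    } else {
      out[k] <- "-"
    }
  }
  paste(out, collapse = "")
}

#' Upper bound on the hairpin-interpretation score of a cell
#'
#' Bounds `Mh[p_A, p_B]` by assuming the maximum number of nucleotide
#' matches and the minimum number of gaps between the two hairpin
#' interiors:
#' `S_str + min(|L_A|, |L_B|) * w2*d_max + I * w2*g + ||L_A| - |L_B|| * w2*e`,
#' with `I = 1` iff the interior lengths differ. Used to skip the expensive
#' interior sequence alignment when the multi-loop interpretation already
#' dominates.
#'
#' @param p_a,p_b Length-2 integer vectors: real base pairs of `sa` / `sb`.
#' @param sch A [scoring_scheme].
#' @param sa,sb The two [structured_rna] objects.
#' @return Numeric bound (quantised to 0.01).
#' @export
hairpin_upper_bound <- function(p_a, p_b, sch, sa, sb) {
  if (p_a[1L] < 1L || p_b[1L] < 1L || p_a[2L] > sa$length || p_b[2L] > sb$length) {
    stop("hairpin bound is defined for real base pairs only")
  }
  la <- p_a[2L] - p_a[1L] - 1L
  lb <- p_b[2L] - p_b[1L] - 1L
  sstr <- sch$scaled$R[dinuc_of(sa, p_a), dinuc_of(sb, p_b)]
  bound <- sstr + min(la, lb) * sch$scaled$d_max +
    (la != lb) * sch$scaled$g + abs(la - lb) * sch$scaled$e
  bound / 100
}

#' Read a scoring configuration file
#'
#' YAML with optional keys `g`, `e`, `w1`, `w2`, and `matrices` (either the
#' string `"default"` or a mapping with inline `R` (16x16, row-major list
#' of rows, dinucleotide order `AA..UU`) and `D` (4x4, order A,C,G,U)).
#'
#' @param path YAML file.
#' @return A [scoring_scheme].
#' @export
read_scoring_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  R <- default_basepair_matrix(); D <- default_nucleotide_matrix()
  if (!is.null(cfg$matrices) && !identical(cfg$matrices, "default")) {
    if (!is.null(cfg$matrices$R)) {
      R <- matrix(unlist(cfg$matrices$R), 16L, 16L, byrow = TRUE,
                  dimnames = list(DINUC, DINUC))
    }
    if (!is.null(cfg$matrices$D)) {
      D <- matrix(unlist(cfg$matrices$D), 4L, 4L, byrow = TRUE,
                  dimnames = list(NUC, NUC))
    }
  }
  get_or <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  scoring_scheme(R = R, D = D,
                 g = get_or("g", -5), e = get_or("e", -1),
                 w1 = get_or("w1", 2), w2 = get_or("w2", 1))
}

#' Write the effective scoring configuration
#'
#' @param sch A [scoring_scheme].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_scoring_config <- function(sch, path) {
  cfg <- list(
    g = sch$g, e = sch$e, w1 = sch$w1, w2 = sch$w2,
    matrices = list(
      R = lapply(seq_len(16L), function(i) as.numeric(sch$R[i, ])),
      D = lapply(seq_len(4L), function(i) as.numeric(sch$D[i, ]))
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
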