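#' Parameters for the random structure generator
#'
#' The generator emulates fixed RNA secondary structures with realistic
#' geometry: helices of a few stacked pairs, hairpin loops of at least
#' three nucleotides, and pair spans following the polymer-zeta power law
#' `P(s) ~ s^(-c)` with `c > 1` (the empirical regime of folded RNA, in
#' which long-range pairs are rare).
#'
#' @param target_length Sequence length `l`.
#' @param target_pairs Desired number of base pairs (default `0.18 * l`,
#'   within the density range of annotated Rfam-style structures). Must
#'   satisfy `2 * target_pairs <= target_length`.
#' @param span_exponent Power-law exponent `c > 1` for helix spans.
#' @param helix_len_range Min/max stacked pairs per placed helix.
#' @param loop_len_range Unused directly by placement (loop sizes emerge
#'   from span sampling) but kept for hairpin minimum control: the first
#'   element sets the minimum hairpin loop (default 3).
#' @param seed Integer seed; identical seeds give identical structures.
#' @return A list of class `gen_params`.
#' @export
gen_params <- function(target_length = 120L, target_pairs = NULL,
                       span_exponent = 1.5, helix_len_range = c(2L, 6L),
                       loop_len_range = c(3L, 8L), seed = 1L) {
  if (is.null(target_pairs)) target_pairs <- max(1L, round(0.18 * target_length))
  stopifnot(span_exponent > 1, 2L * target_pairs <= target_length,
            helix_len_range[1L] >= 1L, loop_len_range[1L] >= 0L)
  structure(list(target_length = as.integer(target_length),
                 target_pairs = as.integer(target_pairs),
                 span_exponent = span_exponent,
                 helix_len_range = as.integer(helix_len_range),
                 loop_len_range = as.integer(loop_len_range),
                 seed = as.integer(seed)),
            class = "gen_params")
}

#' Mutation parameters for homolog generation
#'
#' @param sub_rate Per-site substitution probability (paired sites
#'   substitute as whole canonical dinucleotides so the skeleton stays
#'   pairable).
#' @param loop_indel_rate Per-loop-site indel probability (indels are
#'   confined to loop regions so the structure skeleton is preserved).
#' @param pair_break_rate Probability that a base pair is removed from the
#'   annotation (its nucleotides remain, emulating a mis-predicted pair).
#' @param seed Integer seed.
#' @return A list of class `mut_params`.
#' @export
mut_params <- function(sub_rate = 0.1, loop_indel_rate = 0.05,
                       pair_break_rate = 0.05, seed = 1L) {
  stopifnot(all(c(sub_rate, loop_indel_rate, pair_break_rate) >= 0),
            all(c(sub_rate, loop_indel_rate, pair_break_rate) <= 1))
  structure(list(sub_rate = sub_rate, loop_indel_rate = loop_indel_rate,
                 pair_break_rate = pair_break_rate, seed = as.integer(seed)),
            class = "mut_params")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

CANONICAL_SPLIT <- matrix(c("G", "C", "C", "G", "A", "U", "U", "A", "G", "U", "U", "G"),
                          ncol = 2L, byrow = TRUE)

#' Generate a random fixed secondary structure
#'
#' Places helices one at a time: a helix length is drawn from
#' `helix_len_range`, an anchor position uniformly, and a span from the
#' truncated power law `P(s) ~ s^(-span_exponent)`; the helix is accepted
#' when all its positions are unoccupied, it crosses no existing pair, and
#' it leaves a hairpin loop of at least `loop_len_range[1]` nucleotides.
#' Placement stops when the pair count reaches the target (a shortfall of
#' up to 10 percent is tolerated; a larger one, after bounded retries, is
#' an error). Paired positions are filled with canonical dinucleotides
#' (Watson-Crick or GU), loop positions uniformly.
#'
#' @param p A [gen_params].
#' @return A validated [structured_rna]; identical for identical seeds.
#' @export
random_structure <- function(p) {
  stopifnot(inherits(p, "gen_params"))
  with_local_seed(p$seed, {
    l <- p$target_length
    min_hp <- max(3L, p$loop_len_range[1L])
    occupied <- rep(FALSE, l)
    pairs <- matrix(integer(0), ncol = 2L)
    crosses <- function(a, b) {
      if (nrow(pairs) == 0L) return(FALSE)
      in1 <- pairs[, 1L] > a & pairs[, 1L] < b
      in2 <- pairs[, 2L] > a & pairs[, 2L] < b
      any(xor(in1, in2))
    }
    tries <- 0L
    max_tries <- 200L + 60L * p$target_pairs
    while (nrow(pairs) < p$target_pairs && tries < max_tries) {
      tries <- tries + 1L
      h <- sample(seq(p$helix_len_range[1L], p$helix_len_range[2L]), 1L)
      h <- min(h, p$target_pairs - nrow(pairs))
      smin <- 2L * h + min_hp - 1L
      if (smin >= l) next
      spans <- smin:(l - 1L)
      s <- sample(spans, 1L, prob = spans^(-p$span_exponent))
      a <- sample.int(l - s, 1L)
      b <- a + s
      ok <- TRUE
      for (k in seq_len(h) - 1L) {
        aa <- a + k; bb <- b - k
        if (occupied[aa] || occupied[bb] || crosses(aa, bb)) { ok <- FALSE; break }
      }
      # inner helix pair must keep a hairpin loop open unless it encloses
      # other pairs
      if (ok) {
        aa <- a + h - 1L; bb <- b - h + 1L
        interior_pairs <- nrow(pairs) > 0L &&
          any(pairs[, 1L] > aa & pairs[, 2L] < bb)
        if (!interior_pairs && bb - aa - 1L < min_hp) ok <- FALSE
      }
      if (!ok) next
      for (k in seq_len(h) - 1L) {
        pairs <- rbind(pairs, c(a + k, b - k))
        occupied[c(a + k, b - k)] <- TRUE
      }
    }
    if (nrow(pairs) < ceiling(0.9 * p$target_pairs)) {
      stop(sprintf("could not place %d pairs in %d nt (placed %d); relax the parameters",
                   p$target_pairs, l, nrow(pairs)))
    }
    seq <- sample(NUC, l, replace = TRUE)
    for (k in seq_len(nrow(pairs))) {
      dn <- CANONICAL_SPLIT[sample.int(6L, 1L), ]
      seq[pairs[k, 1L]] <- dn[1L]
      seq[pairs[k, 2L]] <- dn[2L]
    }
    structured_rna(paste(seq, collapse = ""), pairs,
                   id = sprintf("synth_l%d_s%d", l, p$seed))
  })
}

#' Mutate a structure into a homolog
#'
#' Applies, in order: pair breaking (annotation removed, nucleotides
#' kept), substitutions (loop sites individually; kept pairs as whole
#' canonical dinucleotides), and loop-confined indels (each loop site may
#' be deleted or gain an inserted neighbour). The surviving pair skeleton
#' is preserved with coordinates remapped across indels.
#'
#' @param s A [structured_rna].
#' @param m A [mut_params].
#' @return A [structured_rna] homolog; identical for identical seeds.
#' @export
mutate_homolog <- function(s, m) {
  stopifnot(inherits(s, "structured_rna"), inherits(m, "mut_params"))
  with_local_seed(m$seed, {
    n <- nrow(s$pairs)
    keep <- if (n) stats::runif(n) >= m$pair_break_rate else logical(0)
    kept <- s$pairs[keep, , drop = FALSE]
    chars <- strsplit(s$seq, "")[[1]]
    paired <- rep(0L, s$length)
    if (nrow(kept)) {
      paired[kept[, 1L]] <- seq_len(nrow(kept))
      paired[kept[, 2L]] <- -seq_len(nrow(kept))
    }
    # substitutions
    if (nrow(kept)) {
      resub <- stats::runif(nrow(kept)) < m$sub_rate
      for (k in which(resub)) {
        dn <- CANONICAL_SPLIT[sample.int(6L, 1L), ]
        chars[kept[k, 1L]] <- dn[1L]
        chars[kept[k, 2L]] <- dn[2L]
      }
    }
    loop_sites <- which(paired == 0L)
    resub <- loop_sites[stats::runif(length(loop_sites)) < m$sub_rate]
    for (i in resub) chars[i] <- sample(setdiff(NUC, chars[i]), 1L)
    # loop indels: build token stream
    out_chars <- character(0)
    new_left <- integer(nrow(kept)); new_right <- integer(nrow(kept))
    for (i in seq_len(s$length)) {
      if (paired[i] != 0L) {
        out_chars <- c(out_chars, chars[i])
        if (paired[i] > 0L) new_left[paired[i]] <- length(out_chars)
        else new_right[-paired[i]] <- length(out_chars)
      } else {
        r <- stats::runif(1L)
        if (r < m$loop_indel_rate / 2) {
          # deletion: skip
        } else if (r < m$loop_indel_rate) {
          out_chars <- c(out_chars, chars[i], sample(NUC, 1L))
        } else {
          out_chars <- c(out_chars, chars[i])
        }
      }
    }
    structured_rna(paste(out_chars, collapse = ""),
                   if (nrow(kept)) cbind(new_left, new_right) else NULL,
                   id = paste0(s$id, "_hom", m$seed))
  })
}

#' Two-hairpin fixture with one mis-predicted inner pair
#'
#' A constructed instance of the motivating scenario for general
#' edit-distance alignment: two hairpins identical except that molecule
#' `a` carries an inserted uracil which induces one extra inner base pair
#' in its annotation. The correct alignment breaks that pair, aligns its
#' nucleotides as loop sequence, and opens exactly one single-column gap.
#'
#' @return A list with [structured_rna] elements `a` and `b`.
#' @export
insertion_fixture <- function() {
  list(
    a = structured_rna("GGAAAUCC", cbind(c(1L, 2L, 3L), c(8L, 7L, 6L)), id = "hp_insU"),
    b = structured_rna("GGAAACC", cbind(c(1L, 2L), c(7L, 6L)), id = "hp_ref")
  )
}
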