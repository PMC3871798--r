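# Seeded fixture builders shared across test files.

# Toy scheme: nucleotide match +2 / mismatch -1; identical dinucleotides
# score 5 (4 for wobble GU/UG); g = -5, e = -1; both weights 1.
toy_scheme <- function(w1 = 1, w2 = 1, g = -5, e = -1) {
  D <- matrix(-1, 4, 4, dimnames = list(NUC4, NUC4))
  diag(D) <- 2
  R <- matrix(0, 16, 16, dimnames = list(DINUC16, DINUC16))
  diag(R) <- 5
  R["GU", "GU"] <- R["UG", "UG"] <- 4
  scoring_scheme(R = R, D = D, g = g, e = e, w1 = w1, w2 = w2)
}

# A structure pair: a random polymer-zeta structure and a mutated homolog.
random_instance <- function(seed, l_range = c(30L, 60L), frac = 0.15,
                            max_pairs = 12L,
                            sub_rate = 0.15, loop_indel_rate = 0.1,
                            pair_break_rate = 0.15) {
  l <- l_range[1L] + (seed * 7919L) %% (l_range[2L] - l_range[1L] + 1L)
  np <- max(1L, min(max_pairs, as.integer(round(frac * l))))
  sa <- NULL
  for (k in 0:5) {
    sa <- tryCatch(
      random_structure(gen_params(target_length = l, target_pairs = np,
                                  seed = seed * 131L + k)),
      error = function(e) NULL)
    if (!is.null(sa)) break
  }
  stopifnot(!is.null(sa))
  sb <- mutate_homolog(sa, mut_params(sub_rate = sub_rate,
                                      loop_indel_rate = loop_indel_rate,
                                      pair_break_rate = pair_break_rate,
                                      seed = seed + 17L))
  list(a = sa, b = sb)
}

# Tiny instances for the exhaustive-enumeration oracle: at most 4 pairs and
# 24 nt per structure. Odd seeds pair a structure with an independent random
# one, even seeds with a heavily mutated homolog.
tiny_instance <- function(seed) {
  l <- 12L + (seed * 37L) %% 13L   # 12..24
  np <- 1L + (seed * 53L) %% 4L    # 1..4
  gen <- function(s, npairs) {
    out <- NULL
    for (k in 0:6) {
      out <- tryCatch(
        random_structure(gen_params(target_length = l, target_pairs = npairs,
                                    helix_len_range = c(1L, 2L),
                                    seed = s + 1000L * k)),
        error = function(e) NULL)
      if (!is.null(out)) break
      npairs <- max(1L, npairs - 1L)
    }
    stopifnot(!is.null(out))
    out
  }
  sa <- gen(seed * 211L, np)
  sb <- if (seed %% 2L == 1L) {
    gen(seed * 211L + 7L, 1L + (seed * 29L) %% 4L)
  } else {
    mutate_homolog(sa, mut_params(sub_rate = 0.3, loop_indel_rate = 0.2,
                                  pair_break_rate = 0.4, seed = seed + 3L))
  }
  stopifnot(nrow(sa$pairs) <= 4L, nrow(sb$pairs) <= 4L)
  list(a = sa, b = sb)
}

# Two identical perfect helices (five stacked pairs over a short loop).
helix_instance <- function() {
  s <- structured_rna("GGGGGAAACCCCC",
                      cbind(1:5, 13:9), id = "helix5")
  list(a = s, b = s)
}
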