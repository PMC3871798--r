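# Independent reference implementations used as oracles against the C++
# engines. Everything here is plain R and shares no code with src/.

NUC4 <- c("A", "C", "G", "U")
DINUC16 <- as.vector(outer(NUC4, NUC4, paste0))

# Affine-gap global alignment, three-state recursion in R.
ref_gotoh <- function(x, y, sch) ref_gotoh_raw(x, y, sch) / 100

# Same, in the engines' integer-scaled units (exact arithmetic).
ref_gotoh_raw <- function(x, y, sch) {
  g <- sch$scaled$g; e <- sch$scaled$e; D <- sch$scaled$D
  ax <- strsplit(x, "")[[1]]; ay <- strsplit(y, "")[[1]]
  n <- length(ax); m <- length(ay)
  if (n == 0 && m == 0) return(0)
  if (n == 0) return(g + m * e)
  if (m == 0) return(g + n * e)
  NEGR <- -1e15
  Mm <- matrix(NEGR, n + 1, m + 1); Ix <- Mm; Iy <- Mm
  Mm[1, 1] <- 0
  for (j in 2:(m + 1)) Iy[1, j] <- g + (j - 1) * e
  for (i in 2:(n + 1)) Ix[i, 1] <- g + (i - 1) * e
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- D[ax[i - 1], ay[j - 1]]
      Mm[i, j] <- max(Mm[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(Mm[i - 1, j] + g + e, Ix[i - 1, j] + e, Iy[i - 1, j] + g + e)
      Iy[i, j] <- max(Mm[i, j - 1] + g + e, Ix[i, j - 1] + g + e, Iy[i, j - 1] + e)
    }
  }
  max(Mm[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Exhaustive enumeration of every global alignment (for short strings).
enum_align <- function(x, y, sch) {
  g <- sch$scaled$g; e <- sch$scaled$e; D <- sch$scaled$D
  ax <- strsplit(x, "")[[1]]; ay <- strsplit(y, "")[[1]]
  n <- length(ax); m <- length(ay)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > n && j > m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= n && j <= m) rec(i + 1, j + 1, "m", acc + D[ax[i], ay[j]])
    if (i <= n) rec(i + 1, j, "x", acc + if (last == "x") e else g + e)
    if (j <= m) rec(i, j + 1, "y", acc + if (last == "y") e else g + e)
  }
  rec(1, 1, "m", 0)
  best / 100
}

# Score of one order-consistent matching under the edit-distance model:
# w1-weighted base-pair substitution over matched couples plus w2-weighted
# affine similarity over the loop partition the matched pairs induce
# (each loop couple aligned independently; broken pairs are plain sequence).
eq1_score <- function(sa, sb, m, sch, sim = new.env(parent = emptyenv())) {
  simsc <- function(a1, a2, b1, b2) {
    key <- paste(a1, a2, b1, b2)
    v <- sim[[key]]
    if (is.null(v)) {
      x <- if (a1 > a2) "" else substr(sa$seq, a1, a2)
      y <- if (b1 > b2) "" else substr(sb$seq, b1, b2)
      v <- ref_gotoh_raw(x, y, sch)
      sim[[key]] <- v
    }
    v
  }
  dn <- function(s, p) paste0(substr(s$seq, p[1], p[1]), substr(s$seq, p[2], p[2]))
  str_sum <- 0
  for (k in seq_len(nrow(m))) {
    str_sum <- str_sum +
      sch$scaled$R[dn(sa, sa$pairs[m[k, 1], ]), dn(sb, sb$pairs[m[k, 2], ])]
  }
  seq_sum <- 0
  walk <- function(alo, ahi, blo, bhi, rows) {
    top <- integer(0)
    if (length(rows)) {
      la <- sa$pairs[m[rows, 1], 1]; ra <- sa$pairs[m[rows, 1], 2]
      is_top <- vapply(seq_along(rows), function(t) {
        !any(la < la[t] & ra > ra[t])
      }, logical(1))
      top <- rows[is_top][order(ra[is_top])]
    }
    ca <- alo; cb <- blo
    for (t in top) {
      pa <- sa$pairs[m[t, 1], ]; pb <- sb$pairs[m[t, 2], ]
      seq_sum <<- seq_sum + simsc(ca, pa[1] - 1, cb, pb[1] - 1)
      la <- sa$pairs[m[rows, 1], 1]; ra <- sa$pairs[m[rows, 1], 2]
      inner <- rows[la > pa[1] & ra < pa[2]]
      walk(pa[1] + 1, pa[2] - 1, pb[1] + 1, pb[2] - 1, inner)
      ca <- pa[2] + 1; cb <- pb[2] + 1
    }
    seq_sum <<- seq_sum + simsc(ca, ahi, cb, bhi)
  }
  walk(1, sa$length, 1, sb$length, seq_len(nrow(m)))
  (str_sum + seq_sum) / 100
}

# Exhaustive maximisation over every order-consistent one-to-one base-pair
# matching (feasible for a handful of pairs per structure).
enum_matchings <- function(sa, sb, sch) {
  na <- nrow(sa$pairs); nb <- nrow(sb$pairs)
  sim <- new.env(parent = emptyenv())
  best <- -Inf
  chosen <- matrix(integer(0), ncol = 2)
  used_b <- rep(FALSE, nb)
  consistent <- function(i, j) {
    for (k in seq_len(nrow(chosen))) {
      ra <- classify_relation(sa$pairs[chosen[k, 1], ], sa$pairs[i, ])
      rb <- classify_relation(sb$pairs[chosen[k, 2], ], sb$pairs[j, ])
      if (ra != rb) return(FALSE)
    }
    TRUE
  }
  rec <- function(i) {
    if (i > na) {
      best <<- max(best, eq1_score(sa, sb, chosen, sch, sim))
      return(invisible())
    }
    rec(i + 1)
    for (j in seq_len(nb)) {
      if (!used_b[j] && consistent(i, j)) {
        chosen <<- rbind(chosen, c(i, j))
        used_b[j] <<- TRUE
        rec(i + 1)
        chosen <<- chosen[-nrow(chosen), , drop = FALSE]
        used_b[j] <<- FALSE
      }
    }
  }
  rec(1L)
  best
}
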