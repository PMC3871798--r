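#' Benchmark the engines on a synthetic size grid
#'
#' For each requested length and seed, generates a structure pair (a
#' random polymer-zeta structure and a mutated homolog), runs both
#' engines, and records sizes, OPM statistics and wall times. The tibble
#' is suitable for log-log scaling plots of runtime against the pair
#' count and for the OPM reduction ratio `n^2 / z`.
#'
#' @param lengths Sequence lengths to generate.
#' @param seeds Integer seeds (one instance pair per length/seed combo).
#' @param sch A [scoring_scheme].
#' @param pair_density Pairs per nucleotide for the generator.
#' @param span_exponent Polymer-zeta exponent.
#' @param engines Engines to run (`"full"`, `"sparse"` or both).
#' @param mutate A [mut_params] template; its seed is re-derived per
#'   instance.
#' @return A tibble of class `opm_bench`: one row per instance and
#'   engine, with `length`, `seed`, `n` (mean pair count), `z`,
#'   `reduction` (`n^2/z`), `seconds`, `score`.
#' @export
bench_scaling <- function(lengths = c(100L, 200L, 400L, 800L), seeds = 0:2,
                          sch = scoring_scheme(), pair_density = 0.18,
                          span_exponent = 1.5,
                          engines = c("full", "sparse"),
                          mutate = mut_params(sub_rate = 0.1,
                                              loop_indel_rate = 0.05,
                                              pair_break_rate = 0.05)) {
  engines <- match.arg(engines, several.ok = TRUE)
  rows <- list()
  for (l in lengths) {
    for (sd in seeds) {
      gp <- gen_params(target_length = l,
                       target_pairs = max(1L, round(pair_density * l)),
                       span_exponent = span_exponent,
                       seed = 1000L * sd + l %% 1000L)
      sa <- random_structure(gp)
      mutate$seed <- gp$seed + 1L
      sb <- mutate_homolog(sa, mutate)
      n <- (nrow(sa$pairs) + nrow(sb$pairs)) / 2
      res <- list()
      for (eng in engines) {
        t0 <- proc.time()[["elapsed"]]
        st <- if (eng == "full") full_align(sa, sb, sch)
              else sparse_align(sa, sb, sch)
        dt <- proc.time()[["elapsed"]] - t0
        res[[eng]] <- tibble::tibble(
          length = l, seed = sd, engine = eng,
          n_a = nrow(sa$pairs), n_b = nrow(sb$pairs), n = n,
          z = if (eng == "sparse") st$stats$z_peak else NA_real_,
          reduction = if (eng == "sparse") n^2 / max(1, st$stats$z_peak) else NA_real_,
          seconds = dt, score = st$score
        )
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(res)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("opm_bench", class(out))
  out
}

#' Log-log runtime slope of an engine
#'
#' Fits `log(seconds) ~ log(n)` over a benchmark tibble and returns the
#' slope (the empirical growth exponent of runtime in the pair count).
#'
#' @param bench An `opm_bench` tibble.
#' @param engine `"full"` or `"sparse"`.
#' @return Numeric slope.
#' @export
bench_slope <- function(bench, engine) {
  d <- dplyr::filter(bench, .data$engine == !!engine, .data$seconds > 0)
  stats::coef(stats::lm(log(seconds) ~ log(n), data = d))[["log(n)"]]
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scaling plot of a benchmark run
#'
#' @param object An `opm_bench` tibble.
#' @param ... Unused.
#' @return A ggplot: runtime versus mean pair count on log-log axes, one
#'   colour per engine.
#' @export
autoplot.opm_bench <- function(object, ...) {
  d <- dplyr::filter(object, .data$seconds > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$seconds,
                                  colour = .data$engine)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean number of base pairs n", y = "runtime (s)",
                  title = "Engine scaling on synthetic structures")
}
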