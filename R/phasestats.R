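# Per-phase GCP rate summaries and the Monte Carlo randomization test of
# rate differences across exposure phases.

#' Define observation phases
#'
#' @param name Phase names (e.g. `before`, `during`, `recovery`,
#'   `post_recovery`).
#' @param start_s,end_s Phase boundaries in seconds.
#' @return A tibble with `phase`, `start_s`, `end_s`, `duration_h`.
#' @examples
#' observation_phases(c("before", "during"), c(0, 17) * 3600, c(17, 92) * 3600)
#' @export
observation_phases <- function(name, start_s, end_s) {
  if (any(end_s <= start_s)) abort("Each phase must have start_s < end_s.")
  ph <- tibble(
    phase = as.character(name), start_s = start_s, end_s = end_s,
    duration_h = (end_s - start_s) / 3600
  )
  ph <- dplyr::arrange(ph, .data$start_s)
  if (nrow(ph) > 1 && any(ph$start_s[-1] < ph$end_s[-nrow(ph)])) {
    abort("Phases must not overlap.")
  }
  ph
}

assign_phase <- function(start_s, phases) {
  idx <- rep(NA_integer_, length(start_s))
  for (i in seq_len(nrow(phases))) {
    inb <- start_s >= phases$start_s[i] & start_s < phases$end_s[i]
    idx[inb] <- i
  }
  idx
}

#' Summarize GCP counts, rates and edge percentages by phase
#'
#' GCPs are assigned to phases by their start time. Rates are returned
#' unrounded so that `rate_per_h * duration_h` reproduces the integer counts
#' exactly; round to two decimals for a table-style display. The edge
#' percentage is reported to the nearest integer and is missing for phases
#' without GCPs (or when `on_edge` has not been tagged).
#'
#' @param gcps GCP tibble with `start_s` (and optionally `on_edge`).
#' @param phases Phase tibble from [observation_phases()].
#' @return A tibble with `phase`, `duration_h`, `n_gcps`, `rate_per_h`,
#'   `pct_edge`.
#' @export
summarize_rates <- function(gcps, phases) {
  assert_cols(gcps, "start_s")
  assert_cols(phases, c("phase", "start_s", "end_s", "duration_h"))
  if (any(phases$duration_h <= 0)) abort("Zero-duration phase.")
  idx <- assign_phase(gcps$start_s, phases)
  if (anyNA(idx)) {
    abort(sprintf("%d GCP(s) start outside every phase.", sum(is.na(idx))))
  }
  on_edge <- if ("on_edge" %in% names(gcps)) gcps$on_edge else rep(NA, nrow(gcps))
  purrr::map_dfr(seq_len(nrow(phases)), function(i) {
    sel <- which(idx == i)
    n <- length(sel)
    pe <- if (n > 0 && !all(is.na(on_edge[sel]))) {
      round(100 * mean(on_edge[sel], na.rm = TRUE))
    } else {
      NA_real_
    }
    tibble(
      phase = phases$phase[i],
      duration_h = phases$duration_h[i],
      n_gcps = n,
      rate_per_h = n / phases$duration_h[i],
      pct_edge = pe
    )
  })
}

#' Randomization test of GCP rates between two exposure phases
#'
#' Tests whether the GCP rate differs between two phases against a null in
#' which the observed total number of GCP start times is redistributed
#' uniformly at random over the whole observation span (the union of all
#' phases). Under that null the per-phase counts are multinomial with
#' probabilities proportional to phase durations, which is how the null is
#' sampled. The statistic is the rate difference (per hour) between
#' `phase_a` and `phase_b` (or the rate ratio). The two-tailed p-value uses
#' the add-one correction: `p = (1 + #{|T*| >= |T|}) / (n_reps + 1)`, so a
#' Monte Carlo p-value is never exactly zero.
#'
#' With `method = "exhaustive"` the null is not sampled: every placement of
#' the N events over a time grid of step `grid_step_h` is enumerated (via
#' exact multinomial counts over grid slots), which is feasible for small N
#' and is useful for validating the Monte Carlo mode.
#'
#' @param gcps GCP tibble with `start_s`.
#' @param phases Phase tibble from [observation_phases()].
#' @param phase_a,phase_b Names of the two phases to compare.
#' @param n_reps Number of randomized series (Monte Carlo mode).
#' @param seed Integer seed for reproducibility.
#' @param statistic `"difference"` (rate_a - rate_b, per hour; default) or
#'   `"ratio"`.
#' @param method `"monte_carlo"` (default) or `"exhaustive"`.
#' @param grid_step_h Grid step (hours) used to discretize placements in
#'   exhaustive mode.
#' @return An object of class `sonar_rand_test`; see [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' ph <- observation_phases(c("before", "during"), c(0, 3600), c(3600, 7200))
#' gcps <- tibble::tibble(start_s = c(100, 900, 2000, 4000))
#' rt <- randomization_test(gcps, ph, "before", "during",
#'                          n_reps = 1000, seed = 1)
#' tidy(rt)
#' @export
randomization_test <- function(gcps, phases, phase_a, phase_b,
                               n_reps = 1e6, seed = NULL,
                               statistic = c("difference", "ratio"),
                               method = c("monte_carlo", "exhaustive"),
                               grid_step_h = 0.01) {
  assert_cols(gcps, "start_s")
  assert_cols(phases, c("phase", "start_s", "end_s", "duration_h"))
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (identical(phase_a, phase_b)) abort("`phase_a` and `phase_b` must differ.")
  if (!all(c(phase_a, phase_b) %in% phases$phase)) {
    abort("Both phases must be present in `phases`.")
  }
  if (method == "monte_carlo" && (!is.finite(n_reps) || n_reps < 1)) {
    abort("`n_reps` must be >= 1.")
  }

  idx <- assign_phase(gcps$start_s, phases)
  if (anyNA(idx)) abort("All GCP start times must fall inside a phase.")
  counts <- tabulate(idx, nbins = nrow(phases))
  dur <- phases$duration_h
  ia <- match(phase_a, phases$phase)
  ib <- match(phase_b, phases$phase)
  n_total <- sum(counts)

  stat_fun <- if (statistic == "difference") {
    function(ka, kb) ka / dur[ia] - kb / dur[ib]
  } else {
    function(ka, kb) (ka / dur[ia]) / (kb / dur[ib])
  }
  obs <- stat_fun(counts[ia], counts[ib])
  tol <- 1e-9 * max(1, abs(obs))

  if (method == "monte_carlo") {
    n_reps <- as.integer(round(n_reps))
    if (!is.null(seed)) set.seed(seed)
    # Equivalent to dropping n_total uniform start times on the observation
    # span and counting per phase.
    nul <- rmultinom(n_reps, n_total, prob = dur / sum(dur))
    null_stat <- stat_fun(nul[ia, ], nul[ib, ])
    k_extreme <- sum(abs(null_stat) >= abs(obs) - tol)
    p <- (1 + k_extreme) / (n_reps + 1)
    null_sample <- if (n_reps > 10000) {
      null_stat[seq(1, n_reps, length.out = 10000)]
    } else {
      null_stat
    }
    null_pmf <- NULL
  } else {
    # Enumerate placements of n_total events over grid slots exactly.
    m <- round(dur / grid_step_h)
    if (any(abs(m * grid_step_h - dur) > 1e-8 * max(dur))) {
      abort("`grid_step_h` must divide every phase duration in exhaustive mode.")
    }
    s_total <- sum(m)
    cnt_vecs <- compositions_of(n_total, nrow(phases))
    log_m <- log(m)
    weights <- apply(cnt_vecs, 1, function(k) {
      exp(lgamma(n_total + 1) - sum(lgamma(k + 1)) + sum(k * log_m))
    })
    stats_all <- stat_fun(cnt_vecs[, ia], cnt_vecs[, ib])
    n_reps <- s_total^n_total
    k_extreme <- sum(weights[abs(stats_all) >= abs(obs) - tol])
    p <- (1 + k_extreme) / (n_reps + 1)
    null_sample <- NULL
    null_pmf <- tibble(stat = stats_all, prob = weights / n_reps)
  }

  structure(
    list(
      hypothesis = paste(phase_a, "vs", phase_b),
      phase_a = phase_a, phase_b = phase_b,
      statistic = statistic, method = method,
      counts = setNames(counts, phases$phase),
      duration_h = setNames(dur, phases$phase),
      observed_stat = obs,
      n_reps = n_reps,
      p_two_tailed = p,
      seed = seed,
      null_sample = null_sample,
      null_pmf = null_pmf
    ),
    class = "sonar_rand_test"
  )
}

# All vectors of k non-negative integers summing to n (phase count vectors).
compositions_of <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- lapply(0:n, function(i) {
    cbind(i, compositions_of(n - i, k - 1))
  })
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

#' Run the standard set of phase-pair hypotheses
#'
#' Runs the randomization test for the five usual contrasts of a sonar
#' exposure study: before vs during, during vs recovery, during vs
#' post-recovery, before vs recovery, and before vs post-recovery, skipping
#' pairs whose phases are absent.
#'
#' @inheritParams randomization_test
#' @return A tibble with one row per tested hypothesis (`hypothesis`,
#'   `phase_a`, `phase_b`, `observed_stat`, `p_two_tailed`, `n_reps`,
#'   `seed`).
#' @export
run_hypothesis_tests <- function(gcps, phases, n_reps = 1e6, seed = NULL,
                                 statistic = c("difference", "ratio")) {
  statistic <- match.arg(statistic)
  pairs <- list(
    H1 = c("before", "during"),
    H2 = c("during", "recovery"),
    H3 = c("during", "post_recovery"),
    H4 = c("before", "recovery"),
    H5 = c("before", "post_recovery")
  )
  keep <- vapply(pairs, function(p) all(p %in% phases$phase), logical(1))
  purrr::imap_dfr(pairs[keep], function(p, nm) {
    rt <- randomization_test(gcps, phases, p[1], p[2], n_reps = n_reps,
                             seed = seed, statistic = statistic)
    dplyr::mutate(tidy(rt), hypothesis = nm, .before = 1)
  })
}

#' @export
print.sonar_rand_test <- function(x, ...) {
  cat(sprintf("<randomization test: %s (%s of rates)>\n",
              x$hypothesis, x$statistic))
  cat(sprintf("  observed statistic: %.4f per h\n", x$observed_stat))
  cat(sprintf("  p (two-tailed, %s, n_reps = %g): %.3g\n",
              x$method, x$n_reps, x$p_two_tailed))
  invisible(x)
}

#' @export
tidy.sonar_rand_test <- function(x, ...) {
  tibble(
    phase_a = x$phase_a, phase_b = x$phase_b,
    statistic = x$statistic,
    observed_stat = x$observed_stat,
    p_two_tailed = x$p_two_tailed,
    n_reps = x$n_reps,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' @export
glance.sonar_rand_test <- function(x, ...) {
  tibble(
    hypothesis = x$hypothesis,
    observed_stat = x$observed_stat,
    p_two_tailed = x$p_two_tailed,
    n_reps = x$n_reps,
    method = x$method
  )
}

#' @export
autoplot.sonar_rand_test <- function(object, ...) {
  if (!is.null(object$null_sample)) {
    df <- tibble(stat = object$null_sample)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
      ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40")
  } else {
    p <- ggplot2::ggplot(object$null_pmf,
                         ggplot2::aes(x = .data$stat, y = .data$prob)) +
      ggplot2::geom_col(fill = "grey70", colour = "grey40")
  }
  p +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("null %s of GCP rates (per h)", object$statistic),
      y = if (is.null(object$null_sample)) "probability" else "count",
      title = object$hypothesis,
      subtitle = sprintf("two-tailed p = %.3g (n_reps = %g)",
                         object$p_two_tailed, object$n_reps)
    ) +
    ggplot2::theme_minimal()
}
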