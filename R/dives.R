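# Dive segmentation and per-dive response parameters from tag depth series
# and acoustic-audit event tables.

#' Segment dives from a tag depth record
#'
#' Dives are maximal intervals with depth greater than
#' `surface_threshold_m`; the surfacing crossing times are found by linear
#' interpolation between samples. A dive is a deep foraging dive when it
#' contains at least one clicking period (a `click_start` in the audit
#' falling inside the dive).
#'
#' @param profile Tibble with `t_s` (strictly increasing) and `depth_m`
#'   (positive down).
#' @param audit Tibble with `t_s` and `event` in `click_start`,
#'   `click_end`, `buzz`.
#' @param surface_threshold_m Depth defining "at the surface", meters.
#' @return A tibble with `dive_id`, `t_leave_surface_s`,
#'   `t_return_surface_s`, `max_depth_m`, `is_deep_foraging`.
#' @export
segment_dives <- function(profile, audit, surface_threshold_m = 2) {
  assert_cols(profile, c("t_s", "depth_m"))
  assert_cols(audit, c("t_s", "event"))
  if (is.unsorted(profile$t_s, strictly = TRUE)) {
    abort("`profile$t_s` must be strictly increasing.")
  }
  if (nrow(audit) > 0 &&
      (min(audit$t_s) < min(profile$t_s) || max(audit$t_s) > max(profile$t_s))) {
    abort("Audit event times must lie within the depth record.")
  }
  thr <- surface_threshold_m
  under <- profile$depth_m > thr
  if (!any(under)) {
    return(tibble(dive_id = integer(), t_leave_surface_s = numeric(),
                  t_return_surface_s = numeric(), max_depth_m = numeric(),
                  is_deep_foraging = logical()))
  }
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dive_runs <- which(r$values)

  cross_time <- function(i0, i1) {
    # linear interpolation of the threshold crossing between samples i0, i1
    d0 <- profile$depth_m[i0]; d1 <- profile$depth_m[i1]
    if (d1 == d0) return(profile$t_s[i0])
    profile$t_s[i0] + (thr - d0) / (d1 - d0) *
      (profile$t_s[i1] - profile$t_s[i0])
  }
  click_starts <- audit$t_s[audit$event == "click_start"]
  purrr::map_dfr(seq_along(dive_runs), function(k) {
    a <- starts[dive_runs[k]]; b <- ends[dive_runs[k]]
    t_leave <- if (a == 1) profile$t_s[1] else cross_time(a - 1, a)
    t_return <- if (b == nrow(profile)) profile$t_s[b] else cross_time(b, b + 1)
    tibble(
      dive_id = k,
      t_leave_surface_s = t_leave,
      t_return_surface_s = t_return,
      max_depth_m = max(profile$depth_m[a:b]),
      is_deep_foraging = any(click_starts >= t_leave & click_starts <= t_return)
    )
  })
}

depth_at <- function(profile, t) {
  approx(profile$t_s, profile$depth_m, xout = t, rule = 2)$y
}

#' Compute the eleven per-dive response parameters
#'
#' For each deep foraging dive: descent duration is the time from leaving
#' the surface to the first click, and descent rate the depth at first click
#' divided by that duration; clicking duration runs from first to last
#' click; the silent ascent runs from the last regular click to the next
#' surfacing, with ascent rate the depth at last click divided by its
#' duration; dive depth is the maximum depth; dive duration is
#' surface-to-surface; buzz counts and the buzz rate (buzzes per second of
#' clicking) come from the audit. Pre- and post-dive intervals are the
#' surface times to the adjacent *deep foraging* dives and are missing at
#' the ends of the record. Depths at click times are linearly interpolated
#' from the depth series.
#'
#' @param dives Output of [segment_dives()].
#' @param profile,audit As in [segment_dives()].
#' @param buzz_scope Count buzzes anywhere in the dive (`"dive"`, default)
#'   or only within the clicking span (`"clicking"`).
#' @return A tibble with `dive_id` and the eleven parameters, one row per
#'   deep foraging dive.
#' @export
compute_dive_parameters <- function(dives, profile, audit,
                                    buzz_scope = c("dive", "clicking")) {
  assert_cols(dives, c("dive_id", "t_leave_surface_s", "t_return_surface_s",
                       "is_deep_foraging"))
  buzz_scope <- match.arg(buzz_scope)
  deep <- dives[dives$is_deep_foraging, , drop = FALSE]
  if (nrow(deep) == 0) {
    abort("No deep foraging dives (no dive contains a clicking period).")
  }
  in_any_dive <- vapply(audit$t_s, function(t) {
    any(t >= dives$t_leave_surface_s & t <= dives$t_return_surface_s)
  }, logical(1))
  if (any(!in_any_dive)) {
    abort(sprintf("%d audit event(s) fall outside every dive.",
                  sum(!in_any_dive)))
  }
  out <- purrr::map_dfr(seq_len(nrow(deep)), function(k) {
    d <- deep[k, ]
    sel <- audit$t_s >= d$t_leave_surface_s & audit$t_s <= d$t_return_surface_s
    ev <- audit[sel, ]
    t_first <- suppressWarnings(min(ev$t_s[ev$event == "click_start"]))
    t_last <- suppressWarnings(max(ev$t_s[ev$event == "click_end"]))
    if (!is.finite(t_first) || !is.finite(t_last) || t_last < t_first) {
      abort(sprintf("Dive %d has an unpaired clicking period.", d$dive_id))
    }
    buzzes <- ev$t_s[ev$event == "buzz"]
    if (buzz_scope == "clicking") {
      buzzes <- buzzes[buzzes >= t_first & buzzes <= t_last]
    }
    descent_duration <- t_first - d$t_leave_surface_s
    clicking_duration <- t_last - t_first
    ascent_duration <- d$t_return_surface_s - t_last
    tibble(
      dive_id = d$dive_id,
      pre_dive_interval_s = NA_real_,
      descent_rate_mps = depth_at(profile, t_first) / descent_duration,
      descent_duration_s = descent_duration,
      clicking_duration_s = clicking_duration,
      n_buzzes = length(buzzes),
      buzz_rate_per_s = length(buzzes) / clicking_duration,
      dive_depth_m = max(profile$depth_m[profile$t_s >= d$t_leave_surface_s &
                                           profile$t_s <= d$t_return_surface_s]),
      ascent_rate_mps = depth_at(profile, t_last) / ascent_duration,
      silent_ascent_duration_s = ascent_duration,
      dive_duration_s = d$t_return_surface_s - d$t_leave_surface_s,
      post_dive_interval_s = NA_real_,
      t_leave_surface_s = d$t_leave_surface_s,
      t_return_surface_s = d$t_return_surface_s
    )
  })
  # Surface intervals between consecutive deep foraging dives.
  if (nrow(out) > 1) {
    out$pre_dive_interval_s[-1] <-
      out$t_leave_surface_s[-1] - out$t_return_surface_s[-nrow(out)]
    out$post_dive_interval_s[-nrow(out)] <- out$pre_dive_interval_s[-1]
  }
  out[, setdiff(names(out), c("t_leave_surface_s", "t_return_surface_s"))]
}

#' Compare dive parameters between baseline and exposure dives
#'
#' Produces per-parameter descriptive statistics by condition label and
#' histogram counts on bins shared across labels, for response-parameter
#' displays comparing exposure dives to baseline dives. The full per-dive
#' table is retained for export to external model fitting.
#'
#' @param params Dive-parameter tibble with an added `label` column (e.g.
#'   `"baseline"` / `"exposure"`).
#' @param bins Number of shared histogram bins per parameter.
#' @return An object of class `dive_phase_comparison`: list with `summary`,
#'   `histograms` and `data`. See [tidy()] and [autoplot()].
#' @export
phase_compare_table <- function(params, bins = 10) {
  assert_cols(params, "label")
  param_cols <- intersect(
    c("pre_dive_interval_s", "descent_rate_mps", "descent_duration_s",
      "clicking_duration_s", "n_buzzes", "buzz_rate_per_s", "dive_depth_m",
      "ascent_rate_mps", "silent_ascent_duration_s", "dive_duration_s",
      "post_dive_interval_s"),
    names(params)
  )
  if (length(param_cols) == 0) abort("No dive-parameter columns found.")
  labs <- unique(params$label)
  n_by <- table(params$label)
  if (any(n_by == 0) || length(labs) < 1) {
    abort("Every label must have at least one dive.")
  }
  long <- tidyr::pivot_longer(params[, c("label", param_cols)],
                              cols = dplyr::all_of(param_cols),
                              names_to = "parameter", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  summary <- long |>
    dplyr::group_by(.data$parameter, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      min = min(.data$value),
      median = median(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
  histograms <- long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      rng <- range(df$value)
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      breaks <- seq(rng[1], rng[2], length.out = bins + 1)
      purrr::map_dfr(unique(df$label), function(l) {
        h <- graphics::hist(df$value[df$label == l], breaks = breaks,
                            plot = FALSE)
        tibble(label = l, bin_left = head(breaks, -1),
               bin_right = tail(breaks, -1), count = h$counts)
      })
    }) |>
    dplyr::ungroup()
  structure(
    list(summary = summary, histograms = histograms, data = params),
    class = "dive_phase_comparison"
  )
}

#' @export
tidy.dive_phase_comparison <- function(x, ...) x$summary

#' @export
print.dive_phase_comparison <- function(x, ...) {
  cat("<dive_phase_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.dive_phase_comparison <- function(object, ...) {
  h <- object$histograms
  ggplot2::ggplot(h, ggplot2::aes(
    xmin = .data$bin_left, xmax = .data$bin_right,
    ymin = 0, ymax = .data$count, fill = .data$label
  )) +
    ggplot2::geom_rect(alpha = 0.6, colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_manual(values = c("grey60", "red"),
                               breaks = unique(h$label)) +
    ggplot2::labs(x = NULL, y = "dives", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dive profile with its clicking periods
#'
#' @param profile,audit As in [segment_dives()].
#' @return A ggplot object (depth increasing downward, clicking span in
#'   blue, buzzes marked).
#' @export
plot_dive_profile <- function(profile, audit) {
  assert_cols(profile, c("t_s", "depth_m"))
  cs <- audit$t_s[audit$event == "click_start"]
  ce <- audit$t_s[audit$event == "click_end"]
  clicking <- rep(FALSE, nrow(profile))
  for (i in seq_along(cs)) {
    clicking <- clicking | (profile$t_s >= cs[i] & profile$t_s <= ce[i])
  }
  df <- dplyr::mutate(profile, clicking = clicking)
  bz <- audit[audit$event == "buzz", ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s / 3600,
                                        y = .data$depth_m)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = df[df$clicking, ], colour = "blue",
                        size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (h)", y = "depth (m)") +
    ggplot2::theme_minimal()
  if (nrow(bz) > 0) {
    bz$depth_m <- depth_at(profile, bz$t_s)
    p <- p + ggplot2::geom_point(data = bz,
                                 ggplot2::aes(x = .data$t_s / 3600,
                                              y = .data$depth_m),
                                 colour = "red", size = 0.8)
  }
  p
}
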