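# Group clicking period (GCP) detection.
#
# A GCP is the interval over which echolocation click trains from one
# foraging group are detected on a cluster of nearby hydrophones. Detection
# works on click-train event tables (one row per train per hydrophone):
# events are linked when their hydrophones lie within the cluster adjacency
# radius and their trains are separated by no more than the end-gap; the
# connected components of that graph are candidate GCPs. A component becomes
# a GCP at the earliest click for which the following `min_clicks` clicks fit
# inside a `start_window_s` window, and it ends at the end of its last click
# train (which, by construction, is followed by more than `end_gap_s` of
# silence on that cluster). Per-click times are not carried in event tables,
# so clicks are taken to be uniformly spread across each train.

#' Detect group clicking periods from click-train events
#'
#' @param events Tibble of click-train events with columns `phone_id`,
#'   `start_s`, `end_s`, `n_clicks` (and optionally `species`; filter to the
#'   target species before calling). Events with `start_s >= end_s` are
#'   dropped with a warning.
#' @param array Hydrophone array tibble (`phone_id`, `x_m`, `y_m`); must
#'   contain every `phone_id` referenced by `events`.
#' @param start_window_s Window length for the opening rule, seconds.
#' @param min_clicks Minimum clicks within `start_window_s` to open a GCP.
#' @param end_gap_s Silence needed to close a GCP, seconds.
#' @param adjacency_radius_m Hydrophones within this distance belong to the
#'   same cluster; defaults to the maximum click detection range.
#' @return A tibble with one row per GCP: `gcp_id`, `start_s`, `end_s`,
#'   `phones` (list-column of phone ids), `n_events`, `n_clicks`, `on_edge`
#'   (NA until [tag_gcp_edge()]), `phase` (NA until assigned), sorted by
#'   `start_s`.
#' @examples
#' arr <- tibble::tibble(phone_id = "H001", x_m = 0, y_m = 0, depth_m = 1000)
#' ev <- tibble::tibble(phone_id = "H001", start_s = 0, end_s = 25,
#'                      n_clicks = 8, species = "Md")
#' detect_gcps(ev, arr)
#' @export
detect_gcps <- function(events, array, start_window_s = 30, min_clicks = 5,
                        end_gap_s = 180, adjacency_radius_m = 6500) {
  assert_cols(events, c("phone_id", "start_s", "end_s", "n_clicks"))
  assert_cols(array, c("phone_id", "x_m", "y_m"))
  assert_scalar_number(start_window_s, "start_window_s", positive = TRUE)
  assert_scalar_number(end_gap_s, "end_gap_s", positive = TRUE)
  assert_scalar_number(adjacency_radius_m, "adjacency_radius_m", positive = TRUE)

  unknown <- setdiff(unique(events$phone_id), array$phone_id)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown phone_id(s) in events: %s.",
                  paste(unknown, collapse = ", ")))
  }
  bad <- events$start_s >= events$end_s
  if (any(bad)) {
    warn(sprintf("Dropping %d event(s) with start_s >= end_s.", sum(bad)))
    events <- events[!bad, , drop = FALSE]
  }
  empty <- tibble(
    gcp_id = integer(), start_s = numeric(), end_s = numeric(),
    phones = list(), n_events = integer(), n_clicks = integer(),
    on_edge = logical(), phase = character()
  )
  if (nrow(events) == 0) return(empty)

  events <- dplyr::arrange(events, .data$start_s, .data$end_s, .data$phone_id)
  n <- nrow(events)
  pos <- array[match(events$phone_id, array$phone_id), c("x_m", "y_m")]

  # Union-find over events: link events whose phones are within the
  # adjacency radius and whose trains are separated by <= end_gap_s.
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (events$start_s[j] - events$end_s[i] > end_gap_s) break
      gap <- max(events$start_s[i], events$start_s[j]) -
        min(events$end_s[i], events$end_s[j])
      if (gap > end_gap_s) next
      d2 <- (pos$x_m[i] - pos$x_m[j])^2 + (pos$y_m[i] - pos$y_m[j])^2
      if (d2 <= adjacency_radius_m^2) union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  one_component <- function(idx) {
    ev <- events[idx, , drop = FALSE]
    clicks <- unlist(lapply(seq_len(nrow(ev)), function(k) {
      m <- ev$n_clicks[k]
      if (m == 1) (ev$start_s[k] + ev$end_s[k]) / 2
      else seq(ev$start_s[k], ev$end_s[k], length.out = m)
    }))
    clicks <- sort(clicks)
    if (length(clicks) < min_clicks) return(NULL)
    span <- clicks[seq(min_clicks, length(clicks))] -
      clicks[seq_len(length(clicks) - min_clicks + 1)]
    hit <- which(span <= start_window_s)
    if (length(hit) == 0) return(NULL)
    tibble(
      start_s = clicks[hit[1]],
      end_s = max(ev$end_s),
      phones = list(sort(unique(ev$phone_id))),
      n_events = nrow(ev),
      n_clicks = as.integer(sum(ev$n_clicks))
    )
  }
  out <- dplyr::bind_rows(lapply(split(seq_len(n), comp), one_component))
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, .data$start_s, .data$end_s)
  out$gcp_id <- seq_len(nrow(out))
  out$on_edge <- NA
  out$phase <- NA_character_
  out[, c("gcp_id", "start_s", "end_s", "phones", "n_events", "n_clicks",
          "on_edge", "phase")]
}

#' Identify edge hydrophones of an array
#'
#' Edge hydrophones are the outermost phones at the perimeter of the range,
#' taken as the convex hull of the planar positions. `rings = 2` also
#' includes the hull of the remaining interior phones (one ring of dilation),
#' and so on.
#'
#' @param array Hydrophone array tibble (`phone_id`, `x_m`, `y_m`).
#' @param rings Number of successive convex-hull rings to include (>= 1).
#' @return Character vector of edge `phone_id`s.
#' @examples
#' arr <- generate_array(9, spacing_m = 1000, jitter_frac = 0, seed = 1)
#' classify_edge(arr)
#' @export
classify_edge <- function(array, rings = 1) {
  assert_cols(array, c("phone_id", "x_m", "y_m"))
  if (nrow(array) < 3) abort("Need at least 3 phones to define a perimeter.")
  xy <- cbind(array$x_m, array$y_m)
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1)) {
    abort("Degenerate geometry: phones are collinear; no perimeter exists.")
  }
  edge <- character(0)
  remaining <- seq_len(nrow(array))
  for (r in seq_len(rings)) {
    if (length(remaining) == 0) break
    if (length(remaining) <= 2) {
      edge <- c(edge, array$phone_id[remaining])
      break
    }
    h <- hull_perimeter(array$x_m[remaining], array$y_m[remaining])
    edge <- c(edge, array$phone_id[remaining[h]])
    remaining <- remaining[-h]
  }
  sort(unique(edge))
}

# Indices of all points on the convex-hull boundary, including points lying
# on hull edges (chull alone returns only the vertices, which would miss
# mid-edge phones of a regular grid perimeter).
hull_perimeter <- function(x, y) {
  v <- chull(x, y)
  if (length(v) < 3) return(seq_along(x))
  on_boundary <- logical(length(x))
  on_boundary[v] <- TRUE
  scale <- max(diff(range(x)), diff(range(y)))
  tol <- 1e-9 * scale^2
  for (k in seq_along(v)) {
    a <- v[k]
    b <- v[if (k == length(v)) 1 else k + 1]
    cross <- (x - x[a]) * (y[b] - y[a]) - (y - y[a]) * (x[b] - x[a])
    dot <- (x - x[a]) * (x[b] - x[a]) + (y - y[a]) * (y[b] - y[a])
    len2 <- (x[b] - x[a])^2 + (y[b] - y[a])^2
    on_seg <- abs(cross) <= tol & dot >= -tol & dot <= len2 + tol
    on_boundary <- on_boundary | on_seg
  }
  which(on_boundary)
}

#' Flag GCPs detected on edge hydrophones
#'
#' @param gcps GCP tibble from [detect_gcps()].
#' @param edge_ids Character vector of edge phone ids, e.g. from
#'   [classify_edge()].
#' @param rule `"any"`: a GCP is on the edge if any of its detecting phones
#'   is an edge phone; `"majority"`: if more than half are.
#' @return The GCP tibble with `on_edge` filled in.
#' @export
tag_gcp_edge <- function(gcps, edge_ids, rule = c("any", "majority")) {
  assert_cols(gcps, c("phones", "on_edge"))
  rule <- match.arg(rule)
  gcps$on_edge <- vapply(gcps$phones, function(ph) {
    k <- sum(ph %in% edge_ids)
    if (rule == "any") k > 0 else k > length(ph) / 2
  }, logical(1))
  gcps
}
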