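test_that("opening rule: 5 clicks in 30 s opens a GCP, 4 do not", {
  arr <- square_array(3)
  g <- detect_gcps(train("H001", 0, 25, 5), arr)
  expect_equal(nrow(g), 1)
  expect_equal(g$start_s, 0)
  expect_equal(g$end_s, 25)
  expect_equal(g$phones[[1]], "H001")
  expect_equal(nrow(detect_gcps(train("H001", 0, 25, 4), arr)), 0)
})

test_that("gap rule merges trains within 3 min and splits beyond it", {
  arr <- square_array(3)
  ev <- dplyr::bind_rows(
    train("H001", 0, 60, 20),
    train("H002", 200, 260, 20),  # adjacent phone, 140-s gap: merges
    train("H001", 800, 860, 20)   # 540-s gap: new GCP
  )
  g <- detect_gcps(ev, arr, end_gap_s = 180)
  # brute-force expectation: clicks at 0..60 and 200..260 are never separated
  # by more than 180 s, so one GCP spans [0, 260]; the 800-860 train stands
  # alone
  expect_equal(nrow(g), 2)
  expect_equal(g$start_s, c(0, 800))
  expect_equal(g$end_s, c(260, 860))
  expect_setequal(g$phones[[1]], c("H001", "H002"))
})

test_that("simultaneous GCPs on disjoint clusters are reported separately", {
  arr <- square_array(5, spacing_m = 4000)  # 16-km extent
  far_a <- "H001"  # corner (0, 0)
  far_b <- "H025"  # corner (16 km, 16 km): well beyond adjacency radius
  ev <- dplyr::bind_rows(
    train(far_a, 0, 100, 30),
    train(far_b, 10, 110, 30)
  )
  g <- detect_gcps(ev, arr, adjacency_radius_m = 6500)
  expect_equal(nrow(g), 2)
})

test_that("event order does not change the result", {
  arr <- square_array(3)
  ev <- dplyr::bind_rows(
    train("H002", 200, 260, 20),
    train("H001", 0, 60, 20),
    train("H001", 800, 860, 20)
  )
  g1 <- detect_gcps(ev, arr)
  g2 <- detect_gcps(ev[c(3, 1, 2), ], arr)
  expect_equal(g1, g2)
})

test_that("invalid events are handled as specified", {
  arr <- square_array(3)
  expect_error(detect_gcps(train("H999", 0, 10, 9), arr), "Unknown phone_id")
  expect_warning(
    g <- detect_gcps(dplyr::bind_rows(train("H001", 0, 30, 9),
                                      train("H001", 50, 40, 9)), arr),
    "start_s >= end_s"
  )
  expect_equal(nrow(g), 1)
})

test_that("detection is idempotent on its own merged output", {
  arr <- square_array(3)
  ev <- dplyr::bind_rows(
    train("H001", 0, 60, 20),
    train("H002", 100, 160, 20),
    train("H001", 700, 760, 20)
  )
  g1 <- detect_gcps(ev, arr)
  # feed detected intervals back as single trains on one cluster phone
  ev2 <- purrr::map_dfr(seq_len(nrow(g1)), function(i) {
    train(g1$phones[[i]][1], g1$start_s[i], g1$end_s[i], g1$n_clicks[i])
  })
  g2 <- detect_gcps(ev2, arr)
  expect_equal(g2$start_s, g1$start_s)
  expect_equal(g2$end_s, g1$end_s)
})

test_that("convex-hull edge classification finds the perimeter", {
  # exhaustive check on a 3x3 grid: all but the centre phone are on the hull
  arr <- square_array(3)
  edge <- classify_edge(arr)
  expect_setequal(edge, setdiff(arr$phone_id, "H005"))
  # 4 corners of a square
  sq <- square_array(2)
  expect_setequal(classify_edge(sq), sq$phone_id)
  # one dilation ring of a 4x4 grid covers everything
  a4 <- square_array(4)
  expect_setequal(classify_edge(a4, rings = 2), a4$phone_id)
})

test_that("degenerate geometries are rejected", {
  coll <- tibble::tibble(phone_id = c("a", "b", "c"),
                         x_m = c(0, 1, 2), y_m = c(0, 1, 2), depth_m = 0)
  expect_error(classify_edge(coll), "collinear")
  expect_error(classify_edge(coll[1:2, ]), "at least 3")
})

test_that("edge tagging follows the membership rule", {
  gcps <- tibble::tibble(
    gcp_id = 1:3, start_s = c(0, 10, 20), end_s = c(5, 15, 25),
    phones = list("H005", c("H001", "H005"), c("H001", "H002", "H005")),
    on_edge = NA, phase = NA_character_
  )
  edge <- classify_edge(square_array(3))
  any_rule <- tag_gcp_edge(gcps, edge, rule = "any")
  expect_equal(any_rule$on_edge, c(FALSE, TRUE, TRUE))
  maj_rule <- tag_gcp_edge(gcps, edge, rule = "majority")
  expect_equal(maj_rule$on_edge, c(FALSE, FALSE, TRUE))
})
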