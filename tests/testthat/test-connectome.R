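test_that("connection weight is the scaled sum of inverse streamline lengths", {
  p <- parcellation(c("A", "B", "C"))
  recs <- data.frame(region_a = c("A", "A"), region_b = c("B", "B"),
                     length = c(2, 4))
  m <- build_connectivity_matrix(streamline_set(recs), p, threshold = 0)
  expect_equal(m$weights["A", "B"], 0.75)
  expect_equal(m$weights["B", "A"], 0.75)
  expect_equal(m$weights["A", "C"], 0)

  # scale multiplies every weight; threshold keeps weights at/above it
  m2 <- build_connectivity_matrix(streamline_set(recs, scale = 2), p,
                                  threshold = 1)
  expect_equal(m2$weights["A", "B"], 1.5)

  # sub-threshold weights are pruned to zero
  m3 <- build_connectivity_matrix(streamline_set(recs), p, threshold = 1)
  expect_equal(m3$weights["A", "B"], 0)

  # empty record list gives an all-zero matrix
  empty <- streamline_set(data.frame(region_a = character(),
                                     region_b = character(),
                                     length = numeric()))
  m0 <- build_connectivity_matrix(empty, p, threshold = 0)
  expect_true(all(m0$weights == 0))
})

test_that("invalid streamline records are rejected with context", {
  p <- parcellation(c("A", "B"))
  expect_error(streamline_set(data.frame(region_a = "A", region_b = "B",
                                         length = -1)), "record")
  expect_error(streamline_set(data.frame(region_a = "A", region_b = "A",
                                         length = 2)), "self-loop")
  s <- streamline_set(data.frame(region_a = "A", region_b = "Z",
                                 length = 2))
  expect_error(build_connectivity_matrix(s, p, 0), "Z")
  expect_error(streamline_set(data.frame(region_a = "A", region_b = "Z",
                                         length = 2), parcellation = p),
               "Z")
  expect_error(streamline_set(data.frame(region_a = "A", region_b = "B",
                                         length = 1), scale = 0),
               "scale")
})

test_that("building is permutation-equivariant and additive over records", {
  set.seed(41)
  labels <- LETTERS[1:6]
  p <- parcellation(labels)
  recs <- data.frame(
    region_a = sample(labels, 40, replace = TRUE),
    region_b = sample(labels, 40, replace = TRUE),
    length = runif(40, 1, 50))
  recs <- recs[recs$region_a != recs$region_b, ]
  m <- build_connectivity_matrix(streamline_set(recs), p, 0)

  perm <- sample(labels)
  p2 <- parcellation(perm)
  m2 <- build_connectivity_matrix(streamline_set(recs), p2, 0)
  expect_equal(m2$weights[labels, labels], m$weights[labels, labels])

  half <- nrow(recs) %/% 2
  ma <- build_connectivity_matrix(streamline_set(recs[1:half, ]), p, 0)
  mb <- build_connectivity_matrix(
    streamline_set(recs[(half + 1):nrow(recs), ]), p, 0)
  expect_equal(ma$weights + mb$weights, m$weights)
})

test_that("thresholding is idempotent and monotone in the threshold", {
  set.seed(42)
  m <- make_cm(random_weights(8, 0.7, 3))
  t1 <- apply_threshold(m, 1)
  expect_equal(apply_threshold(t1, 1)$weights, t1$weights)
  t2 <- apply_threshold(m, 2)
  expect_true(all(t2$weights <= t1$weights))
  expect_lte(sum(t2$weights > 0), sum(t1$weights > 0))
  expect_true(all(t1$weights[t1$weights > 0] >= 1))
})

test_that("edge-list TSV round trip is lossless and symmetric", {
  set.seed(43)
  m <- make_cm(random_weights(7, 0.6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(m, path)
  m2 <- read_edge_list(path, m$parcellation)
  expect_equal(m2$weights, m$weights)

  # a single listed edge populates both triangles
  p <- parcellation(c("A", "B"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_a\tregion_b\tweight", "A\tB\t1.5"), f)
  m3 <- read_edge_list(f, p)
  expect_equal(m3$weights["A", "B"], 1.5)
  expect_equal(m3$weights["B", "A"], 1.5)
})

test_that("malformed and inconsistent edge lists are rejected by line", {
  p <- parcellation(c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_a\tregion_b\tweight", "A\tB\t1.5", "B\tA\t2.0"), f)
  expect_error(read_edge_list(f, p), "inconsistent duplicate")
  writeLines(c("region_a\tregion_b\tweight", "A\tB\t1.5", "B\tA\t1.5"), f)
  expect_equal(read_edge_list(f, p)$weights["A", "B"], 1.5)
  writeLines(c("region_a\tregion_b\tweight", "A\tB\tnot_a_number"), f)
  expect_error(read_edge_list(f, p), "line 2")
  writeLines(c("region_a\tregion_b\tweight", "A\tB"), f)
  expect_error(read_edge_list(f, p), "line 2")
})

test_that("streamline TSV and parcellation CSV round trip", {
  p <- parcellation(c("A", "B", "C"), rich_club = "A")
  s <- streamline_set(data.frame(region_a = c("A", "B"),
                                 region_b = c("B", "C"),
                                 length = c(2.5, 10)),
                      scale = 1.5, subject_id = "S9", wave = "followup")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_streamlines(s, f)
  s2 <- read_streamlines(f, p)
  expect_equal(s2$records, s$records)
  expect_equal(s2$scale, 1.5)
  expect_equal(s2$subject_id, "S9")
  expect_equal(s2$wave, "followup")

  g <- withr::local_tempfile(fileext = ".csv")
  write_parcellation(p, g)
  p2 <- read_parcellation(g)
  expect_equal(p2$labels, p$labels)
  expect_equal(p2$rich_club, "A")
})
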