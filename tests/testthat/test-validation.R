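test_that("dbscan handles degenerate point sets", {
  five <- matrix(1, 5, 3)
  expect_equal(dbscan_labels(five, eps = 1, min_pts = 3), rep(0L, 5))
  spread <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  expect_equal(dbscan_labels(spread, eps = 1, min_pts = 2), rep(-1L, 3))
  expect_equal(dbscan_labels(matrix(numeric(0), 0, 3), 1, 2), integer(0))
  # min_pts above the point count: everything is noise
  expect_equal(dbscan_labels(five[1:2, ], eps = 1, min_pts = 3), rep(-1L, 2))
})

test_that("dbscan matches the brute-force density-connectivity oracle", {
  set.seed(91)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    # lumpy data: a few Gaussian blobs plus uniform background
    centers <- matrix(runif(9, 0, 10), 3, 3)
    pts <- rbind(
      centers[sample(3, ceiling(n / 2), replace = TRUE), ] +
        matrix(rnorm(3 * ceiling(n / 2), sd = 0.4), ncol = 3),
      matrix(runif(3 * floor(n / 2), 0, 10), ncol = 3)
    )
    eps <- runif(1, 0.3, 3)
    min_pts <- sample(2:6, 1)
    labels <- dbscan_labels(pts, eps, min_pts)
    oracle <- oracle_dbscan(pts, eps, min_pts)
    # same noise set
    expect_equal(labels == -1L, oracle$noise)
    # core points carry the same partition (up to label names)
    core <- oracle$core
    expect_true(all(labels[core] >= 0))
    expect_equal(outer(labels[core], labels[core], `==`),
                 outer(oracle$comp[core], oracle$comp[core], `==`))
    # border points sit in a cluster owned by one of their core neighbors
    border <- !core & labels >= 0
    for (b in which(border)) {
      expect_true(labels[b] %in% labels[oracle$adj[b, ] & core])
    }
  }
})

test_that("dbscan noise and cluster count are order-invariant; eps monotone", {
  set.seed(17)
  pts <- rbind(matrix(rnorm(30, 0, 0.5), ncol = 3),
               matrix(rnorm(30, 5, 0.5), ncol = 3),
               matrix(runif(15, -5, 10), ncol = 3))
  base <- dbscan_labels(pts, eps = 1.5, min_pts = 4)
  for (i in 1:5) {
    perm <- sample(nrow(pts))
    rel <- dbscan_labels(pts[perm, ], eps = 1.5, min_pts = 4)
    expect_equal(sort(which(rel == -1L)), sort(which(base[perm] == -1L)))
    expect_equal(length(unique(rel[rel >= 0])),
                 length(unique(base[base >= 0])))
  }
  noise_count <- vapply(c(0.2, 0.5, 1, 2, 4, 8),
                        function(e) sum(dbscan_labels(pts, e, 4) == -1L),
                        numeric(1))
  expect_true(all(diff(noise_count) <= 0))
})

test_that("twcv evaluates the within-cluster variance formula", {
  same <- matrix(2, 6, 3)
  expect_equal(twcv(same, rep(0L, 6)), 0)
  # two points at distance 2: each 1 from the centroid -> mean sq dev 1
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(twcv(two, c(0L, 0L)), 1)
  expect_equal(twcv(two, c(-1L, -1L)), 0)  # noise only
  set.seed(23)
  for (i in 1:20) {
    pts <- matrix(rnorm(90), ncol = 3)
    labels <- sample(c(-1L, 0L, 1L, 2L), 30, replace = TRUE)
    direct <- sum(vapply(0:2, function(k) {
      m <- pts[labels == k, , drop = FALSE]
      if (!nrow(m)) return(0)
      mean(apply(m, 1, function(x) sum((x - colMeans(m))^2)))
    }, numeric(1)))
    expect_equal(twcv(pts, labels), direct, tolerance = 1e-12)
  }
})

test_that("twcv is translation invariant and scales quadratically", {
  set.seed(5)
  pts <- matrix(rnorm(60), ncol = 3)
  labels <- rep(c(0L, 1L), each = 10)
  t0 <- twcv(pts, labels)
  expect_equal(twcv(pts + matrix(c(3, -2, 7), 20, 3, byrow = TRUE), labels),
               t0)
  expect_equal(twcv(pts * 2.5, labels), 2.5^2 * t0)
})

test_that("validation runs its decision rules in order", {
  spec <- validation_spec(min_complete_graphemes = 4, min_pts = 4,
                          min_num_clusters = 3, max_prop_single_cluster = 0.8)
  # one dominant color cluster across 6 complete graphemes
  mono <- make_participant(stats::setNames(
    replicate(6, rep("#CC0000", 3), simplify = FALSE), LETTERS[1:6]))
  r <- validate_participant(mono, spec)
  expect_false(r$valid)
  expect_equal(as.character(r$reason), "dominant_color_cluster")
  expect_equal(r$prop_largest_cluster, 1.0)
  expect_equal(r$num_clusters, 1L)

  # too few complete graphemes short-circuits before clustering
  sparse <- make_participant(list(A = rep("#CC0000", 3),
                                  B = rep("#00CC00", 3),
                                  C = rep("#0000CC", 3),
                                  D = c("#CC0000", NA, "#CC0000")))
  r2 <- validate_participant(sparse, spec)
  expect_false(r2$valid)
  expect_equal(as.character(r2$reason), "too_few_complete_graphemes")
  expect_equal(r2$num_complete_graphemes, 3L)
  expect_true(is.na(r2$twcv) && is.na(r2$prop_largest_cluster))

  # few clusters with low spread: too few distinct colors
  two_col <- make_participant(stats::setNames(c(
    replicate(3, rep("#CC0000", 3), simplify = FALSE),
    replicate(3, rep("#0000CC", 3), simplify = FALSE)), LETTERS[1:6]))
  r3 <- validate_participant(two_col, spec)
  expect_false(r3$valid)
  expect_equal(as.character(r3$reason), "too_few_distinct_colors")
  expect_equal(r3$num_clusters, 2L)

  # a well-separated synthetic synesthete passes
  syn <- gen_participant(archetype_params("synesthete", seed = 303), "s")
  r4 <- validate_participant(syn, spec)
  expect_true(r4$valid)
  expect_gte(r4$num_clusters, 3)
})

test_that("an empty participant with no required graphemes is decided by rule 5", {
  p <- make_participant(list(A = c(NA_character_, NA, NA)))
  spec0 <- validation_spec(min_complete_graphemes = 0)
  r <- validate_participant(p, spec0)
  expect_false(r$valid)
  expect_equal(as.character(r$reason), "too_few_distinct_colors")
  expect_equal(r$num_clusters, 0L)
  expect_equal(r$twcv, 0)
  # ... and is valid when no distinct colors are required either
  r2 <- validate_participant(p, validation_spec(min_complete_graphemes = 0,
                                                min_num_clusters = 0))
  expect_true(r2$valid)
})

test_that("the rater_strict preset tightens the dominant-color rule to 60%", {
  expect_equal(validation_preset("rater_strict")$max_prop_single_cluster, 0.6)
  expect_equal(validation_preset("default")$max_prop_single_cluster, 0.8)
  # 13 of 18 responses (72%) one color: valid by default, invalid for raters
  p <- make_participant(stats::setNames(c(
    replicate(4, rep("#BB0000", 3), simplify = FALSE),
    list(c("#BB0000", "#00BB00", "#00BB00")),
    list(c("#0000BB", "#0000BB", "#EEEE00"))), LETTERS[1:6]))
  expect_true(validate_participant(p, validation_spec(min_pts = 2))$valid)
  expect_false(validate_participant(
    p, validation_preset("rater_strict", min_pts = 2))$valid)
})

test_that("group validation preserves order and handles empty groups", {
  sim <- gen_group(list(list(archetype_params("synesthete"), 2),
                        list(archetype_params("single_color"), 1)),
                   seed = 77)
  res <- validate_group(sim$group)
  expect_equal(res$participant_id, participant_ids(sim$group))
  expect_equal(nrow(res), 3)
  empty <- build_group(data.frame(participant_id = character(),
                                  symbol = character(),
                                  response_color = character()))
  expect_equal(nrow(validate_group(empty)), 0)
})
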