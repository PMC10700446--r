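test_that("scoring config applies published cutoffs only where they exist", {
  expect_equal(scoring_config("euclidean", "Luv")$cutoff, 135)
  expect_equal(scoring_config("taxicab", "sRGB")$cutoff, 1)
  expect_null(scoring_config("taxicab", "Luv")$cutoff)
  expect_null(scoring_config("euclidean", "sRGB")$cutoff)
  expect_equal(scoring_config("euclidean", "sRGB", cutoff = 0.3)$cutoff, 0.3)
  expect_error(scoring_config(cutoff = -1), "cutoff")
})

test_that("grapheme scores are pairwise distance sums", {
  cfg_tax <- scoring_config("taxicab", "sRGB")
  # identical trials score 0
  expect_equal(grapheme_score(make_grapheme(rep("#ABCDEF", 3)),
                              scoring_config()), 0)
  # (0,0,0), (1,0,0), (0,1,0): taxicab pairs 1 + 1 + 2
  g <- make_grapheme(c("#000000", "#FF0000", "#00FF00"))
  expect_equal(grapheme_score(g, cfg_tax), 4)
  # euclidean on the same triple: 1 + 1 + sqrt(2)
  expect_equal(grapheme_score(g, scoring_config("euclidean", "sRGB")),
               2 + sqrt(2))
})

test_that("completeness rules gate grapheme scoring", {
  g2 <- make_grapheme(c("#FF0000", "#FF0000", NA))
  expect_true(is.na(grapheme_score(g2, scoring_config())))
  # with complete_only off, the two usable responses give one pair
  cfg <- scoring_config("taxicab", "sRGB", complete_only = FALSE)
  expect_equal(grapheme_score(g2, cfg), 0)
  g1 <- make_grapheme(c("#FF0000", NA, NA))
  expect_true(is.na(grapheme_score(g1, cfg)))  # < 2 usable responses
})

test_that("grapheme scores are invariant under trial permutation", {
  hex <- c("#102030", "#A0B0C0", "#FFEE00")
  cfg <- scoring_config("euclidean", "Luv")
  base <- grapheme_score(make_grapheme(hex), cfg)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(grapheme_score(make_grapheme(hex[perm]), cfg), base)
  }
})

test_that("scores scale with coordinates and ignore translations", {
  set.seed(31)
  for (metric in c("euclidean", "taxicab")) {
    m <- matrix(runif(9), 3, 3)
    score <- function(pts) sum(colorcons:::.pairwise_distances(pts, metric))
    s <- runif(1, 0.5, 3)
    expect_equal(score(m * s), s * score(m))
    shift <- matrix(runif(3), 3, 3, byrow = TRUE)
    expect_equal(score(m + shift), score(m))
  }
})

test_that("participant scores average scorable graphemes", {
  cfg <- scoring_config("taxicab", "sRGB")
  p <- make_participant(list(
    A = rep("#FF0000", 3),                   # score 0
    B = c("#000000", "#FF0000", "#00FF00"),  # score 4
    C = c("#FF0000", NA, "#FF0000")          # unscorable
  ))
  expect_equal(participant_score(p, cfg), 2)
  expect_true(is.na(participant_score(p, scoring_config(
    "taxicab", "sRGB", symbol_filter = c("1", "2")))))
  p_all_na <- make_participant(list(A = c(NA_character_, NA, NA)))
  expect_true(is.na(participant_score(p_all_na, cfg)))
})

test_that("group scores keep group order and report usable grapheme counts", {
  df <- rbind(
    make_trial_df(list(A = rep("#FF0000", 3),
                       B = c("#000000", "#FF0000", "#00FF00")), id = "z"),
    make_trial_df(list(A = c(NA, NA, NA)), id = "a")
  )
  grp <- build_group(df, color_space = "sRGB")
  tab <- group_scores(grp, scoring_config("taxicab", "sRGB"))
  expect_equal(tab$participant_id, c("z", "a"))  # group order, not sorted
  expect_equal(tab$score, c(2, NA))
  expect_equal(tab$n_graphemes_used, c(2, 0))
  # cutoff 1 applies by default; mean score 2 is not below it
  expect_equal(tab$synesthetic, c(FALSE, NA))

  empty <- build_group(data.frame(participant_id = character(),
                                  symbol = character(),
                                  response_color = character()))
  expect_equal(nrow(group_scores(empty, scoring_config())), 0)
})

test_that("classification is strictly below the cutoff", {
  expect_true(classify_synesthetic(134.9, 135))
  expect_false(classify_synesthetic(135, 135))
  expect_true(classify_synesthetic(0, 135))
  expect_false(classify_synesthetic(1, 1))
  expect_equal(classify_synesthetic(c(0.5, NA), 1), c(TRUE, NA))
})

test_that("mean colors are per-axis means over non-missing responses", {
  p <- make_participant(list(A = c("#000000", "#FFFFFF", NA)))
  expect_equal(unname(mean_color(p, "sRGB")), c(0.5, 0.5, 0.5))
  single <- make_participant(list(A = rep("#3366CC", 3)))
  expect_equal(
    unname(mean_color(single, "Luv")),
    unname(convert_color(parse_hex("#3366CC"), "Luv")[1, ])
  )
  none <- make_participant(list(A = c(NA_character_, NA, NA)))
  expect_true(all(is.na(mean_color(none, "Luv"))))
  expect_true(all(is.na(mean_color(p, "sRGB", symbol_filter = "Z"))))
})
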