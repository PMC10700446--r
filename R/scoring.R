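# Consistency scoring.
#
# Per grapheme, the consistency score is the sum of pairwise color distances
# over all unordered pairs of trial responses (for 3 trials: d12 + d13 + d23);
# a participant's score is the mean over scored graphemes. Lower scores mean
# more consistent responses. Two published scoring conventions are anchored
# here: taxicab distance on unit-normalized sRGB with synesthesia cutoff 1,
# and Euclidean distance in CIELUV with cutoff 135. Both cutoffs presume
# three trials per inducer; for other trial counts the pair-sum grows with
# the number of pairs and no published cutoff applies.

#' Scoring configuration
#'
#' Bundles the distance metric, the color space scores are computed in, an
#' optional symbol subset, the completeness rule, and the classification
#' cutoff. The cutoff defaults to the published value when one exists for the
#' metric/space pair: 135 for Euclidean CIELUV, 1 for taxicab sRGB; for other
#' pairs no default exists and `cutoff` stays `NULL` unless supplied.
#'
#' @param metric `"euclidean"` or `"taxicab"`.
#' @param color_space One of [color_spaces()].
#' @param symbol_filter Optional character vector of symbols to score.
#' @param complete_only If `TRUE` (default), a grapheme with any missing
#'   response is not scored; if `FALSE`, graphemes are scored over their
#'   non-missing responses when at least two are available (such scores stay
#'   on the smaller pair-count scale and are not rescaled).
#' @param cutoff Classification cutoff; scores strictly below it indicate
#'   synesthesia. `NULL` means no classification.
#' @return A `scoring_config` object.
#' @examples
#' scoring_config()                      # CIELUV Euclidean, cutoff 135
#' scoring_config("taxicab", "sRGB")     # Eagleman-style, cutoff 1
#' @export
scoring_config <- function(metric = c("euclidean", "taxicab"),
                           color_space = "Luv",
                           symbol_filter = NULL,
                           complete_only = TRUE,
                           cutoff = NULL) {
  metric <- match.arg(metric)
  color_space <- .match_space(color_space)
  if (is.null(cutoff)) {
    if (metric == "euclidean" && color_space == "Luv") cutoff <- 135
    if (metric == "taxicab" && color_space == "sRGB") cutoff <- 1
  } else if (cutoff <= 0) {
    stop("cutoff must be > 0", call. = FALSE)
  }
  structure(
    list(metric = metric, color_space = color_space,
         symbol_filter = symbol_filter, complete_only = complete_only,
         cutoff = cutoff),
    class = "scoring_config"
  )
}

#' Consistency score of one grapheme
#'
#' Sum of pairwise distances (per the config's metric, in the config's color
#' space) over all unordered pairs of the grapheme's responses. Returns `NA`
#' if the grapheme cannot be scored: any response missing under
#' `complete_only`, or fewer than two usable responses otherwise.
#'
#' @param grapheme A `grapheme` (see [build_group()]).
#' @param config A [scoring_config()].
#' @return Scalar score (>= 0) or `NA`.
#' @export
grapheme_score <- function(grapheme, config = scoring_config()) {
  stopifnot(inherits(grapheme, "grapheme"))
  rgb <- grapheme$rgb
  if (config$complete_only && anyNA(rgb)) return(NA_real_)
  rgb <- rgb[stats::complete.cases(rgb), , drop = FALSE]
  if (nrow(rgb) < 2L) return(NA_real_)
  pts <- convert_color(rgb, config$color_space)
  sum(.pairwise_distances(pts, config$metric))
}

#' Consistency score of one participant
#'
#' Arithmetic mean of the scorable grapheme scores, over graphemes passing
#' the config's `symbol_filter`. `NA` when no grapheme can be scored.
#'
#' @param participant A `participant`.
#' @param config A [scoring_config()].
#' @return Scalar score or `NA`.
#' @export
participant_score <- function(participant, config = scoring_config()) {
  stopifnot(inherits(participant, "participant"))
  gs <- participant$graphemes
  if (!is.null(config$symbol_filter)) {
    gs <- gs[names(gs) %in% config$symbol_filter]
  }
  scores <- vapply(gs, grapheme_score, numeric(1), config = config)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

#' Consistency scores for every participant in a group
#'
#' @param group A `participant_group`.
#' @param config A [scoring_config()]; defaults to Euclidean scoring in the
#'   group's working color space.
#' @return Tibble with one row per participant, in group order: columns
#'   `participant_id`, `score`, `n_graphemes_used`, and — when the config has
#'   a cutoff — logical `synesthetic` (score strictly below cutoff).
#' @export
group_scores <- function(group, config = NULL) {
  stopifnot(inherits(group, "participant_group"))
  if (is.null(config)) config <- scoring_config(color_space = group$color_space)
  n_used <- function(p) {
    gs <- p$graphemes
    if (!is.null(config$symbol_filter)) {
      gs <- gs[names(gs) %in% config$symbol_filter]
    }
    sum(!is.na(vapply(gs, grapheme_score, numeric(1), config = config)))
  }
  out <- tibble::tibble(
    participant_id = participant_ids(group),
    score = vapply(group$participants, participant_score, numeric(1),
                   config = config, USE.NAMES = FALSE),
    n_graphemes_used = vapply(group$participants, n_used, numeric(1),
                              USE.NAMES = FALSE)
  )
  if (!is.null(config$cutoff)) {
    out$synesthetic <- classify_synesthetic(out$score, config$cutoff)
  }
  out
}

#' Classify scores against a synesthesia cutoff
#'
#' A score strictly below the cutoff indicates synesthesia; the boundary
#' itself does not. `NA` scores give `NA` verdicts.
#'
#' @param score Numeric vector of consistency scores (>= 0).
#' @param cutoff Positive cutoff (e.g. 135 for CIELUV-Euclidean, 1 for
#'   sRGB-taxicab three-trial scores).
#' @return Logical vector.
#' @export
classify_synesthetic <- function(score, cutoff) {
  stopifnot(length(cutoff) == 1L, cutoff > 0)
  score < cutoff
}

#' Mean response color of a participant
#'
#' Per-axis arithmetic mean over all non-missing responses, after conversion
#' to the requested space.
#'
#' @param participant A `participant`.
#' @param space Target color space, one of [color_spaces()].
#' @param symbol_filter Optional character vector of symbols to include.
#' @return Named length-3 numeric vector, or all-`NA` when the participant has
#'   no non-missing response in the filter.
#' @export
mean_color <- function(participant, space = "Luv", symbol_filter = NULL) {
  stopifnot(inherits(participant, "participant"))
  space <- .match_space(space)
  rgb <- .participant_rgb(participant, symbol_filter)
  if (!nrow(rgb)) {
    return(stats::setNames(rep(NA_real_, 3L), c("axis1", "axis2", "axis3")))
  }
  colMeans(convert_color(rgb, space))
}

#' Write a scores table to CSV
#'
#' @param scores Tibble from [group_scores()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}
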