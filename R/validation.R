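# Automated validity classification.
#
# Consistency scores are only interpretable when a participant gave enough
# complete responses and used enough genuinely different colors: a respondent
# who picks (say) red on every trial scores "consistently" without any
# grapheme-color association. Validation therefore clusters a participant's
# response colors with DBSCAN and inspects (a) how many complete graphemes
# there are, (b) whether a single color cluster dominates the responses, and
# (c) whether there are enough distinct clusters / enough within-cluster
# spread (the total within-cluster variance, TWCV).

#' DBSCAN cluster labels for a set of points
#'
#' Classic density-based clustering with noise. A point is a core point when
#' its closed eps-neighborhood (Euclidean, radius inclusive, counting the
#' point itself) holds at least `min_pts` points. Clusters are the maximal
#' density-connected sets of core points, plus border points (non-core points
#' within `eps` of a cluster's core point); everything else is noise.
#'
#' The labeling is deterministic: points are processed in input order,
#' cluster ids are assigned in discovery order starting at 0, and a border
#' point reachable from several clusters is assigned to the first cluster
#' that reaches it.
#'
#' @param points Numeric matrix, one row per point (any dimension; here
#'   3-column color coordinates in one color space).
#' @param eps Neighborhood radius, in the units of `points`.
#' @param min_pts Minimum neighborhood size (including the point itself) for
#'   a core point; at least 2.
#' @return Integer vector of labels aligned to the rows of `points`:
#'   cluster ids `0 .. k-1`, noise = `-1`. Empty input gives an empty vector.
#' @export
dbscan_labels <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 2)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    labels[i] <- next_id
    queue <- nbrs[[i]]
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.na(labels[j])) next
      labels[j] <- next_id
      if (core[j]) queue <- c(queue, nbrs[[j]][is.na(labels[nbrs[[j]]])])
    }
    next_id <- next_id + 1L
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Total within-cluster variance (TWCV)
#'
#' Sum over the non-noise clusters of the mean squared Euclidean distance of
#' the cluster's points to the cluster centroid:
#' \deqn{TWCV = \sum_c \frac{1}{n_c} \sum_{x \in c} \lVert x - \mu_c \rVert^2.}
#' Low TWCV together with few clusters signals too-homogeneous responses.
#' Noise points do not contribute; with no non-noise cluster the value is 0.
#'
#' @param points Numeric matrix of point coordinates.
#' @param labels Integer labels aligned to `points`, as from
#'   [dbscan_labels()] (noise = -1).
#' @return Non-negative scalar.
#' @export
twcv <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels)) {
    stop("labels must align with the rows of points", call. = FALSE)
  }
  ids <- unique(labels[labels >= 0L])
  if (!length(ids)) return(0)
  sum(vapply(ids, function(id) {
    m <- points[labels == id, , drop = FALSE]
    mu <- colMeans(m)
    mean(rowSums((m - matrix(mu, nrow(m), ncol(m), byrow = TRUE))^2))
  }, numeric(1)))
}

#' Validation criteria bundle
#'
#' The defaults operationalize the criteria "complete color response data for
#' at least 4 inducers, and at least 3 clearly different colors", plus a
#' dominant-color rule: data are invalid when 80% or more of all responses
#' fall in one color cluster. `eps`, `min_pts` and `safe_twcv` are expressed
#' in the working color space's units (the defaults assume CIELUV).
#'
#' @param min_complete_graphemes Minimum number of graphemes with a complete
#'   trial set.
#' @param eps DBSCAN neighborhood radius (working-space units).
#' @param min_pts DBSCAN core-point threshold (>= 2).
#' @param min_num_clusters Minimum number of color clusters ("clearly
#'   different colors") for valid data.
#' @param max_prop_single_cluster Data are invalid when the largest cluster
#'   holds at least this proportion of all responses (noise included in the
#'   denominator). In (0, 1].
#' @param safe_twcv TWCV at or above which data are considered to have enough
#'   color spread even with fewer than `min_num_clusters` clusters.
#' @param complete_graphemes_only If `TRUE` (default), only responses from
#'   complete graphemes enter the clustering.
#' @param symbol_filter Optional character vector restricting which symbols
#'   are considered.
#' @return A `validation_spec` object.
#' @seealso [validation_preset()] for named presets.
#' @export
validation_spec <- function(min_complete_graphemes = 4L,
                            eps = 20,
                            min_pts = 4L,
                            min_num_clusters = 3L,
                            max_prop_single_cluster = 0.8,
                            safe_twcv = 250,
                            complete_graphemes_only = TRUE,
                            symbol_filter = NULL) {
  stopifnot(
    min_complete_graphemes >= 0, eps > 0, min_pts >= 2,
    min_num_clusters >= 0,
    max_prop_single_cluster > 0, max_prop_single_cluster <= 1,
    safe_twcv >= 0
  )
  structure(
    list(
      min_complete_graphemes = as.integer(min_complete_graphemes),
      eps = eps,
      min_pts = as.integer(min_pts),
      min_num_clusters = as.integer(min_num_clusters),
      max_prop_single_cluster = max_prop_single_cluster,
      safe_twcv = safe_twcv,
      complete_graphemes_only = isTRUE(complete_graphemes_only),
      symbol_filter = symbol_filter
    ),
    class = "validation_spec"
  )
}

#' Named validation presets
#'
#' `"default"` is [validation_spec()] as documented there. `"rater_strict"`
#' mirrors human-rater criteria where using the same color for 60% or more of
#' all responses invalidates the data (`max_prop_single_cluster = 0.6`).
#'
#' @param name `"default"` or `"rater_strict"`.
#' @param ... Overrides passed to [validation_spec()].
#' @return A `validation_spec`.
#' @export
validation_preset <- function(name = c("default", "rater_strict"), ...) {
  name <- match.arg(name)
  args <- list(...)
  if (name == "rater_strict" && is.null(args$max_prop_single_cluster)) {
    args$max_prop_single_cluster <- 0.6
  }
  do.call(validation_spec, args)
}

.validation_reasons <- c("ok", "too_few_complete_graphemes",
                         "dominant_color_cluster", "too_few_distinct_colors")

#' Validate one participant's response data
#'
#' Decision procedure, in order:
#' 1. Too few complete graphemes (under `min_complete_graphemes`) makes the
#'    data invalid outright (cluster diagnostics are not computed).
#' 2. Responses (from complete graphemes only, under the default
#'    `complete_graphemes_only`) are converted to `space` and clustered with
#'    [dbscan_labels()].
#' 3. If the largest cluster holds at least `max_prop_single_cluster` of all
#'    responses, the data are invalid (dominant color).
#' 4. If there are fewer than `min_num_clusters` clusters and the TWCV falls
#'    below `safe_twcv`, the data are invalid (too few distinct colors).
#'    Note that widely scattered points can yield zero clusters and hence
#'    TWCV 0; such all-noise data fail this rule by design unless
#'    `min_num_clusters` is 0.
#' 5. Otherwise the data are valid.
#'
#' @param participant A `participant`.
#' @param spec A [validation_spec()].
#' @param space Color space in which to cluster, one of [color_spaces()];
#'   the spec's `eps` and `safe_twcv` must be on this space's scale.
#' @return One-row tibble: `participant_id`, `valid`, `reason`,
#'   `num_complete_graphemes`, `num_clusters`, `twcv`,
#'   `prop_largest_cluster`. `twcv` and `prop_largest_cluster` are `NA` when
#'   clustering was not reached.
#' @export
validate_participant <- function(participant, spec = validation_spec(),
                                 space = "Luv") {
  stopifnot(inherits(participant, "participant"),
            inherits(spec, "validation_spec"))
  space <- .match_space(space)
  res <- function(valid, reason, k = NA_integer_, t = NA_real_,
                  prop = NA_real_, n_cg) {
    tibble::tibble(
      participant_id = participant$id,
      valid = valid,
      reason = factor(reason, levels = .validation_reasons),
      num_complete_graphemes = n_cg,
      num_clusters = k,
      twcv = t,
      prop_largest_cluster = prop
    )
  }

  n_cg <- complete_symbol_count(participant, spec$symbol_filter)
  if (n_cg < spec$min_complete_graphemes) {
    return(res(FALSE, "too_few_complete_graphemes", n_cg = n_cg))
  }

  rgb <- .participant_rgb(participant, spec$symbol_filter,
                          complete_only = spec$complete_graphemes_only)
  pts <- convert_color(rgb, space)
  labels <- dbscan_labels(pts, spec$eps, spec$min_pts)
  k <- length(unique(labels[labels >= 0L]))
  prop <- if (k >= 1L) {
    max(tabulate(labels[labels >= 0L] + 1L)) / length(labels)
  } else 0
  t <- twcv(pts, labels)

  if (k >= 1L && prop >= spec$max_prop_single_cluster) {
    return(res(FALSE, "dominant_color_cluster", k, t, prop, n_cg))
  }
  if (k < spec$min_num_clusters && t < spec$safe_twcv) {
    return(res(FALSE, "too_few_distinct_colors", k, t, prop, n_cg))
  }
  res(TRUE, "ok", k, t, prop, n_cg)
}

#' Validate every participant in a group
#'
#' Applies [validate_participant()] to each participant, clustering in the
#' group's working color space.
#'
#' @param group A `participant_group`.
#' @param spec A [validation_spec()].
#' @return Tibble with one row per participant, in group order (columns as in
#'   [validate_participant()]).
#' @export
validate_group <- function(group, spec = validation_spec()) {
  stopifnot(inherits(group, "participant_group"))
  rows <- lapply(group$participants, validate_participant,
                 spec = spec, space = group$color_space)
  if (!length(rows)) {
    return(validate_participant(.new_participant("x", list()),
                                validation_spec(min_complete_graphemes = 1))[0, ])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a validation table to CSV
#'
#' @param results Tibble from [validate_group()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(results, path) {
  out <- results
  out$reason <- as.character(out$reason)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
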