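# Seeded synthetic consistency-test respondents.
#
# Generates participants of known archetype so scoring and validation can be
# exercised, and calibrated, against ground truth:
#   synesthete    - each symbol tied to one palette color (palette colors
#                   pairwise well separated), plus small per-trial jitter;
#   random        - every response uniform on the sRGB cube;
#   single_color  - one base color (plus jitter) for every response;
#   light_varying - hue varies freely but all responses are very light and
#                   desaturated (the pattern that artificially lowers
#                   CIELUV consistency scores);
#   few_colors    - every response drawn from a small shared palette.
# All draws use R's default RNG under an explicit seed; the same parameters
# and seed reproduce the same participant exactly.

.ARCHETYPES <- c("synesthete", "random", "single_color", "light_varying",
                 "few_colors")

#' Parameters for one synthetic respondent archetype
#'
#' @param archetype One of `"synesthete"`, `"random"`, `"single_color"`,
#'   `"light_varying"`, `"few_colors"`.
#' @param n_symbols Number of inducer symbols (default 10).
#' @param trials_per_symbol Trials per symbol (default 3, the standard test
#'   format).
#' @param palette_size Number of base colors for `synesthete` / `few_colors`
#'   (default 6); palette colors are drawn with pairwise sRGB Euclidean
#'   separation of at least 0.5.
#' @param jitter_sd Per-channel Gaussian jitter SD in sRGB units applied to
#'   palette/base colors (default 0.01); jittered values are clipped to the
#'   gamut.
#' @param lightness_range,saturation_range HSL lightness and saturation
#'   intervals for `light_varying` (defaults \[0.85, 0.97\] and \[0, 0.4\]);
#'   hue is always uniform on the circle.
#' @param missing_rate Probability that any single response is missing
#'   (default 0).
#' @param seed Integer RNG seed.
#' @return An `archetype_params` object.
#' @export
archetype_params <- function(archetype,
                             n_symbols = 10L,
                             trials_per_symbol = 3L,
                             palette_size = 6L,
                             jitter_sd = 0.01,
                             lightness_range = c(0.85, 0.97),
                             saturation_range = c(0, 0.4),
                             missing_rate = 0,
                             seed = 1L) {
  archetype <- match.arg(archetype, .ARCHETYPES)
  stopifnot(
    n_symbols >= 1, trials_per_symbol >= 1, palette_size >= 1,
    jitter_sd >= 0, missing_rate >= 0, missing_rate < 1,
    length(lightness_range) == 2L, length(saturation_range) == 2L
  )
  structure(
    list(archetype = archetype, n_symbols = as.integer(n_symbols),
         trials_per_symbol = as.integer(trials_per_symbol),
         palette_size = as.integer(palette_size), jitter_sd = jitter_sd,
         lightness_range = lightness_range,
         saturation_range = saturation_range,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "archetype_params"
  )
}

#' Convert HSL coordinates to sRGB
#'
#' Generation device for the `light_varying` archetype (analysis always runs
#' in the four supported spaces). Standard HSL-to-RGB formula.
#'
#' @param h Hue in \[0, 1) (fraction of the circle).
#' @param s Saturation in \[0, 1\].
#' @param l Lightness in \[0, 1\].
#' @return Numeric matrix (n x 3) of sRGB coordinates.
#' @export
hsl_to_srgb <- function(h, s, l) {
  h6 <- (h %% 1) * 6
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs(h6 %% 2 - 1))
  m <- l - c / 2
  seg <- floor(h6) %% 6
  r <- ifelse(seg == 0 | seg == 5, c, ifelse(seg == 1 | seg == 4, x, 0))
  g <- ifelse(seg == 1 | seg == 2, c, ifelse(seg == 0 | seg == 3, x, 0))
  b <- ifelse(seg == 3 | seg == 4, c, ifelse(seg == 2 | seg == 5, x, 0))
  cbind(R = r + m, G = g + m, B = b + m)
}

# Rejection-sample n sRGB colors with pairwise Euclidean separation >= min_sep
.separated_palette <- function(n, min_sep = 0.5, max_tries = 5000L) {
  pal <- matrix(numeric(0), ncol = 3L)
  tries <- 0L
  while (nrow(pal) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " palette colors with pairwise ",
           "separation ", min_sep, " in the sRGB cube", call. = FALSE)
    }
    cand <- stats::runif(3)
    if (nrow(pal) == 0L ||
        min(sqrt(rowSums((pal - matrix(cand, nrow(pal), 3,
                                       byrow = TRUE))^2))) >= min_sep) {
      pal <- rbind(pal, cand)
    }
  }
  pal
}

.clip01 <- function(m) pmin(pmax(m, 0), 1)

#' Generate one synthetic participant
#'
#' Draws a full set of trial responses according to the archetype in
#' `params` (see [archetype_params()]). Each response is independently
#' replaced by a missing response with probability `missing_rate`. The
#' generator is fully determined by `params` (including its `seed`); the
#' caller's RNG state is left untouched.
#'
#' @param params An [archetype_params()].
#' @param id Participant id string.
#' @return A `participant` whose `archetype` attribute records the ground
#'   truth.
#' @examples
#' p <- gen_participant(archetype_params("synesthete", seed = 7), "s1")
#' participant_score(p, scoring_config())
#' @export
gen_participant <- function(params, id = "p1") {
  stopifnot(inherits(params, "archetype_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(params$seed)

  ns <- params$n_symbols
  nt <- params$trials_per_symbol
  n <- ns * nt
  jitter <- function(base) {
    .clip01(base + matrix(stats::rnorm(length(base), sd = params$jitter_sd),
                          nrow(base), 3L))
  }
  rgb <- switch(params$archetype,
    synesthete = {
      pal <- .separated_palette(params$palette_size)
      sym_col <- pal[(seq_len(ns) - 1L) %% params$palette_size + 1L, ,
                     drop = FALSE]
      jitter(sym_col[rep(seq_len(ns), each = nt), , drop = FALSE])
    },
    random = matrix(stats::runif(3 * n), n, 3L),
    single_color = jitter(matrix(stats::runif(3), n, 3L, byrow = TRUE)),
    light_varying = hsl_to_srgb(
      stats::runif(n),
      stats::runif(n, params$saturation_range[1], params$saturation_range[2]),
      stats::runif(n, params$lightness_range[1], params$lightness_range[2])
    ),
    few_colors = {
      pal <- .separated_palette(params$palette_size)
      jitter(pal[sample.int(params$palette_size, n, replace = TRUE), ,
                 drop = FALSE])
    }
  )
  hex <- format_hex(rgb)
  if (params$missing_rate > 0) {
    hex[stats::runif(n) < params$missing_rate] <- NA_character_
  }

  symbols <- if (ns <= 26L) LETTERS[seq_len(ns)] else paste0("S", seq_len(ns))
  graphemes <- lapply(seq_len(ns), function(i) {
    .new_grapheme(symbols[i], hex[((i - 1L) * nt + 1L):(i * nt)])
  })
  names(graphemes) <- symbols
  p <- .new_participant(as.character(id), graphemes)
  attr(p, "archetype") <- params$archetype
  p
}

#' Generate a mixed group of synthetic participants
#'
#' Builds a `participant_group` from a mixture of archetypes, with a truth
#' table recording each participant's archetype. Each participant gets the
#' deterministic sub-seed `seed + index`, so a fixed `seed` reproduces the
#' group exactly.
#'
#' @param mixture A list of `list(params, count)` pairs, where `params` is an
#'   [archetype_params()] (its `seed` field is overridden by the derived
#'   sub-seed) and `count` the number of participants of that archetype.
#' @param seed Integer master seed.
#' @param color_space Working color space of the resulting group.
#' @return List with elements `group` (a `participant_group`) and `truth`
#'   (tibble: `participant_id`, `archetype`).
#' @examples
#' mix <- list(
#'   list(archetype_params("synesthete"), 2),
#'   list(archetype_params("random"), 2)
#' )
#' gen_group(mix, seed = 42)$truth
#' @export
gen_group <- function(mixture, seed = 1L, color_space = "Luv") {
  color_space <- .match_space(color_space)
  total <- sum(vapply(mixture, function(m) as.integer(m[[2]]), integer(1)))
  participants <- vector("list", total)
  archetypes <- character(total)
  idx <- 0L
  trials <- NULL
  for (m in mixture) {
    params <- m[[1]]
    stopifnot(inherits(params, "archetype_params"))
    count <- as.integer(m[[2]])
    if (is.null(trials)) trials <- params$trials_per_symbol
    for (i in seq_len(count)) {
      idx <- idx + 1L
      params$seed <- as.integer(seed + idx)
      id <- sprintf("p%03d", idx)
      participants[[idx]] <- gen_participant(params, id)
      archetypes[idx] <- params$archetype
    }
  }
  names(participants) <- vapply(participants, function(p) p$id, character(1))
  list(
    group = .new_group(participants, color_space,
                       if (is.null(trials)) 3L else trials),
    truth = tibble::tibble(
      participant_id = names(participants) %||% character(0),
      archetype = archetypes
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
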