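# Data model and tidy ingestion.
#
# The unit of analysis is a participant's set of graphemes (inducer symbols),
# each holding an ordered, fixed-length list of trial response colors. A
# response is either an sRGB triple or missing ("no color", skipped trial, or
# a recoded-to-NA color). Missing is distinct from every color, including
# black.

.new_grapheme <- function(symbol, hex) {
  structure(
    list(symbol = symbol, hex = hex, rgb = parse_hex(hex)),
    class = "grapheme"
  )
}

.new_participant <- function(id, graphemes) {
  structure(list(id = id, graphemes = graphemes), class = "participant")
}

.new_group <- function(participants, color_space, trials_per_symbol) {
  structure(
    list(
      participants = participants,
      color_space = color_space,
      trials_per_symbol = trials_per_symbol
    ),
    class = "participant_group"
  )
}

.normalize_hex <- function(hex) {
  out <- rep(NA_character_, length(hex))
  ok <- !is.na(hex)
  out[ok] <- paste0("#", toupper(sub("^#", "", hex[ok])))
  out
}

#' Build a participant group from a tidy trial table
#'
#' Ingests long-format consistency-test data: one row per trial, with a
#' participant identifier, the inducer symbol presented, and the response
#' color as an `"#RRGGBB"` hex code. Empty strings and configurable marker
#' strings (as well as real `NA`s) are read as missing responses. Rows are
#' grouped per participant by symbol in order of first appearance; trial order
#' within a symbol is file order unless `trial_index_col` is given. A symbol
#' with fewer rows than `trials_per_symbol` is padded with missing responses
#' (aborted tests are common); more rows than `trials_per_symbol` is an error.
#'
#' @param data Data frame with at least the three named columns.
#' @param id_col,symbol_col,color_col Column names for participant id,
#'   inducer symbol and response hex color.
#' @param trials_per_symbol Number of trials per inducer (typically 3).
#' @param color_space Working color space for the group, one of
#'   [color_spaces()]; fixed at construction and used by downstream scoring
#'   and validation defaults.
#' @param na_markers Character values in the color column to read as missing,
#'   in addition to `NA` itself.
#' @param trial_index_col Optional column of within-symbol trial indices; when
#'   given, responses are ordered by it instead of file order.
#' @return A `participant_group` object.
#' @examples
#' df <- data.frame(
#'   participant_id = "p1",
#'   symbol = rep(c("A", "B"), each = 3),
#'   response_color = c("#FF0000", "#FE0000", "#FF0100", "#0000FF", "", "#0000FE")
#' )
#' build_group(df, trials_per_symbol = 3, color_space = "Luv")
#' @export
build_group <- function(data,
                        id_col = "participant_id",
                        symbol_col = "symbol",
                        color_col = "response_color",
                        trials_per_symbol = 3L,
                        color_space = "Luv",
                        na_markers = c("", "NA", "nocolor"),
                        trial_index_col = NULL) {
  color_space <- .match_space(color_space)
  needed <- c(id_col, symbol_col, color_col, trial_index_col)
  absent <- setdiff(needed, names(data))
  if (length(absent)) {
    stop("column(s) not found in input data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (trials_per_symbol < 1L) {
    stop("trials_per_symbol must be a positive integer", call. = FALSE)
  }

  ids <- as.character(data[[id_col]])
  syms <- as.character(data[[symbol_col]])
  cols <- as.character(data[[color_col]])
  cols[!is.na(cols) & cols %in% na_markers] <- NA_character_
  cols <- .normalize_hex(cols)
  # validate early so the error names the offending raw value
  parse_hex(cols)

  participants <- list()
  for (pid in unique(ids)) {
    rows <- which(ids == pid)
    graphemes <- list()
    for (sym in unique(syms[rows])) {
      srows <- rows[syms[rows] == sym]
      if (!is.null(trial_index_col)) {
        srows <- srows[order(data[[trial_index_col]][srows])]
      }
      if (length(srows) > trials_per_symbol) {
        stop("participant '", pid, "', symbol '", sym, "': ",
             length(srows), " trials found but trials_per_symbol = ",
             trials_per_symbol, call. = FALSE)
      }
      hex <- c(cols[srows],
               rep(NA_character_, trials_per_symbol - length(srows)))
      graphemes[[sym]] <- .new_grapheme(sym, hex)
    }
    participants[[pid]] <- .new_participant(pid, graphemes)
  }
  .new_group(participants, color_space, as.integer(trials_per_symbol))
}

#' Read a participant group from a tidy CSV file
#'
#' Thin wrapper around [utils::read.csv()] (RFC 4180, UTF-8, header row
#' required) followed by [build_group()].
#'
#' @param path Path to the CSV file.
#' @param ... Arguments passed to [build_group()] (column names,
#'   `trials_per_symbol`, `color_space`, ...).
#' @return A `participant_group` object.
#' @export
read_group_csv <- function(path, ...) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  build_group(df, ...)
}

#' @export
print.participant_group <- function(x, ...) {
  cat("<participant_group> ", length(x$participants), " participant(s), ",
      "color space ", x$color_space, ", ", x$trials_per_symbol,
      " trial(s) per symbol\n", sep = "")
  invisible(x)
}

#' @export
print.participant <- function(x, ...) {
  cat("<participant> ", x$id, ": ", length(x$graphemes), " grapheme(s)\n",
      sep = "")
  invisible(x)
}

#' Participant ids in a group, in group order
#' @param group A `participant_group`.
#' @return Character vector of participant ids.
#' @export
participant_ids <- function(group) {
  stopifnot(inherits(group, "participant_group"))
  vapply(group$participants, function(p) p$id, character(1), USE.NAMES = FALSE)
}

#' Extract one participant from a group
#' @param group A `participant_group`.
#' @param id Participant id.
#' @return A `participant` object.
#' @export
get_participant <- function(group, id) {
  stopifnot(inherits(group, "participant_group"))
  p <- group$participants[[as.character(id)]]
  if (is.null(p)) stop("no participant with id '", id, "'", call. = FALSE)
  p
}

#' Flatten a participant group back to a tidy trial table
#'
#' Inverse of [build_group()] up to row order within (participant, symbol)
#' and padding of under-filled symbols. Missing responses become `NA` in the
#' color column.
#'
#' @param group A `participant_group`.
#' @return Tibble with columns `participant_id`, `symbol`, `trial`,
#'   `response_color`.
#' @export
group_to_df <- function(group) {
  stopifnot(inherits(group, "participant_group"))
  rows <- lapply(group$participants, function(p) {
    do.call(rbind, lapply(p$graphemes, function(g) {
      data.frame(
        participant_id = p$id,
        symbol = g$symbol,
        trial = seq_along(g$hex),
        response_color = g$hex,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), symbol = character(),
                      trial = integer(), response_color = character())
  }
  tibble::as_tibble(out)
}

#' Recode specific response colors to missing
#'
#' Marks every response whose sRGB triple equals one of the listed colors as
#' missing, leaving all other responses untouched. The usual application is
#' recoding pure black (`"#000000"`) before scoring, since inducers are often
#' displayed in black and black responses may reflect the display rather than
#' a concurrent. The input group is not modified.
#'
#' @param group A `participant_group`.
#' @param hex_set Character vector of hex colors to recode (may be empty).
#' @return A new `participant_group` with the listed colors set to missing.
#' @export
recode_to_missing <- function(group, hex_set) {
  stopifnot(inherits(group, "participant_group"))
  if (length(hex_set) == 0L) return(group)
  parse_hex(hex_set)  # surface parse errors up front
  targets <- .normalize_hex(hex_set)
  group$participants <- lapply(group$participants, function(p) {
    p$graphemes <- lapply(p$graphemes, function(g) {
      hit <- !is.na(g$hex) & g$hex %in% targets
      if (any(hit)) {
        g$hex[hit] <- NA_character_
        g$rgb[hit, ] <- NA_real_
      }
      g
    })
    p
  })
  group
}

#' Count graphemes with a complete set of responses
#'
#' A grapheme is complete when none of its trial responses is missing.
#' Completeness thresholds of this kind are standard inclusion criteria, e.g.
#' requiring at least eight inducers with three valid responses each.
#'
#' @param participant A `participant`.
#' @param symbol_filter Optional character vector restricting which symbols
#'   are counted; symbols absent from the participant contribute nothing.
#' @return Integer count of complete graphemes.
#' @export
complete_symbol_count <- function(participant, symbol_filter = NULL) {
  stopifnot(inherits(participant, "participant"))
  gs <- participant$graphemes
  if (!is.null(symbol_filter)) {
    gs <- gs[names(gs) %in% symbol_filter]
  }
  sum(vapply(gs, function(g) !anyNA(g$hex), logical(1)))
}

# Responses of one participant as an n x 3 sRGB matrix (NA rows = missing),
# optionally restricted to a symbol subset and/or complete graphemes only.
.participant_rgb <- function(participant, symbol_filter = NULL,
                             complete_only = FALSE, drop_missing = TRUE) {
  gs <- participant$graphemes
  if (!is.null(symbol_filter)) gs <- gs[names(gs) %in% symbol_filter]
  if (complete_only) gs <- Filter(function(g) !anyNA(g$hex), gs)
  if (!length(gs)) {
    return(matrix(numeric(0), ncol = 3L,
                  dimnames = list(NULL, c("R", "G", "B"))))
  }
  m <- do.call(rbind, lapply(gs, function(g) g$rgb))
  if (drop_missing) m <- m[stats::complete.cases(m), , drop = FALSE]
  m
}
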