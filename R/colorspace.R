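# Color parsing, color-space conversion and color distances.
#
# All conversions assume the sRGB/D65 viewing conditions: IEC 61966-2-1
# piecewise gamma, the standard sRGB -> XYZ matrix, and the D65 reference
# white scaled so that white has Y = 100. Keeping XYZ on the Y = 100 scale
# puts CIELUV/CIELAB on the standard unit scale that published consistency
# cutoffs (e.g. 135 for CIELUV-Euclidean scoring) presume.

# sRGB (linear) -> XYZ, D65, scaled to white Y = 100
.SRGB_TO_XYZ <- 100 * matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.XYZ_TO_SRGB <- solve(.SRGB_TO_XYZ)

# D65 reference white on the Y = 100 scale: the image of sRGB white under the
# matrix above (~ (95.047, 100, 108.883)), so the gray axis lands exactly on
# u* = v* = 0 and white exactly on L = 100
.WHITE_D65 <- stats::setNames(rowSums(.SRGB_TO_XYZ), c("X", "Y", "Z"))

.COLOR_SPACES <- c("sRGB", "XYZ", "Lab", "Luv")

#' Supported color spaces
#'
#' @return Character vector of the color-space names accepted throughout the
#'   package: `"sRGB"` (channels in \[0, 1\]), `"XYZ"` (D65, white Y = 100),
#'   `"Lab"` and `"Luv"` (CIE 1976, L in \[0, 100\] for in-gamut sRGB input).
#' @export
color_spaces <- function() .COLOR_SPACES

.match_space <- function(space) {
  match.arg(space, .COLOR_SPACES)
}

.as_color_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop("a color must have exactly 3 coordinates, got ", length(x),
           call. = FALSE)
    }
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop("color matrices must have 3 columns, got ", ncol(x), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Parse hex color strings to sRGB coordinates
#'
#' Accepts `"#RRGGBB"` or `"RRGGBB"`, upper or lower case. Each channel is the
#' integer byte value divided by 255, so coordinates lie in \[0, 1\].
#' Eight-digit (alpha) hex codes are rejected: consistency-test software emits
#' opaque colors only. `NA` input rows become `NA` coordinate rows, which is
#' how missing ("no color") responses travel through the package.
#'
#' @param hex Character vector of hex color codes (may contain `NA`).
#' @return Numeric matrix with one row per input and columns `R`, `G`, `B`.
#' @examples
#' parse_hex(c("#FF0000", "00ff00", NA))
#' @export
parse_hex <- function(hex) {
  hex <- as.character(hex)
  out <- matrix(NA_real_, nrow = length(hex), ncol = 3L,
                dimnames = list(NULL, c("R", "G", "B")))
  ok <- !is.na(hex)
  if (any(ok)) {
    h <- sub("^#", "", hex[ok])
    bad <- !grepl("^[0-9a-fA-F]{6}$", h)
    if (any(bad)) {
      stop("malformed hex color(s): ",
           paste(unique(hex[ok][bad]), collapse = ", "), call. = FALSE)
    }
    out[ok, ] <- cbind(
      strtoi(substr(h, 1L, 2L), 16L),
      strtoi(substr(h, 3L, 4L), 16L),
      strtoi(substr(h, 5L, 6L), 16L)
    ) / 255
  }
  out
}

#' Format sRGB coordinates as hex strings
#'
#' Inverse of [parse_hex()] up to 8-bit quantization; `NA` rows give `NA`.
#'
#' @param rgb Numeric matrix (n x 3) of sRGB coordinates in \[0, 1\].
#' @return Character vector of `"#RRGGBB"` codes.
#' @export
format_hex <- function(rgb) {
  rgb <- .as_color_matrix(rgb)
  out <- rep(NA_character_, nrow(rgb))
  ok <- stats::complete.cases(rgb)
  if (any(ok)) {
    out[ok] <- grDevices::rgb(rgb[ok, 1], rgb[ok, 2], rgb[ok, 3])
  }
  out
}

.srgb_to_linear <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.linear_to_srgb <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

.srgb_to_xyz <- function(rgb) {
  lin <- .srgb_to_linear(rgb)
  out <- lin %*% t(.SRGB_TO_XYZ)
  colnames(out) <- c("X", "Y", "Z")
  out
}

.xyz_to_srgb <- function(xyz) {
  lin <- xyz %*% t(.XYZ_TO_SRGB)
  out <- .linear_to_srgb(lin)
  colnames(out) <- c("R", "G", "B")
  out
}

# CIE L* companding; epsilon/kappa in their exact rational forms
.lab_f <- function(t) {
  eps <- 216 / 24389
  kappa <- 24389 / 27
  ifelse(t > eps, t^(1 / 3), (kappa * t + 16) / 116)
}

.xyz_to_lab <- function(xyz) {
  fx <- .lab_f(xyz[, 1] / .WHITE_D65[["X"]])
  fy <- .lab_f(xyz[, 2] / .WHITE_D65[["Y"]])
  fz <- .lab_f(xyz[, 3] / .WHITE_D65[["Z"]])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

.xyz_to_luv <- function(xyz) {
  L <- 116 * .lab_f(xyz[, 2] / .WHITE_D65[["Y"]]) - 16
  denom <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  wdenom <- sum(.WHITE_D65 * c(1, 15, 3))
  un <- 4 * .WHITE_D65[["X"]] / wdenom
  vn <- 9 * .WHITE_D65[["Y"]] / wdenom
  # u', v' are undefined at zero luminance (denominator 0); define u* = v* = 0
  # there so pure black maps continuously to (0, 0, 0)
  up <- ifelse(denom > 0, 4 * xyz[, 1] / pmax(denom, .Machine$double.xmin), un)
  vp <- ifelse(denom > 0, 9 * xyz[, 2] / pmax(denom, .Machine$double.xmin), vn)
  cbind(L = L, u = 13 * L * (up - un), v = 13 * L * (vp - vn))
}

#' Convert colors between color spaces
#'
#' Converts a set of colors from sRGB to any supported space, or from XYZ back
#' to sRGB. sRGB channels must lie in \[0, 1\]; rows with any `NA` coordinate
#' pass through as all-`NA` rows (missing responses).
#'
#' @param colors Numeric matrix (n x 3) or length-3 vector of coordinates.
#' @param to Target space, one of [color_spaces()].
#' @param from Source space; `"sRGB"` (default) or `"XYZ"` (to sRGB only).
#' @return Numeric matrix (n x 3) in the target space.
#' @examples
#' convert_color(parse_hex("#FF0000"), "Luv")
#' @export
convert_color <- function(colors, to, from = "sRGB") {
  to <- .match_space(to)
  from <- .match_space(from)
  m <- .as_color_matrix(colors)
  ok <- stats::complete.cases(m)
  out <- matrix(NA_real_, nrow(m), 3L)
  if (from == to) {
    out[ok, ] <- m[ok, , drop = FALSE]
    colnames(out) <- colnames(m)
    return(out)
  }
  if (from == "sRGB") {
    sub <- m[ok, , drop = FALSE]
    if (length(sub) && (min(sub) < -1e-9 || max(sub) > 1 + 1e-9)) {
      stop("sRGB channels must lie in [0, 1]; got value(s) outside range",
           call. = FALSE)
    }
    sub <- pmin(pmax(sub, 0), 1)
    xyz <- .srgb_to_xyz(sub)
    res <- switch(to,
      XYZ = xyz,
      Lab = .xyz_to_lab(xyz),
      Luv = .xyz_to_luv(xyz)
    )
  } else if (from == "XYZ" && to == "sRGB") {
    res <- .xyz_to_srgb(m[ok, , drop = FALSE])
  } else {
    stop("conversion from ", from, " to ", to, " is not supported",
         call. = FALSE)
  }
  out[ok, ] <- res
  colnames(out) <- colnames(res)
  out
}

#' Distance between two colors
#'
#' Euclidean (`sqrt(sum(delta^2))`) or taxicab/Manhattan (`sum(abs(delta))`)
#' distance between coordinate vectors. Both points must be expressed in the
#' same color space; the function operates on raw coordinates and does not
#' convert.
#'
#' @param p,q Length-3 numeric coordinate vectors (same space).
#' @param metric `"euclidean"` or `"taxicab"`.
#' @return Non-negative scalar distance; `NA` if either point has an `NA`.
#' @export
color_distance <- function(p, q, metric = c("euclidean", "taxicab")) {
  metric <- match.arg(metric)
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L) {
    stop("color_distance expects two length-3 coordinate vectors",
         call. = FALSE)
  }
  d <- p - q
  if (metric == "euclidean") sqrt(sum(d^2)) else sum(abs(d))
}

# All pairwise distances among the rows of a coordinate matrix,
# returned as a flat vector over unordered pairs.
.pairwise_distances <- function(m, metric) {
  n <- nrow(m)
  if (n < 2L) return(numeric(0))
  idx <- utils::combn(n, 2L)
  d <- m[idx[1L, ], , drop = FALSE] - m[idx[2L, ], , drop = FALSE]
  if (metric == "euclidean") sqrt(rowSums(d^2)) else rowSums(abs(d))
}
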