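# Screening arithmetic.
#
# Consistency tests used as screening instruments have a known sensitivity
# and specificity; applied at low population prevalence, even a good test
# yields mostly false positives among those flagged. The positive predictive
# value makes that explicit.

#' Positive predictive value of a screening test
#'
#' \deqn{PPV = \frac{sens \cdot prev}{sens \cdot prev +
#'   (1 - spec)(1 - prev)}}
#' the proportion of true positives among those who test positive. All three
#' arguments are proportions in \[0, 1\] (pass 0.011, never 1.1, for a 1.1%
#' prevalence). With grapheme-color consistency screening at sensitivity
#' 0.90, specificity 0.94 and population prevalence 0.011 the PPV is about
#' 0.143.
#'
#' @param sensitivity,specificity,prevalence Proportions in \[0, 1\]
#'   (vectorized).
#' @return PPV in \[0, 1\].
#' @examples
#' ppv(0.9, 0.94, 0.011)
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  args <- cbind(sensitivity, specificity, prevalence)
  if (any(args < 0 | args > 1)) {
    stop("sensitivity, specificity and prevalence must be proportions ",
         "in [0, 1]", call. = FALSE)
  }
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  if (any(den == 0)) {
    stop("PPV undefined: no individuals test positive under these parameters",
         call. = FALSE)
  }
  num / den
}

#' Expected proportion of false positives among screen positives
#'
#' The complement of [ppv()]: of those testing positive, the proportion
#' expected not to have the condition.
#'
#' @inheritParams ppv
#' @return Proportion in \[0, 1\].
#' @examples
#' false_positive_proportion(0.9, 0.94, 0.011)  # ~0.857
#' @export
false_positive_proportion <- function(sensitivity, specificity, prevalence) {
  1 - ppv(sensitivity, specificity, prevalence)
}
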