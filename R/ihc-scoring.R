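#' Map a positive-cell percentage to its staining category
#'
#' Categories follow the standard immunoreactive-score bins: 0 (exactly 0%),
#' 1 (up to 24%), 2 (25-49%), 3 (50-74%), 4 (75-100%). Any positivity above
#' zero but below 1% counts as category 1, since category 0 is reserved for
#' fully negative sections.
#'
#' @param percent_positive numeric vector in `[0, 100]`.
#' @return integer vector of categories in `0..4`.
#' @export
percent_to_category <- function(percent_positive) {
  if (!is.numeric(percent_positive) || anyNA(percent_positive) ||
      any(percent_positive < 0) || any(percent_positive > 100)) {
    stop_validation("'percent_positive' must lie in [0, 100]")
  }
  ifelse(percent_positive == 0, 0L,
         ifelse(percent_positive < 25, 1L,
                ifelse(percent_positive < 50, 2L,
                       ifelse(percent_positive < 75, 3L, 4L))))
}

#' Immunoreactive score (IRS)
#'
#' The final immunoreactive score is the product of the staining-intensity
#' category (1 = no or weak, 2 = moderate, 3 = strong) and the positive-cell
#' percentage category (0-4), giving a score from 0 to 12. Note the intensity
#' scale starts at 1 even for "no or weak staining", so a section scores 0
#' only through percentage category 0; this quirk of the published scale is
#' preserved verbatim.
#'
#' @param intensity_category integer vector in `{1, 2, 3}`.
#' @param percent_category integer vector in `{0, 1, 2, 3, 4}`.
#' @return integer scores in `[0, 12]`.
#' @export
immunoreactive_score <- function(intensity_category, percent_category) {
  if (!all(intensity_category %in% 1:3)) {
    stop_validation("'intensity_category' must be 1, 2 or 3")
  }
  if (!all(percent_category %in% 0:4)) {
    stop_validation("'percent_category' must be in 0..4")
  }
  as.integer(intensity_category) * as.integer(percent_category)
}

#' Score a table of IHC observations
#'
#' Convenience wrapper: maps raw percentages to categories where needed and
#' appends `percent_category` and `score` columns.
#'
#' @param observations data.frame with `intensity_category` and either
#'   `percent_positive` (raw percentage) or `percent_category`.
#' @return `observations` with `percent_category` and `score` columns added.
#' @export
ihc_score_table <- function(observations) {
  stopifnot(is.data.frame(observations))
  if (!"percent_category" %in% names(observations)) {
    if (!"percent_positive" %in% names(observations)) {
      stop_validation("need 'percent_category' or 'percent_positive'")
    }
    observations$percent_category <- percent_to_category(observations$percent_positive)
  }
  observations$score <- immunoreactive_score(observations$intensity_category,
                                             observations$percent_category)
  observations
}
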