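# Study-population accounting: sequential exclusion arithmetic.

#' Apply a sequential exclusion flow
#'
#' Starting from the number of candidates, subtracts each exclusion step in
#' order and reports the remaining count after every step — the standard
#' inclusion/exclusion flow-chart arithmetic of a cohort study.
#'
#' @param n_start number of candidates entering the flow.
#' @param exclusions named numeric vector (or tibble with `reason`, `n`)
#'   of exclusion counts, applied in order.
#' @return A tibble with `stage`, `n_excluded` and `n_remaining`; the last
#'   row is the analyzed cohort.
#' @examples
#' cohort_flow(2981, c(incident_events = 46, model_failures = 414))
#' @export
cohort_flow <- function(n_start, exclusions) {
  if (is.data.frame(exclusions)) {
    reasons <- exclusions$reason
    counts <- exclusions$n
  } else {
    reasons <- names(exclusions)
    counts <- as.numeric(exclusions)
  }
  if (any(counts < 0)) stop("exclusion counts must be nonnegative")
  remaining <- n_start - cumsum(counts)
  if (any(remaining < 0)) stop("exclusions exceed the available cohort")
  tibble::tibble(
    stage = c("candidates", reasons),
    n_excluded = c(0, counts),
    n_remaining = c(n_start, remaining)
  )
}
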