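#' Age-group definitions used throughout the package
#'
#' Surveillance records are stratified into six age groups: 5-9, 10-14, 15-19,
#' 20-24, 25-59 and over-59 years. Ages below 5 fall outside every group and
#' are excluded from the panels (with a log entry in the ingest reports).
#'
#' @return A data.frame with columns `label`, `lower` and `upper` (upper is
#'   `Inf` for the open-ended oldest group), one row per group, in age order.
#' @export
#' @examples
#' age_groups()
age_groups <- function() {
  data.frame(
    label = c("5-9", "10-14", "15-19", "20-24", "25-59", "gt59"),
    lower = c(5L, 10L, 15L, 20L, 25L, 60L),
    upper = c(9, 14, 19, 24, 59, Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign an age in years to its age group
#'
#' @param age Integer vector of ages in completed years (must be >= 0).
#' @return Character vector of group labels (see [age_groups()]); `NA` for
#'   ages below 5, which belong to no group.
#' @export
#' @examples
#' assign_age_group(c(4, 14, 59, 60))
assign_age_group <- function(age) {
  if (any(!is.finite(age) | age < 0)) {
    stop("`age` must be non-negative and finite", call. = FALSE)
  }
  grp <- age_groups()
  idx <- findInterval(age, grp$lower)
  out <- rep(NA_character_, length(age))
  ok <- idx >= 1
  out[ok] <- grp$label[idx[ok]]
  # findInterval handles containment because groups are contiguous from 5 up;
  # guard the gaps explicitly in case the table ever changes
  ok2 <- ok & age <= grp$upper[pmax(idx, 1)]
  out[!ok2] <- NA_character_
  out
}
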