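#' Construct an analysis panel for one age group
#'
#' A panel holds the three aligned area-by-quarter matrices the models consume:
#' event counts `y[i,t]`, the population offset `offset[i,t]` (person-quarters
#' of exposure in the age group) and the covariate `covariate[i,t]` (here,
#' fixed-internet points per inhabitant).
#'
#' @param counts Integer matrix, areas by quarters, non-negative.
#' @param offset Numeric matrix of the same shape, strictly positive.
#' @param covariate Numeric matrix of the same shape, non-negative. Defaults
#'   to all zeros (no covariate).
#' @param area_ids Character vector of area codes, one per row. Defaults to
#'   the rownames of `counts`.
#' @param age_group Label of the age group the panel describes (see
#'   [age_groups()]), or `NA` for unstratified panels.
#' @return An object of class `panel_data`.
#' @export
panel_data <- function(counts, offset, covariate = NULL, area_ids = NULL,
                       age_group = NA_character_) {
  counts <- as.matrix(counts)
  offset <- as.matrix(offset)
  if (is.null(covariate)) covariate <- matrix(0, nrow(counts), ncol(counts))
  covariate <- as.matrix(covariate)
  if (is.null(area_ids)) area_ids <- rownames(counts)
  if (is.null(area_ids)) area_ids <- sprintf("A%03d", seq_len(nrow(counts)))
  area_ids <- as.character(area_ids)

  if (!identical(dim(counts), dim(offset)) ||
      !identical(dim(counts), dim(covariate))) {
    stop("counts, offset and covariate must share the same shape", call. = FALSE)
  }
  if (length(area_ids) != nrow(counts)) {
    stop("area_ids must have one entry per row of counts", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(!is.finite(offset)) || any(offset <= 0)) {
    stop("offset must be strictly positive everywhere; drop zero-population areas first",
         call. = FALSE)
  }
  if (any(!is.finite(covariate)) || any(covariate < 0)) {
    stop("covariate must be finite and non-negative", call. = FALSE)
  }

  dimnames(counts) <- dimnames(offset) <- dimnames(covariate) <-
    list(area_ids, paste0("t", seq_len(ncol(counts))))
  structure(
    list(
      area_ids = area_ids,
      n_areas = nrow(counts),
      n_quarters = ncol(counts),
      age_group = age_group,
      counts = counts,
      offset = offset,
      covariate = covariate
    ),
    class = "panel_data"
  )
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf(
    "<panel_data> %d areas x %d quarters, age group %s\n  total events %d, total exposure %.4g person-quarters\n",
    x$n_areas, x$n_quarters,
    ifelse(is.na(x$age_group), "(none)", x$age_group),
    sum(x$counts), sum(x$offset)
  ))
  invisible(x)
}
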