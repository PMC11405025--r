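# left-zero-pad all-digit codes to 5 characters; other strings pass through
pad_code <- function(x) {
  x <- trimws(as.character(x))
  digit <- grepl("^[0-9]{1,5}$", x)
  x[digit] <- sprintf("%05d", as.integer(x[digit]))
  x
}

#' Parse an event line-list from CSV
#'
#' Reads a line-list of notifiable events (one row per event) and validates
#' each row. Rows that fail validation are not dropped silently: they are
#' returned in a rejects table with a reason, so ingest is fully accountable.
#'
#' @param path Path to a CSV file (UTF-8, ISO-8601 dates).
#' @param schema Named list mapping the logical fields `date`, `municipality`,
#'   `age` and `sex` to column names in the file. Defaults to those names
#'   verbatim. A YAML file with a top-level `columns:` map can be supplied via
#'   [read_schema()].
#' @return A list of class `line_list` with elements `records` (data.frame:
#'   `date`, `municipality_code`, `age`, `sex`) and `rejects` (data.frame:
#'   `row`, `reason`).
#' @export
parse_line_list <- function(path,
                            schema = list(date = "date",
                                          municipality = "municipality",
                                          age = "age", sex = "sex")) {
  if (!file.exists(path)) stop("line-list file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop("could not read line-list: ", conditionMessage(e),
                             call. = FALSE)
  )
  needed <- unlist(schema[c("date", "municipality", "age", "sex")])
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("line-list is missing configured column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  date_raw <- raw[[schema$date]]
  code_raw <- trimws(raw[[schema$municipality]])
  age_raw <- raw[[schema$age]]
  sex_raw <- raw[[schema$sex]]

  date <- as.Date(date_raw, format = "%Y-%m-%d")
  age <- suppressWarnings(as.numeric(age_raw))
  # DIVIPOLA codes are 5-digit strings; left-pad shorter all-digit codes
  code <- pad_code(code_raw)

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(reason) & !grepl("^[0-9]{5}$", code)] <- "invalid municipality code"
  reason[is.na(reason) & (is.na(age) | age < 0 | age != floor(age))] <- "invalid age"

  ok <- is.na(reason)
  records <- data.frame(
    date = date[ok],
    municipality_code = code[ok],
    age = as.integer(age[ok]),
    sex = sex_raw[ok],
    stringsAsFactors = FALSE
  )
  rejects <- data.frame(row = which(!ok), reason = reason[!ok],
                        stringsAsFactors = FALSE)
  structure(list(records = records, rejects = rejects), class = "line_list")
}

#' Read an ingest column schema from YAML
#'
#' @param path YAML file with a top-level `columns:` mapping of the logical
#'   names `date`, `municipality`, `age`, `sex` to CSV column names.
#' @return A named list usable as the `schema` argument of
#'   [parse_line_list()].
#' @export
read_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$columns)) stop("schema YAML needs a `columns:` map", call. = FALSE)
  cfg$columns
}

#' Map a calendar date to a quarter index
#'
#' Quarters are numbered 1, 2, ... from the first quarter of `origin_year`;
#' the default three-year study window gives indices 1-12.
#'
#' @param date A `Date` vector.
#' @param origin_year First year of the window (default 2018).
#' @param n_quarters Length of the window in quarters (default 12).
#' @return Integer vector of quarter indices.
#' @export
#' @examples
#' assign_quarter(as.Date(c("2018-01-15", "2020-11-02")))
assign_quarter <- function(date, origin_year = 2018, n_quarters = 12) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  t <- as.integer(4 * (yr - origin_year) + ceiling(mo / 3))
  bad <- is.na(t) | t < 1L | t > n_quarters
  if (any(bad)) {
    stop("date(s) outside the study window: ",
         paste(format(date[bad]), collapse = ", "), call. = FALSE)
  }
  t
}

#' Build the analysis panel for one age group
#'
#' Cross-tabulates validated line-list records into area-by-quarter counts and
#' aligns them with the census population offset and the covariate table.
#' Areas with zero population in the group are excluded (the offset must be
#' strictly positive) and reported; records are conserved: the cell counts sum
#' exactly to the number of in-group, in-window records.
#'
#' @param records Data.frame as produced by [parse_line_list()] (`$records`).
#' @param population Data.frame with columns `municipality_code`, `age_group`,
#'   `population` (2018-census head counts; held constant over quarters).
#' @param covariate Optional data.frame with columns `municipality_code`,
#'   `quarter` (index 1..T) and `value`. Gaps are forward-filled within an
#'   area, then zero-filled, and reported. `NULL` gives an all-zero covariate.
#' @param age_group One label from [age_groups()].
#' @param origin_year,n_quarters Study window (defaults 2018, 12).
#' @return A `panel_data` object with attribute `reports`, a list holding
#'   `dropped_areas` (zero population), `excluded_records` (out-of-group or
#'   out-of-window rows) and `covariate_gaps`.
#' @export
build_panel <- function(records, population, covariate = NULL, age_group,
                        origin_year = 2018, n_quarters = 12) {
  stopifnot(age_group %in% age_groups()$label)
  pop <- population[population$age_group == age_group, , drop = FALSE]
  if (nrow(pop) == 0) stop("population table has no rows for group ", age_group,
                           call. = FALSE)
  pop$municipality_code <- pad_code(pop$municipality_code)

  rec <- records
  rec$group <- assign_age_group(rec$age)
  in_group <- !is.na(rec$group) & rec$group == age_group
  rec <- rec[in_group, , drop = FALSE]

  unmatched <- setdiff(unique(rec$municipality_code), pop$municipality_code)
  if (length(unmatched) > 0) {
    stop("municipality code(s) in records but not in population table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }

  # quarter assignment; out-of-window records are excluded, not fatal
  yr <- as.integer(format(rec$date, "%Y"))
  mo <- as.integer(format(rec$date, "%m"))
  t <- 4L * (yr - origin_year) + as.integer(ceiling(mo / 3))
  in_window <- !is.na(t) & t >= 1L & t <= n_quarters
  excluded <- rec[!in_window, , drop = FALSE]
  rec <- rec[in_window, , drop = FALSE]
  t <- t[in_window]

  keep <- pop$population > 0
  dropped <- pop$municipality_code[!keep]
  pop <- pop[keep, , drop = FALSE]
  pop <- pop[order(pop$municipality_code), , drop = FALSE]
  areas <- pop$municipality_code
  lost <- rec$municipality_code %in% dropped
  if (any(lost)) {
    excluded <- rbind(excluded, rec[lost, , drop = FALSE])
    t <- t[!lost]
    rec <- rec[!lost, , drop = FALSE]
  }

  counts <- table(factor(rec$municipality_code, levels = areas),
                  factor(t, levels = seq_len(n_quarters)))
  counts <- matrix(as.integer(counts), nrow = length(areas),
                   dimnames = list(areas, NULL))

  offmat <- matrix(rep(pop$population, n_quarters), nrow = length(areas),
                   dimnames = list(areas, NULL))

  gaps <- data.frame(municipality_code = character(), quarter = integer(),
                     fill = character(), stringsAsFactors = FALSE)
  if (is.null(covariate)) {
    covmat <- matrix(0, length(areas), n_quarters)
  } else {
    cov <- covariate
    cov$municipality_code <- pad_code(cov$municipality_code)
    covmat <- matrix(NA_real_, length(areas), n_quarters,
                     dimnames = list(areas, NULL))
    idx <- cov$municipality_code %in% areas &
      cov$quarter >= 1 & cov$quarter <= n_quarters
    cov <- cov[idx, , drop = FALSE]
    covmat[cbind(match(cov$municipality_code, areas), cov$quarter)] <- cov$value
    for (i in seq_len(nrow(covmat))) {
      row <- covmat[i, ]
      if (anyNA(row)) {
        na_at <- which(is.na(row))
        # forward-fill within the area, then zero-fill leading gaps
        for (tt in na_at) {
          prev <- row[seq_len(tt - 1)]
          prev <- prev[!is.na(prev)]
          fill <- if (length(prev) > 0) prev[length(prev)] else 0
          row[tt] <- fill
          gaps <- rbind(gaps, data.frame(
            municipality_code = areas[i], quarter = tt,
            fill = if (length(prev) > 0) "forward" else "zero",
            stringsAsFactors = FALSE))
        }
        covmat[i, ] <- row
      }
    }
  }

  panel <- panel_data(counts, offmat, covmat, area_ids = areas,
                      age_group = age_group)
  attr(panel, "reports") <- list(
    dropped_areas = dropped,
    excluded_records = excluded,
    covariate_gaps = gaps
  )
  panel
}

#' Build panels for every age group at once
#'
#' @inheritParams build_panel
#' @return Named list of `panel_data`, one per age-group label that has
#'   positive population somewhere.
#' @export
build_all_panels <- function(records, population, covariate = NULL,
                             origin_year = 2018, n_quarters = 12) {
  labs <- intersect(age_groups()$label, unique(population$age_group))
  out <- lapply(labs, function(g)
    build_panel(records, population, covariate, g, origin_year, n_quarters))
  names(out) <- labs
  out
}
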