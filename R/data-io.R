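tsd_core_cols <- c("temperature", "amplitude", "males", "females",
                   "intersexes", "area", "country", "rmu", "reference",
                   "correction_factor")

default_column_map <- c(
  temperature = "Incubation.temperature",
  amplitude = "Incubation.temperature.Amplitude",
  males = "Males",
  females = "Females",
  intersexes = "Intersexes",
  area = "Area",
  country = "Country",
  rmu = "RMU",
  reference = "Reference",
  correction_factor = "Correction.factor"
)

check_counts <- function(x, name) {
  bad <- which(!is.na(x) & (x < 0 | x != floor(x)))
  if (length(bad)) {
    abort(sprintf(
      "Column `%s` must hold non-negative integer counts; offending row(s): %s.",
      name, paste(bad, collapse = ", ")
    ))
  }
}

validate_tsd <- function(data) {
  if (!is.data.frame(data)) abort("Incubation data must be a data frame.")
  need <- c("temperature", "males", "females")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("Missing required column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (nrow(data) && any(!is.finite(data$temperature))) {
    abort("All incubation temperatures must be finite.")
  }
  for (nm in intersect(c("males", "females", "intersexes"), names(data))) {
    if (!is.numeric(data[[nm]])) {
      abort(sprintf("Column `%s` must be numeric counts.", nm))
    }
    check_counts(data[[nm]], nm)
  }
  if ("amplitude" %in% names(data) && nrow(data) &&
      any(data$amplitude < 0, na.rm = TRUE)) {
    abort("Temperature amplitudes cannot be negative.")
  }
  invisible(data)
}

complete_tsd <- function(data) {
  if (!"amplitude" %in% names(data)) data$amplitude <- NA_real_
  if (!"intersexes" %in% names(data)) data$intersexes <- 0
  as_tibble(data)
}

#' Read constant-temperature incubation records
#'
#' Reads a CSV of incubation groups — one row per constant-temperature
#' incubation with counts of male, female and (optionally) intersex embryos —
#' into the tibble layout used throughout the package. The default column
#' names mirror the layout of published TSD incubation databases
#' (`Incubation.temperature`, `Males`, `Females`, ...); pass `column_map` to
#' read files with other headers. A temperature correction factor column, if
#' present, is carried along but never applied to the temperatures.
#'
#' @param path Path to a comma-separated, UTF-8 file with a header row.
#' @param column_map Named character vector mapping internal names
#'   (`temperature`, `males`, `females`, `amplitude`, `intersexes`, `area`,
#'   `country`, `rmu`, `reference`, `correction_factor`) to column names in
#'   the file. Only entries that differ from the defaults need to be given.
#' @return A tibble with one row per incubation group and columns
#'   `temperature`, `amplitude`, `males`, `females`, `intersexes` plus any
#'   label columns present. Missing amplitude values are kept as `NA`
#'   ("unknown"); a missing intersex column is treated as zero intersexes.
#' @examples
#' path <- system.file("extdata", "olive_ridley_tsd.csv", package = "tsdnorm")
#' read_tsd(path)
#' @export
read_tsd <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  map <- default_column_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (need in c("temperature", "males", "females")) {
    if (!map[[need]] %in% names(raw)) {
      abort(sprintf("Required column `%s` (mapped from `%s`) not found in %s.",
                    map[[need]], need, path))
    }
  }
  present <- map[map %in% names(raw)]
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)
  for (nm in intersect(c("temperature", "amplitude", "males", "females",
                         "intersexes", "correction_factor"), names(out))) {
    if (is.character(out[[nm]])) {
      conv <- suppressWarnings(as.numeric(out[[nm]]))
      if (any(is.na(conv) & !is.na(out[[nm]]))) {
        abort(sprintf("Column `%s` contains non-numeric values.", map[[nm]]))
      }
      out[[nm]] <- conv
    }
  }
  out <- complete_tsd(out)
  validate_tsd(out)
  attr(out, "tsd_filters") <- list()
  out
}

#' Write incubation records back to CSV
#'
#' Serialises a dataset to the same comma-separated dialect that
#' [read_tsd()] reads, so filtered or simulated data can round-trip.
#'
#' @param data An incubation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsd <- function(data, path) {
  validate_tsd(data)
  out <- as_tibble(data)
  inv <- default_column_map[intersect(names(default_column_map), names(out))]
  names(out)[match(names(inv), names(out))] <- unname(inv)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Olive ridley constant-temperature incubation data
#'
#' The complete published set of 40 constant-temperature incubation groups
#' for *Lepidochelys olivacea* (277 males, 168 females and 19 intersexes from
#' six nesting beaches in three Regional Management Units), as shipped with
#' the package. Optional selectors subset by RMU, country or beach.
#'
#' @param rmu,country,area Optional character vectors to subset by label
#'   (e.g. `rmu = "East Pacific"`, `country = "Brazil"`).
#' @return An incubation tibble (see [read_tsd()]).
#' @examples
#' nrow(olive_ridley())                      # 40 groups
#' olive_ridley(rmu = "Northeast Indian")    # the 6 Odisha incubations
#' @export
olive_ridley <- function(rmu = NULL, country = NULL, area = NULL) {
  path <- system.file("extdata", "olive_ridley_tsd.csv", package = "tsdnorm")
  d <- read_tsd(path)
  if (!is.null(rmu)) d <- d[d$rmu %in% rmu, ]
  if (!is.null(country)) d <- d[d$country %in% country, ]
  if (!is.null(area)) d <- d[d$area %in% area, ]
  attr(d, "tsd_filters") <- list()
  d
}

#' Apply the standard data-quality filters
#'
#' Two screening rules are applied before fitting a reaction norm:
#' incubations whose recorded temperature amplitude exceeds
#' `max_amplitude` (default 2 degC) are removed, because short excursions to
#' high temperature feminise clutches relative to the mean temperature; and
#' intersex embryos are excluded from the analysable counts, because the
#' ovotestis classification is not fully objective. Groups with an unknown
#' (missing) amplitude are retained. A group that loses its intersexes but
#' still holds sexed embryos is kept.
#'
#' The filter report — rows removed, embryos excluded — is recorded on the
#' returned tibble and can be retrieved with [filter_report()]. The
#' operation is idempotent and never loses embryos silently: retained plus
#' removed counts always reconcile with the input.
#'
#' @param data An incubation tibble.
#' @param max_amplitude Largest admissible temperature amplitude in degC.
#' @param drop_intersex Exclude intersex individuals from the analysis?
#' @return The filtered tibble, with a `tsd_filters` attribute describing
#'   what was removed.
#' @examples
#' d <- filter_tsd(olive_ridley())
#' filter_report(d)
#' @export
filter_tsd <- function(data, max_amplitude = 2, drop_intersex = TRUE) {
  validate_tsd(data)
  data <- complete_tsd(data)
  filters <- attr(data, "tsd_filters") %||% list()
  keep <- is.na(data$amplitude) | data$amplitude <= max_amplitude
  removed <- data[!keep, , drop = FALSE]
  out <- data[keep, , drop = FALSE]
  n_intersex <- 0L
  if (drop_intersex) {
    n_intersex <- sum(out$intersexes)
    out$intersexes <- 0L
  }
  filters <- c(filters, list(list(
    rule = sprintf("amplitude <= %g degC (missing amplitude retained)", max_amplitude),
    groups_removed = nrow(removed),
    embryos_removed = sum(removed$males + removed$females + removed$intersexes)
  )))
  if (drop_intersex) {
    filters <- c(filters, list(list(
      rule = "intersex embryos excluded from analysable counts",
      groups_removed = 0L,
      embryos_removed = as.integer(n_intersex)
    )))
  }
  attr(out, "tsd_filters") <- filters
  out
}

#' Report of filters applied to a dataset
#'
#' @param data A tibble produced by [filter_tsd()].
#' @return A tibble with one row per filtering rule applied (`rule`,
#'   `groups_removed`, `embryos_removed`); zero rows if nothing was filtered.
#' @export
filter_report <- function(data) {
  f <- attr(data, "tsd_filters") %||% list()
  if (!length(f)) {
    return(tibble(rule = character(), groups_removed = integer(),
                  embryos_removed = integer()))
  }
  dplyr::bind_rows(lapply(f, as_tibble))
}

#' Pool incubation groups that share a temperature
#'
#' Groups whose temperatures agree within `tolerance` are pooled by summing
#' their male, female and intersex counts, producing a dataset with strictly
#' distinct temperatures. Label columns keep the first value of each pool.
#' Pooling conserves all counts; on a dataset whose temperatures are already
#' distinct it is the identity (up to label bookkeeping).
#'
#' The number of distinct temperatures after pooling is the sample-size
#' convention used for BIC in dataset comparisons (see
#' [compare_datasets()]).
#'
#' @param data An incubation tibble.
#' @param tolerance Non-negative temperature difference (degC) within which
#'   two groups count as "the same temperature". The default 0 pools exact
#'   duplicates only.
#' @return A tibble with one row per distinct temperature, ordered by
#'   temperature.
#' @examples
#' nrow(merge_temperatures(olive_ridley()))  # 30 distinct temperatures
#' @export
merge_temperatures <- function(data, tolerance = 0) {
  validate_tsd(data)
  data <- complete_tsd(data)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    abort("`tolerance` must be a single non-negative number.")
  }
  if (!nrow(data)) return(data)
  ord <- order(data$temperature)
  tt <- data$temperature[ord]
  grp <- cumsum(c(1, diff(tt) > tolerance))
  d <- data[ord, , drop = FALSE]
  d$.grp <- grp
  counts <- d %>%
    group_by(.data$.grp) %>%
    summarise(
      temperature = .data$temperature[1],
      males = sum(.data$males),
      females = sum(.data$females),
      intersexes = sum(.data$intersexes),
      .groups = "drop"
    )
  labels <- d %>%
    group_by(.data$.grp) %>%
    summarise(across(all_of(setdiff(
      names(data), c("temperature", "males", "females", "intersexes")
    )), ~ .x[1]), .groups = "drop")
  out <- dplyr::left_join(counts, labels, by = ".grp")
  out$.grp <- NULL
  attr(out, "tsd_filters") <- attr(data, "tsd_filters") %||% list()
  out
}

#' Count distinct incubation temperatures
#'
#' Convenience wrapper: the number of rows of [merge_temperatures()].
#'
#' @inheritParams merge_temperatures
#' @return An integer count.
#' @export
n_distinct_temperatures <- function(data, tolerance = 0) {
  nrow(merge_temperatures(data, tolerance))
}
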