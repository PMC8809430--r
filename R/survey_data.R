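#' Assemble a collapsed survey dataset
#'
#' The analysis-ready container for multi-site, multi-month count surveys:
#' a `sites x months x species` count array with the aligned survey effort.
#' Counts are `NA` exactly where a site was not surveyed in a month; zero is
#' an observation, absence of a survey is not.
#'
#' @param sites character vector of site labels (length `S`).
#' @param months integer vector of consecutive month indices (length `T`).
#' @param species character vector of species labels (length `K`).
#' @param counts `S x T x K` array of non-negative integer counts, `NA`
#'   where the site-month was not surveyed.
#' @param effort_raw `S x T` matrix of survey effort in hours, `NA` exactly
#'   where counts are `NA`.
#'
#' @return An object of class `survey_dataset`: a list with the validated
#'   fields above plus `effort_std`, the effort standardized to mean 0 and
#'   sample SD 1 over surveyed cells (see [standardize_effort()]). When all
#'   surveyed efforts are equal the covariate is degenerate: `effort_std`
#'   is all zero and the attribute `degenerate_effort` is `TRUE`, so model
#'   fits drop the effort term.
#' @seealso [collapse_station_counts()], [simulate_counts()]
#' @export
survey_dataset <- function(sites, months, species, counts, effort_raw) {
  sites <- as.character(sites); species <- as.character(species)
  months <- as.integer(months)
  S <- length(sites); Tm <- length(months); K <- length(species)
  if (S < 1L || Tm < 1L || K < 1L)
    stop("survey_dataset needs at least one site, month and species")
  if (anyDuplicated(sites)) stop("duplicate site labels")
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (Tm > 1L && any(diff(months) != 1L))
    stop("months must be consecutive integers")
  counts <- array(counts, dim = c(S, Tm, K),
                  dimnames = list(sites, months, species))
  effort_raw <- matrix(effort_raw, S, Tm, dimnames = list(sites, months))
  cc <- counts[!is.na(counts)]
  if (any(cc < 0) || any(cc != round(cc)))
    stop("counts must be non-negative integers")
  if (any(effort_raw[!is.na(effort_raw)] <= 0))
    stop("effort_raw must be positive (hours)")
  surveyed <- !is.na(effort_raw)
  for (k in seq_len(K)) {
    ck <- counts[, , k, drop = FALSE]
    dim(ck) <- c(S, Tm)
    if (!identical(unname(!is.na(ck)), unname(surveyed)))
      stop("counts must be missing exactly where effort_raw is missing ",
           "(species '", species[k], "' disagrees)")
  }
  degenerate <- FALSE
  eff <- effort_raw[surveyed]
  if (length(eff) >= 2L && stats::sd(eff) > 0) {
    effort_std <- standardize_effort(effort_raw)
  } else {
    effort_std <- effort_raw
    effort_std[surveyed] <- 0
    degenerate <- TRUE
  }
  structure(
    list(sites = sites, months = months, species = species,
         counts = counts, effort_raw = effort_raw, effort_std = effort_std),
    degenerate_effort = degenerate,
    class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Survey dataset:", length(x$sites), "sites x", length(x$months),
      "months x", length(x$species), "species\n")
  n_missing <- sum(is.na(x$effort_raw))
  cat("  surveyed site-months:", sum(!is.na(x$effort_raw)),
      if (n_missing) paste0("(", n_missing, " missing)") else "", "\n")
  cat("  total counts by species:\n")
  tot <- apply(x$counts, 3, sum, na.rm = TRUE)
  print(tot)
  invisible(x)
}

#' Standardize a survey-effort covariate
#'
#' Scales and centers effort to mean 0 and sample SD 1 (denominator
#' `n - 1`) over non-missing values, the convention used when effort enters
#' a count model as a covariate so that the abundance index refers to the
#' mean time spent surveying. Missing values stay missing.
#'
#' @param effort_raw numeric vector, matrix or array of positive efforts,
#'   `NA` allowed.
#' @return An object of the same shape with non-missing values standardized.
#' @examples
#' standardize_effort(c(3, 3.5, 4))   # -1 0 1
#' @export
standardize_effort <- function(effort_raw) {
  v <- effort_raw[!is.na(effort_raw)]
  if (length(v) < 2L)
    stop("need at least 2 non-missing effort values to standardize")
  s <- stats::sd(v)
  if (s == 0)
    stop("degenerate effort covariate: all non-missing values are equal")
  out <- effort_raw
  out[!is.na(out)] <- (v - mean(v)) / s
  out
}

.survey_columns <- c("site_id", "station_id", "survey_date",
                     "interval_index", "species", "count", "effort_minutes")

#' Read a raw survey table from CSV
#'
#' Reads one row per `site x station x survey date x 30-min interval x
#' species` observation record, validates every row, and returns the
#' records in file order. Column names in the file can differ from the
#' canonical names via `dialect`.
#'
#' @param path path to a UTF-8, comma-separated file with a header row.
#' @param dialect named character vector mapping canonical column names
#'   (`site_id`, `station_id`, `survey_date`, `interval_index`, `species`,
#'   `count`, `effort_minutes`) to the names used in the file. Unlisted
#'   columns are assumed to carry their canonical names.
#' @return A `data.frame` of validated records, one per input row, with the
#'   canonical columns; `survey_date` is a `Date`.
#' @export
read_survey_csv <- function(path, dialect = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- stats::setNames(.survey_columns, .survey_columns)
  if (length(dialect)) {
    bad <- setdiff(names(dialect), .survey_columns)
    if (length(bad)) stop("unknown canonical column(s) in dialect: ",
                          paste(bad, collapse = ", "))
    map[names(dialect)] <- dialect
  }
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(unname(missing_cols), collapse = ", "))
  rec <- stats::setNames(raw[, unname(map), drop = FALSE], names(map))
  validate_survey_records(rec)
}

validate_survey_records <- function(rec) {
  rec$survey_date <- as.Date(rec$survey_date)
  if (anyNA(rec$survey_date)) stop("unparseable survey_date in row ",
                                   which(is.na(rec$survey_date))[1L])
  for (col in c("interval_index", "count", "effort_minutes"))
    rec[[col]] <- as.numeric(rec[[col]])
  bad <- which(is.na(rec$count) | rec$count < 0 | rec$count != round(rec$count))
  if (length(bad))
    stop("invalid count (must be a non-negative integer) in row ", bad[1L])
  bad <- which(is.na(rec$effort_minutes) | rec$effort_minutes <= 0)
  if (length(bad))
    stop("invalid effort_minutes (must be > 0) in row ", bad[1L])
  bad <- which(is.na(rec$interval_index) | rec$interval_index < 1 |
                 rec$interval_index != round(rec$interval_index))
  if (length(bad))
    stop("invalid interval_index (must be a positive integer) in row ", bad[1L])
  key <- do.call(paste, c(rec[c("site_id", "station_id", "survey_date",
                                "interval_index", "species")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate record (same site, station, date, interval, species) ",
         "in row ", which(duplicated(key))[1L])
  rec$count <- as.integer(rec$count)
  rec$interval_index <- as.integer(rec$interval_index)
  rec
}

#' Collapse raw interval records to a site-by-month survey dataset
#'
#' Applies the standard point-count collapse: within each station and survey
#' the species count is the maximum over its 30-minute intervals (the
#' highest number seen at once), stations are then combined within a site
#' by `aggregation`, and multiple surveys of one site in a calendar month
#' collapse by maximum. Month indices are derived from the calendar month
#' of `survey_date` and renumbered consecutively from 1. Site-month effort
#' is the total duration, in hours, of that site's survey sessions in the
#' month; a session's duration is the maximum of its stations' (normally
#' identical) effort values.
#'
#' @param records validated records as returned by [read_survey_csv()].
#' @param aggregation how station values combine within a site: `"max"`
#'   (default; conservative against double counting of birds visible from
#'   several stations) or `"sum"`.
#' @return A [survey_dataset()]. Species present in the file but never
#'   recorded at a surveyed site-month get count 0 there; site-months with
#'   no records at all are `NA`.
#' @export
collapse_station_counts <- function(records, aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  if (!NROW(records)) stop("no records to collapse")
  rec <- validate_survey_records(as.data.frame(records))
  # one effort value per station-survey
  sskey <- paste(rec$site_id, rec$station_id, rec$survey_date, sep = "\r")
  eff_by_ss <- tapply(rec$effort_minutes, sskey, function(v) {
    if (length(unique(v)) > 1L)
      stop("conflicting effort values for one station-survey")
    v[1L]
  })
  ym <- as.integer(format(rec$survey_date, "%Y")) * 12L +
    as.integer(format(rec$survey_date, "%m"))
  month_levels <- seq(min(ym), max(ym))
  rec$month <- match(ym, month_levels)
  sites <- sort(unique(rec$site_id))
  species <- sort(unique(rec$species))
  S <- length(sites); Tm <- length(month_levels); K <- length(species)

  # interval max per station-survey-species
  k1 <- paste(rec$site_id, rec$month, rec$survey_date, rec$station_id,
              rec$species, sep = "\r")
  st <- tapply(rec$count, k1, max)
  parts <- do.call(rbind, strsplit(names(st), "\r", fixed = TRUE))
  stn <- data.frame(site = parts[, 1], month = as.integer(parts[, 2]),
                    date = parts[, 3], station = parts[, 4],
                    species = parts[, 5], count = as.vector(st))
  # station -> site within one survey; absent species count as 0
  agg_fun <- if (aggregation == "max") max else sum
  counts <- array(NA_real_, c(S, Tm, K))
  effort_raw <- matrix(NA_real_, S, Tm)
  for (i in seq_len(S)) for (t in seq_len(Tm)) {
    sub <- stn[stn$site == sites[i] & stn$month == t, , drop = FALSE]
    if (!nrow(sub)) next
    dates <- unique(sub$date)
    stations_by_date <- lapply(dates, function(d)
      unique(sub$station[sub$date == d]))
    per_survey <- matrix(0, length(dates), K)
    for (j in seq_along(dates)) {
      dsub <- sub[sub$date == dates[j], , drop = FALSE]
      for (k in seq_len(K)) {
        v <- dsub$count[dsub$species == species[k]]
        # a station with no record of this species saw 0 of it
        if (aggregation == "sum") {
          per_survey[j, k] <- sum(v)
        } else {
          per_survey[j, k] <- if (length(v)) max(c(v, 0)) else 0
        }
      }
    }
    counts[i, t, ] <- apply(per_survey, 2, max)  # same-month surveys: max
    sess_eff <- vapply(seq_along(dates), function(j) {
      keys <- paste(sites[i], stations_by_date[[j]], dates[j], sep = "\r")
      max(eff_by_ss[keys])
    }, numeric(1))
    effort_raw[i, t] <- sum(sess_eff) / 60  # minutes -> hours
  }
  survey_dataset(sites, seq_len(Tm), species, counts, effort_raw)
}

#' Write an abundance summary table to CSV
#'
#' Emits the standard report shape: one row per species/site margin with
#' observation totals and posterior percentiles. Values round-trip through
#' [read_summary_csv()] to at least 6 significant digits.
#'
#' @param summary an `abundance_summary` data frame (see
#'   [species_relative_abundance()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  cols <- c("species", "site", "n_observations", "pct_2_5", "median",
            "pct_97_5")
  if (!all(cols %in% names(summary)))
    stop("summary must have columns: ", paste(cols, collapse = ", "))
  out <- as.data.frame(summary)[, cols, drop = FALSE]
  for (col in c("pct_2_5", "median", "pct_97_5"))
    out[[col]] <- signif(out[[col]], 12)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("abundance_summary", "data.frame")
  out
}
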