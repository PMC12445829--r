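#' Daily climate series for one site
#'
#' Bundles a site's daily minimum / mean / maximum temperature and
#' precipitation with the site metadata (latitude, elevation) that the
#' phenology and frost computations need. Dates must be strictly increasing
#' and `tmin <= tmean <= tmax` must hold on every record.
#'
#' @param records data.frame with columns `date` (Date or ISO-8601 string),
#'   `tmin`, `tmean`, `tmax` (degrees C) and optionally `precip` (mm,
#'   defaults to 0).
#' @param site_id character site identifier.
#' @param latitude site latitude in decimal degrees.
#' @param elevation site elevation in m a.s.l. (metadata only).
#' @return A data.frame of class `climate_series` with added `year` and `doy`
#'   columns and attributes `site_id`, `latitude`, `elevation`.
#' @export
climate_series <- function(records, site_id, latitude, elevation = NA_real_) {
  stopifnot(is.data.frame(records))
  needed <- c("date", "tmin", "tmean", "tmax")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop_field("records", paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  check_scalar_number(latitude, "latitude", lower = -90, upper = 90)
  x <- records
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop_field("records$date", "unparseable dates")
  if (is.unsorted(x$date, strictly = TRUE))
    stop_field("records$date", "dates must be strictly increasing")
  if (!"precip" %in% names(x)) x$precip <- 0
  bad <- which(!(x$tmin <= x$tmean & x$tmean <= x$tmax))
  if (length(bad))
    stop_field("records", sprintf("tmin <= tmean <= tmax violated on %d record(s), first at row %d",
                                  length(bad), bad[1]))
  x$year <- as.integer(format(x$date, "%Y"))
  x$doy <- doy_of(x$date)
  x <- x[, c("date", "year", "doy", "tmin", "tmean", "tmax", "precip")]
  structure(x,
            site_id = as.character(site_id),
            latitude = latitude,
            elevation = elevation,
            class = c("climate_series", "data.frame"))
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> site %s, lat %.2f, %d days (%s .. %s)\n",
              attr(x, "site_id"), attr(x, "latitude"), nrow(x),
              format(min(x$date)), format(max(x$date))))
  invisible(x)
}

site_id_of <- function(climate) attr(climate, "site_id")
latitude_of <- function(climate) attr(climate, "latitude")

# rows of one calendar year, ordered by doy
climate_year <- function(climate, year) {
  climate[climate$year == year, , drop = FALSE]
}

#' Read / write site climate CSV files
#'
#' The on-disk format is one row per day with columns
#' `site_id,date,tmin,tmean,tmax,precip` (ISO-8601 dates, temperatures in
#' degrees C, precipitation in mm). Site latitude/elevation are not part of
#' the CSV and are supplied through `sites`.
#'
#' @param path file path.
#' @param sites data.frame with columns `site_id`, `latitude` and optionally
#'   `elevation`, one row per site present in the file.
#' @return `read_climate_csv()`: a named list of [climate_series()] objects,
#'   one per site. `write_climate_csv()`: the path, invisibly.
#' @export
read_climate_csv <- function(path, sites) {
  stopifnot(all(c("site_id", "latitude") %in% names(sites)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site_id", "date", "tmin", "tmean", "tmax")
  if (!all(needed %in% names(df)))
    stop_field("path", paste("climate CSV must have columns", paste(needed, collapse = ",")))
  out <- lapply(split(df, df$site_id), function(d) {
    meta <- sites[match(d$site_id[1], sites$site_id), ]
    if (is.na(meta$site_id))
      stop_field("sites", paste("no metadata for site", d$site_id[1]))
    climate_series(d[order(as.Date(d$date)), ], d$site_id[1], meta$latitude,
                   if ("elevation" %in% names(meta)) meta$elevation else NA_real_)
  })
  out
}

#' @param climate a [climate_series()] object (or named list of them).
#' @rdname read_climate_csv
#' @export
write_climate_csv <- function(climate, path) {
  if (inherits(climate, "climate_series")) climate <- list(climate)
  rows <- do.call(rbind, lapply(climate, function(x) {
    data.frame(site_id = site_id_of(x), date = format(x$date, "%Y-%m-%d"),
               tmin = x$tmin, tmean = x$tmean, tmax = x$tmax, precip = x$precip,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write leaf-out observation CSV files
#'
#' Columns: `site_id,year,leafout_doy`.
#'
#' @param path file path.
#' @return `read_pheno_csv()`: data.frame with columns `site_id`, `year`,
#'   `leafout_doy`.
#' @export
read_pheno_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "year", "leafout_doy") %in% names(df)))
    stop_field("path", "phenology CSV must have columns site_id,year,leafout_doy")
  bad <- df$leafout_doy < 1 | df$leafout_doy > 366
  if (any(bad)) stop_field("leafout_doy", "must lie in [1, 366]")
  df
}

#' @param observations data.frame with columns `site_id`, `year`, `leafout_doy`.
#' @rdname read_pheno_csv
#' @export
write_pheno_csv <- function(observations, path) {
  utils::write.csv(observations[, c("site_id", "year", "leafout_doy")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
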