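#' Read a Tucson / RWL decadal ring-width file
#'
#' Parses the standard decadal fixed-width text format: series id in columns
#' 1-8, decade start year, then up to ten yearly values. Measurement units
#' are detected per series from the stop marker: `999` means 0.01 mm
#' precision, `-9999` means 0.001 mm. Values are returned in mm.
#'
#' @param path file path.
#' @return wide data.frame of class `rwl`: rownames are years, one column per
#'   series, `NA` outside a series' span. An empty file yields an empty
#'   data.frame with a warning. Malformed lines and duplicate overlapping
#'   series raise errors naming the line.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty RWL file: ", path, call. = FALSE)
    return(structure(data.frame(), class = c("rwl", "data.frame")))
  }
  series <- list()   # id -> named numeric (names = years) of raw integers
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (nchar(line) < 13)
      stop(sprintf("%s line %d: too short for the decadal format", path, ln), call. = FALSE)
    id <- trimws(substr(line, 1, 8))
    rest <- strsplit(trimws(substr(line, 9, nchar(line))), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(rest))
    if (length(vals) < 2 || anyNA(vals))
      stop(sprintf("%s line %d: malformed decade row", path, ln), call. = FALSE)
    year0 <- vals[1]
    vv <- vals[-1]
    yrs <- seq(year0, length.out = length(vv))
    prev <- series[[id]]
    if (!is.null(prev) && any(as.character(yrs) %in% names(prev)))
      stop(sprintf("%s line %d: series %s has overlapping duplicate years", path, ln, id),
           call. = FALSE)
    series[[id]] <- c(prev, stats::setNames(as.numeric(vv), as.character(yrs)))
  }
  # the stop marker is the LAST value of each series; it both terminates the
  # series and encodes its units (999 -> 0.01 mm, -9999 -> 0.001 mm). A 999
  # elsewhere in a 0.001-mm series is a data value (0.999 mm).
  scales <- numeric(0)
  for (id in names(series)) {
    s <- series[[id]]
    last <- s[length(s)]
    if (last == -9999) {
      scales[id] <- 0.001
      series[[id]] <- s[-length(s)]
    } else if (last == 999) {
      scales[id] <- 0.01
      series[[id]] <- s[-length(s)]
    } else {
      scales[id] <- 0.01   # no terminator: assume 0.01 mm
    }
  }
  series <- Filter(length, series)
  if (length(series) == 0) {
    warning("no data rows in RWL file: ", path, call. = FALSE)
    return(structure(data.frame(), class = c("rwl", "data.frame")))
  }
  all_years <- sort(unique(unlist(lapply(series, function(s) as.integer(names(s))))))
  out <- data.frame(row.names = as.character(all_years))
  for (id in names(series)) {
    col <- rep(NA_real_, length(all_years))
    s <- series[[id]]
    col[match(as.integer(names(s)), all_years)] <- s * scales[id]
    out[[id]] <- col
  }
  structure(out, class = c("rwl", "data.frame"))
}

#' Write ring-width series in Tucson / RWL decadal format
#'
#' @param rwl wide data.frame (years as rownames, one series per column),
#'   widths in mm.
#' @param path output path.
#' @param precision 0.001 (stop marker -9999, default) or 0.01 mm (stop
#'   marker 999). Widths are rounded to this precision on output.
#' @return the path, invisibly.
#' @export
write_rwl <- function(rwl, path, precision = 0.001) {
  if (!precision %in% c(0.001, 0.01))
    stop_field("precision", "must be 0.001 or 0.01")
  stop_marker <- if (precision == 0.001) -9999L else 999L
  years <- as.integer(rownames(rwl))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in colnames(rwl)) {
    if (nchar(id) > 8) stop_field("rwl", sprintf("series id '%s' exceeds 8 characters", id))
    v <- rwl[[id]]
    ok <- which(!is.na(v))
    if (length(ok) == 0) next
    yrs <- years[ok[1]:ok[length(ok)]]
    vals <- as.integer(round(v[ok[1]:ok[length(ok)]] / precision))
    vals <- c(vals, stop_marker)
    yr_of <- c(yrs, max(yrs) + 1L)
    i <- 1L
    while (i <= length(vals)) {
      y <- yr_of[i]
      # fill to the end of the decade
      n_in_row <- min(10L - (y %% 10L), length(vals) - i + 1L)
      row_vals <- vals[i:(i + n_in_row - 1L)]
      writeLines(sprintf("%-8s%4d%s", id, y,
                         paste(sprintf("%6d", row_vals), collapse = "")), con)
      i <- i + n_in_row
    }
  }
  invisible(path)
}
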