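# The residual frost-year indicator: subtract the reference-species site
# chronology from each frost-sensitive tree's index series, standardise to
# z-scores, and call a frost year when a supermajority of trees fall below
# the moderate threshold. The subtraction removes the climate signal the two
# species share, so only divergent (species-specific) growth reductions --
# the signature of late-spring-frost defoliation on a deciduous host vs an
# evergreen reference -- survive.

#' Residual z-score series of sensitive trees against a reference chronology
#'
#' For every tree column, residual = tree index minus the reference
#' chronology value of the same year, standardised over the tree's full
#' overlap with the chronology. A degenerate residual SD of 0 yields an
#' all-zero z series with a warning.
#'
#' @param tree_rwi wide data.frame of per-tree indices (years as rownames).
#' @param reference_chronology a [biweight_chronology()]-style data.frame
#'   (`year`, `value`).
#' @param min_overlap minimum overlapping years required per tree (default 20).
#' @return wide data.frame of z-scores (years as rownames, trees as columns);
#'   years without a chronology value are `NA`.
#' @export
residual_series <- function(tree_rwi, reference_chronology, min_overlap = 20L) {
  years <- as.integer(rownames(tree_rwi))
  ref <- reference_chronology$value[match(years, reference_chronology$year)]
  out <- data.frame(row.names = rownames(tree_rwi))
  for (id in colnames(tree_rwi)) {
    resid <- tree_rwi[[id]] - ref
    ok <- !is.na(resid)
    if (sum(ok) < min_overlap)
      stop(sprintf("tree %s overlaps the reference chronology by %d yr (< %d)",
                   id, sum(ok), min_overlap), call. = FALSE)
    s <- stats::sd(resid[ok])
    z <- rep(NA_real_, length(resid))
    if (s == 0) {
      warning(sprintf("tree %s: residual SD is 0; z set to 0", id), call. = FALSE)
      z[ok] <- 0
    } else {
      z[ok] <- (resid[ok] - mean(resid[ok])) / s
    }
    out[[id]] <- z
  }
  out
}

#' Site-level residual chronology
#'
#' Plain per-year mean of the individual residual z series (unlike the
#' species chronologies, which use a biweight mean).
#'
#' @param residual_z wide data.frame from [residual_series()].
#' @return data.frame `year, value, sample_depth`.
#' @export
build_site_residual_chronology <- function(residual_z) {
  m <- as.matrix(residual_z)
  depth <- rowSums(!is.na(m))
  out <- data.frame(year = as.integer(rownames(residual_z)),
                    value = rowMeans(m, na.rm = TRUE),
                    sample_depth = as.integer(depth))
  out <- out[out$sample_depth >= 1, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chronology", "data.frame")
  out
}

#' Call frost years from residual z-scores
#'
#' A year is flagged when at least `tree_fraction` of the contributing trees
#' have z below the moderate threshold; severity is `"severe"` when the same
#' fraction falls below the severe threshold, else `"moderate"`.
#'
#' @param residual_z wide data.frame from [residual_series()].
#' @param moderate_z,severe_z z-score thresholds (defaults -1 and -1.5).
#' @param tree_fraction fraction of trees required (default 0.6, applied as
#'   `>=`).
#' @param min_trees years with fewer contributing trees are not evaluated
#'   (default 3).
#' @return data.frame `year, n_trees, frac_moderate, frac_severe, flagged,
#'   severity`.
#' @export
flag_frost_years <- function(residual_z, moderate_z = -1, severe_z = -1.5,
                             tree_fraction = 0.6, min_trees = 3L) {
  m <- as.matrix(residual_z)
  n <- rowSums(!is.na(m))
  frac_mod <- rowSums(m < moderate_z, na.rm = TRUE) / n
  frac_sev <- rowSums(m < severe_z, na.rm = TRUE) / n
  keep <- n >= min_trees
  flagged <- frac_mod >= tree_fraction
  severity <- ifelse(!flagged, "none",
                     ifelse(frac_sev >= tree_fraction, "severe", "moderate"))
  out <- data.frame(year = as.integer(rownames(residual_z)),
                    n_trees = as.integer(n),
                    frac_moderate = frac_mod, frac_severe = frac_sev,
                    flagged = flagged, severity = severity,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance of tree-ring frost calls with climate-phenology flags
#'
#' For every tree-ring-flagged year, records whether the climate/phenology
#' rule (frost at or below the threshold within the damage window around
#' predicted leaf-out) also flags it, plus the coldest window temperature.
#' For discordant years, if `climate` is supplied, spring frosts outside the
#' window are listed as candidate explanations.
#'
#' @param calls output of [flag_frost_years()].
#' @param margins output of [safety_margin_records()] for the same site.
#' @param climate optional [climate_series()] used to report the coldest
#'   window temperature and out-of-window candidate frosts.
#' @param threshold,window frost rule, see [frost_in_window()].
#' @param candidate_range day-of-year range searched for out-of-window
#'   candidates (default spring, DOY 60-181).
#' @return list: `table` (data.frame `year, treering_flagged,
#'   climate_pheno_flagged, leafout_doy, window_tmin, out_of_window`) and
#'   `fraction_concordant` (`NA` when nothing is flagged).
#' @export
concordance_table <- function(calls, margins, climate = NULL, threshold = -1,
                              window = c(-5L, 14L),
                              candidate_range = c(60L, 181L)) {
  flagged <- calls[calls$flagged, , drop = FALSE]
  if (nrow(flagged) == 0)
    return(list(table = data.frame(), fraction_concordant = NA_real_))
  rows <- lapply(flagged$year, function(y) {
    mi <- match(y, margins$year)
    cp <- if (is.na(mi)) NA else margins$window_frost[mi]
    leaf <- if (is.na(mi)) NA_integer_ else margins$leafout_doy[mi]
    wt <- NA_real_
    cand <- ""
    if (!is.null(climate) && !is.na(leaf)) {
      yr <- climate_year(climate, y)
      win <- yr[yr$doy >= leaf + window[1] & yr$doy <= leaf + window[2], ]
      if (nrow(win)) wt <- min(win$tmin)
      if (!isTRUE(cp)) {
        out <- yr[yr$doy >= candidate_range[1] & yr$doy <= candidate_range[2] &
                    (yr$doy < leaf + window[1] | yr$doy > leaf + window[2]) &
                    yr$tmin <= threshold, ]
        if (nrow(out))
          cand <- paste(sprintf("%.1f@%d", out$tmin, out$doy), collapse = ";")
      }
    }
    data.frame(year = y, treering_flagged = TRUE, climate_pheno_flagged = cp,
               leafout_doy = leaf, window_tmin = wt, out_of_window = cand,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       fraction_concordant = mean(tab$climate_pheno_flagged, na.rm = TRUE))
}

#' Apply the frost-window rule to reported per-year records
#'
#' Worked-example form of the concordance rule for tabulated site records:
#' each row carries a year's coldest window temperature, its day and the
#' predicted leaf-out day; the row is concordant when the temperature is at
#' or below the threshold and its day falls within the damage window around
#' leaf-out.
#'
#' @param rows data.frame with columns `year`, `leafout_doy`, `window_tmin`,
#'   `window_tmin_doy`.
#' @param threshold,window frost rule, see [frost_in_window()].
#' @return list: `table` (rows plus `concordant`), `n_concordant`,
#'   `pct_concordant` (percent of rows).
#' @export
concordance_from_rows <- function(rows, threshold = -1, window = c(-5L, 14L)) {
  stopifnot(all(c("year", "leafout_doy", "window_tmin", "window_tmin_doy")
                %in% names(rows)))
  offs <- rows$window_tmin_doy - rows$leafout_doy
  conc <- rows$window_tmin <= threshold & offs >= window[1] & offs <= window[2]
  rows$concordant <- conc
  list(table = rows, n_concordant = sum(conc),
       pct_concordant = 100 * sum(conc) / nrow(rows))
}

#' Count flagged frost years per period
#'
#' @param call_years integer vector of flagged years (or a
#'   [flag_frost_years()] result, from which flagged years are taken).
#' @param periods list of `c(first_year, last_year)` ranges.
#' @return data.frame `first, last, n_years, count, return_interval_yr`
#'   (period length divided by count; `Inf` when the count is 0).
#' @export
period_counts <- function(call_years, periods) {
  if (is.data.frame(call_years)) call_years <- call_years$year[call_years$flagged]
  out <- do.call(rbind, lapply(periods, function(p) {
    len <- p[2] - p[1] + 1
    if (len <= 0) stop_field("periods", "zero-length period")
    cnt <- sum(call_years >= p[1] & call_years <= p[2])
    data.frame(first = p[1], last = p[2], n_years = len, count = cnt,
               return_interval_yr = if (cnt > 0) len / cnt else Inf)
  }))
  rownames(out) <- NULL
  out
}
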