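#' Average the cores of each tree
#'
#' Arithmetic mean per year over the available cores of a tree; years where
#' only one core has data pass that core's value through.
#'
#' @param rwi wide data.frame of per-core indices (years as rownames).
#' @param tree_ids character vector mapping each column to its tree; by
#'   default the series id minus its trailing core letter.
#' @return wide data.frame with one column per tree; attribute
#'   `single_core_years` lists, per tree, years covered by only one core.
#' @export
average_cores <- function(rwi, tree_ids = sub(".$", "", colnames(rwi))) {
  stopifnot(length(tree_ids) == ncol(rwi))
  trees <- unique(tree_ids)
  out <- data.frame(row.names = rownames(rwi))
  single <- list()
  for (tr in trees) {
    cols <- as.matrix(rwi[, tree_ids == tr, drop = FALSE])
    n_obs <- rowSums(!is.na(cols))
    v <- rowMeans(cols, na.rm = TRUE)
    v[n_obs == 0] <- NA_real_
    out[[tr]] <- v
    if (ncol(cols) > 1) {
      yrs <- rownames(rwi)[n_obs == 1]
      if (length(yrs)) single[[tr]] <- as.integer(yrs)
    }
  }
  structure(out, single_core_years = single, class = c("rwl", "data.frame"))
}

#' Tukey's biweight robust mean
#'
#' Location estimate started at the median with MAD scale, iterated to
#' convergence. With tuning constant 9 (the dendrochronological convention)
#' values beyond nine scaled MADs from the current estimate get zero weight.
#' Falls back to the median when the MAD is zero.
#'
#' @param x numeric values (`NA` dropped).
#' @param const tuning constant (default 9).
#' @param tol convergence tolerance on the location (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return the robust mean (scalar).
#' @export
biweight_mean <- function(x, const = 9, tol = 1e-8, max_iter = 50L) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  m <- stats::median(x)
  s <- stats::mad(x)   # 1.4826 * median absolute deviation
  if (s == 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / (const * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Build a site chronology with a biweight robust mean
#'
#' @param tree_rwi wide data.frame of per-tree indices (years as rownames).
#' @param min_depth sample depth below which a year is flagged (default 6);
#'   flagged years are kept but marked.
#' @param ... passed to [biweight_mean()].
#' @return data.frame of class `chronology`: `year, value, sample_depth,
#'   low_depth`; years with no data are dropped.
#' @export
biweight_chronology <- function(tree_rwi, min_depth = 6L, ...) {
  m <- as.matrix(tree_rwi)
  depth <- rowSums(!is.na(m))
  value <- apply(m, 1, biweight_mean, ...)
  out <- data.frame(year = as.integer(rownames(tree_rwi)),
                    value = as.numeric(value),
                    sample_depth = as.integer(depth),
                    low_depth = depth < min_depth)
  out <- out[out$sample_depth >= 1, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chronology", "data.frame")
  out
}

#' Chronology quality statistics
#'
#' Classical descriptive statistics of a set of tree index series: mean
#' interseries correlation (rbar, over pairs with sufficient overlap), the
#' expressed population signal `EPS = n*rbar / (n*rbar + 1 - rbar)`,
#' first-order autocorrelation and mean sensitivity of the biweight
#' chronology.
#'
#' @param tree_rwi wide data.frame of per-tree indices.
#' @param min_overlap minimum overlapping years for a pair to enter rbar
#'   (default 20).
#' @return list: `rbar`, `eps`, `ar1`, `mean_sensitivity`, `n_trees`, `span`.
#' @export
chronology_stats <- function(tree_rwi, min_overlap = 20L) {
  m <- as.matrix(tree_rwi)
  n_trees <- ncol(m)
  if (n_trees < 2) stop_field("tree_rwi", "needs >= 2 series")
  cors <- c()
  for (i in seq_len(n_trees - 1)) {
    for (j in (i + 1):n_trees) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) >= min_overlap)
        cors <- c(cors, stats::cor(m[ok, i], m[ok, j]))
    }
  }
  if (length(cors) == 0)
    stop("no series pair overlaps by >= min_overlap years", call. = FALSE)
  rbar <- mean(cors)
  eps <- n_trees * rbar / (n_trees * rbar + 1 - rbar)
  chron <- biweight_chronology(tree_rwi, min_depth = 1L)
  v <- chron$value
  ar1 <- if (length(v) > 2 && stats::sd(v) > 0)
    stats::cor(v[-1], v[-length(v)]) else NA_real_
  ms <- mean(abs(2 * diff(v) / (v[-1] + v[-length(v)])))
  list(rbar = rbar, eps = eps, ar1 = ar1, mean_sensitivity = ms,
       n_trees = n_trees, span = range(chron$year))
}
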