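#' Reference range for a laboratory analyte
#'
#' @param analyte Analyte name (e.g. `"serum_25ohd"`).
#' @param lower,upper Bounds of the reference interval in the analyte's
#'   units; `lower < upper` is required. A value `x` is below range when
#'   `x < lower`, within range when `lower <= x <= upper`, above range when
#'   `x > upper`.
#' @return An object of class `reference_range`.
#' @export
reference_range <- function(analyte, lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("invalid reference range: need finite lower < upper")
  structure(list(analyte = analyte, lower = lower, upper = upper),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("Reference range for %s: [%g, %g]\n", x$analyte, x$lower, x$upper))
  invisible(x)
}

#' One site's measurements of a single analyte
#'
#' @param site_id Site identifier.
#' @param analyte Analyte name; panels normalized together must share it.
#' @param values Numeric vector of finite measurements.
#' @param range Optional [reference_range()] (required for
#'   [stratified_quantile_normalize()]).
#' @return An object of class `lab_panel`.
#' @export
lab_panel <- function(site_id, analyte, values, range = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("invalid `values`: all measurements must be finite")
  if (!is.null(range) && !inherits(range, "reference_range"))
    stop("`range` must be a reference_range object")
  structure(list(site_id = site_id, analyte = analyte, values = values,
                 range = range),
            class = "lab_panel")
}

#' @export
print.lab_panel <- function(x, ...) {
  cat(sprintf("Lab panel: site %s, analyte %s, n = %d\n",
              as.character(x$site_id), x$analyte, length(x$values)))
  invisible(x)
}

.panel_values <- function(panels) {
  lapply(panels, function(p) if (inherits(p, "lab_panel")) p$values else as.numeric(p))
}

.panel_rebuild <- function(panels, values) {
  Map(function(p, v) {
    if (inherits(p, "lab_panel")) { p$values <- v; p } else v
  }, panels, values)
}

# Core rank-average normalization on a list of numeric vectors.
# Equal lengths: classic rank averaging (the value of rank i in every panel is
# replaced by the mean over panels of the i-th order statistics). Unequal
# lengths: each panel's empirical quantile function is interpolated onto a
# common probability grid, averaged across panels, and each value is mapped
# back through the averaged quantile function at its own quantile position.
# Ties within a panel receive the mean of the rank-averages they span.
.qnorm_core <- function(vals) {
  ns <- lengths(vals)
  if (length(unique(ns)) == 1L) {
    ref <- rowMeans(do.call(cbind, lapply(vals, sort)))
    lapply(vals, function(x) {
      out <- ref[rank(x, ties.method = "first")]
      as.numeric(stats::ave(out, x, FUN = mean))
    })
  } else {
    m <- max(ns)
    grid <- (seq_len(m) - 0.5) / m
    qgrid <- lapply(vals, function(x) {
      n <- length(x)
      sx <- sort(x)
      if (n == 1L) rep(sx, m)
      else approx((seq_len(n) - 0.5) / n, sx, xout = grid, rule = 2)$y
    })
    qbar <- rowMeans(do.call(cbind, qgrid))
    lapply(vals, function(x) {
      n <- length(x)
      p <- (rank(x, ties.method = "first") - 0.5) / n
      out <- approx(grid, qbar, xout = p, rule = 2)$y
      as.numeric(stats::ave(out, x, FUN = mean))
    })
  }
}

#' Quantile-normalize laboratory panels across sites
#'
#' Forces the panels to share a distribution by averaging values of equal
#' rank: each panel is sorted in ascending order, values at the same rank are
#' averaged across panels, and the average replaces each panel's value at
#' that rank. With equal-length panels every output panel contains the
#' identical multiset of values; with unequal lengths the panels are mapped
#' through a common quantile grid by linear interpolation. Within-panel rank
#' order is always preserved.
#'
#' @param panels A list (length >= 2) of [lab_panel()] objects or bare
#'   numeric vectors, all non-empty and of the same analyte.
#' @return A list of the same type and length with normalized values.
#' @export
#' @examples
#' quantile_normalize(list(c(2, 4, 6), c(5, 1, 3)))
quantile_normalize <- function(panels) {
  vals <- .panel_values(panels)
  if (any(lengths(vals) == 0L)) stop("empty panel: cannot normalize")
  if (length(vals) == 1L) {
    warning("only one panel supplied; returned unchanged")
    return(panels)
  }
  an <- unique(unlist(lapply(panels, function(p)
    if (inherits(p, "lab_panel")) p$analyte else NULL)))
  if (length(an) > 1L)
    stop("panels measure different analytes: ", paste(an, collapse = ", "))
  .panel_rebuild(panels, .qnorm_core(vals))
}

.stratum_of <- function(x, lower, upper) {
  ifelse(x < lower, "below", ifelse(x > upper, "above", "within"))
}

#' Reference-range-stratified quantile normalization
#'
#' Partitions each panel into below-range (`x < lower`), within-range
#' (`lower <= x <= upper`) and above-range (`x > upper`) strata, applies
#' [quantile_normalize()] independently within each stratum across panels,
#' and reassembles results in the original record order. Normalizing within
#' strata preserves the clinical meaning of a value relative to the
#' reference interval. If averaging would push a value across its stratum
#' boundary it is clamped back inside (with a warning); if a stratum is
#' empty in at least one panel, that stratum passes through unchanged in all
#' panels (with a warning), since no cross-panel ranks exist to average.
#'
#' @param panels A list (length >= 2) of [lab_panel()] objects sharing one
#'   [reference_range()], or bare numeric vectors with `range` supplied.
#' @param range A [reference_range()]; defaults to the shared range of the
#'   panels.
#' @return A list matching `panels` with normalized values.
#' @export
stratified_quantile_normalize <- function(panels, range = NULL) {
  vals <- .panel_values(panels)
  if (any(lengths(vals) == 0L)) stop("empty panel: cannot normalize")
  if (length(vals) == 1L) {
    warning("only one panel supplied; returned unchanged")
    return(panels)
  }
  if (is.null(range)) {
    rr <- unique(lapply(panels, function(p)
      if (inherits(p, "lab_panel")) p$range else NULL))
    rr <- Filter(Negate(is.null), rr)
    if (length(rr) != 1L)
      stop("panels must share a single reference range (or supply `range`)")
    range <- rr[[1]]
  }
  lower <- range$lower; upper <- range$upper
  strata <- lapply(vals, .stratum_of, lower = lower, upper = upper)
  out <- vals
  eps <- 1e-8 * (upper - lower)
  for (s in c("below", "within", "above")) {
    idx <- lapply(strata, function(st) which(st == s))
    counts <- lengths(idx)
    if (all(counts == 0L)) next
    if (any(counts == 0L)) {
      warning(sprintf(
        "stratum '%s' empty in %d panel(s); passed through unchanged", s,
        sum(counts == 0L)))
      next
    }
    sub <- Map(function(v, i) v[i], vals, idx)
    norm <- .qnorm_core(sub)
    norm <- lapply(norm, function(v) {
      clamped <- switch(s,
        below = pmin(v, lower - eps),
        within = pmin(pmax(v, lower), upper),
        above = pmax(v, upper + eps))
      if (any(clamped != v))
        warning(sprintf("%d value(s) clamped back into stratum '%s'",
                        sum(clamped != v), s))
      clamped
    })
    for (k in seq_along(out)) out[[k]][idx[[k]]] <- norm[[k]]
  }
  .panel_rebuild(panels, out)
}
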