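#' Peak transgene expansion (Cmax)
#'
#' Maximum copies/ug over all post-infusion (day > 0) points; ties are broken
#' by the earliest day. The window is unrestricted: the peak may occur after
#' day 28.
#'
#' @param series data.frame with `day` (strictly increasing, >= 0) and
#'   `copies_per_ug` (>= 0) for one patient.
#' @return list(cmax, tmax_day).
#' @export
compute_cmax <- function(series) {
  stopifnot(all(diff(series$day) > 0), all(series$copies_per_ug >= 0))
  post <- series[series$day > 0, , drop = FALSE]
  if (!nrow(post))
    stop("Cmax undefined: no post-infusion (day > 0) points", call. = FALSE)
  i <- which.max(post$copies_per_ug)  # first maximum = earliest day (days sorted)
  list(cmax = post$copies_per_ug[i], tmax_day = post$day[i])
}

#' Area under the expansion curve from day 0 to day 28
#'
#' Linear trapezoid on the (day, copies) points restricted to [0, 28]. No
#' extrapolation: if there is no day-0 observation the curve starts at the
#' first observed day, and if the last observation is before day 28 the
#' integration stops there. A point beyond day 28 is interpolated linearly to
#' close the interval at exactly day 28.
#'
#' @param series as in [compute_cmax()].
#' @return AUC in copies x day / ug, or NA (with a warning) when fewer than
#'   two usable points exist.
#' @export
compute_auc_0_28 <- function(series) {
  stopifnot(all(diff(series$day) > 0), all(series$copies_per_ug >= 0))
  d <- series$day
  y <- series$copies_per_ug
  if (any(d > 28) && any(d <= 28)) {
    # interpolate the curve at day 28 so the integral closes at the boundary
    y28 <- stats::approx(d, y, xout = 28)$y
    keep <- d <= 28
    d <- c(d[keep], 28)
    y <- c(y[keep], y28)
  } else {
    keep <- d <= 28
    d <- d[keep]
    y <- y[keep]
  }
  if (length(d) < 2) {
    warning("AUC 0-28 undefined: fewer than 2 points with day <= 28")
    return(NA_real_)
  }
  sum(diff(d) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Transgene persistence at a given week
#'
#' Value at the sampled day nearest to `7 * week` within `window_days`
#' (ties to the earlier day); missing when no sample falls in the window.
#'
#' @param series as in [compute_cmax()].
#' @param week target week post-infusion.
#' @param window_days acceptance half-window in days.
#' @return copies/ug or NA.
#' @export
persistence_at_week <- function(series, week = 4, window_days = 3) {
  target <- 7 * week
  dist <- abs(series$day - target)
  i <- which.min(dist)
  if (!length(i) || dist[i] > window_days) return(NA_real_)
  series$copies_per_ug[i]
}

#' Per-patient expansion summaries
#'
#' Computes Cmax/tmax, AUC day 0-28 and week-4 persistence for each patient
#' in a long expansion table.
#'
#' @param expansion data.frame: patient_id, day, copies_per_ug.
#' @return data.frame: patient_id, cmax, tmax_day, auc_0_28, persistence_wk4.
#' @export
expansion_summary <- function(expansion) {
  ids <- unique(expansion$patient_id)
  rows <- lapply(ids, function(pid) {
    s <- expansion[expansion$patient_id == pid, , drop = FALSE]
    s <- s[order(s$day), , drop = FALSE]
    cm <- tryCatch(compute_cmax(s), error = function(e) list(cmax = NA_real_, tmax_day = NA_real_))
    data.frame(
      patient_id = pid,
      cmax = cm$cmax,
      tmax_day = cm$tmax_day,
      auc_0_28 = suppressWarnings(compute_auc_0_28(s)),
      persistence_wk4 = persistence_at_week(s, 4, 3),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
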