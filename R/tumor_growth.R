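#' Tumor volume from caliper diameters
#'
#' \eqn{V = (\pi/6)\,\mathrm{length}^2\,\mathrm{width}} with length the
#' longer and width the shorter caliper diameter (mm). The formula
#' squares the longer diameter; the conventional ellipsoid variant
#' squaring the shorter diameter is available via `formula`.
#'
#' @param length,width caliper diameters in mm (> 0); vectorized.
#' @param formula `"length2width"` (default) or `"width2length"`.
#' @return volume in mm^3.
#' @examples
#' tumor_volume(6, 3)  # 18*pi ~= 56.5 mm^3
#' @export
tumor_volume <- function(length, width, formula = c("length2width",
                                                    "width2length")) {
  formula <- match.arg(formula)
  if (any(length <= 0) || any(width <= 0)) {
    stopf("tumor_volume: diameters must be > 0")
  }
  if (formula == "length2width") pi / 6 * length^2 * width
  else pi / 6 * width^2 * length
}

# Validate a caliper table and add volume + relative-volume columns.
# Expects columns tumor_id, group, day, length_mm, width_mm; the first
# measurement of every tumor must be at day 0.
add_volumes <- function(caliper, formula = "length2width") {
  need <- c("tumor_id", "group", "day", "length_mm", "width_mm")
  miss <- setdiff(need, names(caliper))
  if (length(miss)) stopf("caliper table missing columns: %s",
                          paste(miss, collapse = ", "))
  caliper <- caliper[order(caliper$tumor_id, caliper$day), , drop = FALSE]
  caliper$volume_mm3 <- tumor_volume(caliper$length_mm, caliper$width_mm,
                                     formula = formula)
  caliper
}

#' Relative tumor volume trajectories
#'
#' Divides each tumor's volume series by its day-0 volume, so every
#' trajectory starts at exactly 1.
#'
#' @param caliper data.frame with `tumor_id`, `group`, `day`,
#'   `length_mm`, `width_mm`.
#' @param formula volume formula variant, see [tumor_volume()].
#' @return the table with `volume_mm3` and `rel_volume` columns added.
#' @export
relative_volume <- function(caliper, formula = "length2width") {
  caliper <- add_volumes(caliper, formula)
  out <- lapply(split(caliper, caliper$tumor_id), function(d) {
    v0 <- d$volume_mm3[d$day == 0]
    if (length(v0) != 1L) {
      stopf("tumor '%s': exactly one day-0 measurement required",
            d$tumor_id[1])
    }
    d$rel_volume <- d$volume_mm3 / v0
    d
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$tumor_id, out$day), , drop = FALSE]
}

#' First crossing of a relative-volume threshold
#'
#' Linear interpolation between the bracketing caliper measurements
#' gives the first day the relative volume reaches `threshold`
#' (default 3-fold). A trajectory that never reaches it within the
#' observation window is censored at its last measurement day.
#'
#' @param rel_volume relative volumes (first value 1 at day 0).
#' @param days measurement days, non-decreasing, starting at 0.
#' @param threshold fold-increase defining the endpoint.
#' @return list with `days` (crossing or last day) and `censored`.
#' @export
time_to_threshold <- function(rel_volume, days, threshold = 3) {
  if (length(rel_volume) != length(days) || length(days) < 1L) {
    stopf("time_to_threshold: mismatched or empty series")
  }
  if (rel_volume[1] >= threshold) return(list(days = 0, censored = FALSE))
  above <- which(rel_volume >= threshold)
  if (!length(above)) {
    return(list(days = days[length(days)], censored = TRUE))
  }
  i <- above[1]
  frac <- (threshold - rel_volume[i - 1]) / (rel_volume[i] - rel_volume[i - 1])
  list(days = days[i - 1] + frac * (days[i] - days[i - 1]), censored = FALSE)
}

#' Per-tumor growth-delay endpoints for a cohort
#'
#' @param caliper caliper table (see [relative_volume()]).
#' @param threshold fold-increase endpoint (default 3).
#' @param formula volume formula variant.
#' @return data.frame: `tumor_id`, `group`, `time_to_threshold` (days),
#'   `censored`.
#' @export
growth_endpoints <- function(caliper, threshold = 3,
                             formula = "length2width") {
  rv <- relative_volume(caliper, formula)
  rows <- lapply(split(rv, rv$tumor_id), function(d) {
    tt <- time_to_threshold(d$rel_volume, d$day, threshold)
    data.frame(tumor_id = d$tumor_id[1], group = d$group[1],
               time_to_threshold = tt$days, censored = tt$censored)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Tumor growth delay of a treated group against controls
#'
#' Difference of group mean times to the fold-increase endpoint,
#' treated minus control. If any treated tumor is censored (never
#' reached the endpoint within the window) the group mean -- and hence
#' the delay -- is a lower bound, reported with `lower_bound = TRUE`
#' ("more than" semantics).
#'
#' @param treated,control per-tumor endpoint tables as produced by
#'   [growth_endpoints()] (columns `time_to_threshold`, `censored`).
#' @return list: `tgd_days`, `treated_mean`, `control_mean`,
#'   `lower_bound`, `n_treated`, `n_control`.
#' @export
tgd_v3 <- function(treated, control) {
  if (!nrow(treated) || !nrow(control)) {
    stopf("tgd_v3: both groups must be non-empty")
  }
  tm <- mean(treated$time_to_threshold)
  cm <- mean(control$time_to_threshold)
  list(tgd_days = tm - cm, treated_mean = tm, control_mean = cm,
       lower_bound = any(treated$censored),
       n_treated = nrow(treated), n_control = nrow(control))
}

#' Compare growth of two groups by linear and quadratic trends
#'
#' Classic two-stage trend analysis of growth curves: each tumor's log
#' relative volume is regressed on orthogonal linear and quadratic
#' polynomial contrasts of measurement day, giving one linear and one
#' quadratic trend score per animal; the groups are then compared by
#' two-sample Student t-tests on those scores. The quadratic-trend
#' comparison is the headline test (treatments bend the growth curve),
#' with animal-to-animal variation as the error term, which keeps the
#' test calibrated under per-tumor growth-rate heterogeneity.
#'
#' @param caliper_a,caliper_b caliper tables for the two groups, each
#'   with >= 2 tumors measured at >= 3 common days.
#' @param formula volume formula variant.
#' @return list with per-group trend-score means and, for `linear` and
#'   `quadratic`, the mean difference (a - b), t statistic and
#'   two-sided p-value.
#' @export
growth_trend_comparison <- function(caliper_a, caliper_b,
                                    formula = "length2width") {
  scores <- function(caliper) {
    rv <- relative_volume(caliper, formula)
    days <- sort(unique(rv$day))
    if (length(days) < 3L) stopf("growth_trend_comparison: need >= 3 days")
    sc <- lapply(split(rv, rv$tumor_id), function(d) {
      co <- stats::coef(stats::lm(log(rel_volume) ~ stats::poly(day, 2),
                                  data = d))
      data.frame(linear = co[2], quadratic = co[3])
    })
    do.call(rbind, c(sc, list(make.row.names = FALSE)))
  }
  sa <- scores(caliper_a); sb <- scores(caliper_b)
  if (nrow(sa) < 2L || nrow(sb) < 2L) {
    stopf("growth_trend_comparison: need >= 2 tumors per group")
  }
  cmp <- function(x, y) {
    tt <- group_ttest(x, y, paired = FALSE)
    list(difference = mean(x) - mean(y), t = tt$t, p = tt$p)
  }
  list(n_a = nrow(sa), n_b = nrow(sb),
       linear = cmp(sa$linear, sb$linear),
       quadratic = cmp(sa$quadratic, sb$quadratic))
}
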