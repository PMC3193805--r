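#' Relative change in percent
#'
#' @param pre,post endpoint values; `pre` must be non-zero.
#' @return `100 * (post - pre) / pre`, vectorized.
#' @export
relative_change <- function(pre, post) {
  if (any(pre == 0)) stopf("relative_change: pre must be non-zero")
  100 * (post - pre) / pre
}

#' Student's t-test between (or within) groups
#'
#' Two-sided Student t-test; the paired variant serves within-group
#' pre- versus post-treatment comparisons on the same tumors, the
#' unpaired pooled-variance variant serves between-group comparisons.
#' Degenerate input (essentially zero variance) yields `t = NaN`,
#' `p = NaN` and `degenerate = TRUE` with a warning instead of an
#' error, so cohort loops survive pathological cells.
#'
#' @param sample_a,sample_b numeric vectors, n >= 2 each (equal n when
#'   paired).
#' @param paired logical.
#' @return list: `t`, `p`, `df`, `degenerate`.
#' @export
group_ttest <- function(sample_a, sample_b, paired = FALSE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stopf("group_ttest: need >= 2 observations per sample")
  }
  if (paired && length(sample_a) != length(sample_b)) {
    stopf("group_ttest: paired samples must have equal length")
  }
  degenerate <- if (paired) {
    stats::sd(sample_a - sample_b) == 0
  } else {
    stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0
  }
  res <- if (degenerate) NULL else tryCatch(
    stats::t.test(sample_a, sample_b, paired = paired, var.equal = TRUE),
    error = function(e) NULL)
  if (is.null(res)) {
    warnf("group_ttest: degenerate (constant) data; returning NaN")
    df <- if (paired) length(sample_a) - 1L
          else length(sample_a) + length(sample_b) - 2L
    return(list(t = NaN, p = NaN, df = df, degenerate = TRUE))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), degenerate = FALSE)
}

#' Pearson correlation with two-sided significance test
#'
#' Product-moment correlation with the usual t-transform p-value.
#'
#' @param x,y numeric vectors, n >= 3 complete pairs, both with
#'   non-zero variance.
#' @return list: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("pearson: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("pearson: zero variance in input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Group summary of imaging, growth and hypoxia endpoints
#'
#' Aggregates a per-tumor endpoint table into per-group means and
#' standard errors. Group relative changes are computed two ways: the
#' mean of per-tumor relative changes (primary, columns `dA_pct` /
#' `dkel_pct`) and the relative change of the group means (exported as
#' `dA_of_means_pct` / `dkel_of_means_pct`).
#'
#' @param tumors data.frame with one row per tumor; recognized columns
#'   are `group`, `A_pre`, `A_post`, `kel_pre`, `kel_post`,
#'   `hypoxic_fraction_pct` and `dvol_pct` (missing ones are skipped).
#' @return data.frame, one row per group.
#' @export
summarize_cohort <- function(tumors) {
  stopifnot("group" %in% names(tumors))
  rows <- lapply(split(tumors, tumors$group), function(d) {
    out <- data.frame(group = d$group[1], n = nrow(d))
    put <- function(out, nm, x) {
      x <- x[!is.na(x)]
      out[[paste0(nm, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(nm, "_sem")]] <- if (length(x)) sem(x) else NA_real_
      out
    }
    if (all(c("A_pre", "A_post") %in% names(d))) {
      out <- put(out, "A_pre", d$A_pre)
      out <- put(out, "A_post", d$A_post)
      dA <- relative_change(d$A_pre, d$A_post)
      out <- put(out, "dA_pct", dA)
      out$dA_of_means_pct <- relative_change(mean(d$A_pre), mean(d$A_post))
    }
    if (all(c("kel_pre", "kel_post") %in% names(d))) {
      out <- put(out, "kel_pre", d$kel_pre)
      out <- put(out, "kel_post", d$kel_post)
      out <- put(out, "dkel_pct", relative_change(d$kel_pre, d$kel_post))
      out$dkel_of_means_pct <- relative_change(mean(d$kel_pre),
                                               mean(d$kel_post))
    }
    if ("hypoxic_fraction_pct" %in% names(d)) {
      out <- put(out, "hypoxic_fraction_pct", d$hypoxic_fraction_pct)
    }
    if ("dvol_pct" %in% names(d)) out <- put(out, "dvol_pct", d$dvol_pct)
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Cross-endpoint correlation table over group means
#'
#' Computes the five canonical pairings across group means: hypoxic
#' fraction against the relative changes in A, kel and tumor volume,
#' and the volume change against the changes in A and kel. A pairing
#' whose endpoint is missing for any group is skipped with a warning.
#'
#' @param summary group-level table from [summarize_cohort()]; the
#'   columns used are `hypoxic_fraction_pct_mean`, `dA_pct_mean`,
#'   `dkel_pct_mean`, `dvol_pct_mean`.
#' @return data.frame: `var_x`, `var_y`, `r`, `p`, `n`, `skipped`.
#' @export
build_correlation_table <- function(summary) {
  if (nrow(summary) < 3L) {
    stopf("build_correlation_table: need >= 3 groups")
  }
  pairings <- list(
    c("hypoxic_fraction_pct", "dA_pct"),
    c("hypoxic_fraction_pct", "dkel_pct"),
    c("hypoxic_fraction_pct", "dvol_pct"),
    c("dvol_pct", "dA_pct"),
    c("dvol_pct", "dkel_pct"))
  rows <- lapply(pairings, function(p) {
    cx <- paste0(p[1], "_mean"); cy <- paste0(p[2], "_mean")
    x <- if (cx %in% names(summary)) summary[[cx]] else
      rep(NA_real_, nrow(summary))
    y <- if (cy %in% names(summary)) summary[[cy]] else
      rep(NA_real_, nrow(summary))
    if (anyNA(x) || anyNA(y)) {
      warnf("correlation %s vs %s skipped: missing group endpoint",
            p[1], p[2])
      return(data.frame(var_x = p[1], var_y = p[2], r = NA_real_,
                        p = NA_real_, n = sum(stats::complete.cases(x, y)),
                        skipped = TRUE))
    }
    pr <- pearson(x, y)
    data.frame(var_x = p[1], var_y = p[2], r = pr$r, p = pr$p, n = pr$n,
               skipped = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
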