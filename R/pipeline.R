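#' Run the full cohort analysis pipeline
#'
#' End-to-end workflow on a simulated cohort: for every tumor, generate
#' ground-truth parameter maps for the pre- and post-treatment
#' sessions, forward-simulate the dynamic acquisitions, fit the Brix
#' model voxel-wise and summarize the ROI; simulate the caliper growth
#' records and derive volumes, growth-delay endpoints and trend
#' comparisons; couple per-tumor hypoxic fractions to the amplitude
#' change; and aggregate everything into group summaries, t-tests and
#' the cross-endpoint correlation table. Deterministic given the
#' configuration: one master seed fans out to per-tumor, per-session
#' and per-stage child seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, endpoint tables are
#'   written as CSV and the report (including the run log) as JSON.
#' @param progress print per-stage progress messages.
#' @return a `pipeline_report` list: `tumors` (per-tumor endpoints),
#'   `caliper`, `summary` (per group), `growth_endpoints`, `tgd`,
#'   `trend_comparisons`, `ttests`, `correlations`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  design <- config$design
  seed <- config$seed
  say <- function(...) if (progress) message(sprintf(...))

  # -- stage 1: simulate acquisitions and fit voxel-wise --------------
  say("stage simulate+fit: %d groups", length(design$groups))
  rows <- list(); excl_total <- 0L
  for (gi in seq_along(design$groups)) {
    grp <- design$groups[[gi]]
    for (ti in seq_len(grp$n_tumors)) {
      per_session <- lapply(c(pre = "pre", post = "post"), function(ss) {
        truth <- generate_parameter_maps(design, gi, ti, ss)
        series <- simulate_dce(truth, design,
                               seed = derive_seed(seed, gi, ti, ss))
        map <- tryCatch(fit_roi(series, options = config$fitting),
                        error = function(e) {
                          stopf("stage fit failed for %s tumor %d (%s): %s",
                                grp$name, ti, ss, conditionMessage(e))
                        })
        list(truth = truth, map = map, summary = summarize_roi(map))
      })
      excl_total <- excl_total + sum(per_session$pre$map$excluded) +
        sum(per_session$post$map$excluded)
      roi <- per_session$pre$truth$roi
      truth_dA <- mean(per_session$post$truth$A[roi]) /
        mean(per_session$pre$truth$A[roi]) - 1
      hf <- simulate_hypoxic_fraction(truth_dA, design,
                                      derive_seed(seed, gi, ti, "hypoxia"))
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = sprintf("%s_%02d",
                           gsub("[^A-Za-z0-9]+", "_", grp$name), ti),
        group = grp$name,
        A_pre = per_session$pre$summary$A_mean,
        A_post = per_session$post$summary$A_mean,
        kel_pre = per_session$pre$summary$kel_mean,
        kel_post = per_session$post$summary$kel_mean,
        kep_pre = per_session$pre$summary$kep_mean,
        kep_post = per_session$post$summary$kep_mean,
        kep_reliable = per_session$pre$summary$kep_reliable &
          per_session$post$summary$kep_reliable,
        n_voxels = per_session$pre$summary$n_voxels,
        n_excluded = per_session$pre$summary$n_excluded +
          per_session$post$summary$n_excluded,
        hypoxic_fraction_pct = 100 * hf)
    }
  }
  tumors <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # -- stage 2: growth ------------------------------------------------
  say("stage growth")
  caliper <- simulate_growth(design, seed = derive_seed(seed, "growth"))
  gopt <- config$growth_opts
  rv <- relative_volume(caliper, gopt$volume_formula)
  endpoints <- growth_endpoints(caliper, threshold = gopt$threshold,
                                formula = gopt$volume_formula)
  # volume change to the measurement day nearest the post-treatment scan
  dday <- unique(rv$day)[which.min(abs(unique(rv$day) - 8))]
  dvol <- rv[rv$day == dday, c("tumor_id", "rel_volume")]
  tumors$dvol_pct <- 100 * (dvol$rel_volume[match(tumors$tumor_id,
                                                  dvol$tumor_id)] - 1)

  ctrl <- gopt$control_group
  grps <- vapply(design$groups, `[[`, "", "name")
  tgd <- list(); trend <- list()
  for (g in setdiff(grps, ctrl)) {
    tgd[[g]] <- tgd_v3(endpoints[endpoints$group == g, ],
                       endpoints[endpoints$group == ctrl, ])
    trend[[g]] <- growth_trend_comparison(
      caliper[caliper$group == g, ], caliper[caliper$group == ctrl, ],
      formula = gopt$volume_formula)
  }

  # -- stage 3: statistics -------------------------------------------
  say("stage stats")
  summary <- summarize_cohort(tumors)
  ttests <- list(within = list(), between = list())
  for (g in grps) {
    d <- tumors[tumors$group == g, ]
    ttests$within[[g]] <- list(
      A = group_ttest(d$A_post, d$A_pre, paired = config$stats_opts$paired),
      kel = group_ttest(d$kel_post, d$kel_pre,
                        paired = config$stats_opts$paired))
  }
  dctrl <- tumors[tumors$group == ctrl, ]
  for (g in setdiff(grps, ctrl)) {
    d <- tumors[tumors$group == g, ]
    ttests$between[[g]] <- list(
      dA = group_ttest(relative_change(d$A_pre, d$A_post),
                       relative_change(dctrl$A_pre, dctrl$A_post)),
      dkel = group_ttest(relative_change(d$kel_pre, d$kel_post),
                         relative_change(dctrl$kel_pre, dctrl$kel_post)))
  }
  if (config$stats_opts$p_adjust == "holm") {
    ps <- unlist(lapply(ttests$between, function(x) c(x$dA$p, x$dkel$p)))
    adj <- stats::p.adjust(ps, "holm")
    k <- 0L
    for (g in names(ttests$between)) {
      ttests$between[[g]]$dA$p_adj <- adj[k + 1L]
      ttests$between[[g]]$dkel$p_adj <- adj[k + 2L]
      k <- k + 2L
    }
  }
  correlations <- build_correlation_table(summary)

  report <- list(
    tumors = tumors, caliper = caliper, summary = summary,
    growth_endpoints = endpoints, tgd = tgd, trend_comparisons = trend,
    ttests = ttests, correlations = correlations,
    log = list(
      package_version = as.character(utils::packageVersion("brixflow")),
      seed = seed,
      n_groups = length(grps), n_tumors = nrow(tumors),
      voxels_excluded = excl_total,
      r2_min = config$fitting$r2_min,
      kep_qc_threshold = config$fitting$kep_qc_threshold,
      volume_formula = gopt$volume_formula,
      growth_threshold = gopt$threshold,
      paired_within_group_tests = config$stats_opts$paired,
      p_adjust = config$stats_opts$p_adjust))
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tumors, file.path(out_dir, "tumors.csv"),
                     row.names = FALSE)
    write_caliper_csv(caliper, file.path(out_dir, "caliper.csv"))
    utils::write.csv(summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(endpoints, file.path(out_dir, "growth_endpoints.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(tgd = tgd, trend_comparisons = trend, ttests = ttests,
           log = report$log),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d tumors in %d groups (seed %d)\n",
              x$log$n_tumors, x$log$n_groups, x$log$seed))
  cat("group summary (relative changes, %):\n")
  cols <- intersect(c("group", "n", "dA_pct_mean", "dkel_pct_mean",
                      "hypoxic_fraction_pct_mean", "dvol_pct_mean"),
                    names(x$summary))
  print(x$summary[, cols], digits = 3, row.names = FALSE)
  cat("growth delay vs control (days):\n")
  for (g in names(x$tgd)) {
    t <- x$tgd[[g]]
    cat(sprintf("  %-20s %s%.1f\n", g, if (t$lower_bound) ">" else "",
                t$tgd_days))
  }
  invisible(x)
}
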