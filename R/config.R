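#' Assemble and validate a pipeline configuration
#'
#' A `pipeline_config` bundles every knob of the end-to-end workflow:
#' the cohort design (groups, acquisition, noise, growth, coupling),
#' the voxel-fitting options, the growth-endpoint options and the
#' statistics options, plus the master seed. All components round-trip
#' losslessly through YAML or JSON.
#'
#' @param design a [cohort_design] or a plain list of overrides for one.
#' @param fitting overrides for [fit_options()].
#' @param growth_opts list: `threshold` (fold increase, default 3),
#'   `volume_formula` (`"length2width"` or `"width2length"`),
#'   `control_group` (name used as the delay reference).
#' @param stats_opts list: `paired` (within-group pre/post tests paired
#'   on tumor identity, default TRUE), `p_adjust` (`"none"` default, or
#'   `"holm"`).
#' @param seed master seed; overrides the design seed.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(design = list(), fitting = list(),
                            growth_opts = list(), stats_opts = list(),
                            seed = 1L) {
  if (!inherits(design, "cohort_design")) {
    design <- do.call(cohort_design, design)
  }
  design$seed <- as.integer(seed)
  cfg <- list(
    design = design,
    fitting = do.call(fit_options, fitting),
    growth_opts = utils::modifyList(list(
      threshold = 3, volume_formula = "length2width",
      control_group = design$groups[[1]]$name), growth_opts),
    stats_opts = utils::modifyList(list(paired = TRUE, p_adjust = "none"),
                                   stats_opts),
    seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  validate_design(cfg$design)
  f <- cfg$fitting
  if (f$r2_min < 0 || f$r2_min > 1) {
    stopf("config error at fitting.r2_min: must be in [0, 1]")
  }
  if (f$kep_qc_threshold < 0 || f$kep_qc_threshold > 1) {
    stopf("config error at fitting.kep_qc_threshold: must be in [0, 1]")
  }
  if (any(f$upper <= f$lower)) {
    stopf("config error at fitting.upper: bounds must exceed lower bounds")
  }
  g <- cfg$growth_opts
  if (g$threshold <= 1) {
    stopf("config error at growth_opts.threshold: must be > 1")
  }
  if (!g$volume_formula %in% c("length2width", "width2length")) {
    stopf("config error at growth_opts.volume_formula: unknown variant '%s'",
          g$volume_formula)
  }
  if (!cfg$stats_opts$p_adjust %in% c("none", "holm")) {
    stopf("config error at stats_opts.p_adjust: must be 'none' or 'holm'")
  }
  invisible(cfg)
}

config_allowed_keys <- list(
  top = c("design", "fitting", "growth_opts", "stats_opts", "seed"),
  design = c("groups", "acquisition", "noise_sd", "roi", "fields",
             "growth", "hypoxia_coupling", "seed"),
  fitting = c("lower", "upper", "starts", "ftol", "maxit", "r2_min",
              "kep_qc_threshold", "bound_tol"),
  growth_opts = c("threshold", "volume_formula", "control_group"),
  stats_opts = c("paired", "p_adjust"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stopf("config error at %s: unknown key(s) %s", where,
          paste0(where, ".", bad, collapse = ", "))
  }
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing fields fall back to package defaults; unknown keys are
#' rejected with the offending field path. An empty file yields the
#' full default configuration.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("load_config: file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  check_keys(raw, config_allowed_keys$top, "config")
  for (sec in c("design", "fitting", "growth_opts", "stats_opts")) {
    if (!is.null(raw[[sec]])) {
      check_keys(raw[[sec]], config_allowed_keys[[sec]], sec)
    }
  }
  design <- raw$design %||% list()
  if (!is.null(design$groups)) {
    design$groups <- lapply(design$groups, function(g) do.call(cohort_group, g))
  }
  # YAML parses vectors as lists; flatten the numeric-vector leaves
  for (nm in c("roi", "growth", "acquisition", "hypoxia_coupling")) {
    if (!is.null(design[[nm]])) design[[nm]] <- lapply(design[[nm]], unlist)
  }
  fitting <- raw$fitting %||% list()
  for (nm in c("lower", "upper")) {
    if (!is.null(fitting[[nm]])) fitting[[nm]] <- unlist(fitting[[nm]])
  }
  if (!is.null(fitting$starts)) fitting$starts <- lapply(fitting$starts, unlist)
  pipeline_config(design = design,
                  fitting = fitting,
                  growth_opts = raw$growth_opts %||% list(),
                  stats_opts = raw$stats_opts %||% list(),
                  seed = raw$seed %||% design$seed %||% 1L)
}

#' Save a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output `.yaml` path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  d <- cfg$design
  raw <- list(
    design = list(
      groups = lapply(d$groups, function(g) unclass(g)),
      acquisition = d$acquisition, noise_sd = d$noise_sd, roi = d$roi,
      fields = d$fields, growth = d$growth,
      hypoxia_coupling = d$hypoxia_coupling, seed = d$seed),
    fitting = lapply(cfg$fitting, function(x)
      if (is.list(x)) lapply(x, as.numeric) else x),
    growth_opts = cfg$growth_opts,
    stats_opts = cfg$stats_opts,
    seed = cfg$seed)
  yaml::write_yaml(raw, path)
  invisible(path)
}
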