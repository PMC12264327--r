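settings_columns <- function() {
  c("observer", "lighting", "outline", "skylight", "field", "repeat",
    "mb_l", "mb_s", "lum_cdm2")
}

ci_columns <- function() {
  c("observer", "lighting", "outline", "skylight", "ci", "a", "b",
    "theta_rad", "n_repeats", "se")
}

# Validate a settings data.frame; reports offending row numbers.
check_settings_df <- function(settings) {
  miss <- setdiff(settings_columns(), names(settings))
  if (length(miss) > 0) {
    stop("settings table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(settings$mb_l) | !is.finite(settings$mb_s) |
                 !is.finite(settings$lum_cdm2) | settings$lum_cdm2 <= 0)
  if (length(bad) > 0) {
    stop("invalid settings rows (non-finite chromaticity or non-positive ",
         "luminance) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(settings)
}

#' Read and write observer-settings tables
#'
#' CSV layout `observer,lighting,outline,skylight,field,repeat,mb_l,mb_s,
#' lum_cdm2`. The reader validates the schema and the numeric columns,
#' reporting offending row numbers; reading a file with a different layout
#' (e.g. a constancy-index table) errors.
#'
#' @param settings settings data.frame.
#' @param path CSV file path.
#' @return `read_settings_csv()` returns the validated data.frame;
#'   `write_settings_csv()` returns `path` invisibly.
#' @export
write_settings_csv <- function(settings, path) {
  check_settings_df(settings)
  utils::write.csv(settings[settings_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_settings_csv
#' @export
read_settings_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_settings_df(d)
}

#' Read and write constancy-index tables
#'
#' CSV layout `observer,lighting,outline,skylight,ci,a,b,theta_rad,
#' n_repeats,se` (the output of [ci_table()]).
#'
#' @param ci CI data.frame.
#' @param path CSV file path.
#' @return `read_ci_csv()` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_ci_csv <- function(ci, path) {
  miss <- setdiff(ci_columns(), names(ci))
  if (length(miss) > 0) {
    stop("CI table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(ci[ci_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ci_csv
#' @export
read_ci_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(ci_columns(), names(d))
  if (length(miss) > 0) {
    stop("not a CI table: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Experiment configuration round-trip
#'
#' Configs (preset lists, possibly edited) serialize to YAML and read back
#' losslessly. A config without a `seed` fails validation: every stochastic
#' run must be seeded.
#'
#' @param config a config list, e.g. from [scenario_preset()].
#' @param path YAML file path.
#' @return `read_config_yaml()` returns the validated config list;
#'   `write_config_yaml()` returns `path` invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  config <- yaml::read_yaml(path)
  validate_config(config)
}

validate_config <- function(config) {
  need <- c("observers", "lightings", "outlines", "skylights", "fields",
            "n_repeats", "seed")
  miss <- need[!vapply(need, function(k) !is.null(config[[k]]), logical(1))]
  if (length(miss) > 0) {
    stop("config schema error: missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  config
}

#' Provenance record for a simulation run
#'
#' Captures what determined the outputs: a hash of the config, the seed, the
#' provenance tags and normalization constants of the colorimetric tables,
#' and the package version and fixed tolerances in effect.
#'
#' @param config the run config.
#' @param fund,convention,cmf tables used.
#' @return A named list (serialize with [jsonlite::write_json()]).
#' @export
run_provenance <- function(config, fund = default_fundamentals(),
                           convention = default_mb_convention(),
                           cmf = default_cmf()) {
  list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    preset = config$preset %||% "custom",
    fundamentals = fund$provenance,
    cmf = cmf$provenance,
    mb_convention = list(k_L = convention$k_L, k_M = convention$k_M,
                         k_S = convention$k_S),
    tolerances = list(illuminant_xy = 0.005, illuminant_lum_rel = 0.02),
    package_version = as.character(utils::packageVersion("shadowconstancy"))
  )
}

#' Simulate an experiment and write its outputs
#'
#' Runs [simulate_experiment()] and writes `settings.csv` and
#' `provenance.json` under `out_dir`. Identical config and seed reproduce
#' the files byte for byte.
#'
#' @param config config list with a `seed`.
#' @param out_dir output directory (created if needed).
#' @param scene illuminant list.
#' @return Invisibly, the paths written.
#' @export
simulate_to_csv <- function(config, out_dir, scene = scene_illuminants()) {
  validate_config(config)
  run <- simulate_experiment(config, scene = scene)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "settings.csv")
  p2 <- file.path(out_dir, "provenance.json")
  write_settings_csv(run$settings, p1)
  jsonlite::write_json(run_provenance(config), p2, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(settings = p1, provenance = p2))
}

#' Analyze a settings table end to end
#'
#' The analysis pipeline over a settings table (or CSV path): axis scaling,
#' constancy-index table, block means, and the block-level statistical
#' comparison appropriate to the design - a paired two-tailed t test on
#' per-observer mean CIs when the design has two lighting blocks, and a
#' two-way repeated-measures ANOVA (skylight x outline) when it has two
#' outline blocks.
#'
#' @param settings settings data.frame or CSV path.
#' @param illuminants named illuminant list.
#' @param scaling_scope `"per_observer"` or `"pooled"`.
#' @param field test field to analyze.
#' @param axis_scale optional explicit scale passed to [ci_table()] (e.g.
#'   `c(1, 1)` for unscaled MB space, required for noise-free settings whose
#'   white-condition SD is zero).
#' @return list with `ci` (the CI table), `block_means` (per observer x
#'   block means over skylights), `summary` (per block grand means), and
#'   `stats` (named list of test results; may be empty for degenerate
#'   designs).
#' @export
analyze_settings <- function(settings, illuminants = scene_illuminants(),
                             scaling_scope = c("per_observer", "pooled"),
                             field = "right", axis_scale = NULL) {
  scaling_scope <- match.arg(scaling_scope)
  if (is.character(settings) && length(settings) == 1L) {
    settings <- read_settings_csv(settings)
  }
  ci <- ci_table(settings, illuminants, scaling_scope, field,
                 axis_scale = axis_scale)

  block_means <- stats::aggregate(
    ci ~ observer + lighting + outline, data = ci, FUN = mean
  )
  summary_tab <- stats::aggregate(
    ci ~ lighting + outline, data = block_means, FUN = mean
  )
  names(summary_tab)[names(summary_tab) == "ci"] <- "mean_ci"

  tests <- list()
  lightings <- sort(unique(ci$lighting))
  if (length(lightings) == 2 && length(unique(ci$observer)) >= 2) {
    w <- stats::reshape(
      block_means[block_means$outline == block_means$outline[1], ],
      idvar = "observer", timevar = "lighting", direction = "wide",
      drop = "outline"
    )
    a <- w[[paste0("ci.", lightings[1])]]
    b <- w[[paste0("ci.", lightings[2])]]
    if (!anyNA(a) && !anyNA(b)) {
      tests$paired_t_lighting <- c(
        list(comparison = paste(lightings, collapse = " vs ")),
        paired_t_two_tailed(a, b)
      )
    }
  }
  outlines <- setdiff(unique(ci$outline), "none")
  if (length(outlines) == 2 && length(unique(ci$observer)) >= 2) {
    sub <- ci[ci$outline %in% outlines & ci$lighting == ci$lighting[1], ]
    tests$rm_anova_skylight_outline <- rm_anova_two_way(
      sub, value = "ci", subject = "observer",
      factor_a = "skylight", factor_b = "outline"
    )
  }
  list(ci = ci, block_means = block_means, summary = summary_tab,
       stats = tests)
}

#' Bar-chart report of a constancy-index table
#'
#' Per-observer CI bars by skylight color, faceted by block, with error
#' bars (plus/minus one SE) where available, a solid reference line at
#' perfect constancy (CI = 1), and a dashed line at the across-skylight
#' mean. Pure rendering: no quantity is recomputed beyond the plotted
#' means.
#'
#' @param ci CI table from [ci_table()].
#' @return A ggplot object.
#' @export
ci_plot <- function(ci) {
  if (nrow(ci) == 0) stop("empty CI table", call. = FALSE)
  ci$block <- paste(ci$lighting, ci$outline, sep = " / ")
  means <- stats::aggregate(ci ~ observer + block, data = ci, FUN = mean)
  names(means)[names(means) == "ci"] <- "mean_ci"
  pal <- c(sky_white = "grey70", sky_yellow = "#E6B800", sky_blue = "#3366CC",
           sky_magenta = "#CC3399", sky_green = "#339933")
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$skylight, y = .data$ci,
                                   fill = .data$skylight)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci - .data$se, ymax = .data$ci + .data$se),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "solid", color = "blue3") +
    ggplot2::geom_hline(
      data = means, ggplot2::aes(yintercept = .data$mean_ci),
      linetype = "dashed", color = "red3"
    ) +
    ggplot2::scale_fill_manual(values = pal, guide = "none") +
    ggplot2::facet_grid(block ~ observer) +
    ggplot2::labs(x = "skylight", y = "constancy index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
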