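#' Default run configuration for the end-to-end pipeline
#'
#' A fully serializable description of one pipeline run: one morphology
#' preset per stromal class, per-class persistent-random-walk parameters
#' (contact guidance increasing with class alignment), and analysis
#' settings. A run is reproducible from the configuration plus its seed
#' alone.
#'
#' @param seed Integer master seed.
#' @param classes Character vector of morphology classes to run.
#' @param n_cells,n_frames,dt_min Trajectory settings per class.
#' @param guidance Named numeric of guidance strengths per class.
#' @param n_bins Orientation histogram bins.
#' @param max_lag_fraction MSD lag cutoff.
#' @param out_dir Output directory (`NULL` = return results only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       classes = c("normal", "benign", "high_risk", "high_grade"),
                       n_cells = 60L, n_frames = 145L, dt_min = 30,
                       guidance = c(normal = 0, benign = 0.05,
                                    high_risk = 0.15, high_grade = 0.25),
                       n_bins = 36L, max_lag_fraction = 1 / 3,
                       out_dir = NULL) {
  structure(list(
    seed = as.integer(seed), classes = classes,
    n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
    dt_min = dt_min, guidance = guidance, n_bins = as.integer(n_bins),
    max_lag_fraction = max_lag_fraction, out_dir = out_dir
  ), class = "run_config")
}

#' Run the image-to-analysis pipeline for each stromal class
#'
#' For every configured morphology class: generates a seeded fiber phantom,
#' discretizes it into a blueprint and scan plan, simulates a fabricated
#' readout and scores its fidelity, simulates cell trajectories on the
#' scaffold (with class-dependent contact guidance), fits the
#' persistent-random-walk motility model, and computes orientation and
#' alignment summaries. Results are returned as tibbles and, when
#' `config$out_dir` is set, written as a machine-readable JSON report plus
#' a plain-text summary.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report`: `metrics` (one-row-per-class
#'   tibble), `per_class` (detailed objects), `config`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(seed = 1, classes = "normal",
#'                                n_cells = 10, n_frames = 30))
#' rep$metrics
#' }
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  per_class <- list()
  rows <- list()
  for (i in seq_along(config$classes)) {
    cl <- config$classes[i]
    # per-class sub-seeds derived deterministically from the master seed
    sd <- (config$seed * 1000L + i * 7L) %% .Machine$integer.max
    ph <- generate_fiber_image(morphology_params(cl), seed = sd)
    bp <- discretize_fibers(ph$image)
    sp <- build_scan_plan(bp)
    fab <- simulate_fabrication(bp, seed = sd + 1L)
    fid <- fidelity_score(bp, fab)

    of <- orientation_field(ph$image, sigma_um = 2)
    dist <- angular_distribution(of, n_bins = config$n_bins,
                                 mask = bp$mask, weight = "coherence")
    ai <- alignment_index(dist)
    axis_deg <- mean_direction(ph$fibers$orientation_deg)

    g <- unname(config$guidance[cl])
    if (is.na(g)) g <- 0
    pp <- prw_params(n_cells = config$n_cells, n_frames = config$n_frames,
                     dt_min = config$dt_min, guidance_strength = g)
    tracks <- generate_trajectories(pp, seed = sd + 2L,
                                    orientation_field = if (g > 0) of else NULL)
    speeds <- instantaneous_speeds(tracks)
    fit <- fit_motility(tracks, mode = "ensemble",
                        max_lag_fraction = config$max_lag_fraction)

    per_class[[cl]] <- list(phantom = ph, blueprint = bp, scan_plan = sp,
                            fidelity = fid, orientation = dist, fit = fit)
    rows[[cl]] <- tibble::tibble(
      class = cl,
      fiber_coverage = mean(bp$mask),
      fidelity_pct = fid$fidelity_pct,
      alignment_index = ai,
      mean_fiber_axis_deg = axis_deg,
      mean_speed_um_per_min = mean(speeds$speed_um_per_min),
      mu_um2_per_min = fit$mu_um2_per_min,
      P_min = fit$P_min
    )
  }
  metrics <- dplyr::bind_rows(rows)
  report <- structure(list(metrics = metrics, per_class = per_class,
                           config = config), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", nrow(x$metrics), "class(es), seed",
      x$config$seed, "\n")
  print(x$metrics)
  invisible(x)
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  cfg$out_dir <- NULL
  payload <- list(
    config = unclass(cfg),
    metrics = report$metrics
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("pipeline run, seed %d, %d class(es)", cfg$seed,
            nrow(report$metrics)),
    utils::capture.output(as.data.frame(report$metrics))
  ), con)
  invisible(file.path(out_dir, "report.json"))
}

#' Group comparison: one-way ANOVA followed by pairwise t-tests
#'
#' Omnibus one-way ANOVA across conditions followed by all pairwise
#' two-sample t-tests (Welch by default, since equal variances are rarely
#' defensible for cell-level metrics), with significance stars at
#' `p < alpha`. No multiplicity correction is applied by default, mirroring
#' common practice in the source field; Holm correction is available and
#' recommended for confirmatory use.
#'
#' @param data Data frame with one row per observation.
#' @param value Name of the numeric metric column.
#' @param group Name of the condition column.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return An object of class `group_comparison`: list with `metric`,
#'   `anova_p`, `pairwise` (tibble: `group_a`, `group_b`, `t_p`,
#'   `p_adjusted`, `significant`), `alpha`, `welch`.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 10),
#'                 v = c(rnorm(10), rnorm(10, 2)))
#' compare_groups(d, "v", "g")
compare_groups <- function(data, value, group, alpha = 0.05,
                           var_equal = FALSE, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 3)) stop("every group needs at least 3 values", call. = FALSE)
  anova_p <- summary(stats::aov(v ~ g))[[1]][["Pr(>F)"]][1]

  combos <- utils::combn(levels(g), 2)
  pw <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    tt <- stats::t.test(v[g == a], v[g == b], var.equal = var_equal)
    tibble::tibble(group_a = a, group_b = b, t_p = tt$p.value)
  })
  pw$p_adjusted <- stats::p.adjust(pw$t_p, method = p_adjust)
  pw$significant <- pw$p_adjusted < alpha
  structure(list(metric = value, anova_p = anova_p, pairwise = pw,
                 alpha = alpha, welch = !var_equal,
                 groups = split(v, g)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s': ANOVA p = %.4g (%s t-tests, alpha = %g)\n",
              x$metric, x$anova_p, if (x$welch) "Welch" else "pooled", x$alpha))
  pw <- x$pairwise
  for (j in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: p = %.4g%s\n", pw$group_a[j], pw$group_b[j],
                pw$p_adjusted[j], if (pw$significant[j]) " *" else ""))
  }
  invisible(x)
}
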