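#' Recover IST indices from a cohort's breath traces
#'
#' Runs sinusoid fitting and one-compartment inversion on every trace,
#' then forms the two-period ratio indices per (animal, step, repeat).
#' Deadspace is taken from the generator's protocol (known input).
#'
#' @param ist IST measurement tibble from [generate_ist_measurements()]
#'   (columns `animal`, `step`, `peep`, `limb`, `repeat_idx`, `period_T`,
#'   `vt_ml`, `vd_ml`, `rr`, `trace`).
#' @param lambda_b Blood--gas partition coefficient.
#' @return A tibble with one row per (animal, step, repeat): identifiers,
#'   recovered `elv_180`, `qp_180`, `elv_60`, `qp_60`, and ratio indices
#'   `h_ratio_v`, `h_ratio_p`.
#' @export
recover_ist_indices <- function(ist, lambda_b = 0.47) {
  res <- ist
  rec <- purrr::pmap_dfr(
    list(res$trace, res$vt_ml, res$vd_ml, res$rr, res$period_T),
    function(tr, vt, vd, rr, T) {
      r <- analyze_ist_trace(tr, VT = vt, V_D = vd, RR = rr, period_T = T,
                             lambda_b = lambda_b)
      tibble(ELV = r$ELV, Qp = r$Qp)
    })
  res$ELV <- rec$ELV
  res$Qp <- rec$Qp
  res %>%
    select(-"trace") %>%
    tidyr::pivot_wider(names_from = "period_T", values_from = c("ELV", "Qp"),
                       names_glue = "{tolower(.value)}_{period_T}") %>%
    mutate(
      h_ratio_v = .data$elv_180 / .data$elv_60,
      h_ratio_p = .data$qp_60 / .data$qp_180
    )
}

#' Estimate LogSD heterogeneity for each (animal, PEEP step)
#'
#' Averages the recovered measurement vectors over repeats at each step
#' (the repeat-averaging convention used throughout the comparison
#' statistics) and fits the simulation-based log-normal spreads, using the
#' 180 s recoveries as reference totals.
#'
#' @param indices Output of [recover_ist_indices()].
#' @param spec The cohort's [protocol_spec()] (forcing and simulator
#'   settings).
#' @param grid_n,bounds Passed to [estimate_logsd()].
#' @return A tibble keyed by (animal, step) with `log_sd_v`, `log_sd_p`,
#'   `loss`, `converged`.
#' @export
estimate_cohort_logsd <- function(indices, spec, grid_n = 13,
                                  bounds = c(0, 3)) {
  by_step <- indices %>%
    group_by(.data$animal, .data$step, .data$peep, .data$limb) %>%
    summarise(across(c("elv_180", "qp_180", "elv_60", "qp_60", "vt_ml",
                       "vd_ml", "rr"), mean), .groups = "drop")
  est <- purrr::pmap_dfr(
    list(by_step$elv_180, by_step$qp_180, by_step$elv_60, by_step$qp_60,
         by_step$vt_ml, by_step$vd_ml, by_step$rr),
    function(e180, q180, e60, q60, vt, vd, rr) {
      ref <- ist_reference(e180, q180, vd, VT = vt, RR = rr,
                           lambda_b = spec$lambda_b, F0 = spec$F0,
                           A = spec$A, n_compartments = spec$n_compartments)
      fit <- estimate_logsd(c(e180, q180, e60, q60), ref,
                            bounds = bounds, grid_n = grid_n)
      tibble(log_sd_v = fit$log_sd_v, log_sd_p = fit$log_sd_p,
             loss = fit$loss, converged = fit$converged)
    })
  bind_rows(dplyr::bind_cols(
    by_step[, c("animal", "step", "peep", "limb")], est))
}

#' Quantitative CT indices for each cohort volume
#'
#' @param ct CT tibble from [simulate_cohort()] (list-column `volume`).
#' @param r1,r2,threshold Ring radii (mm) and pathologic threshold.
#' @return The input tibble with `volume` replaced by `h_ct`, `a_n`, `o_n`.
#' @export
compute_ct_indices <- function(ct, r1 = 2.41, r2 = 3.675, threshold = 1.61) {
  res <- purrr::map_dfr(ct$volume, function(v) {
    map <- cressoni_index(v, r1 = r1, r2 = r2)
    ratios <- aeration_ratios(classify_aeration(v))
    tibble(h_ct = h_ct(map, threshold), a_n = ratios$a_n, o_n = ratios$o_n)
  })
  dplyr::bind_cols(select(ct, -"volume", -dplyr::any_of("ct_heterogeneity_param")),
                   res)
}

#' Assemble the long-format cohort table
#'
#' Joins per-repeat IST indices with per-repeat CT indices and the
#' step-level LogSD estimates into the long cohort table used by the
#' comparison statistics, adding the deadspace ratios `vd_over_elv`
#' (deadspace over 180 s effective lung volume) and `vd_over_vt`.
#'
#' @param indices [recover_ist_indices()] output.
#' @param ct_indices [compute_ct_indices()] output, or `NULL`.
#' @param logsd [estimate_cohort_logsd()] output, or `NULL`.
#' @return A tibble with one row per (animal, step, repeat).
#' @export
assemble_cohort_table <- function(indices, ct_indices = NULL, logsd = NULL) {
  out <- indices %>%
    mutate(vd_over_elv = .data$vd_ml / .data$elv_180,
           vd_over_vt = .data$vd_ml / .data$vt_ml)
  if (!is.null(ct_indices)) {
    out <- left_join(out, ct_indices,
                     by = c("animal", "step", "peep", "limb", "repeat_idx"))
  }
  if (!is.null(logsd)) {
    out <- left_join(out, select(logsd, -"loss", -"converged"),
                     by = c("animal", "step", "peep", "limb"))
  }
  out
}

#' Average a cohort table over repeats
#'
#' @param cohort Per-repeat cohort table.
#' @return Per-(animal, step) tibble of repeat-averaged indices.
#' @export
average_repeats <- function(cohort) {
  cohort %>%
    group_by(.data$animal, .data$step, .data$peep, .data$limb) %>%
    summarise(across(dplyr::where(is.numeric) & !dplyr::any_of("repeat_idx"),
                     mean), .groups = "drop")
}

#' Modality-comparison statistics for a cohort table
#'
#' The full statistical comparison between CT and IST heterogeneity:
#' Pearson correlation matrix over the heterogeneity indices, per-animal
#' and pooled regressions of each IST index on `h_ct`, and four-quadrant
#' trend concordance of consecutive-PEEP-step changes. Expects a
#' per-(animal, step) table (see [average_repeats()]).
#'
#' @param by_step Per-step cohort tibble; must contain both modalities.
#' @param ist_indices IST index columns to compare against `h_ct`.
#' @param exclusion_frac Four-quadrant exclusion-zone fraction.
#' @return A list of class `cohort_comparison`: `correlation`
#'   (pearson_matrix), `regressions` (named list of tibbles), `quadrants`
#'   (named list of quadrant_analysis).
#' @export
compare_cohort <- function(by_step,
                           ist_indices = c("h_ratio_v", "h_ratio_p",
                                           "log_sd_v", "log_sd_p"),
                           exclusion_frac = 0.15) {
  if (!"h_ct" %in% names(by_step)) {
    abort("missing modality: cohort table has no CT indices (`h_ct`).")
  }
  ist_indices <- intersect(ist_indices, names(by_step))
  if (length(ist_indices) == 0) {
    abort("missing modality: cohort table has no IST heterogeneity indices.")
  }
  vars <- c("h_ct", intersect(c("a_n", "o_n"), names(by_step)), ist_indices)
  correlation <- pearson_matrix(by_step, vars)
  regressions <- purrr::map(
    setNames(ist_indices, ist_indices),
    ~ per_animal_regression(by_step, x = "h_ct", y = .x))
  quadrants <- purrr::map(
    setNames(ist_indices, ist_indices),
    ~ four_quadrant(delta_pairs(by_step, x = "h_ct", y = .x),
                    exclusion_frac = exclusion_frac))
  structure(
    list(correlation = correlation, regressions = regressions,
         quadrants = quadrants),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  print(x$correlation)
  for (nm in names(x$quadrants)) {
    cat(sprintf("  dH_CT vs d%-10s concordance %5.1f%%\n",
                nm, x$quadrants[[nm]]$concordance))
  }
  invisible(x)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a synthetic cohort, recovers IST parameters at both forcing
#' periods, computes the ratio and (optionally) simulation-fitted LogSD
#' heterogeneity indices, analyses the CT volumes, assembles the cohort
#' table and runs the modality comparison. Everything is deterministic
#' given the protocol seed. When `outdir` is given, the stage outputs are
#' written as CSV (and the configuration as YAML) together with an MD5
#' manifest.
#'
#' @param spec A [protocol_spec()].
#' @param do_ct,do_logsd Toggle the CT and LogSD stages.
#' @param grid_n LogSD grid resolution.
#' @param r1,r2,threshold CT analysis settings.
#' @param exclusion_frac Four-quadrant exclusion fraction.
#' @param outdir Optional output directory.
#' @return A list of class `lunghet_pipeline`: `spec`, `truth`, `cohort`
#'   (per repeat), `by_step` (repeat-averaged), `comparison` (or `NULL`
#'   when CT is disabled), `manifest` (or `NULL`).
#' @export
run_pipeline <- function(spec = protocol_spec(), do_ct = TRUE,
                         do_logsd = TRUE, grid_n = 13,
                         r1 = 2.41, r2 = 3.675, threshold = 1.61,
                         exclusion_frac = 0.15, outdir = NULL) {
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }
  cohort_data <- run_stage("simulate-cohort",
                           simulate_cohort(spec, ct = do_ct))
  indices <- run_stage("ist-analyze",
                       recover_ist_indices(cohort_data$ist,
                                           lambda_b = spec$lambda_b))
  logsd <- if (do_logsd) {
    run_stage("logsd", estimate_cohort_logsd(indices, spec, grid_n = grid_n))
  }
  ct_idx <- if (do_ct) {
    run_stage("ct-analyze",
              compute_ct_indices(cohort_data$ct, r1 = r1, r2 = r2,
                                 threshold = threshold))
  }
  cohort <- assemble_cohort_table(indices, ct_idx, logsd)
  by_step <- average_repeats(cohort)
  comparison <- if (do_ct) {
    run_stage("compare", compare_cohort(by_step,
                                        exclusion_frac = exclusion_frac))
  }
  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      truth = "ground_truth.csv", cohort = "cohort.csv",
      by_step = "cohort_by_step.csv"
    )
    readr::write_csv(cohort_data$truth, file.path(outdir, files["truth"]))
    readr::write_csv(cohort, file.path(outdir, files["cohort"]))
    readr::write_csv(by_step, file.path(outdir, files["by_step"]))
    if (do_ct) {
      readr::write_csv(tidy(comparison$correlation),
                       file.path(outdir, "correlation.csv"))
      readr::write_csv(
        purrr::map_dfr(comparison$regressions, dplyr::bind_rows,
                       .id = "index"),
        file.path(outdir, "regressions.csv"))
      readr::write_csv(
        purrr::map_dfr(comparison$quadrants, glance, .id = "index"),
        file.path(outdir, "quadrants.csv"))
      files <- c(files, correlation = "correlation.csv",
                 regressions = "regressions.csv", quadrants = "quadrants.csv")
    }
    cfg <- unclass(spec)
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
    files <- c(files, config = "config.yaml")
    manifest <- tibble(
      file = unname(files),
      md5 = unname(tools::md5sum(file.path(outdir, files)))
    )
    readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  }
  structure(
    list(spec = spec, truth = cohort_data$truth, cohort = cohort,
         by_step = by_step, comparison = comparison, manifest = manifest),
    class = "lunghet_pipeline"
  )
}

#' @export
print.lunghet_pipeline <- function(x, ...) {
  cat(sprintf("<lunghet_pipeline> %d animals | %d cohort rows | seed %d\n",
              x$spec$n_animals, nrow(x$cohort), x$spec$seed))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Mean/SD PEEP trend plot for a cohort index
#'
#' @param by_step Per-step cohort tibble.
#' @param index Column name to plot.
#' @return A ggplot: mean +/- SD against PEEP, by protocol limb.
#' @export
plot_peep_trend <- function(by_step, index) {
  df <- by_step %>%
    group_by(.data$peep, .data$limb) %>%
    summarise(mean = mean(.data[[index]]),
              sd = sqrt(mean((.data[[index]] - mean(.data[[index]]))^2)),
              .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$peep, .data$mean,
                                   linetype = .data$limb)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "PEEP (cmH2O)", y = index, linetype = NULL)
}
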