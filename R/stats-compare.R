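#' Cohort summary statistics (population-SD convention)
#'
#' Arithmetic mean and population standard deviation (denominator `n`),
#' the convention under which the cohort baseline table's printed SDs are
#' reproduced exactly.
#'
#' @param values Numeric vector (length >= 1; `NA` dropped).
#' @return A one-row tibble with `n`, `mean`, `sd`.
#' @examples
#' summary_stats(c(90, 77, 88, 75, 89, 88))
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("`values` must contain at least one number.")
  tibble(
    n = length(values),
    mean = mean(values),
    sd = sqrt(mean((values - mean(values))^2))
  )
}

#' Baseline characteristics of the reference porcine cohort
#'
#' Per-animal baseline physiology (weight, haemodynamics, gas exchange
#' after saline lavage) for a six-pig lavage-injury cohort, with the
#' printed summary columns retained for cross-checking.
#'
#' @return A tibble with columns `parameter`, `animal_1` ... `animal_6`,
#'   `printed_mean`, `printed_sd`.
#' @export
baseline_characteristics <- function() {
  path <- system.file("extdata", "baseline_characteristics.csv",
                      package = "lunghet", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson correlations between all pairs of the requested columns, with
#' two-sided p-values from the t transform and pairwise-complete
#' observation handling. Zero-variance variables yield `NA` entries with a
#' warning.
#'
#' @param data A data frame (typically a per-step-averaged cohort table).
#' @param variables Character vector of column names (>= 2).
#' @return An object of class `pearson_matrix`: list with symmetric
#'   matrices `r`, `p`, `n` and the variable names.
#' @export
pearson_matrix <- function(data, variables) {
  stopifnot(length(variables) >= 2, all(variables %in% names(data)))
  k <- length(variables)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  degenerate <- FALSE
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    nm[i, i] <- sum(!is.na(data[[variables[i]]]))
    for (j in seq_len(k)) {
      if (j >= i) next
      x <- data[[variables[i]]]
      y <- data[[variables[j]]]
      ok <- complete.cases(x, y)
      n <- sum(ok)
      nm[i, j] <- nm[j, i] <- n
      if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        degenerate <- TRUE
        next
      }
      rv <- cor(x[ok], y[ok])
      r[i, j] <- r[j, i] <- rv
      tstat <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  if (degenerate) {
    warn("some variable pairs had < 3 complete cases or zero variance; entries set to NA.")
  }
  structure(list(r = r, p = p, n = nm, variables = variables),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  cat("<pearson_matrix> r (lower triangle) / p (upper triangle):\n")
  m <- x$r
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, digits))
  invisible(x)
}

#' @export
tidy.pearson_matrix <- function(x, ...) {
  pairs <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble(
    var1 = x$variables[pairs[, "col"]],
    var2 = x$variables[pairs[, "row"]],
    r = x$r[pairs],
    p_value = x$p[pairs],
    n = x$n[pairs]
  )
}

#' Per-animal and pooled linear regression between two indices
#'
#' Ordinary least squares of `y` on `x` within each animal, plus a pooled
#' fit over all rows labelled `"overall"`. Animals with fewer than 3
#' points or a degenerate design are flagged with `NA` and a warning.
#'
#' @param data Cohort data frame.
#' @param x,y Column names (strings) of predictor and response.
#' @param animal Column name of the animal identifier.
#' @return A tibble with `animal`, `n`, `slope`, `intercept`, `r_squared`.
#' @export
per_animal_regression <- function(data, x, y, animal = "animal") {
  stopifnot(all(c(x, y, animal) %in% names(data)))
  fit_one <- function(df, label) {
    ok <- complete.cases(df[[x]], df[[y]])
    df <- df[ok, ]
    if (nrow(df) < 3 || sd(df[[x]]) == 0) {
      warn(sprintf("regression for %s is rank-deficient or underdetermined.",
                   label))
      return(tibble(animal = label, n = nrow(df), slope = NA_real_,
                    intercept = NA_real_, r_squared = NA_real_))
    }
    fit <- lm(stats::reformulate(x, y), data = df)
    tibble(animal = label, n = nrow(df), slope = coef(fit)[[2]],
           intercept = coef(fit)[[1]],
           r_squared = suppressWarnings(summary(fit)$r.squared))
  }
  per <- data %>%
    dplyr::group_split(.data[[animal]]) %>%
    purrr::map_dfr(~ fit_one(.x, as.character(.x[[animal]][1])))
  bind_rows(per, fit_one(data, "overall"))
}

#' Consecutive-step changes of two indices
#'
#' Computes, within each animal and ordered by protocol step, the change
#' of two indices between consecutive steps (the per-step values should
#' already be repeat-averaged). Non-consecutive steps are skipped with a
#' warning.
#'
#' @param data Per-(animal, step) data frame.
#' @param x,y Column names of the two indices.
#' @param animal,step Identifier column names.
#' @return A tibble with `animal`, `step_from`, `step_to`, `dx`, `dy` —
#'   `n_animals * (n_steps - 1)` rows when no steps are missing.
#' @export
delta_pairs <- function(data, x, y, animal = "animal", step = "step") {
  stopifnot(all(c(x, y, animal, step) %in% names(data)))
  out <- data %>%
    arrange(.data[[animal]], .data[[step]]) %>%
    group_by(.data[[animal]]) %>%
    mutate(
      step_gap = .data[[step]] - lag(.data[[step]]),
      dx = .data[[x]] - lag(.data[[x]]),
      dy = .data[[y]] - lag(.data[[y]])
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$dx))
  skipped <- out$step_gap != 1
  if (any(skipped)) {
    warn(sprintf("%d delta(s) skipped across missing protocol steps.",
                 sum(skipped)))
    out <- out[!skipped, ]
  }
  tibble(
    animal = out[[animal]],
    step_from = out[[step]] - out$step_gap,
    step_to = out[[step]],
    dx = out$dx,
    dy = out$dy
  )
}

#' Four-quadrant trend-concordance analysis
#'
#' Classifies paired changes `(dx, dy)` by quadrant. Pairs inside the
#' exclusion zone — the axis-aligned rectangle at `exclusion_frac` of each
#' axis' maximum absolute change — are not counted; the concordance rate
#' is the percentage of included pairs with same-sign changes
#' (`dx * dy > 0`; pairs exactly on an axis count as discordant). Slope
#' and R-squared come from OLS over all pairs.
#'
#' @param pairs Data frame with columns `dx`, `dy` (e.g. [delta_pairs()]).
#' @param exclusion_frac Exclusion-zone fraction of per-axis maxima
#'   (default 0.15).
#' @return An object of class `quadrant_analysis`: list with `pairs`
#'   (input plus `excluded`, `concordant`), `concordance` (percent),
#'   `slope`, `r_squared`, `n_excluded`, `exclusion_frac`, and the zone
#'   half-widths `x_lim`, `y_lim`.
#' @export
four_quadrant <- function(pairs, exclusion_frac = 0.15) {
  stopifnot(all(c("dx", "dy") %in% names(pairs)), nrow(pairs) >= 1)
  x_lim <- exclusion_frac * max(abs(pairs$dx))
  y_lim <- exclusion_frac * max(abs(pairs$dy))
  excluded <- abs(pairs$dx) < x_lim & abs(pairs$dy) < y_lim
  concordant <- pairs$dx * pairs$dy > 0
  included <- !excluded
  if (!any(included)) {
    warn("all pairs fall inside the exclusion zone; concordance undefined.")
    concordance <- NA_real_
  } else {
    concordance <- 100 * sum(concordant[included]) / sum(included)
  }
  fit <- lm(dy ~ dx, data = pairs)
  structure(
    list(
      pairs = mutate(as_tibble(pairs), excluded = excluded,
                     concordant = concordant),
      concordance = concordance,
      slope = coef(fit)[[2]],
      r_squared = summary(fit)$r.squared,
      n_excluded = sum(excluded),
      exclusion_frac = exclusion_frac,
      x_lim = x_lim, y_lim = y_lim
    ),
    class = "quadrant_analysis"
  )
}

#' @export
print.quadrant_analysis <- function(x, ...) {
  cat(sprintf(
    "<quadrant_analysis> %d pairs (%d excluded) | concordance %.1f%% | slope %.3f | R^2 %.3f\n",
    nrow(x$pairs), x$n_excluded, x$concordance, x$slope, x$r_squared))
  invisible(x)
}

#' @export
tidy.quadrant_analysis <- function(x, ...) {
  x$pairs
}

#' @export
glance.quadrant_analysis <- function(x, ...) {
  tibble(
    concordance = x$concordance, slope = x$slope, r_squared = x$r_squared,
    n = nrow(x$pairs), n_excluded = x$n_excluded
  )
}

#' @export
autoplot.quadrant_analysis <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$dx, .data$dy)) +
    ggplot2::annotate("rect", xmin = -object$x_lim, xmax = object$x_lim,
                      ymin = -object$y_lim, ymax = object$y_lim,
                      fill = NA, colour = "black", linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(
      x = expression(Delta * "H (x)"), y = expression(Delta * "H (y)"),
      subtitle = sprintf("Concordance %.0f%% | slope %.2f | R^2 %.2f",
                         object$concordance, object$slope, object$r_squared))
}
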