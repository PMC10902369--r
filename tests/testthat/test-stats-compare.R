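test_that("summary statistics reproduce the printed cohort baseline table", {
  base <- baseline_characteristics()
  vals <- as.matrix(base[, paste0("animal_", 1:6)])
  # gas-exchange rows reproduce exactly at printed precision under the
  # population-SD convention
  exact <- c("fio2_pct", "pao2_kpa", "pf_ratio_mmhg")
  for (i in seq_len(nrow(base))) {
    s <- summary_stats(vals[i, ])
    digits_mean <- nchar(sub("^[^.]*\\.?", "", as.character(base$printed_mean[i])))
    digits_sd <- nchar(sub("^[^.]*\\.?", "", as.character(base$printed_sd[i])))
    if (base$parameter[i] %in% exact) {
      expect_equal(round(s$mean, digits_mean), base$printed_mean[i],
                   info = base$parameter[i])
      expect_equal(round(s$sd, digits_sd), base$printed_sd[i],
                   info = base$parameter[i])
    } else {
      # remaining printed rows are reproduced to within one unit of the
      # last printed digit (a few are internally rounded in the source
      # table)
      expect_lte(abs(s$mean - base$printed_mean[i]),
                 10^(-digits_mean) * 1.01)
      expect_lte(abs(s$sd - base$printed_sd[i]), 10^(-digits_sd) * 1.01)
    }
  }
  expect_equal(summary_stats(rep(4.2, 5))$sd, 0)
  expect_error(summary_stats(numeric(0)), "at least one")
})

test_that("pearson matrix matches the textbook formula and flags degeneracy", {
  df <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 4, 5, 9), z = c(1, 1, 1, 1))
  pm <- pearson_matrix(df, c("x", "y"))
  # hand evaluation of the covariance formula
  r_hand <- sum((df$x - mean(df$x)) * (df$y - mean(df$y))) /
    sqrt(sum((df$x - mean(df$x))^2) * sum((df$y - mean(df$y))^2))
  expect_equal(pm$r["x", "y"], r_hand)
  expect_equal(pm$r["x", "x"], 1)
  df$negx <- -df$x
  pm2 <- pearson_matrix(df, c("x", "negx"))
  expect_equal(pm2$r["x", "negx"], -1)
  expect_warning(pearson_matrix(df, c("x", "z")), "zero variance")
  td <- tidy(pm)
  expect_equal(nrow(td), 1L)
  expect_true(all(c("r", "p_value", "n") %in% names(td)))
})

test_that("per-animal regression separates individual from pooled fits", {
  perfect <- tibble::tibble(animal = rep(1, 5), x = 1:5, y = 2 * (1:5) + 1)
  fit <- per_animal_regression(perfect, "x", "y")
  expect_equal(fit$r_squared[fit$animal == "1"], 1)
  expect_equal(fit$slope[fit$animal == "1"], 2)

  set.seed(4)
  noise <- tibble::tibble(animal = rep(1, 200), x = rnorm(200),
                          y = rnorm(200))
  fitn <- per_animal_regression(noise, "x", "y")
  expect_lt(fitn$r_squared[fitn$animal == "1"], 0.1)

  # animal-specific intercepts degrade the pooled fit below the best
  # per-animal fit
  set.seed(5)
  multi <- purrr::map_dfr(1:4, function(a) {
    x <- runif(7)
    tibble::tibble(animal = a, x = x, y = 3 * x + 2 * a + rnorm(7, 0, 0.05))
  })
  fm <- per_animal_regression(multi, "x", "y")
  pooled <- fm$r_squared[fm$animal == "overall"]
  expect_lte(pooled, max(fm$r_squared[fm$animal != "overall"]))

  w <- testthat::capture_warnings(
    per_animal_regression(tibble::tibble(animal = 1, x = 1:2, y = 1:2),
                          "x", "y"))
  expect_match(w, "rank-deficient", all = TRUE)
  expect_length(w, 2)  # the lone animal and the pooled fit
})

test_that("delta pairs difference consecutive protocol steps per animal", {
  ladder_vals <- c(1.0, 0.8, 0.6, 0.4, 0.6, 0.8, 1.0)
  df <- tidyr::expand_grid(animal = 1:2, step = 1:7) %>%
    dplyr::mutate(h = ladder_vals[step], g = rev(ladder_vals)[step])
  d <- delta_pairs(df, "h", "g")
  expect_equal(nrow(d), 2 * 6)
  expect_equal(d$dx[d$animal == 1], c(rep(-0.2, 3), rep(0.2, 3)))

  const <- dplyr::mutate(df, h = 1, g = 1)
  dc <- delta_pairs(const, "h", "g")
  expect_true(all(dc$dx == 0))

  gap <- df[df$step != 3, ]
  expect_warning(dg <- delta_pairs(gap, "h", "g"), "skipped")
  expect_equal(nrow(dg), 2 * 4)
})

test_that("four-quadrant concordance honours the exclusion zone", {
  q1 <- four_quadrant(tibble::tibble(dx = c(1, 2, 3), dy = c(1, 1, 2)))
  expect_equal(q1$concordance, 100)
  expect_equal(q1$n_excluded, 0L)

  sym <- four_quadrant(tibble::tibble(dx = c(1, -1, 1, -1),
                                      dy = c(1, -1, -1, 1)))
  expect_equal(sym$concordance, 50)

  zone <- four_quadrant(tibble::tibble(dx = c(0.05, 1), dy = c(0.05, 1)))
  expect_equal(zone$n_excluded, 1L)
  expect_equal(zone$concordance, 100)

  # on-axis pairs count as discordant
  axis <- four_quadrant(tibble::tibble(dx = c(1, 1), dy = c(0.9, 0)))
  expect_equal(axis$concordance, 50)

  expect_warning(
    all_in <- four_quadrant(tibble::tibble(dx = 0.1, dy = 0.1),
                            exclusion_frac = 1.5),
    "undefined")
  expect_true(is.na(all_in$concordance))
})

test_that("concordance is invariant to positive rescaling of either axis", {
  set.seed(8)
  pairs <- tibble::tibble(dx = rnorm(40), dy = rnorm(40))
  base <- four_quadrant(pairs)
  scaled <- four_quadrant(dplyr::mutate(pairs, dx = 3.7 * dx, dy = 0.2 * dy))
  expect_equal(scaled$concordance, base$concordance)
  expect_equal(scaled$n_excluded, base$n_excluded)
})

test_that("quadrant tidiers report pairs and summary", {
  q <- four_quadrant(tibble::tibble(dx = c(1, -0.01), dy = c(1, 0.01)))
  expect_true(all(c("excluded", "concordant") %in% names(tidy(q))))
  g <- glance(q)
  expect_equal(g$n, 2L)
  expect_equal(g$n_excluded, 1L)
})
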