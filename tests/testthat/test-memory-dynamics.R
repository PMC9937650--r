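test_that("PI -> probability -> log-odds transforms are exact and clipped", {
  expect_equal(pi_to_prob(0), 0.5)
  expect_equal(pi_to_prob(1), 1 - 1e-3)    # clipped at the bound
  expect_equal(pi_to_prob(-1), 1e-3)
  expect_equal(pi_to_prob(0.5), 0.75)
  expect_error(pi_to_prob(1.5), class = "mblearn_argument_error")

  expect_equal(log_odds(0.5), 0)
  expect_equal(log_odds(0.75), log(3))
  expect_error(log_odds(0), class = "mblearn_argument_error")
  expect_error(log_odds(1), class = "mblearn_argument_error")

  # round trip: p -> PI -> p is the identity on [eps, 1 - eps]
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(pi_to_prob(2 * p - 1), p)
  # antisymmetry of log-odds under PI sign flip (unclipped range)
  pi_vals <- seq(-0.9, 0.9, 0.1)
  expect_equal(log_odds(pi_to_prob(-pi_vals)),
               -log_odds(pi_to_prob(pi_vals)))
})

test_that("non-negative decomposition recovers exact mixtures and zeroes anticorrelated drivers", {
  basis <- default_basis_curves()[1:2, ] |>
    dplyr::cross_join(default_protocol()) |>
    dplyr::mutate(pi = purrr::pmap_dbl(
      list(pi_max, learn_rate, decay_rate, react_drop, phase, trial),
      mblearn:::basis_pi_value)) |>
    dplyr::select(driver, phase, trial, pi)

  target <- mix_curves(basis, c(0.5, 0.2))
  fit <- nnls_decompose(target, basis)
  expect_equal(unname(fit$weights), c(0.5, 0.2), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-8)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$weight, unname(fit$weights))
  expect_equal(glance(fit)$n_points, nrow(default_protocol()))

  # anticorrelated target: non-negativity pins that driver's weight at 0
  b1 <- basis |> dplyr::filter(driver == "MB032B")
  anti <- b1 |> dplyr::transmute(phase, trial, pi = -pi)
  fit2 <- nnls_decompose(anti, b1)
  expect_equal(unname(fit2$weights), 0)
})

test_that("decomposition matches a box-constrained optimiser on random problems", {
  proto <- default_protocol()
  for (s in 1:5) {
    withr::with_seed(400 + s, {
      basis <- default_basis_curves()[1:3, ] |>
        dplyr::cross_join(proto) |>
        dplyr::mutate(pi = purrr::pmap_dbl(
          list(pi_max, learn_rate, decay_rate, react_drop, phase, trial),
          mblearn:::basis_pi_value)) |>
        dplyr::select(driver, phase, trial, pi)
      target <- mix_curves(basis, runif(3, 0, 0.8))
      target$pi <- pmin(1, pmax(-1, target$pi + rnorm(nrow(target), 0, 0.05)))
    })
    fit <- nnls_decompose(target, basis)
    A <- vapply(unique(basis$driver), function(d) {
      log_odds(pi_to_prob(basis$pi[basis$driver == d]))
    }, numeric(nrow(proto)))
    b <- log_odds(pi_to_prob(target$pi))
    expect_equal(unname(fit$weights), bf_nnls(A, b), tolerance = 1e-4)
  }
})

test_that("decomposition alignment errors name missing points and warns when underdetermined", {
  basis <- tibble::tibble(driver = "d1", phase = "training", trial = 1:5,
                          pi = c(0.1, 0.2, 0.3, 0.35, 0.4))
  target <- tibble::tibble(phase = "training", trial = 1:6,
                           pi = rep(0.2, 6))
  expect_error(nnls_decompose(target, basis), "training:6",
               class = "mblearn_alignment_error")

  basis2 <- tibble::tibble(driver = c("d1", "d2"), phase = "training",
                           trial = 1L, pi = c(0.3, 0.2))
  target2 <- tibble::tibble(phase = "training", trial = 1L, pi = 0.25)
  expect_warning(nnls_decompose(target2, basis2), "underdetermined")
})

test_that("scaling all basis log-odds by c divides the fitted weights by c", {
  proto <- default_protocol()
  basis <- default_basis_curves()[1:2, ] |>
    dplyr::cross_join(proto) |>
    dplyr::mutate(pi = purrr::pmap_dbl(
      list(pi_max, learn_rate, decay_rate, react_drop, phase, trial),
      mblearn:::basis_pi_value)) |>
    dplyr::select(driver, phase, trial, pi)
  target <- mix_curves(basis, c(0.4, 0.3))
  scaled <- basis |>
    dplyr::mutate(pi = 2 * stats::plogis(3 * log_odds(pi_to_prob(pi))) - 1)
  fit1 <- nnls_decompose(target, basis)
  fit3 <- nnls_decompose(target, scaled)
  expect_equal(unname(fit3$weights), unname(fit1$weights) / 3,
               tolerance = 1e-6)
})

test_that("memory-dynamics indices follow their figure-legend formulas", {
  curve <- dplyr::bind_rows(
    tibble::tibble(phase = "training", trial = 1:5,
                   pi = c(0.2, 0.3, 0.4, 0.35, 0.3)),
    tibble::tibble(phase = "extinction", trial = 1:12,
                   pi = rep(0.2, 12)),
    tibble::tibble(phase = "reversal", trial = 1:5, pi = rep(-0.3, 5)),
    tibble::tibble(phase = "re-reversal", trial = 1:5,
                   pi = c(0.1, 0.2, 0.3, 0.35, 0.4)),
    tibble::tibble(phase = "reactivation", trial = 1:3,
                   pi = c(0.12, 0.1, 0.08)))
  expect_equal(learning_rate(curve), 0.2 / 0.4)
  expect_equal(training_persistency(curve), 0.3 / 0.4)
  expect_equal(memory_persistency(curve), 0.2 / 0.4)
  expect_equal(reactivation_resistance(curve), mean(c(0.12, 0.1, 0.08)) / 0.4)
  expect_equal(early_test_persistency(curve), 0.2 / 0.2)

  # all five indices equal 1 on a perfectly flat positive curve
  flat <- curve |> dplyr::mutate(pi = 0.5)
  idx <- memory_indices(flat)
  expect_true(all(idx$defined))
  expect_equal(idx$value, rep(1, 5))

  # fully extinguished memory scores 0, not undefined
  gone <- curve
  gone$pi[gone$phase == "extinction"] <- 0
  expect_equal(memory_persistency(gone), 0)
})

test_that("indices with non-positive denominators are flagged undefined, not coerced", {
  bad <- dplyr::bind_rows(
    tibble::tibble(phase = "training", trial = 1:5, pi = rep(-0.1, 5)),
    tibble::tibble(phase = "extinction", trial = 1:12, pi = rep(0.1, 12)))
  expect_warning(v <- learning_rate(bad), "undefined")
  expect_true(is.na(v))
  expect_warning(expect_true(is.na(training_persistency(bad))))
  expect_warning(expect_true(is.na(memory_persistency(bad))))

  idx <- memory_indices(bad)
  expect_false(idx$defined[idx$index == "learning_rate"])
  # phases missing entirely are a data error for the direct call ...
  expect_error(reactivation_resistance(bad), class = "mblearn_data_error")
  # ... and reported as undefined by the batch summary
  expect_false(idx$defined[idx$index == "reactivation_resistance"])
  # too few extinction tests is a data error, not a silent subset
  short <- bad |> dplyr::filter(!(phase == "extinction" & trial > 6))
  expect_error(memory_persistency(short), class = "mblearn_data_error")
})
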