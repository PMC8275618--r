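test_that("zero-noise generation reproduces group growth means exactly", {
  spec <- synthetic_spec(n_units = 8, n_growth_groups = 4,
                         group_growth_means = c(-10, 10, 40, 80),
                         growth_noise_sd = 0, seed = 1)
  counts <- generate_species_counts(spec)
  expect_equal(nrow(counts), 8)
  pct <- percentage_increase(counts$count_t0, counts$count_t1)
  expect_equal(pct, c(-10, -10, 10, 10, 40, 40, 80, 80))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- synthetic_spec(n_units = 18, growth_noise_sd = 5, seed = 7)
  a <- generate_species_counts(spec)
  b <- generate_species_counts(spec)
  expect_identical(a, b)
  expect_identical(generate_attributes(a, spec), generate_attributes(b, spec))
})

test_that("within-group mean growth converges to the group mean at large n", {
  spec <- synthetic_spec(n_units = 200, n_growth_groups = 4,
                         group_growth_means = c(0, 20, 40, 60),
                         growth_noise_sd = 5, seed = 3)
  counts <- generate_species_counts(spec)
  observed <- counts |>
    dplyr::mutate(pct = percentage_increase(count_t0, count_t1)) |>
    dplyr::group_by(growth_group) |>
    dplyr::summarise(mean_pct = mean(pct)) |>
    dplyr::pull(mean_pct)
  expect_true(all(abs(observed - c(0, 20, 40, 60)) < 1))
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_spec(n_units = 3, n_growth_groups = 4,
                              group_growth_means = 1:4),
               class = "qicd_bad_spec")
  expect_error(synthetic_spec(growth_noise_sd = -1), class = "qicd_bad_spec")
  spec <- synthetic_spec(seed = 5)
  other <- generate_species_counts(synthetic_spec(n_units = 10,
                                                  group_growth_means = c(0, 1, 2, 3)))
  expect_error(generate_attributes(other, spec), "unit mismatch")
})

test_that("driver aggregates follow the injected community-level association", {
  base_spec <- synthetic_spec(n_units = 20, seed = 11)
  counts <- generate_species_counts(base_spec)

  flat <- base_spec
  flat$driver_effect <- 0
  flat$driver_noise_sd <- 0
  attrs0 <- generate_attributes(counts, flat)
  groups <- tibble::tibble(unit_id = counts$unit_id,
                           community = counts$growth_group)
  agg0 <- aggregate_by_community(attrs0, groups, "temp_anomaly_t1", "mean")
  expect_equal(agg0$value, rep(agg0$value[1], 4), tolerance = 1e-10)

  ramp <- base_spec
  ramp$driver_effect <- 1
  ramp$driver_noise_sd <- 0
  attrs1 <- generate_attributes(counts, ramp)
  agg1 <- aggregate_by_community(attrs1, groups, "temp_anomaly_t1", "mean")
  expect_equal(diff(agg1$value), rep(1, 3), tolerance = 1e-10)
  expect_equal(pearson_r(agg1$value, seq_len(4)), 1, tolerance = 1e-12)
})

test_that("package pearson matches the closed-form oracle on noisy aggregates", {
  spec <- synthetic_spec(n_units = 20, driver_effect = 1,
                         driver_noise_sd = 0.1, seed = 11)
  counts <- generate_species_counts(spec)
  attrs <- generate_attributes(counts, spec)
  groups <- tibble::tibble(unit_id = counts$unit_id,
                           community = counts$growth_group)
  agg <- aggregate_by_community(attrs, groups, "precip_anomaly_t2", "mean")
  expect_equal(pearson_r(agg$value, seq_len(4)),
               pearson_closed_form(agg$value, seq_len(4)),
               tolerance = 1e-12)
})

test_that("growth-group labels are recoverable when group ranges do not overlap", {
  spec <- synthetic_spec(n_units = 24, group_growth_means = c(-20, 10, 40, 80),
                         growth_noise_sd = 2, seed = 9)
  counts <- generate_species_counts(spec)
  recovered <- assign_growth_groups(counts, n_groups = 4)
  truth <- tibble::tibble(unit_id = counts$unit_id,
                          community = counts$growth_group)
  expect_equal(nmi(recovered, truth), 1)
  expect_equal(ari(recovered, truth), 1)
})

test_that("the packaged fixture matches the study design", {
  fx <- tiger_fixture()
  expect_equal(nrow(fx$counts), 18)
  expect_equal(nrow(fx$attributes), 18)
  expect_setequal(fx$counts$unit_id, fx$attributes$unit_id)
  expect_true(all(fx$attributes$landscape_class %in% 1:4))
  expect_equal(length(unique(fx$attributes$landscape_class)), 4)
  # threshold split at 3 reserves yields exactly two classes
  cls <- fx$attributes$reserve_count >= 3
  expect_equal(length(unique(cls)), 2)
  expect_true(all(fx$counts$count_t0 > 0))
  expect_true(all(c("Uttar Pradesh", "Karnataka", "Madhya Pradesh",
                    "Maharashtra", "Rajasthan", "Tamil Nadu", "Assam",
                    "Uttarakhand", "Chhattisgarh", "Arunachal Pradesh",
                    "Mizoram", "Sunderbans") %in% fx$counts$unit_id))
})
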