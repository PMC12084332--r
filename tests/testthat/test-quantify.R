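# small noiseless cohort used across strategy tests
noiseless_cohort <- function(n_samples = 4, seed = 7) {
  simulate_cohort(sim_config(
    seed = seed, n_samples = n_samples, n_species = 12,
    area_cv_pct = 0, descriptor_noise = 0
  ))
}

test_that("partition percentage follows its defining ratio", {
  expect_equal(partition_percent(100, 100), 50)
  expect_equal(partition_percent(0, 42), 100)
  expect_equal(partition_percent(42, 0), 0)
  expect_true(is.na(partition_percent(0, 0)))
  expect_equal(partition_percent(c(1, 3), c(1, 1)), c(50, 25))
})

test_that("spiked ISTD amounts follow unit arithmetic", {
  # 12.5 uL x 20 ug/mL = 0.25 ug; 0.25 ug of a 1250 Da ISTD = 0.2 nmol
  expect_equal(spiked_amount_nmol(12.5, 20, 1250), 0.2)
  expect_equal(spiked_amount_nmol(0, 20, 1250), 0)
  istds <- default_istds()
  expect_equal(nrow(istds), 5)
  expect_equal(istds$spiked_nmol, 0.25 * 1000 / istds$molecular_mass)
})

test_that("Strategy I reverts analyte amounts through the cohort partition", {
  cfg <- quant_config()
  spiked <- cfg$istds$spiked_nmol[cfg$istds$istd == "GD3 18:1;O2/18:0-d3"]
  analytes <- tibble::tibble(
    sample_id = "S1", name = "GD3 18:1;O2/18:0", area = 1000
  )
  istd_f2 <- tibble::tibble(
    sample_id = "S1", istd = "GD3 18:1;O2/18:0-d3", area_f2 = 1000
  )
  # area ratio 1, A-bar 100 -> C equals the spiked amount
  abar <- tibble::tibble(istd = "GD3 18:1;O2/18:0-d3", A_bar_pct = 100)
  rec <- quantify_strategy_I(analytes, istd_f2, abar, cfg)
  expect_equal(rec$C_nmol, spiked, tolerance = 1e-12)

  # area ratio 2, A-bar 50 -> C = 2 x spiked x 0.5
  analytes2 <- dplyr::mutate(analytes, area = 2000)
  abar50 <- tibble::tibble(istd = "GD3 18:1;O2/18:0-d3", A_bar_pct = 50)
  rec2 <- quantify_strategy_I(analytes2, istd_f2, abar50, cfg)
  expect_equal(rec2$C_nmol, 2 * spiked * 0.5, tolerance = 1e-12)

  # missing cohort partition for a mapped ISTD errors
  expect_error(
    quantify_strategy_I(analytes, istd_f2,
      tibble::tibble(istd = "GM3 18:1;O2/18:0-d5", A_bar_pct = 70), cfg
    ),
    "missing"
  )
})

test_that("Strategy II recovers noiseless generator truth exactly", {
  sim <- noiseless_cohort()
  rec <- quantify_strategy_II(sim$analyte_areas, sim$istd_areas)
  joined <- dplyr::inner_join(
    rec, sim$truth,
    by = c("sample_id", "name")
  )
  expect_gt(nrow(joined), 0)
  expect_false(any(joined$flag_missing))
  expect_equal(joined$C_nmol, joined$C_f2_nmol, tolerance = 1e-9)
  # per-sample partition was used
  expect_equal(joined$A_used_pct, joined$A_pct, tolerance = 1e-9)
})

test_that("Strategy I equals Strategy II when per-sample partition equals A-bar", {
  sim <- simulate_cohort(sim_config(
    seed = 11, n_samples = 3, n_species = 10,
    area_cv_pct = 0,
    partitions = dplyr::mutate(reference_partitions(), partition_cv_pct = 0)
  ))
  part <- partition_records(sim$istd_areas)
  abar <- cohort_partition(part)
  rec1 <- quantify_strategy_I(
    sim$analyte_areas,
    dplyr::select(sim$istd_areas, "sample_id", "istd", "area_f2"),
    abar
  )
  rec2 <- quantify_strategy_II(sim$analyte_areas, sim$istd_areas)
  expect_equal(rec1$C_nmol, rec2$C_nmol, tolerance = 1e-9)
})

test_that("quantification is invariant to scaling all areas in a sample", {
  sim <- noiseless_cohort()
  scaled_analytes <- sim$analyte_areas |>
    dplyr::mutate(area = ifelse(.data$sample_id == "S01", area * 17, area))
  scaled_istds <- sim$istd_areas |>
    dplyr::mutate(
      area_f1 = ifelse(.data$sample_id == "S01", area_f1 * 17, area_f1),
      area_f2 = ifelse(.data$sample_id == "S01", area_f2 * 17, area_f2)
    )
  rec <- quantify_strategy_II(sim$analyte_areas, sim$istd_areas)
  rec_scaled <- quantify_strategy_II(scaled_analytes, scaled_istds)
  expect_equal(rec$C_nmol, rec_scaled$C_nmol, tolerance = 1e-12)
})

test_that("two samples with equal ratios but different partitions scale with A", {
  cfg <- quant_config()
  analytes <- tibble::tibble(
    sample_id = c("S1", "S2"), name = "GD3 18:1;O2/18:0", area = 500
  )
  istds <- tibble::tibble(
    sample_id = c("S1", "S2"), istd = "GD3 18:1;O2/18:0-d3",
    area_f1 = c(500, 1500), area_f2 = c(500, 500) # A = 50 vs 25
  )
  rec <- quantify_strategy_II(analytes, istds, cfg)
  expect_equal(rec$C_nmol[1] / rec$C_nmol[2], 2, tolerance = 1e-12)
  # A = 100 reduces to single-fraction quantification
  istds100 <- dplyr::mutate(istds, area_f1 = 0)
  rec100 <- quantify_strategy_II(analytes, istds100, cfg)
  spiked <- cfg$istds$spiked_nmol[cfg$istds$istd == "GD3 18:1;O2/18:0-d3"]
  expect_equal(rec100$C_nmol, rep(spiked, 2), tolerance = 1e-12)
})

test_that("partition outlier detection flags only aberrant samples", {
  part <- tibble::tibble(
    sample_id = rep(sprintf("S%d", 1:6), each = 1),
    istd = "GD3 18:1;O2/18:0-d3",
    area_f1 = 100 - c(78, 79, 78.5, 78.2, 78.9, 48),
    area_f2 = c(78, 79, 78.5, 78.2, 78.9, 48)
  ) |> partition_records()
  flagged <- detect_partition_outliers(part)
  expect_equal(flagged, "S6")

  # identical samples: none flagged
  same <- dplyr::mutate(part, area_f1 = 22, area_f2 = 78) |> partition_records()
  expect_length(detect_partition_outliers(same), 0)

  # rule parameters at infinity: none flagged
  expect_length(detect_partition_outliers(part, k_mad = Inf, abs_pp = Inf), 0)

  expect_warning(
    none <- detect_partition_outliers(part[1:2, ]),
    "fewer than 3"
  )
  expect_length(none, 0)
})

test_that("combined strategy corrects only flagged samples", {
  sim <- noiseless_cohort(n_samples = 6)
  # make S06 a partition outlier: shift its ISTD areas by +30 points
  istds <- sim$istd_areas |>
    dplyr::group_by(sample_id, istd) |>
    dplyr::mutate(
      total = area_f1 + area_f2,
      A = partition_percent(area_f1, area_f2),
      A_new = ifelse(sample_id == "S06", pmin(A + 30, 99), A),
      area_f2 = total * A_new / 100,
      area_f1 = total * (1 - A_new / 100)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "istd", "area_f1", "area_f2")

  cfg <- quant_config(base_strategy = "I")
  combined <- quantify_combined(sim$analyte_areas, istds, config = cfg)
  base <- quantify_strategy_I(
    sim$analyte_areas,
    dplyr::select(istds, "sample_id", "istd", "area_f2"),
    cohort_partition(partition_records(istds)), cfg
  )
  expect_true(all(combined$corrected[combined$sample_id == "S06"]))
  expect_false(any(combined$corrected[combined$sample_id != "S06"]))
  # unflagged samples identical to the base strategy
  k <- combined$sample_id != "S06"
  b <- base[base$sample_id != "S06", ]
  expect_equal(
    combined$C_nmol[k][order(paste(combined$sample_id[k], combined$name[k]))],
    b$C_nmol[order(paste(b$sample_id, b$name))],
    tolerance = 1e-12
  )
  # corrected sample differs from its base-strategy value
  expect_false(isTRUE(all.equal(
    combined$C_nmol[combined$sample_id == "S06"],
    base$C_nmol[base$sample_id == "S06"]
  )))

  # with no outliers the combined output is the base strategy output
  calm <- quantify_combined(sim$analyte_areas, sim$istd_areas, config = cfg)
  base_calm <- quantify_strategy_I(
    sim$analyte_areas,
    dplyr::select(sim$istd_areas, "sample_id", "istd", "area_f2"),
    cohort_partition(partition_records(sim$istd_areas)), cfg
  )
  expect_equal(calm$C_nmol, base_calm$C_nmol, tolerance = 1e-12)
  expect_false(any(calm$corrected))

  # the swapped ordering (base II, correction I) is selectable
  cfg2 <- quant_config(base_strategy = "II")
  swapped <- quantify_combined(sim$analyte_areas, istds, config = cfg2)
  expect_true(all(swapped$strategy[swapped$sample_id != "S06"] == "II"))
  expect_true(all(swapped$strategy[swapped$sample_id == "S06"] == "I"))
})

test_that("replicate CVs and the threshold summary behave", {
  rec <- tibble::tibble(
    sample_id = rep(c("R1", "R2"), each = 4),
    name = rep(c("a", "b", "c", "d"), 2),
    C_nmol = c(1, 1, 1, 1, 3, 1.1, 1.2, 1.05)
  )
  cv <- cv_table(rec)
  # two replicates (1, 3): CV = 100 * sd / mean = 70.71%
  expect_equal(cv$per_species$cv_pct[cv$per_species$name == "a"], 70.71068,
    tolerance = 1e-6
  )
  # 1 of 4 species above 35% -> 75% below
  expect_equal(cv$pct_below, 75)

  same <- dplyr::mutate(rec, C_nmol = rep(c(1, 2, 3, 4), 2))
  cv0 <- cv_table(same)
  expect_true(all(cv0$per_species$cv_pct == 0))
  expect_equal(cv0$pct_below, 100)

  # constructed table with 2 of 4 species under the threshold
  half <- tibble::tibble(
    sample_id = rep(c("R1", "R2"), each = 4),
    name = rep(c("a", "b", "c", "d"), 2),
    C_nmol = c(1, 1, 1, 1, 1.05, 1.1, 3, 4)
  )
  expect_equal(cv_table(half)$pct_below, 50)

  # zero-mean species are excluded and counted
  z <- tibble::tibble(
    sample_id = rep(c("R1", "R2"), 2), name = rep(c("a", "z"), each = 2),
    C_nmol = c(1, 1.2, 0, 0)
  )
  cvz <- cv_table(z)
  expect_equal(cvz$n_undefined, 1)
})

test_that("fraction-1 normalization is a scale-invariant ratio", {
  areas <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"), name = c("HexCer 18:1;O2/16:0", "SHexCer 18:1;O2/16:0", "HexCer 18:1;O2/16:0"),
    area = c(100, 0, 500)
  )
  istd <- tibble::tibble(sample_id = c("S1", "S2"), istd_area = c(100, 1000))
  norm <- normalize_fraction1(areas, istd)
  expect_equal(norm$norm_abundance, c(1, 0, 0.5))
  # doubling all areas in a sample leaves ratios unchanged
  norm2 <- normalize_fraction1(
    dplyr::mutate(areas, area = area * 2),
    dplyr::mutate(istd, istd_area = istd_area * 2)
  )
  expect_equal(norm2$norm_abundance, norm$norm_abundance)
  # missing ISTD flags the sample
  norm3 <- normalize_fraction1(areas, tibble::tibble(sample_id = "S1", istd_area = 100))
  expect_true(any(norm3$flag_missing[norm3$sample_id == "S2"]))
})
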