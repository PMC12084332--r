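make_feature <- function(entry, ...) {
  tibble::tibble(
    feature_id = "F1", sample_id = "S1", fraction = entry$fraction,
    polarity = entry$polarity, mz = entry$mz, z = entry$charge,
    rt_min = entry$rt_min, ccs_A2 = entry$ccs_A2, area = 1e5,
    spectrum_id = NA_character_, ...
  )
}

test_that("cosine spectral score is symmetric, bounded and scale-invariant", {
  s <- data.frame(mz = c(100, 200, 300), intensity = c(1, 2, 3))
  expect_equal(spectral_score(s, s), 1000)
  s7 <- transform(s, intensity = intensity * 7)
  expect_equal(spectral_score(s, s7), 1000, tolerance = 1e-12)

  other <- data.frame(mz = c(150, 250), intensity = c(5, 5))
  expect_equal(spectral_score(s, other), 0)
  expect_equal(
    spectral_score(s, other),
    spectral_score(other, s)
  )

  partial <- data.frame(mz = c(100, 250), intensity = c(1, 1))
  sc <- spectral_score(s, partial)
  expect_gt(sc, 0)
  expect_lt(sc, 1000)

  expect_warning(
    sc0 <- spectral_score(data.frame(mz = numeric(0), intensity = numeric(0)), s),
    "empty"
  )
  expect_equal(sc0, 0)
})

test_that("exact features match their own entry at rank 1", {
  lib <- serum_fixture()
  entries <- lib[!is.na(lib$mz), ][c(1, 50, 200, 350), ]
  for (i in seq_len(nrow(entries))) {
    ann <- match_features(make_feature(entries[i, ]), lib)
    expect_equal(ann$entry_name[ann$rank == 1], entries$name[i])
    expect_equal(ann$delta_mz_mDa[ann$rank == 1], 0, tolerance = 1e-9)
  }
})

test_that("features outside the m/z window come back unknown", {
  lib <- serum_fixture()
  entry <- lib[which(!is.na(lib$mz))[1], ]
  f <- make_feature(entry)
  f$mz <- f$mz + 0.020 # +20 mDa
  ann <- match_features(f, lib)
  expect_equal(ann$entry_name, "unknown")
})

test_that("composition isomers are disambiguated by the CCS window", {
  lib <- serum_fixture()
  gm1 <- lib[lib$name == "GM1 18:1;O2/18:0", ]
  nlc <- lib[lib$name == "Neu5Ac-nLc4Cer 18:1;O2/18:0", ]
  expect_equal(gm1$mz, nlc$mz, tolerance = 1e-9) # isobaric isomers

  for (truth in list(gm1, nlc)) {
    f <- make_feature(truth)
    ann <- match_features(f, lib)
    top <- ann$entry_name[ann$rank == 1]
    expect_equal(top, truth$name)
    # the isomer pair is never co-reported at rank 1
    expect_equal(sum(ann$rank == 1), 1)
  }
})

test_that("shrinking any tolerance never adds annotations", {
  set.seed(42)
  lib <- serum_fixture()
  pool <- lib[!is.na(lib$mz) & lib$fraction == 2, ]
  idx <- sample(nrow(pool), 20)
  feats <- purrr::map_dfr(seq_along(idx), function(k) {
    e <- pool[idx[k], ]
    f <- make_feature(e)
    f$feature_id <- sprintf("F%02d", k)
    f$mz <- f$mz + rnorm(1, 0, 0.002)
    f$rt_min <- f$rt_min + rnorm(1, 0, 0.2)
    f$ccs_A2 <- f$ccs_A2 * (1 + rnorm(1, 0, 0.008))
    f
  })
  wide <- tolerance_config(mz_mDa = 5, rt_min = 0.5, ccs_pct = 2)
  narrow_list <- list(
    tolerance_config(mz_mDa = 2, rt_min = 0.5, ccs_pct = 2),
    tolerance_config(mz_mDa = 5, rt_min = 0.1, ccs_pct = 2),
    tolerance_config(mz_mDa = 5, rt_min = 0.5, ccs_pct = 0.5),
    tolerance_config(mz_mDa = 2, rt_min = 0.1, ccs_pct = 0.5)
  )
  ann_wide <- match_features(feats, lib, wide)
  keys_wide <- paste(ann_wide$feature_id, ann_wide$entry_name)
  for (tol in narrow_list) {
    ann_n <- match_features(feats, lib, tol)
    ann_n <- ann_n[ann_n$entry_name != "unknown", ]
    expect_true(all(paste(ann_n$feature_id, ann_n$entry_name) %in% keys_wide))
  }
})

test_that("spectral evidence feeds the composite score and the msms floor", {
  lib <- serum_fixture()
  entry <- lib[lib$name == "GD1 18:1;O2/18:0", ]
  fr <- glycosidic_fragments("GD1 18:1;O2/18:0", "-")
  ref_peaks <- tibble::tibble(mz = fr$mz, intensity = 100)
  spectra <- tibble::tibble(
    spectrum_id = c("q_good", "q_bad", "ref_gd1"),
    precursor_mz = entry$mz, charge = 2L, polarity = "-",
    peaks = list(
      ref_peaks,
      tibble::tibble(mz = c(111.1, 222.2), intensity = c(1, 1)),
      ref_peaks
    )
  )
  lib$spectrum_ref[lib$name == "GD1 18:1;O2/18:0"] <- "ref_gd1"

  f_good <- make_feature(entry)
  f_good$spectrum_id <- "q_good"
  ann <- match_features(f_good, lib, spectra = spectra)
  expect_equal(ann$entry_name[ann$rank == 1], "GD1 18:1;O2/18:0")
  expect_equal(ann$msms_score[ann$rank == 1], 1000, tolerance = 1e-9)

  # a spectrum failing the msms floor removes the entry from candidates
  f_bad <- f_good
  f_bad$spectrum_id <- "q_bad"
  ann_bad <- match_features(f_bad, lib, spectra = spectra)
  expect_false("GD1 18:1;O2/18:0" %in% ann_bad$entry_name)
})

test_that("diagnostic pre-screening keeps only flagged spectra", {
  spectra <- tibble::tibble(
    spectrum_id = c("sial", "noise", "pos274"),
    precursor_mz = c(917.48, 500, 900),
    charge = c(2L, 1L, 1L),
    polarity = c("-", "-", "+"),
    peaks = list(
      tibble::tibble(mz = c(290.088, 581.184), intensity = c(10, 4)),
      tibble::tibble(mz = c(345.6, 401.2), intensity = c(9, 9)),
      tibble::tibble(mz = 274.092, intensity = 5)
    )
  )
  feats <- tibble::tibble(
    feature_id = c("F1", "F2", "F3"),
    mz = c(917.48, 500, 900), polarity = c("-", "-", "+"),
    spectrum_id = c("sial", "noise", "pos274")
  )
  kept_neg <- screen_candidates(feats[1:2, ], spectra, "-")
  expect_equal(kept_neg$feature_id, "F1")
  kept_pos <- screen_candidates(feats[3, ], spectra, "+")
  expect_equal(kept_pos$feature_id, "F3")

  # neutral-loss mode
  prec <- 800
  spectra_nl <- tibble::tibble(
    spectrum_id = "nl", precursor_mz = prec, charge = 1L, polarity = "+",
    peaks = list(tibble::tibble(mz = prec - 162.0528, intensity = 10))
  )
  feats_nl <- tibble::tibble(
    feature_id = "F4", mz = prec, polarity = "+", spectrum_id = "nl"
  )
  expect_equal(
    screen_candidates(feats_nl, spectra_nl, "+", mode = "neutral")$feature_id,
    "F4"
  )
})

test_that("partial-evidence features still match on remaining dimensions", {
  lib <- serum_fixture()
  entry <- lib[lib$name == "GM3 18:1;O2/18:0", ]
  f <- make_feature(entry)
  f$rt_min <- NA_real_
  f$ccs_A2 <- NA_real_
  ann <- match_features(f, lib)
  expect_equal(ann$entry_name[ann$rank == 1], "GM3 18:1;O2/18:0")
  expect_true(all(ann$partial_evidence))
})
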