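test_that("glycosidic fragmentation is branch-aware and complementary", {
  gd1b <- glycosidic_fragments("GD1b 18:1;O2/18:0", "-")
  # terminal Neu5Ac-Neu5Ac disialo element as a B ion at nominal 581
  expect_true(581 %in% gd1b$nominal[gd1b$type == "B"])

  hexcer <- glycosidic_fragments("HexCer 18:1;O2/16:0", "-")
  expect_equal(sum(hexcer$type == "B"), 1)
  expect_equal(sum(hexcer$type == "Y"), 1)

  # GM3 Y0 (ceramide) ion is Cer minus a proton
  gm3 <- glycosidic_fragments("GM3 18:1;O2/18:0", "-")
  y0 <- gm3$mz[gm3$label == "Y1"]
  expect_equal(y0, ORACLE_CER_18_1_18_0 - ORACLE_PROTON, tolerance = 1e-4)
})

test_that("B/Y pairs sum to a constant on linear chains", {
  for (nm in c("Hex3Cer 18:1;O2/16:0", "GM3 18:1;O2/18:0", "Neu5Ac-nLc6Cer 18:1;O2/16:0")) {
    fr <- glycosidic_fragments(nm, "-")
    fr <- fr[fr$type %in% c("B", "Y"), ]
    m <- species_formula(nm)$mass
    for (b in unique(fr$bond)) {
      pair_sum <- sum(fr$mz[fr$bond == b])
      expect_equal(pair_sum, m - 2 * ORACLE_PROTON, tolerance = 1e-3)
    }
  }
})

test_that("sphingoid-base ions land on the diagnostic nominal masses", {
  f181 <- ceramide_fragments("GM3 18:1;O2/18:0")
  sph <- f181[f181$type == "sphingoid", ]
  expect_true(264 %in% sph$nominal)
  expect_equal(min(sph$mz), 264.2686, tolerance = 1e-4)

  f182 <- ceramide_fragments("HexCer 18:2;O2/16:0")
  expect_true(262 %in% f182$nominal[f182$type == "sphingoid"])

  f180 <- ceramide_fragments("HexCer 18:0;O2/16:0")
  sph180 <- min(f180$mz[f180$type == "sphingoid"])
  expect_true(266 %in% f180$nominal[f180$type == "sphingoid"])
  expect_equal(sph180 - 264.2686, 2.0157, tolerance = 1e-3)

  expect_error(ceramide_fragments("SHexCer unidentified"), "placeholder")
})

test_that("the diagnostic catalog reproduces the printed nominal ions", {
  neg <- diagnostic_catalog("-")
  pos <- diagnostic_catalog("+")
  expect_equal(neg$nominal[neg$flag == "sialylated_neg"], 290)
  expect_equal(neg$nominal[neg$flag == "disialo_element"], 581)
  expect_equal(neg$nominal[neg$flag == "o_acetyl_sialic"], 332)
  expect_equal(neg$nominal[neg$flag == "neu5gc"], 306)
  expect_equal(pos$nominal[pos$flag == "sialylated_pos"], 274)
  expect_equal(pos$nominal[pos$flag == "sphingoid_18_1"], 264)
  expect_equal(pos$nominal[pos$flag == "sphingoid_18_2"], 262)
  # exact values from residue arithmetic
  expect_equal(neg$mz[neg$flag == "sialylated_neg"], ORACLE_NEU5AC - ORACLE_PROTON,
    tolerance = 1e-6
  )
  expect_equal(neg$mz[neg$flag == "disialo_element"], 2 * ORACLE_NEU5AC - ORACLE_PROTON,
    tolerance = 1e-6
  )
  expect_equal(pos$mz[pos$flag == "sialylated_pos"],
    ORACLE_NEU5AC + ORACLE_PROTON - ORACLE_H2O,
    tolerance = 1e-6
  )
  # neutral losses: one hexose and free lactose
  expect_equal(neg$mz[neg$flag == "hex_loss"], 162.0528, tolerance = 1e-4)
  expect_equal(neg$mz[neg$flag == "hex2_loss"], 342.1162, tolerance = 1e-4)
  # nominal is the integer rounding of the exact mass for every entry
  both <- rbind(neg, pos)
  expect_equal(both$nominal, round(both$mz))
})

test_that("spectrum classification follows the diagnostic rules", {
  empty <- classify_spectrum(data.frame(mz = numeric(0), intensity = numeric(0)), "-")
  expect_false(any(unlist(empty)))

  # synthetic GD1b spectrum from its own fragments
  fr <- glycosidic_fragments("GD1b 18:1;O2/18:0", "-")
  spec <- data.frame(mz = fr$mz, intensity = 100)
  fl <- classify_spectrum(spec, "-")
  expect_true(fl$sialylated_neg)
  expect_true(fl$disialo_element)
  expect_false(fl$neu5gc)

  # O-acetyl rule at 332
  fl332 <- classify_spectrum(data.frame(mz = 332.099, intensity = 5), "-")
  expect_true(fl332$o_acetyl_sialic)

  # neutral-loss rules need a precursor
  prec <- species_mz("Hex2Cer 18:1;O2/16:0", ion = "[M+H]1+")$mz
  fl_nl <- classify_spectrum(
    data.frame(mz = prec - 342.1162, intensity = 10), "+",
    precursor_mz = prec
  )
  expect_true(fl_nl$hex2_loss)
  expect_false(fl_nl$hex_loss)
})

test_that("composition-implied flags round-trip through simulated spectra", {
  cases <- c(
    "GM3 18:1;O2/18:0", "GD1b 18:1;O2/18:0", "GD1a 18:1;O2/18:0",
    "GQ1b 18:1;O2/18:0", "Neu5Gc-GD1 18:1;O2/18:0", "OAc-GD1 18:1;O2/18:0",
    "SHexCer 18:1;O2/16:0", "HexCer 18:1;O2/16:0",
    "Neu5Ac-nLc6Cer 18:1;O2/16:0"
  )
  comp_flags <- c(
    "sialylated_neg", "disialo_element", "o_acetyl_sialic", "neu5gc",
    "sulfate_signature"
  )
  for (nm in cases) {
    fr <- glycosidic_fragments(nm, "-")
    got <- classify_spectrum(data.frame(mz = fr$mz, intensity = 1), "-")
    want <- expected_flags(nm, "-")
    expect_identical(got[comp_flags], want[comp_flags], label = nm)
  }
})

test_that("C/Z ions are off by default but available", {
  default <- glycosidic_fragments("GM3 18:1;O2/18:0", "-")
  expect_false(any(default$type %in% c("C", "Z")))
  with_cz <- glycosidic_fragments("GM3 18:1;O2/18:0", "-", include_cz = TRUE)
  expect_true(all(c("C", "Z") %in% with_cz$type))
  # C = B + H2O
  b1 <- with_cz$mz[with_cz$label == "B1"]
  c1 <- with_cz$mz[with_cz$label == "C1"]
  expect_equal(c1 - b1, ORACLE_H2O, tolerance = 1e-6)
})
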