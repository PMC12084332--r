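test_that("shorthand names parse to registry compositions", {
  gd1 <- parse_species("GD1 18:1;O2/18:0")
  expect_equal(gd1$class_name, "GD1")
  expect_equal(gd1$neu5ac, 2)
  expect_equal(gd1$hex, 3)
  expect_equal(gd1$hexnac, 1)
  expect_equal(gd1$base_c, 18)
  expect_equal(gd1$acyl_c, 18)

  shex2 <- parse_species("SHex2Cer 18:1;O2/16:0")
  expect_equal(shex2$hex, 2)
  expect_equal(shex2$sulfate, 1)
  expect_equal(shex2$neu5ac, 0)

  istd <- parse_species("GM3 18:1;O2/18:0-d5")
  expect_equal(istd$label_d, 5)

  legacy <- parse_species("GM3 d18:1/16:0")
  expect_equal(legacy$name, "GM3 18:1;O2/16:0")

  hydroxy <- parse_species("SHexCer 18:1;O3/16:0;O")
  expect_equal(hydroxy$acyl_oh, 1)
  expect_equal(hydroxy$base_oh, 3)
})

test_that("parse errors are informative", {
  expect_error(parse_species("NotAClass 18:1;O2/18:0"), "NotAClass")
  expect_error(parse_species("GM3 18:1;O2"), "base/acyl")
  expect_error(parse_species("GM3 18x1;O2/18:0"), "malformed")
  expect_error(parse_species("GM3 18:1;O2/8:0"), "range")
})

test_that("parse/format round-trips every fixture name", {
  names <- serum_fixture()$name
  expect_length(names, 376)
  expect_identical(format_species(parse_species(names)), names)
})

test_that("elemental formulas assemble additively", {
  cer <- ceramide_formula(18, 1, 2, 18, 0, 0)
  expect_identical(formula_string(cer), "C36H71NO3")

  gm1 <- species_formula("GM1 18:1;O2/18:0")
  expect_identical(gm1$formula, "C73H131N3O31")

  # residue additivity: HexCer X minus Cer X is exactly one Hex
  hexcer <- formula_parse(species_formula("HexCer 18:1;O2/18:0")$formula)[[1]]
  diff <- formula_subtract(hexcer, cer)
  expect_identical(formula_string(diff), "C6H10O5")
})

test_that("monoisotopic masses match independent atomic-mass sums", {
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C11H17NO8"), ORACLE_NEU5AC, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C11H17NO8"), 291.09542, tolerance = 1e-5)
  expect_equal(
    species_formula("GM1 18:1;O2/18:0")$mass, ORACLE_GM1_18_1_18_0,
    tolerance = 1e-9
  )
  expect_equal(species_formula("GM1 18:1;O2/18:0")$mass, 1545.8767,
    tolerance = 1e-4
  )
  expect_error(monoisotopic_mass("Xx2"), "unknown element")
})

test_that("ion m/z reproduces the printed reference values", {
  gd1 <- species_mz("GD1 18:1;O2/18:0", ion = "[M-2H]2-")
  expect_equal(round(gd1$mz, 2), 917.48)

  gm1 <- species_mz("GM1 18:1;O2/18:0", ion = "[M+HCOOH-2H]2-")
  expect_equal(round(gm1$mz, 2), 794.93)

  # definition: [M-H]- is M minus one proton
  m <- species_formula("GM3 18:1;O2/16:0")$mass
  expect_equal(species_mz("GM3 18:1;O2/16:0", ion = "[M-H]-")$mz,
    m - 1.007276,
    tolerance = 1e-10
  )
  expect_error(mz_from_mass(1000, "[M+4H]4+"), "unknown ion")
})

test_that("per-class default ion types follow the rules", {
  expect_equal(default_ion_type("GM3", "-"), "[M-H]1-")
  expect_equal(default_ion_type("GM2", "-"), "[M-H]1-")
  expect_equal(default_ion_type("GM1", "-"), "[M+HCOOH-2H]2-")
  expect_equal(default_ion_type("Neu5Ac-nLc4Cer", "-"), "[M+HCOOH-2H]2-")
  expect_equal(default_ion_type("GD1b", "-"), "[M-2H]2-")
  expect_equal(default_ion_type("GQ1b", "-"), "[M-2H]2-")
  expect_equal(default_ion_type("GP1", "-"), "[M-H2O-2H]2-")
  expect_equal(default_ion_type("HexCer", "-"), "[M-H]1-")
  expect_equal(default_ion_type("SHexCer", "+"), "[M+H]1+")
  expect_error(default_ion_type("GX9", "-"), "unknown")
})

test_that("mass additivity holds for every residue type", {
  pairs <- list(
    c("Hex2Cer 18:1;O2/16:0", "HexCer 18:1;O2/16:0", ORACLE_HEX),
    c("GM2 18:1;O2/18:0", "GM3 18:1;O2/18:0", ORACLE_HEXNAC),
    c("Fuc-GD1 18:1;O2/20:0", "GD1 18:1;O2/20:0", ORACLE_FUC),
    c("GD3 18:1;O2/18:0", "GM3 18:1;O2/18:0", ORACLE_NEU5AC),
    c("Neu5Gc-GM3 18:1;O2/18:0", "GM3 18:1;O2/18:0", ORACLE_NEU5GC - ORACLE_NEU5AC),
    c("SHexCer 18:1;O2/16:0", "HexCer 18:1;O2/16:0", ORACLE_SO3),
    c("OAc-GD1 18:1;O2/18:0", "GD1 18:1;O2/18:0", ORACLE_OAC)
  )
  for (p in pairs) {
    m1 <- species_formula(p[[1]])$mass
    m2 <- species_formula(p[[2]])$mass
    expect_equal(m1 - m2, as.numeric(p[[3]]), tolerance = 1e-4)
  }
  # frozen reference increments
  expect_equal(ORACLE_HEX, 162.05282, tolerance = 1e-5)
  expect_equal(ORACLE_HEXNAC, 203.07937, tolerance = 1e-5)
  expect_equal(ORACLE_FUC, 146.05791, tolerance = 1e-5)
  expect_equal(ORACLE_NEU5AC, 291.09542, tolerance = 1e-5)
  expect_equal(ORACLE_NEU5GC, 307.09033, tolerance = 1e-5)
  expect_equal(ORACLE_SO3, 79.95682, tolerance = 1e-5)
  expect_equal(ORACLE_OAC, 42.01057, tolerance = 1e-5)
})

test_that("doubly charged m/z is charge-consistent", {
  m <- species_formula("GD1 18:1;O2/18:0")$mass
  mz2 <- mz_from_mass(m, "[M-2H]2-")
  expect_equal(mz2 * 2, m - 2 * ORACLE_PROTON, tolerance = 1e-6)
  mzf <- mz_from_mass(m, "[M+HCOOH-2H]2-")
  expect_equal(mzf * 2, m + oracle_mass(C = 1, H = 2, O = 2) - 2 * ORACLE_PROTON,
    tolerance = 1e-6
  )
})

test_that("deuterium labels raise the mass by K x 1.006277", {
  for (k in c(3, 5, 9)) {
    lab <- species_formula(sprintf("GM3 18:1;O2/18:0-d%d", k))$mass
    unlab <- species_formula("GM3 18:1;O2/18:0")$mass
    expect_equal(lab - unlab, k * 1.006277, tolerance = 1e-5)
  }
})

test_that("formula arithmetic guards invariants", {
  expect_error(formula_subtract(c(C = 1), c(C = 2)), "negative")
  expect_equal(monoisotopic_mass(""), 0)
  expect_identical(
    formula_string(formula_add(c(C = 1, H = 4), c(O = 2))), "CH4O2"
  )
})

test_that("the exported class registry JSON mirrors the in-code registry", {
  path <- withr::local_tempfile(fileext = ".json")
  export_class_registry(path)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(reg$format, "gsl4d-class-registry")
  cls <- gsl_classes()
  expect_setequal(names(reg$classes), cls$class_name)
  gd1b <- reg$classes$GD1b
  expect_equal(gd1b$composition$neu5ac, 2)
  expect_equal(gd1b$default_ion_neg, "[M-2H]2-")
})
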