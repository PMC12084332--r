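## 4D reference-library data model: a library is a tibble with one row per
## (species, ion, polarity) carrying reference m/z, RT (min), CCS (A^2),
## fraction and provenance, plus an optional spectrum_ref key into a spectra
## table.

.LIBRARY_COLUMNS <- c(
  "name", "class_name", "series", "ion", "polarity", "charge", "mz",
  "rt_min", "ccs_A2", "fraction", "provenance", "spectrum_ref"
)

.validate_library <- function(lib) {
  missing <- setdiff(.LIBRARY_COLUMNS, names(lib))
  if (length(missing) > 0) {
    stop("library is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(lib$name, lib$ion, lib$polarity)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (species, ion, polarity) entries: ",
      paste(utils::head(dup, 5), collapse = "; "),
      call. = FALSE
    )
  }
  bad <- which(!is.na(lib$rt_min) & lib$rt_min <= 0 |
    !is.na(lib$ccs_A2) & lib$ccs_A2 <= 0)
  if (length(bad) > 0) {
    stop("non-positive RT or CCS in row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(lib)
}

#' Build a 4D library from annotated replicate runs
#'
#' Averages the measured descriptors of replicate runs per species: RT and
#' CCS become arithmetic means over runs, while the stored m/z is the
#' theoretical ion m/z of the species (placeholder species keep their
#' measured mean m/z).
#'
#' @param runs A data frame with one row per species per run: `name`
#'   (shorthand species name), `polarity`, `rt_min`, `ccs_A2`, and optionally
#'   `ion` (defaults to the class default for the polarity), `mz` (measured),
#'   `fraction`, `provenance`, `spectrum_ref`.
#' @return A library tibble (see [serum_fixture()] for the column layout).
#' @export
build_library <- function(runs) {
  stopifnot(is.data.frame(runs), all(c("name", "polarity", "rt_min", "ccs_A2") %in% names(runs)))
  pol_check <- runs |>
    dplyr::distinct(.data$name, .data$polarity) |>
    dplyr::count(.data$name)
  if (any(pol_check$n > 1)) {
    stop(
      "inconsistent polarity across runs for: ",
      paste(pol_check$name[pol_check$n > 1], collapse = ", "),
      call. = FALSE
    )
  }
  if (!"fraction" %in% names(runs)) runs$fraction <- NA_integer_
  if (!"provenance" %in% names(runs)) runs$provenance <- "standard"
  if (!"spectrum_ref" %in% names(runs)) runs$spectrum_ref <- NA_character_
  if (!"ion" %in% names(runs)) runs$ion <- NA_character_
  if (!"mz" %in% names(runs)) runs$mz <- NA_real_

  agg <- runs |>
    dplyr::group_by(.data$name, .data$polarity) |>
    dplyr::summarise(
      rt_min = mean(.data$rt_min),
      ccs_A2 = mean(.data$ccs_A2),
      mz_measured = mean(.data$mz),
      ion = dplyr::first(.data$ion),
      fraction = dplyr::first(.data$fraction),
      provenance = dplyr::first(.data$provenance),
      spectrum_ref = dplyr::first(.data$spectrum_ref),
      .groups = "drop"
    )
  sp <- parse_species(agg$name)
  out <- purrr::map_dfr(seq_len(nrow(agg)), function(i) {
    row <- agg[i, ]
    s <- sp[i, ]
    ion <- row$ion
    if (is.na(ion)) ion <- default_ion_type(s$class_name, row$polarity)
    mz <- if (s$placeholder) row$mz_measured else {
      mz_from_mass(species_formula(s)$mass, ion)
    }
    tibble::tibble(
      name = s$name, class_name = s$class_name, series = s$series,
      ion = .normalize_ion(ion), polarity = row$polarity,
      charge = ion_info(ion)$z, mz = mz,
      rt_min = row$rt_min, ccs_A2 = row$ccs_A2,
      fraction = row$fraction, provenance = row$provenance,
      spectrum_ref = row$spectrum_ref
    )
  })
  .validate_library(out)
  out
}

## ---------------------------------------------------------------------------
## Serum inventory: per-row (subclass, sphingoid base, acyl carbon range,
## double-bond range, hydroxylation range) species counts. The enumeration
## rule that fills each printed count from its range prefers even acyl
## carbons ascending, then odd, then further double-bond/hydroxyl variants.
.serum_rows <- function() {
  r <- function(class_name, base, c_lo, c_hi, db_lo, db_hi, oh_lo, oh_hi, n) {
    tibble::tibble(
      class_name = class_name, base = base, c_lo = c_lo, c_hi = c_hi,
      db_lo = db_lo, db_hi = db_hi, oh_lo = oh_lo, oh_hi = oh_hi, n = n
    )
  }
  u <- function(class_name, n) r(class_name, NA, NA, NA, NA, NA, NA, NA, n)
  dplyr::bind_rows(
    # gangliosides
    r("GM3", "18:0;O2", 14, 22, 0, 0, 0, 0, 5),
    r("GM3", "18:1;O2", 10, 26, 0, 3, 0, 0, 37),
    r("GM3", "18:0;O3", 16, 22, 0, 0, 0, 0, 2),
    r("GM3", "18:1;O3", 10, 24, 0, 2, 0, 0, 22),
    r("GM2", "18:1;O2", 16, 18, 0, 1, 0, 0, 3),
    r("GM1", "18:1;O2", 16, 18, 0, 0, 0, 0, 2),
    r("GD3", "18:0;O2", 16, 16, 0, 0, 0, 0, 1),
    r("GD3", "18:1;O2", 14, 24, 0, 2, 0, 0, 15),
    r("GD3", "18:1;O3", 16, 16, 0, 0, 0, 0, 1),
    r("GD2", "18:1;O2", 16, 24, 0, 1, 0, 0, 4),
    r("GD1", "18:0;O2", 16, 16, 0, 0, 0, 0, 1),
    r("GD1", "18:1;O2", 14, 24, 0, 2, 0, 0, 15),
    r("GD1", "18:1;O3", 16, 18, 0, 0, 0, 0, 2),
    r("GT1b", "18:0;O2", 16, 16, 0, 0, 0, 0, 1),
    r("GT1b", "18:1;O2", 14, 24, 0, 2, 0, 0, 12),
    r("GQ1b", "18:1;O2", 16, 18, 0, 0, 0, 0, 2),
    r("OAc-GD1", "18:1;O2", 16, 18, 0, 1, 0, 0, 3),
    r("Fuc-GD1", "18:1;O2", 20, 20, 0, 0, 0, 0, 1),
    # sialylated neolacto-series
    r("Neu5Ac-nLc4Cer", "18:1;O2", 14, 24, 0, 2, 0, 0, 10),
    r("Neu5Ac-nLc6Cer", "18:1;O2", 16, 24, 0, 2, 0, 0, 6),
    r("Neu5Ac-nLc8Cer", "18:1;O2", 16, 24, 0, 1, 0, 0, 3),
    r("Neu5Ac-nLc10Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Neu5Ac-Fuc-nLc6Cer", "18:1;O2", 16, 18, 0, 1, 0, 0, 3),
    r("Neu5Ac-Fuc-nLc8Cer", "18:1;O2", 16, 24, 0, 1, 0, 0, 3),
    r("Neu5Ac-Fuc-nLc10Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Neu5Ac-Fuc-nLc12Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Neu5Ac-Fuc2-nLc10Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Neu5Ac-Fuc2-nLc12Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    # neutral glycosphingolipids
    r("HexCer", "16:1;O2", 18, 24, 0, 1, 0, 1, 8),
    r("HexCer", "17:1;O2", 24, 24, 0, 0, 0, 0, 1),
    r("HexCer", "18:1;O2", 16, 24, 0, 2, 0, 1, 19),
    r("HexCer", "18:2;O2", 16, 24, 0, 1, 0, 1, 13),
    r("HexCer", "18:0;O3", 16, 24, 0, 1, 0, 1, 3),
    r("HexCer", "18:0;O4", 24, 24, 1, 1, 0, 0, 1),
    r("Hex2Cer", "16:1;O2", 14, 24, 0, 2, 0, 1, 11),
    r("Hex2Cer", "16:2;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Hex2Cer", "17:1;O2", 16, 24, 0, 1, 0, 0, 4),
    r("Hex2Cer", "17:2;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Hex2Cer", "18:0;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Hex2Cer", "18:1;O2", 12, 24, 0, 2, 0, 1, 19),
    r("Hex2Cer", "18:2;O2", 12, 24, 0, 2, 0, 1, 14),
    r("Hex2Cer", "18:1;O3", 16, 16, 0, 0, 0, 0, 1),
    u("Hex2Cer", 1),
    r("Hex3Cer", "16:1;O2", 12, 22, 0, 0, 0, 1, 6),
    r("Hex3Cer", "17:1;O2", 16, 18, 0, 0, 0, 0, 2),
    r("Hex3Cer", "18:0;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Hex3Cer", "18:1;O2", 10, 24, 0, 2, 0, 1, 13),
    r("Hex3Cer", "18:2;O2", 12, 24, 0, 1, 0, 1, 11),
    u("Hex3Cer", 1),
    r("HexNAcHex3Cer", "16:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("HexNAcHex3Cer", "17:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("HexNAcHex3Cer", "18:1;O2", 14, 24, 0, 1, 0, 0, 5),
    r("HexNAcHex3Cer", "18:2;O2", 16, 22, 0, 0, 0, 0, 2),
    u("HexNAcHex3Cer", 2),
    r("HexNAcHex4Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    r("Fuc-HexNAcHex3Cer", "18:1;O2", 16, 16, 0, 0, 0, 0, 1),
    # sulfatides
    r("SHexCer", "16:1;O2", 16, 24, 0, 1, 0, 1, 7),
    r("SHexCer", "17:1;O2", 16, 16, 0, 0, 0, 1, 2),
    r("SHexCer", "18:0;O2", 16, 16, 0, 0, 0, 1, 2),
    r("SHexCer", "18:1;O2", 14, 24, 0, 1, 0, 1, 17),
    r("SHexCer", "18:2;O2", 16, 24, 0, 1, 0, 1, 14),
    r("SHexCer", "16:0;O3", 18, 24, 0, 1, 0, 1, 3),
    r("SHexCer", "18:0;O3", 16, 24, 0, 1, 0, 1, 5),
    r("SHexCer", "18:1;O3", 16, 16, 0, 0, 1, 1, 1),
    r("SHexCer", "18:0;O4", 24, 24, 2, 2, 0, 0, 1),
    u("SHexCer", 6),
    r("SHex2Cer", "16:1;O2", 18, 18, 0, 0, 1, 1, 1),
    r("SHex2Cer", "18:1;O2", 16, 24, 0, 1, 0, 1, 5),
    r("SHex2Cer", "18:2;O2", 16, 24, 0, 1, 0, 0, 4),
    u("SHex2Cer", 4)
  )
}

## Enumerate exactly n ceramides for one inventory row.
.enumerate_row <- function(row) {
  carbons <- row$c_lo:row$c_hi
  carbons <- c(carbons[carbons %% 2 == 0], carbons[carbons %% 2 == 1])
  grid <- expand.grid(
    acyl_c = carbons, acyl_oh = row$oh_lo:row$oh_hi,
    acyl_db = row$db_lo:row$db_hi
  )
  # ordering: double bonds outermost, then hydroxyls, then even/odd carbons
  grid <- grid[order(grid$acyl_db, grid$acyl_oh, match(grid$acyl_c, carbons)), ]
  if (nrow(grid) < row$n) {
    stop("inventory row cannot fill ", row$n, " species", call. = FALSE)
  }
  grid <- grid[seq_len(row$n), ]
  sprintf(
    "%s %s/%d:%d%s", row$class_name, row$base, grid$acyl_c, grid$acyl_db,
    ifelse(grid$acyl_oh == 0, "", ifelse(grid$acyl_oh == 1, ";O", ";O2"))
  )
}

## Deterministic monotone descriptor model used for fixture RT/CCS. RT rises
## with acyl chain length and falls with unsaturation, hydroxylation and
## glycan length; CCS tracks mass with small per-topology offsets so that
## composition isomers (GM1 vs Neu5Ac-nLc4Cer, GD1a vs GD1b) stay resolved.
.fixture_rt <- function(sp) {
  n_res <- sp$hex + sp$hexnac + sp$dhex + sp$neu5ac + sp$neu5gc
  rt <- 1.5 + 0.45 * sp$acyl_c - 0.8 * sp$acyl_db - 0.5 * sp$acyl_oh +
    0.25 * (sp$base_c - 18) - 0.6 * sp$base_db - 0.4 * (sp$base_oh - 2) -
    0.22 * n_res - 0.35 * (sp$neu5ac + sp$neu5gc)
  pmax(rt, 0.5)
}

.CCS_CLASS_OFFSET <- c(
  "GD1a" = 5.6, "GD1" = 5.6, "GT1b" = 3.0, "GQ1b" = 3.0
)

.fixture_ccs <- function(sp, mass) {
  off <- ifelse(sp$series == "neolacto", -8,
    ifelse(sp$class_name %in% names(.CCS_CLASS_OFFSET),
      .CCS_CLASS_OFFSET[sp$class_name], 0
    )
  )
  162.5 + 0.16 * mass + 1.2 * sp$acyl_db + off
}

## Descriptor anchors measured on standards; they override the model.
.FIXTURE_ANCHORS <- tibble::tibble(
  name = "GD1b 18:1;O2/18:0", polarity = "-", ccs_A2 = 456.4
)

#' Packaged serum 4D library fixture
#'
#' Deterministically enumerates the serum glycosphingolipid inventory: for
#' each (subclass, sphingoid base, acyl-carbon range, double-bond range,
#' hydroxylation range) inventory row, exactly the recorded number of species
#' is generated by the documented enumeration rule (even acyl carbons
#' ascending, then odd, then further double-bond/hydroxyl variants).
#' Sialylated species (ganglio- and neolacto-series) sit in fraction 2 with
#' negative-mode default ions; neutral species and sulfatides sit in fraction
#' 1 in positive mode. RT and CCS are synthesized by a deterministic monotone
#' model (anchored to measured standards where available) and are fixture
#' descriptors for exercising matching logic, not reference values.
#' "Unidentified sphingoid base" inventory rows become placeholder entries
#' with counts but no mass.
#'
#' @return A library tibble with columns `name`, `class_name`, `series`,
#'   `ion`, `polarity`, `charge`, `mz`, `rt_min`, `ccs_A2`, `fraction`,
#'   `provenance`, `spectrum_ref`.
#' @examples
#' lib <- serum_fixture()
#' nrow(lib) # 376
#' @export
serum_fixture <- function() {
  rows <- .serum_rows()
  names <- unlist(lapply(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    if (is.na(row$base)) {
      sprintf("%s unidentified %d", row$class_name, seq_len(row$n))
    } else {
      .enumerate_row(row)
    }
  }))
  sp <- species_formula(parse_species(names))
  fraction <- ifelse(sp$series %in% c("ganglio", "neolacto"), 2L, 1L)
  polarity <- ifelse(fraction == 2L, "-", "+")
  ion <- vapply(seq_len(nrow(sp)), function(i) {
    default_ion_type(sp$class_name[i], polarity[i])
  }, character(1))
  mz <- ifelse(is.na(sp$mass), NA_real_,
    vapply(seq_len(nrow(sp)), function(i) {
      if (is.na(sp$mass[i])) NA_real_ else mz_from_mass(sp$mass[i], ion[i])
    }, numeric(1))
  )
  ccs <- ifelse(is.na(sp$mass), NA_real_, .fixture_ccs(sp, sp$mass))
  rt <- ifelse(sp$placeholder, NA_real_, .fixture_rt(sp))
  lib <- tibble::tibble(
    name = sp$name, class_name = sp$class_name, series = sp$series,
    ion = ion, polarity = polarity,
    charge = vapply(ion, function(x) ion_info(x)$z, integer(1)),
    mz = mz, rt_min = rt, ccs_A2 = ccs,
    fraction = fraction, provenance = "fixture",
    spectrum_ref = NA_character_
  )
  for (i in seq_len(nrow(.FIXTURE_ANCHORS))) {
    a <- .FIXTURE_ANCHORS[i, ]
    hit <- lib$name == a$name & lib$polarity == a$polarity
    lib$ccs_A2[hit] <- a$ccs_A2
  }
  .validate_library(lib)
  lib
}

#' Per-class library statistics
#'
#' @param lib A library tibble.
#' @return A tibble with `class_name`, `series`, `n_entries`.
#' @export
library_stats <- function(lib) {
  .validate_library(lib)
  lib |>
    dplyr::count(.data$series, .data$class_name, name = "n_entries") |>
    dplyr::arrange(.data$series, dplyr::desc(.data$n_entries))
}

#' Save / load a 4D library
#'
#' TSV (columns as in [serum_fixture()]) or JSON, chosen by file extension.
#' The save/load round trip is lossless; loading validates the schema and
#' errors on duplicate (species, ion, polarity) rows.
#'
#' @param lib A library tibble.
#' @param path File path ending in `.tsv` or `.json`.
#' @return `save_library()` returns `path` invisibly; `load_library()`
#'   returns the library tibble.
#' @export
save_library <- function(lib, path) {
  .validate_library(lib)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(format = "gsl4d-library", version = 1L, entries = lib),
      path,
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    utils::write.table(lib, path,
      sep = "\t", row.names = FALSE, quote = FALSE, na = ""
    )
  }
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  lib <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tibble::as_tibble(obj$entries)
  } else {
    tibble::as_tibble(utils::read.delim(path,
      sep = "\t", stringsAsFactors = FALSE, na.strings = c("NA", "")
    ))
  }
  num_cols <- c("mz", "rt_min", "ccs_A2")
  for (cc in num_cols) lib[[cc]] <- as.numeric(lib[[cc]])
  lib$charge <- as.integer(lib$charge)
  lib$fraction <- as.integer(lib$fraction)
  if (!"spectrum_ref" %in% names(lib)) lib$spectrum_ref <- NA_character_
  lib$spectrum_ref <- as.character(lib$spectrum_ref)
  .validate_library(lib)
  lib
}
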