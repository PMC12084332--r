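## Shorthand nomenclature: "<class> <base>/<acyl>[-dK]", where the sphingoid
## base is "c:d;On" (legacy "d18:1" / "t18:0" accepted) and the fatty acyl is
## "x:y" with optional ";O"/";O2" hydroxylation and optional "-dK" deuterium
## label. Placeholder rows ("<class> unidentified") carry counts but no mass.

.parse_base <- function(s, name) {
  m <- regmatches(s, regexec("^(\\d+):(\\d+);O(\\d+)$", s))[[1]]
  if (length(m) == 0) {
    m2 <- regmatches(s, regexec("^([dt])(\\d+):(\\d+)$", s))[[1]]
    if (length(m2) == 0) {
      stop(
        "malformed sphingoid base '", s, "' in '", name,
        "' (expected e.g. 18:1;O2)",
        call. = FALSE
      )
    }
    return(list(
      c = as.integer(m2[3]), db = as.integer(m2[4]),
      oh = if (m2[2] == "d") 2L else 3L
    ))
  }
  list(c = as.integer(m[2]), db = as.integer(m[3]), oh = as.integer(m[4]))
}

.parse_acyl <- function(s, name) {
  m <- regmatches(s, regexec("^(\\d+):(\\d+)(;O(\\d*))?$", s))[[1]]
  if (length(m) == 0) {
    stop(
      "malformed fatty acyl '", s, "' in '", name, "' (expected e.g. 18:0)",
      call. = FALSE
    )
  }
  oh <- 0L
  if (nzchar(m[4])) oh <- if (nzchar(m[5])) as.integer(m[5]) else 1L
  list(c = as.integer(m[2]), db = as.integer(m[3]), oh = oh)
}

.check_ceramide <- function(base, acyl, name) {
  ok <- base$c >= 14 && base$c <= 26 && base$db >= 0 && base$db <= 3 &&
    base$oh >= 2 && base$oh <= 4 &&
    acyl$c >= 10 && acyl$c <= 26 && acyl$db >= 0 && acyl$db <= 3 &&
    acyl$oh >= 0 && acyl$oh <= 2
  if (!ok) {
    stop("ceramide out of supported range in '", name, "'", call. = FALSE)
  }
}

.parse_one_species <- function(name) {
  name <- trimws(name)
  sp <- regmatches(name, regexec("^(\\S+)\\s+(\\S.*)$", name))[[1]]
  if (length(sp) == 0) {
    stop("cannot split '", name, "' into class and ceramide", call. = FALSE)
  }
  cls <- sp[2]
  entry <- .class_entry(cls) # errors on unknown class token
  cer <- sp[3]

  if (grepl("^[Uu]nidentified", cer)) {
    return(tibble::tibble(
      class_name = cls, placeholder = TRUE, placeholder_label = cer,
      base_c = NA_integer_, base_db = NA_integer_, base_oh = NA_integer_,
      acyl_c = NA_integer_, acyl_db = NA_integer_, acyl_oh = NA_integer_,
      label_d = 0L
    ))
  }

  label_d <- 0L
  lm <- regmatches(cer, regexec("-d(\\d+)$", cer))[[1]]
  if (length(lm) > 0) {
    label_d <- as.integer(lm[2])
    cer <- sub("-d\\d+$", "", cer)
  }
  halves <- strsplit(cer, "/", fixed = TRUE)[[1]]
  if (length(halves) != 2) {
    stop(
      "malformed ceramide '", cer, "' in '", name,
      "' (expected base/acyl)",
      call. = FALSE
    )
  }
  base <- .parse_base(halves[1], name)
  acyl <- .parse_acyl(halves[2], name)
  .check_ceramide(base, acyl, name)
  if (label_d > acyl$c * 2) {
    stop("deuterium label exceeds available positions in '", name, "'",
      call. = FALSE
    )
  }
  tibble::tibble(
    class_name = cls, placeholder = FALSE, placeholder_label = NA_character_,
    base_c = base$c, base_db = base$db, base_oh = base$oh,
    acyl_c = acyl$c, acyl_db = acyl$db, acyl_oh = acyl$oh,
    label_d = label_d
  )
}

#' Parse glycosphingolipid shorthand names
#'
#' Parses shorthand species names such as `"GD1 18:1;O2/18:0"`,
#' `"SHex2Cer 18:1;O2/16:0"` or the deuterated internal standard
#' `"GM3 18:1;O2/18:0-d5"`. The legacy `d18:1`/`t18:0` sphingoid dialect is
#' accepted on input; [format_species()] always emits the `;On` dialect.
#'
#' @param name Character vector of shorthand names.
#' @return A tibble with one row per name: `name` (canonical form),
#'   `class_name`, `series`, ceramide descriptors (`base_c`, `base_db`,
#'   `base_oh`, `acyl_c`, `acyl_db`, `acyl_oh`, `label_d`), glycan composition
#'   counts (`hex`, `hexnac`, `dhex`, `neu5ac`, `neu5gc`, `sulfate`, `oac`)
#'   and `placeholder` (TRUE for "unidentified" ceramide rows).
#' @examples
#' parse_species(c("GD1 18:1;O2/18:0", "SHex2Cer 18:1;O2/16:0"))
#' @export
parse_species <- function(name) {
  stopifnot(is.character(name))
  if (length(name) == 0) {
    return(tibble::tibble(
      name = character(0), class_name = character(0), series = character(0),
      placeholder = logical(0), placeholder_label = character(0),
      base_c = integer(0), base_db = integer(0), base_oh = integer(0),
      acyl_c = integer(0), acyl_db = integer(0), acyl_oh = integer(0),
      label_d = integer(0), hex = numeric(0), hexnac = numeric(0),
      dhex = numeric(0), neu5ac = numeric(0), neu5gc = numeric(0),
      sulfate = numeric(0), oac = numeric(0)
    ))
  }
  rows <- purrr::map_dfr(name, .parse_one_species)
  comp <- purrr::map_dfr(rows$class_name, function(cls) {
    e <- .class_entry(cls)
    as.data.frame(as.list(.topo_composition(e$topology)))
  })
  total_mono <- comp$hex + comp$hexnac + comp$dhex + comp$neu5ac + comp$neu5gc
  stopifnot(all(total_mono <= 15))
  out <- dplyr::bind_cols(rows, tibble::as_tibble(comp))
  out$series <- vapply(out$class_name, function(cls) .class_entry(cls)$series,
    character(1)
  )
  out$name <- format_species(out)
  dplyr::select(
    out, "name", "class_name", "series", "placeholder", "placeholder_label",
    "base_c", "base_db", "base_oh", "acyl_c", "acyl_db", "acyl_oh",
    "label_d", "hex", "hexnac", "dhex", "neu5ac", "neu5gc", "sulfate", "oac"
  )
}

#' Format species rows as canonical shorthand names
#'
#' The canonical dialect writes the sphingoid base as `c:d;On`, a single acyl
#' hydroxyl as `;O`, two as `;O2`, and the deuterium label as `-dK`.
#' `format_species(parse_species(x))` returns the canonical form of `x`.
#'
#' @param species A data frame with the ceramide descriptor columns produced
#'   by [parse_species()].
#' @return Character vector of shorthand names.
#' @export
format_species <- function(species) {
  stopifnot(is.data.frame(species))
  vapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    if (isTRUE(s$placeholder)) {
      lbl <- if ("placeholder_label" %in% names(s) && !is.na(s$placeholder_label)) {
        s$placeholder_label
      } else {
        "unidentified"
      }
      return(paste(s$class_name, lbl))
    }
    acyl <- sprintf("%d:%d", s$acyl_c, s$acyl_db)
    if (s$acyl_oh == 1) acyl <- paste0(acyl, ";O")
    if (s$acyl_oh >= 2) acyl <- paste0(acyl, ";O", s$acyl_oh)
    lab <- if (s$label_d > 0) sprintf("-d%d", s$label_d) else ""
    sprintf(
      "%s %d:%d;O%d/%s%s", s$class_name, s$base_c, s$base_db, s$base_oh,
      acyl, lab
    )
  }, character(1))
}

## Free sphingoid base formula C_c H_(2c-2d+3) N O_n.
.base_formula <- function(c, db, oh) {
  c(C = c, H = 2 * c - 2 * db + 3, N = 1, O = oh)
}

## Free fatty acid formula C_x H_(2x-2y) O_(2+h).
.acyl_formula <- function(c, db, oh) {
  c(C = c, H = 2 * c - 2 * db, O = 2 + oh)
}

#' Elemental formula of a ceramide
#'
#' Ceramide = sphingoid base + fatty acid - H2O (amide condensation); a
#' deuterium label `-dK` substitutes K hydrogens by deuterium.
#'
#' @param base_c,base_db,base_oh Sphingoid base carbons, double bonds and
#'   oxygens (the `;On` suffix).
#' @param acyl_c,acyl_db,acyl_oh Fatty acyl carbons, double bonds, hydroxyls.
#' @param label_d Number of deuterium substitutions (0 for unlabelled).
#' @return A named numeric vector of element counts.
#' @examples
#' formula_string(ceramide_formula(18, 1, 2, 18, 0, 0))
#' @export
ceramide_formula <- function(base_c, base_db, base_oh, acyl_c, acyl_db,
                             acyl_oh = 0, label_d = 0) {
  f <- formula_subtract(
    formula_add(
      .base_formula(base_c, base_db, base_oh),
      .acyl_formula(acyl_c, acyl_db, acyl_oh)
    ),
    c(H = 2, O = 1)
  )
  if (label_d > 0) {
    if (label_d > f[["H"]]) stop("label exceeds hydrogen count", call. = FALSE)
    f <- formula_add(formula_subtract(f, c(H = label_d)), c(D = label_d))
  }
  f
}

#' Elemental formulas of species
#'
#' Assembles each species' molecular formula as ceramide + anhydro residue
#' formulas + modification formulas (SO3 per sulfate, C2H2O per O-acetyl), and
#' appends `formula` and `mass` (monoisotopic, Da) columns. Placeholder
#' species get `NA`.
#'
#' @param species A species tibble from [parse_species()], or a character
#'   vector of shorthand names.
#' @return The input tibble with `formula` and `mass` columns added.
#' @examples
#' parse_species("GM1 18:1;O2/18:0") |> species_formula()
#' @export
species_formula <- function(species) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(is.data.frame(species))
  fm <- vapply(seq_len(nrow(species)), function(i) {
    s <- species[i, ]
    if (isTRUE(s$placeholder)) {
      return(NA_character_)
    }
    f <- ceramide_formula(
      s$base_c, s$base_db, s$base_oh, s$acyl_c, s$acyl_db, s$acyl_oh,
      s$label_d
    )
    glycan <- list(
      Hex = s$hex, HexNAc = s$hexnac, dHex = s$dhex,
      Neu5Ac = s$neu5ac, Neu5Gc = s$neu5gc
    )
    for (r in names(glycan)) {
      if (glycan[[r]] > 0) {
        f <- formula_add(f, .RESIDUE_FORMULA[[r]] * glycan[[r]])
      }
    }
    if (s$sulfate > 0) f <- formula_add(f, .MOD_FORMULA$sulfate * s$sulfate)
    if (s$oac > 0) f <- formula_add(f, .MOD_FORMULA$oac * s$oac)
    formula_string(f)
  }, character(1))
  species$formula <- fm
  species$mass <- ifelse(is.na(fm), NA_real_, monoisotopic_mass(ifelse(is.na(fm), "", fm)))
  species
}

#' Ion m/z of species
#'
#' Appends `ion`, `polarity`, `charge` and `mz` columns. With `ion = NULL`
#' each species gets its class default ion type for the requested polarity
#' (see [default_ion_type()]).
#'
#' @param species A species tibble (from [parse_species()], with or without
#'   `mass`), or a character vector of names.
#' @param ion Ion type label applied to all rows, or `NULL` for per-class
#'   defaults.
#' @param polarity `"-"` or `"+"`; used only when `ion` is `NULL`.
#' @return The input tibble with ion columns added.
#' @examples
#' species_mz("GD1 18:1;O2/18:0", ion = "[M-2H]2-")
#' @export
species_mz <- function(species, ion = NULL, polarity = "-") {
  if (is.character(species)) species <- parse_species(species)
  if (!"mass" %in% names(species)) species <- species_formula(species)
  ions <- if (is.null(ion)) {
    vapply(species$class_name, default_ion_type, character(1),
      polarity = polarity
    )
  } else {
    rep_len(.normalize_ion(ion), nrow(species))
  }
  info <- lapply(ions, ion_info)
  species$ion <- vapply(info, `[[`, character(1), "ion")
  species$polarity <- vapply(info, `[[`, character(1), "polarity")
  species$charge <- vapply(info, `[[`, integer(1), "z")
  species$mz <- vapply(seq_len(nrow(species)), function(i) {
    if (is.na(species$mass[i])) {
      return(NA_real_)
    }
    mz_from_mass(species$mass[i], species$ion[i])
  }, numeric(1))
  species
}
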