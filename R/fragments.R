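## In-silico glycosidic and ceramide fragmentation. All fragment ions are
## generated singly charged; the diagnostic rules operate on singly charged
## nominal masses.

## round half away from zero (nominal fragment masses)
.nominal <- function(mz) {
  sign(mz) * floor(abs(mz) + 0.5)
}

## subtree residue indices rooted at idx (inclusive)
.subtree <- function(topo, idx) {
  members <- idx
  repeat {
    more <- topo$idx[topo$parent %in% members & !topo$idx %in% members]
    if (length(more) == 0) {
      return(sort(members))
    }
    members <- c(members, more)
  }
}

## neutral formula of a set of topology rows (anhydro residues + mods)
.rows_formula <- function(topo_rows) {
  f <- stats::setNames(numeric(0), character(0))
  for (i in seq_len(nrow(topo_rows))) {
    f <- formula_add(f, .RESIDUE_FORMULA[[topo_rows$residue[i]]])
    if (topo_rows$oac[i] > 0) {
      f <- formula_add(f, .MOD_FORMULA$oac * topo_rows$oac[i])
    }
    if (topo_rows$sulfate[i] > 0) {
      f <- formula_add(f, .MOD_FORMULA$sulfate * topo_rows$sulfate[i])
    }
  }
  f
}

.species_row <- function(species) {
  if (is.character(species)) species <- parse_species(species)
  stopifnot(is.data.frame(species), nrow(species) == 1)
  if (!"mass" %in% names(species)) species <- species_formula(species)
  species
}

#' In-silico glycosidic fragments of a species
#'
#' Generates singly charged B and Y ions at every glycosidic bond of the
#' class topology tree (branch-aware: cleaving a branch bond yields the whole
#' branch as the B ion). Modifications (O-acetyl, sulfate) ride with the
#' residue that carries them. B ions are the non-reducing-side fragments
#' (oxonium in positive mode, deprotonated in negative mode); Y ions retain
#' the ceramide. C (`B + H2O`) and Z (`Y - H2O`) variants can be added with
#' `include_cz = TRUE` but take part in no diagnostic rule.
#'
#' @param species A single-row species tibble or one shorthand name.
#' @param polarity `"-"` (default) or `"+"`.
#' @param include_cz Also emit C/Z ions (default `FALSE`).
#' @return A tibble with columns `label`, `type`, `bond`, `formula` (neutral
#'   fragment formula), `mz`, `nominal`, `polarity`.
#' @examples
#' glycosidic_fragments("GD1b 18:1;O2/18:0")
#' @export
glycosidic_fragments <- function(species, polarity = "-", include_cz = FALSE) {
  s <- .species_row(species)
  if (isTRUE(s$placeholder)) {
    stop("placeholder species has no topology-resolved ceramide", call. = FALSE)
  }
  topo <- class_topology(s$class_name)
  if (nrow(topo) == 0) stop("species topology missing", call. = FALSE)
  M <- s$mass
  q <- if (polarity == "+") 1 else -1

  rows <- purrr::map_dfr(topo$idx, function(i) {
    sub <- topo[topo$idx %in% .subtree(topo, i), ]
    b_f <- .rows_formula(sub)
    b_mass <- monoisotopic_mass(list(b_f))
    y_mass <- M - b_mass
    tibble::tibble(
      label = c(sprintf("B%d", i), sprintf("Y%d", i)),
      type = c("B", "Y"),
      bond = i,
      formula = c(formula_string(b_f), NA_character_),
      neutral_mass = c(b_mass, y_mass)
    )
  })
  if (include_cz) {
    h2o <- .H2O_MASS
    cz <- rows |>
      dplyr::mutate(
        label = ifelse(.data$type == "B", sub("^B", "C", .data$label),
          sub("^Y", "Z", .data$label)
        ),
        type = ifelse(.data$type == "B", "C", "Z"),
        neutral_mass = .data$neutral_mass +
          ifelse(.data$type == "C", h2o, -h2o),
        formula = NA_character_
      )
    rows <- dplyr::bind_rows(rows, cz)
  }
  # sulfatides: the sulfate-loss ion and the bisulfate reporter
  if (polarity == "-" && sum(topo$sulfate) > 0) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      label = c("[M-SO3]", "HSO4"),
      type = c("sulfate_loss", "sulfate"),
      bond = NA_integer_,
      formula = c(NA_character_, "HO4S"),
      neutral_mass = c(
        M - monoisotopic_mass(list(.MOD_FORMULA$sulfate)),
        monoisotopic_mass(list(.MOD_FORMULA$sulfate)) + .H2O_MASS
      )
    ))
  }
  rows |>
    dplyr::mutate(
      mz = .data$neutral_mass + q * PROTON_MASS,
      nominal = .nominal(.data$mz),
      polarity = polarity
    ) |>
    dplyr::select("label", "type", "bond", "formula", "mz", "nominal", "polarity")
}

#' Ceramide fragment ions (positive mode)
#'
#' Emits the sphingoid-base diagnostic ions `[base + H - 2 H2O]+` (nominal 264
#' for an 18:1;O2 base, 262 for 18:2;O2) and `[base + H - H2O]+`, plus the
#' precursor neutral-loss ions of the fatty acyl chain (loss of the free fatty
#' acid and of its ketene).
#'
#' @param species A single-row species tibble or one shorthand name.
#' @return A tibble with columns `label`, `type`, `mz`, `nominal`, `polarity`.
#' @examples
#' ceramide_fragments("GM3 18:1;O2/18:0")
#' @export
ceramide_fragments <- function(species) {
  s <- .species_row(species)
  if (isTRUE(s$placeholder)) {
    stop("placeholder species has no defined ceramide", call. = FALSE)
  }
  base_mass <- monoisotopic_mass(list(
    .base_formula(s$base_c, s$base_db, s$base_oh)
  ))
  acid_mass <- monoisotopic_mass(list(
    .acyl_formula(s$acyl_c, s$acyl_db, s$acyl_oh)
  )) + s$label_d * (.ATOMIC_MASS[["D"]] - .ATOMIC_MASS[["H"]])
  prec <- s$mass + PROTON_MASS
  out <- tibble::tibble(
    label = c(
      sprintf("Sph(%d:%d;O%d)-2H2O", s$base_c, s$base_db, s$base_oh),
      sprintf("Sph(%d:%d;O%d)-H2O", s$base_c, s$base_db, s$base_oh),
      "[M+H-FA]", "[M+H-FA+H2O]"
    ),
    type = c("sphingoid", "sphingoid", "acyl_loss", "acyl_loss"),
    mz = c(
      base_mass + PROTON_MASS - 2 * .H2O_MASS,
      base_mass + PROTON_MASS - .H2O_MASS,
      prec - acid_mass,
      prec - (acid_mass - .H2O_MASS)
    )
  )
  out$nominal <- .nominal(out$mz)
  out$polarity <- "+"
  out
}

#' Diagnostic fragment-ion catalog
#'
#' Exact and nominal masses of the diagnostic ions used for glycosphingolipid
#' screening, all computed from atomic masses at run time. Negative mode:
#' the deprotonated Neu5Ac B ion (nominal 290), the disialo Neu5Ac2 B ion
#' (581), the O-acetyl-Neu5Ac B ion (332), the Neu5Gc B ion (306) and the
#' sulfate signature `HSO4-` (97). Positive mode: the Neu5Ac oxonium minus
#' water (274) and the 18:1;O2 / 18:2;O2 sphingoid ions (264 / 262). Neutral
#' losses of one hexose (162.0528) and of free lactose (342.1162) are listed
#' as `type = "neutral_loss"` and are matched against precursor - peak.
#'
#' @param polarity `"-"` or `"+"`.
#' @return A tibble with columns `flag`, `type`, `mz`, `nominal`.
#' @examples
#' diagnostic_catalog("-")
#' @export
diagnostic_catalog <- function(polarity = "-") {
  neu5ac <- monoisotopic_mass(list(.RESIDUE_FORMULA$Neu5Ac))
  neu5gc <- monoisotopic_mass(list(.RESIDUE_FORMULA$Neu5Gc))
  hex <- monoisotopic_mass(list(.RESIDUE_FORMULA$Hex))
  oac <- monoisotopic_mass(list(.MOD_FORMULA$oac))
  so3 <- monoisotopic_mass(list(.MOD_FORMULA$sulfate))
  sph <- function(db) {
    monoisotopic_mass(list(.base_formula(18, db, 2))) + PROTON_MASS -
      2 * .H2O_MASS
  }
  out <- if (polarity == "-") {
    tibble::tibble(
      flag = c(
        "sialylated_neg", "disialo_element", "o_acetyl_sialic", "neu5gc",
        "sulfate_signature", "hex_loss", "hex2_loss", "sulfate_loss"
      ),
      type = c(rep("peak", 5), rep("neutral_loss", 3)),
      mz = c(
        neu5ac - PROTON_MASS,
        2 * neu5ac - PROTON_MASS,
        neu5ac + oac - PROTON_MASS,
        neu5gc - PROTON_MASS,
        so3 + .H2O_MASS - PROTON_MASS, # HSO4-
        hex,
        hex * 2 + .H2O_MASS, # free lactose C12H22O11
        so3
      )
    )
  } else {
    tibble::tibble(
      flag = c(
        "sialylated_pos", "sphingoid_18_1", "sphingoid_18_2",
        "hex_loss", "hex2_loss"
      ),
      type = c(rep("peak", 3), rep("neutral_loss", 2)),
      mz = c(
        neu5ac + PROTON_MASS - .H2O_MASS,
        sph(1), sph(2),
        hex,
        hex * 2 + .H2O_MASS
      )
    )
  }
  out$nominal <- .nominal(out$mz)
  out$polarity <- polarity
  out
}

.ALL_FLAGS <- c(
  "sialylated_neg", "sialylated_pos", "disialo_element", "o_acetyl_sialic",
  "neu5gc", "sphingoid_18_1", "sphingoid_18_2", "hex_loss", "hex2_loss",
  "sulfate_signature"
)

#' Screen an MS/MS spectrum for diagnostic ions
#'
#' Sets a flag iff some peak lies within the fragment tolerance of a catalog
#' exact m/z; neutral-loss entries are tested against `precursor_mz - peak`
#' (and require `precursor_mz`). An empty spectrum sets no flags. The sulfate
#' signature fires on either the `HSO4-` peak or an SO3 neutral loss.
#'
#' @param spectrum A data frame with columns `mz` and `intensity` (intensity
#'   optional for screening), or a two-column matrix.
#' @param polarity `"-"` or `"+"`.
#' @param fragment_tol_mDa Fragment match tolerance in mDa (default 10).
#' @param precursor_mz Optional precursor m/z for neutral-loss rules (singly
#'   charged convention).
#' @return A one-row tibble of logical flags: `sialylated_neg`,
#'   `sialylated_pos`, `disialo_element`, `o_acetyl_sialic`, `neu5gc`,
#'   `sphingoid_18_1`, `sphingoid_18_2`, `hex_loss`, `hex2_loss`,
#'   `sulfate_signature`.
#' @examples
#' classify_spectrum(data.frame(mz = 290.088, intensity = 100), "-")
#' @export
classify_spectrum <- function(spectrum, polarity = "-", fragment_tol_mDa = 10,
                              precursor_mz = NULL) {
  flags <- stats::setNames(rep(FALSE, length(.ALL_FLAGS)), .ALL_FLAGS)
  peaks <- if (is.data.frame(spectrum)) spectrum$mz else spectrum[, 1]
  if (length(peaks) > 0) {
    tol <- fragment_tol_mDa / 1000
    cat_tbl <- diagnostic_catalog(polarity)
    for (i in seq_len(nrow(cat_tbl))) {
      fl <- cat_tbl$flag[i]
      hit <- if (cat_tbl$type[i] == "peak") {
        any(abs(peaks - cat_tbl$mz[i]) <= tol)
      } else if (!is.null(precursor_mz)) {
        any(abs((precursor_mz - peaks) - cat_tbl$mz[i]) <= tol)
      } else {
        FALSE
      }
      if (fl == "sulfate_loss") {
        if (hit) flags[["sulfate_signature"]] <- TRUE
      } else if (fl %in% names(flags)) {
        flags[[fl]] <- flags[[fl]] || hit
      }
    }
  }
  tibble::as_tibble(as.list(flags))
}

#' Flags implied by a species' composition
#'
#' The diagnostic flags a (noise-free) spectrum of the species' own fragments
#' is expected to set: Neu5Ac > 0 implies the sialylated flag for the
#' polarity; two adjacent Neu5Ac in the topology imply the disialo element;
#' Neu5Gc and O-acetyl counts imply their flags; an 18:1/18:2 sphingoid base
#' implies the positive-mode sphingoid ion.
#'
#' @param species A single-row species tibble or one shorthand name.
#' @param polarity `"-"` or `"+"`.
#' @return A one-row tibble of logical flags (same columns as
#'   [classify_spectrum()]).
#' @export
expected_flags <- function(species, polarity = "-") {
  s <- .species_row(species)
  topo <- class_topology(s$class_name)
  adjacent_disialo <- any(vapply(seq_len(nrow(topo)), function(i) {
    topo$residue[i] == "Neu5Ac" && topo$parent[i] > 0 &&
      topo$residue[topo$parent[i]] == "Neu5Ac"
  }, logical(1)))
  n_sia <- s$neu5ac + s$neu5gc
  flags <- stats::setNames(rep(FALSE, length(.ALL_FLAGS)), .ALL_FLAGS)
  if (polarity == "-") {
    flags[["sialylated_neg"]] <- s$neu5ac > 0
    flags[["disialo_element"]] <- adjacent_disialo
    flags[["o_acetyl_sialic"]] <- s$oac > 0 && n_sia > 0
    flags[["neu5gc"]] <- s$neu5gc > 0
    flags[["sulfate_signature"]] <- s$sulfate > 0
  } else {
    flags[["sialylated_pos"]] <- s$neu5ac > 0
    flags[["sphingoid_18_1"]] <-
      !isTRUE(s$placeholder) && s$base_c == 18 && s$base_db == 1 && s$base_oh == 2
    flags[["sphingoid_18_2"]] <-
      !isTRUE(s$placeholder) && s$base_c == 18 && s$base_db == 2 && s$base_oh == 2
  }
  tibble::as_tibble(as.list(flags))
}
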