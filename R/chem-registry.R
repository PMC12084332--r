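## Anhydro residue formulas (as incorporated in a glycan chain) and the two
## residue-level modifications.
.RESIDUE_FORMULA <- list(
  Hex = c(C = 6, H = 10, O = 5),
  HexNAc = c(C = 8, H = 13, N = 1, O = 5),
  dHex = c(C = 6, H = 10, O = 4),
  Neu5Ac = c(C = 11, H = 17, N = 1, O = 8),
  Neu5Gc = c(C = 11, H = 17, N = 1, O = 9)
)
.MOD_FORMULA <- list(
  sulfate = c(S = 1, O = 3),
  oac = c(C = 2, H = 2, O = 1)
)

#' Monosaccharide residue masses
#'
#' Monoisotopic masses of the anhydro residues and modifications used in
#' glycosphingolipid glycans.
#'
#' @return A tibble with columns `residue`, `formula`, `mass`.
#' @export
residue_masses <- function() {
  all <- c(.RESIDUE_FORMULA, .MOD_FORMULA)
  tibble::tibble(
    residue = names(all),
    formula = formula_string(all),
    mass = monoisotopic_mass(all)
  )
}

## ---------------------------------------------------------------------------
## Glycan topology construction. A topology is a tibble of residues with
## columns: idx, residue, parent (0 = ceramide), oac (count), sulfate (count).
## Bond i is the glycosidic bond between residue i and its parent; cleaving it
## yields the subtree rooted at i as the B ion and the remainder as the Y ion.
.topo <- function(residue, parent, oac = 0, sulfate = 0) {
  n <- length(residue)
  tibble::tibble(
    idx = seq_len(n), residue = residue, parent = as.integer(parent),
    oac = rep_len(oac, n), sulfate = rep_len(sulfate, n)
  )
}

## Ganglio-series core up to the tetraose (Gal-GalNAc-Gal-Glc-Cer), with
## n_inner sialic acids chained on the inner Gal and n_term on the terminal
## Gal. depth: 1 = lactosyl only (GM3/GD3 style cores), 2 = + GalNAc,
## 3 = + terminal Gal.
.ganglio_topo <- function(depth, n_inner, n_term = 0) {
  res <- c("Hex", "Hex")
  par <- c(0L, 1L)
  inner_gal <- 2L
  if (depth >= 2) {
    res <- c(res, "HexNAc")
    par <- c(par, inner_gal)
  }
  term <- NA_integer_
  if (depth >= 3) {
    res <- c(res, "Hex")
    par <- c(par, 3L)
    term <- 4L
  }
  # inner sialic chain
  p <- inner_gal
  for (i in seq_len(n_inner)) {
    res <- c(res, "Neu5Ac")
    par <- c(par, p)
    p <- length(res)
  }
  if (n_term > 0) {
    p <- term
    for (i in seq_len(n_term)) {
      res <- c(res, "Neu5Ac")
      par <- c(par, p)
      p <- length(res)
    }
  }
  .topo(res, par)
}

## Neolacto chain nLc{2k}: Glc-Gal then (GlcNAc-Gal) repeats; n_sia Neu5Ac on
## terminal Gal; n_fuc fucoses on the outermost GlcNAc residues.
.nlc_topo <- function(n_core, n_sia = 1, n_fuc = 0) {
  stopifnot(n_core %% 2 == 0, n_core >= 4)
  res <- c("Hex", "Hex")
  par <- c(0L, 1L)
  for (k in seq_len((n_core - 2) / 2)) {
    res <- c(res, "HexNAc", "Hex")
    par <- c(par, length(par), length(par) + 1L)
  }
  term_gal <- length(res)
  p <- term_gal
  for (i in seq_len(n_sia)) {
    res <- c(res, "Neu5Ac")
    par <- c(par, p)
    p <- length(res)
  }
  if (n_fuc > 0) {
    glcnac_idx <- rev(which(res == "HexNAc"))
    stopifnot(n_fuc <= length(glcnac_idx))
    for (i in seq_len(n_fuc)) {
      res <- c(res, "dHex")
      par <- c(par, glcnac_idx[i])
    }
  }
  .topo(res, par)
}

.linear_topo <- function(residues, oac_on = NULL, sulfate_on = NULL) {
  t <- .topo(residues, c(0L, seq_len(length(residues) - 1)))
  if (!is.null(oac_on)) t$oac[oac_on] <- 1
  if (!is.null(sulfate_on)) t$sulfate[sulfate_on] <- 1
  t
}

## Attach an O-acetyl to the terminal-most sialic acid of a topology.
.add_oac <- function(topo) {
  i <- max(which(topo$residue %in% c("Neu5Ac", "Neu5Gc")))
  topo$oac[i] <- topo$oac[i] + 1
  topo
}

## Append one residue to a given parent.
.append_res <- function(topo, residue, parent) {
  dplyr::bind_rows(topo, tibble::tibble(
    idx = nrow(topo) + 1L, residue = residue,
    parent = as.integer(parent), oac = 0, sulfate = 0
  ))
}

.CLASS_REGISTRY_CACHE <- new.env(parent = emptyenv())

.build_class_registry <- function() {
  reg <- list()
  add <- function(name, topo, series) {
    reg[[name]] <<- list(name = name, topology = topo, series = series)
  }

  # Ganglio-series (Svennerholm roots; a/b suffixes are topology tags only)
  add("GM4", .topo(c("Hex", "Neu5Ac"), c(0L, 1L)), "ganglio")
  add("GM3", .ganglio_topo(1, 1), "ganglio")
  add("GD3", .ganglio_topo(1, 2), "ganglio")
  add("GT3", .ganglio_topo(1, 3), "ganglio")
  add("GM2", .ganglio_topo(2, 1), "ganglio")
  add("GD2", .ganglio_topo(2, 2), "ganglio")
  add("GM1", .ganglio_topo(3, 1), "ganglio")
  add("GD1", .ganglio_topo(3, 1, 1), "ganglio") # unresolved isomer: a-type tree
  add("GD1a", .ganglio_topo(3, 1, 1), "ganglio")
  add("GD1b", .ganglio_topo(3, 2, 0), "ganglio")
  add("GT1", .ganglio_topo(3, 2, 1), "ganglio")
  add("GT1b", .ganglio_topo(3, 2, 1), "ganglio")
  add("GQ1", .ganglio_topo(3, 2, 2), "ganglio")
  add("GQ1b", .ganglio_topo(3, 2, 2), "ganglio")
  add("GP1", .ganglio_topo(3, 2, 3), "ganglio")
  # Modified gangliosides
  fuc_gd1 <- .append_res(.ganglio_topo(3, 1, 1), "dHex", 4L)
  add("Fuc-GD1", fuc_gd1, "ganglio")
  add("Fuc-GM1", .append_res(.ganglio_topo(3, 1, 0), "dHex", 4L), "ganglio")
  add("GalNAc-GD1", .append_res(.ganglio_topo(3, 1, 1), "HexNAc", 4L), "ganglio")
  add("OAc-GD1", .add_oac(.ganglio_topo(3, 1, 1)), "ganglio")
  add("OAc-GD3", .add_oac(.ganglio_topo(1, 2)), "ganglio")
  add("OAc-GT1", .add_oac(.ganglio_topo(3, 2, 1)), "ganglio")
  add("OAc-GQ1b", .add_oac(.ganglio_topo(3, 2, 2)), "ganglio")
  # Neu5Gc-substituted species: terminal-most Neu5Ac -> Neu5Gc
  gc_sub <- function(topo) {
    i <- max(which(topo$residue == "Neu5Ac"))
    topo$residue[i] <- "Neu5Gc"
    topo
  }
  add("Neu5Gc-GM3", gc_sub(.ganglio_topo(1, 1)), "ganglio")
  add("Neu5Gc-GD3", gc_sub(.ganglio_topo(1, 2)), "ganglio")
  add("Neu5Gc-GD1", gc_sub(.ganglio_topo(3, 1, 1)), "ganglio")

  # Sialylated neolacto-series
  for (core in c(4, 6, 8, 10, 12)) {
    add(
      sprintf("Neu5Ac-nLc%dCer", core), .nlc_topo(core, 1, 0),
      "neolacto"
    )
    if (core >= 6) {
      add(
        sprintf("Neu5Ac-Fuc-nLc%dCer", core), .nlc_topo(core, 1, 1),
        "neolacto"
      )
    }
    if (core >= 10) {
      add(
        sprintf("Neu5Ac-Fuc2-nLc%dCer", core), .nlc_topo(core, 1, 2),
        "neolacto"
      )
    }
  }

  # Neutral series
  add("HexCer", .linear_topo("Hex"), "neutral")
  add("Hex2Cer", .linear_topo(c("Hex", "Hex")), "neutral")
  add("Hex3Cer", .linear_topo(c("Hex", "Hex", "Hex")), "neutral")
  add("HexNAcHex3Cer", .linear_topo(c("Hex", "Hex", "Hex", "HexNAc")), "neutral")
  add("HexNAcHex4Cer",
    .linear_topo(c("Hex", "Hex", "Hex", "HexNAc", "Hex")), "neutral")
  add("Fuc-HexNAcHex3Cer",
    .append_res(.linear_topo(c("Hex", "Hex", "Hex", "HexNAc")), "dHex", 4L),
    "neutral")

  # Sulfatides: sulfate on the terminal hexose
  add("SHexCer", .linear_topo("Hex", sulfate_on = 1), "sulfatide")
  add("SHex2Cer", .linear_topo(c("Hex", "Hex"), sulfate_on = 2), "sulfatide")

  reg
}

.class_registry <- function() {
  if (!exists("registry", envir = .CLASS_REGISTRY_CACHE)) {
    assign("registry", .build_class_registry(), envir = .CLASS_REGISTRY_CACHE)
  }
  get("registry", envir = .CLASS_REGISTRY_CACHE)
}

.class_entry <- function(class_name) {
  reg <- .class_registry()
  if (!class_name %in% names(reg)) {
    stop("unknown GSL class token: '", class_name, "'", call. = FALSE)
  }
  reg[[class_name]]
}

.topo_composition <- function(topo) {
  c(
    hex = sum(topo$residue == "Hex"),
    hexnac = sum(topo$residue == "HexNAc"),
    dhex = sum(topo$residue == "dHex"),
    neu5ac = sum(topo$residue == "Neu5Ac"),
    neu5gc = sum(topo$residue == "Neu5Gc"),
    sulfate = sum(topo$sulfate),
    oac = sum(topo$oac)
  )
}

#' Registered glycosphingolipid classes
#'
#' One row per registered class with its glycan composition, series and the
#' default negative-mode ion type.
#'
#' @return A tibble with columns `class_name`, `series`, monosaccharide and
#'   modification counts, `n_monosaccharides`, and `default_ion_neg`.
#' @examples
#' gsl_classes()
#' @export
gsl_classes <- function() {
  reg <- .class_registry()
  purrr::map_dfr(reg, function(e) {
    comp <- .topo_composition(e$topology)
    tibble::tibble(
      class_name = e$name, series = e$series,
      hex = comp[["hex"]], hexnac = comp[["hexnac"]], dhex = comp[["dhex"]],
      neu5ac = comp[["neu5ac"]], neu5gc = comp[["neu5gc"]],
      sulfate = comp[["sulfate"]], oac = comp[["oac"]],
      n_monosaccharides = nrow(e$topology)
    )
  }) |>
    dplyr::mutate(
      default_ion_neg = vapply(.data$class_name, default_ion_type,
        character(1),
        polarity = "-"
      )
    )
}

#' Glycan topology of a registered class
#'
#' The rooted residue tree used for in-silico fragmentation: one row per
#' residue with its parent (0 = ceramide) and any riding modifications.
#'
#' @param class_name A registered class token, e.g. `"GD1b"`.
#' @return A tibble with columns `idx`, `residue`, `parent`, `oac`, `sulfate`.
#' @examples
#' class_topology("GD1b")
#' @export
class_topology <- function(class_name) {
  .class_entry(class_name)$topology
}

#' Export the class registry as JSON
#'
#' Writes the versioned class registry (composition, parent-child residue
#' edges, default ion types) in the documented JSON interchange layout.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_class_registry <- function(path) {
  reg <- .class_registry()
  out <- list(
    format = "gsl4d-class-registry",
    version = 1L,
    classes = purrr::map(reg, function(e) {
      comp <- as.list(.topo_composition(e$topology))
      list(
        name = e$name, series = e$series, composition = comp,
        default_ion_neg = default_ion_type(e$name, "-"),
        default_ion_pos = default_ion_type(e$name, "+"),
        topology = as.list(e$topology[c("idx", "residue", "parent", "oac", "sulfate")])
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Ion / adduct registry. m/z = (M + delta_neutral + z_signed * proton) / z,
## with z_signed = +z in positive mode (protons gained) and -z in negative
## mode (protons lost). Proton mass 1.007276 Da per charge.
.ION_REGISTRY <- tibble::tibble(
  ion = c(
    "[M-H]1-", "[M-2H]2-", "[M-3H]3-", "[M+HCOOH-2H]2-", "[M-H2O-2H]2-",
    "[M+H]1+", "[M+2H]2+", "[M+H-H2O]1+"
  ),
  polarity = c("-", "-", "-", "-", "-", "+", "+", "+"),
  z = c(1L, 2L, 3L, 2L, 2L, 1L, 2L, 1L),
  delta_neutral = c(0, 0, 0, NA, NA, 0, 0, NA)
)
.ION_REGISTRY$delta_neutral[.ION_REGISTRY$ion == "[M+HCOOH-2H]2-"] <- .HCOOH_MASS
.ION_REGISTRY$delta_neutral[.ION_REGISTRY$ion == "[M-H2O-2H]2-"] <- -.H2O_MASS
.ION_REGISTRY$delta_neutral[.ION_REGISTRY$ion == "[M+H-H2O]1+"] <- -.H2O_MASS

.normalize_ion <- function(ion) {
  ion <- gsub("−", "-", ion) # unicode minus
  # accept "[M-H]-" / "[M-2H]2-" / "[M+H]+" spellings
  ion <- sub("\\]-$", "]1-", ion)
  ion <- sub("\\]\\+$", "]1+", ion)
  ion
}

.ion_entry <- function(ion) {
  ion <- .normalize_ion(ion)
  hit <- .ION_REGISTRY[.ION_REGISTRY$ion == ion, ]
  if (nrow(hit) != 1) {
    stop("unknown ion type: '", ion, "'", call. = FALSE)
  }
  hit
}

#' m/z of an ion from a neutral monoisotopic mass
#'
#' Computes `(M + delta + q * z * 1.007276) / z` where `delta` is the neutral
#' adduct/loss mass and `q` is +1 (protonation) or -1 (deprotonation).
#'
#' @param mass Neutral monoisotopic mass (Da), vectorized.
#' @param ion Ion type label, e.g. `"[M-2H]2-"`, `"[M+HCOOH-2H]2-"`,
#'   `"[M+H]1+"` (the trailing charge digit may be omitted for z = 1).
#' @return Numeric vector of m/z values (full precision; round only for
#'   presentation).
#' @examples
#' mz_from_mass(1836.9721, "[M-2H]2-")
#' @export
mz_from_mass <- function(mass, ion) {
  e <- .ion_entry(ion)
  q <- if (e$polarity == "+") 1 else -1
  if (e$z < 1) stop("charge must be >= 1", call. = FALSE)
  (mass + e$delta_neutral + q * e$z * PROTON_MASS) / e$z
}

#' Polarity and charge of an ion type
#'
#' @param ion Ion type label.
#' @return A list with elements `polarity` (`"+"`/`"-"`) and `z`.
#' @export
ion_info <- function(ion) {
  e <- .ion_entry(ion)
  list(ion = e$ion, polarity = e$polarity, z = e$z)
}

#' Default ion type for a GSL class
#'
#' Negative mode follows the per-class ion-type rules: GM4/GM3/GM2 form
#' `[M-H]1-`; GM1 and mono-sialylated neolacto species form the formate adduct
#' `[M+HCOOH-2H]2-`; di- to tetra-sialylated species form `[M-2H]2-`;
#' penta-sialylated species form `[M-H2O-2H]2-`; neutral GSLs and sulfatides
#' form `[M-H]1-`. Positive mode defaults to `[M+H]1+` for all classes.
#'
#' @param class_name Registered class token.
#' @param polarity `"-"` (default) or `"+"`.
#' @return Ion type label.
#' @examples
#' default_ion_type("GM3")
#' default_ion_type("GQ1b")
#' @export
default_ion_type <- function(class_name, polarity = "-") {
  e <- .class_entry(class_name)
  if (polarity == "+") {
    return("[M+H]1+")
  }
  comp <- .topo_composition(e$topology)
  n_sia <- comp[["neu5ac"]] + comp[["neu5gc"]]
  if (n_sia == 0) {
    return("[M-H]1-")
  }
  if (n_sia == 1) {
    # short mono-sialylated gangliosides (GM4/GM3/GM2) stay singly
    # deprotonated; the tetraose GM1 and the neolacto chains pick up formate
    n_neutral <- comp[["hex"]] + comp[["hexnac"]] + comp[["dhex"]]
    if (n_neutral <= 3) {
      return("[M-H]1-")
    }
    return("[M+HCOOH-2H]2-")
  }
  if (n_sia >= 5) {
    return("[M-H2O-2H]2-")
  }
  "[M-2H]2-"
}
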