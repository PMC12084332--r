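## Partition-corrected semi-quantification for two-fraction serum extracts.
## Strategy I uses the cohort-average ISTD partition (A-bar) from reference
## extracts; Strategy II uses each sample's own partition; the combined
## protocol applies one strategy and recomputes outlier samples with the
## other. The fraction-2 partition percentage A is a single function used by
## both strategies.

#' Fraction-2 partition percentage of an internal standard
#'
#' `A = 100 * area_f2 / (area_f1 + area_f2)`. Both areas zero gives `NA`
#' (flagged missing downstream).
#'
#' @param area_f1,area_f2 Peak areas of the ISTD in fractions 1 and 2
#'   (vectorized).
#' @return Partition percentage in `[0, 100]`, `NA` where both areas are 0.
#' @examples
#' partition_percent(100, 100) # 50
#' @export
partition_percent <- function(area_f1, area_f2) {
  total <- area_f1 + area_f2
  ifelse(total > 0, 100 * area_f2 / total, NA_real_)
}

#' Amount of spiked internal standard
#'
#' `mass_ug = volume_uL * conc_ug_per_mL / 1000`; `nmol = mass_ug * 1000 /
#' molecular_mass`.
#'
#' @param volume_uL Spiked volume in uL.
#' @param conc_ug_per_mL ISTD concentration in ug/mL.
#' @param molecular_mass Molecular mass in g/mol.
#' @return Amount in nmol.
#' @examples
#' spiked_amount_nmol(12.5, 20, 1250) # 0.2 nmol
#' @export
spiked_amount_nmol <- function(volume_uL, conc_ug_per_mL, molecular_mass) {
  stopifnot(all(volume_uL >= 0), all(conc_ug_per_mL >= 0), all(molecular_mass > 0))
  (volume_uL * conc_ug_per_mL / 1000) * 1000 / molecular_mass
}

#' Default internal-standard panel
#'
#' The five-ISTD spike panel (12.5 uL of a 20 ug/mL mixture each) with
#' monoisotopic masses computed from the shorthand names.
#'
#' @param volume_uL,conc_ug_per_mL Spike volume and concentration.
#' @return A tibble with `istd`, `molecular_mass`, `spiked_nmol`.
#' @export
default_istds <- function(volume_uL = 12.5, conc_ug_per_mL = 20) {
  names <- c(
    "GM3 18:1;O2/18:0-d5", "GM1 18:1;O2/18:0-d5", "GD1a 18:1;O2/17:0",
    "GM2 18:1;O2/16:0-d9", "GD3 18:1;O2/18:0-d3"
  )
  mm <- species_formula(parse_species(names))$mass
  tibble::tibble(
    istd = names, molecular_mass = mm,
    spiked_nmol = spiked_amount_nmol(volume_uL, conc_ug_per_mL, mm)
  )
}

#' Default class-to-ISTD map (sub-strategy 3)
#'
#' GM1, GM2 and GM3 use their own deuterated standards; GD3, GD2, GD1, GT1b
#' and GQ1b (and, as cross-class defaults, the remaining sialylated classes)
#' use GD3 18:1;O2/18:0-d3.
#'
#' @return A tibble with `class_name`, `istd`.
#' @export
default_istd_map <- function() {
  classes <- gsl_classes()
  sial <- classes$class_name[classes$neu5ac + classes$neu5gc > 0]
  map <- tibble::tibble(
    class_name = sial,
    istd = "GD3 18:1;O2/18:0-d3"
  )
  map$istd[map$class_name == "GM1"] <- "GM1 18:1;O2/18:0-d5"
  map$istd[map$class_name == "GM2"] <- "GM2 18:1;O2/16:0-d9"
  map$istd[map$class_name %in% c("GM3", "GM4", "Neu5Gc-GM3")] <- "GM3 18:1;O2/18:0-d5"
  map
}

#' Quantification configuration
#'
#' @param istd_map Tibble `class_name` -> `istd` (every quantified class maps
#'   to exactly one ISTD); default [default_istd_map()].
#' @param istds Tibble with `istd`, `molecular_mass`, `spiked_nmol`; default
#'   [default_istds()].
#' @param strategy `"I"`, `"II"` or `"combined"`.
#' @param base_strategy For the combined protocol, the strategy applied to
#'   all samples (the other corrects flagged outliers). Default `"I"`.
#' @param cv_threshold_pct CV cut-off in percent (default 35).
#' @param serum_volume_uL Serum volume per sample (default 300).
#' @param outlier_k_mad,outlier_abs_pp Partition outlier rule: flag a sample
#'   if any ISTD partition deviates from the cohort median by more than
#'   `k * MAD` or by more than `outlier_abs_pp` percentage points.
#' @return A list with class `quant_config`.
#' @export
quant_config <- function(istd_map = default_istd_map(),
                         istds = default_istds(),
                         strategy = c("II", "I", "combined"),
                         base_strategy = "I",
                         cv_threshold_pct = 35,
                         serum_volume_uL = 300,
                         outlier_k_mad = 3.5,
                         outlier_abs_pp = 15) {
  strategy <- match.arg(strategy)
  stopifnot(
    all(c("class_name", "istd") %in% names(istd_map)),
    !anyDuplicated(istd_map$class_name),
    all(c("istd", "molecular_mass", "spiked_nmol") %in% names(istds)),
    all(istds$spiked_nmol > 0),
    cv_threshold_pct > 0, serum_volume_uL > 0
  )
  structure(
    list(
      istd_map = istd_map, istds = istds, strategy = strategy,
      base_strategy = base_strategy, cv_threshold_pct = cv_threshold_pct,
      serum_volume_uL = serum_volume_uL, outlier_k_mad = outlier_k_mad,
      outlier_abs_pp = outlier_abs_pp
    ),
    class = "quant_config"
  )
}

#' Per-sample ISTD partition records
#'
#' @param istd_areas Tibble with `sample_id`, `istd`, `area_f1`, `area_f2`.
#' @return The input with `A_pct` added.
#' @export
partition_records <- function(istd_areas) {
  stopifnot(all(c("sample_id", "istd", "area_f1", "area_f2") %in% names(istd_areas)))
  istd_areas |>
    dplyr::mutate(A_pct = partition_percent(.data$area_f1, .data$area_f2)) |>
    tibble::as_tibble()
}

#' Cohort-average partition per ISTD
#'
#' @param partition A tibble from [partition_records()] (reference extracts).
#' @return A tibble with `istd`, `A_bar_pct`, `cv_pct`, `n`.
#' @export
cohort_partition <- function(partition) {
  partition |>
    dplyr::filter(!is.na(.data$A_pct)) |>
    dplyr::group_by(.data$istd) |>
    dplyr::summarise(
      A_bar_pct = mean(.data$A_pct),
      cv_pct = 100 * stats::sd(.data$A_pct) / mean(.data$A_pct),
      n = dplyr::n(), .groups = "drop"
    )
}

## shared core: given per-(sample, istd) fraction-2 ISTD areas and the
## partition percentage to use, compute B and C for each analyte row
.quantify_core <- function(analyte_areas, istd_f2, a_by, config, strategy_label) {
  stopifnot(all(c("sample_id", "name", "area") %in% names(analyte_areas)))
  sp <- species_formula(parse_species(unique(analyte_areas$name)))
  info <- sp |> dplyr::select("name", "class_name", "mass")
  rec <- analyte_areas |>
    dplyr::left_join(info, by = "name") |>
    dplyr::left_join(config$istd_map, by = "class_name") |>
    dplyr::left_join(
      config$istds |> dplyr::select("istd", "spiked_nmol"),
      by = "istd"
    ) |>
    dplyr::left_join(istd_f2, by = c("sample_id", "istd")) |>
    dplyr::left_join(a_by, by = intersect(c("sample_id", "istd"), names(a_by)))
  rec |>
    dplyr::mutate(
      flag_missing = is.na(.data$istd) | is.na(.data$istd_area_f2) |
        .data$istd_area_f2 <= 0 | is.na(.data$A_used_pct),
      B_nmol = ifelse(.data$flag_missing, NA_real_,
        .data$spiked_nmol * .data$A_used_pct / 100
      ),
      C_nmol = ifelse(.data$flag_missing, NA_real_,
        .data$area / .data$istd_area_f2 * .data$B_nmol
      ),
      conc_ng_per_uL = .data$C_nmol * .data$mass / config$serum_volume_uL,
      strategy = strategy_label,
      corrected = FALSE
    ) |>
    dplyr::select(
      "sample_id", "name", "class_name", "istd", "area", "A_used_pct",
      "B_nmol", "C_nmol", "conc_ng_per_uL", "strategy", "corrected",
      "flag_missing"
    ) |>
    tibble::as_tibble()
}

.istd_f2_from <- function(istd_areas) {
  istd_areas |>
    dplyr::select("sample_id", "istd", istd_area_f2 = "area_f2")
}

#' Strategy I: cohort-average partition correction
#'
#' `B = spiked_nmol * A_bar / 100`; `C = (analyte area / ISTD fraction-2
#' area) * B`. Only fraction-2 data are required per sample; the cohort
#' average partition comes from reference extracts.
#'
#' @param analyte_areas Tibble with `sample_id`, `name` (shorthand species),
#'   `area` (fraction-2 peak area).
#' @param istd_f2_areas Tibble with `sample_id`, `istd`, `area_f2`.
#' @param abar Tibble with `istd`, `A_bar_pct` (see [cohort_partition()]).
#' @param config A [quant_config()].
#' @return A tibble of concentration records: `sample_id`, `name`,
#'   `class_name`, `istd`, `A_used_pct`, `B_nmol`, `C_nmol`,
#'   `conc_ng_per_uL`, `strategy`, `corrected`, `flag_missing`.
#' @export
quantify_strategy_I <- function(analyte_areas, istd_f2_areas, abar,
                                config = quant_config()) {
  stopifnot(all(c("istd", "A_bar_pct") %in% names(abar)))
  classes <- parse_species(unique(analyte_areas$name))$class_name
  needed <- unique(config$istd_map$istd[config$istd_map$class_name %in% classes])
  if (!all(needed %in% abar$istd)) {
    stop("cohort average partition missing for: ",
      paste(setdiff(needed, abar$istd), collapse = ", "),
      call. = FALSE
    )
  }
  istd_f2 <- istd_f2_areas |>
    dplyr::select("sample_id", "istd", istd_area_f2 = "area_f2")
  a_by <- abar |> dplyr::select("istd", A_used_pct = "A_bar_pct")
  .quantify_core(analyte_areas, istd_f2, a_by, config, "I")
}

#' Strategy II: per-sample partition correction
#'
#' Each sample's own ISTD partition `A` (from its two-fraction ISTD areas)
#' replaces the cohort average: `B = spiked_nmol * A / 100`;
#' `C = (analyte area / ISTD fraction-2 area) * B`.
#'
#' @param analyte_areas Tibble with `sample_id`, `name`, `area` (fraction 2).
#' @param istd_areas Tibble with `sample_id`, `istd`, `area_f1`, `area_f2`.
#' @param config A [quant_config()].
#' @return A tibble of concentration records (see [quantify_strategy_I()]).
#' @export
quantify_strategy_II <- function(analyte_areas, istd_areas,
                                 config = quant_config()) {
  part <- partition_records(istd_areas)
  a_by <- part |>
    dplyr::select("sample_id", "istd", A_used_pct = "A_pct")
  .quantify_core(
    analyte_areas, .istd_f2_from(istd_areas), a_by, config, "II"
  )
}

#' Detect partition-outlier samples
#'
#' A sample is flagged when any of its ISTD partition percentages deviates
#' from the cohort median (per ISTD) by more than `k * MAD` or by more than
#' an absolute number of percentage points, whichever triggers. Cohorts of
#' fewer than 3 samples are not flagged (with a warning).
#'
#' @param partition A tibble from [partition_records()].
#' @param k_mad MAD multiplier (default 3.5).
#' @param abs_pp Absolute deviation threshold in percentage points
#'   (default 15).
#' @return Character vector of flagged `sample_id`s.
#' @export
detect_partition_outliers <- function(partition, k_mad = 3.5, abs_pp = 15) {
  n_samples <- length(unique(partition$sample_id))
  if (n_samples < 3) {
    warning("fewer than 3 samples: no outlier flagging", call. = FALSE)
    return(character(0))
  }
  flagged <- partition |>
    dplyr::filter(!is.na(.data$A_pct)) |>
    dplyr::group_by(.data$istd) |>
    dplyr::mutate(
      med = stats::median(.data$A_pct),
      mad = stats::mad(.data$A_pct),
      dev = abs(.data$A_pct - .data$med),
      out = (.data$mad > 0 & .data$dev > k_mad * .data$mad) |
        .data$dev > abs_pp
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$out)
  sort(unique(flagged$sample_id))
}

#' Combined strategy with outlier correction
#'
#' Applies the base strategy to all samples, detects partition-outlier
#' samples from their ISTD partition records, and recomputes only those
#' samples with the alternate strategy, marking them `corrected`.
#'
#' @param analyte_areas Tibble with `sample_id`, `name`, `area`.
#' @param istd_areas Tibble with `sample_id`, `istd`, `area_f1`, `area_f2`
#'   (both fractions; needed for partitions).
#' @param abar Cohort-average partitions ([cohort_partition()]); when `NULL`
#'   they are computed from `istd_areas` itself.
#' @param config A [quant_config()]; `config$base_strategy` selects which
#'   strategy is the base (`"I"` default) and which corrects.
#' @return A tibble of concentration records with `corrected = TRUE` on
#'   recomputed samples.
#' @export
quantify_combined <- function(analyte_areas, istd_areas, abar = NULL,
                              config = quant_config()) {
  part <- partition_records(istd_areas)
  if (is.null(abar)) abar <- cohort_partition(part)
  base <- config$base_strategy
  run <- function(strategy, areas) {
    if (strategy == "I") {
      quantify_strategy_I(areas, istd_areas, abar, config)
    } else {
      quantify_strategy_II(areas, istd_areas, config)
    }
  }
  out <- run(base, analyte_areas)
  outliers <- detect_partition_outliers(
    part, config$outlier_k_mad, config$outlier_abs_pp
  )
  if (length(outliers) > 0) {
    alt <- setdiff(c("I", "II"), base)
    redo <- run(alt, analyte_areas[analyte_areas$sample_id %in% outliers, ,
      drop = FALSE
    ])
    redo$corrected <- TRUE
    out <- dplyr::bind_rows(
      out[!out$sample_id %in% outliers, , drop = FALSE], redo
    ) |>
      dplyr::arrange(.data$sample_id, .data$name)
  }
  out
}

#' Replicate CV table
#'
#' Per-species coefficient of variation (`100 * sd / mean`, sample sd) across
#' replicates, and the share of species with CV below a threshold. Species
#' with mean 0 have undefined CV and are excluded (counted in `n_undefined`).
#'
#' @param records Concentration records with `name` and a value column.
#' @param value Column to summarise (default `C_nmol`).
#' @param threshold_pct CV threshold (default 35).
#' @return A list with `per_species` (tibble `name`, `mean`, `sd`, `cv_pct`,
#'   `n`), `pct_below` and `n_undefined`.
#' @export
cv_table <- function(records, value = "C_nmol", threshold_pct = 35) {
  stopifnot(value %in% names(records))
  per <- records |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sd = stats::sd(.data[[value]]),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::mutate(cv_pct = ifelse(.data$mean == 0, NA_real_, 100 * .data$sd / .data$mean))
  n_undef <- sum(is.na(per$cv_pct))
  defined <- per$cv_pct[!is.na(per$cv_pct)]
  list(
    per_species = per,
    pct_below = if (length(defined) > 0) 100 * mean(defined < threshold_pct) else NA_real_,
    n_undefined = n_undef,
    threshold_pct = threshold_pct
  )
}

#' Fraction-1 single-ISTD normalization
#'
#' Neutral GSL and sulfatide peak areas are normalized to the fraction-1 peak
#' area of a single ISTD per sample (unitless ratio).
#'
#' @param areas Tibble with `sample_id`, `name`, `area`.
#' @param istd_f1_areas Tibble with `sample_id`, `istd_area` (> 0).
#' @return The input with `norm_abundance` added; samples with a missing or
#'   non-positive ISTD area are flagged (`flag_missing`).
#' @export
normalize_fraction1 <- function(areas, istd_f1_areas) {
  stopifnot(
    all(c("sample_id", "name", "area") %in% names(areas)),
    all(c("sample_id", "istd_area") %in% names(istd_f1_areas))
  )
  areas |>
    dplyr::left_join(istd_f1_areas, by = "sample_id") |>
    dplyr::mutate(
      flag_missing = is.na(.data$istd_area) | .data$istd_area <= 0,
      norm_abundance = ifelse(.data$flag_missing, NA_real_,
        .data$area / .data$istd_area
      )
    ) |>
    tibble::as_tibble()
}
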