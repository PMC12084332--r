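## Seeded generators emulating the study design: two-fraction serum extracts
## with ISTD partitioning, lognormal species abundances, diagnostic-ion
## spectra and calibration dilution series. All randomness is governed by the
## config seed; the same seed reproduces outputs exactly.

## normal truncated to (lo, hi) by rejection
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lo & draw < hi])
  }
  out[seq_len(n)]
}

## multiplicative lognormal noise with unit mean and given CV (percent)
.ln_noise <- function(n, cv_pct) {
  if (cv_pct == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Reference ISTD partition truths
#'
#' The fraction-2 partition means and CVs of the four deuterated internal
#' standards measured in replicate reference-serum extracts: 78.70/80.40/
#' 75.99/70.35 % with CVs 5.59/2.94/3.95/7.40 % for GD3-d3, GM1-d5, GM2-d9
#' and GM3-d5 respectively.
#'
#' @return A tibble with `istd`, `partition_mean_pct`, `partition_cv_pct`.
#' @export
reference_partitions <- function() {
  tibble::tibble(
    istd = c(
      "GD3 18:1;O2/18:0-d3", "GM1 18:1;O2/18:0-d5",
      "GM2 18:1;O2/16:0-d9", "GM3 18:1;O2/18:0-d5"
    ),
    partition_mean_pct = c(78.70, 80.40, 75.99, 70.35),
    partition_cv_pct = c(5.59, 2.94, 3.95, 7.40)
  )
}

#' Simulation configuration
#'
#' @param seed Integer seed fixing all outputs.
#' @param n_samples Number of samples.
#' @param species Character vector of shorthand species names (default: the
#'   sialylated fraction-2 entries of [serum_fixture()] quantifiable under
#'   the default ISTD map, subsampled to `n_species`).
#' @param n_species Number of species when defaulting (default 25).
#' @param conc_median_nmol,conc_cv_pct Lognormal law of true per-species
#'   serum amounts (median in nmol, biological CV in percent).
#' @param partitions ISTD partition truths ([reference_partitions()]
#'   layout).
#' @param area_cv_pct Multiplicative lognormal measurement noise on peak
#'   areas (percent; 0 = noiseless).
#' @param effect_map Optional tibble `name` -> `fold_change` applied to the
#'   case group.
#' @param descriptor_noise Positional noise as a fraction of the default
#'   tolerance windows for m/z, RT, CCS (0 = exact library descriptors).
#' @param area_per_nmol Detector response (area units per nmol, shared by
#'   analytes and ISTDs; response factors default to 1).
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 6, species = NULL,
                       n_species = 25,
                       conc_median_nmol = 0.05, conc_cv_pct = 60,
                       partitions = reference_partitions(),
                       area_cv_pct = 7,
                       effect_map = NULL,
                       descriptor_noise = 0,
                       area_per_nmol = 1e6) {
  stopifnot(
    n_samples >= 1,
    all(partitions$partition_mean_pct > 0 & partitions$partition_mean_pct < 100),
    all(partitions$partition_cv_pct >= 0), area_cv_pct >= 0,
    descriptor_noise >= 0
  )
  structure(
    list(
      seed = as.integer(seed), n_samples = n_samples, species = species,
      n_species = n_species, conc_median_nmol = conc_median_nmol,
      conc_cv_pct = conc_cv_pct, partitions = partitions,
      area_cv_pct = area_cv_pct, effect_map = effect_map,
      descriptor_noise = descriptor_noise, area_per_nmol = area_per_nmol
    ),
    class = "sim_config"
  )
}

.default_sim_species <- function(config) {
  lib <- serum_fixture()
  map <- default_istd_map()
  ok <- lib$fraction == 2 & !is.na(lib$mz) & lib$class_name %in% map$class_name
  pool <- lib$name[ok]
  pool[seq(1, length(pool), length.out = min(config$n_species, length(pool)))]
}

#' Simulate a two-fraction cohort
#'
#' Per sample: true species amounts are drawn from the lognormal abundance
#' law (times any case-group fold change); each ISTD's fraction-2 partition
#' is drawn from a truncated normal at its configured truth; analytes
#' partition like their mapped ISTD; areas are amounts times the detector
#' response with multiplicative lognormal noise; feature descriptors are the
#' library values plus Gaussian jitter scaled to the tolerance windows.
#'
#' @param config A [sim_config()].
#' @param design Optional tibble `sample_id`, `group` (`"control"`/`"case"`),
#'   optional `sex`; defaults to all-control samples `S01..`.
#' @param library Reference library for descriptors (default
#'   [serum_fixture()]).
#' @return A list: `features` (fraction-2 feature table with descriptors),
#'   `analyte_areas`, `istd_areas`, `truth` (per sample and species:
#'   `C_total_nmol`, `A_pct` of the mapped ISTD, `C_f2_nmol`), `design`,
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), design = NULL,
                            library = NULL) {
  set.seed(config$seed)
  if (is.null(library)) library <- serum_fixture()
  species <- config$species
  if (is.null(species)) species <- .default_sim_species(config)
  sp <- species_formula(parse_species(species))
  map <- default_istd_map()
  sp <- sp |> dplyr::left_join(map, by = "class_name")
  if (any(is.na(sp$istd))) {
    stop("species without ISTD mapping: ",
      paste(sp$name[is.na(sp$istd)], collapse = ", "),
      call. = FALSE
    )
  }
  istds <- default_istds()
  if (is.null(design)) {
    design <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(config$n_samples)),
      group = "control"
    )
  }
  n <- nrow(design)
  sdlog <- sqrt(log(1 + (config$conc_cv_pct / 100)^2))

  part_truth <- config$partitions
  istd_rows <- purrr::map_dfr(seq_len(n), function(i) {
    a <- vapply(seq_len(nrow(part_truth)), function(k) {
      .rtruncnorm(
        1, part_truth$partition_mean_pct[k],
        part_truth$partition_mean_pct[k] * part_truth$partition_cv_pct[k] / 100
      )
    }, numeric(1))
    tibble::tibble(
      sample_id = design$sample_id[i], istd = part_truth$istd, A_true_pct = a
    )
  })

  truth <- purrr::map_dfr(seq_len(n), function(i) {
    c_total <- stats::rlnorm(nrow(sp), log(config$conc_median_nmol), sdlog)
    if (!is.null(config$effect_map) && design$group[i] == "case") {
      fc <- config$effect_map$fold_change[match(sp$name, config$effect_map$name)]
      c_total <- c_total * ifelse(is.na(fc), 1, fc)
    }
    a <- istd_rows$A_true_pct[istd_rows$sample_id == design$sample_id[i]]
    names(a) <- istd_rows$istd[istd_rows$sample_id == design$sample_id[i]]
    a_sp <- unname(a[sp$istd])
    tibble::tibble(
      sample_id = design$sample_id[i], name = sp$name,
      istd = sp$istd, C_total_nmol = c_total, A_pct = a_sp,
      C_f2_nmol = c_total * a_sp / 100
    )
  })

  resp <- config$area_per_nmol
  istd_areas <- istd_rows |>
    dplyr::left_join(istds, by = "istd") |>
    dplyr::mutate(
      area_f2 = .data$spiked_nmol * .data$A_true_pct / 100 * resp *
        .ln_noise(dplyr::n(), config$area_cv_pct),
      area_f1 = .data$spiked_nmol * (1 - .data$A_true_pct / 100) * resp *
        .ln_noise(dplyr::n(), config$area_cv_pct)
    ) |>
    dplyr::select("sample_id", "istd", "area_f1", "area_f2")

  analyte_areas <- truth |>
    dplyr::mutate(
      area = .data$C_f2_nmol * resp * .ln_noise(dplyr::n(), config$area_cv_pct)
    ) |>
    dplyr::select("sample_id", "name", "area")

  lib_idx <- match(truth$name, library$name)
  tol <- tolerance_config()
  jit <- config$descriptor_noise
  features <- truth |>
    dplyr::mutate(
      feature_id = sprintf("%s_%04d", .data$sample_id, seq_along(.data$name)),
      fraction = 2L,
      polarity = library$polarity[lib_idx],
      z = library$charge[lib_idx],
      mz = library$mz[lib_idx] +
        stats::rnorm(dplyr::n(), 0, jit * tol$mz_mDa / 1000),
      rt_min = library$rt_min[lib_idx] +
        stats::rnorm(dplyr::n(), 0, jit * tol$rt_min),
      ccs_A2 = library$ccs_A2[lib_idx] *
        (1 + stats::rnorm(dplyr::n(), 0, jit * tol$ccs_pct / 100)),
      spectrum_id = NA_character_
    ) |>
    dplyr::left_join(analyte_areas, by = c("sample_id", "name")) |>
    dplyr::select(
      "feature_id", "sample_id", "fraction", "polarity", "mz", "z",
      "rt_min", "ccs_A2", "area", "spectrum_id",
      truth_name = "name"
    )

  list(
    features = features, analyte_areas = analyte_areas,
    istd_areas = istd_areas, truth = truth, design = design, config = config
  )
}

#' Simulate replicate two-fraction extracts for one ISTD
#'
#' Replicate extracts at a configured partition truth: each replicate draws
#' its partition from a truncated normal, splits the ISTD between the two
#' fraction areas accordingly and applies multiplicative area noise.
#'
#' @param istd ISTD name (one of [reference_partitions()] by default).
#' @param n_replicates Number of replicate extracts.
#' @param seed Integer seed.
#' @param partition_mean_pct,partition_cv_pct Partition truth; defaults are
#'   looked up in [reference_partitions()].
#' @param area_cv_pct Area measurement noise (percent).
#' @return A [partition_records()] tibble with `A_pct` per replicate.
#' @export
simulate_partition_replicates <- function(istd = "GD3 18:1;O2/18:0-d3",
                                          n_replicates = 4, seed = 1,
                                          partition_mean_pct = NULL,
                                          partition_cv_pct = NULL,
                                          area_cv_pct = 2) {
  ref <- reference_partitions()
  if (is.null(partition_mean_pct)) {
    hit <- match(istd, ref$istd)
    if (is.na(hit)) stop("unknown ISTD and no partition truth given", call. = FALSE)
    partition_mean_pct <- ref$partition_mean_pct[hit]
    partition_cv_pct <- ref$partition_cv_pct[hit]
  }
  set.seed(seed)
  a <- .rtruncnorm(
    n_replicates, partition_mean_pct,
    partition_mean_pct * partition_cv_pct / 100
  )
  total <- 1e6 * .ln_noise(n_replicates, area_cv_pct)
  partition_records(tibble::tibble(
    sample_id = sprintf("R%04d", seq_len(n_replicates)),
    istd = istd,
    area_f1 = total * (1 - a / 100) * .ln_noise(n_replicates, area_cv_pct),
    area_f2 = total * (a / 100) * .ln_noise(n_replicates, area_cv_pct)
  ))
}

#' Simulate diagnostic-ion MS/MS spectra
#'
#' One spectrum per species containing its in-silico fragment ions (glycan
#' B/Y ions; in positive mode also the sphingoid and acyl-loss ions) with
#' random intensities, plus optional random decoy peaks. Placeholder species
#' are skipped with a warning. [classify_spectrum()] on the output sets the
#' composition-implied flags.
#'
#' @param species Character vector of shorthand names.
#' @param polarity `"-"` or `"+"`.
#' @param seed Integer seed.
#' @param n_decoys Random decoy peaks per spectrum (default 5).
#' @param out Optional MGF path; when given the spectra are also written.
#' @return A spectra tibble ([read_mgf()] layout).
#' @export
simulate_spectra <- function(species, polarity = "-", seed = 1, n_decoys = 5,
                             out = NULL) {
  set.seed(seed)
  sp <- parse_species(species)
  keep <- !sp$placeholder
  if (any(!keep)) {
    warning("skipping placeholder species: ",
      paste(sp$name[!keep], collapse = ", "),
      call. = FALSE
    )
  }
  sp <- species_formula(sp[keep, , drop = FALSE])
  spectra <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    s <- sp[i, ]
    frags <- glycosidic_fragments(s, polarity)
    if (polarity == "+") {
      frags <- dplyr::bind_rows(
        frags[c("mz")], ceramide_fragments(s)[c("mz")]
      )
    }
    mz <- frags$mz[frags$mz > 50]
    if (n_decoys > 0) {
      mz <- c(mz, stats::runif(n_decoys, 200, 1500))
    }
    ion <- default_ion_type(s$class_name, polarity)
    tibble::tibble(
      spectrum_id = s$name,
      precursor_mz = mz_from_mass(s$mass, ion),
      charge = ion_info(ion)$z,
      polarity = polarity,
      peaks = list(tibble::tibble(
        mz = mz,
        intensity = stats::runif(length(mz), 10, 1000)
      ))
    )
  })
  if (!is.null(out)) write_mgf(spectra, out)
  spectra
}

#' Simulate a calibration dilution series
#'
#' `y = intercept + slope * x + e`, `e ~ N(0, sigma^2)`, over the two-fold
#' dilution grid.
#'
#' @param slope,intercept Line parameters.
#' @param sigma Response noise SD (0 gives the exact line).
#' @param design Concentration grid (default [dilution_series()]).
#' @param seed Integer seed.
#' @return A tibble with `x`, `y`.
#' @export
simulate_calibration <- function(slope = 1, intercept = 0, sigma = 0,
                                 design = dilution_series(), seed = 1) {
  stopifnot(sigma >= 0)
  set.seed(seed)
  tibble::tibble(
    x = design,
    y = intercept + slope * design + stats::rnorm(length(design), 0, sigma)
  )
}
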