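## Differential-abundance layer: per-species two-sided Mann-Whitney U tests
## with Benjamini-Hochberg adjustment and the conventional star annotation.

.stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

.mw_one <- function(values, groups) {
  g <- sort(unique(groups))
  x <- values[groups == g[1]]
  y <- values[groups == g[2]]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble::tibble(
      U = NA_real_, p_value = NA_real_, n1 = length(x), n2 = length(y),
      skipped = "group with < 2 samples"
    ))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL, correct = TRUE))
  tibble::tibble(
    U = unname(wt$statistic), p_value = wt$p.value,
    n1 = length(x), n2 = length(y), skipped = NA_character_
  )
}

#' Mann-Whitney differential-abundance table
#'
#' Two-sided Mann-Whitney U test per species between two groups, with
#' Benjamini-Hochberg adjustment across species and star annotation
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Small tie-free groups use
#' the exact distribution; larger or tied data the normal approximation with
#' continuity and tie correction (the `stats::wilcox.test()` switch). With
#' `stratify_by_sex = TRUE` the test is run separately within each sex and BH
#' adjustment is applied within each stratum.
#'
#' @param concentrations Tibble with `sample_id`, `name`, and a value column.
#' @param design Tibble with `sample_id`, `group` (two levels), optional
#'   `sex` and `age` (carried but unused by the nonparametric test).
#' @param value Value column name (default `"C_nmol"`).
#' @param stratify_by_sex Run within-sex tests (requires `design$sex`).
#' @return A tibble with `name` (and `sex` when stratified), `U`, `p_value`,
#'   `p_adj`, `stars`, group sizes and a `skipped` reason for species with a
#'   group of fewer than 2 samples.
#' @export
mann_whitney_table <- function(concentrations, design, value = "C_nmol",
                               stratify_by_sex = FALSE) {
  stopifnot(
    all(c("sample_id", "name") %in% names(concentrations)),
    value %in% names(concentrations),
    all(c("sample_id", "group") %in% names(design))
  )
  if (length(unique(design$group)) != 2) {
    stop("design must have exactly two groups", call. = FALSE)
  }
  if (stratify_by_sex && !"sex" %in% names(design)) {
    stop("stratify_by_sex requires a 'sex' column in the design", call. = FALSE)
  }
  dat <- concentrations |>
    dplyr::inner_join(design, by = "sample_id")
  run_stratum <- function(d) {
    d |>
      dplyr::group_by(.data$name) |>
      dplyr::group_modify(function(g, key) {
        .mw_one(g[[value]], g$group)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        p_adj = stats::p.adjust(.data$p_value, method = "BH"),
        stars = .stars(.data$p_value)
      )
  }
  if (!stratify_by_sex) {
    return(run_stratum(dat))
  }
  dat |>
    dplyr::group_by(.data$sex) |>
    dplyr::group_modify(function(d, key) run_stratum(d)) |>
    dplyr::ungroup()
}

#' Per-subclass summed abundances
#'
#' Sums species-level values to GSL subclass totals per sample; sums are
#' preserved (`sum(species) == sum(class totals)` per sample). Species whose
#' class cannot be derived from the name and is absent from `class_map`
#' raise an error listing them.
#'
#' @param concentrations Tibble with `sample_id`, `name`, and a value column.
#' @param value Value column (default `"C_nmol"`).
#' @param class_map Optional tibble `name` -> `class_name` overriding the
#'   parser-derived mapping.
#' @return A tibble `sample_id`, `class_name`, `total`.
#' @export
class_totals <- function(concentrations, value = "C_nmol", class_map = NULL) {
  stopifnot(all(c("sample_id", "name") %in% names(concentrations)),
    value %in% names(concentrations))
  nm <- unique(concentrations$name)
  if (is.null(class_map)) {
    cls <- vapply(nm, function(x) {
      tryCatch(parse_species(x)$class_name, error = function(e) NA_character_)
    }, character(1))
    class_map <- tibble::tibble(name = nm, class_name = unname(cls))
  }
  unmapped <- setdiff(nm, class_map$name[!is.na(class_map$class_name)])
  if (length(unmapped) > 0) {
    stop("species without a class mapping: ",
      paste(utils::head(unmapped, 10), collapse = ", "),
      call. = FALSE
    )
  }
  concentrations |>
    dplyr::left_join(class_map, by = "name") |>
    dplyr::group_by(.data$sample_id, .data$class_name) |>
    dplyr::summarise(total = sum(.data[[value]]), .groups = "drop")
}
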