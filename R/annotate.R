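#' Tolerance configuration for 4D matching
#'
#' Windows follow the annotation settings used for automatic
#' glycosphingolipid annotation: m/z 2-5 mDa, RT 0.1-0.5 min, CCS 0.1-2.0 %,
#' MS/MS score floor 500-900 (on the 0-1000 cosine scale).
#'
#' @param mz_mDa m/z window in mDa (default 5).
#' @param rt_min RT window in minutes (default 0.5).
#' @param ccs_pct CCS window in percent (default 2.0).
#' @param msms_score_min Minimum spectral score when both spectra are present
#'   (default 500).
#' @param fragment_tol_mDa Fragment-level tolerance used for spectral scoring
#'   and diagnostic screening (default 10).
#' @return A list with class `tolerance_config`.
#' @export
tolerance_config <- function(mz_mDa = 5, rt_min = 0.5, ccs_pct = 2.0,
                             msms_score_min = 500, fragment_tol_mDa = 10) {
  stopifnot(mz_mDa > 0, rt_min > 0, ccs_pct > 0, msms_score_min >= 0,
    fragment_tol_mDa > 0)
  structure(
    list(
      mz_mDa = mz_mDa, rt_min = rt_min, ccs_pct = ccs_pct,
      msms_score_min = msms_score_min, fragment_tol_mDa = fragment_tol_mDa
    ),
    class = "tolerance_config"
  )
}

#' Cosine spectral similarity score
#'
#' 1000 x cosine similarity over tolerance-matched peak intensity vectors.
#' Peaks are greedily paired within the fragment tolerance; unmatched peaks
#' contribute zero-intensity partners. The score is symmetric and invariant
#' to intensity scaling. An empty spectrum scores 0 with a warning.
#'
#' @param query,reference Data frames with columns `mz`, `intensity`.
#' @param fragment_tol_mDa Peak match tolerance in mDa.
#' @return A score in `[0, 1000]`.
#' @examples
#' s <- data.frame(mz = c(100, 200), intensity = c(1, 2))
#' spectral_score(s, s) # 1000
#' @export
spectral_score <- function(query, reference, fragment_tol_mDa = 10) {
  if (nrow(query) == 0 || nrow(reference) == 0) {
    warning("empty spectrum: score 0", call. = FALSE)
    return(0)
  }
  tol <- fragment_tol_mDa / 1000
  q <- query[order(query$mz), , drop = FALSE]
  r <- reference[order(reference$mz), , drop = FALSE]
  # greedy pairing of nearest peaks within tolerance
  pairs_q <- integer(0)
  pairs_r <- integer(0)
  used_r <- rep(FALSE, nrow(r))
  for (i in seq_len(nrow(q))) {
    d <- abs(r$mz - q$mz[i])
    d[used_r] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tol) {
      pairs_q <- c(pairs_q, i)
      pairs_r <- c(pairs_r, j)
      used_r[j] <- TRUE
    }
  }
  qv <- c(q$intensity, rep(0, sum(!used_r)))
  rv <- c(rep(0, nrow(q)), r$intensity[!used_r])
  rv[pairs_q] <- r$intensity[pairs_r]
  qv_norm <- sqrt(sum(qv^2))
  rv_norm <- sqrt(sum(rv^2))
  if (qv_norm == 0 || rv_norm == 0) {
    return(0)
  }
  1000 * sum(qv * rv) / (qv_norm * rv_norm)
}

## per-candidate composite score; missing dimensions are renormalized
.composite_score <- function(dmz_frac, drt_frac, dccs_frac, msms) {
  w <- c(mz = 0.4, rt = 0.2, ccs = 0.2, msms = 0.2)
  comp <- c(
    mz = 1 - dmz_frac,
    rt = if (is.na(drt_frac)) NA else 1 - drt_frac,
    ccs = if (is.na(dccs_frac)) NA else 1 - dccs_frac,
    msms = if (is.na(msms)) NA else msms / 1000
  )
  ok <- !is.na(comp)
  sum(w[ok] * comp[ok]) / sum(w[ok])
}

#' Match features against a 4D library
#'
#' A library entry is a candidate for a feature when every active tolerance
#' window passes: m/z always; RT and CCS when present on both sides; the
#' MS/MS floor when both a query spectrum and a reference spectrum exist.
#' Candidates are ranked by a composite score (weighted normalized deltas
#' plus spectral score; weights 0.4/0.2/0.2/0.2 with missing dimensions
#' renormalized), with deterministic tie-breaking by smaller |dCCS|, then
#' |dmz|, then name. Features with no candidate are returned annotated as
#' `"unknown"`.
#'
#' @param features A data frame with columns `mz`, `polarity`, and optionally
#'   `feature_id`, `sample_id`, `fraction`, `z`, `rt_min`, `ccs_A2`, `area`,
#'   `spectrum_id`.
#' @param library A library tibble (see [serum_fixture()]).
#' @param tol A [tolerance_config()].
#' @param spectra Optional spectra tibble ([read_mgf()] layout) supplying
#'   query spectra via `features$spectrum_id` and reference spectra via
#'   `library$spectrum_ref`.
#' @return A tibble with one row per (feature, candidate) plus one `"unknown"`
#'   row per unmatched feature: feature columns, `entry_name`,
#'   `delta_mz_mDa`, `delta_rt_min`, `delta_ccs_pct`, `msms_score`, `score`,
#'   `rank`, `partial_evidence`.
#' @export
match_features <- function(features, library, tol = tolerance_config(),
                           spectra = NULL) {
  stopifnot(is.data.frame(features), all(c("mz", "polarity") %in% names(features)))
  .validate_library(library)
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- sprintf("F%04d", seq_len(nrow(features)))
  }
  for (cc in c("rt_min", "ccs_A2")) {
    if (!cc %in% names(features)) features[[cc]] <- NA_real_
  }
  if (!"spectrum_id" %in% names(features)) features$spectrum_id <- NA_character_

  get_spectrum <- function(id) {
    if (is.null(spectra) || is.na(id)) {
      return(NULL)
    }
    hit <- which(spectra$spectrum_id == id)
    if (length(hit) == 0) {
      return(NULL)
    }
    spectra$peaks[[hit[1]]]
  }

  lib_usable <- library[!is.na(library$mz), , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    cand <- lib_usable[lib_usable$polarity == f$polarity, , drop = FALSE]
    dmz <- abs(cand$mz - f$mz) * 1000
    keep <- dmz <= tol$mz_mDa
    cand <- cand[keep, , drop = FALSE]
    dmz <- dmz[keep]
    drt <- rep(NA_real_, nrow(cand))
    dccs <- rep(NA_real_, nrow(cand))
    if (!is.na(f$rt_min)) {
      have <- !is.na(cand$rt_min)
      drt[have] <- abs(cand$rt_min[have] - f$rt_min)
      keep <- is.na(drt) | drt <= tol$rt_min
      cand <- cand[keep, , drop = FALSE]
      dmz <- dmz[keep]
      drt <- drt[keep]
      dccs <- dccs[keep]
    }
    if (!is.na(f$ccs_A2)) {
      have <- !is.na(cand$ccs_A2)
      dccs[have] <- abs(cand$ccs_A2[have] - f$ccs_A2) / cand$ccs_A2[have] * 100
      keep <- is.na(dccs) | dccs <= tol$ccs_pct
      cand <- cand[keep, , drop = FALSE]
      dmz <- dmz[keep]
      drt <- drt[keep]
      dccs <- dccs[keep]
    }
    qspec <- get_spectrum(f$spectrum_id)
    msms <- rep(NA_real_, nrow(cand))
    if (!is.null(qspec) && nrow(cand) > 0) {
      for (k in seq_len(nrow(cand))) {
        rspec <- get_spectrum(cand$spectrum_ref[k])
        if (!is.null(rspec)) {
          msms[k] <- spectral_score(qspec, rspec, tol$fragment_tol_mDa)
        }
      }
      keep <- is.na(msms) | msms >= tol$msms_score_min
      cand <- cand[keep, , drop = FALSE]
      dmz <- dmz[keep]
      drt <- drt[keep]
      dccs <- dccs[keep]
      msms <- msms[keep]
    }
    base_cols <- f[intersect(
      c(
        "feature_id", "sample_id", "fraction", "polarity", "mz", "z",
        "rt_min", "ccs_A2", "area", "spectrum_id"
      ),
      names(f)
    )]
    if (nrow(cand) == 0) {
      return(dplyr::bind_cols(base_cols, tibble::tibble(
        entry_name = "unknown", delta_mz_mDa = NA_real_,
        delta_rt_min = NA_real_, delta_ccs_pct = NA_real_,
        msms_score = NA_real_, score = NA_real_, rank = NA_integer_,
        partial_evidence = is.na(f$rt_min) || is.na(f$ccs_A2)
      )))
    }
    score <- vapply(seq_len(nrow(cand)), function(k) {
      .composite_score(
        dmz[k] / tol$mz_mDa,
        if (is.na(drt[k])) NA else drt[k] / tol$rt_min,
        if (is.na(dccs[k])) NA else dccs[k] / tol$ccs_pct,
        msms[k]
      )
    }, numeric(1))
    ord <- order(-score, ifelse(is.na(dccs), Inf, dccs), dmz, cand$name)
    dplyr::bind_cols(
      base_cols[rep(1, nrow(cand)), , drop = FALSE],
      tibble::tibble(
        entry_name = cand$name[ord], delta_mz_mDa = dmz[ord],
        delta_rt_min = drt[ord], delta_ccs_pct = dccs[ord],
        msms_score = msms[ord], score = score[ord],
        rank = seq_len(nrow(cand)),
        partial_evidence = is.na(f$rt_min) || is.na(f$ccs_A2)
      )
    )
  })
  tibble::as_tibble(out)
}

#' Pre-screen features for GSL candidacy by diagnostic ions
#'
#' Implements the diagnostic pre-filter: in negative mode, features whose
#' spectra contain the deprotonated Neu5Ac B ion (nominal 290) are kept; in
#' positive mode those with the Neu5Ac oxonium minus water (nominal 274); in
#' `mode = "neutral"` those showing a neutral loss of one hexose (162) or of
#' lactose (342) from the precursor.
#'
#' @param features Feature data frame with a `spectrum_id` column.
#' @param spectra Spectra tibble ([read_mgf()] layout).
#' @param polarity `"-"` or `"+"`.
#' @param mode `"sialylated"` (default) or `"neutral"`.
#' @param fragment_tol_mDa Fragment tolerance in mDa.
#' @return The features that pass, with a `flags` list-column of diagnostic
#'   flag tibbles.
#' @export
screen_candidates <- function(features, spectra, polarity = "-",
                              mode = c("sialylated", "neutral"),
                              fragment_tol_mDa = 10) {
  mode <- match.arg(mode)
  stopifnot("spectrum_id" %in% names(features))
  flags <- purrr::map(seq_len(nrow(features)), function(i) {
    hit <- which(spectra$spectrum_id == features$spectrum_id[i])
    if (length(hit) == 0) {
      return(classify_spectrum(
        data.frame(mz = numeric(0), intensity = numeric(0)), polarity
      ))
    }
    classify_spectrum(
      spectra$peaks[[hit[1]]], polarity, fragment_tol_mDa,
      precursor_mz = spectra$precursor_mz[hit[1]]
    )
  })
  keep <- vapply(flags, function(fl) {
    if (mode == "neutral") {
      fl$hex_loss || fl$hex2_loss
    } else if (polarity == "-") {
      fl$sialylated_neg
    } else {
      fl$sialylated_pos
    }
  }, logical(1))
  out <- features[keep, , drop = FALSE]
  out$flags <- flags[keep]
  tibble::as_tibble(out)
}
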