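## Plain-text spectrum formats. Spectra are kept as a named list of tibbles
## (columns mz, intensity) keyed by spectrum id; MGF carries the precursor as
## PEPMASS, MSP as PrecursorMZ.

#' Read an MGF file
#'
#' @param path Path to an MGF file. Each `BEGIN IONS`/`END IONS` block must
#'   carry a `TITLE` (used as spectrum id) and may carry `PEPMASS` and
#'   `CHARGE`.
#' @return A tibble with one row per spectrum: `spectrum_id`, `precursor_mz`,
#'   `charge`, `polarity` and a `peaks` list-column of tibbles
#'   (`mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) {
    stop("unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  }
  purrr::map2_dfr(starts, ends, function(a, b) {
    block <- lines[(a + 1):(b - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- block[kv]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    peak_lines <- block[!kv & grepl("^[0-9]", trimws(block))]
    peaks <- if (length(peak_lines) > 0) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"), function(p) {
        as.numeric(p[1:2])
      }))
      tibble::tibble(mz = mat[, 1], intensity = mat[, 2])
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    ch <- get("CHARGE")
    polarity <- if (!is.na(ch) && grepl("-", ch)) "-" else "+"
    z <- if (is.na(ch)) NA_integer_ else as.integer(gsub("[^0-9]", "", ch))
    tibble::tibble(
      spectrum_id = ifelse(is.na(get("TITLE")), paste0("spectrum_", a), get("TITLE")),
      precursor_mz = suppressWarnings(as.numeric(sub(" .*$", "", get("PEPMASS")))),
      charge = z,
      polarity = polarity,
      peaks = list(peaks)
    )
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra A tibble as returned by [read_mgf()] (columns `spectrum_id`,
#'   `precursor_mz`, `charge`, `polarity`, `peaks`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", spectra$spectrum_id[i]), con)
    if (!is.na(spectra$precursor_mz[i])) {
      writeLines(sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]), con)
    }
    z <- spectra$charge[i]
    if (!is.null(z) && !is.na(z)) {
      writeLines(sprintf("CHARGE=%d%s", z, ifelse(spectra$polarity[i] == "-", "-", "+")), con)
    }
    pk <- spectra$peaks[[i]]
    if (nrow(pk) > 0) {
      writeLines(sprintf("%.6f %.6g", pk$mz, pk$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read an MSP spectral library file
#'
#' @param path Path to an MSP file (`Name:` headers, `Num Peaks:` then
#'   peak lines).
#' @return A tibble like [read_mgf()]'s, with `spectrum_id` taken from
#'   `Name:`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name_idx <- grep("^Name:", lines, ignore.case = TRUE)
  if (length(name_idx) == 0) {
    return(tibble::tibble(
      spectrum_id = character(0), precursor_mz = numeric(0),
      charge = integer(0), polarity = character(0), peaks = list()
    ))
  }
  bounds <- c(name_idx, length(lines) + 1)
  purrr::map_dfr(seq_along(name_idx), function(k) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1)]
    get <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, ignore.case = TRUE, value = TRUE)
      if (length(hit) == 0) {
        return(NA_character_)
      }
      trimws(sub("^[^:]*:", "", hit[1]))
    }
    np_line <- grep("^Num ?Peaks:", block, ignore.case = TRUE)
    peaks <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
    if (length(np_line) == 1) {
      pl <- block[-seq_len(np_line)]
      pl <- pl[grepl("^[0-9]", trimws(pl))]
      if (length(pl) > 0) {
        mat <- do.call(rbind, lapply(strsplit(trimws(pl), "[ \t;]+"), function(p) {
          as.numeric(p[1:2])
        }))
        peaks <- tibble::tibble(mz = mat[, 1], intensity = mat[, 2])
      }
    }
    pol <- get("Ion_mode")
    tibble::tibble(
      spectrum_id = get("Name"),
      precursor_mz = suppressWarnings(as.numeric(get("PrecursorMZ"))),
      charge = suppressWarnings(as.integer(gsub("[^0-9]", "", get("Charge")))),
      polarity = ifelse(is.na(pol), "-", ifelse(toupper(pol) %in% c("N", "NEGATIVE", "-"), "-", "+")),
      peaks = list(peaks)
    )
  })
}

#' Write spectra to an MSP file
#'
#' @param spectra A spectra tibble (see [read_mgf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    writeLines(paste0("Name: ", spectra$spectrum_id[i]), con)
    if (!is.na(spectra$precursor_mz[i])) {
      writeLines(sprintf("PrecursorMZ: %.6f", spectra$precursor_mz[i]), con)
    }
    z <- spectra$charge[i]
    if (!is.null(z) && !is.na(z)) writeLines(paste0("Charge: ", z), con)
    writeLines(paste0(
      "Ion_mode: ",
      ifelse(spectra$polarity[i] == "-", "N", "P")
    ), con)
    pk <- spectra$peaks[[i]]
    writeLines(paste0("Num Peaks: ", nrow(pk)), con)
    if (nrow(pk) > 0) {
      writeLines(sprintf("%.6f %.6g", pk$mz, pk$intensity), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
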