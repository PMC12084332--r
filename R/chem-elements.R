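## Monoisotopic atomic masses (IUPAC); D = deuterium (2H).
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177785,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

## Neutral small molecules used in adducts and neutral losses.
.H2O_MASS <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
.HCOOH_MASS <- .ATOMIC_MASS[["C"]] + 2 * .ATOMIC_MASS[["H"]] + 2 * .ATOMIC_MASS[["O"]]

#' Parse a molecular formula string into element counts
#'
#' Formulas use element symbols C, H, D (deuterium), N, O, S followed by an
#' optional count, e.g. `"C36H71NO3"` or `"C18H32D5NO2"`.
#'
#' @param x Character vector of formula strings. `""` parses to the empty
#'   composition (mass 0).
#' @return A list of named numeric vectors (element -> count), one per input.
#' @examples
#' formula_parse("C6H10O5")
#' @export
formula_parse <- function(x) {
  stopifnot(is.character(x))
  lapply(x, function(f) {
    if (is.na(f) || !nzchar(f)) {
      return(stats::setNames(numeric(0), character(0)))
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    if (sum(nchar(parts)) != nchar(f)) {
      stop("malformed formula: '", f, "'", call. = FALSE)
    }
    el <- sub("[0-9]*$", "", parts)
    n <- as.numeric(ifelse(grepl("[0-9]+$", parts),
      sub("^[A-Za-z]+", "", parts), "1"
    ))
    bad <- setdiff(el, names(.ATOMIC_MASS))
    if (length(bad) > 0) {
      stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    counts <- tapply(n, el, sum)
    out <- as.numeric(counts)
    names(out) <- names(counts)
    formula_canonical(out)
  })
}

## Order elements C, H, D, then alphabetical; drop zero counts.
formula_canonical <- function(fc) {
  fc <- fc[fc != 0]
  pref <- c("C", "H", "D")
  rest <- sort(setdiff(names(fc), pref))
  fc[c(intersect(pref, names(fc)), rest)]
}

#' Combine element-count vectors
#'
#' `formula_add()` sums compositions; `formula_subtract()` subtracts and
#' errors if any element count would go negative.
#'
#' @param ... Named numeric vectors (element -> count) or formula strings.
#' @return A named numeric vector.
#' @export
formula_add <- function(...) {
  parts <- lapply(list(...), .as_counts)
  all_el <- unique(unlist(lapply(parts, names)))
  out <- stats::setNames(numeric(length(all_el)), all_el)
  for (p in parts) out[names(p)] <- out[names(p)] + p
  formula_canonical(out)
}

#' @rdname formula_add
#' @param x,y Compositions (named numeric vectors or formula strings).
#' @export
formula_subtract <- function(x, y) {
  x <- .as_counts(x)
  y <- .as_counts(y)
  all_el <- unique(c(names(x), names(y)))
  out <- stats::setNames(numeric(length(all_el)), all_el)
  out[names(x)] <- x
  out[names(y)] <- out[names(y)] - y
  if (any(out < 0)) {
    stop(
      "negative element count after subtraction: ",
      paste(names(out)[out < 0], collapse = ", "),
      call. = FALSE
    )
  }
  formula_canonical(out)
}

.as_counts <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    return(formula_parse(x)[[1]])
  }
  stopifnot(is.numeric(x), !is.null(names(x)) || length(x) == 0)
  formula_canonical(x)
}

#' Format element counts as a formula string
#'
#' @param fc A named numeric vector (element -> count), or a list of them.
#' @return Character vector of formula strings (Hill-like order C, H, D, then
#'   alphabetical).
#' @export
formula_string <- function(fc) {
  if (is.list(fc)) {
    return(vapply(fc, formula_string, character(1)))
  }
  fc <- formula_canonical(.as_counts(fc))
  if (length(fc) == 0) {
    return("")
  }
  paste0(names(fc), ifelse(fc == 1, "", as.character(fc)), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums monoisotopic atomic masses over the composition. Deterministic to
#' better than 1e-5 Da.
#'
#' @param formula A formula string (vectorized), or a named numeric vector of
#'   element counts, or a list of such vectors.
#' @return Numeric vector of masses in Da. The empty composition has mass 0.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C11H17NO8") # Neu5Ac residue
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- formula_parse(formula)
  if (!is.list(formula)) formula <- list(.as_counts(formula))
  vapply(formula, function(fc) {
    if (length(fc) == 0) {
      return(0)
    }
    bad <- setdiff(names(fc), names(.ATOMIC_MASS))
    if (length(bad) > 0) {
      stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    sum(.ATOMIC_MASS[names(fc)] * fc)
  }, numeric(1))
}
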