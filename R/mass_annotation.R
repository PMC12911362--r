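#' @include AllClasses.R
NULL

# CODATA/IUPAC monoisotopic masses (Da)
.MONOISOTOPIC <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207117)
.ELECTRON_MASS <- 0.00054858

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas such as "C6H13O9P" or "H2PO4"; element
#' symbols may repeat (counts are summed).
#'
#' @param formula character formula, or an already-parsed named numeric
#'   vector (returned unchanged).
#' @return named numeric vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula))) stop("parsed formulas must be named")
    return(formula)
  }
  s <- gsub("\\s", "", formula)
  if (!nzchar(s)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", formula)
  counts <- numeric(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + n
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums per-element monoisotopic masses; the anion convention adds one
#' electron mass, the cation convention subtracts one (singly charged
#' ions), the neutral convention adds none. Printed fragment masses such
#' as m/z 96.969 for H2PO4 follow the neutral-moiety convention.
#'
#' @param formula formula string or named count vector
#'   (\code{\link{parseFormula}}).
#' @param convention "neutral" (default), "anion" or "cation".
#' @return mass in Da (m/z for the charged conventions).
#' @export
monoisotopicMass <- function(formula,
                             convention = c("neutral", "anion", "cation")) {
  convention <- match.arg(convention)
  counts <- parseFormula(formula)
  if (any(counts < 0)) stop("element counts must be >= 0")
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  m <- sum(.MONOISOTOPIC[names(counts)] * counts)
  switch(convention, neutral = m, anion = m + .ELECTRON_MASS,
         cation = m - .ELECTRON_MASS)
}

#' Match an observed m/z against an expected mass at a ppm tolerance
#'
#' \code{ppm_error = 1e6 * (observed - expected) / expected}; the match is
#' within tolerance when |ppm_error| <= \code{tolerance_ppm} (boundary
#' inclusive).
#'
#' @param observed,expected m/z values (> 0).
#' @param tolerance_ppm tolerance in parts per million (default 1).
#' @return list with \code{observed_mz}, \code{expected_mz},
#'   \code{ppm_error}, \code{within_tolerance}.
#' @export
ppmMatch <- function(observed, expected, tolerance_ppm = 1.0) {
  if (observed <= 0 || expected <= 0) stop("m/z values must be > 0")
  ppm <- 1e6 * (observed - expected) / expected
  list(observed_mz = observed, expected_mz = expected, ppm_error = ppm,
       within_tolerance = abs(ppm) <= tolerance_ppm)
}

#' Exact mass difference between two analog formulas
#'
#' Signed neutral monoisotopic mass difference mass(a) - mass(b), e.g. the
#' 0.0095 Da difference between glucose 6-phosphate (C6H13O9P) and glucose
#' 6-sulfate (C6H12O9S) used to support a sulfate-analog identification.
#' When an observed precursor mass delta is supplied, its magnitude is
#' compared with the expected magnitude at an absolute tolerance.
#'
#' @param formula_a,formula_b formulas (string or parsed).
#' @param observed_delta optional observed mass difference magnitude (Da).
#' @param tolerance absolute tolerance for the comparison (default 0.001
#'   Da).
#' @return list with \code{delta} (signed, Da), \code{observed_delta} and
#'   \code{matches} (NA when no observed delta is given).
#' @export
analogDelta <- function(formula_a, formula_b, observed_delta = NULL,
                        tolerance = 0.001) {
  delta <- monoisotopicMass(formula_a) - monoisotopicMass(formula_b)
  matches <- if (is.null(observed_delta)) NA
             else abs(abs(observed_delta) - abs(delta)) <= tolerance
  list(delta = delta, observed_delta = observed_delta, matches = matches)
}
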