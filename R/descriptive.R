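# Descriptive statistics and DOM optical indices.

#' Moment-based descriptive statistics for a concentration vector
#'
#' Reports the summary statistics used to characterise heavy-metal
#' distributions: mean, sample standard deviation, coefficient of variation
#' (as a ratio and as percent), quartiles, moment skewness and kurtosis.
#' Kurtosis is reported in both conventions — raw (normal = 3) and excess
#' (normal = 0) — with `kurtosis_convention` selecting which one populates
#' the `kurtosis` field (default `"raw"`).
#'
#' @param values Numeric vector, n >= 2, all finite.
#' @param kurtosis_convention `"raw"` or `"excess"`.
#' @return An object of class `descriptive_stats`: a list with fields `n`,
#'   `mean`, `sd`, `cv` (ratio), `cv_pct`, `cv_defined`, `min`, `q1`,
#'   `median`, `q3`, `max`, `skewness`, `kurtosis`, `kurtosis_raw`,
#'   `kurtosis_excess`, `kurtosis_convention`.
#' @details Skewness is the moment estimator m3 / m2^(3/2) and raw kurtosis
#'   m4 / m2^2 with central moments mk = mean((x - xbar)^k). A constant
#'   vector has sd 0, cv 0 and skewness 0 by convention; its kurtosis is
#'   undefined (`NA`). When the mean is 0 the cv is undefined and flagged.
#' @export
descriptive_stats <- function(values, kurtosis_convention = c("raw", "excess")) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  values <- as.numeric(values)
  if (length(values) < 2) stop("insufficient data: need n >= 2")
  if (!all(is.finite(values))) stop("all values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  centered <- values - m
  m2 <- mean(centered^2)
  m3 <- mean(centered^3)
  m4 <- mean(centered^4)
  if (m2 == 0) {
    skew <- 0
    kurt_raw <- NA_real_
  } else {
    skew <- m3 / m2^1.5
    kurt_raw <- m4 / m2^2
  }
  kurt_excess <- kurt_raw - 3
  cv_defined <- m != 0
  cv <- if (!cv_defined) NA_real_ else s / m
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  out <- list(
    n = n, mean = m, sd = s,
    cv = cv, cv_pct = 100 * cv, cv_defined = cv_defined,
    min = min(values), q1 = q[1], median = q[2], q3 = q[3], max = max(values),
    skewness = skew,
    kurtosis = if (kurtosis_convention == "raw") kurt_raw else kurt_excess,
    kurtosis_raw = kurt_raw, kurtosis_excess = kurt_excess,
    kurtosis_convention = kurtosis_convention
  )
  class(out) <- "descriptive_stats"
  out
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf(
    "n=%d mean=%.4g sd=%.4g cv=%.4g skewness=%.4g kurtosis(%s)=%.4g\n",
    x$n, x$mean, x$sd, x$cv, x$skewness, x$kurtosis_convention, x$kurtosis))
  invisible(x)
}

#' A DOM UV-visible absorbance record
#'
#' Holds the absorbance readings of a dissolved-organic-matter extract at
#' the eight standard wavelengths, the cuvette path length, and the
#' dissolved organic carbon concentration needed for the optical indices.
#'
#' @param a250,a254,a365,a400,a436,a465,a600,a665 Absorbances (unitless,
#'   >= 0) at the named wavelengths in nm.
#' @param path_length_cm Optical path length in cm (> 0).
#' @param doc Dissolved organic carbon concentration (> 0).
#' @param doc_unit `"g_per_l"` (default) or `"mg_per_l"`; mg/L input is
#'   converted to g/L so SUVA254 comes out in L g^-1 cm^-1.
#' @return An object of class `dom_optical_record`.
#' @export
dom_optical_record <- function(a250, a254, a365, a400, a436, a465, a600, a665,
                               path_length_cm = 1, doc,
                               doc_unit = c("g_per_l", "mg_per_l")) {
  doc_unit <- match.arg(doc_unit)
  absorbances <- c(a250 = a250, a254 = a254, a365 = a365, a400 = a400,
                   a436 = a436, a465 = a465, a600 = a600, a665 = a665)
  if (any(!is.finite(absorbances)) || any(absorbances < 0)) {
    stop("all absorbances must be finite and >= 0")
  }
  if (!is.finite(path_length_cm) || path_length_cm <= 0) {
    stop("path_length_cm must be > 0")
  }
  if (!is.finite(doc) || doc <= 0) stop("doc must be > 0")
  doc_g_l <- if (doc_unit == "mg_per_l") doc / 1000 else doc
  structure(
    list(absorbances = absorbances, path_length_cm = path_length_cm,
         doc_g_l = doc_g_l),
    class = "dom_optical_record"
  )
}

#' DOM optical indices: SUVA254, delta log K and E ratios
#'
#' Computes SUVA254 = A254 / (l * DOC) with DOC in g/L (L g^-1 cm^-1),
#' the humification index delta log K = log10(A400) - log10(A600), and the
#' absorbance ratios E2/E3 = A250/A365, E2/E4 = A254/A436 and
#' E4/E6 = A465/A665. SUVA254 and delta log K track DOM aromaticity and
#' humification degree; the E ratios characterise DOM composition.
#'
#' @param record A [dom_optical_record()].
#' @return List with `suva254`, `delta_log_k`, `e2_e3`, `e2_e4`, `e4_e6`
#'   and `undefined`, a character vector naming indices whose denominator
#'   (A365, A400/A600 or A436/A665) was zero; those values are `NA`, not an
#'   error.
#' @export
dom_optical_indices <- function(record) {
  stopifnot(inherits(record, "dom_optical_record"))
  a <- record$absorbances
  undefined <- character(0)
  suva254 <- a[["a254"]] / (record$path_length_cm * record$doc_g_l)

  if (a[["a400"]] > 0 && a[["a600"]] > 0) {
    delta_log_k <- log10(a[["a400"]]) - log10(a[["a600"]])
  } else {
    delta_log_k <- NA_real_
    undefined <- c(undefined, "delta_log_k")
  }
  ratio <- function(num, den, name) {
    if (a[[den]] > 0) return(a[[num]] / a[[den]])
    undefined <<- c(undefined, name)
    NA_real_
  }
  e2_e3 <- ratio("a250", "a365", "e2_e3")
  e2_e4 <- ratio("a254", "a436", "e2_e4")
  e4_e6 <- ratio("a465", "a665", "e4_e6")
  list(suva254 = suva254, delta_log_k = delta_log_k,
       e2_e3 = e2_e3, e2_e4 = e2_e4, e4_e6 = e4_e6,
       undefined = undefined)
}
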