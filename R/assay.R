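# Closed-form assay computations: specific lysis for the bioluminescence
# and 51Cr-release cytotoxicity readouts, and caliper tumor volume.

#' Percent specific lysis
#'
#' Normalizes a test signal to the assay window spanned by the
#' spontaneous and maximum-release controls:
#' \itemize{
#'   \item bioluminescence (live target cells emit light):
#'     `100 * (spontaneous - test) / (spontaneous - maximum)`
#'   \item chromium (lysed target cells release 51Cr):
#'     `100 * (test - spontaneous) / (maximum - spontaneous)`
#' }
#' Both forms return 0 at the spontaneous control and 100 at the maximum
#' control. Vectorized over wells.
#'
#' @param test Test-well signal (RLU or cpm).
#' @param spontaneous Spontaneous-release control signal.
#' @param maximum Maximum-release (full lysis) control signal.
#' @param modality `"bioluminescence"` or `"chromium"`.
#' @return Percent specific lysis. Values outside `[-25, 125]` are kept
#'   but flagged with a warning (out-of-range measurement).
#' @export
specific_lysis <- function(test, spontaneous, maximum,
                           modality = c("bioluminescence", "chromium")) {
  modality <- match.arg(modality)
  if (any(c(test, spontaneous, maximum) < 0, na.rm = TRUE))
    stop("specific_lysis: signals must be >= 0")
  if (modality == "bioluminescence") {
    den <- spontaneous - maximum
    num <- spontaneous - test
    if (any(spontaneous < maximum, na.rm = TRUE))
      warning("specific_lysis: spontaneous < maximum is inconsistent ",
              "with a bioluminescence readout (live cells emit more light)")
  } else {
    den <- maximum - spontaneous
    num <- test - spontaneous
    if (any(maximum < spontaneous, na.rm = TRUE))
      warning("specific_lysis: maximum < spontaneous is inconsistent ",
              "with a chromium-release readout")
  }
  if (any(den == 0, na.rm = TRUE))
    stop("specific_lysis: zero denominator (no assay window between ",
         "spontaneous and maximum controls)")
  out <- 100 * num / den
  if (any(out < -25 | out > 125, na.rm = TRUE))
    warning("specific_lysis: result(s) outside [-25, 125]%; kept but ",
            "likely out-of-range measurements")
  out
}

#' Add specific lysis to a per-well table
#'
#' @param df data.frame with columns `test`, `spontaneous`, `maximum` and
#'   optionally `modality` (single modality per table otherwise supplied
#'   via `modality`).
#' @param modality Used when the table has no `modality` column.
#' @return `df` with a `specific_lysis_pct` column appended.
#' @export
specific_lysis_table <- function(df, modality = "bioluminescence") {
  need <- c("test", "spontaneous", "maximum")
  if (!all(need %in% names(df)))
    stop("specific_lysis_table: need columns ",
         paste(need, collapse = ", "))
  mod <- if ("modality" %in% names(df)) df$modality else modality
  df$specific_lysis_pct <- vapply(seq_len(nrow(df)), function(i)
    specific_lysis(df$test[i], df$spontaneous[i], df$maximum[i],
                   match.arg(mod[[min(i, length(mod))]],
                             c("bioluminescence", "chromium"))),
    numeric(1))
  df
}

#' Caliper tumor volume
#'
#' Sphere volume `V = 4/3 * pi * r^3` from the caliper radius.
#'
#' @param radius_mm Tumor radius in mm (> 0). Calipers measure diameter;
#'   see [caliper_volume()].
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(radius_mm) {
  if (any(radius_mm <= 0)) stop("tumor_volume: radius must be > 0")
  4 / 3 * pi * radius_mm^3
}

#' Tumor volume from a caliper diameter
#'
#' @param diameter_mm Measured diameter in mm (> 0); the radius is
#'   `diameter / 2`.
#' @return Volume in mm^3.
#' @export
caliper_volume <- function(diameter_mm) tumor_volume(diameter_mm / 2)
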