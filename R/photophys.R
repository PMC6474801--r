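# Beer-Lambert arithmetic for dye and dye-conjugate photophysics:
# A = epsilon * c * l, brightness = epsilon * quantum yield.

#' Absorbance reading
#'
#' @param absorbance dimensionless absorbance A (>= 0).
#' @param concentration_M molar concentration, when known (> 0 or NA).
#' @param path_cm cuvette path length, cm (default 1, the standard cuvette).
#' @param context free-text context tag (e.g. `"sds"`, `"buffer_free_dye"`,
#'   `"conjugate_3eq"`, `"conjugate_6eq"`).
#' @return an `AbsorbanceReading` list.
#' @export
absorbance_reading <- function(absorbance, concentration_M = NA_real_,
                               path_cm = 1, context = NA_character_) {
  stopifnot(is.finite(absorbance), absorbance >= 0,
            is.finite(path_cm), path_cm > 0)
  if (!is.na(concentration_M)) stopifnot(concentration_M > 0)
  structure(list(absorbance = absorbance, concentration_M = concentration_M,
                 path_cm = path_cm, context = context),
            class = "AbsorbanceReading")
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * l)`, e.g. for determining stock concentrations from
#' a reference extinction coefficient.
#'
#' @param reading an [absorbance_reading()].
#' @param epsilon molar extinction coefficient, 1/(M cm) (> 0).
#' @return concentration in mol/L.
#' @export
concentration_from_absorbance <- function(reading, epsilon) {
  stopifnot(inherits(reading, "AbsorbanceReading"))
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  reading$absorbance / (epsilon * reading$path_cm)
}

#' Extinction coefficient from absorbance at known concentration
#'
#' `epsilon = A / (c * l)`.
#'
#' @param reading an [absorbance_reading()] with known concentration.
#' @return epsilon in 1/(M cm).
#' @export
extinction_coefficient <- function(reading) {
  stopifnot(inherits(reading, "AbsorbanceReading"))
  if (is.na(reading$concentration_M) || reading$concentration_M <= 0)
    stop("concentration must be known and positive")
  reading$absorbance / (reading$concentration_M * reading$path_cm)
}

#' Saturation (complete-consumption) check
#'
#' Compares absorbance at 3 vs 6 molar equivalents of enzyme: when the two
#' readings agree within `rel_tol` the dye was completely consumed at the
#' lower excess, i.e. the labeling reaction was saturated.
#'
#' @param a3,a6 [absorbance_reading()]s at 3 and 6 equivalents.
#' @param rel_tol relative tolerance (default 0.05).
#' @return logical.
#' @export
saturation_check <- function(a3, a6, rel_tol = 0.05) {
  stopifnot(inherits(a3, "AbsorbanceReading"), inherits(a6, "AbsorbanceReading"))
  if (a3$absorbance == 0) stop("reference absorbance is zero")
  abs(a6$absorbance - a3$absorbance) / a3$absorbance <= rel_tol
}

#' Dye-conjugate record
#'
#' @param dye dye name (e.g. `"SiR"`, `"TMR"`, `"JF549"`, `"JF646"`).
#' @param tag `"halo"`, `"snap"` or `"free"`.
#' @param epsilon molar extinction coefficient, 1/(M cm) (> 0).
#' @param quantum_yield fluorescence quantum yield in (0, 1], supplied
#'   externally (never hard-coded), or NA when unknown.
#' @return a `ConjugateRecord` list with `brightness = epsilon *
#'   quantum_yield` when the yield is present.
#' @export
conjugate_record <- function(dye, tag = c("halo", "snap", "free"),
                             epsilon, quantum_yield = NA_real_) {
  tag <- match.arg(tag)
  stopifnot(is.finite(epsilon), epsilon > 0)
  if (!is.na(quantum_yield))
    stopifnot(quantum_yield > 0, quantum_yield <= 1)
  structure(list(dye = dye, tag = tag, epsilon = epsilon,
                 quantum_yield = quantum_yield,
                 brightness = if (is.na(quantum_yield)) NA_real_
                              else epsilon * quantum_yield),
            class = "ConjugateRecord")
}

#' Extinction and brightness fold between two conjugates
#'
#' `epsilon_fold = epsilon_a / epsilon_b`; `brightness_fold =
#' (epsilon_a * phi_a) / (epsilon_b * phi_b)` only when both quantum yields
#' are supplied, `NA` otherwise. Antisymmetric:
#' `fold(a, b) * fold(b, a) = 1`.
#'
#' @param a,b [conjugate_record()]s.
#' @return list: `epsilon_fold`, `brightness_fold`.
#' @export
brightness_fold <- function(a, b) {
  stopifnot(inherits(a, "ConjugateRecord"), inherits(b, "ConjugateRecord"))
  eps_fold <- a$epsilon / b$epsilon
  br_fold <- if (is.na(a$brightness) || is.na(b$brightness)) NA_real_
             else a$brightness / b$brightness
  list(epsilon_fold = eps_fold, brightness_fold = br_fold)
}

#' Summarize a table of absorbance readings
#'
#' Takes a data.frame of readings (columns `dye`, `tag`, `context`,
#' `absorbance`, `concentration_M`, `path_cm`, optional `quantum_yield`)
#' and returns per-row extinction coefficients and brightness where
#' computable.
#'
#' @param readings data.frame as above.
#' @return data.frame with `epsilon` and `brightness` columns appended.
#' @export
photophysics_table <- function(readings) {
  stopifnot(is.data.frame(readings),
            all(c("absorbance", "concentration_M", "path_cm") %in% names(readings)))
  eps <- vapply(seq_len(nrow(readings)), function(i) {
    r <- readings[i, ]
    if (is.na(r$concentration_M) || r$concentration_M <= 0) return(NA_real_)
    extinction_coefficient(absorbance_reading(r$absorbance, r$concentration_M,
                                              r$path_cm))
  }, numeric(1))
  qy <- if ("quantum_yield" %in% names(readings)) readings$quantum_yield
        else rep(NA_real_, nrow(readings))
  readings$epsilon <- eps
  readings$brightness <- ifelse(is.na(qy), NA_real_, eps * qy)
  readings
}
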