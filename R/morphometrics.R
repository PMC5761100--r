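#' Sex-specific fat-free body mass model
#'
#' A per-sex linear regression of fat-free mass on natural wing chord,
#' used as a structural body-size proxy.  Coefficients are a required
#' input (typically estimated from banding data on lean, fat-score-zero
#' birds); the synthetic generator supplies its own ground-truth values.
#'
#' @param coefficients named list: for each sex code (`F`, `M`) a list
#'   with `intercept` (grams) and `slope` (grams per mm wing chord).
#' @param provenance free text describing where the coefficients came from.
#' @return an object of class `fat_free_model`.
#' @export
fat_free_model <- function(coefficients, provenance = "") {
  if (!all(c("F", "M") %in% names(coefficients)))
    stop("coefficients must be supplied for both sexes F and M",
         call. = FALSE)
  for (s in names(coefficients)) {
    co <- coefficients[[s]]
    if (!is.finite(co$intercept) || !is.finite(co$slope))
      stop(sprintf("non-finite coefficients for sex '%s'", s), call. = FALSE)
  }
  structure(list(coefficients = coefficients, provenance = provenance),
            class = "fat_free_model")
}

#' Fat-free body mass from wing chord
#'
#' @param wing_chord_mm wing chord, millimetres.
#' @param sex character vector of sex codes matching the model (`F`/`M`).
#' @param model a [fat_free_model()].
#' @param chord_window plausibility window (mm); out-of-window chords
#'   raise a warning but are still computed.
#' @return fat-free mass, grams.
#' @export
fat_free_mass <- function(wing_chord_mm, sex, model,
                          chord_window = c(30, 60)) {
  stopifnot(inherits(model, "fat_free_model"))
  sex <- as.character(sex)
  unknown <- setdiff(unique(sex), names(model$coefficients))
  if (length(unknown))
    stop(sprintf("unknown sex code(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  out_of_window <- wing_chord_mm < chord_window[1] |
    wing_chord_mm > chord_window[2]
  if (any(out_of_window))
    warning(sprintf("%d wing chord(s) outside the plausibility window [%g, %g] mm",
                    sum(out_of_window), chord_window[1], chord_window[2]),
            call. = FALSE)
  vapply(seq_along(wing_chord_mm), function(i) {
    co <- model$coefficients[[sex[i]]]
    co$intercept + co$slope * wing_chord_mm[i]
  }, numeric(1))
}

#' Fuel load: capture mass minus fat-free mass
#'
#' Negative values (possible under measurement noise) are retained — and
#' flagged with a warning — rather than clamped, so downstream models stay
#' unbiased.
#'
#' @param mass_g capture mass, grams.
#' @param fat_free_mass_g fat-free mass, grams.
#' @return fuel load, grams.
#' @export
fuel_load <- function(mass_g, fat_free_mass_g) {
  stopifnot(all(is.finite(mass_g)), all(is.finite(fat_free_mass_g)))
  fl <- mass_g - fat_free_mass_g
  if (any(fl < 0))
    warning(sprintf("%d negative fuel load(s) retained (not clamped)",
                    sum(fl < 0)), call. = FALSE)
  fl
}

#' Ordinal day of year
#'
#' Jan 1 = 1; leap-aware for real calendar dates.
#'
#' @param date a `Date` vector or strings parseable as `%Y-%m-%d`.
#' @return integer day-of-year.
#' @export
ordinal_day <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(d)))
    stop("parse error: invalid calendar date", call. = FALSE)
  as.integer(format(d, "%j"))
}

#' Augment a migrant table with derived morphometric columns
#'
#' Adds `fat_free_mass_g`, `fuel_load_g` and (when absent) `ordinal_day`
#' computed from `capture_date`.
#'
#' @param migrants data frame with columns `sex`, `mass_g`,
#'   `wing_chord_mm` and either `ordinal_day` or `capture_date`.
#' @param model a [fat_free_model()].
#' @return the augmented data frame.
#' @export
augment_morphometrics <- function(migrants, model) {
  stopifnot(is.data.frame(migrants))
  out <- migrants
  out$fat_free_mass_g <- fat_free_mass(out$wing_chord_mm, out$sex, model)
  out$fuel_load_g <- fuel_load(out$mass_g, out$fat_free_mass_g)
  if (!"ordinal_day" %in% names(out))
    out$ordinal_day <- ordinal_day(out$capture_date)
  out
}
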