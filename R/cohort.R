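## Synthetic and trial patient cohorts.

#' Construct a patient record
#'
#' One record describes a (virtual or trial) Fontan patient at one imaging
#' time point: anthropometrics plus the state of the implanted conduit.
#'
#' @param patient_id Character label.
#' @param bsa Body surface area, m2.
#' @param implant_diameter Nominal graft diameter at implant, mm (16 or 18
#'   for trial-mimicking cohorts).
#' @param min_diameter Minimum graft diameter at the time point, mm.
#' @param elastic_modulus Tuned graft wall elastic modulus, kPa.
#' @param months_post_fontan Time point, months after the Fontan operation.
#' @param weight Body mass, kg; derived from `bsa` via [weight_from_bsa()]
#'   when missing.
#' @param wall_thickness Graft wall thickness, mm.
#' @param area_stenosis Independently measured cross-sectional area stenosis,
#'   percent from implant.  Carried through as data, never recomputed from
#'   diameters (luminal cross-sections are not circular).
#' @param dilated Logical; `TRUE` permits `min_diameter > implant_diameter`
#'   (early graft dilation).
#' @return An object of class `patient_record`.
#' @seealso [generate_cohort()], [trial_cohort()]
#' @export
patient_record <- function(patient_id, bsa, implant_diameter, min_diameter,
                           elastic_modulus = 13, months_post_fontan = 6,
                           weight = NULL, wall_thickness = 1.5,
                           area_stenosis = NA_real_, dilated = FALSE) {
  stopifnot(bsa > 0, implant_diameter > 0, min_diameter > 0,
            elastic_modulus > 0, wall_thickness > 0)
  if (!dilated && min_diameter > implant_diameter + 1e-9)
    stop("min_diameter exceeds implant_diameter; set dilated = TRUE for a dilated graft")
  if (is.null(weight)) weight <- weight_from_bsa(bsa)
  stopifnot(weight > 0)
  structure(list(patient_id = as.character(patient_id), bsa = bsa,
                 weight = weight, implant_diameter = implant_diameter,
                 months_post_fontan = months_post_fontan,
                 min_diameter = min_diameter,
                 elastic_modulus = elastic_modulus,
                 wall_thickness = wall_thickness,
                 area_stenosis = area_stenosis, dilated = dilated),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record> %s: BSA %.2f m2, weight %.1f kg, implant %g mm, min %g mm, E %g kPa\n",
    x$patient_id, x$bsa, x$weight, x$implant_diameter, x$min_diameter,
    x$elastic_modulus))
  invisible(x)
}

#' Pediatric weight from body surface area
#'
#' Inverts the Costeff pediatric relation BSA = (4W + 7)/(W + 90) to give
#' body mass from body surface area: W = (90 BSA - 7)/(4 - BSA).  Strictly
#' increasing on the pediatric range.
#'
#' @param bsa Body surface area, m2 (must be in (0, 4)).
#' @return Body mass, kg.
#' @examples
#' weight_from_bsa(0.67)
#' @export
weight_from_bsa <- function(bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0))
    stop("bsa must be positive")
  if (any(bsa >= 4)) stop("bsa out of pediatric range for the Costeff relation")
  w <- (90 * bsa - 7) / (4 - bsa)
  if (any(w <= 0)) stop("bsa below the validity range of the Costeff relation")
  w
}

#' Diameter stenosis relative to the implanted graft
#'
#' Percent reduction of the minimum conduit diameter relative to the nominal
#' diameter at implant, rounded to integer percent for reporting.
#'
#' @param min_diameter Minimum diameter, mm.
#' @param implant_diameter Nominal diameter at implant, mm.
#' @return Integer percent stenosis (negative values, i.e. dilation, clamp
#'   to 0).
#' @examples
#' diameter_stenosis(6.8, 16)  # 58
#' @export
diameter_stenosis <- function(min_diameter, implant_diameter) {
  if (any(min_diameter <= 0) || any(implant_diameter <= 0))
    stop("diameters must be positive")
  # half-up rounding (clinical reporting convention), with a guard against
  # binary representation error at exact .5 percent values
  pmax(0, floor(100 * (1 - min_diameter / implant_diameter) + 0.5 + 1e-9))
}

#' The four-patient trial cohort
#'
#' Loads the clinical description of the four trial patients shipped with
#' the package (minimum graft diameters, diameter and area stenosis, BSA and
#' tuned elastic moduli at each imaging event).
#'
#' @param time_point `"MRI I"` (6 months, default), `"MRI II"` (3 years),
#'   or `"all"` for the full event table as a data.frame.
#' @return For a specific time point, a list of [patient_record()]s (one per
#'   patient); for `"all"`, the full event data.frame.
#' @examples
#' trial_cohort("all")
#' @export
trial_cohort <- function(time_point = c("MRI I", "MRI II", "all")) {
  time_point <- match.arg(time_point)
  path <- system.file("extdata", "trial_cohort.csv", package = "fontanlpn",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (time_point == "all") return(tab)
  rows <- tab[tab$event == time_point & !is.na(tab$bsa_m2), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    patient_record(
      patient_id = r$patient_id, bsa = r$bsa_m2,
      implant_diameter = r$implant_diameter_mm,
      min_diameter = r$min_diameter_mm,
      elastic_modulus = r$elastic_modulus_kpa,
      months_post_fontan = r$months_post_fontan,
      area_stenosis = r$area_stenosis_pct,
      dilated = r$min_diameter_mm >= r$implant_diameter_mm)
  })
}

#' Generate a virtual Fontan cohort
#'
#' Samples virtual patients that statistically emulate the trial cohort:
#' BSA uniform on [0.53, 0.83] m2, implanted conduit diameter 16 or 18 mm,
#' tuned wall modulus uniform on [8, 17] kPa, and a minimum diameter drawn
#' as a uniform 0-60 percent diameter reduction from implant.  Sampling
#' distributions are uniform over the observed ranges because no
#' distributional information beyond the ranges is available.
#'
#' @param n Number of patients (>= 1).
#' @param seed RNG seed; a fixed seed reproduces the cohort bit-identically.
#' @param trial_fixture If `TRUE` and `n == 4`, return the four trial
#'   patients at 6 months post-Fontan instead of sampling.
#' @return List of [patient_record()]s.
#' @examples
#' cohort <- generate_cohort(6, seed = 1)
#' @export
generate_cohort <- function(n, seed = 1L, trial_fixture = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  if (trial_fixture) {
    if (n != 4) stop("the trial fixture has exactly 4 patients")
    return(trial_cohort("MRI I"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  bsa <- runif(n, 0.53, 0.83)
  implant <- sample(c(16, 18), n, replace = TRUE, prob = c(0.75, 0.25))
  sten <- runif(n, 0, 0.6)
  modulus <- runif(n, 8, 17)
  months <- sample(c(6, 36), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    patient_record(
      patient_id = sprintf("V%02d", i), bsa = bsa[i],
      implant_diameter = implant[i],
      min_diameter = implant[i] * (1 - sten[i]),
      elastic_modulus = modulus[i], months_post_fontan = months[i])
  })
}

## Save/restore the global RNG state so cohort generation does not disturb
## the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cohort as a data frame
#'
#' @param cohort List of [patient_record()]s.
#' @return data.frame with one row per record.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$patient_id, bsa = p$bsa, weight = p$weight,
               implant_diameter = p$implant_diameter,
               min_diameter = p$min_diameter,
               elastic_modulus = p$elastic_modulus,
               months_post_fontan = p$months_post_fontan,
               stringsAsFactors = FALSE)))
}
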