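# Treatment effects: how adherence to the medication classes modifies event
# hazards. Protective relative risks on CVD combine multiplicatively across
# classes; adverse effects raise the diabetes and GI-bleed hazards and add a
# one-shot cough probability under ACE-inhibitor use; antihypertensives
# lower the heart-failure hazard. An `itt_adjustment` exponent on the
# log-RRs supports the per-protocol sensitivity analysis.

#' Construct a treatment-effects parameter block
#'
#' All relative risks are per medication class versus no treatment, applied
#' only while the individual is adherent. Defaults are illustrative values
#' of the size meta-analyses of intention-to-treat trials report.
#'
#' @param rr_cvd_statin,rr_cvd_aht,rr_cvd_aspirin relative risks on the
#'   composite CVD hazard (> 0; < 1 is protective).
#' @param rr_diabetes_tx relative risk of new-onset diabetes under statin or
#'   antihypertensive treatment (> 0).
#' @param rr_gi_bleed_aspirin relative risk of gastrointestinal bleeding
#'   under aspirin (> 0).
#' @param p_cough_acei placebo-adjusted probability of a persistent cough
#'   per ACE-inhibitor initiation, in `[0, 1]`.
#' @param rr_hf_aht relative risk of heart failure under antihypertensives
#'   (> 0).
#' @param itt_adjustment exponent applied to every log-RR (> 0; default 1 =
#'   intention-to-treat effects as published; > 1 strengthens effects as a
#'   per-protocol sensitivity).
#' @return Object of class `treatment_effects`.
#' @export
treatment_effects <- function(rr_cvd_statin = 0.75,
                              rr_cvd_aht = 0.80,
                              rr_cvd_aspirin = 0.81,
                              rr_diabetes_tx = 1.10,
                              rr_gi_bleed_aspirin = 1.60,
                              p_cough_acei = 0.06,
                              rr_hf_aht = 0.72,
                              itt_adjustment = 1) {
  fx <- list(
    rr_cvd_statin = rr_cvd_statin, rr_cvd_aht = rr_cvd_aht,
    rr_cvd_aspirin = rr_cvd_aspirin, rr_diabetes_tx = rr_diabetes_tx,
    rr_gi_bleed_aspirin = rr_gi_bleed_aspirin, p_cough_acei = p_cough_acei,
    rr_hf_aht = rr_hf_aht, itt_adjustment = itt_adjustment
  )
  v <- validator()
  for (f in c("rr_cvd_statin", "rr_cvd_aht", "rr_cvd_aspirin",
              "rr_diabetes_tx", "rr_gi_bleed_aspirin", "rr_hf_aht",
              "itt_adjustment")) {
    v$check(is_pos(fx[[f]]) && length(fx[[f]]) == 1L,
            sprintf("%s: must be a single value > 0", f))
  }
  v$check(is_prob(fx$p_cough_acei) && length(fx$p_cough_acei) == 1L,
          "p_cough_acei: must be a probability in [0, 1]")
  v$fail_if_any("invalid treatment effects")
  structure(fx, class = "treatment_effects")
}

#' @export
print.treatment_effects <- function(x, ...) {
  cat("Treatment effects (relative risks vs no treatment):\n")
  cat(sprintf("  CVD: statin %.3f, antihypertensives %.3f, aspirin %.3f\n",
              x$rr_cvd_statin, x$rr_cvd_aht, x$rr_cvd_aspirin))
  cat(sprintf("  Adverse: diabetes %.3f, GI bleed (aspirin) %.3f, cough probability (ACEi) %.3f\n",
              x$rr_diabetes_tx, x$rr_gi_bleed_aspirin, x$p_cough_acei))
  cat(sprintf("  Heart failure (AHT): %.3f; ITT adjustment exponent: %.2f\n",
              x$rr_hf_aht, x$itt_adjustment))
  invisible(x)
}

# Medication profile helper: which classes does this regimen include?
# Both arms of the comparison cover all three indicated classes (the
# polypill combines them; usual care prescribes them separately).
regimen_classes <- function(statin = TRUE, aht = TRUE, aspirin = TRUE,
                            acei = TRUE) {
  list(statin = statin, aht = aht, aspirin = aspirin, acei = acei)
}

#' Treatment-adjusted CVD hazard
#'
#' While adherent, the baseline composite CVD hazard is multiplied by the
#' product of the class relative risks (each raised to the ITT-adjustment
#' exponent) over the classes in the individual's regimen. Non-adherent (or
#' ceased) individuals keep the baseline hazard.
#'
#' @param baseline per-year composite CVD hazard (>= 0).
#' @param meds regimen as a named list with logical `statin`, `aht`,
#'   `aspirin` (see details in the simulation).
#' @param adherent logical.
#' @param fx a [treatment_effects()] object.
#' @return Adjusted per-year hazard.
#' @export
adjusted_cvd_hazard <- function(baseline, meds, adherent, fx) {
  stopifnot(baseline >= 0)
  if (!isTRUE(adherent)) {
    return(baseline)
  }
  m <- 1
  a <- fx$itt_adjustment
  if (isTRUE(meds$statin)) m <- m * fx$rr_cvd_statin^a
  if (isTRUE(meds$aht)) m <- m * fx$rr_cvd_aht^a
  if (isTRUE(meds$aspirin)) m <- m * fx$rr_cvd_aspirin^a
  baseline * m
}

#' Adverse-event hazards under treatment
#'
#' While adherent: the diabetes hazard is multiplied by `rr_diabetes_tx`
#' when the regimen includes a statin or antihypertensive; the GI-bleed
#' hazard is multiplied by `rr_gi_bleed_aspirin` under aspirin; and a
#' persistent cough fires once, with probability `p_cough_acei`, at
#' ACE-inhibitor initiation.
#'
#' @param meds regimen (named list with logical `statin`, `aht`, `aspirin`,
#'   `acei`).
#' @param adherent logical.
#' @param baseline_diabetes,baseline_gi per-year baseline hazards (>= 0).
#' @param fx a [treatment_effects()] object.
#' @return List with `diabetes` and `gi_bleed` hazards and `p_cough`.
#' @export
adverse_event_hazards <- function(meds, adherent, baseline_diabetes,
                                  baseline_gi, fx) {
  stopifnot(baseline_diabetes >= 0, baseline_gi >= 0)
  if (!isTRUE(adherent)) {
    return(list(diabetes = baseline_diabetes, gi_bleed = baseline_gi,
                p_cough = 0))
  }
  a <- fx$itt_adjustment
  dia <- baseline_diabetes *
    if (isTRUE(meds$statin) || isTRUE(meds$aht)) fx$rr_diabetes_tx^a else 1
  gi <- baseline_gi *
    if (isTRUE(meds$aspirin)) fx$rr_gi_bleed_aspirin^a else 1
  list(diabetes = dia, gi_bleed = gi,
       p_cough = if (isTRUE(meds$acei)) fx$p_cough_acei else 0)
}

#' Packaged illustrative heart-failure baseline incidence table
#'
#' Per-year first-heart-failure incidence rising roughly exponentially with
#' age, the shape population incidence studies report.
#' @export
default_hf_table <- function() {
  age <- seq(30, 100, by = 5)
  data.frame(age = age, rate = 1e-4 * exp(0.072 * (age - 30)))
}

#' Age-interpolated heart-failure hazard under treatment
#'
#' Linear interpolation of the baseline incidence table at the given age,
#' multiplied by `rr_hf_aht` while adherent to an antihypertensive. Ages
#' outside the table range are clamped to the nearest endpoint with a
#' warning.
#'
#' @param age years.
#' @param baseline_hf_by_age data frame with columns `age` and `rate`.
#' @param adherent_aht logical: adherent to an antihypertensive?
#' @param fx a [treatment_effects()] object.
#' @return Per-year hazard.
#' @export
heart_failure_hazard <- function(age, baseline_hf_by_age = default_hf_table(),
                                 adherent_aht = FALSE,
                                 fx = treatment_effects()) {
  rng <- range(baseline_hf_by_age$age)
  if (any(age < rng[1] | age > rng[2])) {
    warning(sprintf(
      "heart_failure_hazard: age outside table range [%g, %g]; clamped", rng[1], rng[2]
    ))
  }
  h <- hf_hazard_at(age, baseline_hf_by_age)
  if (isTRUE(adherent_aht)) h <- h * fx$rr_hf_aht^fx$itt_adjustment
  h
}

# warning-free interpolation used inside the simulation loop
hf_hazard_at <- function(age, tab) {
  approx(tab$age, tab$rate, xout = age, rule = 2)$y
}
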