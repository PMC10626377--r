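#' Tumor self-dose, equal-dose activity matching and tandem prescriptions
#'
#' Converts cumulated activity into absorbed tumor self-dose per injected
#' activity (absorbed fraction 1 for the filtered emissions; cross-dose from
#' neighbouring organs ignored), solves the equal-dose activity-matching
#' problem between two isotopes, and scales matched mono prescriptions into a
#' tandem regimen.
#'
#' @name dosimetry
NULL

#' Tumor self-dose from cumulated activity
#'
#' `dose = A-tilde[uCi·h] * Delta[Gy·g/(uCi·h)] / mass[g]`, where the
#' cumulated activity in %IA·h is first scaled by the injected activity
#' (A-tilde[kBq·h] = value/100 * injected kBq; 37 kBq = 1 uCi exactly).
#' Reported both as total Gy for the given prescription and as cGy per
#' injected kBq (which is independent of the injected activity).
#'
#' @param cumulated a [cumulated_activity()] result (%IA·h).
#' @param delta a [dose_constant()].
#' @param tumor_mass grams (> 0).
#' @param injected_kbq injected activity in kBq.
#' @return object of class `absorbed_dose`: `total_gy`,
#'   `dose_per_injected_activity` (cGy/kBq), inputs retained.
#' @export
self_dose <- function(cumulated, delta, tumor_mass, injected_kbq) {
  stopifnot(inherits(cumulated, "cumulated_activity"),
            inherits(delta, "dose_constant"))
  if (!is.finite(tumor_mass) || tumor_mass <= 0) stop("tumor_mass must be > 0")
  if (!is.finite(injected_kbq) || injected_kbq <= 0) stop("injected_kbq must be > 0")
  a_kbq_h <- cumulated$value / 100 * injected_kbq
  a_uci_h <- a_kbq_h / KBQ_PER_UCI
  total_gy <- a_uci_h * delta$value / tumor_mass
  structure(list(total_gy = total_gy,
                 dose_per_injected_activity = total_gy * 100 / injected_kbq,
                 tumor_mass = tumor_mass, injected_kbq = injected_kbq,
                 dose_constant_used = delta, cumulated_activity_used = cumulated),
            class = "absorbed_dose")
}

#' @export
print.absorbed_dose <- function(x, ...) {
  cat(sprintf("Absorbed tumor self-dose: %.4g Gy (%.4g cGy/kBq, mass %.3g g, injected %.4g kBq)\n",
              x$total_gy, x$dose_per_injected_activity, x$tumor_mass, x$injected_kbq))
  invisible(x)
}

#' Equal-dose activity matching
#'
#' Injected activity of a target isotope that deposits the same tumor dose as
#' a reference prescription: `A_target = A_ref * D_ref / D_target`, with D the
#' dose per injected activity (any common unit). Alternatively pass
#' `dose_ratio = D_target / D_ref` directly.
#'
#' @param ref_kbq reference injected activity (kBq).
#' @param ref_dose,target_dose dose-per-injected-activity of the reference and
#'   target isotopes (`absorbed_dose` objects or numbers, same unit).
#' @param dose_ratio target:reference dose-per-activity ratio (used when the
#'   per-isotope doses are not supplied).
#' @return matched target activity in kBq.
#' @examples
#' match_activity(35000, dose_ratio = 850)  # ~41.2 kBq
#' @export
match_activity <- function(ref_kbq, ref_dose = NULL, target_dose = NULL,
                           dose_ratio = NULL) {
  stopifnot(ref_kbq > 0)
  as_rate <- function(x) if (inherits(x, "absorbed_dose")) x$dose_per_injected_activity else x
  if (is.null(dose_ratio)) {
    ref_dose <- as_rate(ref_dose); target_dose <- as_rate(target_dose)
    if (is.null(ref_dose) || is.null(target_dose)) {
      stop("supply either dose_ratio or both ref_dose and target_dose")
    }
    if (ref_dose <= 0 || target_dose <= 0) stop("dose rates must be > 0")
    dose_ratio <- target_dose / ref_dose
  }
  if (dose_ratio <= 0) stop("dose ratio must be > 0")
  ref_kbq / dose_ratio
}

#' Build an activity prescription
#'
#' @param nuclides character vector of component nuclide names.
#' @param kbq injected activities in kBq (> 0), one per component.
#' @param label `"mono"` or `"tandem"`.
#' @return object of class `activity_prescription` with a component table
#'   carrying both raw and reporting-rounded activities (integer MBq above
#'   1 MBq, integer kBq below; halves round down, so 17.5 MBq reports as 17).
#' @export
activity_prescription <- function(nuclides, kbq, label = c("mono", "tandem")) {
  label <- match.arg(label)
  stopifnot(length(nuclides) == length(kbq), all(kbq > 0))
  if (label == "tandem" && length(nuclides) < 2) {
    stop("a tandem prescription needs >= 2 components")
  }
  reported <- vapply(kbq, function(a) {
    if (a >= 1000) round_half_down(a / 1000) * 1000 else round_half_down(a)
  }, numeric(1))
  structure(list(components = data.frame(nuclide = normalize_nuclide(nuclides),
                                         kbq = kbq, kbq_reported = reported,
                                         stringsAsFactors = FALSE),
                 label = label),
            class = "activity_prescription")
}

#' @export
print.activity_prescription <- function(x, ...) {
  cat("Activity prescription (", x$label, "):\n", sep = "")
  for (i in seq_len(nrow(x$components))) {
    a <- x$components$kbq_reported[i]
    shown <- if (a >= 1000) sprintf("%g MBq", a / 1000) else sprintf("%g kBq", a)
    cat(sprintf("  %-8s %s (raw %.6g kBq)\n", x$components$nuclide[i], shown,
                x$components$kbq[i]))
  }
  invisible(x)
}

#' Scale mono prescriptions into a tandem regimen
#'
#' Each component activity is multiplied by its fraction (the design in the
#' emulated study halves both single-agent activities), then reported under
#' the integer-MBq / integer-kBq round-half-down rule; raw values are kept.
#'
#' @param mono_prescriptions list of single-component
#'   [activity_prescription()] objects (or one multi-component prescription).
#' @param fractions numeric in (0, 1], one per component.
#' @return a tandem `activity_prescription`.
#' @examples
#' lu <- activity_prescription("177Lu", 35000)
#' ac <- activity_prescription("225Ac", 40)
#' tandem_prescription(list(lu, ac), c(0.5, 0.5))  # 17 MBq + 20 kBq
#' @export
tandem_prescription <- function(mono_prescriptions, fractions) {
  if (inherits(mono_prescriptions, "activity_prescription")) {
    comp <- mono_prescriptions$components
  } else {
    comp <- do.call(rbind, lapply(mono_prescriptions, function(p) {
      stopifnot(inherits(p, "activity_prescription"))
      p$components
    }))
  }
  if (length(fractions) != nrow(comp)) {
    stop("need one fraction per component (", nrow(comp), ")")
  }
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  if (length(fractions) == 1) {
    return(activity_prescription(comp$nuclide, comp$kbq * fractions, "mono"))
  }
  activity_prescription(comp$nuclide, comp$kbq * fractions, "tandem")
}
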