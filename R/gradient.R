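# Isopycnic CsCl gradient fraction analytics.

#' Refractive-index to buoyant-density calibration
#'
#' Linear calibration `density = slope * ri + intercept`. The default is the
#' standard CsCl / AR200 refractometer line; instruments should be calibrated
#' and the fitted line supplied here.
#'
#' @param slope (g/mL) per refractive-index unit, > 0.
#' @param intercept g/mL.
#' @return object of class `density_calibration`.
#' @export
density_calibration <- function(slope = 10.8507, intercept = -13.4411) {
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept),
            class = "density_calibration")
}

#' Convert refractive index to buoyant density
#'
#' @param ri refractive index (vectorized). Values outside the plausible CsCl
#'   range \[1.3, 1.5\] trigger a warning, not an error.
#' @param cal a [density_calibration()].
#' @return buoyant density, g/mL.
#' @examples
#' density_from_refractive_index(1.4000)  # 1.7499 with the default line
#' @export
density_from_refractive_index <- function(ri, cal = density_calibration()) {
  if (any(ri < 1.3 | ri > 1.5)) {
    warning("refractive index outside plausible CsCl range [1.3, 1.5]")
  }
  cal$slope * ri + cal$intercept
}

#' Assemble a gradient fraction profile
#'
#' Ordered gradient fractions for one sample with per-marker qPCR copies.
#'
#' @param fractions data frame with columns `fraction` (1..K), `density`
#'   (g/mL, strictly monotone along fraction order), `marker`, `copies`
#'   (copies/uL, >= 0). Fraction 1 is the densest (bottom-first collection).
#' @param sample sample identifier.
#' @param treatment optional treatment code string.
#' @return object of class `fraction_profile`.
#' @export
fraction_profile <- function(fractions, sample = "sample", treatment = NA_character_) {
  need <- c("fraction", "density", "marker", "copies")
  miss <- setdiff(need, names(fractions))
  if (length(miss)) stop("fractions missing columns: ", paste(miss, collapse = ", "))
  if (any(fractions$copies < 0)) stop("copy numbers must be >= 0")
  dens <- unique(fractions[order(fractions$fraction), c("fraction", "density")])
  if (nrow(dens) < 3) stop("a profile needs at least 3 fractions")
  dd <- diff(dens$density)
  if (!(all(dd > 0) || all(dd < 0))) {
    stop("densities must be strictly monotone along fraction order")
  }
  structure(list(sample = sample, treatment = treatment,
                 fractions = fractions[order(fractions$fraction), ]),
            class = "fraction_profile")
}

profile_marker <- function(profile, marker) {
  sub <- profile$fractions[profile$fractions$marker == marker, ]
  if (!nrow(sub)) stop("marker ", marker, " absent from profile ", profile$sample)
  sub
}

#' Normalize a marker's gradient profile to percentages
#'
#' Each fraction's gene abundance as a percentage of the marker's total copy
#' number over the gradient; the output sums to 100.
#'
#' @param profile a [fraction_profile()].
#' @param marker gene name present in the profile.
#' @return data frame `fraction`, `density`, `percent`.
#' @export
normalize_profile <- function(profile, marker) {
  sub <- profile_marker(profile, marker)
  tot <- sum(sub$copies)
  if (tot <= 0) stop("all-zero ", marker, " profile cannot be normalized")
  data.frame(fraction = sub$fraction, density = sub$density,
             percent = 100 * sub$copies / tot)
}

#' Partition fractions into heavy and light sets
#'
#' Heavy = buoyant density >= threshold. The threshold used is recorded on
#' the result, since downstream heavy-fraction statistics are only
#' interpretable relative to it.
#'
#' @param profile a [fraction_profile()].
#' @param threshold g/mL; default 1.725 (the gradient loading density).
#' @return list `heavy`, `light` (fraction indices), `threshold`.
#' @export
demarcate_heavy <- function(profile, threshold = 1.725) {
  dens <- unique(profile$fractions[, c("fraction", "density")])
  if (threshold < min(dens$density) || threshold > max(dens$density)) {
    warning("threshold ", threshold, " g/mL outside the profile density range")
  }
  list(heavy = dens$fraction[dens$density >= threshold],
       light = dens$fraction[dens$density < threshold],
       threshold = threshold)
}

#' Copy-weighted buoyant-density shift between labelled and unlabelled profiles
#'
#' The labelling shift is the difference of copy-weighted mean densities,
#' `shift = wmean(labelled) - wmean(unlabelled)`; positive values indicate
#' isotope incorporation. Antisymmetric by construction.
#'
#' @param labeled,unlabeled [fraction_profile()]s.
#' @param marker gene name present in both.
#' @return shift in g/mL.
#' @export
labeling_shift <- function(labeled, unlabeled, marker) {
  wmean <- function(p) {
    sub <- profile_marker(p, marker)
    if (sum(sub$copies) <= 0) stop("zero total copies for ", marker)
    stats::weighted.mean(sub$density, sub$copies)
  }
  wmean(labeled) - wmean(unlabeled)
}

#' Compare labelled vs unlabelled heavy-fraction totals
#'
#' Equal-variance two-tailed unpaired Student's t test on replicate totals of
#' summed heavy-fraction copies. Identical groups (zero pooled variance)
#' return t = 0, p = 1.
#'
#' @param labeled,unlabeled numeric vectors of replicate heavy totals
#'   (>= 2 each).
#' @param marker gene name, carried through to the result.
#' @param alpha significance level for the direction call.
#' @return list of class `enrichment_result`: `marker`, `total_labeled`,
#'   `total_unlabeled`, `t_statistic`, `p_value`, `direction`
#'   (`enriched` / `depleted` / `ns`).
#' @export
compare_heavy_totals <- function(labeled, unlabeled, marker = NA_character_,
                                 alpha = 0.05) {
  if (length(labeled) < 2 || length(unlabeled) < 2) {
    stop("need at least 2 replicates per group")
  }
  if (stats::sd(c(labeled, unlabeled)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(labeled, unlabeled, var.equal = TRUE,
                        alternative = "two.sided")
  }
  diffm <- mean(labeled) - mean(unlabeled)
  direction <- if (tt$p.value < alpha) {
    if (diffm > 0) "enriched" else "depleted"
  } else "ns"
  structure(list(marker = marker,
                 total_labeled = labeled, total_unlabeled = unlabeled,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 direction = direction, alpha = alpha),
            class = "enrichment_result")
}
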