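#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Cq = slope * log10(copies) + intercept` over a serial
#' dilution series of linearized plasmid (the convention is 5 ten-fold
#' dilutions from 1e9 to 1e5 copies). Amplification efficiency is
#' `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' `-1/log10(2) = -3.3219` and efficiency 1.
#'
#' @param copies plasmid copy numbers; positive, strictly decreasing by a
#'   constant dilution factor.
#' @param cq measured quantification cycles.
#' @return list of class `StandardCurve`: `points`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`.
#' @export
fit_standard_curve <- function(copies, cq) {
  if (length(copies) < 3 || length(cq) != length(copies))
    stop("need at least 3 (copies, cq) points")
  if (any(copies <= 0)) stop("copy numbers must be positive")
  ratios <- copies[-length(copies)] / copies[-1]
  if (any(ratios <= 1) || diff(range(ratios)) > 1e-6 * ratios[1])
    stop("copies must decrease strictly by a constant dilution factor")
  fit <- stats::lm(cq ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("non-amplifying curve: slope must be negative")
  structure(list(points = data.frame(copies = copies, cq = cq),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "StandardCurve")
}

#' The conventional 5-point dilution series (1e9 .. 1e5 copies)
#' @return numeric vector of copy numbers.
#' @export
standard_dilution_series <- function() 10^(9:5)

#' Simulate Cq values for a copy-number series
#'
#' Fixture generator for titration tests: `Cq = slope * log10(copies) +
#' intercept` plus optional Gaussian noise.
#'
#' @param copies copy numbers.
#' @param slope,intercept curve parameters; the default slope is the
#'   perfect-efficiency value `-1/log10(2)`.
#' @param noise_sd Gaussian Cq noise SD (0 = noiseless).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return numeric Cq vector.
#' @export
simulate_cq <- function(copies, slope = -1 / log10(2), intercept = 40,
                        noise_sd = 0, seed = 1L) {
  cq <- slope * log10(copies) + intercept
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "cq"))
    cq <- cq + stats::rnorm(length(cq), 0, noise_sd)
  }
  cq
}

#' Viral titer from a qPCR standard curve
#'
#' Inverts the standard curve at the sample's Cq and scales by the dilution
#' factor and reaction-volume factor:
#' `copies = 10^((cq - intercept) / slope) * dilution_factor *
#' reaction_volume_scale`. Extrapolation beyond the curve's Cq range is
#' warned about, and the result is checked against the plausible rAAV band
#' (1e11 to 1e14 genomic particles/ml; typical preparations run 1e12-1e13).
#'
#' @param curve a [fit_standard_curve()] object, or a data frame with
#'   `copies` and `cq` columns to fit on the fly.
#' @param sample_cq measured Cq of the diluted rAAV sample.
#' @param dilution_factor fold-dilution applied before the reaction.
#' @param reaction_volume_scale reactions-per-ml conversion factor.
#' @param sanity_band plausible titer range; outside it the result is flagged.
#' @return list: `slope`, `intercept`, `efficiency`, `copies_per_ml`,
#'   `extrapolated`, `within_expected_band`.
#' @export
qpcr_titer <- function(curve, sample_cq, dilution_factor = 1,
                       reaction_volume_scale = 1,
                       sanity_band = c(1e11, 1e14)) {
  if (!inherits(curve, "StandardCurve"))
    curve <- fit_standard_curve(curve$copies, curve$cq)
  stopifnot(length(sample_cq) == 1, is.finite(sample_cq),
            dilution_factor > 0, reaction_volume_scale > 0)
  rng <- range(curve$points$cq)
  extrapolated <- sample_cq < rng[1] || sample_cq > rng[2]
  if (extrapolated)
    warning("sample Cq ", signif(sample_cq, 4),
            " lies outside the standard-curve range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]; extrapolating")
  copies <- 10^((sample_cq - curve$intercept) / curve$slope) *
    dilution_factor * reaction_volume_scale
  list(slope = curve$slope, intercept = curve$intercept,
       efficiency = curve$efficiency, copies_per_ml = copies,
       extrapolated = extrapolated,
       within_expected_band = copies >= sanity_band[1] & copies <= sanity_band[2])
}
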