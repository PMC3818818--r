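# Quantitative genomic PCR: standard curves from a genomic-DNA dilution
# series (the study used 1-100 ng per primer pair) and ChIP fold-enrichment
# arithmetic.

#' Fit a qPCR standard curve
#'
#' Least-squares line \code{Ct = slope * log10(mass) + intercept} through a
#' dilution series.  The amplification efficiency follows from the slope as
#' \code{10^(-1/slope) - 1} (1.0 = 100%, perfect doubling, slope -3.32).
#'
#' @param dilutions data frame (or list) with columns/elements \code{mass_ng}
#'   and \code{ct}.
#' @return List of class \code{standard_curve}: \code{slope} (Ct per log10
#'   ng), \code{intercept} (Ct), \code{r_squared}, \code{efficiency}
#'   (fraction).
#' @examples
#' fit_standard_curve(data.frame(mass_ng = c(1, 10, 100),
#'                               ct = c(30, 26.678, 23.356)))
#' @export
fit_standard_curve <- function(dilutions) {
  mass <- dilutions$mass_ng
  ct <- dilutions$ct
  if (length(mass) < 3) stop("need at least 3 dilution points")
  if (any(mass <= 0)) stop("masses must be > 0")
  lx <- log10(mass)
  if (max(lx) - min(lx) < 1) stop("dilution series must span at least one log10 unit")
  fit <- stats::lm(ct ~ lx)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  if (slope >= 0) {
    warning("non-negative slope; Ct should decrease with template mass")
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Ct = %.4f log10(ng) + %.4f  (R2 %.5f, efficiency %.1f%%)\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantity from a Ct via a standard curve
#'
#' Inverts the fitted line: \code{mass = 10^((ct - intercept) / slope)}.
#'
#' @param curve a \code{\link{fit_standard_curve}} result.
#' @param ct threshold cycle value(s).
#' @return Template mass in ng.
#' @export
quantity_from_ct <- function(curve, ct) {
  10^((ct - curve$intercept) / curve$slope)
}

#' ChIP fold enrichment
#'
#' Normalizes the immunoprecipitated quantity to the input-DNA reference and
#' expresses the ratio relative to the unstimulated baseline ratio:
#' \code{(ip / input) / baseline_ratio}.
#'
#' @param ip_quantity immunoprecipitate DNA quantity, ng.
#' @param input_quantity input DNA quantity, ng (> 0).
#' @param baseline_ratio unstimulated IP/input ratio (> 0).
#' @return Fold change (1.0 = no enrichment over baseline).
#' @export
chip_fold_enrichment <- function(ip_quantity, input_quantity, baseline_ratio) {
  if (any(input_quantity <= 0)) stop("input_quantity must be > 0")
  if (any(baseline_ratio <= 0)) stop("baseline_ratio must be > 0")
  (ip_quantity / input_quantity) / baseline_ratio
}
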