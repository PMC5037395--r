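# Relative quantification: comparative-Ct fold change.

#' 2^-ddCt fold change over control
#'
#' Comparative threshold-cycle quantification.  Per measurement,
#' `dCt = Ct(target) - Ct(reference)` within each group; the default
#' (`"as-printed"`) convention then takes
#' `ddCt = dCt(control) - dCt(treatment)` and returns `2^-ddCt` as the fold
#' increase over control.  The more widespread sign convention
#' (`ddCt = dCt(treatment) - dCt(control)`, Livak & Schmittgen) is available
#' as `convention = "standard"`; the two are exact reciprocals.
#'
#' @param ct_target_control,ct_reference_control Threshold cycles in the
#'   control group (target and reference gene, e.g. GAPDH).
#' @param ct_target_treatment,ct_reference_treatment Threshold cycles in the
#'   treatment group.
#' @param convention `"as-printed"` (default) or `"standard"`.
#' @return Numeric vector of fold changes (strictly positive).
#' @examples
#' ddct_fold_change(20, 15, 19, 15)  # dCt 5 vs 4 -> ddCt 1 -> fold 0.5
#' @export
ddct_fold_change <- function(ct_target_control, ct_reference_control,
                             ct_target_treatment, ct_reference_treatment,
                             convention = c("as-printed", "standard")) {
  convention <- match.arg(convention)
  vals <- list(ct_target_control, ct_reference_control,
               ct_target_treatment, ct_reference_treatment)
  for (v in vals) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("all Ct values must be finite and positive", call. = FALSE)
    }
  }
  dct_control <- ct_target_control - ct_reference_control
  dct_treatment <- ct_target_treatment - ct_reference_treatment
  ddct <- dct_control - dct_treatment
  if (convention == "standard") ddct <- -ddct
  2^(-ddct)
}
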