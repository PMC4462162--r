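## Published reference estimates used as fixed inputs.

#' Reference sibling ICC estimates for the MDD subphenotypes
#'
#' Family-level intraclass correlations reported by the multicentre
#' affected-full-sibling study of recurrent depression whose design this
#' package models: sqrt(age at onset) with and without age adjustment (linear
#' mixed model), episode count (negative-binomial mixed model, reduced
#' model), and log episode frequency (linear mixed model).  These printed
#' estimates are inputs to the maximal-heritability arithmetic; they are not
#' recomputable without the original clinical data.
#'
#' @return data.frame with columns `phenotype`, `model`, `age_adjusted`,
#'   `icc`, `ci_low`, `ci_high`.
#' @export
reference_icc_estimates <- function() {
  data.frame(
    phenotype = c("aao", "aao", "episodicity", "episodicity"),
    model = c("lmm_sqrt_aao", "lmm_sqrt_aao", "nb_glmm_count", "lmm_lnepisfreq"),
    age_adjusted = c(FALSE, TRUE, NA, NA),
    icc = c(0.278, 0.229, 0.074, 0.167),
    ci_low = c(0.185, 0.140, 0.051, 0.089),
    ci_high = c(0.395, 0.354, 0.096, 0.292),
    stringsAsFactors = FALSE)
}

#' Reference GREML sample sizes
#'
#' Numbers of unrelated genotyped cases used for the SNP-heritability
#' analyses in the reference study: 3468 cases with complete age-at-onset
#' data, and the 2368-case recurrent-MDD subset with complete episode
#' counts.  These drive the analytic power calculations.
#'
#' @return Named numeric vector with elements `aao` and `episodicity`.
#' @export
reference_greml_samples <- function() {
  c(aao = 3468, episodicity = 2368)
}
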