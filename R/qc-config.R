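#' Quality-control and analysis thresholds
#'
#' Constructor for \linkS4class{QcConfig}. Defaults are the standard
#' imputed-genotype QC and PRS-construction thresholds: MAF >= 1\%, call
#' rate >= 90\%, HWE p > 1e-6, imputation r-squared > 0.9, genome-wide
#' significance 5e-8, LD pruning threshold r-squared 0.1 (a pair at or above
#' the threshold counts as linked), nominal significance 0.05, and 10
#' ancestry principal components.
#'
#' @param maf_min minimum minor allele frequency retained
#' @param call_rate_min minimum per-variant call rate retained
#' @param hwe_p_min variants with HWE p-value at or below this are dropped
#' @param imp_r2_min variants with imputation quality at or below this are dropped
#' @param gwas_sig genome-wide significance level for catalog admission
#' @param ld_r2 LD r-squared at or above which two variants are linked
#' @param nominal_p nominal significance level for approach-3 filtering
#' @param n_pcs number of ancestry principal components used as covariates
#' @return a \linkS4class{QcConfig}
#' @examples
#' cfg <- qcConfig()
#' cfg <- qcConfig(maf_min = 0.05)
#' @export
qcConfig <- function(maf_min = 0.01, call_rate_min = 0.90, hwe_p_min = 1e-6,
                     imp_r2_min = 0.9, gwas_sig = 5e-8, ld_r2 = 0.1,
                     nominal_p = 0.05, n_pcs = 10L) {
    methods::new("QcConfig", maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, imp_r2_min = imp_r2_min,
                 gwas_sig = gwas_sig, ld_r2 = ld_r2, nominal_p = nominal_p,
                 n_pcs = as.integer(n_pcs))
}

setMethod("show", "QcConfig", function(object) {
    cat("QcConfig:\n")
    cat(sprintf("  maf_min=%.3g call_rate_min=%.3g hwe_p_min=%.3g imp_r2_min=%.3g\n",
                object@maf_min, object@call_rate_min, object@hwe_p_min,
                object@imp_r2_min))
    cat(sprintf("  gwas_sig=%.3g ld_r2=%.3g nominal_p=%.3g n_pcs=%d\n",
                object@gwas_sig, object@ld_r2, object@nominal_p, object@n_pcs))
})
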