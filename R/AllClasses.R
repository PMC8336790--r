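#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

## Phenotypes carried on the latent (z-score) scale by the generator.
.PHENOS <- c("BMI", "WC", "HC", "BFpct", "SAT", "VAT")
## Source traits a published variant can be attributed to.
.TRAITS <- c("BMI", "WHRadjBMI", "WCadjBMI", "BFpct")
## Adiposity outcomes of the association analyses (VSR = VAT:SAT ratio).
.ADIPOSITY <- c("BFpct", "SAT", "VAT", "VSR")

#' GenotypeMatrix: imputed dosages with variant metadata
#'
#' Container for a variants x samples dosage matrix (assay \code{"DS"}, values
#' in \eqn{[0,2]}, missing allowed) built on
#' \linkS4class{RangedSummarizedExperiment}. Row ranges hold one position per
#' variant; row metadata columns are \code{ref}, \code{alt},
#' \code{imputation_r2}, \code{call_rate}, \code{alt_freq} and \code{maf}.
#' Variant keys (\code{chrom:pos:ref:alt}) are the rownames.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"DS" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'DS' is required")
    else {
        ds <- SummarizedExperiment::assay(object, "DS")
        bad <- !is.na(ds) & (ds < 0 | ds > 2)
        if (any(bad))
            msg <- c(msg, "all non-missing dosages must lie in [0, 2]")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate variant keys")
    need <- c("ref", "alt", "imputation_r2", "call_rate", "alt_freq", "maf")
    miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("missing variant metadata column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' QcConfig: thresholds for variant QC and risk-set construction
#'
#' Holds the quality-control and analysis thresholds: minimum minor allele
#' frequency (1\%), minimum call rate (90\%), Hardy-Weinberg equilibrium
#' p-value floor (1e-6), minimum imputation quality r-squared (0.9),
#' genome-wide significance level (5e-8), LD pruning r-squared threshold
#' (0.1, pairs at or above it count as linked), the nominal significance
#' level (0.05) and the number of ancestry principal components (10).
#'
#' @export
setClass("QcConfig",
    representation(maf_min = "numeric", call_rate_min = "numeric",
                   hwe_p_min = "numeric", imp_r2_min = "numeric",
                   gwas_sig = "numeric", ld_r2 = "numeric",
                   nominal_p = "numeric", n_pcs = "integer"),
    prototype(maf_min = 0.01, call_rate_min = 0.90, hwe_p_min = 1e-6,
              imp_r2_min = 0.9, gwas_sig = 5e-8, ld_r2 = 0.1,
              nominal_p = 0.05, n_pcs = 10L))

setValidity("QcConfig", function(object) {
    msg <- character()
    chk01 <- function(x, nm, lo = 0, hi = 1) {
        if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
            paste0(nm, " must be a single value in [", lo, ", ", hi, "]")
        else character()
    }
    msg <- c(msg,
             chk01(object@maf_min, "maf_min", 0, 0.5),
             chk01(object@call_rate_min, "call_rate_min"),
             chk01(object@hwe_p_min, "hwe_p_min"),
             chk01(object@imp_r2_min, "imp_r2_min"),
             chk01(object@gwas_sig, "gwas_sig"),
             chk01(object@ld_r2, "ld_r2"),
             chk01(object@nominal_p, "nominal_p"))
    if (object@n_pcs < 0L) msg <- c(msg, "n_pcs must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ArchitectureSpec: generating model of the synthetic cohort
#'
#' Describes a cohort of \code{nSamples} individuals in \code{nFamilies}
#' family clusters, a variant panel with per-variant minor-allele frequency,
#' LD-block membership and within-block target dosage r-squared, an additive
#' effects matrix (z-score units per alt allele) over the latent phenotypes
#' BMI, WC, HC, BF\%, SAT and VAT, loadings of each phenotype on shared
#' latent adiposity factors, age/sex covariate slopes, per-phenotype residual
#' standard deviations, and the master seed.
#'
#' @export
setClass("ArchitectureSpec",
    representation(nSamples = "integer", nFamilies = "integer",
                   familySd = "numeric", variants = "data.frame",
                   effects = "matrix", factorLoadings = "matrix",
                   covariateEffects = "matrix", residualSd = "numeric",
                   seed = "integer"))

setValidity("ArchitectureSpec", function(object) {
    msg <- character()
    v <- object@variants
    need <- c("maf", "block_id", "target_r2", "source_trait")
    miss <- setdiff(need, colnames(v))
    if (length(miss))
        return(paste0("variants table lacks column(s): ",
                      paste(miss, collapse = ", ")))
    bad <- which(!(v$maf > 0 & v$maf < 1))
    if (length(bad))
        msg <- c(msg, paste0("maf must lie strictly in (0,1); offending variant(s): ",
                             paste(bad, collapse = ", ")))
    bad <- which(!(v$target_r2 >= 0 & v$target_r2 < 1))
    if (length(bad))
        msg <- c(msg, paste0("target_r2 must lie in [0,1); offending variant(s): ",
                             paste(bad, collapse = ", ")))
    if (nrow(object@effects) != nrow(v) ||
        ncol(object@effects) != length(.PHENOS))
        msg <- c(msg, "effects matrix must be n_variants x n_phenotypes")
    if (!identical(colnames(object@effects), .PHENOS))
        msg <- c(msg, "effects columns must be named BMI, WC, HC, BFpct, SAT, VAT")
    if (ncol(object@factorLoadings) != length(.PHENOS))
        msg <- c(msg, "factorLoadings must have one column per phenotype")
    if (!all(object@residualSd > 0))
        msg <- c(msg, "residualSd must be > 0 for every phenotype")
    if (length(object@residualSd) != length(.PHENOS))
        msg <- c(msg, "residualSd must have one entry per phenotype")
    if (object@nSamples < 1L || object@nFamilies < 1L)
        msg <- c(msg, "nSamples and nFamilies must be >= 1")
    if (object@familySd < 0)
        msg <- c(msg, "familySd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' RiskSet: an LD-pruned, approach-filtered PRS variant list
#'
#' The definition of one PRS: the trait, the filtering approach (1 = all
#' published genome-wide-significant loci after LD pruning; 2 = the subset
#' with directional replication in the internal screen; 3 = the approach-2
#' subset with nominal internal significance), the retained catalog entries
#' in priority order, and an audit table of every admission/drop decision.
#'
#' @export
setClass("RiskSet",
    representation(trait = "character", approach = "integer",
                   entries = "data.frame", audit = "data.frame"))

setValidity("RiskSet", function(object) {
    msg <- character()
    if (!object@approach %in% 1:3)
        msg <- c(msg, "approach must be 1, 2 or 3")
    need <- c("key", "chrom", "pos", "ref", "alt", "effect_allele",
              "trait", "reported_p", "study_year", "study_n")
    miss <- setdiff(need, colnames(object@entries))
    if (length(miss))
        msg <- c(msg, paste0("entries lack column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' PrsVector: per-sample unweighted risk-allele sums
#'
#' Scores are raw counts of trait-increasing alleles summed over the risk
#' set's variants (each variant weighted 1), in the sample order of the
#' genotype matrix they were computed from.
#'
#' @export
setClass("PrsVector",
    representation(sample_ids = "character", scores = "numeric",
                   trait = "character", approach = "integer",
                   nVariantsUsed = "integer", audit = "data.frame"))

setValidity("PrsVector", function(object) {
    msg <- character()
    if (length(object@sample_ids) != length(object@scores))
        msg <- c(msg, "sample_ids and scores lengths differ")
    ub <- 2 * object@nVariantsUsed
    if (any(object@scores < 0 | object@scores > ub, na.rm = TRUE))
        msg <- c(msg, "scores must lie in [0, 2 * nVariantsUsed]")
    if (length(msg)) msg else TRUE
})

#' AssociationResult: one PRS x phenotype x adjustment model fit
#'
#' Slope reported as \code{beta_x100}, the percent change in the outcome
#' z-score per additional trait-increasing allele, with its 95\% confidence
#' interval, two-sided p-value, model type ("ols" or "mixed"), BMI-adjustment
#' flag, and the incremental R-squared of the PRS over the covariate-only
#' model (OLS only).
#'
#' @export
setClass("AssociationResult",
    representation(outcome = "character", prs_trait = "character",
                   approach = "integer", beta_x100 = "numeric",
                   ci95 = "numeric", p = "numeric", model = "character",
                   bmi_adjusted = "logical", r2_incremental = "numeric",
                   n = "integer"))

setValidity("AssociationResult", function(object) {
    msg <- character()
    if (length(object@ci95) != 2L)
        msg <- c(msg, "ci95 must have length 2")
    else if (is.finite(object@beta_x100) && all(is.finite(object@ci95)) &&
             (object@beta_x100 < object@ci95[1] || object@beta_x100 > object@ci95[2]))
        msg <- c(msg, "ci95 must bracket beta_x100")
    if (is.finite(object@r2_incremental) && object@r2_incremental < -1e-12)
        msg <- c(msg, "r2_incremental must be >= 0")
    if (!object@model %in% c("ols", "mixed"))
        msg <- c(msg, "model must be 'ols' or 'mixed'")
    if (length(msg)) msg else TRUE
})

#' EffectMatrix: per-variant effect sizes across adiposity traits
#'
#' Matrix of beta x 100 estimates (rows = variants grouped by the source
#' trait of their risk set, columns = adiposity traits BF\%, SAT, VAT, VSR)
#' used for Ward clustering and heatmap rendering.
#'
#' @export
setClass("EffectMatrix",
    representation(values = "matrix", source_trait = "character",
                   audit = "data.frame"))

setValidity("EffectMatrix", function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@source_trait))
        msg <- c(msg, "source_trait must annotate every row")
    if (nrow(object@values) > 0 && any(!is.finite(object@values)))
        msg <- c(msg, "all cells must be finite (drop incomplete rows first)")
    if (length(msg)) msg else TRUE
})
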