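#' Per-variant covariate-adjusted association test
#'
#' Ordinary least squares of an inverse-normal-transformed phenotype on a
#' single variant's dosage plus covariates, with a two-sided Wald t test
#' at residual degrees of freedom. Missing dosages are mean-imputed per
#' variant (preserving n, standard for imputed data); rows with a missing
#' phenotype or covariate are dropped. The reported slope is oriented to
#' the effect allele: when \code{effect_allele_is_alt} is FALSE the sign
#' is negated (the effect allele is the reference allele).
#'
#' @param dosage numeric dosage vector (per alt allele)
#' @param phenotype_z inverse-normal-transformed phenotype
#' @param covariates numeric matrix or data.frame of covariates (may have
#'   zero columns)
#' @param effect_allele_is_alt logical; orientation of the reported beta
#' @return one-row data.frame: beta, se, p, n_used
#' @export
assocPerVariant <- function(dosage, phenotype_z, covariates = NULL,
                            effect_allele_is_alt = TRUE) {
    n <- length(phenotype_z)
    stopifnot(length(dosage) == n)
    if (is.null(covariates))
        covariates <- matrix(numeric(), n, 0)
    covariates <- as.matrix(covariates)
    if (anyNA(dosage)) dosage[is.na(dosage)] <- mean(dosage, na.rm = TRUE)
    ok <- stats::complete.cases(phenotype_z, covariates)
    if (sum(ok) < ncol(covariates) + 3L)
        stop("too few complete cases (", sum(ok), ") for ",
             ncol(covariates), " covariates")
    y <- phenotype_z[ok]
    X <- cbind(`(Intercept)` = 1, dosage = dosage[ok], covariates[ok, , drop = FALSE])
    if (stats::sd(X[, "dosage"]) == 0)
        stop("degenerate variant: constant dosage")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    fit <- stats::lm.fit(X, y)
    df <- length(y) - ncol(X)
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    beta <- unname(fit$coefficients["dosage"])
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df)
    if (!effect_allele_is_alt) beta <- -beta
    data.frame(beta = beta, se = se, p = p, n_used = length(y))
}

## trait -> (latent phenotype column, analysis visit, BMI covariate?)
.traitPlan <- function(trait) {
    switch(trait,
        BMI       = list(col = "BMI",   visit = 1L, bmi = FALSE),
        WCadjBMI  = list(col = "WC",    visit = 1L, bmi = TRUE),
        WHRadjBMI = list(col = "WHR",   visit = 2L, bmi = TRUE),
        BFpct     = list(col = "BFpct", visit = 2L, bmi = FALSE),
        SAT       = list(col = "SAT",   visit = 2L, bmi = FALSE),
        VAT       = list(col = "VAT",   visit = 2L, bmi = FALSE),
        VSR       = list(col = "VSR",   visit = 2L, bmi = FALSE),
        stop("unknown trait: ", trait))
}

## phenotype vector for a trait from a single-visit cohort slice
.traitValues <- function(ct, trait) {
    col <- .traitPlan(trait)$col
    if (col == "VSR") return(ct$VAT / ct$SAT)
    if (!col %in% colnames(ct)) stop("missing trait column: ", col)
    ct[[col]]
}

#' Internal replication screen: per-variant GWAS
#'
#' For one trait: selects the analysis visit (visit 1 for BMI and WC to
#' maximize sample size, visit 2 otherwise; overridable), applies the
#' sample exclusion flags, inverse-normal transforms the phenotype within
#' the analysed sample, then runs \code{\link{assocPerVariant}} for every
#' variant with age and sex (plus BMI for the BMI-adjusted traits WHR and
#' WC, plus optional ancestry PCs) as covariates. Betas are reported per
#' alt allele.
#'
#' @param gm a QC-passing \linkS4class{GenotypeMatrix}
#' @param ct cohort data.frame (both visits)
#' @param trait one of BMI, WHRadjBMI, WCadjBMI, BFpct, SAT, VAT, VSR
#' @param cfg a \linkS4class{QcConfig}
#' @param pcs optional samples x k matrix of ancestry PCs (rownames =
#'   sample ids)
#' @param visit override the default analysis visit
#' @return data.frame of per-variant results: key, trait, beta, se, p,
#'   n_used, bmi_adjusted
#' @export
runInternalGwas <- function(gm, ct, trait, cfg = qcConfig(), pcs = NULL,
                            visit = NULL) {
    plan <- .traitPlan(trait)
    if (is.null(visit)) visit <- plan$visit
    ct <- applySampleExclusions(ct)
    slice <- ct[ct$visit == visit, , drop = FALSE]
    idx <- match(sampleIds(gm), slice$sample_id)
    if (all(is.na(idx)))
        stop("no cohort rows at visit ", visit, " match the genotype samples")
    slice <- slice[idx, , drop = FALSE]
    y <- inverseNormalTransform(.traitValues(slice, trait))
    covs <- cbind(age = slice$age, sex_male = as.numeric(slice$sex == "male"))
    if (plan$bmi) covs <- cbind(covs, BMI = slice$BMI)
    if (!is.null(pcs))
        covs <- cbind(covs, pcs[match(sampleIds(gm), rownames(pcs)), ,
                                drop = FALSE])
    ds <- dosages(gm)
    res <- lapply(seq_len(nrow(ds)), function(i)
        assocPerVariant(ds[i, ], y, covs, effect_allele_is_alt = TRUE))
    out <- do.call(rbind, res)
    out <- cbind(data.frame(key = rownames(ds), trait = trait,
                            stringsAsFactors = FALSE),
                 out, bmi_adjusted = plan$bmi)
    rownames(out) <- NULL
    logMsg("gwas", trait, ": ", nrow(out), " variants at visit ", visit,
           ", n = ", out$n_used[1])
    out
}
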