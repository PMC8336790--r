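#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the Hardy-Weinberg expectation computed from the sample
#' allele frequency (no continuity correction). Monomorphic input (one
#' allele absent) returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote)
#' @return two-sided p-value
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: p = 1
#' hweTest(50, 0, 50)    # extreme heterozygote deficit: p ~ 1.5e-23
#' @export
hweTest <- function(n_AA, n_Aa, n_aa) {
    stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
    n <- n_AA + n_Aa + n_aa
    if (n == 0) stop("no genotypes")
    p <- (2 * n_AA + n_Aa) / (2 * n)
    if (p == 0 || p == 1) return(1)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chisq <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
    stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Apply variant quality-control filters
#'
#' Retains variants with MAF >= \code{maf_min}, call rate >=
#' \code{call_rate_min}, HWE p-value > \code{hwe_p_min} (computed on hard
#' calls, i.e. dosages rounded to the nearest integer) and imputation
#' quality > \code{imp_r2_min}. All filters are evaluated on the input, so
#' the retained set does not depend on evaluation order and the operation
#' is idempotent.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param cfg a \linkS4class{QcConfig}
#' @return list with \code{genotypes} (the filtered matrix) and
#'   \code{audit} (one row per dropped variant: key, reason(s), value)
#' @export
applyVariantQc <- function(gm, cfg = qcConfig()) {
    gm <- refreshVariantStats(gm)
    vi <- variantInfo(gm)
    ds <- dosages(gm)
    hwe_p <- apply(round(ds), 1L, function(g) {
        g <- g[!is.na(g)]
        if (!length(g)) return(1)
        hweTest(sum(g == 0), sum(g == 1), sum(g == 2))
    })
    fails <- cbind(maf = vi$maf < cfg@maf_min,
                   call_rate = vi$call_rate < cfg@call_rate_min,
                   hwe = hwe_p <= cfg@hwe_p_min,
                   imputation_r2 = vi$imputation_r2 <= cfg@imp_r2_min)
    drop <- rowSums(fails) > 0
    audit <- data.frame(
        key = vi$key[drop],
        reason = apply(fails[drop, , drop = FALSE], 1L, function(f)
            paste(colnames(fails)[f], collapse = ",")),
        maf = vi$maf[drop], call_rate = vi$call_rate[drop],
        hwe_p = hwe_p[drop], imputation_r2 = vi$imputation_r2[drop],
        stringsAsFactors = FALSE, row.names = NULL)
    for (i in seq_len(nrow(audit)))
        logMsg("variant-qc", "drop ", audit$key[i], " (", audit$reason[i], ")")
    list(genotypes = gm[!drop, ], audit = audit)
}

#' Apply sample exclusion flags
#'
#' Removes rows flagged \code{pregnancy_excluded} or
#' \code{missing_implausible}. The retained row count is attached as
#' attribute \code{n_retained}.
#'
#' @param ct a cohort data.frame with the two flag columns
#' @return the filtered cohort table (warns if nothing survives)
#' @export
applySampleExclusions <- function(ct) {
    stopifnot(all(c("pregnancy_excluded", "missing_implausible") %in%
                  colnames(ct)))
    keep <- !(ct$pregnancy_excluded | ct$missing_implausible)
    out <- ct[keep, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out) == 0L) warning("all rows excluded; empty cohort returned")
    logMsg("exclusions", "retained ", nrow(out), " of ", nrow(ct), " rows")
    attr(out, "n_retained") <- nrow(out)
    out
}
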