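#' Orient a catalog effect allele against a genotype record
#'
#' @param effect_allele the published trait-increasing allele
#' @param ref,alt the genotype record's alleles
#' @return \code{"same"} when the effect allele is alt (the score uses the
#'   dosage g), \code{"flip"} when it is ref (the score uses 2 - g),
#'   \code{"mismatch"} when it is neither (the variant is excluded).
#' @export
alignAlleles <- function(effect_allele, ref, alt) {
    ifelse(effect_allele == alt, "same",
           ifelse(effect_allele == ref, "flip", "mismatch"))
}

#' Unweighted polygenic risk score
#'
#' Per-sample sum of effect-allele dosages over the risk set's variants:
#' the dosage g for "same"-oriented entries, 2 - g for "flip"-oriented
#' entries, every variant contributing with weight 1. A missing dosage is
#' replaced by twice the in-sample effect-allele frequency (its
#' expectation); a variant missing in all samples, absent from the
#' genotypes, or with a mismatching effect allele is excluded with an
#' audit entry. Strand-ambiguous (A/T, C/G) variants are retained with a
#' warning unless \code{strict_ambiguous} is set, since alignment is by
#' ref/alt identity rather than strand.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param rs a \linkS4class{RiskSet}
#' @param strict_ambiguous drop strand-ambiguous variants (default FALSE)
#' @return a \linkS4class{PrsVector} in the sample order of \code{gm}
#' @export
computePrs <- function(gm, rs, strict_ambiguous = FALSE) {
    ent <- riskSetEntries(rs)
    if (nrow(ent) == 0L)
        stop("empty risk set for trait ", rs@trait, " approach ", rs@approach)
    ds <- dosages(gm)
    vi <- variantInfo(gm)
    scores <- numeric(ncol(ds))
    used <- 0L
    audit <- data.frame(key = ent$key, outcome = NA_character_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ent))) {
        ri <- match(ent$key[i], vi$key)
        if (is.na(ri)) { audit$outcome[i] <- "absent"; next }
        ori <- alignAlleles(ent$effect_allele[i], vi$ref[ri], vi$alt[ri])
        if (ori == "mismatch") { audit$outcome[i] <- "allele_mismatch"; next }
        ambiguous <- paste0(vi$ref[ri], vi$alt[ri]) %in% c("AT", "TA", "CG", "GC")
        if (ambiguous) {
            if (strict_ambiguous) { audit$outcome[i] <- "strand_ambiguous"; next }
            warning("strand-ambiguous variant retained: ", ent$key[i])
        }
        g <- ds[ri, ]
        d <- if (ori == "flip") 2 - g else g
        if (all(is.na(d))) { audit$outcome[i] <- "all_missing"; next }
        ## 2 x in-sample effect-allele frequency = mean effect-allele dosage
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        scores <- scores + d
        used <- used + 1L
        audit$outcome[i] <- ori
    }
    if (used == 0L)
        stop("no risk-set variant could be scored")
    methods::new("PrsVector", sample_ids = sampleIds(gm), scores = scores,
                 trait = rs@trait, approach = rs@approach,
                 nVariantsUsed = used, audit = audit)
}

#' @describeIn PrsVector per-sample scores, named by sample id
#' @export
setMethod("prsScores", "PrsVector", function(x)
    stats::setNames(x@scores, x@sample_ids))

#' @describeIn PrsVector per-variant alignment audit
#' @export
setMethod("prsAudit", "PrsVector", function(x) x@audit)

setMethod("show", "PrsVector", function(object) {
    cat("PrsVector:", object@trait, "approach", object@approach, "-",
        length(object@scores), "samples,", object@nVariantsUsed,
        "variants\n")
    cat("  score range:",
        paste(signif(range(object@scores), 4), collapse = " - "), "\n")
})
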