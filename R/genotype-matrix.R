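#' Build a GenotypeMatrix from a dosage matrix and variant table
#'
#' @param dosages numeric matrix, variants in rows and samples in columns,
#'   values in \eqn{[0,2]} with \code{NA} for missing genotypes.
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally \code{imputation_r2} (defaults
#'   to 1, i.e. directly genotyped quality).
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   column names of \code{dosages}.
#'
#' @details Alt-allele frequency, minor allele frequency and call rate are
#'   computed from the dosage matrix (mean dosage / 2 over non-missing
#'   samples, the standard estimator for imputed data). Variant keys are
#'   \code{chrom:pos:ref:alt} with 1-based positions as in VCF, giving
#'   bit-exact joins against a variant catalog.
#'
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(dosages, variants, sample_ids = colnames(dosages)) {
    dosages <- as.matrix(dosages)
    if (is.null(sample_ids))
        sample_ids <- paste0("S", seq_len(ncol(dosages)))
    stopifnot(nrow(variants) == nrow(dosages),
              length(sample_ids) == ncol(dosages))
    if (any(variants$ref == variants$alt))
        stop("ref and alt alleles must differ for every variant")
    if (is.null(variants$imputation_r2))
        variants$imputation_r2 <- rep(1, nrow(variants))
    keys <- variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)
    if (anyDuplicated(keys))
        stop("duplicate variant keys: ",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
    alt_freq <- rowMeans(dosages, na.rm = TRUE) / 2
    call_rate <- rowMeans(!is.na(dosages))
    rr <- GenomicRanges::GRanges(as.character(variants$chrom),
                                 IRanges::IRanges(variants$pos, width = 1L))
    names(rr) <- keys
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
        ref = as.character(variants$ref),
        alt = as.character(variants$alt),
        imputation_r2 = variants$imputation_r2,
        call_rate = call_rate,
        alt_freq = alt_freq,
        maf = pmin(alt_freq, 1 - alt_freq))
    dimnames(dosages) <- list(keys, sample_ids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(DS = dosages),
        rowRanges = rr,
        colData = S4Vectors::DataFrame(row.names = sample_ids))
    methods::new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix dosage matrix (variants x samples)
#' @param x a \linkS4class{GenotypeMatrix}
#' @export
setMethod("dosages", "GenotypeMatrix", function(x)
    SummarizedExperiment::assay(x, "DS"))

#' @describeIn GenotypeMatrix sample identifiers
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))

#' @describeIn GenotypeMatrix variant keys (chrom:pos:ref:alt)
#' @export
setMethod("variantKeys", "GenotypeMatrix", function(x) rownames(x))

#' @describeIn GenotypeMatrix variant metadata as a data.frame (chrom, pos,
#'   ref, alt, imputation_r2, call_rate, alt_freq, maf)
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    out <- data.frame(key = names(rr),
                      chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      as.data.frame(S4Vectors::mcols(rr)),
                      row.names = NULL,
                      stringsAsFactors = FALSE)
    out
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix with", nrow(object), "variants x",
        ncol(object), "samples\n")
    ds <- dosages(object)
    cat("  dosage range:", paste(signif(range(ds, na.rm = TRUE), 3),
                                 collapse = " - "),
        "; missing:", sum(is.na(ds)), "\n")
    mi <- variantInfo(object)
    cat("  MAF range:", paste(signif(range(mi$maf), 3), collapse = " - "), "\n")
})

## canonical variant key: 1-based VCF coordinates
variantKey <- function(chrom, pos, ref, alt)
    paste(chrom, pos, ref, alt, sep = ":")

#' Refresh computed variant statistics
#'
#' Recomputes call rate, alt-allele frequency and MAF from the current
#' dosage matrix (used after subsetting samples).
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @return a \linkS4class{GenotypeMatrix} with refreshed row statistics
#' @export
refreshVariantStats <- function(gm) {
    ds <- dosages(gm)
    f <- rowMeans(ds, na.rm = TRUE) / 2
    rd <- SummarizedExperiment::rowData(gm)
    rd$alt_freq <- f
    rd$maf <- pmin(f, 1 - f)
    rd$call_rate <- rowMeans(!is.na(ds))
    SummarizedExperiment::rowData(gm) <- rd
    gm
}
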