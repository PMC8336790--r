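#' Read imputed dosages from a VCF
#'
#' Reads a VCF 4.x file into a \linkS4class{GenotypeMatrix}. For each
#' genotype entry the \code{DS} (estimated alt-allele dosage) FORMAT field
#' takes precedence when present and non-missing; otherwise the dosage is
#' the count of alt alleles in \code{GT}. A missing genotype
#' (\code{./.} with no \code{DS}) becomes a missing dosage. Imputation
#' quality is taken from the \code{R2} INFO field when present (1
#' otherwise). Only biallelic records are supported.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped)
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readDosages <- function(vcf_path) {
    if (!file.exists(vcf_path))
        stop("VCF file not found: ", vcf_path)
    vcf <- tryCatch(VariantAnnotation::readVcf(vcf_path),
                    error = function(e)
                        stop("malformed VCF '", vcf_path, "': ",
                             conditionMessage(e), call. = FALSE))
    alt <- VariantAnnotation::alt(vcf)
    if (any(lengths(alt) != 1L))
        stop("multi-allelic records are not supported; split them first")
    rr <- SummarizedExperiment::rowRanges(vcf)
    gen <- VariantAnnotation::geno(vcf)
    n <- ncol(vcf); m <- nrow(vcf)
    ds <- NULL
    if ("DS" %in% names(gen)) {
        ds <- matrix(as.numeric(gen$DS), m, n)
        if (any(!is.na(ds) & (ds < 0 | ds > 2)))
            stop("DS values outside [0, 2] in ", vcf_path)
    }
    if ("GT" %in% names(gen)) {
        gt <- gen$GT
        cnt <- matrix(NA_real_, m, n)
        ok <- !is.na(gt) & !grepl("\\.", gt)
        cnt[ok] <- vapply(strsplit(gt[ok], "[/|]"),
                          function(a) sum(a == "1"), 0)
        if (is.null(ds)) ds <- cnt
        else ds[is.na(ds)] <- cnt[is.na(ds)]
    }
    if (is.null(ds))
        stop("VCF has neither DS nor GT genotype fields")
    info <- VariantAnnotation::info(vcf)
    r2 <- if ("R2" %in% colnames(info)) as.numeric(info$R2) else rep(1, m)
    r2[is.na(r2)] <- 1
    vtab <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = as.character(unlist(alt)),
        imputation_r2 = r2,
        stringsAsFactors = FALSE)
    GenotypeMatrix(ds, vtab, sample_ids = colnames(vcf))
}

#' Write a GenotypeMatrix as a VCF with DS and GT fields
#'
#' Dosages are written to the \code{DS} FORMAT field (rounded to 3
#' decimals); hard-call genotypes rounded from the dosage go to \code{GT};
#' imputation quality goes to the \code{R2} INFO field. Reading the file
#' back with \code{\link{readDosages}} reproduces the matrix up to the
#' 3-decimal dosage rounding.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param path output path (".vcf")
#' @return the path, invisibly
#' @export
writeDosagesVcf <- function(gm, path) {
    vi <- variantInfo(gm)
    ds <- round(dosages(gm), 3)
    m <- nrow(ds); n <- ncol(ds)
    hard <- round(ds)
    gt <- matrix("./.", m, n)
    gt[!is.na(hard) & hard == 0] <- "0/0"
    gt[!is.na(hard) & hard == 1] <- "0/1"
    gt[!is.na(hard) & hard == 2] <- "1/1"
    dimnames(gt) <- dimnames(ds)
    rr <- GenomicRanges::GRanges(vi$chrom, IRanges::IRanges(vi$pos, width = 1L))
    names(rr) <- vi$key
    hdr <- VariantAnnotation::VCFHeader(samples = sampleIds(gm))
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"))
    VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
        Number = c("1", "1"), Type = c("String", "Float"),
        Description = c("Genotype",
                        "Estimated alternate allele dosage"),
        row.names = c("GT", "DS"))
    VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
        Number = "1", Type = "Float",
        Description = "Imputation quality r-squared",
        row.names = "R2")
    vcf <- VariantAnnotation::VCF(
        rowRanges = rr,
        colData = S4Vectors::DataFrame(Samples = seq_len(n),
                                       row.names = sampleIds(gm)),
        exptData = list(header = hdr),
        fixed = S4Vectors::DataFrame(
            REF = Biostrings::DNAStringSet(vi$ref),
            ALT = methods::as(vi$alt, "CharacterList"),
            QUAL = rep(NA_real_, m), FILTER = rep("PASS", m)),
        info = S4Vectors::DataFrame(R2 = vi$imputation_r2),
        geno = S4Vectors::SimpleList(GT = gt, DS = ds))
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}
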