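#' Tab-separated table input/output
#'
#' Thin wrappers fixing the conventions used throughout the package:
#' header row, tab separator, no quoting, no row names.
#'
#' @param x a data.frame
#' @param path file path
#' @return \code{writeTsv} returns the path invisibly; \code{readTsv}
#'   returns a data.frame
#' @export
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a variant catalog TSV
#'
#' Required columns: key (or chrom/pos/ref/alt from which the key is
#' built), effect_allele, trait, reported_p, study_year, study_n.
#'
#' @param path catalog file path
#' @return catalog data.frame
#' @export
readCatalogTsv <- function(path) {
    cat <- readTsv(path)
    if (!"key" %in% colnames(cat)) {
        need <- c("chrom", "pos", "ref", "alt")
        if (!all(need %in% colnames(cat)))
            stop("catalog needs 'key' or chrom/pos/ref/alt columns")
        cat$key <- variantKey(cat$chrom, cat$pos, cat$ref, cat$alt)
    }
    need <- c("effect_allele", "trait", "reported_p", "study_year", "study_n")
    miss <- setdiff(need, colnames(cat))
    if (length(miss))
        stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
    cat
}

#' Write a RiskSet (entries plus audit) as TSV
#'
#' @param rs a \linkS4class{RiskSet}
#' @param path output path; the audit table goes to \code{<path>.audit.tsv}
#' @return the path, invisibly
#' @export
writeRiskSetTsv <- function(rs, path) {
    ent <- rs@entries
    ent$trait <- rep(rs@trait, nrow(ent))
    ent$approach <- rep(rs@approach, nrow(ent))
    writeTsv(ent, path)
    writeTsv(rs@audit, paste0(path, ".audit.tsv"))
    invisible(path)
}

#' Write PRS values as TSV
#'
#' @param prs a \linkS4class{PrsVector}
#' @param path output path
#' @return the path, invisibly
#' @export
writePrsTsv <- function(prs, path) {
    writeTsv(data.frame(sample_id = prs@sample_ids, trait = prs@trait,
                        approach = prs@approach, score = prs@scores,
                        n_variants_used = prs@nVariantsUsed,
                        stringsAsFactors = FALSE), path)
}
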