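#' Assemble the variant x adiposity-trait effect matrix
#'
#' Rows are the variants of the supplied risk sets (annotated by the source
#' trait of their set); columns are the adiposity traits BF\%, SAT, VAT and
#' VSR; cells are 100 x the internal per-variant beta of each adiposity
#' trait on the variant, oriented to the published effect allele. Variants
#' lacking an estimate for any column are dropped with an audit entry.
#'
#' @param results data.frame of internal per-variant results covering the
#'   adiposity traits (betas per alt allele)
#' @param risk_sets list of \linkS4class{RiskSet} (one per source trait)
#' @return an \linkS4class{EffectMatrix}
#' @export
buildEffectMatrix <- function(results, risk_sets) {
    traits <- .ADIPOSITY
    rows <- do.call(rbind, lapply(risk_sets, function(rs) {
        ent <- riskSetEntries(rs)
        if (nrow(ent) == 0L) return(NULL)
        data.frame(key = ent$key, source = riskSetTrait(rs),
                   flip = ent$effect_allele == ent$ref,
                   stringsAsFactors = FALSE)
    }))
    vals <- matrix(NA_real_, nrow(rows), length(traits),
                   dimnames = list(rows$key, traits))
    for (tr in traits) {
        sub <- results[results$trait == tr, , drop = FALSE]
        idx <- match(rows$key, sub$key)
        vals[, tr] <- 100 * sub$beta[idx] * ifelse(rows$flip, -1, 1)
    }
    bad <- !stats::complete.cases(vals)
    audit <- data.frame(key = rows$key[bad],
                        reason = rep("missing estimate", sum(bad)),
                        stringsAsFactors = FALSE)
    methods::new("EffectMatrix", values = vals[!bad, , drop = FALSE],
                 source_trait = rows$source[!bad], audit = audit)
}

#' @describeIn EffectMatrix the beta x 100 matrix
#' @export
setMethod("effectValues", "EffectMatrix", function(x) x@values)

#' @describeIn EffectMatrix source-trait annotation per row
#' @export
setMethod("sourceTrait", "EffectMatrix", function(x) x@source_trait)

setMethod("show", "EffectMatrix", function(object) {
    cat("EffectMatrix:", nrow(object@values), "variants x",
        ncol(object@values), "adiposity traits\n")
    print(table(object@source_trait))
})

#' Ward minimum-variance hierarchical clustering
#'
#' Agglomerative clustering under Ward's criterion on Euclidean distances
#' (the "Ward.D2" convention: each merge minimizes the increase in total
#' within-cluster sum of squares, and the recorded height is
#' \eqn{\sqrt{2 \Delta SSE}}), so merge heights are non-decreasing.
#'
#' @param points numeric matrix, one row per object
#' @return an \code{\link[stats]{hclust}} tree (merge, height, order)
#' @export
wardLinkage <- function(points) {
    points <- as.matrix(points)
    if (nrow(points) < 2L) stop("need at least 2 points")
    if (any(!is.finite(points))) stop("non-finite input")
    stats::hclust(stats::dist(points), method = "ward.D2")
}

#' Render the clustered effect heatmap
#'
#' Writes a raster heatmap (via pheatmap) of the effect matrix under the
#' supplied row/column trees, plus a TSV of the matrix reordered to the
#' dendrogram leaf order so the clustering result is machine-checkable
#' without parsing the image. Repeated calls on identical inputs produce
#' byte-identical TSVs.
#'
#' @param em an \linkS4class{EffectMatrix}
#' @param rows_tree,cols_tree \code{hclust} trees on the matrix rows and
#'   columns (e.g. from \code{\link{wardLinkage}}); pass NULL to leave an
#'   axis unclustered
#' @param path output image path (".png"); the ordered matrix goes to
#'   \code{<path>.ordered.tsv}
#' @return invisible list with the ordered matrix and the TSV path
#' @export
renderHeatmap <- function(em, rows_tree = NULL, cols_tree = NULL, path) {
    vals <- effectValues(em)
    ord <- vals[if (is.null(rows_tree)) seq_len(nrow(vals)) else rows_tree$order,
                if (is.null(cols_tree)) seq_len(ncol(vals)) else cols_tree$order,
                drop = FALSE]
    tsv <- paste0(path, ".ordered.tsv")
    df <- data.frame(key = rownames(ord),
                     source_trait = sourceTrait(em)[match(rownames(ord),
                                                          rownames(vals))],
                     ord, check.names = FALSE, stringsAsFactors = FALSE)
    writeTsv(df, tsv)
    ann <- data.frame(source = sourceTrait(em), row.names = rownames(vals))
    pheatmap::pheatmap(
        vals,
        cluster_rows = if (is.null(rows_tree)) FALSE else rows_tree,
        cluster_cols = if (is.null(cols_tree)) FALSE else cols_tree,
        annotation_row = ann, show_rownames = nrow(vals) <= 60,
        main = "Per-variant effects (beta x 100) on adiposity traits",
        filename = path, silent = TRUE)
    invisible(list(ordered = ord, tsv = tsv, image = path))
}
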