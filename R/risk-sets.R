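#' In-sample LD between two dosage vectors
#'
#' Squared Pearson correlation over samples non-missing in both vectors
#' (composite LD on dosages). A vector constant over the complete-pair
#' samples has no defined LD and raises a condition of class
#' \code{"undefinedLd"}; \code{\link{pruneByLd}} treats such a pair as
#' unlinked with a warning.
#'
#' @param dosage_i,dosage_j numeric dosage vectors of equal length
#' @return r-squared in [0, 1]
#' @examples
#' computeLdR2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 2, 1, 2))  # r = 0.5, r2 = 0.25
#' @export
computeLdR2 <- function(dosage_i, dosage_j) {
    stopifnot(length(dosage_i) == length(dosage_j))
    ok <- !is.na(dosage_i) & !is.na(dosage_j)
    x <- dosage_i[ok]; y <- dosage_j[ok]
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
        stop(structure(class = c("undefinedLd", "error", "condition"),
                       list(message = "LD undefined: constant dosage vector over complete pairs",
                            call = sys.call())))
    stats::cor(x, y)^2
}

## priority ordering for sentinel selection: strongest published signal
## first, then larger and then more recent studies, then key for determinism
.priorityOrder <- function(entries)
    order(entries$reported_p, -entries$study_n, -entries$study_year,
          entries$key, method = "radix")

#' Greedy LD pruning with sentinel prioritization
#'
#' Entries are ranked by published p-value (ascending), then study size
#' (descending), then study year (descending), then variant key. Walking
#' down that ranking, an entry is kept iff its in-sample dosage r-squared
#' with every already-kept entry is below \code{cfg@ld_r2}; a pair at or
#' above the threshold counts as linked and the lower-priority member is
#' dropped, recorded in the audit with the sentinel that displaced it.
#' Entries absent from the genotype matrix are skipped with an audit entry.
#'
#' @param entries catalog data.frame (one trait's entries)
#' @param gm a \linkS4class{GenotypeMatrix} providing in-sample LD
#' @param cfg a \linkS4class{QcConfig}
#' @param trait trait label for the resulting set (defaults to the
#'   entries' trait)
#' @param approach approach label to record (default 1)
#' @return a \linkS4class{RiskSet}
#' @export
pruneByLd <- function(entries, gm, cfg = qcConfig(),
                      trait = entries$trait[1], approach = 1L) {
    ds <- dosages(gm)
    audit <- data.frame(key = character(), status = character(),
                        reason = character(), sentinel_of = character(),
                        stringsAsFactors = FALSE)
    note <- function(key, status, reason, sentinel = "")
        rbind(audit, data.frame(key = key, status = status, reason = reason,
                                sentinel_of = sentinel,
                                stringsAsFactors = FALSE))
    present <- entries$key %in% rownames(ds)
    for (k in entries$key[!present])
        audit <- note(k, "skipped", "absent from genotype data")
    entries <- entries[present, , drop = FALSE]
    ord <- .priorityOrder(entries)
    kept <- integer()
    for (i in ord) {
        linked_to <- NA_character_
        for (j in kept) {
            r2 <- tryCatch(computeLdR2(ds[entries$key[i], ],
                                       ds[entries$key[j], ]),
                           undefinedLd = function(e) {
                               warning("LD undefined for pair ",
                                       entries$key[i], " / ", entries$key[j],
                                       "; treated as unlinked")
                               0
                           })
            if (r2 >= cfg@ld_r2) { linked_to <- entries$key[j]; break }
        }
        if (is.na(linked_to)) {
            kept <- c(kept, i)
            audit <- note(entries$key[i], "kept", "sentinel")
        } else {
            audit <- note(entries$key[i], "dropped", "linked", linked_to)
        }
    }
    out <- entries[kept, , drop = FALSE]   # priority order: permutation-invariant
    rownames(out) <- NULL
    methods::new("RiskSet", trait = as.character(trait),
                 approach = as.integer(approach),
                 entries = out, audit = audit)
}

#' Build a risk set under one of the three filtering approaches
#'
#' Approach 1: all catalog entries for the trait published at genome-wide
#' significance, LD-pruned. Approach 2: the subset whose internal
#' (replication-screen) effect for the published effect allele is positive
#' (directional replication), then LD-pruned. Approach 3: the approach-2
#' subset that is also nominally significant internally
#' (p < \code{cfg@nominal_p}), then LD-pruned. Entries with published
#' p-values above \code{cfg@gwas_sig} are never admitted.
#'
#' @param catalog catalog data.frame (all traits)
#' @param internal data.frame of internal per-variant results
#'   (\code{key}, \code{trait}, \code{beta} oriented to the alt allele,
#'   \code{p}); required for approaches 2 and 3
#' @param approach 1, 2 or 3
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param cfg a \linkS4class{QcConfig}
#' @param trait trait to build the set for
#' @return a \linkS4class{RiskSet}
#' @export
buildRiskSet <- function(catalog, internal = NULL, approach = 1L, gm,
                         cfg = qcConfig(), trait = "BMI") {
    approach <- as.integer(approach)
    ent <- catalog[catalog$trait == trait &
                   catalog$reported_p <= cfg@gwas_sig, , drop = FALSE]
    if (approach >= 2L) {
        if (is.null(internal))
            stop("approach ", approach, " requires internal GWAS results")
        int <- internal[internal$trait == trait, , drop = FALSE]
        idx <- match(ent$key, int$key)
        if (anyNA(idx))
            stop("internal results do not cover catalog entries: ",
                 paste(ent$key[is.na(idx)], collapse = ", "))
        ## orient internal beta (per alt allele) to the published effect allele
        ref <- if ("ref" %in% colnames(ent)) ent$ref
           else vapply(strsplit(ent$key, ":", fixed = TRUE), `[`, "", 3L)
        sign_flip <- ifelse(ent$effect_allele == ref, -1, 1)
        beta_eff <- int$beta[idx] * sign_flip
        keep <- beta_eff > 0
        if (approach == 3L) keep <- keep & int$p[idx] < cfg@nominal_p
        ent <- ent[keep, , drop = FALSE]
    }
    pruneByLd(ent, gm, cfg, trait = trait, approach = approach)
}

#' @describeIn RiskSet retained entries (priority-pruned catalog rows)
#' @export
setMethod("riskSetEntries", "RiskSet", function(x) x@entries)

#' @describeIn RiskSet audit of kept/dropped/skipped decisions
#' @export
setMethod("riskSetAudit", "RiskSet", function(x) x@audit)

#' @describeIn RiskSet trait the set scores
#' @export
setMethod("riskSetTrait", "RiskSet", function(x) x@trait)

#' @describeIn RiskSet filtering approach (1, 2 or 3)
#' @export
setMethod("riskSetApproach", "RiskSet", function(x) x@approach)

setMethod("show", "RiskSet", function(object) {
    cat("RiskSet:", object@trait, "approach", object@approach, "-",
        nrow(object@entries), "variants (",
        sum(object@audit$status == "dropped"), "pruned )\n")
})
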