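.defaultConfig <- function() list(
    seed = 1L,
    n_samples = 2554L,
    n_families = 600L,
    n_false_catalog = 15L,
    n_pregnant = 10L,
    n_missing = 124L,
    approaches = c(1L, 2L, 3L),
    model = "ols",
    bmi_adjust = "both",
    heatmap = TRUE,
    cluster_rows = TRUE,
    cluster_cols = TRUE,
    qc = list(maf_min = 0.01, call_rate_min = 0.90, hwe_p_min = 1e-6,
              imp_r2_min = 0.9, gwas_sig = 5e-8, ld_r2 = 0.1,
              nominal_p = 0.05, n_pcs = 10L))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills every missing key
#' with its default (the QC block defaults to the standard thresholds:
#' MAF 1\%, call rate 90\%, HWE 1e-6, imputation r2 0.9, genome-wide
#' significance 5e-8, LD r2 0.1, nominal 0.05, 10 PCs), and collects all
#' validation errors (unknown keys, out-of-range thresholds, bad trait or
#' approach values) into a single error message.
#'
#' @param config path to a YAML file, a list, or NULL for all defaults
#' @return the normalized configuration list
#' @export
validateConfig <- function(config = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    def <- .defaultConfig()
    errs <- character()
    unknown <- setdiff(names(config), names(def))
    if (length(unknown))
        errs <- c(errs, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
    if (!is.null(config$qc)) {
        uq <- setdiff(names(config$qc), names(def$qc))
        if (length(uq))
            errs <- c(errs, paste0("unknown qc key(s): ",
                                   paste(uq, collapse = ", ")))
        def$qc[names(config$qc)] <- config$qc
    }
    config$qc <- NULL
    def[names(config)] <- config
    cfg <- def
    chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
    for (nm in c("maf_min", "call_rate_min", "hwe_p_min", "imp_r2_min",
                 "gwas_sig", "ld_r2", "nominal_p")) {
        v <- cfg$qc[[nm]]
        hi <- if (nm == "maf_min") 0.5 else 1
        chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= hi,
            paste0("qc$", nm, " out of range [0, ", hi, "]"))
    }
    chk(cfg$qc$n_pcs >= 0, "qc$n_pcs must be >= 0")
    chk(all(cfg$approaches %in% 1:3), "approaches must be within 1..3")
    chk(cfg$model %in% c("ols", "mixed"), "model must be 'ols' or 'mixed'")
    chk(cfg$bmi_adjust %in% c("on", "off", "both"),
        "bmi_adjust must be on/off/both")
    chk(cfg$n_samples >= 2, "n_samples must be >= 2")
    chk(cfg$n_families >= 1, "n_families must be >= 1")
    if (length(errs))
        stop("invalid configuration:\n  - ",
             paste(errs, collapse = "\n  - "), call. = FALSE)
    cfg$qc$n_pcs <- as.integer(cfg$qc$n_pcs)
    cfg$approaches <- as.integer(cfg$approaches)
    cfg
}

.qcFromConfig <- function(cfg)
    do.call(qcConfig, cfg$qc)

## Table-2-shaped presentation: rows = adiposity outcomes, one column per
## PRS trait, cells "beta (p) (lo, hi)", one block per adjustment model
.formatTable2 <- function(assoc) {
    blocks <- split(assoc, assoc$bmi_adjusted)
    do.call(rbind, lapply(names(blocks), function(b) {
        a <- blocks[[b]]
        wide <- do.call(cbind, lapply(split(a, a$prs_trait)[unique(a$prs_trait)],
            function(d) {
                d <- d[match(.ADIPOSITY, d$outcome), ]
                sprintf("%.1f (%.1e) (%.1f, %.1f)",
                        d$beta_x100, d$p, d$ci_lo, d$ci_hi)
            }))
        data.frame(outcome = .ADIPOSITY, wide, bmi_adjusted = b,
                   check.names = FALSE, stringsAsFactors = FALSE)
    }))
}

#' Run the full PRS pipeline on a simulated cohort
#'
#' Executes, in order: cohort simulation, variant QC, sample exclusions,
#' ancestry PCs, the internal per-variant screen (when approaches beyond 1
#' or the heatmap are requested), risk-set construction per trait and
#' approach, PRS computation, PRS-outcome association models (with and/or
#' without BMI adjustment), the Spearman trait-correlation matrix, and
#' Ward-clustered effect heatmap. Every stage writes its table under
#' \code{outdir} and the run manifest (config hash, seed, per-stage
#' counts, output paths) is written as JSON. Identical config and seed
#' give identical outputs.
#'
#' @param config configuration (path, list or NULL; see
#'   \code{\link{validateConfig}})
#' @param outdir output directory (created if needed)
#' @param seed overrides the config seed when given
#' @return the manifest list, invisibly
#' @export
runPipeline <- function(config = NULL, outdir = tempfile("prsrun"),
                        seed = NULL) {
    cfg <- validateConfig(config)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    qc <- .qcFromConfig(cfg)
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    counts <- list()
    paths <- list()
    out <- function(f) file.path(outdir, f)

    sim <- stage("simulate", {
        spec <- defaultArchitecture(cfg$n_samples, cfg$n_families, cfg$seed)
        simulateCohort(spec, n_false = cfg$n_false_catalog,
                       n_pregnant = cfg$n_pregnant, n_missing = cfg$n_missing)
    })
    writeTsv(sim$cohort, out("cohort.tsv"))
    writeTsv(sim$catalog, out("catalog.tsv"))
    counts$n_samples <- cfg$n_samples
    counts$n_variants_simulated <- nrow(sim$genotypes)

    vqc <- stage("variant_qc", applyVariantQc(sim$genotypes, qc))
    writeTsv(vqc$audit, out("variant_qc_audit.tsv"))
    gm <- vqc$genotypes
    counts$n_variants_qc <- nrow(gm)

    ct <- stage("exclusions", applySampleExclusions(sim$cohort))
    counts$n_retained_visit2 <- sum(ct$visit == 2L)

    pcs <- stage("ancestry_pcs", ancestryPcs(gm, qc@n_pcs))

    need_internal <- any(cfg$approaches > 1L) || isTRUE(cfg$heatmap)
    internal <- NULL
    if (need_internal) {
        internal <- stage("internal_gwas", {
            traits <- unique(c(.TRAITS, if (isTRUE(cfg$heatmap)) .ADIPOSITY))
            do.call(rbind, lapply(traits, function(tr)
                runInternalGwas(gm, sim$cohort, tr, qc, pcs = pcs)))
        })
        writeTsv(internal, out("internal_gwas.tsv"))
        counts$n_internal_tests <- nrow(internal)
    }

    risk_sets <- stage("risk_sets", {
        rs <- list()
        for (tr in .TRAITS) for (ap in cfg$approaches) {
            r <- buildRiskSet(sim$catalog, internal, ap, gm, qc, trait = tr)
            writeRiskSetTsv(r, out(sprintf("riskset_%s_a%d.tsv", tr, ap)))
            rs[[paste0(tr, "_a", ap)]] <- r
        }
        rs
    })
    counts$risk_set_sizes <- vapply(risk_sets,
                                    function(r) nrow(riskSetEntries(r)), 0L)

    prs_list <- stage("prs", {
        lapply(risk_sets, function(r)
            if (nrow(riskSetEntries(r)) > 0) computePrs(gm, r) else NULL)
    })
    prs_tab <- do.call(rbind, lapply(Filter(Negate(is.null), prs_list),
        function(p) data.frame(sample_id = p@sample_ids, trait = p@trait,
                               approach = p@approach, score = p@scores,
                               n_variants_used = p@nVariantsUsed,
                               stringsAsFactors = FALSE)))
    writeTsv(prs_tab, out("prs.tsv"))

    ## PRS validity check: each score against its own phenotype (visit 2)
    validation <- stage("prs_validation", {
        slice <- ct[ct$visit == 2L, , drop = FALSE]
        idx <- match(sampleIds(gm), slice$sample_id)
        slice <- slice[idx, , drop = FALSE]
        covs <- cbind(age = slice$age,
                      sex_male = as.numeric(slice$sex == "male"), pcs)
        res <- lapply(Filter(Negate(is.null), prs_list), function(p) {
            y <- inverseNormalTransform(.traitValues(slice, p@trait))
            bmi <- if (.traitPlan(p@trait)$bmi) slice$BMI else NULL
            fitPrsAssociation(y, p, covs, bmi = bmi, model = cfg$model,
                              family_ids = slice$family_id,
                              outcome = p@trait)
        })
        associationTable(res)
    })
    writeTsv(validation, out("prs_validation.tsv"))

    assoc <- stage("associations", {
        slice <- ct[ct$visit == 2L, , drop = FALSE]
        idx <- match(sampleIds(gm), slice$sample_id)
        slice <- slice[idx, , drop = FALSE]
        covs <- cbind(age = slice$age,
                      sex_male = as.numeric(slice$sex == "male"),
                      pcs)
        adjopts <- switch(cfg$bmi_adjust, on = TRUE, off = FALSE,
                          both = c(FALSE, TRUE))
        res <- list()
        for (p in Filter(Negate(is.null), prs_list))
            for (outc in .ADIPOSITY) for (adj in adjopts) {
                y <- inverseNormalTransform(.traitValues(slice, outc))
                res[[length(res) + 1L]] <- fitPrsAssociation(
                    y, p, covs, bmi = if (adj) slice$BMI else NULL,
                    model = cfg$model, family_ids = slice$family_id,
                    outcome = outc)
            }
        associationTable(res)
    })
    writeTsv(assoc, out("associations.tsv"))
    t2 <- .formatTable2(assoc[assoc$approach == min(cfg$approaches), ])
    writeTsv(t2, out("associations_main.tsv"))

    sp <- stage("spearman",
                spearmanMatrix(ct[ct$visit == 2L, , drop = FALSE]))
    writeTsv(data.frame(trait = rownames(sp), sp, check.names = FALSE),
             out("spearman.tsv"))

    if (isTRUE(cfg$heatmap)) {
        stage("clustering", {
            ap <- max(cfg$approaches)
            sets <- risk_sets[grep(paste0("_a", ap, "$"), names(risk_sets))]
            em <- buildEffectMatrix(internal, sets)
            if (nrow(effectValues(em)) >= 2L) {
                rt <- if (isTRUE(cfg$cluster_rows))
                    wardLinkage(effectValues(em)) else NULL
                cl <- if (isTRUE(cfg$cluster_cols))
                    wardLinkage(t(effectValues(em))) else NULL
                renderHeatmap(em, rt, cl, out("effect_heatmap.png"))
                counts$n_heatmap_variants <- nrow(effectValues(em))
            }
        })
    }

    cfg_path <- out("config_used.yaml")
    yaml::write_yaml(cfg, cfg_path)
    manifest <- list(
        package_version = as.character(utils::packageVersion("adiposePRS")),
        seed = cfg$seed,
        config_hash = unname(tools::md5sum(cfg_path)),
        counts = counts,
        outputs = list.files(outdir))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
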