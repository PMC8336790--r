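## Natural-unit location/scale used to map latent z-scores to reported
## phenotype values; chosen to mirror descriptives of a middle-aged,
## predominantly female African American cohort with high adiposity.
.PHENO_SCALE <- data.frame(
    pheno = .PHENOS,
    mean = c(32.2, 102.9, 114.7, 38.2, 2335.8, 839.4),
    sd = c(7.2, 16.2, 14.9, 9.9, 1014.7, 383.1),
    row.names = .PHENOS)

#' Construct an ArchitectureSpec
#'
#' @param nSamples number of individuals
#' @param nFamilies number of family clusters
#' @param familySd standard deviation of the per-family shared intercept
#'   (latent z-score units)
#' @param variants data.frame with columns \code{maf} (strictly in (0,1)),
#'   \code{block_id} (LD-block label), \code{target_r2} (within-block
#'   pairwise dosage r-squared in [0,1)) and \code{source_trait}
#'   (one of BMI, WHRadjBMI, WCadjBMI, BFpct, or "null")
#' @param effects numeric matrix, variants x phenotypes
#'   (columns BMI, WC, HC, BFpct, SAT, VAT), additive z-score units per
#'   alt allele
#' @param factorLoadings loadings of each phenotype on shared latent
#'   adiposity factors (factors x phenotypes)
#' @param covariateEffects 2 x phenotypes matrix of age (per year, centred
#'   at 60) and male-sex slopes
#' @param residualSd per-phenotype residual standard deviation (> 0)
#' @param seed master seed; stages draw from deterministic substreams
#' @return an \linkS4class{ArchitectureSpec}
#' @export
architectureSpec <- function(nSamples, nFamilies, familySd, variants, effects,
                             factorLoadings, covariateEffects, residualSd,
                             seed = 1L) {
    colnames(effects) <- .PHENOS
    colnames(factorLoadings) <- .PHENOS
    colnames(covariateEffects) <- .PHENOS
    rownames(covariateEffects) <- c("age", "sex_male")
    names(residualSd) <- .PHENOS
    methods::new("ArchitectureSpec",
                 nSamples = as.integer(nSamples),
                 nFamilies = as.integer(nFamilies),
                 familySd = familySd, variants = variants,
                 effects = effects, factorLoadings = factorLoadings,
                 covariateEffects = covariateEffects,
                 residualSd = residualSd, seed = as.integer(seed))
}

setMethod("show", "ArchitectureSpec", function(object) {
    cat("ArchitectureSpec:", object@nSamples, "samples,",
        object@nFamilies, "families,", nrow(object@variants), "variants\n")
    cat("  source traits:",
        paste(names(table(object@variants$source_trait)),
              table(object@variants$source_trait), collapse = ", "), "\n")
    cat("  familySd =", object@familySd, " seed =", object@seed, "\n")
})

#' Default multi-trait adiposity architecture
#'
#' A cohort in which BMI- and BF\%-attributed variants load predominantly on
#' subcutaneous fat (SAT) and overall body fat, while WHR-attributed
#' variants raise waist circumference, lower hip circumference and load
#' predominantly on visceral fat (VAT) -- so that by construction BMI/BF\%
#' scores predict SAT positively and WHR scores predict VAT and the VAT:SAT
#' ratio positively. Panel: 30 BMI, 12 WHRadjBMI, 10 WCadjBMI and 8 BF\%
#' causal variants plus 15 null variants; two 2-variant LD blocks
#' (dosage r-squared 0.5) exercise pruning; every third causal variant has
#' its alt-allele effects negated so its trait-increasing allele is the
#' reference allele, exercising allele alignment. Defaults: 2554
#' individuals (the visit-2 pool before exclusions), 600 families,
#' family intercept SD 0.3, one shared adiposity factor, residual SDs
#' chosen so each latent phenotype has unit variance net of age/sex terms.
#'
#' @param nSamples number of individuals (default 2554)
#' @param nFamilies number of family clusters (default 600)
#' @param seed master seed
#' @return an \linkS4class{ArchitectureSpec}
#' @export
defaultArchitecture <- function(nSamples = 2554L, nFamilies = 600L, seed = 1L) {
    counts <- c(BMI = 30L, WHRadjBMI = 12L, WCadjBMI = 10L, BFpct = 8L,
                null = 15L)
    src <- rep(names(counts), counts)
    m <- length(src)
    maf <- round(0.05 + 0.45 * (((seq_len(m) * 17) %% m) / m), 3)
    maf[maf <= 0.01] <- 0.05
    block_id <- paste0("b", seq_len(m))
    target_r2 <- rep(0, m)
    ## two linked pairs: first two BMI variants, first two WHR variants
    block_id[1:2] <- "ld_bmi"; target_r2[1:2] <- 0.5
    w1 <- which(src == "WHRadjBMI")[1:2]
    block_id[w1] <- "ld_whr"; target_r2[w1] <- 0.5
    ## linked variants share a frequency (high r2 is only achievable for
    ## similar allele frequencies)
    maf[2] <- maf[1]; maf[w1[2]] <- maf[w1[1]]
    variants <- data.frame(maf = maf, block_id = block_id,
                           target_r2 = target_r2, source_trait = src,
                           stringsAsFactors = FALSE)
    ## per-source-trait effect rows on (BMI, WC, HC, BFpct, SAT, VAT)
    rows <- rbind(
        BMI       = c(0.045, 0.030,  0.020, 0.030, 0.035, 0.020),
        WHRadjBMI = c(0.000, 0.030, -0.030, 0.015, 0.005, 0.050),
        WCadjBMI  = c(0.020, 0.050,  0.015, 0.025, 0.030, 0.030),
        BFpct     = c(0.030, 0.020,  0.015, 0.060, 0.045, 0.010),
        null      = c(0, 0, 0, 0, 0, 0))
    effects <- rows[src, , drop = FALSE]
    rownames(effects) <- NULL
    ## every third causal variant: alt allele decreases the trait
    causal <- which(src != "null")
    flip <- causal[seq_along(causal) %% 3 == 0]
    effects[flip, ] <- -effects[flip, ]
    loadings <- matrix(c(0.55, 0.55, 0.45, 0.55, 0.55, 0.35), nrow = 1)
    covEff <- rbind(age = c(-0.005, 0.003, 0.002, 0.004, 0.003, 0.008),
                    sex_male = c(-0.2, 0.25, -0.3, -0.9, -0.5, 0.25))
    familySd <- 0.3
    genVar <- colSums(2 * maf * (1 - maf) * effects^2)
    residVar <- 1 - genVar - colSums(loadings^2) - familySd^2
    stopifnot(all(residVar > 0.01))
    architectureSpec(nSamples, nFamilies, familySd, variants, effects,
                     loadings, covEff, sqrt(residVar), seed)
}

## Latent-Gaussian threshold correlation giving a target allele-level
## correlation. Alleles are indicators {latent > qnorm(1 - maf)}; the joint
## upper-quadrant probability is integrated numerically and the latent rho
## solved by root finding.
.quadrantProb <- function(t1, t2, rho) {
    if (abs(rho) < 1e-12) return(pnorm(t1, lower.tail = FALSE) *
                                 pnorm(t2, lower.tail = FALSE))
    f <- function(z) dnorm(z) * pnorm((rho * z - t2) / sqrt(1 - rho^2))
    stats::integrate(f, t1, Inf, rel.tol = 1e-10)$value
}

.latentRho <- function(maf1, maf2, r_target) {
    if (r_target <= 0) return(0)
    t1 <- qnorm(1 - maf1); t2 <- qnorm(1 - maf2)
    denom <- sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
    g <- function(rho) (.quadrantProb(t1, t2, rho) - maf1 * maf2) / denom - r_target
    hi <- 0.99995
    if (g(hi) < 0)
        stop("target_r2 unachievable for MAF pair (", maf1, ", ", maf2, ")")
    stats::uniroot(g, c(0, hi), tol = 1e-9)$root
}

#' Simulate block-LD genotype dosages
#'
#' Hard-call dosages \{0,1,2\}: within each LD block, two independent
#' haplotypes per individual are drawn from a multivariate Gaussian whose
#' pairwise latent correlation is solved numerically so that the realized
#' allele-level (and hence dosage-level) r-squared matches
#' \code{target_r2}; alleles are the indicator \{latent > qnorm(1 - maf)\},
#' which fixes each variant's allele frequency exactly at its MAF.
#' Cross-block dosages are independent. Deterministic under the spec seed.
#'
#' @param spec an \linkS4class{ArchitectureSpec}
#' @return a \linkS4class{GenotypeMatrix} (alt allele = trait-modelled allele)
#' @export
simulateGenotypes <- function(spec) {
    methods::validObject(spec)
    v <- spec@variants
    m <- nrow(v); n <- spec@nSamples
    ds <- matrix(NA_real_, m, n)
    withSeed(substreamSeed(spec@seed, "genotypes"), {
        blocks <- split(seq_len(m), factor(v$block_id, levels = unique(v$block_id)))
        for (idx in blocks) {
            k <- length(idx)
            if (k == 1L) {
                ds[idx, ] <- stats::rbinom(n, 2L, v$maf[idx])
            } else {
                R <- diag(k)
                for (a in seq_len(k - 1)) for (b in (a + 1):k) {
                    r_allele <- sqrt(min(v$target_r2[idx[a]], v$target_r2[idx[b]]))
                    R[a, b] <- R[b, a] <- .latentRho(v$maf[idx[a]],
                                                    v$maf[idx[b]], r_allele)
                }
                U <- chol(R)
                thr <- qnorm(1 - v$maf[idx])
                hap <- function() {
                    Z <- matrix(stats::rnorm(n * k), n, k) %*% U
                    t(Z) > thr   # k x n allele indicators
                }
                ds[idx, ] <- (hap() + hap())
            }
        }
    })
    pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                  c("A", "C"), c("G", "T"))
    al <- pairs[(seq_len(m) - 1L) %% length(pairs) + 1L]
    bnum <- match(v$block_id, unique(v$block_id))
    within <- stats::ave(seq_len(m), v$block_id, FUN = seq_along)
    vtab <- data.frame(
        chrom = as.character(((bnum - 1L) %% 22L) + 1L),
        pos = bnum * 100000L + within * 1000L,
        ref = vapply(al, `[`, "", 1L),
        alt = vapply(al, `[`, "", 2L),
        imputation_r2 = round(0.91 + 0.089 * (((seq_len(m) * 13L) %% 17L) / 17), 4),
        stringsAsFactors = FALSE)
    gm <- GenotypeMatrix(ds, vtab,
                         sample_ids = sprintf("S%05d", seq_len(n)))
    logMsg("simulate", "generated ", m, " variants x ", n, " samples")
    gm
}

#' True additive genetic values implied by an architecture
#'
#' \code{G_centered \%*\% effects} with genotypes centred at twice the spec
#' MAF; used by variance-decomposition and recovery tests.
#'
#' @param gm genotypes simulated from \code{spec}
#' @param spec the generating \linkS4class{ArchitectureSpec}
#' @return samples x phenotypes matrix of genetic values (z-score units)
#' @export
geneticValues <- function(gm, spec) {
    Gc <- t(dosages(gm)) - rep(2 * spec@variants$maf, each = ncol(gm))
    Gc %*% spec@effects
}

#' Simulate phenotypes, demographics and family structure
#'
#' Each latent phenotype is the sum of the additive genetic value, shared
#' latent adiposity factors, age and sex terms, a per-family intercept and
#' Gaussian noise, then mapped to natural units by a fixed location/scale.
#' Anthropometrics (BMI, WC, HC and hence WHR) are measured at both visits
#' (visit-1 values share the genetic/factor/family components but have
#' independent measurement noise and age offset by -5 years); bioimpedance
#' and CT traits (BF\%, SAT, VAT) are measured at visit 2 only. WHR is
#' computed as WC/HC; SAT and VAT are truncated below at 1 cm^3.
#'
#' @param gm genotypes from \code{\link{simulateGenotypes}}
#' @param spec the same \linkS4class{ArchitectureSpec}
#' @return a cohort data.frame (one row per sample per visit) with columns
#'   sample_id, family_id, sex, age, visit, BMI, WC, HC, WHR, BFpct, SAT,
#'   VAT, pregnancy_excluded, missing_implausible
#' @export
simulatePhenotypes <- function(gm, spec) {
    n <- spec@nSamples
    if (ncol(gm) != n)
        stop("genotype sample count (", ncol(gm),
             ") does not match spec nSamples (", n, ")")
    P <- length(.PHENOS)
    gv <- geneticValues(gm, spec)
    out <- withSeed(substreamSeed(spec@seed, "phenotypes"), {
        fam <- sample(rep(seq_len(spec@nFamilies), length.out = n))
        male <- stats::rbinom(n, 1L, 0.369)
        age2 <- round(stats::runif(n, 35, 84), 1)
        age1 <- pmax(age2 - 5, 21)
        famInt <- matrix(stats::rnorm(spec@nFamilies * P, 0, spec@familySd),
                         spec@nFamilies, P)[fam, , drop = FALSE]
        nf <- nrow(spec@factorLoadings)
        fac <- matrix(stats::rnorm(n * nf), n, nf) %*% spec@factorLoadings
        base <- gv + fac + famInt
        covTerm <- function(age) outer(age - 60, spec@covariateEffects["age", ]) +
            outer(male, spec@covariateEffects["sex_male", ])
        noise <- function() sweep(matrix(stats::rnorm(n * P), n, P), 2,
                                  spec@residualSd, `*`)
        z2 <- base + covTerm(age2) + noise()
        z1 <- base + covTerm(age1) + noise()
        list(fam = fam, male = male, age1 = age1, age2 = age2,
             z1 = z1, z2 = z2)
    })
    natural <- function(z) {
        vals <- sweep(sweep(z, 2, .PHENO_SCALE$sd, `*`), 2,
                      .PHENO_SCALE$mean, `+`)
        colnames(vals) <- .PHENOS
        vals[, "SAT"] <- pmax(vals[, "SAT"], 1)
        vals[, "VAT"] <- pmax(vals[, "VAT"], 1)
        vals[, "BFpct"] <- pmin(pmax(vals[, "BFpct"], 3), 75)
        vals
    }
    v2 <- natural(out$z2)
    v1 <- natural(out$z1)
    v1[, c("BFpct", "SAT", "VAT")] <- NA_real_
    row <- function(vals, age, visit) data.frame(
        sample_id = sampleIds(gm),
        family_id = sprintf("F%04d", out$fam),
        sex = ifelse(out$male == 1L, "male", "female"),
        age = age, visit = visit,
        BMI = vals[, "BMI"], WC = vals[, "WC"], HC = vals[, "HC"],
        WHR = vals[, "WC"] / vals[, "HC"],
        BFpct = vals[, "BFpct"], SAT = vals[, "SAT"], VAT = vals[, "VAT"],
        pregnancy_excluded = FALSE, missing_implausible = FALSE,
        stringsAsFactors = FALSE)
    ct <- rbind(row(v1, out$age1, 1L), row(v2, out$age2, 2L))
    rownames(ct) <- NULL
    ct
}

#' Simulate a published-variant catalog with known ground truth
#'
#' Emits one entry per truly causal variant of the architecture (the effect
#' allele is the trait-increasing allele for its source trait, with a
#' fabricated discovery p-value at or below genome-wide significance,
#' study year and sample size) plus \code{n_false} null variants published
#' as spurious hits. Ground truth is retained in the \code{is_causal}
#' column for filter testing.
#'
#' @param gm simulated genotypes
#' @param spec the generating \linkS4class{ArchitectureSpec}
#' @param n_false number of null variants to include as false entries
#' @param seed seed for the fabricated provenance fields
#' @return data.frame of catalog entries (key, chrom, pos, ref, alt,
#'   effect_allele, trait, reported_p, study_year, study_n, ancestry_tag,
#'   is_causal)
#' @export
simulateCatalog <- function(gm, spec, n_false = 0L, seed = spec@seed) {
    v <- spec@variants
    vi <- variantInfo(gm)
    causal <- which(v$source_trait %in% .TRAITS)
    nulls <- which(!(v$source_trait %in% .TRAITS))
    if (n_false > length(nulls))
        stop("n_false (", n_false, ") exceeds available null variants (",
             length(nulls), ")")
    withSeed(substreamSeed(seed, "catalog"), {
        false_idx <- if (n_false > 0) sort(sample(nulls, n_false)) else integer()
        idx <- c(causal, false_idx)
        trait <- c(v$source_trait[causal],
                   rep_len(.TRAITS, n_false))
        ## trait-increasing direction of the alt allele for the source trait
        defdir <- function(i, tr) {
            e <- spec@effects[i, ]
            switch(tr,
                   BMI = e[["BMI"]], WCadjBMI = e[["WC"]],
                   BFpct = e[["BFpct"]],
                   WHRadjBMI = e[["WC"]] - e[["HC"]],
                   0)
        }
        dir <- mapply(defdir, idx, trait)
        effect_allele <- ifelse(dir < 0, vi$ref[idx], vi$alt[idx])
        m <- length(idx)
        data.frame(
            key = vi$key[idx], chrom = vi$chrom[idx], pos = vi$pos[idx],
            ref = vi$ref[idx], alt = vi$alt[idx],
            effect_allele = effect_allele, trait = trait,
            reported_p = 10^-stats::runif(m, 7.31, 30),
            study_year = sample(2007:2020, m, replace = TRUE),
            study_n = sample(10000:700000, m, replace = TRUE),
            ancestry_tag = sample(c("EUR", "MULTI", "AFR"), m, replace = TRUE,
                                  prob = c(0.7, 0.2, 0.1)),
            is_causal = c(rep(TRUE, length(causal)), rep(FALSE, n_false)),
            stringsAsFactors = FALSE, row.names = NULL)
    })
}

#' Visit-2 exclusion fixture
#'
#' A visit-2 cohort table with exactly \code{n_pregnant} pregnancy flags
#' (always on female rows) and \code{n_missing} missing/implausible flags,
#' disjoint by construction. The defaults (2554 visit-2 participants, 10
#' pregnancy exclusions, 124 missing/implausible exclusions) leave 2420
#' analysed individuals after \code{\link{applySampleExclusions}}.
#'
#' @param n_visit2 number of visit-2 rows
#' @param n_pregnant number of pregnancy-flagged rows
#' @param n_missing number of missing/implausible-flagged rows
#' @param seed seed for demographics
#' @return a cohort data.frame (visit 2 only) with exclusion flags set
#' @export
makeExclusionFixture <- function(n_visit2 = 2554L, n_pregnant = 10L,
                                 n_missing = 124L, seed = 1L) {
    if (n_pregnant + n_missing > n_visit2)
        stop("requested flags (", n_pregnant + n_missing,
             ") exceed table size (", n_visit2, "); flags must be disjoint")
    withSeed(substreamSeed(seed, "fixture"), {
        n <- n_visit2
        sex <- ifelse(stats::rbinom(n, 1L, 0.369) == 1L, "male", "female")
        flagged <- sample(n, n_pregnant + n_missing)
        preg_rows <- flagged[seq_len(n_pregnant)]
        miss_rows <- setdiff(flagged, preg_rows)
        sex[preg_rows] <- "female"
        zs <- function(ph) .PHENO_SCALE[ph, "mean"] +
            .PHENO_SCALE[ph, "sd"] * stats::rnorm(n)
        wc <- zs("WC"); hc <- zs("HC")
        ct <- data.frame(
            sample_id = sprintf("S%05d", seq_len(n)),
            family_id = sprintf("F%05d", seq_len(n)),
            sex = sex, age = round(stats::runif(n, 35, 84), 1), visit = 2L,
            BMI = zs("BMI"), WC = wc, HC = hc, WHR = wc / hc,
            BFpct = pmin(pmax(zs("BFpct"), 3), 75),
            SAT = pmax(zs("SAT"), 1), VAT = pmax(zs("VAT"), 1),
            pregnancy_excluded = FALSE, missing_implausible = FALSE,
            stringsAsFactors = FALSE)
        ct$pregnancy_excluded[preg_rows] <- TRUE
        ct$missing_implausible[miss_rows] <- TRUE
        ct
    })
}

#' Simulate a complete cohort bundle
#'
#' Convenience wrapper: genotypes, phenotypes (with default exclusion flags
#' applied to visit-2 rows) and the variant catalog, all from one
#' architecture and seed.
#'
#' @param spec an \linkS4class{ArchitectureSpec}
#' @param n_false null variants to publish in the catalog
#' @param n_pregnant,n_missing exclusion flags set on random visit-2 rows
#'   (pregnancy flags on females only)
#' @return list with elements \code{genotypes}, \code{cohort},
#'   \code{catalog}, \code{spec}
#' @export
simulateCohort <- function(spec = defaultArchitecture(), n_false = 15L,
                           n_pregnant = 10L, n_missing = 124L) {
    gm <- simulateGenotypes(spec)
    ct <- simulatePhenotypes(gm, spec)
    withSeed(substreamSeed(spec@seed, "fixture"), {
        i2 <- which(ct$visit == 2L)
        fem <- i2[ct$sex[i2] == "female"]
        preg <- sample(fem, min(n_pregnant, length(fem)))
        rest <- setdiff(i2, preg)
        miss <- sample(rest, min(n_missing, length(rest)))
        ct$pregnancy_excluded[preg] <- TRUE
        ct$missing_implausible[miss] <- TRUE
    })
    list(genotypes = gm, cohort = ct,
         catalog = simulateCatalog(gm, spec, n_false = n_false), spec = spec)
}
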