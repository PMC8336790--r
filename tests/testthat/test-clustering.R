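mkResults <- function(keys, betas) {
    ## betas: named list adiposity trait -> numeric vector over keys
    do.call(rbind, lapply(names(betas), function(tr)
        data.frame(key = keys, trait = tr, beta = betas[[tr]], se = 0.01,
                   p = 0.5, n_used = 100, bmi_adjusted = FALSE,
                   stringsAsFactors = FALSE)))
}

mkSet <- function(gm, keys, trait = "BMI", effect_allele = NULL) {
    vi <- variantInfo(gm)
    idx <- match(keys, vi$key)
    if (is.null(effect_allele)) effect_allele <- vi$alt[idx]
    ent <- data.frame(key = keys, chrom = vi$chrom[idx], pos = vi$pos[idx],
                      ref = vi$ref[idx], alt = vi$alt[idx],
                      effect_allele = effect_allele, trait = trait,
                      reported_p = 1e-10, study_year = 2018, study_n = 1e5,
                      stringsAsFactors = FALSE)
    new("RiskSet", trait = trait, approach = 3L, entries = ent,
        audit = data.frame())
}

test_that("effect cells are betas scaled by 100, oriented to the effect allele", {
    gm <- toyGm(matrix(rep(0:2, 4), 4, 3, byrow = TRUE))
    vi <- variantInfo(gm)
    res <- mkResults(vi$key[1], list(BFpct = 0.01, SAT = -0.02,
                                     VAT = 0.005, VSR = 0))
    em <- buildEffectMatrix(res, list(mkSet(gm, vi$key[1])))
    expect_equal(unname(effectValues(em)[1, ]), c(1, -2, 0.5, 0))
    ## ref-oriented entry flips the sign
    em2 <- buildEffectMatrix(res, list(mkSet(gm, vi$key[1],
                                             effect_allele = vi$ref[1])))
    expect_equal(unname(effectValues(em2)[1, ]), c(-1, 2, -0.5, 0))
})

test_that("rows lacking an estimate are dropped and audited", {
    gm <- toyGm(matrix(rbinom(12, 2, 0.5), 4, 3))
    vi <- variantInfo(gm)
    res <- mkResults(vi$key[1:2], list(BFpct = c(1, 2) / 100,
                                       SAT = c(1, 2) / 100,
                                       VAT = c(1, 2) / 100,
                                       VSR = c(1, 2) / 100))
    res <- res[!(res$key == vi$key[2] & res$trait == "VAT"), ]
    em <- buildEffectMatrix(res, list(mkSet(gm, vi$key[1:2])))
    expect_equal(rownames(effectValues(em)), vi$key[1])
    expect_equal(em@audit$key, vi$key[2])
})

test_that("Ward linkage equals the exhaustive minimum-variance oracle", {
    set.seed(25)
    for (rep in 1:30) {
        n <- sample(3:6, 1)
        pts <- matrix(runif(n * sample(1:3, 1)), n)
        hc <- wardLinkage(pts)
        bw <- bruteWard(pts)
        expect_equal(hc$height, bw$heights, tolerance = 1e-9)
        expect_identical(hclustMerges(hc), bw$merges)
        expect_true(all(diff(hc$height) >= -1e-12))
    }
})

test_that("Ward handles duplicate points and rejects bad input", {
    hc <- wardLinkage(rbind(c(1, 1), c(1, 1)))
    expect_equal(hc$height, 0)
    expect_error(wardLinkage(rbind(c(1, NA), c(0, 1))), "non-finite")
    expect_error(wardLinkage(matrix(1, 1, 2)), "at least 2")
    ## the known 1-d case: pairs merge first, heights as derived by hand
    hc4 <- wardLinkage(matrix(c(0, 1, 10, 11), 4, 1))
    expect_identical(hclustMerges(hc4),
                     list(c(1L, 2L), c(3L, 4L), c(1L, 2L, 3L, 4L)))
    expect_equal(hc4$height[1:2], c(1, 1))
    expect_equal(hc4$height[3], sqrt(2 * 2 * (10)^2 / 2))  # centroid gap 10
})

test_that("cutting the tree gives non-increasing within-cluster variance", {
    set.seed(26)
    pts <- matrix(rnorm(40), 20, 2)
    hc <- wardLinkage(pts)
    wss <- vapply(1:6, function(k) {
        cl <- cutree(hc, k)
        sum(vapply(split(seq_len(20), cl), function(ix)
            sum(scale(pts[ix, , drop = FALSE], scale = FALSE)^2), 0))
    }, numeric(1))
    expect_true(all(diff(wss) <= 1e-9))
})

test_that("the ordered heatmap TSV follows the dendrogram leaf order", {
    set.seed(27)
    vals <- matrix(rnorm(24), 6, 4,
                   dimnames = list(paste0("v", 1:6),
                                   c("BFpct", "SAT", "VAT", "VSR")))
    em <- new("EffectMatrix", values = vals,
              source_trait = rep("BMI", 6), audit = data.frame())
    rt <- wardLinkage(vals); ctree <- wardLinkage(t(vals))
    f <- file.path(tempdir(), "hm.png")
    out <- renderHeatmap(em, rt, ctree, f)
    tab <- readTsv(out$tsv)
    expect_equal(tab$key, rownames(vals)[rt$order])
    expect_equal(colnames(tab)[-(1:2)], colnames(vals)[ctree$order])
    expect_true(file.exists(f))
    ## byte-identical on repetition
    out2 <- renderHeatmap(em, rt, ctree, file.path(tempdir(), "hm2.png"))
    expect_identical(readLines(out$tsv), readLines(out2$tsv))
    ## permuting input rows leaves the ordered matrix unchanged
    perm <- sample(6)
    emp <- new("EffectMatrix", values = vals[perm, ],
               source_trait = rep("BMI", 6), audit = data.frame())
    outp <- renderHeatmap(emp, wardLinkage(vals[perm, ]), ctree,
                          file.path(tempdir(), "hm3.png"))
    expect_equal(sort(outp$ordered[, 1]), sort(out$ordered[, 1]))
    expect_identical(outp$ordered[tab$key, ], out$ordered[tab$key, ])
})

test_that("the default architecture yields the expected clustering structure", {
    ## BMI-attributed variants load on SAT by construction; columns split
    ## into the subcutaneous-like and visceral-like pair
    nrep <- 10
    sat_pos <- logical(0); sep <- logical(nrep)
    catSet <- function(gm, catalog, trait) {
        sub <- catalog[catalog$is_causal & catalog$trait == trait, ]
        mkSet(gm, sub$key, trait, effect_allele = sub$effect_allele)
    }
    for (r in seq_len(nrep)) {
        spec <- defaultArchitecture(seed = 100 + r)
        gm <- simulateGenotypes(spec)
        ct <- simulatePhenotypes(gm, spec)
        catalog <- simulateCatalog(gm, spec)
        adip <- do.call(rbind, lapply(c("BFpct", "SAT", "VAT", "VSR"),
            function(tr) runInternalGwas(gm, ct, tr)))
        ## internally replicated (approach 3) BMI- and BF%-attributed rows
        for (tr in c("BMI", "BFpct")) {
            internal_f <- runInternalGwas(gm, ct, tr)
            rs3 <- buildRiskSet(catalog, internal_f, 3, gm, trait = tr)
            if (nrow(riskSetEntries(rs3)) == 0) next
            em <- buildEffectMatrix(adip, list(rs3))
            sat_pos <- c(sat_pos, effectValues(em)[, "SAT"] > 0)
        }
        ## column split computed on the full causal panel
        emall <- buildEffectMatrix(adip, list(
            catSet(gm, catalog, "BMI"), catSet(gm, catalog, "WHRadjBMI"),
            catSet(gm, catalog, "BFpct")))
        cl <- cutree(wardLinkage(t(effectValues(emall))), 2)
        sep[r] <- cl[["BFpct"]] == cl[["SAT"]] && cl[["VAT"]] == cl[["VSR"]] &&
            cl[["BFpct"]] != cl[["VAT"]]
    }
    ## replicated overall-adiposity variants are positive SAT predictors
    expect_gt(mean(sat_pos), 0.9)
    ## subcutaneous vs visceral column split in at least 80% of cohorts
    expect_gte(mean(sep), 0.8)
})
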