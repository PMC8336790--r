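test_that("simulated allele frequencies converge to the spec MAF", {
    spec <- miniArch(10000, nvar = 1, maf = 0.5, effect = 0, seed = 41)
    gm <- simulateGenotypes(spec)
    emp <- mean(dosages(gm)) / 2
    expect_lt(abs(emp - 0.5), 0.02)  # 4 binomial standard errors
})

test_that("within-block dosage correlation hits the target r2", {
    phenos <- c("BMI", "WC", "HC", "BFpct", "SAT", "VAT")
    mkblock <- function(k, r2, maf = 0.3, n = 50000) {
        variants <- data.frame(maf = rep(maf, k), block_id = "b1",
                               target_r2 = r2,
                               source_trait = rep("null", k))
        architectureSpec(n, 10L, 0, variants,
                         matrix(0, k, 6, dimnames = list(NULL, phenos)),
                         matrix(0, 1, 6), matrix(0, 2, 6),
                         rep(1, 6), seed = 17L)
    }
    ## independence case
    ds0 <- dosages(simulateGenotypes(mkblock(2, 0)))
    expect_lt(computeLdR2(ds0[1, ], ds0[2, ]), 0.01)
    ## strong LD, all pairs of a 3-variant block
    ds8 <- dosages(simulateGenotypes(mkblock(3, 0.8)))
    for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
        expect_lt(abs(computeLdR2(ds8[pair[1], ], ds8[pair[2], ]) - 0.8), 0.05)
})

test_that("the generator is deterministic under a fixed seed", {
    spec <- defaultArchitecture(nSamples = 300, nFamilies = 80, seed = 9)
    gm1 <- simulateGenotypes(spec); gm2 <- simulateGenotypes(spec)
    expect_identical(dosages(gm1), dosages(gm2))
    ct1 <- simulatePhenotypes(gm1, spec)
    ct2 <- simulatePhenotypes(gm2, spec)
    expect_identical(ct1, ct2)
    expect_identical(simulateCatalog(gm1, spec, 5), simulateCatalog(gm2, spec, 5))
})

test_that("null architecture yields no genotype-phenotype association", {
    spec <- miniArch(5000, nvar = 10, effect = 0, familySd = 0, seed = 23)
    gm <- simulateGenotypes(spec)
    ct <- simulatePhenotypes(gm, spec)
    prs_true <- colSums(dosages(gm))
    y <- ct$BFpct[ct$visit == 2]
    tval <- summary(lm(y ~ prs_true))$coefficients[2, "t value"]
    expect_lt(abs(tval), 3)
})

test_that("a single causal effect is recovered by OLS within 3 se", {
    spec <- miniArch(5000, nvar = 1, maf = 0.3, effect = 0.3, seed = 5)
    gm <- simulateGenotypes(spec)
    ct <- simulatePhenotypes(gm, spec)
    z <- (ct$BFpct[ct$visit == 2] - 38.2) / 9.9   # back to latent scale
    fit <- summary(lm(z ~ dosages(gm)[1, ]))
    expect_lt(abs(fit$coefficients[2, 1] - 0.3),
              3 * fit$coefficients[2, 2])
})

test_that("family intercepts produce the expected intraclass correlation", {
    spec <- miniArch(2500, nvar = 1, effect = 0, familySd = 0.5,
                     nFamilies = 500L, seed = 31)
    gm <- simulateGenotypes(spec)
    ct <- simulatePhenotypes(gm, spec)
    v2 <- ct[ct$visit == 2, ]
    z <- (v2$BFpct - 38.2) / 9.9
    fam <- v2$family_id
    ## one-way ANOVA estimate of the ICC
    k <- length(unique(fam)); n <- length(z); m <- n / k
    msb <- m * var(tapply(z, fam, mean))
    msw <- sum((z - ave(z, fam))^2) / (n - k)
    icc <- (msb - msw) / (msb + (m - 1) * msw)
    expected <- 0.25 / (0.25 + spec@residualSd[["BFpct"]]^2)
    expect_lt(abs(icc - expected), 0.05)
})

test_that("genetic variance matches the architecture-implied heritability", {
    spec <- miniArch(8000, nvar = 20, maf = 0.25, effect = 0.1, seed = 13)
    gm <- simulateGenotypes(spec)
    ct <- simulatePhenotypes(gm, spec)
    gv <- geneticValues(gm, spec)[, "BFpct"]
    z <- (ct$BFpct[ct$visit == 2] - 38.2) / 9.9
    h2_emp <- var(gv) / var(z)
    h2_spec <- 20 * 2 * 0.25 * 0.75 * 0.1^2  # 0.075
    expect_lt(abs(h2_emp - h2_spec), 0.02)
    expect_lt(abs(var(z) - 1), 0.05)
})

test_that("the catalog honours ground truth and significance admission", {
    spec <- defaultArchitecture(nSamples = 200, nFamilies = 50, seed = 3)
    gm <- simulateGenotypes(spec)
    cat0 <- simulateCatalog(gm, spec, n_false = 0)
    expect_true(all(cat0$is_causal))
    catalog <- simulateCatalog(gm, spec, n_false = 5)
    expect_equal(nrow(catalog), sum(spec@variants$source_trait != "null") + 5)
    expect_equal(sum(!catalog$is_causal), 5)
    expect_true(all(catalog$reported_p <= 5e-8))
    expect_error(simulateCatalog(gm, spec, n_false = 1000), "exceeds")
})

test_that("catalog entries for a counting fixture", {
    spec <- miniArch(100, nvar = 10, effect = 0.2, seed = 8)
    ## add 6 null variants so 5 false entries are available
    v <- rbind(spec@variants,
               data.frame(maf = rep(0.3, 6), block_id = paste0("n", 1:6),
                          target_r2 = 0, source_trait = "null"))
    eff <- rbind(spec@effects, matrix(0, 6, 6))
    colnames(eff) <- colnames(spec@effects)
    spec2 <- architectureSpec(100, 20, 0, v, eff, spec@factorLoadings,
                              spec@covariateEffects, spec@residualSd, 8)
    gm <- simulateGenotypes(spec2)
    catalog <- simulateCatalog(gm, spec2, n_false = 5)
    expect_equal(nrow(catalog), 15)
    expect_equal(sum(!catalog$is_causal), 5)
})

test_that("the exclusion fixture sets exactly the requested flags", {
    ct <- makeExclusionFixture()
    expect_equal(nrow(ct), 2554)
    expect_equal(sum(ct$pregnancy_excluded), 10)
    expect_equal(sum(ct$missing_implausible), 124)
    expect_false(any(ct$pregnancy_excluded & ct$missing_implausible))
    expect_true(all(ct$sex[ct$pregnancy_excluded] == "female"))
    ## WHR consistency
    expect_equal(ct$WHR, ct$WC / ct$HC)

    none <- makeExclusionFixture(100, 0, 0)
    expect_equal(sum(none$pregnancy_excluded | none$missing_implausible), 0)

    some <- makeExclusionFixture(100, 10, 20)
    expect_equal(nrow(applySampleExclusions(some)), 70)

    expect_error(makeExclusionFixture(100, 60, 50), "disjoint")
})
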