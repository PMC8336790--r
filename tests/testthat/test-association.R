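test_that("Blom inverse-normal scores match hand-computed quantiles", {
    out3 <- inverseNormalTransform(c(10, 20, 30))
    expect_equal(out3[2], 0)
    expect_equal(out3[1], -out3[3])
    expect_equal(out3[1], qnorm((1 - 3 / 8) / (3 + 1 / 4)))
    ## n = 5 distinct values: (r - 3/8)/(5.25)
    out5 <- inverseNormalTransform(c(3, 1, 4, 15, 9))
    want <- qnorm((rank(c(3, 1, 4, 15, 9)) - 3 / 8) / 5.25)
    expect_equal(out5, want, tolerance = 1e-9)
    expect_equal(sort(round(pnorm(sort(out5)), 3)),
                 c(0.119, 0.31, 0.5, 0.69, 0.881))
})

test_that("INT is invariant under strictly monotone recoding and keeps NAs", {
    set.seed(14)
    x <- rnorm(100)
    x[c(5, 50)] <- NA
    a <- inverseNormalTransform(x)
    b <- inverseNormalTransform(exp(2 * x) + 7)
    expect_equal(a, b)
    expect_true(all(is.na(a[c(5, 50)])))
    ## ties share the average-rank score
    tied <- inverseNormalTransform(c(1, 2, 2, 3))
    expect_equal(tied[2], tied[3])
    expect_error(inverseNormalTransform(rep(4, 10)), "identical")
    expect_error(inverseNormalTransform(c(1, NA)), "at least 2")
})

test_that("INT output is centred with variance approaching 1", {
    set.seed(15)
    z <- inverseNormalTransform(runif(4000))
    expect_lt(abs(mean(z)), 1e-10)   # antisymmetry of Blom scores
    expect_lt(abs(var(z) - 1), 0.01)
})

test_that("ancestry PCs match an explicit eigen-decomposition oracle", {
    set.seed(16)
    ds <- t(replicate(12, rbinom(40, 2, runif(1, 0.2, 0.5))))
    gm <- toyGm(ds)
    k <- 3
    scores <- ancestryPcs(gm, k)
    ## oracle: eigen-decomposition of the standardized covariance
    f <- rowMeans(ds) / 2
    Z <- t((ds - 2 * f) / sqrt(2 * f * (1 - f)))
    ev <- eigen(tcrossprod(Z))
    oracle <- ev$vectors[, 1:k] * rep(sqrt(ev$values[1:k]), each = nrow(Z))
    for (j in 1:k)
        expect_lt(min(sum(abs(scores[, j] - oracle[, j])),
                      sum(abs(scores[, j] + oracle[, j]))), 1e-6)
    vp <- attr(scores, "varprop")
    expect_true(all(diff(vp) <= 1e-12))
    ## k = 0: empty covariate block
    expect_equal(ncol(ancestryPcs(gm, 0)), 0)
})

test_that("PC1 separates two diverged subpopulations", {
    set.seed(17)
    n <- 200; m <- 60
    pop <- rep(0:1, each = n / 2)
    f1 <- runif(m, 0.1, 0.4); f2 <- pmin(f1 + 0.3, 0.9)
    ds <- sapply(seq_len(n), function(i)
        rbinom(m, 2, if (pop[i] == 0) f1 else f2))
    gm <- toyGm(ds)
    pc1 <- ancestryPcs(gm, 2)[, 1]
    expect_gt(abs(cor(pc1, pop)), 0.9)
})

test_that("beta_x100 is the raw slope scaled by 100", {
    set.seed(18)
    n <- 600
    prs <- rbinom(n, 20, 0.4)
    y <- 0.012 * prs + rnorm(n)
    fit <- fitPrsAssociation(y, prs, outcome = "BFpct")
    raw <- unname(coef(lm(y ~ prs))["prs"])
    expect_equal(fit@beta_x100, 100 * raw, tolerance = 1e-10)
    expect_true(fit@ci95[1] < fit@beta_x100 & fit@beta_x100 < fit@ci95[2])
})

test_that("a planted PRS effect is recovered within 3 se", {
    set.seed(19)
    n <- 5000
    prs <- rbinom(n, 30, 0.3)
    y <- 0.01 * prs + rnorm(n)
    fit <- fitPrsAssociation(y, prs, covariates = cbind(age = rnorm(n)))
    se100 <- (fit@ci95[2] - fit@ci95[1]) / (2 * qt(0.975, n - 3))
    expect_lt(abs(fit@beta_x100 - 1.0), 3 * se100)
    ## zero-effect PRS: incremental R2 stays near its 1/(n-p) bias
    fit0 <- fitPrsAssociation(rnorm(n), prs)
    expect_lt(fit0@r2_incremental, 10 / n)
})

test_that("beta_x100 is invariant to affine rescaling of covariates", {
    set.seed(20)
    n <- 500
    prs <- rbinom(n, 20, 0.4)
    age <- runif(n, 35, 84)
    y <- 0.01 * prs + 0.01 * age + rnorm(n)
    a <- fitPrsAssociation(y, prs, covariates = cbind(age = age))
    b <- fitPrsAssociation(y, prs, covariates = cbind(age = 10 * age - 300))
    expect_equal(a@beta_x100, b@beta_x100, tolerance = 1e-10)
    expect_equal(a@p, b@p, tolerance = 1e-10)
})

test_that("profiled REML matches the closed-form balanced ANOVA estimator", {
    set.seed(21)
    k <- 80; m <- 5
    fam <- rep(seq_len(k), each = m)
    y <- rnorm(k, 0, 0.8)[fam] + rnorm(k * m)
    fit <- mixedRandomIntercept(y, matrix(1, k * m, 1), fam)
    msb <- m * var(tapply(y, fam, mean))
    msw <- sum((y - ave(y, fam))^2) / (k * (m - 1))
    lam_anova <- max((msb - msw) / m, 0) / msw
    expect_lt(abs(fit$lambda - lam_anova), 1e-4)
})

test_that("REML agrees with an independent mixed-model implementation", {
    skip_if_not_installed("lme4")
    set.seed(22)
    k <- 60; m <- 4
    fam <- rep(seq_len(k), each = m)
    x <- rnorm(k * m)
    y <- 0.3 * x + rnorm(k, 0, 0.7)[fam] + rnorm(k * m)
    fit <- mixedRandomIntercept(y, cbind(1, x = x), fam)
    lf <- lme4::lmer(y ~ x + (1 | fam), REML = TRUE)
    expect_equal(unname(fit$coefficients["x"]),
                 unname(lme4::fixef(lf)["x"]), tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$lambda, vc$vcov[1] / vc$vcov[2], tolerance = 1e-3)
})

test_that("with zero family variance the mixed fit collapses to OLS", {
    set.seed(23)
    n <- 60
    fam <- rep(1:30, each = 2)
    x <- rnorm(n)
    ## identical family means: the between-family mean square is zero, so
    ## the REML optimum sits exactly at the lambda = 0 boundary
    a <- rnorm(30)
    y <- as.vector(rbind(a, -a)) + 0.4
    fit <- mixedRandomIntercept(y, cbind(1, x = x), fam)
    ols <- lm.fit(cbind(1, x), y)$coefficients
    expect_equal(fit$lambda, 0)
    expect_lt(max(abs(fit$coefficients - ols) / pmax(abs(ols), 1e-12)), 1e-6)
    ## and through the association interface
    pa <- fitPrsAssociation(y, x + 3, model = "mixed", family_ids = fam)
    po <- fitPrsAssociation(y, x + 3, model = "ols")
    expect_equal(pa@beta_x100, po@beta_x100, tolerance = 1e-6)
})

test_that("REML recovers a true variance ratio of 1", {
    set.seed(24)
    lams <- vapply(1:60, function(i) {
        k <- 100; m <- 5
        fam <- rep(seq_len(k), each = m)
        y <- rnorm(k)[fam] + rnorm(k * m)
        mixedRandomIntercept(y, matrix(1, k * m, 1), fam)$lambda
    }, numeric(1))
    expect_gt(median(lams), 0.8)
    expect_lt(median(lams), 1.25)
})

test_that("mixed model requires family ids and at least two families", {
    y <- rnorm(20)
    expect_error(fitPrsAssociation(y, rbinom(20, 10, 0.5), model = "mixed"),
                 "family_ids")
    expect_error(mixedRandomIntercept(y, matrix(1, 20, 1), rep(1, 20)),
                 "2 families")
})

test_that("Spearman matrix has unit diagonal and rank invariance", {
    ct <- makeExclusionFixture(300, 0, 0, seed = 4)
    sp <- spearmanMatrix(ct)
    expect_equal(unname(diag(sp)), rep(1, ncol(sp)))
    expect_equal(sp, t(sp))
    ## monotone transform of one trait leaves the matrix unchanged
    ct2 <- ct
    ct2$BMI <- exp(ct2$BMI / 10)
    expect_equal(spearmanMatrix(ct2), sp)
    ## hand-derived value on tied ranks: Pearson correlation of the ranks
    x <- 1:5; y <- c(5, 6, 7, 8, 7)
    ry <- c(1, 2, 3.5, 5, 3.5)
    want <- sum((x - 3) * (ry - 3)) /
        sqrt(sum((x - 3)^2) * sum((ry - 3)^2))
    ct3 <- data.frame(BMI = x, WC = y)
    expect_equal(spearmanMatrix(ct3, c("BMI", "WC"))[1, 2], want)
    ## insufficient pairs produce NA with a warning
    ct4 <- data.frame(BMI = c(1, 2, NA, NA), WC = c(NA, NA, 1, 2))
    expect_warning(sp4 <- spearmanMatrix(ct4, c("BMI", "WC")), "pairs")
    expect_true(is.na(sp4[1, 2]))
})
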