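#' Rank-based inverse-normal transform (Blom scores)
#'
#' Maps non-missing values to standard-normal quantiles
#' \eqn{\Phi^{-1}((r - 3/8) / (n + 1/4))} where r is the (average, for
#' ties) rank and n the number of non-missing values; missing values stay
#' missing. The Blom offset 3/8 is the convention of genetic epidemiology.
#'
#' @param values numeric vector, missing allowed
#' @return transformed vector of the same length
#' @examples
#' inverseNormalTransform(c(10, 20, 30))  # antisymmetric, middle -> 0
#' @export
inverseNormalTransform <- function(values) {
    ok <- !is.na(values)
    x <- values[ok]
    if (length(x) < 2L)
        stop("need at least 2 non-missing values")
    if (length(unique(x)) == 1L)
        stop("degenerate input: all non-missing values identical")
    r <- rank(x, ties.method = "average")
    out <- rep(NA_real_, length(values))
    out[ok] <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
    out
}

#' Ancestry principal components of the dosage matrix
#'
#' Principal components of the variant-standardized dosage matrix: each
#' variant is centred by twice its alt-allele frequency and scaled by
#' \eqn{\sqrt{2f(1-f)}} (the expected binomial SD), monomorphic variants
#' are excluded, missing dosages are mean-imputed (zero after centring),
#' and sample scores are taken from the singular value decomposition.
#' Explained variance is non-increasing in component index.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param k number of components (0 gives an empty covariate block)
#' @return samples x k matrix of PC scores (rownames = sample ids), with
#'   attribute \code{"varprop"} of explained-variance proportions
#' @export
ancestryPcs <- function(gm, k = 10L) {
    k <- as.integer(k)
    ds <- dosages(gm)
    if (k == 0L)
        return(matrix(numeric(), ncol(ds), 0,
                      dimnames = list(colnames(ds), NULL)))
    f <- rowMeans(ds, na.rm = TRUE) / 2
    poly <- f > 0 & f < 1
    ds <- ds[poly, , drop = FALSE]; f <- f[poly]
    if (k > min(dim(ds)))
        stop("k exceeds min(n_samples, n_polymorphic_variants)")
    Z <- (ds - 2 * f) / sqrt(2 * f * (1 - f))
    Z[is.na(Z)] <- 0
    sv <- svd(t(Z), nu = k, nv = 0)
    scores <- sv$u * rep(sv$d[seq_len(k)], each = ncol(ds))
    dimnames(scores) <- list(colnames(ds), paste0("PC", seq_len(k)))
    attr(scores, "varprop") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
    scores
}

#' Family random-intercept linear mixed model by profiled REML
#'
#' Fits \eqn{y = X\beta + b_{family} + e} with
#' \eqn{b \sim N(0, \lambda\sigma^2)} per family, profiling the REML
#' criterion over the single variance ratio
#' \eqn{\lambda = \sigma^2_{family} / \sigma^2_{resid}} by one-dimensional
#' optimization, with generalized-least-squares slopes at the optimum.
#' The boundary \eqn{\lambda = 0} (no family variance; GLS = OLS) is
#' evaluated explicitly, so null random effects are recovered exactly.
#'
#' @param y numeric response
#' @param X design matrix including the intercept column
#' @param family_ids family labels, one per row
#' @param lambda_max upper bound of the profiled interval
#' @return list: coefficients, se, lambda, sigma2_resid, sigma2_family,
#'   reml (the maximized criterion), df
#' @export
mixedRandomIntercept <- function(y, X, family_ids, lambda_max = 1e3) {
    X <- as.matrix(X)
    ok <- stats::complete.cases(y, X)
    y <- y[ok]; X <- X[ok, , drop = FALSE]
    fam <- factor(family_ids[ok])
    if (nlevels(fam) < 2L) stop("need at least 2 families")
    n <- length(y); p <- ncol(X)
    gidx <- split(seq_len(n), fam)
    ## negative REML log-likelihood (up to a constant), profiled over sigma2
    nllAt <- function(lambda) {
        XtVX <- matrix(0, p, p); XtVy <- numeric(p)
        yty <- 0; logdetV <- 0
        for (ix in gidx) {
            ni <- length(ix)
            w <- lambda / (1 + ni * lambda)
            Xi <- X[ix, , drop = FALSE]; yi <- y[ix]
            sx <- colSums(Xi); sy <- sum(yi)
            XtVX <- XtVX + crossprod(Xi) - w * tcrossprod(sx)
            XtVy <- XtVy + crossprod(Xi, yi) - w * sx * sy
            yty <- yty + sum(yi^2) - w * sy^2
            logdetV <- logdetV + log1p(ni * lambda)
        }
        ch <- chol(XtVX)
        beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
        rss <- yty - sum(XtVy * beta)
        sigma2 <- rss / (n - p)
        nll <- 0.5 * ((n - p) * log(sigma2) + logdetV +
                      2 * sum(log(diag(ch))))
        list(nll = nll, beta = beta, sigma2 = sigma2, chol = ch)
    }
    opt <- stats::optimize(function(l) nllAt(l)$nll, c(0, lambda_max),
                           tol = 1e-9)
    lambda <- opt$minimum
    if (nllAt(0)$nll <= opt$objective) lambda <- 0
    if (lambda_max - lambda < 1e-4 * lambda_max)
        stop("REML profiling did not converge on [0, ", lambda_max,
             "]; lambda at upper bound")
    fit <- nllAt(lambda)
    cov_beta <- chol2inv(fit$chol) * fit$sigma2
    se <- sqrt(diag(cov_beta))
    names(fit$beta) <- names(se) <- colnames(X)
    list(coefficients = fit$beta, se = se, lambda = lambda,
         sigma2_resid = fit$sigma2, sigma2_family = lambda * fit$sigma2,
         reml = -fit$nll, df = n - p)
}

#' PRS-phenotype association with covariate adjustment
#'
#' Regresses the inverse-normal-transformed outcome on the raw (allele
#' count) PRS plus covariates (age, sex, ancestry PCs), optionally adding
#' BMI as covariate, by OLS or by a family random-intercept mixed model.
#' The slope is reported as \code{beta_x100} -- the percent change in
#' outcome z-score per additional trait-increasing allele -- with a
#' t-quantile 95\% confidence interval. For OLS the incremental R-squared
#' of the PRS over the covariate-only model is attached.
#'
#' @param outcome_z inverse-normal-transformed outcome
#' @param prs a \linkS4class{PrsVector} or numeric vector of scores
#' @param covariates data.frame or matrix of covariates (may be NULL)
#' @param bmi optional BMI vector appended as covariate
#' @param model \code{"ols"} or \code{"mixed"}
#' @param family_ids required for the mixed model
#' @param outcome label of the outcome trait
#' @return an \linkS4class{AssociationResult}
#' @export
fitPrsAssociation <- function(outcome_z, prs, covariates = NULL, bmi = NULL,
                              model = c("ols", "mixed"), family_ids = NULL,
                              outcome = "trait") {
    model <- match.arg(model)
    trait <- "PRS"; approach <- NA_integer_
    if (methods::is(prs, "PrsVector")) {
        trait <- prs@trait; approach <- prs@approach
        prs <- prs@scores
    }
    n <- length(outcome_z)
    stopifnot(length(prs) == n)
    if (stats::sd(prs, na.rm = TRUE) == 0) stop("constant PRS")
    C <- if (is.null(covariates)) matrix(numeric(), n, 0) else as.matrix(covariates)
    bmi_adjusted <- !is.null(bmi)
    if (bmi_adjusted) C <- cbind(C, BMI = bmi)
    X <- cbind(`(Intercept)` = 1, prs = prs, C)
    ok <- stats::complete.cases(outcome_z, X)
    if (sum(ok) <= ncol(X)) stop("complete-case n does not exceed parameters")
    if (model == "mixed") {
        if (is.null(family_ids)) stop("mixed model requires family_ids")
        fit <- mixedRandomIntercept(outcome_z[ok], X[ok, , drop = FALSE],
                                    family_ids[ok])
        beta <- fit$coefficients["prs"]; se <- fit$se["prs"]; df <- fit$df
        r2inc <- NA_real_
    } else {
        yv <- outcome_z[ok]; Xv <- X[ok, , drop = FALSE]
        qrX <- qr(Xv)
        if (qrX$rank < ncol(Xv)) stop("rank-deficient design")
        f <- stats::lm.fit(Xv, yv)
        df <- length(yv) - ncol(Xv)
        sigma2 <- sum(f$residuals^2) / df
        se <- sqrt(sigma2 * chol2inv(qr.R(qrX))[2, 2])
        beta <- unname(f$coefficients["prs"])
        sst <- sum((yv - mean(yv))^2)
        r2_full <- 1 - sum(f$residuals^2) / sst
        X0 <- Xv[, -2, drop = FALSE]
        r2_cov <- 1 - sum(stats::lm.fit(X0, yv)$residuals^2) / sst
        r2inc <- max(r2_full - r2_cov, 0)
    }
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df)
    ci <- beta + c(-1, 1) * stats::qt(0.975, df) * se
    methods::new("AssociationResult", outcome = outcome, prs_trait = trait,
                 approach = approach, beta_x100 = unname(100 * beta),
                 ci95 = unname(100 * ci), p = unname(p), model = model,
                 bmi_adjusted = bmi_adjusted, r2_incremental = r2inc,
                 n = as.integer(sum(ok)))
}

setMethod("show", "AssociationResult", function(object) {
    cat(sprintf("AssociationResult: %s-PRS (approach %s) -> %s [%s%s]\n",
                object@prs_trait, object@approach, object@outcome,
                object@model,
                if (object@bmi_adjusted) ", BMI-adjusted" else ""))
    cat(sprintf("  beta x100 = %.2f (95%% CI %.2f, %.2f), p = %.3g, n = %d\n",
                object@beta_x100, object@ci95[1], object@ci95[2],
                object@p, object@n))
    if (is.finite(object@r2_incremental))
        cat(sprintf("  incremental R^2 = %.4f\n", object@r2_incremental))
})

#' Convert association results to a data.frame
#'
#' @param results list of \linkS4class{AssociationResult}
#' @return data.frame, one row per result
#' @export
associationTable <- function(results) {
    do.call(rbind, lapply(results, function(r) data.frame(
        outcome = r@outcome, prs_trait = r@prs_trait, approach = r@approach,
        beta_x100 = r@beta_x100, ci_lo = r@ci95[1], ci_hi = r@ci95[2],
        p = r@p, model = r@model, bmi_adjusted = r@bmi_adjusted,
        r2_incremental = r@r2_incremental, n = r@n,
        stringsAsFactors = FALSE)))
}

#' Pairwise-complete Spearman correlation matrix of traits
#'
#' @param ct single-visit cohort data.frame
#' @param traits trait names (columns of \code{ct}, or VSR = VAT/SAT)
#' @param min_pairs minimum complete pairs per cell (cells below it are NA
#'   with a warning)
#' @return symmetric correlation matrix with unit diagonal
#' @export
spearmanMatrix <- function(ct, traits = c("BMI", "WC", "WHR", "BFpct",
                                          "SAT", "VAT"),
                           min_pairs = 3L) {
    vals <- vapply(traits, function(tr)
        if (tr == "VSR") ct$VAT / ct$SAT else ct[[tr]],
        numeric(nrow(ct)))
    k <- length(traits)
    out <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
    for (i in seq_len(k)) for (j in i:k) {
        if (i == j) next   # diagonal is 1 by definition
        ok <- stats::complete.cases(vals[, i], vals[, j])
        if (sum(ok) < min_pairs) {
            warning("fewer than ", min_pairs, " complete pairs for ",
                    traits[i], " / ", traits[j])
            next
        }
        out[i, j] <- out[j, i] <- stats::cor(vals[ok, i], vals[ok, j],
                                             method = "spearman")
    }
    diag(out) <- 1
    out
}
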