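## Independent oracles and fixture builders shared across tests. These are
## deliberately naive (double loops, explicit enumeration) so they cannot
## share a defect with the implementation they check.

## brute-force unweighted PRS: explicit double loop over samples x entries
brutePrs <- function(ds, vi, entries) {
    n <- ncol(ds)
    scores <- numeric(n)
    used <- 0L
    for (i in seq_len(nrow(entries))) {
        ri <- which(vi$key == entries$key[i])
        if (!length(ri)) next
        ea <- entries$effect_allele[i]
        if (ea == vi$alt[ri]) flip <- FALSE
        else if (ea == vi$ref[ri]) flip <- TRUE
        else next
        g <- ds[ri, ]
        d <- if (flip) 2 - g else g
        if (all(is.na(d))) next
        fill <- mean(d, na.rm = TRUE)
        for (s in seq_len(n))
            scores[s] <- scores[s] + if (is.na(d[s])) fill else d[s]
        used <- used + 1L
    }
    list(scores = scores, used = used)
}

## exhaustive greedy LD pruning: rank entries, then test each candidate
## against every kept entry by explicitly recomputing r-squared
bruteGreedyPrune <- function(entries, ds, ld_r2 = 0.1) {
    ord <- order(entries$reported_p, -entries$study_n, -entries$study_year,
                 entries$key, method = "radix")
    kept <- character()
    for (i in ord) {
        ki <- entries$key[i]
        linked <- FALSE
        for (kj in kept) {
            x <- ds[ki, ]; y <- ds[kj, ]
            ok <- !is.na(x) & !is.na(y)
            if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
            if (cor(x[ok], y[ok])^2 >= ld_r2) { linked <- TRUE; break }
        }
        if (!linked) kept <- c(kept, ki)
    }
    kept
}

## exhaustive Ward: at each step evaluate the variance increase of every
## cluster pair and merge the minimum; heights are sqrt(2 * delta SSE)
bruteWard <- function(pts) {
    clusters <- lapply(seq_len(nrow(pts)), identity)
    heights <- numeric()
    merges <- list()
    while (length(clusters) > 1) {
        best <- NULL; bestd <- Inf
        for (a in seq_len(length(clusters) - 1))
            for (b in (a + 1):length(clusters)) {
                A <- clusters[[a]]; B <- clusters[[b]]
                d <- length(A) * length(B) / (length(A) + length(B)) *
                    sum((colMeans(pts[A, , drop = FALSE]) -
                         colMeans(pts[B, , drop = FALSE]))^2)
                if (d < bestd - 1e-12) { bestd <- d; best <- c(a, b) }
            }
        heights <- c(heights, sqrt(2 * bestd))
        merges[[length(merges) + 1L]] <-
            sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    list(heights = heights, merges = merges)
}

## cluster compositions per merge step of an hclust tree
hclustMerges <- function(hc) {
    sets <- list()
    lapply(seq_len(nrow(hc$merge)), function(i) {
        get1 <- function(v) if (v < 0) -v else sets[[v]]
        s <- sort(c(get1(hc$merge[i, 1]), get1(hc$merge[i, 2])))
        sets[[i]] <<- s
        s
    })
}

## minimal GenotypeMatrix from a dosage matrix (variants in rows)
toyGm <- function(ds, ref = NULL, alt = NULL, imputation_r2 = NULL) {
    m <- nrow(ds)
    if (is.null(ref)) ref <- rep(c("A", "C", "G", "T"), length.out = m)
    if (is.null(alt)) alt <- rep(c("G", "T", "A", "C"), length.out = m)
    GenotypeMatrix(ds, data.frame(
        chrom = rep("1", m), pos = seq_len(m) * 1000L,
        ref = ref, alt = alt,
        imputation_r2 = if (is.null(imputation_r2)) rep(1, m) else imputation_r2,
        stringsAsFactors = FALSE))
}

## single-phenotype architecture: nvar independent variants of equal maf
## and equal effect on one latent phenotype, optional family clustering
miniArch <- function(n, nvar = 10L, maf = 0.3, effect = 0.1,
                     pheno = "BFpct", familySd = 0, nFamilies = max(2L, n %/% 5L),
                     covariates = FALSE, seed = 1L) {
    phenos <- c("BMI", "WC", "HC", "BFpct", "SAT", "VAT")
    variants <- data.frame(maf = rep(maf, nvar),
                           block_id = paste0("s", seq_len(nvar)),
                           target_r2 = 0,
                           source_trait = rep(pheno, nvar),
                           stringsAsFactors = FALSE)
    effects <- matrix(0, nvar, 6, dimnames = list(NULL, phenos))
    effects[, pheno] <- effect
    loadings <- matrix(0, 1, 6)
    covEff <- matrix(0, 2, 6)
    if (covariates)
        covEff <- rbind(c(-0.005, 0.003, 0.002, 0.004, 0.003, 0.008),
                        c(-0.2, 0.25, -0.3, -0.9, -0.5, 0.25))
    genVar <- colSums(2 * variants$maf * (1 - variants$maf) * effects^2)
    residSd <- sqrt(pmax(1 - genVar - familySd^2, 0.05))
    architectureSpec(n, nFamilies, familySd, variants, effects, loadings,
                     covEff, residSd, seed)
}

## random dosage matrix with planted LD structure, for pruning tests
randomLdGenotypes <- function(n, m, rho_range = c(0, 0.95)) {
    R <- diag(m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m)
        R[a, b] <- R[b, a] <- runif(1, rho_range[1], rho_range[2]) *
            sample(c(0, 1), 1)   # half the pairs uncorrelated
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    Z <- matrix(rnorm(n * m), n, m) %*% chol(R)
    maf <- runif(m, 0.1, 0.5)
    ds <- t((Z > rep(qnorm(1 - maf), each = n)) +
            (matrix(rnorm(n * m), n, m) %*% chol(R) >
             rep(qnorm(1 - maf), each = n)))
    storage.mode(ds) <- "double"
    ds
}

## random catalog for a set of variant keys
randomCatalog <- function(keys, vi, trait = "BMI") {
    m <- length(keys)
    idx <- match(keys, vi$key)
    data.frame(key = keys, chrom = vi$chrom[idx], pos = vi$pos[idx],
               ref = vi$ref[idx], alt = vi$alt[idx],
               effect_allele = ifelse(runif(m) < 0.5, vi$ref[idx], vi$alt[idx]),
               trait = trait,
               reported_p = 10^-runif(m, 7.31, 30),
               study_year = sample(2007:2020, m, replace = TRUE),
               study_n = sample(10000:700000, m, replace = TRUE),
               ancestry_tag = "EUR", stringsAsFactors = FALSE)
}
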