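## Seed substreams: one master seed, deterministic per-stage offsets, so a
## stage re-run in isolation reproduces its in-pipeline draws. Kept < 2^31.
.STAGE_OFFSETS <- c(genotypes = 1L, phenotypes = 2L, catalog = 3L,
                    fixture = 4L, pipeline = 5L, clustering = 6L)

substreamSeed <- function(seed, stage) {
    off <- .STAGE_OFFSETS[[stage]]
    as.integer((as.numeric(seed) * 10007 + off * 101) %% 2147483647)
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## structured one-line log records, silenced via option
logMsg <- function(stage, ...) {
    if (isTRUE(getOption("adiposePRS.quiet", TRUE))) return(invisible(NULL))
    message(sprintf("[%s] %s", stage, paste0(...)))
}
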