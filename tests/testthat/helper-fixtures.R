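# shared fixture builders (everything generated in code; no stored data)

# FCStatistics stub from explicit matrices (defaults: zero-lag identity-ish)
fc_stub <- function(fc, fcForward = fc, fcReversal = t(fcForward),
                    lagTRs = 1L) {
    new("FCStatistics", fc = fc, fcForward = fcForward,
        fcReversal = fcReversal, lagTRs = as.integer(lagTRs))
}

# symmetric correlation-like matrix with unit diagonal
random_corr <- function(n, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(rnorm(n * n), n)
        s <- cov2cor(crossprod(m) + diag(n))
        (s + t(s)) / 2
    })
}

# small signed ground truth + cohort, cached across tests in one session
tiny_cohort <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            gt <- makeGroundTruth(nRegions = 16, nModules = 2,
                                  density = 0.4, seed = 42)
            cache <<- list(gt = gt,
                           cohort = makeCohort(gt, nSubjects = 2,
                                               nVolumes = 200, seed = 43))
        }
        cache
    }
})

# delay-line reservoir: directed ring with one epsilon link, so the spectral
# normalization at alpha = rho(w0) makes every line weight exactly 1
delay_ring <- function(n = 25) {
    w0 <- matrix(0, n, n)
    for (i in seq_len(n - 1)) w0[i + 1, i] <- 1
    w0[1, n] <- 1e-10
    w0
}
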