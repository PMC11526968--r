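# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so library code never clobbers user seeds
with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# population (divide-by-n) standard deviation; hierarchy measures use this
sd_pop <- function(x) {
    x <- x[is.finite(x)]
    sqrt(mean((x - mean(x))^2))
}

# Pearson correlation between the strictly-upper triangles of two matrices
uptri_cor <- function(a, b) {
    ut <- upper.tri(a)
    va <- a[ut]; vb <- b[ut]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
        stop("zero-variance upper triangle; correlation undefined")
    stats::cor(va, vb)
}

# analytic signal via FFT (Marple's method): z = s + i*H[s]
analytic_signal <- function(s) {
    n <- length(s)
    f <- stats::fft(s)
    h <- numeric(n)
    if (n %% 2 == 0) {
        h[1] <- 1; h[n / 2 + 1] <- 1
        h[2:(n / 2)] <- 2
    } else {
        h[1] <- 1
        h[2:((n + 1) / 2)] <- 2
    }
    stats::fft(f * h, inverse = TRUE) / n
}

# derive a stream of distinct child seeds from one master seed (keeps values
# within 32-bit integer range)
child_seeds <- function(seed, n) {
    with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
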