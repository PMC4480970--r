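# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv,
                        inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
    expr
}

# Centered moving average over a numeric vector; window w covers offsets
# -floor((w-1)/2) .. +floor(w/2), truncated at the ends. NA entries are
# dropped from each window (renormalised); a window with no data gives NA.
movingAverage <- function(x, window) {
    w <- as.integer(window)
    if (w < 1) stop("window must be >= 1")
    n <- length(x)
    if (w > n) stop("window exceeds profile length")
    lo <- floor((w - 1) / 2)
    hi <- floor(w / 2)
    ok <- !is.na(x)
    xz <- ifelse(ok, x, 0)
    csx <- c(0, cumsum(xz))
    csn <- c(0, cumsum(as.numeric(ok)))
    i <- seq_len(n)
    a <- pmax(i - lo, 1L)
    b <- pmin(i + hi, n)
    s <- csx[b + 1] - csx[a]
    m <- csn[b + 1] - csn[a]
    out <- ifelse(m > 0, s / m, NA_real_)
    names(out) <- names(x)
    out
}
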