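# Shared fixture builders; everything is generated in code.

# A deterministic noisy cubic Marey-like fixture.
cubicFixture <- function(n = 20, seed = 42L,
                         coefs = c(1, 2.5, -0.08, 0.003), sd = 0.5) {
    withr::with_seed(seed, {
        x <- sort(runif(n, 0, 30))
        y <- coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3 +
            rnorm(n, 0, sd)
        MareyMap(x, pmax(y, 0))
    })
}

# Uniformly spread markers with a linear genetic map.
uniformFixture <- function(n = 200, L = 50, seed = 1L, genLength = 100) {
    p <- withr::with_seed(seed, runif(n, 0, L))
    MareyMap(p, seq(0, genLength, length.out = n))
}

# Write a small Marey CSV and return its path.
writeCsvFixture <- function(df, sep = ",", ext = ".csv") {
    f <- tempfile(fileext = ext)
    write.table(df, f, sep = sep, row.names = FALSE, quote = FALSE)
    f
}

# Least-squares cubic through the normal equations: an oracle independent
# of lm.fit's QR path.
normalEquationsCubic <- function(x, y) {
    X <- cbind(1, x, x^2, x^3)
    as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# R^2 of a cubic fit computed from scratch (normal equations on centred
# abscissae -- R^2 is invariant to the shift -- plus the definition).
bruteR2 <- function(x, y) {
    xc <- x - mean(x)
    cf <- normalEquationsCubic(xc, y)
    pred <- cbind(1, xc, xc^2, xc^3) %*% cf
    tss <- sum((y - mean(y))^2)
    if (tss == 0) 1 else 1 - sum((y - pred)^2) / tss
}
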