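## Periodized orthogonal Daubechies DWT (Mallat pyramid), used for
## motion-artifact correction. Synthesis is the transpose of analysis, so
## reconstruction without thresholding is exact.

daubechiesFilter <- function(family = c("db2", "db1", "db4")) {
    family <- match.arg(family)
    switch(family,
           db1 = c(1, 1) / sqrt(2),
           db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
               (4 * sqrt(2)),
           db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
                   -0.027983769416984, -0.187034811718881, 0.030841381835987,
                   0.032883011666983, -0.010597401784997))
}

## one analysis step: returns list(approx, detail), length n/2 each
dwtStep <- function(x, h) {
    n <- length(x)
    g <- rev(h) * (-1)^(seq_along(h) - 1)    # quadrature mirror
    half <- n / 2
    a <- d <- numeric(half)
    base <- 2 * (seq_len(half) - 1)
    for (k in seq_along(h)) {
        idx <- (base + k - 1) %% n + 1
        a <- a + h[k] * x[idx]
        d <- d + g[k] * x[idx]
    }
    list(approx = a, detail = d)
}

## transpose of dwtStep
idwtStep <- function(a, d, h) {
    g <- rev(h) * (-1)^(seq_along(h) - 1)
    n <- 2 * length(a)
    x <- numeric(n)
    base <- 2 * (seq_along(a) - 1)
    for (k in seq_along(h)) {
        idx <- (base + k - 1) %% n + 1
        add <- h[k] * a + g[k] * d
        x[idx] <- x[idx] + add
    }
    x
}

#' Periodized discrete wavelet transform
#'
#' @param x numeric signal; internally reflected-padded to a power of two.
#' @param levels decomposition depth.
#' @param family Daubechies family (\code{"db2"} default).
#' @return list with \code{details} (fine to coarse), \code{approx},
#'   \code{n} (original length) and padding info; invert with
#'   \code{\link{idwtPeriodized}}.
#' @export
dwtPeriodized <- function(x, levels, family = "db2") {
    n <- length(x)
    nfft <- 2^ceiling(log2(n))
    if (2^levels > nfft) stop("signal too short for requested levels")
    if (nfft > n) {
        pad <- rev(x)[seq_len(nfft - n)]     # reflection padding
        xx <- c(x, pad)
    } else xx <- x
    h <- daubechiesFilter(family)
    details <- vector("list", levels)
    a <- xx
    for (j in seq_len(levels)) {
        st <- dwtStep(a, h)
        details[[j]] <- st$detail
        a <- st$approx
    }
    list(details = details, approx = a, n = n, nfft = nfft, family = family)
}

#' @rdname dwtPeriodized
#' @param w a decomposition from \code{dwtPeriodized}.
#' @return \code{idwtPeriodized}: the reconstructed signal (original length).
#' @export
idwtPeriodized <- function(w) {
    h <- daubechiesFilter(w$family)
    a <- w$approx
    for (j in rev(seq_along(w$details)))
        a <- idwtStep(a, w$details[[j]], h)
    a[seq_len(w$n)]
}

#' Wavelet motion-artifact correction
#'
#' Decomposes each channel with a Daubechies DWT down to the detail scale
#' just above \code{min_detail_hz} (so the slow hemodynamic band stays in
#' the untouched approximation), and zeroes detail coefficients lying more
#' than \code{iqr} interquartile ranges beyond the quartiles of their level.
#' Sharp motion spikes concentrate in exactly those outlying coefficients,
#' while a clean slow signal is nearly unchanged.
#'
#' @param x channels x time matrix (OD) or a numeric vector.
#' @param fs sampling rate (Hz).
#' @param iqr outlier threshold in interquartile ranges (default 0.5).
#' @param family Daubechies family (default \code{"db2"}).
#' @param min_detail_hz decompose only while the detail band lies above this
#'   frequency (default 0.15 Hz), so the hemodynamic band stays in the
#'   untouched approximation.
#' @return corrected signal, same shape as \code{x}.
#' @export
waveletCorrect <- function(x, fs, iqr = 0.5, family = "db2",
                           min_detail_hz = 0.15) {
    one <- function(v) {
        levels <- max(1L, floor(log2(fs / (2 * min_detail_hz))))
        minlen <- 2 * length(daubechiesFilter(family))
        if (length(v) < minlen)
            stop("signal too short for wavelet decomposition")
        levels <- min(levels, floor(log2(length(v))) - 1L)
        w <- dwtPeriodized(v, levels, family)
        w$details <- lapply(w$details, function(d) {
            q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
            spread <- q[2] - q[1]
            d[d < q[1] - iqr * spread | d > q[2] + iqr * spread] <- 0
            d
        })
        idwtPeriodized(w)
    }
    if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}
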