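## Inter-observer agreement: tolerance time-unit kappa, event-alignment
## kappa (GSEQ-style), Cohen's kappa, two-way mixed ICC.

kappaFromTable <- function(tab) {
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    if (abs(1 - pe) < .Machine$double.eps^0.5) {
        warning("kappa undefined: degenerate marginals (single code)")
        return(list(kappa = NA_real_, agreement = 100 * po))
    }
    list(kappa = (po - pe) / (1 - pe), agreement = 100 * po)
}

#' Cohen's kappa for paired label sequences
#'
#' Standard unweighted chance-corrected agreement between two coders'
#' labels of the same units (e.g. per-segment touch codes, including
#' \code{"none"}).
#'
#' @param a,b equal-length label vectors.
#' @return list with \code{kappa}, \code{agreement} (percent) and \code{n}.
#' @export
cohensKappa <- function(a, b) {
    if (length(a) != length(b)) stop("label sequences differ in length")
    if (!length(a)) stop("empty label sequences")
    lev <- sort(unique(c(a, b)))
    tab <- table(factor(a, lev), factor(b, lev))
    c(kappaFromTable(tab), n = length(a))
}

#' Time-unit kappa with timing tolerance
#'
#' Chance-corrected agreement over discretized time units in the style of
#' sequential-analysis software: a unit coded by observer A agrees if
#' observer B holds the same code in some unit within \code{tolerance_s}
#' (symmetric window). Agreeing units are tallied on the diagonal; a unit
#' without a tolerated match is tallied against B's code at the same unit.
#' With \code{tolerance_s = 0} this reduces exactly to
#' \code{\link{cohensKappa}} on the unit labels.
#'
#' @param a,b equal-length per-unit label vectors.
#' @param tolerance_s tolerated timing deviation in seconds (default 1).
#' @param unit_s time-unit resolution in seconds (default 1).
#' @return list with \code{kappa}, \code{agreement} (percent), \code{n}.
#' @export
timeUnitKappa <- function(a, b, tolerance_s = 1, unit_s = 1) {
    if (length(a) != length(b)) stop("sequences differ in length")
    n <- length(a)
    if (!n) stop("empty sequences")
    tol <- as.integer(round(tolerance_s / unit_s))
    lev <- sort(unique(c(a, b)))
    tab <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_len(n)) {
        win <- max(1, i - tol):min(n, i + tol)
        if (any(b[win] == a[i]))
            tab[a[i], a[i]] <- tab[a[i], a[i]] + 1
        else
            tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
    }
    c(kappaFromTable(tab), n = n)
}

alignmentMatchOk <- function(on_a, off_a, on_b, off_b, tolerance_s,
                             min_overlap) {
    if (abs(on_a - on_b) > tolerance_s) return(FALSE)
    ov <- min(off_a, off_b) - max(on_a, on_b)
    shorter <- min(off_a - on_a, off_b - on_b)
    if (shorter <= 0) return(ov >= 0)      # point events: require contact
    ov / shorter >= min_overlap
}

#' Event-alignment kappa
#'
#' Globally aligns two coders' event sequences by dynamic programming.
#' Two events may be aligned only if their onsets differ by at most
#' \code{tolerance_s} and they overlap at least \code{min_overlap} of the
#' shorter event's duration. The alignment maximizes the number of aligned
#' pairs, breaking ties in favor of code agreements. Aligned pairs are
#' tallied by their codes; unaligned events are tallied against a nil code.
#'
#' @param a_events,b_events \code{data.frame}s with columns \code{code},
#'   \code{onset_s}, \code{offset_s}, sorted by onset.
#' @param tolerance_s tolerated onset deviation in seconds (default 2).
#' @param min_overlap required overlap as a fraction of the shorter event
#'   (default 0.8).
#' @return list with \code{kappa}, \code{agreement} (percent),
#'   \code{n_pairs} (aligned pairs) and \code{n} (total tallies).
#' @export
eventAlignmentKappa <- function(a_events, b_events, tolerance_s = 2,
                                min_overlap = 0.8) {
    na <- nrow(a_events); nb <- nrow(b_events)
    if (!na && !nb) stop("both event sequences empty: kappa undefined")
    if (na > 1 && is.unsorted(a_events$onset_s)) stop("a_events unsorted")
    if (nb > 1 && is.unsorted(b_events$onset_s)) stop("b_events unsorted")
    MATCH <- 1000                      # pair weight; +1 tie-break for agreement
    S <- matrix(0, na + 1, nb + 1)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
        best <- max(S[i, j + 1], S[i + 1, j])
        if (alignmentMatchOk(a_events$onset_s[i], a_events$offset_s[i],
                             b_events$onset_s[j], b_events$offset_s[j],
                             tolerance_s, min_overlap)) {
            w <- MATCH + (a_events$code[i] == b_events$code[j])
            best <- max(best, S[i, j] + w)
        }
        S[i + 1, j + 1] <- best
    }
    # traceback
    pairs <- matrix(integer(), 0, 2)
    i <- na; j <- nb
    while (i > 0 && j > 0) {
        ok <- alignmentMatchOk(a_events$onset_s[i], a_events$offset_s[i],
                               b_events$onset_s[j], b_events$offset_s[j],
                               tolerance_s, min_overlap)
        w <- if (ok) MATCH + (a_events$code[i] == b_events$code[j]) else -Inf
        if (ok && S[i + 1, j + 1] == S[i, j] + w) {
            pairs <- rbind(pairs, c(i, j)); i <- i - 1; j <- j - 1
        } else if (S[i + 1, j + 1] == S[i, j + 1]) {
            i <- i - 1
        } else {
            j <- j - 1
        }
    }
    nil <- "<nil>"
    lev <- sort(unique(c(a_events$code, b_events$code, nil)))
    tab <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    for (k in seq_len(nrow(pairs))) {
        ca <- a_events$code[pairs[k, 1]]; cb <- b_events$code[pairs[k, 2]]
        tab[ca, cb] <- tab[ca, cb] + 1
    }
    for (i in setdiff(seq_len(na), pairs[, 1]))
        tab[a_events$code[i], nil] <- tab[a_events$code[i], nil] + 1
    for (j in setdiff(seq_len(nb), pairs[, 2]))
        tab[nil, b_events$code[j]] <- tab[nil, b_events$code[j]] + 1
    c(kappaFromTable(tab), n_pairs = nrow(pairs), n = sum(tab))
}

#' Two-way mixed-model intraclass correlation
#'
#' Single-rater ICC from the two-way (targets x raters) ANOVA mean squares.
#' The default, consistency ICC(3,1), is
#' \eqn{(MS_T - MS_E) / (MS_T + (k-1) MS_E)} with \eqn{k} raters; the
#' absolute-agreement variant ICC(A,1) additionally charges the rater
#' variance component.
#'
#' @param scores numeric matrix, raters in rows, targets in columns, no
#'   missing cells.
#' @param type \code{"consistency"} (default) or \code{"agreement"}.
#' @return the ICC (numeric scalar).
#' @export
iccTwoWayMixed <- function(scores, type = c("consistency", "agreement")) {
    type <- match.arg(type)
    scores <- as.matrix(scores)
    k <- nrow(scores); n <- ncol(scores)
    if (k < 2 || n < 2) stop("need >= 2 raters and >= 2 targets")
    if (anyNA(scores)) stop("missing cells not supported")
    if (stats::var(as.vector(scores)) == 0)
        stop("ICC undefined: scores are constant")
    d <- data.frame(score = as.vector(scores),
                    rater = factor(rep(seq_len(k), times = n)),
                    target = factor(rep(seq_len(n), each = k)))
    ms <- summary(stats::aov(score ~ target + rater, data = d))[[1]][, "Mean Sq"]
    MST <- ms[1]; MSR <- ms[2]; MSE <- ms[3]
    if (type == "consistency")
        (MST - MSE) / (MST + (k - 1) * MSE)
    else
        (MST - MSE) / (MST + (k - 1) * MSE + k / n * (MSR - MSE))
}
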