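## Independent oracles and fixture builders shared across tests. These stay
## deliberately naive (quadratic scans, exhaustive enumeration, explicit
## mean-squares algebra) so they cannot share a defect with the package's
## implementations.

## Brute-force contingency detection: for every infant event inside mutual
## gaze, scan all maternal events inside gaze for the earliest onset in the
## operative window, excluding exact onset ties.
bruteforceContingent <- function(mother, infant, gaze, W_ms = 1000) {
    inside <- function(t) {
        ep <- episodes(gaze)
        any(t >= ep$start_ms & t < ep$end_ms)
    }
    mev <- events(mother)
    mev <- mev[vapply(mev$onset_ms, inside, logical(1)), , drop = FALSE]
    iev <- events(infant)
    iev <- iev[vapply(iev$onset_ms, inside, logical(1)), , drop = FALSE]
    out <- NULL
    for (i in seq_len(nrow(iev))) {
        hi <- if (iev$modality[i] == "vocal") iev$offset_ms[i] + W_ms
              else iev$onset_ms[i] + W_ms
        best <- NA
        for (j in seq_len(nrow(mev))) {
            if (mev$onset_ms[j] <= iev$onset_ms[i]) next
            if (mev$onset_ms[j] > hi) next
            if (is.na(best) || mev$onset_ms[j] < mev$onset_ms[best])
                best <- j
        }
        if (!is.na(best))
            out <- rbind(out, c(i, best, iev$onset_ms[i],
                                mev$onset_ms[best]))
    }
    out
}

## Random coded session on a 100-ms grid (deliberately producing onset ties,
## simultaneity groups, and events outside gaze).
randomSession <- function(seed, max_events = 50, horizon_ms = 60000) {
    set.seed(seed)
    nI <- sample(0:max_events, 1)
    nM <- sample(0:max_events, 1)
    mk <- function(n, who) {
        on <- sort(sample(seq(0, horizon_ms, by = 100), n, replace = TRUE))
        du <- sample(seq(100, 1500, by = 100), n, replace = TRUE)
        vocal <- runif(n) < 0.3
        EventStream(who,
                    code = ifelse(vocal, "vocal", "smile"),
                    modality = ifelse(vocal, "vocal", "facial"),
                    onset_ms = on, offset_ms = on + du)
    }
    n_ep <- sample(1:3, 1)
    bounds <- sort(sample(seq(0, horizon_ms, by = 1000), 2 * n_ep))
    ok <- bounds[seq(2, 2 * n_ep, 2)] > bounds[seq(1, 2 * n_ep, 2)]
    gaze <- if (any(ok))
        GazeEpisodes(bounds[seq(1, 2 * n_ep, 2)][ok],
                     bounds[seq(2, 2 * n_ep, 2)][ok])
    else GazeEpisodes(0, horizon_ms)
    list(mother = mk(nM, "mother"), infant = mk(nI, "infant"), gaze = gaze)
}

## Exhaustive enumeration of monotone event alignments; mirrors the DP's
## objective (pairs first, code agreements as tie-break).
exhaustiveAlignmentScore <- function(a, b, tolerance_s = 2,
                                     min_overlap = 0.8) {
    okmat <- function(i, j) {
        if (abs(a$onset_s[i] - b$onset_s[j]) > tolerance_s) return(FALSE)
        ov <- min(a$offset_s[i], b$offset_s[j]) -
            max(a$onset_s[i], b$onset_s[j])
        sh <- min(a$offset_s[i] - a$onset_s[i], b$offset_s[j] - b$onset_s[j])
        if (sh <= 0) return(ov >= 0)
        ov / sh >= min_overlap
    }
    best <- 0
    rec <- function(i, j, score) {
        if (i > nrow(a) || j > nrow(b)) {
            best <<- max(best, score)
            return(invisible())
        }
        rec(i + 1, j, score)
        rec(i, j + 1, score)
        if (okmat(i, j))
            rec(i + 1, j + 1,
                score + 1000 + (a$code[i] == b$code[j]))
        invisible()
    }
    rec(1, 1, 0)
    best
}

## Two-way within-subject ANOVA from explicit cell means.
handRmAnova <- function(bins) {
    y <- xtabs(mean_uM ~ subject + condition + bin, bins)
    m <- mean(y)
    ms <- apply(y, 1, mean); mc <- apply(y, 2, mean); mb <- apply(y, 3, mean)
    msc <- apply(y, c(1, 2), mean); msb <- apply(y, c(1, 3), mean)
    nS <- dim(y)[1]; nC <- dim(y)[2]; nB <- dim(y)[3]
    SSC <- nS * nB * sum((mc - m)^2)
    SSSC <- nB * sum((msc - outer(ms, mc, "+") + m)^2)
    SSB <- nS * nC * sum((mb - m)^2)
    SSSB <- nC * sum((msb - outer(ms, mb, "+") + m)^2)
    mcb <- apply(y, c(2, 3), mean)
    resid3 <- 0
    for (s in seq_len(nS)) for (ci in seq_len(nC)) for (bi in seq_len(nB))
        resid3 <- resid3 + (y[s, ci, bi] - msc[s, ci] - msb[s, bi] -
                            mcb[ci, bi] + ms[s] + mc[ci] + mb[bi] - m)^2
    SSCB <- nS * sum((mcb - outer(mc, mb, "+") + m)^2)
    list(F_condition = unname((SSC / (nC - 1)) /
                              (SSSC / ((nS - 1) * (nC - 1)))),
         F_bin = unname((SSB / (nB - 1)) / (SSSB / ((nS - 1) * (nB - 1)))),
         F_inter = unname((SSCB / ((nC - 1) * (nB - 1))) /
             (resid3 / ((nS - 1) * (nC - 1) * (nB - 1)))))
}

## Null (or condition-shifted) 2x6 within-subject bin table.
nullBins <- function(seed, ns = 10, effect = 0) {
    set.seed(seed)
    d <- expand.grid(subject = sprintf("s%02d", seq_len(ns)), roi = "right",
                     chromophore = "HbO",
                     condition = c("contingent", "noncontingent"),
                     bin = 1:6, stringsAsFactors = FALSE)
    d$mean_uM <- rnorm(nrow(d)) +
        ifelse(d$condition == "contingent", effect, 0)
    d
}

## Minimal NirsRecording built from explicit per-channel intensity rows.
makeRecording <- function(i760, i850, fs = 7.8125, n_trials = 4,
                          looking = NULL, montage = NULL) {
    nch <- nrow(i760)
    if (is.null(montage))
        montage <- data.frame(channel = seq_len(nch),
                              source = "S1", detector = "D1",
                              distance_mm = 22.5,
                              hemisphere = "right")
    block <- 27
    markers <- data.frame(trial = seq_len(n_trials),
                          condition = conditionOrder(ceiling(n_trials / 2))
                              [seq_len(n_trials)],
                          baseline_onset_s = (seq_len(n_trials) - 1) * block,
                          trial_onset_s = (seq_len(n_trials) - 1) * block + 12,
                          trial_end_s = seq_len(n_trials) * block)
    if (is.null(looking))
        looking <- data.frame(trial = seq_len(n_trials), frac_trial = 1,
                              frac_brush = 1)
    NirsRecording(i760, i850, montage, fs = fs, markers = markers,
                  looking = looking)
}

## Synthetic one-subject EpochSet with explicit epoch matrices.
makeEpochSet <- function(hbo_cont, hbo_noncont, fs = 7.8125,
                         hbr_cont = -hbo_cont / 3,
                         hbr_noncont = -hbo_noncont / 3, roi = "right") {
    ep <- list()
    ep[[roi]] <- list(contingent = list(HbO = hbo_cont, HbR = hbr_cont),
                      noncontingent = list(HbO = hbo_noncont,
                                           HbR = hbr_noncont))
    nv <- matrix(c(nrow(hbo_cont), nrow(hbo_noncont)), 1, 2,
                 dimnames = list(roi, c("contingent", "noncontingent")))
    new("EpochSet", epochs = ep,
        time_s = (seq_len(ncol(hbo_cont)) - 1) / fs, nValid = nv,
        rois = roi)
}
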