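constRec <- function(levels760, levels850 = levels760, n = 400, ...) {
    nch <- length(levels760)
    makeRecording(matrix(levels760, nch, n),
                  matrix(levels850, nch, n), ...)
}

test_that("looking-time rules are strict on trial, lenient on brush", {
    lk <- data.frame(trial = 1:5,
                     frac_trial = c(0.49, 1.00, 0.50, 0.51, NA),
                     frac_brush = c(1.00, 1.00, 1.00, 0.50, 1.00))
    rec <- makeRecording(matrix(0.5, 1, 400), matrix(0.5, 1, 400),
                         n_trials = 5, looking = lk)
    expect_warning(v <- filterTrialsByLooking(rec), "without looking")
    expect_equal(v, c(FALSE, TRUE, FALSE, TRUE, FALSE))

    # fewer than three valid trials in either condition excludes the subject
    conds <- rep(c("contingent", "noncontingent"), each = 5)
    expect_false(meetsTrialMinimum(c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                     rep(TRUE, 5)), conds))
    expect_true(meetsTrialMinimum(rep(TRUE, 10), conds))
    expect_false(meetsTrialMinimum(c(rep(TRUE, 5), rep(FALSE, 5)), conds))
})

test_that("channel pruning applies the voltage range and SNR rules", {
    set.seed(2)
    n <- 400
    i <- rbind(0.05 + numeric(n),                      # below range
               rep(c(0.12, 3.5), c(0.9 * n, 0.1 * n)), # SNR < 0 dB
               0.5 + rnorm(n, 0, 0.01),               # healthy
               1.6 + rnorm(n, 0, 0.01))               # above range
    rec <- makeRecording(i, i)
    expect_equal(unname(pruneChannels(rec)), c(FALSE, FALSE, TRUE, FALSE))
    # the SNR rule alone: mean 0.5, SD 0.6 -> 20 log10(.5/.6) < 0
    expect_lt(20 * log10(0.5 / 0.6), 0)
})

test_that("optical density is the negative log ratio to the channel mean", {
    n <- 300
    x <- matrix(0.4, 2, n)
    rec <- makeRecording(x, x)
    od <- intensityToOd(rec)
    expect_equal(max(abs(od$od760)), 0)

    set.seed(9)
    y <- matrix(runif(2 * n, 0.2, 0.8), 2)
    rec2 <- makeRecording(y, y)
    od2 <- intensityToOd(rec2)
    expect_equal(unname(od2$od850), -log(y / rowMeans(y)))

    y2 <- y; y2[1, 5] <- mean(y[1, ]) * exp(-1)
    od3 <- intensityToOd(makeRecording(y2, y2))
    expect_equal(unname(od3$od760[1, 5]),
                 -log(y2[1, 5] / mean(y2[1, ])))

    bad <- y; bad[2, 10] <- 0
    expect_error(intensityToOd(makeRecording(bad, bad)), "channel\\(s\\) 2")
})

test_that("motion detection flags amplitude jumps and spares clean signal", {
    fs <- 7.8125
    n <- 1024
    t <- (0:(n - 1)) / fs
    clean <- 0.005 * sin(2 * pi * 0.1 * t)
    step <- clean
    step[500:503] <- step[500:503] + 0.45      # 0.45 OD within half a second
    od <- list(od760 = rbind(clean, step), od850 = rbind(clean, step))
    fl <- detectMotion(od, fs)
    expect_false(any(fl[1, ]))
    expect_true(any(fl[2, 495:510]))

    segs <- artifactSegments(fl, fs)
    expect_true(all(segs$channel == 2))
    expect_true(any(segs$start_s < 503 / fs & segs$end_s > 500 / fs))
})

test_that("detected artifacts overlap the injected motion events", {
    rec <- simulateNirs(nirsSimConfig(seed = 12), montage = roiMontage())
    fs <- samplingRate(rec)
    gt <- groundTruth(rec)$spikes
    fl <- detectMotion(intensityToOd(rec), fs)
    n <- ncol(rec)
    hit <- mapply(function(ch, a, b) {
        any(fl[ch, max(1, floor(a * fs)):min(n, ceiling(b * fs))])
    }, gt$channel, gt$start_s, gt$end_s)
    expect_true(all(hit))
})

test_that("heart-rate check accepts cardiac pulsation, rejects noise", {
    fs <- 7.8125
    t <- (0:4095) / fs
    set.seed(3)
    cardiac <- rbind(0.003 * sin(2 * pi * 2.5 * t) + rnorm(4096, 0, 5e-4))
    expect_true(heartRateCheck(cardiac, fs))
    expect_false(heartRateCheck(rbind(rnorm(4096, 0, 0.001)), fs))
    expect_false(heartRateCheck(matrix(0, 1, 4096), fs))

    # simulated recording without a cardiac component fails everywhere
    rec0 <- simulateNirs(nirsSimConfig(seed = 4, cardiac_uM = 0),
                         montage = roiMontage())
    oc <- waveletCorrect(intensityToOd(rec0)$od850, fs)
    expect_false(any(heartRateCheck(oc, fs)))
    # ... and with it, passes everywhere
    rec1 <- simulateNirs(nirsSimConfig(seed = 4), montage = roiMontage())
    oc1 <- waveletCorrect(intensityToOd(rec1)$od850, fs)
    expect_true(all(heartRateCheck(oc1, fs)))
})

test_that("contaminated trials are rejected over the configured span", {
    mk <- data.frame(trial = 1:3, condition = c("contingent",
                                                "noncontingent",
                                                "contingent"),
                     baseline_onset_s = c(0, 27, 54),
                     trial_onset_s = c(12, 39, 66),
                     trial_end_s = c(27, 54, 81))
    segs <- data.frame(channel = 1, start_s = 28, end_s = 29) # baseline of 2
    expect_equal(rejectContaminatedTrials(segs, mk),
                 c(TRUE, FALSE, TRUE))
    expect_equal(rejectContaminatedTrials(segs, mk, span = "trial"),
                 c(TRUE, TRUE, TRUE))
    none <- data.frame(channel = integer(), start_s = numeric(),
                       end_s = numeric())
    expect_equal(rejectContaminatedTrials(none, mk), rep(TRUE, 3))
    # channel restriction
    expect_equal(rejectContaminatedTrials(segs, mk, channels = 2),
                 rep(TRUE, 3))
})

test_that("band-pass keeps the passband and removes DC and cardiac", {
    fs <- 7.8125
    t <- (0:4095) / fs
    dc <- bandpassFilter(rep(1, 4096), fs)
    expect_lt(max(abs(dc[500:3500])), 1e-6)

    keep <- sin(2 * pi * 0.1 * t)
    out <- bandpassFilter(keep, fs)
    expect_lt(abs(diff(range(out[500:3500])) / 2 - 1), 0.05)

    drop <- sin(2 * pi * 2.5 * t)
    out2 <- bandpassFilter(drop, fs)
    expect_lt(max(abs(out2[500:3500])), 0.05)

    expect_error(bandpassFilter(rnorm(100), fs = 1.5), "too low")
})

test_that("Beer-Lambert inversion is exact and scales with DPF", {
    m <- roiMontage()
    zero <- matrix(0, nrow(m), 50)
    c0 <- odToConcentration(zero, zero, m)
    expect_equal(max(abs(c0$HbO)), 0)
    expect_equal(max(abs(c0$HbR)), 0)

    set.seed(5)
    HbO <- matrix(rnorm(nrow(m) * 50, 0, 0.3), nrow(m))
    HbR <- matrix(rnorm(nrow(m) * 50, 0, 0.1), nrow(m))
    od <- concentrationToOd(HbO, HbR, m)
    back <- odToConcentration(od$od760, od$od850, m)
    expect_equal(back$HbO, HbO, tolerance = 1e-10)
    expect_equal(back$HbR, HbR, tolerance = 1e-10)

    half <- odToConcentration(od$od760, od$od850, m, dpf = 10.2)
    expect_equal(half$HbO, HbO / 2, tolerance = 1e-10)

    expect_error(odToConcentration(zero, zero, m,
                                   extinction = matrix(1, 2, 2)),
                 "singular")
})

test_that("ROI epochs are baseline-corrected and need two channels", {
    fs <- 7.8125
    n <- round(88 * fs)
    mont <- roiMontage()
    mk <- data.frame(trial = 1:3,
                     condition = c("contingent", "noncontingent",
                                   "contingent"),
                     baseline_onset_s = c(0, 27, 54),
                     trial_onset_s = c(12, 39, 66),
                     trial_end_s = c(27, 54, 81))
    conc <- list(HbO = matrix(2.5, nrow(mont), n),
                 HbR = matrix(-1, nrow(mont), n))
    es <- buildEpochs(conc, mk, rep(TRUE, 3), rep(TRUE, nrow(mont)),
                      mont, fs)
    expect_equal(max(abs(epochMatrix(es, "right", "contingent"))), 0)
    expect_equal(unname(validTrials(es)["right", ]), c(2L, 1L))
    expect_equal(length(epochTime(es)), round(18 * fs))

    # one surviving right-ROI channel: right absent, left unaffected
    keep <- mont$channel %in% c(8, 23, 24, 28, 29)
    es2 <- buildEpochs(conc, mk, rep(TRUE, 3), keep, mont, fs)
    expect_null(epochMatrix(es2, "right", "contingent"))
    expect_false(is.null(epochMatrix(es2, "left", "contingent")))
})

test_that("epoch means recover the simulated response shape", {
    cfg <- nirsSimConfig(seed = 8, cardiac_uM = 0.1, resp_uM = 0,
                         mayer_uM = 0, drift_uM = 0, white_uM = 0.01,
                         spike_rate_per_min = 0,
                         looking_beta = c(1e6, 1))
    rec <- simulateNirs(cfg, montage = roiMontage())
    pp <- preprocessNirs(rec)
    expect_true(pp$included)
    expect_true(all(pp$masks$trials))

    # reference: identical epoching applied to the noiseless ground truth
    gt <- groundTruth(rec)
    ref <- buildEpochs(list(HbO = gt$HbO, HbR = gt$HbR), trialMarkers(rec),
                       pp$masks$trials, pp$masks$channels, montage(rec),
                       samplingRate(rec))
    for (roi in c("left", "right")) {
        d_est <- mean(colMeans(epochMatrix(pp$epochs, roi, "contingent"))) -
            mean(colMeans(epochMatrix(pp$epochs, roi, "noncontingent")))
        d_ref <- mean(colMeans(epochMatrix(ref, roi, "contingent"))) -
            mean(colMeans(epochMatrix(ref, roi, "noncontingent")))
        expect_lt(abs(d_est - d_ref), 0.05)
        expect_lt(d_est, 0)   # noncontingent amplitude exceeds contingent
    }
})

test_that("the preprocessing manifest records stage order and decisions", {
    rec <- simulateNirs(nirsSimConfig(seed = 2), montage = roiMontage())
    pp1 <- preprocessNirs(rec)
    pp2 <- preprocessNirs(rec)
    expect_identical(pp1$masks, pp2$masks)   # exclusion is deterministic
    expect_equal(pp1$manifest$stages[1], "looking_filter")
    expect_equal(pp1$manifest$stages[4], "motion_detect")
    expect_equal(tail(pp1$manifest$stages, 1), "roi_epochs")
    expect_equal(pp1$manifest$parameters$dpf, 5.1)
    expect_type(pp1$manifest$exclusions$subject_included, "logical")
})
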