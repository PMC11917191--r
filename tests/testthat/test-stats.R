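fsmatch <- 7.8125

test_that("time-bin averaging: constants, ramps, HRF peak location", {
    n <- round(18 * fsmatch)
    const <- makeEpochSet(matrix(0.7, 3, n), matrix(0.7, 2, n))
    b <- binEpochs(const)
    expect_equal(nrow(b), 12)
    expect_true(all(abs(b$mean_uM - 0.7) < 1e-12))

    # linear ramp 0 -> 18 s: bin means are the 3-s interval midpoints
    ramp <- matrix(seq(0, 18, length.out = n + 1)[seq_len(n)], 1, n,
                   byrow = TRUE)
    br <- binEpochs(makeEpochSet(ramp, ramp))
    mids <- c(1.5, 4.5, 7.5, 10.5, 13.5, 16.5)
    expect_equal(br$mean_uM[br$condition == "contingent"], mids,
                 tolerance = 0.07)

    # simulated response peaking ~6 s lands in bin 2 or 3
    tt <- (seq_len(n) - 1) / fsmatch
    resp <- doubleGammaHrf(tt, peak_s = 6)
    bh <- binEpochs(makeEpochSet(matrix(resp, 1, byrow = TRUE),
                                 matrix(0, 1, n)))
    peak_bin <- bh$bin[bh$condition == "contingent"][
        which.max(bh$mean_uM[bh$condition == "contingent"])]
    expect_true(peak_bin %in% c(2, 3))

    short <- makeEpochSet(matrix(1, 1, 20), matrix(1, 1, 20))
    expect_error(binEpochs(short), "epoch_s")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
    for (s in 1:5) {
        d <- nullBins(s, effect = 0.4)
        a <- rmAnova(d)
        o <- handRmAnova(d)
        expect_equal(a$F[a$effect == "condition"], o$F_condition,
                     tolerance = 1e-10)
        expect_equal(a$F[a$effect == "bin"], o$F_bin, tolerance = 1e-10)
        expect_equal(a$F[a$effect == "condition:bin"], o$F_inter,
                     tolerance = 1e-10)
    }
    d <- nullBins(1)
    a <- rmAnova(d)
    expect_equal(a$df1, c(1, 5, 5))
    expect_equal(a$df2, c(9, 45, 45))
})

mirrorConditions <- function(d) {
    src <- d[d$condition == "contingent", ]
    d$mean_uM <- src$mean_uM[match(interaction(d$subject, d$bin),
                                   interaction(src$subject, src$bin))]
    d
}

test_that("identical conditions give a zero condition effect", {
    d <- mirrorConditions(nullBins(3))
    # the exact sums of squares vanish; both routes return 0/0 noise there
    o <- handRmAnova(d)$F_condition
    expect_true(is.nan(o) || abs(o) < 1e-6)
    a <- rmAnova(d)
    expect_lt(a$F[a$effect == "condition"], 0.01)
})

test_that("with one bin the ANOVA collapses to the paired t-test, F = t^2", {
    set.seed(6)
    ns <- 12
    d <- expand.grid(subject = paste0("s", seq_len(ns)), roi = "right",
                     chromophore = "HbO",
                     condition = c("contingent", "noncontingent"), bin = 1,
                     stringsAsFactors = FALSE)
    d$mean_uM <- rnorm(nrow(d)) + ifelse(d$condition == "contingent",
                                         0.5, 0)
    a <- rmAnova(d)
    wide <- matrix(d$mean_uM, ns)
    tt <- t.test(wide[, 1], wide[, 2], paired = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("per-bin post-hoc t-tests localize an injected effect", {
    d <- nullBins(9, ns = 40)
    d$mean_uM <- d$mean_uM +
        ifelse(d$condition == "contingent" & d$bin %in% 2:4, 1.5, 0)
    ph <- posthocBins(d)
    expect_true(all(ph$p[ph$bin %in% 2:4] < 0.01))
    expect_equal(ph$mean_diff_uM[ph$bin == 3], 1.5, tolerance = 0.5)
    # identical conditions: degenerate zero-variance case signaled
    d2 <- mirrorConditions(nullBins(2))
    suppressWarnings(expect_warning(ph2 <- posthocBins(d2),
                                    "zero-variance"))
    expect_true(all(ph2$p == 1))
})

test_that("difference scores follow the sign convention and the bin means", {
    n <- round(18 * fsmatch)
    es <- makeEpochSet(matrix(0, 2, n), matrix(0.15, 2, n))
    ds <- diffScores(es)
    expect_equal(ds$diff_uM, -0.15)

    same <- makeEpochSet(matrix(0.4, 2, n), matrix(0.4, 2, n))
    expect_equal(diffScores(same)$diff_uM, 0)

    # internal consistency: diff score equals the difference of bin means
    set.seed(10)
    eO <- matrix(rnorm(3 * n), 3); eN <- matrix(rnorm(2 * n), 2)
    es2 <- makeEpochSet(eO, eN)
    b <- binEpochs(es2)
    d_bins <- mean(b$mean_uM[b$condition == "contingent"]) -
        mean(b$mean_uM[b$condition == "noncontingent"])
    # bins hold unequal sample counts at this sampling rate, so the
    # equality is approximate
    expect_equal(diffScores(es2)$diff_uM, d_bins, tolerance = 0.05)
})

fakeRows <- function(n, beta = c(0, 0, 0, 0, 0), sd = 0.1, seed = 1,
                     intercept = 0) {
    set.seed(seed)
    d <- data.frame(subject = paste0("s", seq_len(n)),
                    all_touch = runif(n), affective_touch = runif(n),
                    sensitivity = sample(1:7, n, TRUE),
                    contingency = rnorm(n, 0.2, 0.1),
                    age_days = round(rnorm(n, 180, 10)))
    d$diff_right <- intercept + as.matrix(d[, 2:6]) %*% beta +
        rnorm(n, 0, sd)
    d
}

test_that("OLS regression equals the normal-equations solution", {
    d <- fakeRows(40, beta = c(0.4, -0.2, 0.05, 0.3, 0.001), seed = 4)
    fr <- fitRegression(d, "diff_right")
    X <- cbind(1, as.matrix(d[, c("all_touch", "affective_touch",
                                  "sensitivity", "contingency",
                                  "age_days")]))
    beta_hat <- solve(t(X) %*% X, t(X) %*% d$diff_right)
    expect_equal(fr$coefficients$estimate, as.numeric(beta_hat),
                 tolerance = 1e-10)
    expect_equal(fr$n, 40)
    expect_equal(fr$df, c(5, 34))
})

test_that("regression recovers known coefficients and degenerates sanely", {
    d <- fakeRows(200, beta = c(0.5, 0, 0.08, 0, 0), sd = 0.05, seed = 7)
    fr <- fitRegression(d, "diff_right")
    co <- fr$coefficients
    for (term in c("all_touch", "sensitivity")) {
        i <- which(co$term == term)
        truth <- c(all_touch = 0.5, sensitivity = 0.08)[term]
        expect_lt(abs(co$estimate[i] - truth), 3 * co$se[i])
    }

    dc <- fakeRows(30, seed = 2); dc$diff_right <- 1.25
    frc <- fitRegression(dc, "diff_right")
    expect_equal(frc$coefficients$estimate[1], 1.25, tolerance = 1e-8)
    expect_true(all(abs(frc$coefficients$estimate[-1]) < 1e-8))

    dd <- fakeRows(30, seed = 3); dd$affective_touch <- dd$all_touch
    expect_error(fitRegression(dd, "diff_right"), "collinear")
    expect_error(fitRegression(fakeRows(5), "diff_right"), "fewer than")
})

test_that("condition-wise regressions reuse the same machinery", {
    d <- fakeRows(30, seed = 5)
    act <- rbind(data.frame(subject = d$subject, roi = "right",
                            condition = "contingent", mean_uM = 0.3),
                 data.frame(subject = d$subject, roi = "right",
                            condition = "noncontingent", mean_uM = 0.3))
    set.seed(6); act$mean_uM <- act$mean_uM + rep(rnorm(30, 0, 0.1), 2)
    pr <- posthocConditionRegressions(d, act)
    expect_equal(pr$contingent$coefficients$estimate,
                 pr$noncontingent$coefficients$estimate)
})
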