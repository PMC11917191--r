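test_that("latency-window rules: first response, onset tie, vocal offset", {
    gz <- GazeEpisodes(0, 20000)

    # two maternal responses inside one window: only the earliest pairs
    inf <- EventStream("infant", "smile", onset_ms = 5000, offset_ms = 5400)
    mom <- EventStream("mother", c("smile", "smile"),
                       onset_ms = c(5300, 5800), offset_ms = c(5500, 6000))
    p <- detectContingent(mom, inf, gz)
    expect_equal(nrow(p), 1)
    expect_equal(p$mother_onset_ms, 5300)

    # simultaneous maternal onset is not contingent
    mom2 <- EventStream("mother", "smile", onset_ms = 5000,
                        offset_ms = 5400)
    expect_equal(nrow(detectContingent(mom2, inf, gz)), 0)

    # vocal infant events extend the window to offset + W
    infv <- EventStream("infant", "vocal", onset_ms = 4000,
                        offset_ms = 6000)
    momv <- EventStream("mother", "smile", onset_ms = 6900,
                        offset_ms = 7100)
    pv <- detectContingent(momv, infv, gz)
    expect_equal(nrow(pv), 1)
    # ... but a facial event with the same times would not reach 6900
    inff <- EventStream("infant", "smile", onset_ms = 4000,
                        offset_ms = 6000)
    expect_equal(nrow(detectContingent(momv, inff, gz)), 0)

    # window upper bound is inclusive at exactly onset + W
    mom3 <- EventStream("mother", "smile", onset_ms = 6000,
                        offset_ms = 6200)
    expect_equal(nrow(detectContingent(mom3, inf, gz)), 1)
})

test_that("simultaneous infant behaviors each get their own pairing", {
    gz <- GazeEpisodes(0, 20000)
    inf <- EventStream("infant", c("smile", "vocal"),
                       modality = c("facial", "vocal"),
                       onset_ms = c(5000, 5000), offset_ms = c(5300, 5600))
    mom <- EventStream("mother", "smile", onset_ms = 5400,
                       offset_ms = 5600)
    p <- detectContingent(mom, inf, gz)
    expect_equal(nrow(p), 2)
    expect_equal(p$mother_onset_ms, c(5400, 5400))
})

test_that("events outside mutual gaze are ignored", {
    gz <- GazeEpisodes(10000, 20000)
    inf <- EventStream("infant", c("smile", "smile"),
                       onset_ms = c(5000, 12000), offset_ms = c(5200, 12200))
    mom <- EventStream("mother", c("smile", "smile"),
                       onset_ms = c(5300, 12300), offset_ms = c(5500, 12500))
    p <- detectContingent(mom, inf, gz)
    expect_equal(nrow(p), 1)
    expect_equal(p$infant_onset_ms, 12000)
})

test_that("responsiveness index evaluates the chance-corrected formula", {
    # C/I - (1 - exp(-M*W/D)); direct high-precision evaluation
    expect_equal(responsivenessIndex(5, 10, 20, 240000, 1000),
                 0.5 - (1 - exp(-20 * 1000 / 240000)), tolerance = 1e-12)
    expect_equal(round(responsivenessIndex(5, 10, 20, 240000), 3), 0.420)
    # both terms vanish
    expect_equal(responsivenessIndex(0, 5, 0, 240000), 0)
    # undefined cases
    expect_error(responsivenessIndex(0, 0, 5, 240000), "I = 0")
    expect_error(responsivenessIndex(0, 5, 5, 0), "D = 0")
})

test_that("index is strictly monotone in C with I, M, D fixed", {
    vals <- vapply(0:10, responsivenessIndex, numeric(1),
                   I = 10, M = 20, D_ms = 240000)
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals <= (0:10) / 10))
})

test_that("pipeline clips the warm-up and analysis window", {
    # events only in the first 60 s never reach the analysis
    inf <- EventStream("infant", "smile", onset_ms = 30000,
                       offset_ms = 30200)
    mom <- EventStream("mother", "smile", onset_ms = 30300,
                       offset_ms = 30500)
    gz <- GazeEpisodes(0, 300000)
    expect_error(contingencyPipeline(mom, inf, gz), "no infant behaviors")

    # identical analysis with or without out-of-window extras
    inf2 <- EventStream("infant", c("smile", "smile", "smile"),
                        onset_ms = c(30000, 100000, 299500),
                        offset_ms = c(30200, 100200, 299700))
    mom2 <- EventStream("mother", c("smile", "smile"),
                        onset_ms = c(100300, 301000),
                        offset_ms = c(100500, 301200))
    inf3 <- EventStream("infant", "smile", onset_ms = 100000,
                        offset_ms = 100200)
    mom3 <- EventStream("mother", "smile", onset_ms = 100300,
                        offset_ms = 100500)
    s2 <- contingencyPipeline(mom2, inf2, gz)
    s3 <- contingencyPipeline(mom3, inf3, gz)
    expect_equal(s2@C, s3@C)
    expect_equal(s2@M, s3@M)
    # the 299500 event is inside [60, 300) s and counts toward I
    expect_equal(s2@I, s3@I + 1)
    expect_equal(s2@D_ms, s3@D_ms)

    expect_warning(contingencyPipeline(mom3, inf3, gz, session_ms = 200000),
                   "truncated")
    expect_error(contingencyPipeline(mom3, inf3, GazeEpisodes(0, 50000)),
                 "no mutual gaze")
})

test_that("a fully responsive simulated mother answers every infant event", {
    d <- simulateDyad(dyadSimConfig(seed = 4, response_prob = 1,
                                    maternal_base_rate = 0,
                                    response_latency_ms = c(500, 500),
                                    gaze_coverage = 1))
    expect_equal(sort(events(d$mother)$onset_ms),
                 sort(events(d$infant)$onset_ms + 500))
    p <- detectContingent(d$mother, d$infant, d$gaze)
    expect_equal(nrow(p), length(d$infant))
})

test_that("detection matches the brute-force window scan on random sessions", {
    for (s in 1:120) {
        ses <- randomSession(s)
        p <- detectContingent(ses$mother, ses$infant, ses$gaze)
        o <- bruteforceContingent(ses$mother, ses$infant, ses$gaze)
        expect_equal(nrow(p), if (is.null(o)) 0 else nrow(o),
                     info = paste("seed", s))
        if (!is.null(o) && nrow(o)) {
            expect_equal(p$infant_onset_ms, o[, 3], info = paste("seed", s))
            expect_equal(p$mother_onset_ms, o[, 4], info = paste("seed", s))
        }
    }
})

test_that("unsorted streams are rejected and empty infant streams are not", {
    gz <- GazeEpisodes(0, 10000)
    ok <- EventStream("mother", "smile", onset_ms = 100, offset_ms = 200)
    expect_error(new("EventStream", actor = "infant",
                     events = data.frame(code = c("smile", "smile"),
                                         modality = "facial",
                                         onset_ms = c(5000, 1000),
                                         offset_ms = c(5200, 1200))),
                 "sorted")
    empty <- EventStream("infant")
    expect_equal(nrow(detectContingent(ok, empty, gz)), 0)
})
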