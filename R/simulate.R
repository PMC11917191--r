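## Synthetic dyads: behavioral streams, touch sequences and block-design
## fNIRS recordings with known ground truth.

#' Configuration for a simulated dyadic interaction
#'
#' Infant behaviors arrive as a homogeneous Poisson process restricted to
#' mutual-gaze episodes; each independently triggers a maternal response
#' with probability \code{response_prob} at a latency drawn uniformly from
#' \code{response_latency_ms}; spontaneous maternal behaviors arrive at
#' \code{maternal_base_rate} within gaze.
#'
#' @slot duration_ms session length (default 240000 ms, the coded 4 min).
#' @slot infant_rate infant behaviors per second of mutual gaze.
#' @slot maternal_base_rate spontaneous maternal behaviors per second.
#' @slot response_prob probability of a maternal response per infant behavior.
#' @slot response_latency_ms \code{c(low, high)} of the uniform latency (ms).
#' @slot gaze_coverage fraction of the session spent in mutual gaze.
#' @slot p_vocal probability an event is vocal (vs. facial).
#' @slot event_duration_ms \code{c(low, high)} uniform event duration (ms).
#' @slot seed RNG seed.
#' @export
setClass("DyadSimConfig",
         representation(duration_ms = "numeric", infant_rate = "numeric",
                        maternal_base_rate = "numeric",
                        response_prob = "numeric",
                        response_latency_ms = "numeric",
                        gaze_coverage = "numeric", p_vocal = "numeric",
                        event_duration_ms = "numeric", seed = "numeric"),
         prototype(duration_ms = 240000, infant_rate = 0.4,
                   maternal_base_rate = 0.3, response_prob = 0.6,
                   response_latency_ms = c(200, 900), gaze_coverage = 0.8,
                   p_vocal = 0.3, event_duration_ms = c(200, 800), seed = 1))

setValidity("DyadSimConfig", function(object) {
    msg <- character()
    if (object@duration_ms <= 0) msg <- c(msg, "duration_ms must be > 0")
    if (object@infant_rate < 0 || object@maternal_base_rate < 0)
        msg <- c(msg, "rates must be >= 0")
    if (object@response_prob < 0 || object@response_prob > 1)
        msg <- c(msg, "response_prob must lie in [0, 1]")
    if (object@gaze_coverage < 0 || object@gaze_coverage > 1)
        msg <- c(msg, "gaze_coverage must lie in [0, 1]")
    if (object@p_vocal < 0 || object@p_vocal > 1)
        msg <- c(msg, "p_vocal must lie in [0, 1]")
    if (length(object@response_latency_ms) != 2 ||
        diff(object@response_latency_ms) < 0 ||
        any(object@response_latency_ms < 0))
        msg <- c(msg, "response_latency_ms must be c(low, high), low <= high")
    if (length(msg)) msg else TRUE
})

#' @rdname DyadSimConfig-class
#' @param ... slot values overriding the defaults.
#' @return A \code{DyadSimConfig}.
#' @export
dyadSimConfig <- function(...) new("DyadSimConfig", ...)

sampleCode <- function(n, p_vocal) {
    vocal <- stats::runif(n) < p_vocal
    code <- ifelse(vocal, "vocal",
                   sample(c("smile", "eyebrow", "tongue"), n, replace = TRUE))
    data.frame(code = code,
               modality = ifelse(vocal, "vocal", "facial"))
}

simulateGazeEpisodes <- function(duration_ms, coverage,
                                 mean_episode_ms = 15000) {
    if (coverage >= 1)
        return(GazeEpisodes(0, duration_ms))
    if (coverage <= 0)
        return(GazeEpisodes(numeric(), numeric()))
    mean_gap_ms <- mean_episode_ms * (1 - coverage) / coverage
    t <- stats::rexp(1, 1 / mean_gap_ms)
    starts <- ends <- numeric()
    while (t < duration_ms) {
        len <- stats::rexp(1, 1 / mean_episode_ms)
        starts <- c(starts, t)
        ends <- c(ends, min(t + len, duration_ms))
        t <- t + len + stats::rexp(1, 1 / mean_gap_ms)
    }
    keep <- ends > starts
    GazeEpisodes(starts[keep], ends[keep])
}

poissonOnsets <- function(gaze, rate_per_s) {
    ep <- episodes(gaze)
    onsets <- numeric()
    for (i in seq_len(nrow(ep))) {
        len <- ep$end_ms[i] - ep$start_ms[i]
        n <- stats::rpois(1, rate_per_s * len / 1000)
        if (n) onsets <- c(onsets, ep$start_ms[i] + sort(stats::runif(n)) * len)
    }
    onsets
}

#' Simulate one dyadic interaction
#'
#' @param cfg a \linkS4class{DyadSimConfig}.
#' @return list with \code{mother}, \code{infant}
#'   (\linkS4class{EventStream}s), \code{gaze}
#'   (\linkS4class{GazeEpisodes}) and \code{truth} (\code{data.frame} of
#'   infant events and whether/when a response was generated).
#' @examples
#' d <- simulateDyad(dyadSimConfig(seed = 7))
#' length(d$infant)
#' @export
simulateDyad <- function(cfg = dyadSimConfig()) {
    validObject(cfg)
    set.seed(cfg@seed)
    gaze <- simulateGazeEpisodes(cfg@duration_ms, cfg@gaze_coverage)
    inf_on <- poissonOnsets(gaze, cfg@infant_rate)
    nI <- length(inf_on)
    inf_meta <- sampleCode(nI, cfg@p_vocal)
    inf_dur <- stats::runif(nI, cfg@event_duration_ms[1],
                            cfg@event_duration_ms[2])
    responded <- stats::runif(nI) < cfg@response_prob
    latency <- stats::runif(nI, cfg@response_latency_ms[1],
                            cfg@response_latency_ms[2])
    resp_on <- inf_on[responded] + latency[responded]
    base_on <- poissonOnsets(gaze, cfg@maternal_base_rate)
    mom_on <- c(resp_on, base_on)
    nM <- length(mom_on)
    mom_meta <- sampleCode(nM, cfg@p_vocal)
    mom_dur <- stats::runif(nM, cfg@event_duration_ms[1],
                            cfg@event_duration_ms[2])
    mother <- EventStream("mother", code = mom_meta$code,
                          modality = mom_meta$modality, onset_ms = mom_on,
                          offset_ms = mom_on + mom_dur)
    infant <- EventStream("infant", code = inf_meta$code,
                          modality = inf_meta$modality, onset_ms = inf_on,
                          offset_ms = inf_on + inf_dur)
    truth <- data.frame(infant_onset_ms = inf_on, responded = responded,
                        response_onset_ms = ifelse(responded,
                                                   inf_on + latency, NA))
    list(mother = mother, infant = infant, gaze = gaze, truth = truth)
}

#' Simulate a per-segment touch sequence
#'
#' Independent draw per 2-s segment from a categorical distribution over the
#' seven touch categories plus \code{"none"}.
#'
#' @param n_segments number of 2-s segments.
#' @param category_probs named probability vector over
#'   \code{\link{touchCodes}} (missing names get probability 0); must sum
#'   to 1 and be non-negative.
#' @param seed RNG seed.
#' @param segment_s segment length in seconds.
#' @return A \linkS4class{TouchRecord}.
#' @export
simulateTouch <- function(n_segments, category_probs, seed = 1,
                          segment_s = 2) {
    p <- stats::setNames(numeric(length(touchCodes)), touchCodes)
    bad <- setdiff(names(category_probs), touchCodes)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    p[names(category_probs)] <- category_probs
    if (any(p < 0)) stop("negative category probabilities")
    if (abs(sum(p) - 1) > 1e-8) stop("category probabilities must sum to 1")
    set.seed(seed)
    TouchRecord(sample(touchCodes, n_segments, replace = TRUE, prob = p),
                segment_s = segment_s)
}

## ---------------------------------------------------------------------------
## fNIRS simulation
## ---------------------------------------------------------------------------

#' Default 30-channel bilateral temporal montage
#'
#' Thirty channels (8 sources x 16 detectors, bilateral temporal placement),
#' channels 1-15 on the right hemisphere and 16-30 on the left, with
#' source-detector distances inside the 20-25 mm infant separation range.
#'
#' @param distance_mm source-detector distance, recycled per channel.
#' @return montage \code{data.frame}.
#' @export
defaultMontage <- function(distance_mm = 22.5) {
    data.frame(channel = 1:30,
               source = paste0("S", ((0:29) %/% 4) + 1),
               detector = paste0("D", ((0:29) %% 16) + 1),
               distance_mm = rep_len(distance_mm, 30),
               hemisphere = rep(c("right", "left"), each = 15))
}

#' Bilateral pSTS region-of-interest definition
#'
#' Channels over the posterior superior temporal sulcus: right = channels
#' 8, 9, 13, 14; left = channels 23, 24, 28, 29. An ROI contributes data only
#' when at least \code{min_channels} of its channels survive pruning.
#'
#' @return list with \code{right}, \code{left} channel vectors and
#'   \code{min_channels}.
#' @export
roiDefinition <- function() {
    list(right = c(8, 9, 13, 14), left = c(23, 24, 28, 29), min_channels = 2)
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t time in seconds (>= 0).
#' @param peak_s time to peak of the positive lobe (default 5 s).
#' @param undershoot_s time to peak of the undershoot (default 15 s).
#' @param ratio undershoot amplitude relative to the peak (default 1/6).
#' @return HRF values, peak normalized to 1.
#' @export
doubleGammaHrf <- function(t, peak_s = 5, undershoot_s = 15, ratio = 1/6) {
    a1 <- peak_s + 1; a2 <- undershoot_s + 1   # gamma shape with rate 1
    h <- stats::dgamma(t, shape = a1, rate = 1) -
        ratio * stats::dgamma(t, shape = a2, rate = 1)
    h / max(stats::dgamma(peak_s, shape = a1, rate = 1))
}

#' Configuration for a simulated fNIRS recording
#'
#' Block design: each trial of 15 s is preceded by a 12 s baseline; the
#' condition order tiles the ABBABAAB pattern starting with the contingent
#' condition (A). Hemodynamic responses are condition- and ROI-specific
#' double-gamma responses; physiological noise comprises cardiac (~2.5 Hz for
#' an infant), respiratory (~0.6 Hz), Mayer-wave (~0.1 Hz), slow-drift and
#' white components; motion spikes are injected in OD space.
#'
#' @slot n_trials_per_condition trials per condition (default 10).
#' @slot baseline_s,trial_s block timing in seconds (12 / 15).
#' @slot fs sampling rate in Hz (default 7.8125).
#' @slot amplitude_uM 2x2 matrix of HbO peak amplitudes (uMol), rows
#'   \code{contingent}/\code{noncontingent}, columns \code{left}/\code{right}.
#' @slot hbr_ratio HbR amplitude relative to HbO (default -1/3).
#' @slot hrf_peak_s,hrf_undershoot_s,hrf_ratio double-gamma parameters.
#' @slot cardiac_hz,cardiac_uM,resp_hz,resp_uM,mayer_hz,mayer_uM sinusoidal
#'   physiological components (frequency Hz, HbO amplitude uMol).
#' @slot drift_uM low-frequency drift amplitude (uMol).
#' @slot white_uM white-noise SD (uMol).
#' @slot spike_rate_per_min,spike_amp_od,spike_dur_s motion-event process:
#'   recording-wide movement events per minute, each hitting every channel
#'   with a per-channel amplitude drawn uniformly from \code{spike_amp_od}
#'   (random sign) and uniform duration \code{spike_dur_s}.
#' @slot looking_beta \code{c(shape1, shape2)} of the Beta distribution of
#'   per-trial looking proportions.
#' @slot intensity_v mean detector intensity (V).
#' @slot dpf differential pathlength factor used by the forward model.
#' @slot seed RNG seed.
#' @export
setClass("NirsSimConfig",
         representation(n_trials_per_condition = "numeric",
                        baseline_s = "numeric", trial_s = "numeric",
                        fs = "numeric", amplitude_uM = "matrix",
                        hbr_ratio = "numeric", hrf_peak_s = "numeric",
                        hrf_undershoot_s = "numeric", hrf_ratio = "numeric",
                        cardiac_hz = "numeric", cardiac_uM = "numeric",
                        resp_hz = "numeric", resp_uM = "numeric",
                        mayer_hz = "numeric", mayer_uM = "numeric",
                        drift_uM = "numeric", white_uM = "numeric",
                        spike_rate_per_min = "numeric",
                        spike_amp_od = "numeric", spike_dur_s = "numeric",
                        looking_beta = "numeric", intensity_v = "numeric",
                        dpf = "numeric", seed = "numeric"),
         prototype(n_trials_per_condition = 10, baseline_s = 12,
                   trial_s = 15, fs = 7.8125,
                   amplitude_uM = matrix(c(0.30, 0.30, 0.39, 0.45), 2, 2,
                                         byrow = TRUE,
                                         dimnames = list(
                                             c("contingent", "noncontingent"),
                                             c("left", "right"))),
                   hbr_ratio = -1/3, hrf_peak_s = 5, hrf_undershoot_s = 15,
                   hrf_ratio = 1/6, cardiac_hz = 2.5, cardiac_uM = 0.15,
                   resp_hz = 0.6, resp_uM = 0.10, mayer_hz = 0.1,
                   mayer_uM = 0.10, drift_uM = 0.3, white_uM = 0.05,
                   spike_rate_per_min = 0.5, spike_amp_od = c(0.5, 1.5),
                   spike_dur_s = c(0.1, 0.4), looking_beta = c(4, 1.5),
                   intensity_v = 0.5, dpf = 5.1, seed = 1))

setValidity("NirsSimConfig", function(object) {
    msg <- character()
    if (object@n_trials_per_condition < 1 ||
        object@n_trials_per_condition > 10)
        msg <- c(msg, "n_trials_per_condition must lie in 1..10")
    if (!all(is.finite(object@amplitude_uM)))
        msg <- c(msg, "amplitudes must be finite")
    if (object@fs <= 2 * object@cardiac_hz)
        msg <- c(msg, "sampling rate must exceed twice the cardiac frequency")
    if (length(msg)) msg else TRUE
})

#' @rdname NirsSimConfig-class
#' @param ... slot values overriding the defaults.
#' @return A \code{NirsSimConfig}.
#' @export
nirsSimConfig <- function(...) new("NirsSimConfig", ...)

#' Condition order of the block design
#'
#' Tiles the ABBABAAB pattern (A = contingent) until each condition has the
#' requested number of trials.
#'
#' @param n_per_condition trials per condition.
#' @return character vector of conditions.
#' @export
conditionOrder <- function(n_per_condition) {
    pat <- c("A", "B", "B", "A", "B", "A", "A", "B")
    seqc <- rep(pat, length.out = 2 * n_per_condition)
    ifelse(seqc == "A", "contingent", "noncontingent")
}

#' Simulate a block-design fNIRS recording
#'
#' Builds ground-truth HbO/HbR concentration traces (condition-specific
#' double-gamma responses convolved with the trial boxcars, restricted to
#' ROI channels), adds physiological noise in concentration space,
#' forward-projects to dual-wavelength intensity through the same modified
#' Beer-Lambert model the preprocessing inverts, and injects motion spikes
#' in OD space. The noiseless hemodynamic ground truth, the injected spike
#' windows and the configuration are attached for recovery tests.
#'
#' @param cfg a \linkS4class{NirsSimConfig}.
#' @param montage montage \code{data.frame} (default
#'   \code{\link{defaultMontage}()}); only channels listed in
#'   \code{\link{roiDefinition}} carry a hemodynamic response.
#' @return A \linkS4class{NirsRecording}.
#' @export
simulateNirs <- function(cfg = nirsSimConfig(), montage = defaultMontage()) {
    validObject(cfg)
    set.seed(cfg@seed)
    conds <- conditionOrder(cfg@n_trials_per_condition)
    ntr <- length(conds)
    block_s <- cfg@baseline_s + cfg@trial_s
    total_s <- ntr * block_s + 20          # tail so the last HRF resolves
    n <- ceiling(total_s * cfg@fs)
    tt <- (seq_len(n) - 1) / cfg@fs
    markers <- data.frame(trial = seq_len(ntr), condition = conds,
                          baseline_onset_s = (seq_len(ntr) - 1) * block_s,
                          trial_onset_s = (seq_len(ntr) - 1) * block_s +
                              cfg@baseline_s,
                          trial_end_s = seq_len(ntr) * block_s)

    ## condition regressors, peak-normalized so amplitude_uM is the per-trial
    ## peak response
    kern_t <- seq(0, 32, by = 1 / cfg@fs)
    h <- doubleGammaHrf(kern_t, cfg@hrf_peak_s, cfg@hrf_undershoot_s,
                        cfg@hrf_ratio)
    boxcar1 <- rep(1, round(cfg@trial_s * cfg@fs))
    single <- stats::convolve(c(boxcar1, numeric(length(h))), rev(h),
                              type = "open") / cfg@fs
    scale <- max(single)
    regr <- sapply(c("contingent", "noncontingent"), function(cond) {
        box <- numeric(n)
        for (k in which(conds == cond)) {
            i0 <- floor(markers$trial_onset_s[k] * cfg@fs) + 1
            i1 <- min(n, floor(markers$trial_end_s[k] * cfg@fs))
            box[i0:i1] <- 1
        }
        r <- stats::convolve(c(box, numeric(length(h))), rev(h),
                             type = "open")[seq_len(n)] / cfg@fs
        r / scale
    })

    nch <- nrow(montage)
    rois <- roiDefinition()
    roi_of <- rep(NA_character_, nch)
    roi_of[montage$channel %in% rois$right] <- "right"
    roi_of[montage$channel %in% rois$left] <- "left"

    HbO_true <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
        if (is.na(roi_of[ch])) next
        HbO_true[ch, ] <-
            cfg@amplitude_uM["contingent", roi_of[ch]] * regr[, "contingent"] +
            cfg@amplitude_uM["noncontingent", roi_of[ch]] *
                regr[, "noncontingent"]
    }
    HbR_true <- cfg@hbr_ratio * HbO_true

    ## physiological noise (concentration space, per channel random phases)
    noiseChan <- function() {
        ph <- stats::runif(3, 0, 2 * pi)
        s <- cfg@cardiac_uM * sin(2 * pi * cfg@cardiac_hz * tt + ph[1]) +
            cfg@resp_uM * sin(2 * pi * cfg@resp_hz * tt + ph[2]) +
            cfg@mayer_uM * sin(2 * pi * cfg@mayer_hz * tt + ph[3])
        if (cfg@drift_uM > 0) {
            fd <- stats::runif(1, 0.002, 0.008)
            s <- s + cfg@drift_uM * sin(2 * pi * fd * tt +
                                        stats::runif(1, 0, 2 * pi))
        }
        if (cfg@white_uM > 0) s <- s + stats::rnorm(n, 0, cfg@white_uM)
        s
    }
    HbO <- HbO_true
    HbR <- HbR_true
    for (ch in seq_len(nch)) {
        nz <- noiseChan()
        HbO[ch, ] <- HbO[ch, ] + nz
        HbR[ch, ] <- HbR[ch, ] - 0.3 * nz + if (cfg@white_uM > 0)
            stats::rnorm(n, 0, cfg@white_uM / 2) else 0
    }

    od <- concentrationToOd(HbO, HbR, montage, dpf = cfg@dpf)

    ## motion events in OD space: infant movements hit the whole montage at
    ## once, with a per-channel amplitude, identically at both wavelengths
    spikes <- data.frame(event = integer(), channel = integer(),
                         start_s = numeric(), end_s = numeric(),
                         amp_od = numeric())
    if (cfg@spike_rate_per_min > 0) {
        k <- stats::rpois(1, cfg@spike_rate_per_min * total_s / 60)
        if (k) {
            st <- sort(stats::runif(k, 0, total_s - max(cfg@spike_dur_s)))
            du <- stats::runif(k, cfg@spike_dur_s[1], cfg@spike_dur_s[2])
            for (s in seq_len(k)) {
                ## an event always affects at least the nearest sample, even
                ## when shorter than one sample period
                i0 <- min(n, floor(st[s] * cfg@fs) + 1)
                i1 <- min(n, max(i0, ceiling((st[s] + du[s]) * cfg@fs)))
                idx <- i0:i1
                am <- stats::runif(nch, cfg@spike_amp_od[1],
                                   cfg@spike_amp_od[2]) *
                    sample(c(-1, 1), nch, replace = TRUE)
                od$od760[, idx] <- od$od760[, idx] + am
                od$od850[, idx] <- od$od850[, idx] + am
                spikes <- rbind(spikes, data.frame(
                    event = s, channel = seq_len(nch), start_s = st[s],
                    end_s = st[s] + du[s], amp_od = am))
            }
        }
    }

    I760 <- cfg@intensity_v * exp(-od$od760)
    I850 <- cfg@intensity_v * exp(-od$od850)

    looking <- data.frame(trial = seq_len(ntr),
                          frac_trial = stats::rbeta(ntr, cfg@looking_beta[1],
                                                    cfg@looking_beta[2]),
                          frac_brush = stats::rbeta(ntr, cfg@looking_beta[1],
                                                    cfg@looking_beta[2]))
    brush <- do.call(rbind, lapply(seq_len(ntr), function(k) {
        ns <- sample(2:3, 1)
        st <- sort(stats::runif(ns, markers$trial_onset_s[k],
                                markers$trial_end_s[k] - 1))
        data.frame(trial = k, start_s = st, end_s = st + 0.7)
    }))

    NirsRecording(I760, I850, montage, fs = cfg@fs, markers = markers,
                  looking = looking, brush = brush,
                  ground_truth = list(HbO = HbO_true, HbR = HbR_true,
                                      HbO_noisy = HbO, HbR_noisy = HbR,
                                      spikes = spikes, config = cfg))
}
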