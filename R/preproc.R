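## fNIRS preprocessing: raw intensity -> baseline-corrected HbO/HbR ROI
## epochs, applying the stated exclusion and correction rules in order:
## looking filter -> channel pruning -> OD -> motion detection -> wavelet
## correction -> heart-rate check -> residual check / trial rejection ->
## band-pass -> Beer-Lambert -> ROI epochs.

#' Trial validity from infant looking behavior
#'
#' A trial is valid only if the infant looked at the screen more than 50\%
#' of the trial time and at least 50\% of the time while the brushstrokes
#' were applied. Trials without looking data are invalid (with a warning).
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @return logical vector, one entry per trial.
#' @export
filterTrialsByLooking <- function(rec) {
    lk <- lookingTable(rec)
    mk <- trialMarkers(rec)
    if (is.null(lk)) stop("no looking annotations in recording")
    valid <- rep(FALSE, nrow(mk))
    m <- match(mk$trial, lk$trial)
    miss <- is.na(m) | is.na(lk$frac_trial[m]) | is.na(lk$frac_brush[m])
    if (any(miss))
        warning(sum(miss), " trial(s) without looking data marked invalid")
    ok <- !miss
    valid[ok] <- lk$frac_trial[m[ok]] > 0.5 & lk$frac_brush[m[ok]] >= 0.5
    valid
}

#' Does a trial mask satisfy the minimum-trials rule?
#'
#' @param mask logical trial validity vector.
#' @param conditions condition per trial.
#' @param min_trials minimum valid trials per condition (default 3).
#' @return \code{TRUE} if every condition has at least \code{min_trials}
#'   valid trials.
#' @export
meetsTrialMinimum <- function(mask, conditions, min_trials = 3) {
    all(vapply(unique(conditions),
               function(cd) sum(mask[conditions == cd]) >= min_trials,
               logical(1)))
}

#' Prune channels by intensity range and signal-to-noise ratio
#'
#' A channel is dropped when its mean raw intensity lies outside
#' \code{[0.09, 1]} V, or its SNR \eqn{20 \log_{10}(mean/SD)} falls below
#' 0 dB, at either wavelength.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param range_v allowed mean-intensity range in volts.
#' @param snr_db_min minimum SNR in dB.
#' @return logical vector, \code{TRUE} for channels kept.
#' @export
pruneChannels <- function(rec, range_v = c(0.09, 1), snr_db_min = 0) {
    ok <- rep(TRUE, nrow(rec))
    for (a in c("intensity760", "intensity850")) {
        x <- SummarizedExperiment::assay(rec, a)
        mu <- rowMeans(x)
        sdv <- apply(x, 1, stats::sd)
        snr <- ifelse(sdv > 0, 20 * log10(mu / sdv), Inf)
        ok <- ok & mu >= range_v[1] & mu <= range_v[2] & snr >= snr_db_min
    }
    ok
}

#' Convert intensity to optical density
#'
#' \eqn{OD(t) = -\ln(I(t)/\bar I)} per channel and wavelength.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @return list with \code{od760}, \code{od850} channels x time matrices.
#' @export
intensityToOd <- function(rec) {
    conv <- function(a) {
        x <- SummarizedExperiment::assay(rec, a)
        if (any(x <= 0)) {
            bad <- which(rowSums(x <= 0) > 0)
            stop("non-positive intensity in channel(s) ",
                 paste(montage(rec)$channel[bad], collapse = ", "))
        }
        -log(x / rowMeans(x))
    }
    list(od760 = conv("intensity760"), od850 = conv("intensity850"))
}

rollingRange <- function(x, w) {
    n <- length(x) - w + 1
    if (n < 1) return(numeric())
    hi <- lo <- x[seq_len(n)]
    for (k in seq_len(w - 1)) {
        hi <- pmax(hi, x[seq_len(n) + k])
        lo <- pmin(lo, x[seq_len(n) + k])
    }
    hi - lo
}

#' Detect motion artifacts
#'
#' Sliding 1-s windows per channel; a window is flagged when the signal
#' range within it exceeds \code{amp_thresh} OD, or exceeds
#' \code{sd_thresh} standard deviations of the channel's sample-to-sample
#' signal change. Flags from both wavelengths are combined.
#'
#' @param od list with \code{od760}, \code{od850} (channels x time), from
#'   \code{\link{intensityToOd}}.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 1).
#' @param sd_thresh SD criterion (default 14).
#' @param amp_thresh amplitude criterion in OD units (default 0.4).
#' @return logical channels x time matrix, \code{TRUE} where flagged.
#' @export
detectMotion <- function(od, fs, window_s = 1, sd_thresh = 14,
                         amp_thresh = 0.4) {
    w <- max(2L, round(window_s * fs))
    nch <- nrow(od$od760); n <- ncol(od$od760)
    flag <- matrix(FALSE, nch, n)
    for (ch in seq_len(nch)) {
        for (x in list(od$od760[ch, ], od$od850[ch, ])) {
            rng <- rollingRange(x, w)
            thr <- min(amp_thresh, sd_thresh * stats::sd(diff(x)))
            bad <- which(rng > thr)
            for (i in bad) flag[ch, i:(i + w - 1)] <- TRUE
        }
    }
    flag
}

#' Artifact flags as per-channel segments
#'
#' @param flag logical channels x time matrix from \code{\link{detectMotion}}.
#' @param fs sampling rate (Hz).
#' @return \code{data.frame} with \code{channel}, \code{start_s},
#'   \code{end_s} of each contiguous flagged segment.
#' @export
artifactSegments <- function(flag, fs) {
    out <- data.frame(channel = integer(), start_s = numeric(),
                      end_s = numeric())
    for (ch in seq_len(nrow(flag))) {
        r <- rle(flag[ch, ])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        k <- which(r$values)
        if (length(k))
            out <- rbind(out, data.frame(channel = ch,
                                         start_s = (starts[k] - 1) / fs,
                                         end_s = ends[k] / fs))
    }
    out
}

#' Heart-rate quality check
#'
#' Automated surrogate for visual channel inspection: a channel passes when
#' its smoothed periodogram shows a peak in the cardiac band whose power
#' exceeds \code{prominence} times the median power above 1 Hz. Simulated
#' infant cardiac pulsation (~2.5 Hz) passes; channels without optical
#' contact (noise only) fail.
#'
#' @param x channels x time matrix (corrected OD, one wavelength).
#' @param fs sampling rate (Hz); must exceed twice the band's upper edge
#'   divided by safety margin (\code{fs > 7} with the default band).
#' @param band_hz cardiac search band (default \code{c(1.5, 3.5)}).
#' @param prominence required peak-to-background power ratio (default 30;
#'   simulated cardiac pulsation yields ratios above 300, channels without
#'   it stay below ~15).
#' @return logical vector, \code{TRUE} for channels passing.
#' @export
heartRateCheck <- function(x, fs, band_hz = c(1.5, 3.5), prominence = 30) {
    if (fs <= 2 * band_hz[2] * 0.9)
        warning("sampling rate barely resolves the cardiac band")
    ok <- logical(nrow(x))
    for (ch in seq_len(nrow(x))) {
        v <- x[ch, ]
        if (stats::sd(v) == 0) { ok[ch] <- FALSE; next }
        sp <- stats::spec.pgram(stats::ts(v, frequency = fs),
                                spans = c(7, 7), taper = 0.1, detrend = TRUE,
                                plot = FALSE)
        inband <- sp$freq >= band_hz[1] & sp$freq <= band_hz[2]
        backgr <- sp$freq > 1
        if (!any(inband) || !any(backgr)) { ok[ch] <- FALSE; next }
        ok[ch] <- max(sp$spec[inband]) >
            prominence * stats::median(sp$spec[backgr])
    }
    ok
}

#' Reject trials contaminated by residual motion artifacts
#'
#' A trial is invalid when any residual artifact segment (on any of the
#' channels considered) overlaps its baseline-plus-trial span; set
#' \code{span = "trial"} to restrict to the trial itself.
#'
#' @param segments artifact segments from \code{\link{artifactSegments}}.
#' @param markers trial markers of the recording.
#' @param channels optional channel indices to consider (default all).
#' @param span \code{"baseline_trial"} (default) or \code{"trial"}.
#' @return logical trial validity vector (\code{TRUE} = uncontaminated).
#' @export
rejectContaminatedTrials <- function(segments, markers, channels = NULL,
                                     span = c("baseline_trial", "trial")) {
    span <- match.arg(span)
    if (!is.null(channels) && nrow(segments))
        segments <- segments[segments$channel %in% channels, , drop = FALSE]
    ok <- rep(TRUE, nrow(markers))
    if (!nrow(segments)) return(ok)
    lo <- if (span == "baseline_trial") markers$baseline_onset_s
          else markers$trial_onset_s
    hi <- markers$trial_end_s
    for (k in seq_len(nrow(markers)))
        ok[k] <- !any(segments$start_s < hi[k] & segments$end_s > lo[k])
    ok
}

#' Zero-phase band-pass filter
#'
#' Cascaded zero-phase Butterworth sections: a 2nd-order high-pass at
#' \code{low} Hz followed by a 4th-order low-pass at \code{high} Hz, each
#' applied forward-backward (\code{filtfilt}), so the passband is
#' \code{[low, high]} with no phase distortion and the DC component removed.
#'
#' @param x channels x time matrix or numeric vector.
#' @param fs sampling rate (Hz); must exceed \code{2 * high}.
#' @param low,high band edges in Hz (defaults 0.01 and 1).
#' @return filtered signal, same shape.
#' @export
bandpassFilter <- function(x, fs, low = 0.01, high = 1) {
    if (fs <= 2 * high) stop("sampling rate too low for requested band")
    hp <- signal::butter(2, low / (fs / 2), type = "high")
    lp <- signal::butter(4, high / (fs / 2), type = "low")
    one <- function(v) {
        v <- signal::filtfilt(hp, v - mean(v))
        signal::filtfilt(lp, v)
    }
    if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' Cut baseline-corrected ROI epochs
#'
#' Averages the HbO/HbR signal over the surviving channels of each ROI
#' (requiring at least \code{min_channels}), cuts epochs of
#' \code{epoch_s} seconds from each valid trial onset, and subtracts the
#' mean of the final \code{baseline_ref_s} seconds of the preceding
#' baseline from each epoch.
#'
#' @param conc list with \code{HbO}, \code{HbR} (channels x time, uMol).
#' @param markers trial markers.
#' @param trial_mask logical trial validity vector.
#' @param channel_mask logical channel survival vector.
#' @param montage montage \code{data.frame} (row order matching \code{conc}).
#' @param fs sampling rate (Hz).
#' @param rois ROI definition (default \code{\link{roiDefinition}()}).
#' @param epoch_s post-stimulus epoch length (default 18 s, i.e. six 3-s
#'   bins; extends past the 15-s trial into the next baseline).
#' @param baseline_ref_s baseline-correction reference interval (default
#'   final 3 s before trial onset).
#' @return An \linkS4class{EpochSet}.
#' @export
buildEpochs <- function(conc, markers, trial_mask, channel_mask, montage,
                        fs, rois = roiDefinition(), epoch_s = 18,
                        baseline_ref_s = 3) {
    nsamp <- round(epoch_s * fs)
    nref <- round(baseline_ref_s * fs)
    time_s <- (seq_len(nsamp) - 1) / fs
    conds <- c("contingent", "noncontingent")
    roi_names <- setdiff(names(rois), "min_channels")
    epochs <- list()
    nValid <- matrix(0L, length(roi_names), length(conds),
                     dimnames = list(roi_names, conds))
    for (r in roi_names) {
        chans <- which(montage$channel %in% rois[[r]] & channel_mask)
        if (length(chans) < rois$min_channels) {
            epochs[[r]] <- stats::setNames(vector("list", 2), conds)
            next
        }
        tr <- list(HbO = colMeans(conc$HbO[chans, , drop = FALSE]),
                   HbR = colMeans(conc$HbR[chans, , drop = FALSE]))
        ep <- list()
        for (cond in conds) {
            ks <- which(trial_mask & markers$condition == cond)
            mO <- mR <- matrix(NA_real_, length(ks), nsamp)
            for (i in seq_along(ks)) {
                i0 <- floor(markers$trial_onset_s[ks[i]] * fs) + 1
                idx <- i0:(i0 + nsamp - 1)
                ref <- (i0 - nref):(i0 - 1)
                if (max(idx) > length(tr$HbO) || min(ref) < 1)
                    stop("epoch window outside recording for trial ", ks[i])
                mO[i, ] <- tr$HbO[idx] - mean(tr$HbO[ref])
                mR[i, ] <- tr$HbR[idx] - mean(tr$HbR[ref])
            }
            ep[[cond]] <- list(HbO = mO, HbR = mR)
            nValid[r, cond] <- length(ks)
        }
        epochs[[r]] <- ep
    }
    new("EpochSet", epochs = epochs, time_s = time_s, nValid = nValid,
        rois = roi_names)
}

#' Run the full fNIRS preprocessing chain
#'
#' Applies, in order: looking-time trial filter, channel pruning
#' (intensity range and SNR), optical-density conversion, motion-artifact
#' detection, wavelet correction, heart-rate quality check, residual
#' artifact check with trial rejection, band-pass filter, modified
#' Beer-Lambert conversion, and ROI epoching. Every stage's parameters and
#' exclusion decisions are recorded in the returned manifest.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param dpf differential pathlength factor (default 5.1).
#' @param bandpass_hz band edges (default \code{c(0.01, 1)}).
#' @param motion_sd,motion_amp_od,motion_window_s motion-detection
#'   parameters (14 SD / 0.4 OD / 1 s).
#' @param wavelet_iqr wavelet outlier threshold (default 0.5).
#' @param hr_band_hz,hr_prominence heart-rate check parameters.
#' @param min_trials minimum valid trials per condition (default 3).
#' @param epoch_s,baseline_ref_s epoching parameters.
#' @param contamination_span \code{"baseline_trial"} or \code{"trial"}.
#' @param contamination_channels \code{"roi"} (default: only ROI channels'
#'   residual artifacts reject trials) or \code{"all"}.
#' @param rois ROI definition.
#' @return list with \code{included} (did the subject survive the
#'   minimum-trials rule), \code{epochs} (\linkS4class{EpochSet} or
#'   \code{NULL}), \code{masks} (looking/channel/heart-rate/trial vectors),
#'   \code{conc} (full-length HbO/HbR matrices) and \code{manifest}.
#' @export
preprocessNirs <- function(rec, dpf = 5.1, bandpass_hz = c(0.01, 1),
                           motion_sd = 14, motion_amp_od = 0.4,
                           motion_window_s = 1, wavelet_iqr = 0.5,
                           hr_band_hz = c(1.5, 3.5), hr_prominence = 30,
                           min_trials = 3, epoch_s = 18, baseline_ref_s = 3,
                           contamination_span = "baseline_trial",
                           contamination_channels = c("roi", "all"),
                           rois = roiDefinition()) {
    contamination_channels <- match.arg(contamination_channels)
    fs <- samplingRate(rec)
    mk <- trialMarkers(rec)
    mont <- montage(rec)

    looking_ok <- filterTrialsByLooking(rec)
    keep_ch <- pruneChannels(rec)
    od <- intensityToOd(rec)
    flags <- detectMotion(od, fs, motion_window_s, motion_sd, motion_amp_od)
    od_corr <- list(od760 = waveletCorrect(od$od760, fs, wavelet_iqr),
                    od850 = waveletCorrect(od$od850, fs, wavelet_iqr))
    hr_ok <- heartRateCheck(od_corr$od850, fs, hr_band_hz, hr_prominence)
    keep_ch <- keep_ch & hr_ok
    resid <- detectMotion(od_corr, fs, motion_window_s, motion_sd,
                          motion_amp_od)
    segs <- artifactSegments(resid & keep_ch, fs)
    contam_ch <- if (contamination_channels == "roi")
        which(mont$channel %in% unlist(rois[c("left", "right")]) & keep_ch)
    else which(keep_ch)
    clean_ok <- rejectContaminatedTrials(segs, mk, channels = contam_ch,
                                         span = contamination_span)
    trial_ok <- looking_ok & clean_ok
    included <- meetsTrialMinimum(trial_ok, mk$condition, min_trials)

    od_filt <- list(od760 = bandpassFilter(od_corr$od760, fs,
                                           bandpass_hz[1], bandpass_hz[2]),
                    od850 = bandpassFilter(od_corr$od850, fs,
                                           bandpass_hz[1], bandpass_hz[2]))
    conc <- odToConcentration(od_filt$od760, od_filt$od850, mont, dpf = dpf)
    epochs <- if (included)
        buildEpochs(conc, mk, trial_ok, keep_ch, mont, fs, rois,
                    epoch_s, baseline_ref_s)
    else NULL

    manifest <- list(
        stages = c("looking_filter", "channel_prune", "optical_density",
                   "motion_detect", "wavelet_correct", "heart_rate_check",
                   "residual_check_trial_reject", "bandpass",
                   "beer_lambert", "roi_epochs"),
        parameters = list(fs = fs, dpf = dpf, bandpass_hz = bandpass_hz,
                          motion_sd = motion_sd,
                          motion_amp_od = motion_amp_od,
                          motion_window_s = motion_window_s,
                          wavelet_iqr = wavelet_iqr,
                          hr_band_hz = hr_band_hz,
                          hr_prominence = hr_prominence,
                          min_trials = min_trials, epoch_s = epoch_s,
                          baseline_ref_s = baseline_ref_s,
                          contamination_span = contamination_span,
                          contamination_channels = contamination_channels),
        exclusions = list(
            trials_failing_looking = which(!looking_ok),
            channels_pruned = mont$channel[!keep_ch],
            channels_failing_heart_rate = mont$channel[!hr_ok],
            trials_contaminated = which(!clean_ok),
            subject_included = included))

    list(included = included, epochs = epochs,
         masks = list(looking = looking_ok, channels = keep_ch,
                      heart_rate = hr_ok, trials = trial_ok),
         conc = conc, manifest = manifest)
}
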