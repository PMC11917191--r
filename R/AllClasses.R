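#' @import methods
#' @importFrom S4Vectors metadata SimpleList DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Touch category vocabulary
#'
#' The seven hand-touch categories, ordered by coding priority (earlier wins
#' when several categories occur within one 2-s segment), plus the pseudo-code
#' \code{"none"} for untouched segments.
#'
#' @format Character vectors.
#' @export
touchCategories <- c("affective", "harsh", "playful", "attention_getting",
                     "instrumental", "static", "incidental")

#' @rdname touchCategories
#' @export
touchCodes <- c(touchCategories, "none")

behaviorCodes <- c("smile", "eyebrow", "tongue", "vocal")

## ---------------------------------------------------------------------------
## EventStream
## ---------------------------------------------------------------------------

#' EventStream: timestamped coded behaviors of one interaction partner
#'
#' Holds the coded behaviors (facial expressions and vocal utterances) of one
#' partner of a dyadic interaction, each with onset and offset in milliseconds
#' from the start of the recording.
#'
#' @slot actor \code{"mother"} or \code{"infant"}.
#' @slot events \code{data.frame} with columns \code{code}, \code{modality}
#'   (\code{"facial"}/\code{"vocal"}), \code{onset_ms}, \code{offset_ms},
#'   sorted by onset.
#'
#' @export
setClass("EventStream",
         representation(actor = "character", events = "data.frame"))

setValidity("EventStream", function(object) {
    ev <- object@events
    msg <- character()
    if (!object@actor %in% c("mother", "infant"))
        msg <- c(msg, "actor must be 'mother' or 'infant'")
    need <- c("code", "modality", "onset_ms", "offset_ms")
    if (!all(need %in% names(ev)))
        return(paste("events needs columns:", paste(need, collapse = ", ")))
    if (nrow(ev)) {
        if (any(ev$onset_ms < 0)) msg <- c(msg, "event times must be >= 0")
        if (any(ev$offset_ms < ev$onset_ms))
            msg <- c(msg, "event offset before onset")
        if (is.unsorted(ev$onset_ms))
            msg <- c(msg, "events must be sorted by onset")
        if (!all(ev$modality %in% c("facial", "vocal")))
            msg <- c(msg, "modality must be 'facial' or 'vocal'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EventStream
#'
#' @param actor \code{"mother"} or \code{"infant"}.
#' @param code behavior codes (e.g. \code{"smile"}, \code{"vocal"}).
#' @param modality \code{"facial"} or \code{"vocal"} per event; by default
#'   \code{"vocal"} for code \code{"vocal"} and \code{"facial"} otherwise.
#' @param onset_ms,offset_ms event boundaries in ms.
#'
#' @return An \linkS4class{EventStream}.
#' @examples
#' EventStream("infant", code = "smile", onset_ms = 5000, offset_ms = 5600)
#' @export
EventStream <- function(actor, code = character(), modality = NULL,
                        onset_ms = numeric(), offset_ms = onset_ms) {
    if (is.null(modality))
        modality <- ifelse(code == "vocal", "vocal", "facial")
    ev <- data.frame(code = as.character(code),
                     modality = as.character(modality),
                     onset_ms = as.numeric(onset_ms),
                     offset_ms = as.numeric(offset_ms),
                     stringsAsFactors = FALSE)
    ev <- ev[order(ev$onset_ms, ev$offset_ms), , drop = FALSE]
    rownames(ev) <- NULL
    new("EventStream", actor = actor, events = ev)
}

#' @describeIn EventStream number of events
#' @param x,object an \code{EventStream}
#' @export
setMethod("length", "EventStream", function(x) nrow(x@events))

setMethod("show", "EventStream", function(object) {
    cat(sprintf("EventStream (%s) with %d events\n",
                object@actor, nrow(object@events)))
    if (nrow(object@events))
        print(utils::head(object@events, 5))
})

#' Event table of an EventStream
#' @param x an \linkS4class{EventStream}
#' @return \code{data.frame} of events.
#' @export
events <- function(x) x@events

#' Actor of an EventStream
#' @param x an \linkS4class{EventStream}
#' @return \code{"mother"} or \code{"infant"}.
#' @export
actor <- function(x) x@actor

## ---------------------------------------------------------------------------
## GazeEpisodes
## ---------------------------------------------------------------------------

#' GazeEpisodes: intervals of mutual gaze
#'
#' Non-overlapping, sorted intervals (ms) during which mother and infant were
#' in mutual gaze. Behavioral coding and the responsiveness index are
#' restricted to these intervals.
#'
#' @slot episodes \code{data.frame} with \code{start_ms}, \code{end_ms}.
#' @export
setClass("GazeEpisodes", representation(episodes = "data.frame"))

setValidity("GazeEpisodes", function(object) {
    ep <- object@episodes
    if (!all(c("start_ms", "end_ms") %in% names(ep)))
        return("episodes needs columns start_ms, end_ms")
    if (nrow(ep)) {
        if (any(ep$end_ms <= ep$start_ms))
            return("zero- or negative-duration gaze episode")
        if (is.unsorted(ep$start_ms)) return("episodes must be sorted")
        if (nrow(ep) > 1 && any(ep$start_ms[-1] < ep$end_ms[-nrow(ep)]))
            return("episodes must not overlap")
    }
    TRUE
})

#' Construct GazeEpisodes
#'
#' @param start_ms,end_ms episode boundaries in ms (\code{end_ms > start_ms}).
#' @return A \linkS4class{GazeEpisodes}.
#' @examples
#' GazeEpisodes(c(0, 10000), c(8000, 30000))
#' @export
GazeEpisodes <- function(start_ms = numeric(), end_ms = numeric()) {
    ep <- data.frame(start_ms = as.numeric(start_ms),
                     end_ms = as.numeric(end_ms))
    ep <- ep[order(ep$start_ms), , drop = FALSE]
    rownames(ep) <- NULL
    new("GazeEpisodes", episodes = ep)
}

#' Episode table of a GazeEpisodes object
#' @param x a \linkS4class{GazeEpisodes}
#' @return \code{data.frame} with \code{start_ms}, \code{end_ms}.
#' @export
episodes <- function(x) x@episodes

#' Total mutual-gaze duration
#' @param x a \linkS4class{GazeEpisodes}
#' @return duration in ms.
#' @export
gazeDuration <- function(x) sum(x@episodes$end_ms - x@episodes$start_ms)

setMethod("show", "GazeEpisodes", function(object) {
    cat(sprintf("GazeEpisodes: %d episodes, total %.1f s\n",
                nrow(object@episodes), gazeDuration(object) / 1000))
})

## ---------------------------------------------------------------------------
## ContingencySummary
## ---------------------------------------------------------------------------

#' ContingencySummary: counts behind the responsiveness index
#'
#' Counts and durations entering the chance-corrected maternal responsiveness
#' index: \code{C} maternal contingent behaviors, \code{I} infant behaviors,
#' \code{M} maternal behaviors, \code{D_ms} total mutual-gaze duration and
#' \code{W_ms} the latency window, together with the resulting index
#' \eqn{C/I - (1 - e^{-M W / D})}.
#'
#' @slot C,I,M event counts (within mutual gaze, inside the analysis window).
#' @slot D_ms gaze duration (ms); @slot W_ms latency window (ms).
#' @slot index the responsiveness index (dimensionless).
#' @slot pairs \code{data.frame} of detected (infant event, maternal event)
#'   pairs with their onsets.
#' @export
setClass("ContingencySummary",
         representation(C = "numeric", I = "numeric", M = "numeric",
                        D_ms = "numeric", W_ms = "numeric", index = "numeric",
                        pairs = "data.frame"),
         prototype(C = 0, I = 0, M = 0, D_ms = 0, W_ms = 1000,
                   index = numeric()))

setValidity("ContingencySummary", function(object) {
    if (object@C < 0 || object@I < 0 || object@M < 0)
        return("counts must be non-negative")
    if (object@I > 0 && length(object@index) &&
        is.finite(object@index) && object@index > object@C / object@I + 1e-12)
        return("index cannot exceed C/I")
    TRUE
})

setMethod("show", "ContingencySummary", function(object) {
    cat("ContingencySummary\n")
    cat(sprintf("  contingent C = %d, infant I = %d, maternal M = %d\n",
                object@C, object@I, object@M))
    cat(sprintf("  mutual gaze D = %.1f s, window W = %d ms\n",
                object@D_ms / 1000, as.integer(object@W_ms)))
    cat(sprintf("  responsiveness index = %.4f\n", object@index))
})

#' @describeIn ContingencySummary coerce the summary to a named list
#' @param x a \code{ContingencySummary}
#' @param ... ignored
#' @export
setMethod("as.list", "ContingencySummary", function(x, ...) {
    list(C = x@C, I = x@I, M = x@M, D_ms = x@D_ms, W_ms = x@W_ms,
         index = x@index)
})

#' Responsiveness index stored in a ContingencySummary
#' @param x a \linkS4class{ContingencySummary}
#' @return numeric index.
#' @export
respIndex <- function(x) x@index

#' Contingent pairs stored in a ContingencySummary
#' @param x a \linkS4class{ContingencySummary}
#' @return \code{data.frame} of pairings.
#' @export
contingentPairs <- function(x) x@pairs

## ---------------------------------------------------------------------------
## TouchRecord
## ---------------------------------------------------------------------------

#' TouchRecord: per-segment maternal touch codes
#'
#' One resolved touch code per 2-s video segment (or \code{"none"}), plus the
#' video duration used to normalize category durations into proportions.
#' A final partial segment may be shorter than \code{segment_s}; its weight is
#' its actual duration.
#'
#' @slot codes character vector over \code{\link{touchCodes}}.
#' @slot segment_s nominal segment length (s), 2 by convention.
#' @slot segment_durations_s actual duration of each segment (s).
#' @slot video_duration_s total video duration (s).
#' @export
setClass("TouchRecord",
         representation(codes = "character", segment_s = "numeric",
                        segment_durations_s = "numeric",
                        video_duration_s = "numeric"))

setValidity("TouchRecord", function(object) {
    if (!all(object@codes %in% touchCodes))
        return(paste("unknown touch code(s):",
                     paste(setdiff(object@codes, touchCodes), collapse = ", ")))
    if (length(object@segment_durations_s) != length(object@codes))
        return("one duration per segment required")
    if (any(object@segment_durations_s <= 0))
        return("segment durations must be positive")
    if (object@video_duration_s <= 0)
        return("video_duration_s must be positive")
    TRUE
})

#' Construct a TouchRecord
#'
#' @param codes resolved per-segment codes over \code{\link{touchCodes}}.
#' @param segment_s nominal segment length in seconds (default 2).
#' @param video_duration_s total video duration; defaults to
#'   \code{sum(segment_durations_s)}.
#' @param segment_durations_s per-segment durations; defaults to
#'   \code{segment_s} for all segments, with the final segment truncated so
#'   the total matches \code{video_duration_s} when that is supplied.
#' @return A \linkS4class{TouchRecord}.
#' @examples
#' TouchRecord(c("affective", "none", "instrumental"))
#' @export
TouchRecord <- function(codes, segment_s = 2, video_duration_s = NULL,
                        segment_durations_s = NULL) {
    n <- length(codes)
    if (is.null(segment_durations_s)) {
        segment_durations_s <- rep(segment_s, n)
        if (!is.null(video_duration_s)) {
            extra <- n * segment_s - video_duration_s
            if (extra >= segment_s || extra < 0)
                stop("video_duration_s incompatible with number of segments")
            if (extra > 0)
                segment_durations_s[n] <- segment_s - extra
        }
    }
    if (is.null(video_duration_s))
        video_duration_s <- sum(segment_durations_s)
    new("TouchRecord", codes = as.character(codes), segment_s = segment_s,
        segment_durations_s = segment_durations_s,
        video_duration_s = video_duration_s)
}

setMethod("show", "TouchRecord", function(object) {
    cat(sprintf("TouchRecord: %d segments (%.0f s nominal), video %.1f s\n",
                length(object@codes), object@segment_s,
                object@video_duration_s))
    tb <- table(factor(object@codes, levels = touchCodes))
    print(tb[tb > 0])
})

#' @describeIn TouchRecord number of segments
#' @param x a \code{TouchRecord}
#' @export
setMethod("length", "TouchRecord", function(x) length(x@codes))

#' Segment codes of a TouchRecord
#' @param x a \linkS4class{TouchRecord}
#' @return character vector of per-segment codes.
#' @export
touchSegments <- function(x) x@codes

## ---------------------------------------------------------------------------
## NirsRecording
## ---------------------------------------------------------------------------

#' NirsRecording: raw dual-wavelength fNIRS recording
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are channels, columns are
#' time samples. Two assays, \code{"intensity760"} and \code{"intensity850"},
#' hold raw detector intensity in volts at 760 and 850 nm. \code{rowData}
#' carries the montage (source, detector, distance in mm, hemisphere);
#' \code{metadata} carries the sampling rate \code{fs}, trial \code{markers},
#' per-trial \code{looking} proportions, \code{brush} stroke windows and —
#' for simulated recordings — the \code{ground_truth} hemodynamics.
#'
#' @export
setClass("NirsRecording", contains = "SummarizedExperiment")

setValidity("NirsRecording", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("intensity760", "intensity850") %in% an))
        msg <- c(msg, "assays intensity760 and intensity850 required")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("channel", "source", "detector", "distance_mm", "hemisphere")
    if (!all(need %in% names(rd)))
        msg <- c(msg, paste("rowData needs:", paste(need, collapse = ", ")))
    else if (any(rd$distance_mm < 20 | rd$distance_mm > 25))
        msg <- c(msg, "source-detector distance must lie in [20, 25] mm")
    md <- metadata(object)
    if (is.null(md$fs) || md$fs <= 0)
        msg <- c(msg, "metadata$fs (sampling rate, Hz) required")
    mk <- md$markers
    if (!is.null(mk) && nrow(mk) &&
        !all(mk$condition %in% c("contingent", "noncontingent")))
        msg <- c(msg, "conditions must be contingent/noncontingent")
    if (length(msg)) msg else TRUE
})

#' Construct a NirsRecording
#'
#' @param intensity760,intensity850 channels x time intensity matrices (V).
#' @param montage \code{data.frame} with \code{channel}, \code{source},
#'   \code{detector}, \code{distance_mm}, \code{hemisphere} (one row per
#'   channel, same order as the matrices). See \code{\link{defaultMontage}}.
#' @param fs sampling rate in Hz.
#' @param markers \code{data.frame} of trials: \code{trial}, \code{condition},
#'   \code{baseline_onset_s}, \code{trial_onset_s}, \code{trial_end_s}.
#' @param looking per-trial looking proportions: \code{trial},
#'   \code{frac_trial}, \code{frac_brush}.
#' @param brush optional \code{data.frame} of brushstroke windows.
#' @param ground_truth optional list of simulation ground truth.
#' @return A \linkS4class{NirsRecording}.
#' @export
NirsRecording <- function(intensity760, intensity850, montage, fs,
                          markers = NULL, looking = NULL, brush = NULL,
                          ground_truth = NULL) {
    stopifnot(all(dim(intensity760) == dim(intensity850)),
              nrow(intensity760) == nrow(montage))
    rownames(intensity760) <- rownames(intensity850) <-
        paste0("ch", montage$channel)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = SimpleList(intensity760 = intensity760,
                            intensity850 = intensity850),
        rowData = DataFrame(montage),
        metadata = list(fs = fs, markers = markers, looking = looking,
                        brush = brush, ground_truth = ground_truth))
    new("NirsRecording", se)
}

#' Sampling rate of a recording
#' @param x a \linkS4class{NirsRecording}
#' @return sampling rate in Hz.
#' @export
samplingRate <- function(x) metadata(x)$fs

#' Montage of a recording
#' @param x a \linkS4class{NirsRecording}
#' @return montage \code{data.frame}.
#' @export
montage <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' Trial markers of a recording
#' @param x a \linkS4class{NirsRecording}
#' @return \code{data.frame} of trial markers.
#' @export
trialMarkers <- function(x) metadata(x)$markers

#' Per-trial looking proportions
#' @param x a \linkS4class{NirsRecording}
#' @return \code{data.frame} with \code{frac_trial}, \code{frac_brush}.
#' @export
lookingTable <- function(x) metadata(x)$looking

#' Simulation ground truth attached to a recording
#' @param x a \linkS4class{NirsRecording}
#' @return list with \code{HbO}, \code{HbR} (uMol, channels x time),
#'   \code{spikes}, \code{config}; \code{NULL} for real recordings.
#' @export
groundTruth <- function(x) metadata(x)$ground_truth

#' Time axis of a recording
#' @param x a \linkS4class{NirsRecording}
#' @return sample times in seconds.
#' @export
timeAxis <- function(x) (seq_len(ncol(x)) - 1) / samplingRate(x)

setMethod("show", "NirsRecording", function(object) {
    mk <- trialMarkers(object)
    cat(sprintf("NirsRecording: %d channels x %d samples @ %.4f Hz (%.1f s)\n",
                nrow(object), ncol(object), samplingRate(object),
                ncol(object) / samplingRate(object)))
    if (!is.null(mk))
        cat(sprintf("  %d trials (%s)\n", nrow(mk),
                    paste(table(mk$condition), collapse = " + ")))
    if (!is.null(groundTruth(object)))
        cat("  simulation ground truth attached\n")
})

## ---------------------------------------------------------------------------
## EpochSet
## ---------------------------------------------------------------------------

#' EpochSet: baseline-corrected HbO/HbR ROI epochs
#'
#' Per (ROI, condition): matrices of valid-trial epochs (trials x time) for
#' HbO and HbR in uMol, time-locked to trial onset and baseline-corrected.
#' ROIs with fewer than two surviving channels are absent (\code{NULL}).
#'
#' @slot epochs nested list \code{[[roi]][[condition]]$HbO/$HbR}.
#' @slot time_s epoch time axis (s from trial onset).
#' @slot nValid matrix ROI x condition of valid trial counts.
#' @slot rois character vector of ROI names.
#' @export
setClass("EpochSet",
         representation(epochs = "list", time_s = "numeric",
                        nValid = "matrix", rois = "character"))

setValidity("EpochSet", function(object) {
    for (r in names(object@epochs))
        for (cond in names(object@epochs[[r]])) {
            e <- object@epochs[[r]][[cond]]
            if (is.null(e)) next
            if (!all(c("HbO", "HbR") %in% names(e)))
                return("each epoch entry needs HbO and HbR")
            if (ncol(e$HbO) != length(object@time_s))
                return("epoch width must match time axis")
        }
    TRUE
})

setMethod("show", "EpochSet", function(object) {
    cat(sprintf("EpochSet: %d ROI(s), epoch 0-%.1f s\n",
                length(object@epochs), max(object@time_s)))
    print(object@nValid)
})

#' Valid trial counts of an EpochSet
#' @param x an \linkS4class{EpochSet}
#' @return matrix ROI x condition.
#' @export
validTrials <- function(x) x@nValid

#' Extract epochs for one ROI and condition
#' @param x an \linkS4class{EpochSet}
#' @param roi ROI name (\code{"left"}/\code{"right"})
#' @param condition \code{"contingent"} or \code{"noncontingent"}
#' @param chromophore \code{"HbO"} or \code{"HbR"}
#' @return trials x time matrix (uMol), or \code{NULL} if the ROI is missing.
#' @export
epochMatrix <- function(x, roi, condition, chromophore = "HbO") {
    e <- x@epochs[[roi]][[condition]]
    if (is.null(e)) NULL else e[[chromophore]]
}

#' Epoch time axis
#' @param x an \linkS4class{EpochSet}
#' @return time in seconds from trial onset.
#' @export
epochTime <- function(x) x@time_s
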