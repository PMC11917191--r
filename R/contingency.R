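## Maternal contingency detection and the chance-corrected responsiveness
## index. All times in ms.

inGaze <- function(t, gaze) {
    ep <- episodes(gaze)
    if (!nrow(ep)) return(rep(FALSE, length(t)))
    out <- logical(length(t))
    for (i in seq_len(nrow(ep)))
        out <- out | (t >= ep$start_ms[i] & t < ep$end_ms[i])
    out
}

#' Detect maternal contingent responses
#'
#' A maternal behavior is contingent on an infant behavior when it starts
#' within \code{W_ms} (default 1000 ms) after the infant behavior's onset;
#' for infant vocal expressions the window extends to \code{W_ms} after the
#' offset. A maternal behavior starting at exactly the infant onset is not
#' contingent. If several maternal behaviors fall within one window, only the
#' first is paired. Infant behaviors with identical onsets (a simultaneity
#' group) are each paired separately, possibly to the same maternal behavior.
#' Only events whose onset lies inside a mutual-gaze episode are considered.
#'
#' @param mother,infant \linkS4class{EventStream} objects.
#' @param gaze \linkS4class{GazeEpisodes}.
#' @param W_ms latency window in ms (default 1000). The window is open at the
#'   infant onset and closed at its upper end.
#' @param allow_reuse may one maternal behavior be paired to several
#'   non-simultaneous infant behaviors? Default \code{TRUE} (pairing is
#'   per-infant-event).
#' @return \code{data.frame} with one row per pairing: \code{infant_idx},
#'   \code{mother_idx} (row indices into the gaze-restricted event tables
#'   returned as attributes), \code{infant_onset_ms}, \code{mother_onset_ms},
#'   \code{latency_ms}.
#' @examples
#' inf <- EventStream("infant", "smile", onset_ms = 5000, offset_ms = 5400)
#' mom <- EventStream("mother", c("smile", "smile"),
#'                    onset_ms = c(5300, 5800), offset_ms = c(5500, 6000))
#' gz <- GazeEpisodes(0, 10000)
#' detectContingent(mom, inf, gz)   # pairs the 5300 ms event only
#' @export
detectContingent <- function(mother, infant, gaze, W_ms = 1000,
                             allow_reuse = TRUE) {
    mev <- events(mother)
    iev <- events(infant)
    if (nrow(mev) && is.unsorted(mev$onset_ms)) stop("mother stream unsorted")
    if (nrow(iev) && is.unsorted(iev$onset_ms)) stop("infant stream unsorted")
    mev <- mev[inGaze(mev$onset_ms, gaze), , drop = FALSE]
    iev <- iev[inGaze(iev$onset_ms, gaze), , drop = FALSE]
    pairs <- data.frame(infant_idx = integer(), mother_idx = integer(),
                        infant_onset_ms = numeric(),
                        mother_onset_ms = numeric(), latency_ms = numeric())
    used <- logical(nrow(mev))
    if (nrow(iev) && nrow(mev)) {
        for (i in seq_len(nrow(iev))) {
            hi <- if (iev$modality[i] == "vocal")
                iev$offset_ms[i] + W_ms else iev$onset_ms[i] + W_ms
            ok <- mev$onset_ms > iev$onset_ms[i] & mev$onset_ms <= hi
            if (!allow_reuse) ok <- ok & !used
            if (!any(ok)) next
            j <- which(ok)[which.min(mev$onset_ms[ok])]
            used[j] <- TRUE
            pairs <- rbind(pairs, data.frame(
                infant_idx = i, mother_idx = j,
                infant_onset_ms = iev$onset_ms[i],
                mother_onset_ms = mev$onset_ms[j],
                latency_ms = mev$onset_ms[j] - iev$onset_ms[i]))
        }
    }
    rownames(pairs) <- NULL
    attr(pairs, "infant_events") <- iev
    attr(pairs, "mother_events") <- mev
    pairs
}

#' Chance-corrected maternal responsiveness index
#'
#' Computes \eqn{C/I - (1 - e^{-M W / D})}: the observed fraction of infant
#' behaviors answered contingently, minus the probability that at least one
#' maternal behavior would fall in a window of length \eqn{W} by chance if
#' maternal behaviors arrived as a Poisson process of rate \eqn{M/D} over the
#' mutual-gaze time \eqn{D}. Zero therefore means chance-level responding.
#' \eqn{D} and \eqn{W} are both in ms, so \eqn{M W / D} is the expected
#' number of maternal behaviors per latency window.
#'
#' @param C maternal contingent behaviors (count of pairings).
#' @param I infant behaviors within gaze and analysis window.
#' @param M maternal behaviors within gaze and analysis window.
#' @param D_ms total mutual-gaze duration (ms).
#' @param W_ms latency window (ms), default 1000.
#' @return the index (dimensionless).
#' @examples
#' responsivenessIndex(C = 5, I = 10, M = 20, D_ms = 240000)  # ~0.420
#' @export
responsivenessIndex <- function(C, I, M, D_ms, W_ms = 1000) {
    if (I <= 0) stop("undefined responsiveness index: no infant behaviors (I = 0)")
    if (D_ms <= 0) stop("undefined responsiveness index: no mutual gaze (D = 0)")
    C / I - (1 - exp(-M * W_ms / D_ms))
}

clipStream <- function(stream, from_ms, to_ms) {
    ev <- events(stream)
    ev <- ev[ev$onset_ms >= from_ms & ev$onset_ms < to_ms, , drop = FALSE]
    rownames(ev) <- NULL
    new("EventStream", actor = actor(stream), events = ev)
}

clipGaze <- function(gaze, from_ms, to_ms) {
    ep <- episodes(gaze)
    ep$start_ms <- pmax(ep$start_ms, from_ms)
    ep$end_ms <- pmin(ep$end_ms, to_ms)
    ep <- ep[ep$end_ms > ep$start_ms, , drop = FALSE]
    rownames(ep) <- NULL
    new("GazeEpisodes", episodes = ep)
}

#' Full contingency scoring pipeline for one dyad
#'
#' Discards a warm-up phase (default first 60 s), restricts all streams and
#' gaze episodes to the coded window (default the following 4 min), detects
#' contingent pairs and computes the responsiveness index.
#'
#' @inheritParams detectContingent
#' @param warmup_ms warm-up duration excluded from analysis (default 60000).
#' @param coded_ms analyzed duration after warm-up (default 240000).
#' @param session_ms recording length, if known; a session shorter than
#'   \code{warmup_ms + coded_ms} triggers a truncation warning.
#' @return A \linkS4class{ContingencySummary}.
#' @export
contingencyPipeline <- function(mother, infant, gaze, W_ms = 1000,
                                warmup_ms = 60000, coded_ms = 240000,
                                allow_reuse = TRUE, session_ms = NULL) {
    end_ms <- warmup_ms + coded_ms
    if (!is.null(session_ms) && session_ms < end_ms)
        warning(sprintf(paste("recording ends at %.1f s, before the analysis",
                              "window (%.1f s); analysis truncated"),
                        session_ms / 1000, end_ms / 1000))
    mother <- clipStream(mother, warmup_ms, end_ms)
    infant <- clipStream(infant, warmup_ms, end_ms)
    gaze <- clipGaze(gaze, warmup_ms, end_ms)
    D <- gazeDuration(gaze)
    if (D <= 0) stop("undefined responsiveness index: no mutual gaze in the analysis window")
    pairs <- detectContingent(mother, infant, gaze, W_ms = W_ms,
                              allow_reuse = allow_reuse)
    I <- nrow(attr(pairs, "infant_events"))
    M <- nrow(attr(pairs, "mother_events"))
    C <- nrow(pairs)
    if (I == 0) stop("undefined responsiveness index: no infant behaviors in the analysis window")
    idx <- responsivenessIndex(C, I, M, D, W_ms)
    ## initialize() rather than new(): a slot named C would partially match
    ## new()'s Class argument
    initialize(new("ContingencySummary"), C = C, I = I, M = M, D_ms = D,
               W_ms = W_ms, index = idx, pairs = as.data.frame(pairs))
}
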