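## Plain-text I/O: CSV event logs, per-segment touch codes, wide-TSV fNIRS
## recordings with a JSON sidecar for montage/markers/looking.

#' Write / read coded event streams
#'
#' CSV columns: \code{actor}, \code{modality}, \code{code},
#' \code{onset_ms}, \code{offset_ms}.
#'
#' @param x an \linkS4class{EventStream}.
#' @param path file path.
#' @return \code{readEventStream} returns an \linkS4class{EventStream}.
#' @export
writeEventStream <- function(x, path) {
    ev <- events(x)
    utils::write.csv(cbind(actor = actor(x),
                           ev[, c("modality", "code", "onset_ms",
                                  "offset_ms")]),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEventStream
#' @export
readEventStream <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    EventStream(actor = d$actor[1], code = d$code, modality = d$modality,
                onset_ms = d$onset_ms, offset_ms = d$offset_ms)
}

#' Write / read gaze episodes
#'
#' CSV columns: \code{start_ms}, \code{end_ms}.
#'
#' @param x a \linkS4class{GazeEpisodes}.
#' @param path file path.
#' @return \code{readGazeEpisodes} returns a \linkS4class{GazeEpisodes}.
#' @export
writeGazeEpisodes <- function(x, path) {
    utils::write.csv(episodes(x), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGazeEpisodes
#' @export
readGazeEpisodes <- function(path) {
    d <- utils::read.csv(path)
    GazeEpisodes(d$start_ms, d$end_ms)
}

#' Read per-segment touch coding
#'
#' CSV columns: \code{segment_index} and \code{categories_present}, the
#' latter a \code{|}-separated list of touch categories observed in the
#' segment (empty = no touch). Each segment is resolved by the priority
#' rule (\code{\link{resolveSegment}}).
#'
#' @param path file path.
#' @param segment_s nominal segment length (default 2 s).
#' @param video_duration_s optional total video duration.
#' @return A \linkS4class{TouchRecord}.
#' @export
readTouchSegments <- function(path, segment_s = 2,
                              video_duration_s = NULL) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    d <- d[order(d$segment_index), ]
    codes <- vapply(d$categories_present, function(s) {
        cats <- strsplit(s, "|", fixed = TRUE)[[1]]
        resolveSegment(cats[nzchar(cats)])
    }, character(1), USE.NAMES = FALSE)
    TouchRecord(codes, segment_s = segment_s,
                video_duration_s = video_duration_s)
}

#' Write an fNIRS recording as wide TSV + JSON sidecar
#'
#' The TSV holds \code{time_s} plus one column per channel and wavelength
#' (\code{ch<k>_760}, \code{ch<k>_850}); the sidecar JSON
#' (\code{<path>.json}) holds sampling rate, montage, trial markers,
#' looking proportions and brush windows.
#'
#' @param rec a \linkS4class{NirsRecording}.
#' @param path TSV file path (sidecar written next to it).
#' @return \code{readNirsRecording} returns a \linkS4class{NirsRecording}.
#' @export
writeNirsRecording <- function(rec, path) {
    i760 <- SummarizedExperiment::assay(rec, "intensity760")
    i850 <- SummarizedExperiment::assay(rec, "intensity850")
    ch <- montage(rec)$channel
    d <- data.frame(time_s = timeAxis(rec), t(i760), t(i850))
    names(d) <- c("time_s", paste0("ch", ch, "_760"), paste0("ch", ch, "_850"))
    utils::write.table(d, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    side <- list(fs = samplingRate(rec), montage = montage(rec),
                 markers = trialMarkers(rec), looking = lookingTable(rec),
                 brush = metadata(rec)$brush)
    jsonlite::write_json(side, paste0(path, ".json"), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeNirsRecording
#' @param path TSV path written by \code{writeNirsRecording}.
#' @export
readNirsRecording <- function(path) {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    d <- utils::read.table(path, sep = "\t", header = TRUE)
    ch <- side$montage$channel
    i760 <- t(as.matrix(d[, paste0("ch", ch, "_760")]))
    i850 <- t(as.matrix(d[, paste0("ch", ch, "_850")]))
    NirsRecording(i760, i850, as.data.frame(side$montage),
                  fs = side$fs,
                  markers = as.data.frame(side$markers),
                  looking = if (!is.null(side$looking))
                      as.data.frame(side$looking) else NULL,
                  brush = if (!is.null(side$brush))
                      as.data.frame(side$brush) else NULL)
}

#' Write a contingency summary as JSON
#'
#' @param x a \linkS4class{ContingencySummary}.
#' @param path file path.
#' @export
writeContingencyJson <- function(x, path) {
    jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
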