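## Maternal touch: segment resolution by category priority, and duration
## proportions per category.

#' Resolve the touch code of one 2-s segment
#'
#' When several touch categories occur within a segment, the one earliest in
#' the priority enumeration (affective > harsh > playful > attention_getting
#' > instrumental > static > incidental) is coded; an empty set codes
#' \code{"none"}.
#'
#' @param present character vector (possibly empty) of categories observed in
#'   the segment, a subset of \code{\link{touchCategories}}.
#' @return a single code from \code{\link{touchCodes}}.
#' @examples
#' resolveSegment(c("instrumental", "affective"))  # "affective"
#' resolveSegment(character())                     # "none"
#' @export
resolveSegment <- function(present) {
    present <- unique(present)
    bad <- setdiff(present, touchCategories)
    if (length(bad))
        stop("unknown touch category: ", paste(bad, collapse = ", "))
    if (!length(present)) return("none")
    touchCategories[min(match(present, touchCategories))]
}

#' Aggregate touch codes into duration proportions
#'
#' Each coded segment is assumed touched for its whole duration (nominally
#' 2 s; a final partial segment counts its actual length). Per-category
#' duration is divided by the total video duration; \code{all_touch} sums the
#' seven touch categories, so together with the untouched proportion it
#' accounts for the full video when the segments tile it.
#'
#' @param x a \linkS4class{TouchRecord}.
#' @return named list: \code{proportions} (one entry per category, fractions
#'   of video duration), \code{all_touch}, \code{affective}, and
#'   \code{video_duration_s}.
#' @examples
#' r <- TouchRecord(rep(c("affective", "none"), c(90, 60)))
#' aggregateTouch(r)$all_touch   # 0.6
#' @export
aggregateTouch <- function(x) {
    stopifnot(is(x, "TouchRecord"))
    if (!length(x@codes)) stop("no coded segments")
    dur <- vapply(touchCategories, function(ct)
        sum(x@segment_durations_s[x@codes == ct]), numeric(1))
    prop <- dur / x@video_duration_s
    list(proportions = prop,
         all_touch = sum(prop),
         affective = unname(prop["affective"]),
         video_duration_s = x@video_duration_s)
}
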