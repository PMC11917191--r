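## Group-level statistics: time-bin averaging, two-way within-subject
## ANOVA, per-bin post-hoc t-tests, condition difference scores, and the
## maternal-predictor regressions.

#' Average epochs into post-stimulus time bins
#'
#' Averages the condition-averaged epoch of each ROI into \code{n_bins}
#' consecutive bins of \code{bin_s} seconds (default six 3-s bins spanning
#' the 18-s post-stimulus window).
#'
#' @param epochs an \linkS4class{EpochSet} (one subject), or a list of them
#'   (named by subject).
#' @param n_bins,bin_s binning scheme.
#' @param chromophore \code{"HbO"} (default) or \code{"HbR"}.
#' @return \code{data.frame} with \code{subject}, \code{roi},
#'   \code{chromophore}, \code{condition}, \code{bin}, \code{mean_uM}.
#' @export
binEpochs <- function(epochs, n_bins = 6, bin_s = 3, chromophore = "HbO") {
    if (is(epochs, "EpochSet")) epochs <- list(s1 = epochs)
    out <- list()
    for (subj in names(epochs)) {
        es <- epochs[[subj]]
        fs <- 1 / diff(es@time_s[1:2])
        need <- n_bins * bin_s
        if (max(es@time_s) + 1 / fs < need - 1e-9)
            stop("epoch shorter than ", need,
                 " s: rebuild epochs with epoch_s >= ", need)
        bin_of <- pmin(floor(es@time_s / bin_s) + 1, n_bins)
        sel <- es@time_s < need - 1e-9
        for (r in names(es@epochs)) for (cond in names(es@epochs[[r]])) {
            e <- es@epochs[[r]][[cond]]
            if (is.null(e)) next
            avg <- colMeans(e[[chromophore]])
            bm <- tapply(avg[sel], bin_of[sel], mean)
            out[[length(out) + 1]] <- data.frame(
                subject = subj, roi = r, chromophore = chromophore,
                condition = cond, bin = as.integer(names(bm)),
                mean_uM = as.numeric(bm))
        }
    }
    do.call(rbind, out)
}

#' Two-way within-subject (repeated-measures) ANOVA
#'
#' Condition (2 levels) and time bin (6 levels) as within-subject factors,
#' classical uncorrected degrees of freedom: each effect is tested against
#' its subject-by-effect interaction.
#'
#' @param bins a bin table from \code{\link{binEpochs}}, restricted to one
#'   ROI and chromophore (pass \code{roi =} to subset).
#' @param roi optional ROI to subset.
#' @return \code{data.frame} with rows \code{condition}, \code{bin},
#'   \code{condition:bin} and columns \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @export
rmAnova <- function(bins, roi = NULL) {
    if (!is.null(roi)) bins <- bins[bins$roi == roi, , drop = FALSE]
    bins <- bins[stats::complete.cases(bins), , drop = FALSE]
    ns <- length(unique(bins$subject))
    if (ns < 3) stop("need at least 3 subjects")
    ok <- stats::aggregate(mean_uM ~ subject, bins, length)
    if (length(unique(ok$mean_uM)) != 1)
        stop("incomplete within-subject design")
    d <- data.frame(y = bins$mean_uM, subject = factor(bins$subject),
                    condition = factor(bins$condition),
                    bin = factor(bins$bin))
    if (nlevels(d$bin) == 1) {
        # single bin: the design collapses to a paired comparison
        fit <- stats::aov(y ~ condition + Error(subject / condition),
                          data = d)
        tab <- summary(fit)[["Error: subject:condition"]][[1]]
        return(data.frame(effect = "condition", F = tab[1, "F value"],
                          df1 = tab[1, "Df"], df2 = tab[2, "Df"],
                          p = tab[1, "Pr(>F)"]))
    }
    fit <- stats::aov(y ~ condition * bin +
                          Error(subject / (condition * bin)), data = d)
    sm <- summary(fit)
    pull <- function(stratum, effect) {
        tab <- sm[[stratum]][[1]]
        i <- grep(effect, trimws(rownames(tab)), fixed = TRUE)[1]
        j <- grep("Residuals", trimws(rownames(tab)), fixed = TRUE)[1]
        data.frame(effect = effect, F = tab[i, "F value"],
                   df1 = tab[i, "Df"], df2 = tab[j, "Df"],
                   p = tab[i, "Pr(>F)"])
    }
    out <- rbind(pull("Error: subject:condition", "condition"),
                 pull("Error: subject:bin", "bin"),
                 pull("Error: subject:condition:bin", "condition:bin"))
    rownames(out) <- NULL
    out
}

#' Per-bin post-hoc paired t-tests
#'
#' Paired t-test (contingent vs. noncontingent) within each time bin.
#' Uncorrected p-values by default; set \code{adjust} for a correction.
#'
#' @param bins a bin table (one ROI/chromophore; use \code{roi =} to subset).
#' @param roi optional ROI to subset.
#' @param adjust p-adjustment method passed to \code{p.adjust}
#'   (default \code{"none"}).
#' @return \code{data.frame} with \code{bin}, \code{t}, \code{df}, \code{p},
#'   \code{p_adj}, \code{mean_diff_uM}.
#' @export
posthocBins <- function(bins, roi = NULL, adjust = "none") {
    if (!is.null(roi)) bins <- bins[bins$roi == roi, , drop = FALSE]
    res <- lapply(sort(unique(bins$bin)), function(b) {
        d <- bins[bins$bin == b, ]
        wide <- merge(d[d$condition == "contingent",
                        c("subject", "mean_uM")],
                      d[d$condition == "noncontingent",
                        c("subject", "mean_uM")], by = "subject")
        dif <- wide$mean_uM.x - wide$mean_uM.y
        if (stats::sd(dif) == 0) {
            warning("zero-variance difference in bin ", b,
                    ": t-test degenerate")
            return(data.frame(bin = b, t = NA_real_,
                              df = length(dif) - 1,
                              p = if (all(dif == 0)) 1 else 0,
                              mean_diff_uM = mean(dif)))
        }
        tt <- stats::t.test(dif)
        data.frame(bin = b, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   mean_diff_uM = mean(dif))
    })
    out <- do.call(rbind, res)
    out$p_adj <- stats::p.adjust(out$p, method = adjust)
    out
}

#' Condition difference scores
#'
#' Mean HbO over the whole post-stimulus window, contingent minus
#' noncontingent, per ROI. Negative values mean more activation in the
#' noncontingent condition.
#'
#' @param epochs an \linkS4class{EpochSet} (one subject) or list of them.
#' @param chromophore \code{"HbO"} (default) or \code{"HbR"}.
#' @return \code{data.frame} with \code{subject}, \code{roi},
#'   \code{diff_uM} (NA when a condition or the ROI is missing).
#' @export
diffScores <- function(epochs, chromophore = "HbO") {
    if (is(epochs, "EpochSet")) epochs <- list(s1 = epochs)
    out <- list()
    for (subj in names(epochs)) {
        es <- epochs[[subj]]
        for (r in es@rois) {
            e <- es@epochs[[r]]
            val <- NA_real_
            if (!is.null(e$contingent) && !is.null(e$noncontingent))
                val <- mean(colMeans(e$contingent[[chromophore]])) -
                    mean(colMeans(e$noncontingent[[chromophore]]))
            out[[length(out) + 1]] <- data.frame(subject = subj, roi = r,
                                                 diff_uM = val)
        }
    }
    do.call(rbind, out)
}

#' Per-condition mean activation
#'
#' Mean HbO over the post-stimulus window for each condition separately
#' (the quantities behind the post-hoc condition-wise regressions).
#'
#' @inheritParams diffScores
#' @return \code{data.frame} with \code{subject}, \code{roi},
#'   \code{condition}, \code{mean_uM}.
#' @export
conditionMeans <- function(epochs, chromophore = "HbO") {
    if (is(epochs, "EpochSet")) epochs <- list(s1 = epochs)
    out <- list()
    for (subj in names(epochs)) {
        es <- epochs[[subj]]
        for (r in es@rois) for (cond in names(es@epochs[[r]])) {
            e <- es@epochs[[r]][[cond]]
            if (is.null(e)) next
            out[[length(out) + 1]] <- data.frame(
                subject = subj, roi = r, condition = cond,
                mean_uM = mean(colMeans(e[[chromophore]])))
        }
    }
    do.call(rbind, out)
}

regressionFormula <- stats::as.formula(
    "outcome ~ all_touch + affective_touch + sensitivity + contingency + age_days")

#' Maternal-predictor regression on ROI activation
#'
#' Ordinary least squares of a per-dyad outcome (by default the
#' contingent-minus-noncontingent difference score of one ROI) on the five
#' maternal/infant predictors: overall touch proportion, affective-touch
#' proportion, maternal sensitivity, the contingency responsiveness index
#' and infant age. Listwise deletion of incomplete rows.
#'
#' @param rows \code{data.frame} with columns \code{all_touch},
#'   \code{affective_touch}, \code{sensitivity}, \code{contingency},
#'   \code{age_days} and the outcome columns (\code{diff_left},
#'   \code{diff_right}, ...).
#' @param outcome name of the outcome column (e.g. \code{"diff_right"}).
#' @param min_rows minimum complete rows required (default 10).
#' @return list with \code{coefficients} (Estimate, SE, CI, t, p),
#'   \code{F}, \code{df}, \code{p}, \code{adj_r_squared}, \code{n} and the
#'   underlying \code{lm} fit.
#' @export
fitRegression <- function(rows, outcome, min_rows = 10) {
    preds <- c("all_touch", "affective_touch", "sensitivity", "contingency",
               "age_days")
    stopifnot(all(c(preds, outcome) %in% names(rows)))
    d <- rows[, c(preds, outcome)]
    names(d)[ncol(d)] <- "outcome"
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) < min_rows)
        stop("fewer than ", min_rows, " complete rows")
    X <- stats::model.matrix(regressionFormula, d)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[-seq_len(qrX$rank)]
        stop("rank-deficient design; collinear predictor(s): ",
             paste(dropped, collapse = ", "))
    }
    fit <- stats::lm(regressionFormula, data = d)
    sm <- summary(fit)
    ci <- stats::confint(fit)
    co <- data.frame(term = rownames(sm$coefficients),
                     estimate = sm$coefficients[, 1],
                     se = sm$coefficients[, 2],
                     ci_lo = ci[, 1], ci_hi = ci[, 2],
                     t = sm$coefficients[, 3],
                     p = sm$coefficients[, 4], row.names = NULL)
    fstat <- sm$fstatistic
    list(coefficients = co,
         F = unname(fstat[1]), df = unname(fstat[2:3]),
         p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
         adj_r_squared = sm$adj.r.squared, n = nrow(d), fit = fit)
}

#' Post-hoc condition-wise regressions
#'
#' The same OLS model fitted separately to each condition's mean activation
#' instead of the difference score.
#'
#' @param rows predictor table as in \code{\link{fitRegression}}.
#' @param activations \code{data.frame} from \code{\link{conditionMeans}}
#'   for one ROI, with a \code{subject} column matching
#'   \code{rows$subject}.
#' @param min_rows minimum complete rows (default 10).
#' @return named list of two \code{\link{fitRegression}} results
#'   (\code{contingent}, \code{noncontingent}).
#' @export
posthocConditionRegressions <- function(rows, activations, min_rows = 10) {
    out <- list()
    for (cond in c("contingent", "noncontingent")) {
        a <- activations[activations$condition == cond,
                         c("subject", "mean_uM")]
        m <- merge(rows, a, by = "subject")
        names(m)[names(m) == "mean_uM"] <- "cond_mean"
        out[[cond]] <- fitRegression(m, "cond_mean", min_rows = min_rows)
    }
    out
}
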