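## End-to-end orchestration: simulate a study of dyads, score behavior,
## preprocess fNIRS, and run the group statistics, with a reproducible
## manifest.

#' ROI-only montage
#'
#' The subset of \code{\link{defaultMontage}} restricted to the eight
#' bilateral pSTS ROI channels; useful for simulation studies where the
#' non-ROI channels carry no signal of interest.
#'
#' @param distance_mm source-detector distance (default 22.5).
#' @return montage \code{data.frame} with 8 rows.
#' @export
roiMontage <- function(distance_mm = 22.5) {
    m <- defaultMontage(distance_mm)
    rois <- roiDefinition()
    m[m$channel %in% c(rois$left, rois$right), , drop = FALSE]
}

#' Simulate a full dyadic study with known ground truth
#'
#' Generates \code{n_dyads} dyads. Per dyad: maternal covariates
#' (sensitivity, touch profile, response probability, infant age), a coded
#' interaction scored with \code{\link{contingencyPipeline}}, a touch
#' record aggregated with \code{\link{aggregateTouch}}, and a block-design
#' fNIRS recording preprocessed with \code{\link{preprocessNirs}}. The
#' noncontingent HbO amplitude is attenuated by standardized maternal
#' sensitivity and overall touch (\code{beta_sensitivity},
#' \code{beta_touch}, in uMol per SD), which induces the dependence of the
#' difference score on those predictors that the regression should detect.
#'
#' @param n_dyads number of dyads.
#' @param seed RNG seed (each dyad derives its own sub-seeds).
#' @param beta_sensitivity,beta_touch attenuation of the noncontingent
#'   amplitude per SD of the predictor (uMol; defaults 0.15).
#' @param amp_contingent,amp_noncontingent_base named vectors
#'   (\code{left}, \code{right}) of HbO peak amplitudes (uMol).
#' @param montage montage used for the simulated recordings (default
#'   \code{\link{roiMontage}()} — the channels the analysis uses).
#' @param nirs_overrides named list of \linkS4class{NirsSimConfig} slot
#'   overrides applied to every dyad (e.g. \code{list(white_uM = 0)}).
#' @param behavioral include the behavioral simulation (default TRUE;
#'   turning it off leaves covariates at their generating values only).
#' @return list with \code{rows} (one \code{data.frame} row per dyad:
#'   covariates, responsiveness index, \code{diff_left}, \code{diff_right},
#'   inclusion flag), \code{epochs} (list of \linkS4class{EpochSet}s of
#'   included dyads), \code{condition_means} and \code{truth} (generating
#'   parameters per dyad).
#' @export
simulateStudy <- function(n_dyads = 30, seed = 1,
                          beta_sensitivity = 0.15, beta_touch = 0.15,
                          amp_contingent = c(left = 0.30, right = 0.30),
                          amp_noncontingent_base = c(left = 0.39,
                                                     right = 0.45),
                          montage = roiMontage(),
                          nirs_overrides = list(),
                          behavioral = TRUE) {
    set.seed(seed)
    seeds <- sample.int(2^31 - 1, n_dyads * 3)
    rows <- list(); epochs <- list(); cmeans <- list(); truth <- list()
    for (i in seq_len(n_dyads)) {
        sens <- pmin(7, pmax(1, round(stats::rnorm(1, 5, 1.2))))
        p_touch <- stats::rbeta(1, 2.5, 2.5)
        f_aff <- stats::rbeta(1, 2, 5)
        resp_p <- stats::rbeta(1, 4, 2)
        age <- round(stats::rnorm(1, 180, 12))

        probs <- c(affective = p_touch * f_aff,
                   playful = p_touch * (1 - f_aff) * 0.3,
                   instrumental = p_touch * (1 - f_aff) * 0.5,
                   static = p_touch * (1 - f_aff) * 0.2,
                   none = 1 - p_touch)
        touch <- aggregateTouch(simulateTouch(150, probs,
                                              seed = seeds[3 * i - 2]))

        contingency <- NA_real_
        if (behavioral) {
            dy <- simulateDyad(dyadSimConfig(duration_ms = 300000,
                                             response_prob = resp_p,
                                             seed = seeds[3 * i - 1]))
            contingency <- tryCatch(
                respIndex(contingencyPipeline(dy$mother, dy$infant, dy$gaze,
                                              session_ms = 300000)),
                error = function(e) NA_real_)
        }

        ## standardize by the generating distributions (not the sample)
        z_sens <- (sens - 5) / 1.2
        z_touch <- (touch$all_touch - 0.5) / sqrt(0.25 / 6)  # Beta(2.5,2.5) SD
        amp_nc <- pmax(amp_noncontingent_base -
                           beta_sensitivity * z_sens -
                           beta_touch * z_touch, 0)
        amp <- matrix(c(amp_contingent["left"], amp_contingent["right"],
                        amp_nc["left"], amp_nc["right"]), 2, 2,
                      byrow = TRUE,
                      dimnames = list(c("contingent", "noncontingent"),
                                      c("left", "right")))
        args <- c(list(amplitude_uM = amp, seed = seeds[3 * i]),
                  nirs_overrides)
        cfg <- do.call(nirsSimConfig, args)
        rec <- simulateNirs(cfg, montage = montage)
        pp <- preprocessNirs(rec)

        dl <- dr <- NA_real_
        if (pp$included) {
            ds <- diffScores(pp$epochs)
            dl <- ds$diff_uM[ds$roi == "left"]
            dr <- ds$diff_uM[ds$roi == "right"]
            epochs[[paste0("dyad", i)]] <- pp$epochs
            cm <- conditionMeans(pp$epochs)
            cm$subject <- paste0("dyad", i)
            cmeans[[i]] <- cm
        }
        rows[[i]] <- data.frame(subject = paste0("dyad", i),
                                all_touch = touch$all_touch,
                                affective_touch = touch$affective,
                                sensitivity = sens,
                                contingency = contingency,
                                age_days = age,
                                diff_left = dl, diff_right = dr,
                                included = pp$included)
        truth[[i]] <- data.frame(subject = paste0("dyad", i),
                                 response_prob = resp_p,
                                 amp_nc_left = amp_nc["left"],
                                 amp_nc_right = amp_nc["right"],
                                 row.names = NULL)
    }
    list(rows = do.call(rbind, rows), epochs = epochs,
         condition_means = do.call(rbind, cmeans),
         truth = do.call(rbind, truth))
}

#' Default pipeline configuration
#'
#' Every stage parameter with its default, as a nested list; suitable for
#' serialization to YAML and for \code{\link{runPipeline}}.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
    list(seed = 1,
         simulate = list(n_dyads = 12),
         contingency = list(window_ms = 1000, warmup_ms = 60000,
                            coded_ms = 240000),
         touch = list(segment_s = 2),
         preproc = list(dpf = 5.1, bandpass_hz = c(0.01, 1),
                        motion_sd = 14, motion_amp_od = 0.4,
                        wavelet_iqr = 0.5, min_trials = 3, epoch_s = 18,
                        baseline_ref_s = 3),
         stats = list(n_bins = 6, bin_s = 3, min_rows = 10))
}

checkConfigKeys <- function(config, reference = defaultConfig(),
                            path = "config") {
    extra <- setdiff(names(config), names(reference))
    if (length(extra))
        stop("unknown ", path, " key(s): ", paste(extra, collapse = ", "))
    for (k in names(config))
        if (is.list(reference[[k]]) && is.list(config[[k]]))
            checkConfigKeys(config[[k]], reference[[k]],
                            paste0(path, "$", k))
    invisible(TRUE)
}

mergeConfig <- function(user, reference) {
    for (k in names(user)) {
        if (is.list(reference[[k]]) && is.list(user[[k]]))
            reference[[k]] <- mergeConfig(user[[k]], reference[[k]])
        else reference[[k]] <- user[[k]]
    }
    reference
}

#' Run the whole pipeline on a simulated study
#'
#' Simulates a study under \code{config}, scores contingency and touch,
#' preprocesses every recording, runs the time-bin ANOVA and the
#' difference-score regression (when enough dyads survive), and writes
#' JSON reports plus a run manifest into \code{out_dir}. Fully
#' reproducible from \code{config$seed}.
#'
#' @param config nested list as from \code{\link{defaultConfig}} (partial
#'   lists are merged over the defaults; unknown keys are rejected), or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @return list with \code{study} (see \code{\link{simulateStudy}}),
#'   \code{anova} per ROI, \code{regression} per ROI (or \code{NULL}),
#'   and \code{manifest}.
#' @export
runPipeline <- function(config = defaultConfig(), out_dir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    checkConfigKeys(config)
    config <- mergeConfig(config, defaultConfig())
    study <- simulateStudy(n_dyads = config$simulate$n_dyads,
                           seed = config$seed)
    rows <- study$rows
    bins <- if (length(study$epochs))
        binEpochs(study$epochs, n_bins = config$stats$n_bins,
                  bin_s = config$stats$bin_s)
    else NULL
    anova <- list(); regression <- list()
    for (r in c("left", "right")) {
        rb <- if (is.null(bins)) NULL
              else bins[bins$roi == r & !is.na(bins$mean_uM), , drop = FALSE]
        anova[[r]] <- tryCatch(rmAnova(rb), error = function(e) NULL)
        outcome <- paste0("diff_", r)
        regression[[r]] <- tryCatch(
            fitRegression(rows, outcome, min_rows = config$stats$min_rows),
            error = function(e) NULL)
    }
    manifest <- list(config = config,
                     n_dyads = nrow(rows),
                     n_included = sum(rows$included),
                     package_version =
                         as.character(utils::packageVersion("dyadnirs")))
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        utils::write.csv(rows, file.path(out_dir, "dyad_rows.csv"),
                         row.names = FALSE)
        reg_out <- lapply(regression, function(x)
            if (is.null(x)) NULL else x[c("coefficients", "F", "df", "p",
                                          "adj_r_squared", "n")])
        jsonlite::write_json(list(anova = anova, regression = reg_out),
                             file.path(out_dir, "stats.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA, force = TRUE)
    }
    list(study = study, anova = anova, regression = regression,
         manifest = manifest)
}
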