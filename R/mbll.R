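## Modified Beer-Lambert law: optical density <-> chromophore concentration.
## Natural-log OD convention throughout; concentrations in uMol.

#' Hemoglobin extinction coefficients
#'
#' Base-10 molar extinction coefficients (cm^-1 M^-1) for oxy- and
#' deoxyhemoglobin at the two measurement wavelengths, from the standard
#' Prahl compilation. Internally rescaled by \code{ln(10)} because optical
#' density is computed with the natural logarithm.
#'
#' @param wavelengths numeric, must be \code{c(760, 850)} for the shipped
#'   table; a custom 2x2 matrix (rows = wavelengths, cols = HbO/HbR) may be
#'   supplied to downstream functions instead.
#' @return 2x2 matrix, rows \code{"760"}/\code{"850"}, columns
#'   \code{"HbO"}/\code{"HbR"}, in cm^-1 M^-1 (base 10).
#' @export
extinctionCoefficients <- function(wavelengths = c(760, 850)) {
    tab <- matrix(c(586, 1548.52,
                    1058, 691.32),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("760", "850"), c("HbO", "HbR")))
    key <- as.character(wavelengths)
    if (!all(key %in% rownames(tab)))
        stop("extinction table shipped for 760/850 nm only")
    tab[key, , drop = FALSE]
}

## per-channel 2x2 system matrix K (ln-OD per uMol), rows = wavelengths
mbllSystemMatrix <- function(distance_mm, dpf = 5.1,
                             extinction = extinctionCoefficients()) {
    # cm^-1 M^-1 (base10) -> ln-units per uMol per cm, times pathlength
    extinction * log(10) * 1e-6 * (distance_mm / 10) * dpf
}

#' Convert optical density to HbO/HbR concentration
#'
#' Solves the modified Beer-Lambert 2x2 system per channel:
#' \eqn{\Delta OD_\lambda = (\epsilon_{HbO,\lambda}\Delta HbO +
#' \epsilon_{HbR,\lambda}\Delta HbR) \cdot d \cdot DPF}. Because OD is
#' referenced to the channel's mean intensity, the recovered concentrations
#' are changes about an arbitrary per-channel baseline.
#'
#' @param od760,od850 channels x time OD matrices (natural-log units).
#' @param montage montage \code{data.frame} with \code{distance_mm}.
#' @param dpf differential pathlength factor (default 5.1).
#' @param extinction base-10 extinction matrix as returned by
#'   \code{\link{extinctionCoefficients}}.
#' @return list with \code{HbO} and \code{HbR} channels x time matrices
#'   (uMol).
#' @export
odToConcentration <- function(od760, od850, montage, dpf = 5.1,
                              extinction = extinctionCoefficients()) {
    stopifnot(all(dim(od760) == dim(od850)),
              nrow(od760) == nrow(montage))
    HbO <- HbR <- matrix(NA_real_, nrow(od760), ncol(od760),
                         dimnames = dimnames(od760))
    for (ch in seq_len(nrow(od760))) {
        K <- mbllSystemMatrix(montage$distance_mm[ch], dpf, extinction)
        if (abs(det(K)) < .Machine$double.eps)
            stop("singular extinction system for channel ", ch)
        conc <- solve(K, rbind(od760[ch, ], od850[ch, ]))
        HbO[ch, ] <- conc[1, ]
        HbR[ch, ] <- conc[2, ]
    }
    list(HbO = HbO, HbR = HbR)
}

#' Forward-project concentrations to optical density
#'
#' The exact inverse companion of \code{\link{odToConcentration}}: maps
#' HbO/HbR concentration changes (uMol) to natural-log optical density at
#' both wavelengths. Used by the simulator so that simulation and recovery
#' share one optical model.
#'
#' @param HbO,HbR channels x time concentration matrices (uMol).
#' @inheritParams odToConcentration
#' @return list with \code{od760} and \code{od850} matrices.
#' @export
concentrationToOd <- function(HbO, HbR, montage, dpf = 5.1,
                              extinction = extinctionCoefficients()) {
    stopifnot(all(dim(HbO) == dim(HbR)), nrow(HbO) == nrow(montage))
    od760 <- od850 <- matrix(NA_real_, nrow(HbO), ncol(HbO),
                             dimnames = dimnames(HbO))
    for (ch in seq_len(nrow(HbO))) {
        K <- mbllSystemMatrix(montage$distance_mm[ch], dpf, extinction)
        od <- K %*% rbind(HbO[ch, ], HbR[ch, ])
        od760[ch, ] <- od[1, ]
        od850[ch, ] <- od[2, ]
    }
    list(od760 = od760, od850 = od850)
}
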