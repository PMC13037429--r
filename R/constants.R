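#' Packaged physical and physiological constants
#'
#' Default tissue optical properties, hemoglobin extinction coefficients and
#' glycemic classification thresholds used throughout the pipeline. All are
#' overridable through the function arguments that consume them.
#'
#' @details
#' Extinction coefficients are base-10 molar extinction values (Prahl /
#' Gratzer compilation) converted to mm^-1 per micromolar. The modified
#' Beer-Lambert conversion to an absorption coefficient multiplies by
#' ln(10), which the code does explicitly where concentrations are turned
#' into \eqn{\Delta\mu_a}.
#'
#' @name glucodot-constants
NULL

# base-10 extinction, mm^-1 / uM, rows = wavelength, cols = c(HbO, HbR)
# 780 nm: HbO 710, HbR 1075.4  (cm^-1 / M); 850 nm: HbO 1058, HbR 691.3
.ext_table <- matrix(
  c(710, 1075.4,
    1058, 691.3) * 1e-7,
  nrow = 2, byrow = TRUE,
  dimnames = list(c("780", "850"), c("HbO", "HbR"))
)

#' Default extinction coefficient matrix
#'
#' @param wavelengths numeric vector of wavelengths in nm (must be a subset
#'   of the packaged table, default c(780, 850)).
#' @return 2x2 matrix, rows = wavelengths, columns = c(HbO, HbR), units
#'   mm^-1 per uM (base-10 convention; multiply by ln(10) for mu_a).
#' @export
extinction_defaults <- function(wavelengths = c(780, 850)) {
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(.ext_table)))
    stop("no packaged extinction values for wavelength(s): ",
         paste(setdiff(key, rownames(.ext_table)), collapse = ", "))
  .ext_table[key, , drop = FALSE]
}

# default bulk optical properties of neonatal head tissue, per mm
.optical_defaults <- list(mua = 0.01, musp = 1.0)

# glycemic thresholds (mg/dL). Printed bounds leave 47-48 and 179-180
# unassigned; the half-open completion below preserves every printed strict
# inequality: S_hypo (0,47), m_hypo [47,72), euglycemia [72,144],
# m_hyper (144,180], S_hyper (180,Inf).
.glycemic_defaults <- list(
  eu_lo = 72, eu_hi = 144,
  s_hypo_hi = 47,   # sgc <  47 -> S_hypo; [47, 72) -> m_hypo
  s_hyper_lo = 180  # sgc > 180 -> S_hyper; (144, 180] -> m_hyper
)

# Daubechies-5 orthogonal analysis filters (standard published taps)
.db5_dec_lo <- c(
  0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
  0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
  0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
  0.16010239797419293)
.db5_dec_hi <- c(
  -0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
  0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
  -0.07757149384004572, -0.006241490212798274, 0.012580751999081999,
  0.0033357252854737712)

# canonical unit-sphere 10-20 landmark coordinates (x = right, y = anterior,
# z = superior), normalized exactly; the nine ROI centers of the
# frontal-to-parietal montage
.norm_rows <- function(m) m / sqrt(rowSums(m^2))

.landmark_unit <- local({
  m <- rbind(
    F3 = c(-0.5450,  0.6730, 0.5000),
    FZ = c( 0.0000,  0.5878, 0.8090),
    F4 = c( 0.5450,  0.6730, 0.5000),
    C3 = c(-0.5878,  0.0000, 0.8090),
    CZ = c( 0.0000,  0.0000, 1.0000),
    C4 = c( 0.5878,  0.0000, 0.8090),
    P3 = c(-0.5450, -0.6730, 0.5000),
    PZ = c( 0.0000, -0.5878, 0.8090),
    P4 = c( 0.5450, -0.6730, 0.5000))
  colnames(m) <- c("x", "y", "z")
  .norm_rows(m)
})

# approximate 10-5 optode positions as normalized blends of 10-20 anchors;
# the montage: 8 sources FC3,FCz,FC4,CP3,CPz,CP4,PO5h,PO6h and
# 8 detectors F1,F2,CCP5,C1,C2,CCP6,P1,P2 (frontal-to-parietal coverage)
.optode_unit <- local({
  L <- .landmark_unit
  C5 <- c(-0.8090, 0.0000, 0.5878)
  C6 <- c( 0.8090, 0.0000, 0.5878)
  O1 <- c(-0.3090, -0.9511, 0.0000)
  O2 <- c( 0.3090, -0.9511, 0.0000)
  src <- rbind(
    FC3  = L["F3", ] + L["C3", ],
    FCz  = L["FZ", ] + L["CZ", ],
    FC4  = L["F4", ] + L["C4", ],
    CP3  = L["C3", ] + L["P3", ],
    CPz  = L["CZ", ] + L["PZ", ],
    CP4  = L["C4", ] + L["P4", ],
    PO5h = 0.6 * L["P3", ] + 0.4 * O1,
    PO6h = 0.6 * L["P4", ] + 0.4 * O2)
  det <- rbind(
    F1   = L["FZ", ] + L["F3", ],
    F2   = L["FZ", ] + L["F4", ],
    CCP5 = 0.7 * C5 + 0.3 * L["P3", ],
    C1   = L["CZ", ] + L["C3", ],
    C2   = L["CZ", ] + L["C4", ],
    CCP6 = 0.7 * C6 + 0.3 * L["P4", ],
    P1   = L["PZ", ] + L["P3", ],
    P2   = L["PZ", ] + L["P4", ])
  list(sources = .norm_rows(src), detectors = .norm_rows(det))
})
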