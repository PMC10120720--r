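#' Radiotracer specification
#'
#' Radiochemical constants needed to convert scintillation counts (DPM,
#' disintegrations per minute) into molar amounts of total analyte. The
#' analyte is only partially labeled: `labeled_fraction` is the mole fraction
#' of tracer in the total pool. 1 Ci = 2.22e12 DPM is a fixed physical
#' constant.
#'
#' The default `labeled_fraction = 0.05` corresponds to the target of 5
#' percent tritiated retinol in the working solutions; a strict 1:20 tracer:unlabeled
#' mixing ratio gives 1/21 (~0.0476) instead, so the field is configurable
#' when the actual measured ratio is known.
#'
#' @param specific_activity Ci per mmol of labeled compound (default 30, the
#'   supplier value for \[15-3H(N)\]-retinol).
#' @param labeled_fraction Mole fraction of labeled analyte in (0, 1].
#' @return Object of class `"tracer_spec"`.
#' @examples
#' tracer_spec()                          # 3H-retinol defaults
#' tracer_spec(30, labeled_fraction = 1)  # fully labeled tracer
#' @export
tracer_spec <- function(specific_activity = 30, labeled_fraction = 0.05) {
  if (!is.numeric(specific_activity) || length(specific_activity) != 1L ||
      is.na(specific_activity) || specific_activity <= 0)
    stop("specific_activity must be > 0 Ci/mmol", call. = FALSE)
  if (!is.numeric(labeled_fraction) || length(labeled_fraction) != 1L ||
      is.na(labeled_fraction) || labeled_fraction <= 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in (0, 1]", call. = FALSE)
  structure(list(specific_activity = specific_activity,
                 labeled_fraction = labeled_fraction,
                 dpm_per_ci = 2.22e12),
            class = "tracer_spec")
}

#' Cell geometry for cell-volume based concentration estimates
#'
#' @param area Mean area of one cell, um^2 (default 402, measured for BMECs).
#' @param height Mean cell height, um (default 3.4).
#' @param n_cells Number of cells in the well or insert. No default: absolute
#'   cellular concentrations depend on it, and it must be an explicit choice
#'   (e.g. seeding density x growth area).
#' @return Object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(area = 402, height = 3.4, n_cells = NULL) {
  if (!is.numeric(area) || area < 0 || !is.numeric(height) || height < 0)
    stop("area and height must be >= 0", call. = FALSE)
  if (!is.null(n_cells)) {
    if (!is.numeric(n_cells) || length(n_cells) != 1L || is.na(n_cells) ||
        n_cells < 0 || n_cells != round(n_cells))
      stop("n_cells must be a non-negative integer", call. = FALSE)
  }
  structure(list(area = area, height = height, n_cells = n_cells),
            class = "cell_geometry")
}

#' Volume of a single cell
#'
#' Area x height, converted from um^3 to litres (1 um^3 = 1e-15 L). The
#' default BMEC geometry (402 um^2 x 3.4 um) gives 1.37e-12 L/cell.
#'
#' @param geometry A [cell_geometry()].
#' @return Volume in L per cell.
#' @examples
#' cell_volume(cell_geometry(402, 3.4))
#' @export
cell_volume <- function(geometry = cell_geometry()) {
  stopifnot(inherits(geometry, "cell_geometry"))
  geometry$area * geometry$height * 1e-15
}

#' Convert DPM to total analyte amount
#'
#' Labeled mol = DPM / (2.22e12 DPM/Ci x specific activity Ci/mmol) / 1000;
#' total mol = labeled mol / labeled fraction. Vectorised in `dpm`.
#'
#' @param dpm Disintegrations per minute (>= 0).
#' @param tracer A [tracer_spec()].
#' @return Total analyte amount, mol.
#' @examples
#' dpm_to_total_amount(6.66e4, tracer_spec(30, 0.05))  # 2e-11 mol
#' @export
dpm_to_total_amount <- function(dpm, tracer = tracer_spec()) {
  stopifnot(inherits(tracer, "tracer_spec"))
  if (any(dpm < 0, na.rm = TRUE)) stop("dpm must be >= 0", call. = FALSE)
  labeled_mmol <- dpm / (tracer$dpm_per_ci * tracer$specific_activity)
  labeled_mmol / 1000 / tracer$labeled_fraction
}

#' Convert a total analyte amount to DPM (simulator inverse)
#'
#' Exact inverse of [dpm_to_total_amount()]; used by the synthetic-data
#' generator to express noiseless concentrations at the counting level before
#' applying counting noise.
#'
#' @param amount_mol Total analyte amount, mol.
#' @param tracer A [tracer_spec()].
#' @return DPM.
#' @export
amount_to_dpm <- function(amount_mol, tracer = tracer_spec()) {
  stopifnot(inherits(tracer, "tracer_spec"))
  amount_mol * tracer$labeled_fraction * 1000 *
    tracer$dpm_per_ci * tracer$specific_activity
}

#' Cellular concentration from lysate DPM
#'
#' Total analyte amount divided by the total cell volume of the monolayer
#' (`n_cells` x single-cell volume), reported in uM. The result inherits the
#' `n_cells` assumption; it is an estimate of mean concentration over the
#' whole cell volume, not a measure of internalised versus membrane-bound
#' material.
#'
#' @param dpm Lysate DPM.
#' @param tracer A [tracer_spec()].
#' @param geometry A [cell_geometry()] with `n_cells` set (> 0).
#' @return Concentration, uM.
#' @export
cellular_concentration <- function(dpm, tracer = tracer_spec(),
                                   geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (is.null(geometry$n_cells) || geometry$n_cells <= 0)
    stop("geometry$n_cells must be set and > 0", call. = FALSE)
  v <- cell_volume(geometry) * geometry$n_cells
  if (v <= 0) stop("total cell volume is zero", call. = FALSE)
  dpm_to_total_amount(dpm, tracer) / v * 1e6   # mol/L -> uM
}

#' Chamber concentration from fluid DPM
#'
#' @param dpm Sample-scaled DPM attributable to the chamber fluid.
#' @param tracer A [tracer_spec()].
#' @param volume Chamber fluid volume, L (> 0).
#' @return Concentration, uM.
#' @export
chamber_concentration <- function(dpm, tracer = tracer_spec(), volume) {
  if (!is.numeric(volume) || length(volume) != 1L || is.na(volume) ||
      volume <= 0)
    stop("volume must be > 0 L", call. = FALSE)
  dpm_to_total_amount(dpm, tracer) / volume * 1e6
}

#' Area-corrected transendothelial electrical resistance
#'
#' TEER readings in ohm are multiplied by the insert membrane area to give the
#' standard ohm.cm^2 barrier-tightness readout.
#'
#' @param resistance Resistance reading, ohm (>= 0).
#' @param area Membrane area, cm^2 (default 1.12, the 12-well Transwell).
#' @return TEER, ohm.cm^2.
#' @export
teer_area_corrected <- function(resistance, area = 1.12) {
  if (any(resistance < 0) || any(area < 0))
    stop("resistance and area must be >= 0", call. = FALSE)
  resistance * area
}
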