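# Unit conversion between the model's cell-normalized amounts and media
# concentrations. The kinetic core is geometry-free; everything that depends
# on how many cells conditioned how much medium lives here.

AVOGADRO <- 6.02214076e23

#' Experiment geometry
#'
#' The constants linking molecules/cell to a media concentration: how many
#' cells conditioned the medium, its volume, and the protein's molecular
#' weight (sFLT1 runs at roughly 90-110 kDa depending on glycoform; the
#' default is 100 kDa and should be set explicitly for quantitative work).
#'
#' @param n_cells Number of cells conditioning the medium.
#' @param media_volume_ml Media volume, mL.
#' @param molecular_weight_g_per_mol Protein molecular weight, g/mol.
#' @return An object of class `sflt_geometry`.
#' @export
sflt_geometry <- function(n_cells, media_volume_ml,
                          molecular_weight_g_per_mol = 1e5) {
  vals <- c(n_cells = n_cells, media_volume_ml = media_volume_ml,
            molecular_weight_g_per_mol = molecular_weight_g_per_mol)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("geometry values (n_cells, media_volume_ml, ",
         "molecular_weight_g_per_mol) must all be > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "sflt_geometry")
}

#' Convert cell-normalized amounts to media concentration
#'
#' `ng/mL = molecules_per_cell * n_cells / (N_A * volume_mL) * MW * 1e9`.
#'
#' @param amount Amount, molecules/cell (vectorised). Must be >= 0.
#' @param geometry An [sflt_geometry()].
#' @return Concentration, ng/mL.
#' @export
molecules_per_cell_to_ng_per_ml <- function(amount, geometry) {
  stopifnot(inherits(geometry, "sflt_geometry"))
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  amount * geometry$n_cells / (AVOGADRO * geometry$media_volume_ml) *
    geometry$molecular_weight_g_per_mol * 1e9
}

#' Convert media concentration to cell-normalized amount
#'
#' Exact inverse of [molecules_per_cell_to_ng_per_ml()].
#'
#' @param conc Concentration, ng/mL (vectorised). Must be >= 0.
#' @param geometry An [sflt_geometry()].
#' @return Amount, molecules/cell.
#' @export
concentration_to_molecules <- function(conc, geometry) {
  stopifnot(inherits(geometry, "sflt_geometry"))
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  conc / 1e9 / geometry$molecular_weight_g_per_mol *
    (AVOGADRO * geometry$media_volume_ml) / geometry$n_cells
}
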