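# Solvent-accessible surface areas (Shrake-Rupley) and buried surface area.

#' Surface calculation parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_sphere_points quadrature density of the golden-section spiral
#'   point set per atom (default 960; must be >= 32).
#' @param exposure_epsilon per-atom area (Angstrom^2) strictly above which
#'   an atom counts as solvent exposed (default 0: any accessible area).
#' @return list of class `surface_params`.
#' @export
surface_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                           exposure_epsilon = 0) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 32, exposure_epsilon >= 0)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 exposure_epsilon = exposure_epsilon),
            class = "surface_params")
}

#' Solvent-accessible surface area of a structure
#'
#' Shrake-Rupley quadrature: each atom sphere is inflated by the probe
#' radius and sampled with a deterministic golden-section spiral point
#' set; points falling inside any neighbouring inflated sphere are
#' inaccessible.  Deterministic for a fixed point count.
#'
#' @param structure a `pp_structure`, hydrogens stripped, radii assigned.
#' @param params a [surface_params()].
#' @return list of class `sasa_result` with `atom_area` (Angstrom^2 per
#'   atom), `residue_area` (named by `chain:resid:icode` key, ordered by
#'   first occurrence) and `total`.
#' @export
compute_sasa <- function(structure, params = surface_params()) {
  r <- structure$atoms$radius
  if (anyNA(r)) stop("assign radii before computing SASA")
  if (any(structure$atoms$element %in% c("H", "D")))
    stop("strip hydrogens before computing SASA")
  area <- sasa_shrake_rupley(structure$xyz, r, params$probe_radius,
                             params$n_sphere_points)
  keys <- residue_keys(structure)
  res_area <- rowsum(area, group = factor(keys, levels = unique(keys)))
  structure(list(atom_area = as.numeric(area),
                 residue_area = setNames(as.numeric(res_area),
                                         rownames(res_area)),
                 total = sum(area)),
            class = "sasa_result")
}

#' Indices of solvent-exposed atoms
#'
#' @param sasa a `sasa_result`.
#' @param params a [surface_params()]; exposure uses a strict `>` against
#'   `exposure_epsilon`.
#' @return integer vector of exposed atom indices.
#' @export
exposed_atoms <- function(sasa, params = surface_params()) {
  which(sasa$atom_area > params$exposure_epsilon)
}

#' Buried surface area of a binder pair
#'
#' BSA = SASA(binder A alone, frozen conformation) + SASA(binder B alone)
#' - SASA(complex), all under the same accessible-surface model.  Small
#' negative quadrature residues (|value| < tol) are clamped to zero.
#'
#' @param structure a `pp_structure` (heavy atoms, radii assigned).
#' @param split a [binder_split()].
#' @param params a [surface_params()].
#' @param tol clamp tolerance in Angstrom^2.
#' @return BSA in Angstrom^2.
#' @export
compute_bsa <- function(structure, split, params = surface_params(),
                        tol = 1e-6) {
  idx <- split_binders(structure, split)
  if (!length(idx$a) || !length(idx$b)) stop("empty binder")
  sa <- compute_sasa(subset_structure(structure, idx$a), params)$total
  sb <- compute_sasa(subset_structure(structure, idx$b), params)$total
  sab <- compute_sasa(subset_structure(structure, c(idx$a, idx$b)),
                      params)$total
  bsa <- sa + sb - sab
  if (bsa < 0 && abs(bsa) < tol) bsa <- 0
  bsa
}

#' Write a per-atom SASA report as TSV
#'
#' @param structure the structure the SASA was computed on.
#' @param sasa a `sasa_result` for the same structure.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sasa_report <- function(structure, sasa, path) {
  stopifnot(length(sasa$atom_area) == n_atoms(structure))
  df <- data.frame(chain = structure$atoms$chain,
                   resid = structure$atoms$resid,
                   resname = structure$atoms$resname,
                   atom = structure$atoms$name,
                   area = round(sasa$atom_area, 4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
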