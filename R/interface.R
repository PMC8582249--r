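# Interface detection, hydrophobicity classification, HBS, contacts, FNAT.

#' Kyte-Doolittle tri-classification of the 20 canonical residues
#'
#' Residues with a Kyte-Doolittle hydropathy above -0.4 are hydrophobic,
#' below -3.2 hydrophilic, the rest neutral:
#' hydrophobic = CYS, MET, PHE, ILE, LEU, ALA, VAL, GLY;
#' neutral = SER, THR, TYR, PRO, TRP;
#' hydrophilic = LYS, ASP, GLN, ASN, HIS, ARG, GLU.
#'
#' @param aliases named character vector mapping non-standard residue
#'   names onto canonical ones (default maps MSE to MET).
#' @return named character vector: class per residue name.
#' @export
residue_class_table <- function(aliases = c(MSE = "MET")) {
  cls <- c(
    CYS = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
    ILE = "hydrophobic", LEU = "hydrophobic", ALA = "hydrophobic",
    VAL = "hydrophobic", GLY = "hydrophobic",
    SER = "neutral", THR = "neutral", TYR = "neutral",
    PRO = "neutral", TRP = "neutral",
    LYS = "hydrophilic", ASP = "hydrophilic", GLN = "hydrophilic",
    ASN = "hydrophilic", HIS = "hydrophilic", ARG = "hydrophilic",
    GLU = "hydrophilic")
  if (length(aliases)) {
    extra <- cls[aliases]
    names(extra) <- names(aliases)
    cls <- c(cls, extra[!is.na(extra)])
  }
  cls
}

#' Hydrophobicity class of a residue name
#'
#' @param resname 3-letter residue name(s).
#' @param table see [residue_class_table()].
#' @param default class to assign to unknown residue names; `NULL`
#'   (default) makes unknown names an error.
#' @return character vector of classes.
#' @export
classify_residue <- function(resname, table = residue_class_table(),
                             default = NULL) {
  cls <- unname(table[toupper(resname)])
  if (anyNA(cls)) {
    if (is.null(default))
      stop("unknown residue name(s): ",
           paste(unique(resname[is.na(cls)]), collapse = ", "))
    cls[is.na(cls)] <- default
  }
  cls
}

#' Full interface characterization of a binder pair
#'
#' A residue belongs to the binding interface when its accessible surface
#' area drops by strictly more than `residue_threshold` (default 1
#' Angstrom^2) between the isolated binder and the complex.  An interface
#' atom is a heavy atom of an interface residue whose own per-atom area
#' drops by strictly more than `atom_epsilon`.  HBS is the pooled count of
#' interface atoms (both binders) belonging to hydrophobic residues.
#'
#' @param structure a `pp_structure`, heavy atoms only, radii assigned.
#' @param split a [binder_split()].
#' @param params a [surface_params()].
#' @param residue_threshold residue delta-SASA threshold, Angstrom^2.
#' @param atom_epsilon per-atom delta-SASA threshold, Angstrom^2.
#' @param class_table see [residue_class_table()].
#' @param hbs_mode `"interface_atoms"` (default) counts interface atoms of
#'   hydrophobic residues; `"all_atoms"` counts every heavy atom of the
#'   hydrophobic interface residues.
#' @return list of class `interface_result` with elements `residues`
#'   (data.frame: binder, chain, resid, icode, resname, class, dsasa),
#'   `atoms` (data.frame: binder, index, chain, resid, icode, resname,
#'   name, class, dsasa), per-class `residue_counts` and `atom_counts`,
#'   `hbs`, and `bsa`.
#' @export
interface_analysis <- function(structure, split, params = surface_params(),
                               residue_threshold = 1.0, atom_epsilon = 0.1,
                               class_table = residue_class_table(),
                               hbs_mode = c("interface_atoms", "all_atoms")) {
  hbs_mode <- match.arg(hbs_mode)
  idx <- split_binders(structure, split)
  if (!length(idx$a) || !length(idx$b)) stop("empty binder")
  both <- c(idx$a, idx$b)
  cplx <- subset_structure(structure, both)
  sasa_cplx <- compute_sasa(cplx, params)
  binder_res <- function(which_idx, binder_label, atom_offset) {
    iso <- compute_sasa(subset_structure(structure, which_idx), params)
    cplx_atom <- sasa_cplx$atom_area[atom_offset + seq_along(which_idx)]
    datom <- iso$atom_area - cplx_atom
    at <- structure$atoms[which_idx, , drop = FALSE]
    keys <- paste(at$chain, at$resid, at$icode, sep = ":")
    ukeys <- unique(keys)
    dres <- rowsum(datom, group = factor(keys, levels = ukeys))[, 1]
    iface_res <- ukeys[dres > residue_threshold]
    in_iface_res <- keys %in% iface_res
    iface_atom <- in_iface_res & (datom > atom_epsilon)
    first <- match(iface_res, keys)
    res_df <- data.frame(binder = rep(binder_label, length(iface_res)),
                         chain = at$chain[first], resid = at$resid[first],
                         icode = at$icode[first],
                         resname = at$resname[first],
                         class = classify_residue(at$resname[first],
                                                  class_table),
                         dsasa = unname(dres[iface_res]),
                         stringsAsFactors = FALSE)
    atom_df <- data.frame(binder = rep(binder_label, sum(iface_atom)),
                          index = which_idx[iface_atom],
                          chain = at$chain[iface_atom],
                          resid = at$resid[iface_atom],
                          icode = at$icode[iface_atom],
                          resname = at$resname[iface_atom],
                          name = at$name[iface_atom],
                          class = classify_residue(at$resname[iface_atom],
                                                   class_table),
                          dsasa = datom[iface_atom],
                          stringsAsFactors = FALSE)
    list(res = res_df, atoms = atom_df, iso_total = iso$total,
         n_res_atoms = sum(in_iface_res))
  }
  a <- binder_res(idx$a, "A", 0L)
  b <- binder_res(idx$b, "B", length(idx$a))
  residues <- rbind(a$res, b$res)
  atoms <- rbind(a$atoms, b$atoms)
  bsa <- a$iso_total + b$iso_total - sasa_cplx$total
  if (bsa < 0 && abs(bsa) < 1e-6) bsa <- 0
  count3 <- function(x) {
    out <- c(hydrophobic = 0L, neutral = 0L, hydrophilic = 0L)
    tab <- table(x)
    out[names(tab)] <- as.integer(tab)
    out
  }
  hbs <- if (hbs_mode == "interface_atoms") {
    sum(atoms$class == "hydrophobic")
  } else {
    res_h <- residues[residues$class == "hydrophobic", , drop = FALSE]
    keys_all <- residue_keys(structure)
    sum(keys_all %in% paste(res_h$chain, res_h$resid, res_h$icode, sep = ":"))
  }
  structure(list(
    residues = residues, atoms = atoms, bsa = bsa,
    residue_counts = list(A = count3(a$res$class), B = count3(b$res$class)),
    atom_counts = list(A = count3(a$atoms$class), B = count3(b$atoms$class)),
    hbs = as.integer(hbs),
    residue_threshold = residue_threshold, atom_epsilon = atom_epsilon,
    hbs_mode = hbs_mode), class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat("interface_result:", sum(x$residues$binder == "A"), "+",
      sum(x$residues$binder == "B"), "interface residues;",
      nrow(x$atoms), "interface atoms; BSA", round(x$bsa, 1),
      "A^2; HBS", x$hbs, "\n")
  invisible(x)
}

#' Interface residues of a binder pair
#'
#' @inheritParams interface_analysis
#' @return data.frame of interface residues (see [interface_analysis()]).
#' @export
interface_residues <- function(structure, split, params = surface_params(),
                               residue_threshold = 1.0) {
  interface_analysis(structure, split, params,
                     residue_threshold = residue_threshold)$residues
}

#' Interface atom indices of a binder pair
#'
#' @inheritParams interface_analysis
#' @return list with integer atom index vectors `a` and `b` (indices into
#'   the full structure).
#' @export
interface_atoms <- function(structure, split, params = surface_params(),
                            residue_threshold = 1.0, atom_epsilon = 0.1) {
  res <- interface_analysis(structure, split, params,
                            residue_threshold = residue_threshold,
                            atom_epsilon = atom_epsilon)
  list(a = res$atoms$index[res$atoms$binder == "A"],
       b = res$atoms$index[res$atoms$binder == "B"])
}

#' Hydrophobicity of the buried surface (HBS)
#'
#' Number of heavy atoms at the binding interface belonging to
#' hydrophobic residues, pooled over both binders.
#'
#' @inheritParams interface_analysis
#' @return integer count.
#' @export
hbs <- function(structure, split, params = surface_params(),
                residue_threshold = 1.0, atom_epsilon = 0.1,
                hbs_mode = c("interface_atoms", "all_atoms")) {
  interface_analysis(structure, split, params,
                     residue_threshold = residue_threshold,
                     atom_epsilon = atom_epsilon,
                     hbs_mode = match.arg(hbs_mode))$hbs
}

# Integer residue factor per atom subset, plus residue metadata.
.residue_index <- function(structure, idx) {
  at <- structure$atoms[idx, , drop = FALSE]
  keys <- paste(at$chain, at$resid, at$icode, sep = ":")
  ukeys <- unique(keys)
  list(fac = match(keys, ukeys), keys = ukeys,
       resname = at$resname[match(ukeys, keys)])
}

#' Cross-binder residue-residue contact table
#'
#' All residue pairs, one from each binder, whose minimum heavy-atom
#' distance does not exceed `cutoff`.  The polar-polar column holds the
#' minimum distance between nitrogen/oxygen atoms of the pair (the
#' ionic/hydrogen-bond proxy), `NA` when either residue has no N/O atom
#' or the N/O pair is beyond `polar_cutoff`.
#'
#' @param structure a `pp_structure`, heavy atoms only.
#' @param split a [binder_split()].
#' @param cutoff heavy-atom contact cutoff in Angstrom (default 5).
#' @param polar_cutoff distance above which the polar-polar column is
#'   reported as `NA` (default `Inf`: always reported when N/O atoms
#'   exist on both sides).
#' @return data.frame with columns `res_a`, `resname_a`, `res_b`,
#'   `resname_b`, `dist`, `polar_dist`.
#' @export
residue_contact_pairs <- function(structure, split, cutoff = 5.0,
                                  polar_cutoff = Inf) {
  idx <- split_binders(structure, split)
  ra <- .residue_index(structure, idx$a)
  rb <- .residue_index(structure, idx$b)
  hits <- residue_min_distances(structure$xyz[idx$a, , drop = FALSE],
                                as.integer(ra$fac),
                                structure$xyz[idx$b, , drop = FALSE],
                                as.integer(rb$fac), cutoff)
  if (!nrow(hits))
    return(data.frame(res_a = character(), resname_a = character(),
                      res_b = character(), resname_b = character(),
                      dist = numeric(), polar_dist = numeric()))
  polar_a <- structure$atoms$element[idx$a] %in% c("N", "O")
  polar_b <- structure$atoms$element[idx$b] %in% c("N", "O")
  polar <- vapply(seq_len(nrow(hits)), function(k) {
    ia <- idx$a[ra$fac == hits[k, 1] & polar_a]
    ib <- idx$b[rb$fac == hits[k, 2] & polar_b]
    if (!length(ia) || !length(ib)) return(NA_real_)
    d <- min_pair_distance(structure$xyz[ia, , drop = FALSE],
                           structure$xyz[ib, , drop = FALSE])
    if (d > polar_cutoff) NA_real_ else d
  }, numeric(1))
  data.frame(res_a = ra$keys[hits[, 1]],
             resname_a = ra$resname[hits[, 1]],
             res_b = rb$keys[hits[, 2]],
             resname_b = rb$resname[hits[, 2]],
             dist = hits[, 3],
             polar_dist = polar,
             stringsAsFactors = FALSE)
}

# Residue-pair contact keys at a cutoff (internal, used by fnat and the
# synthetic drift generator).
.contact_keys <- function(structure, split, cutoff = 5.0) {
  tab <- residue_contact_pairs(structure, split, cutoff)
  if (!nrow(tab)) character(0) else paste(tab$res_a, tab$res_b, sep = "|")
}

#' Fraction of native contacts (FNAT)
#'
#' CAPRI-convention residue contacts: a cross-binder residue pair is in
#' contact when any heavy-atom pair is within `cutoff` (default 5
#' Angstrom).  FNAT is the fraction of the reference structure's contact
#' pairs retained by the pose.
#'
#' @param pose,reference `pp_structure`s sharing residue keys for both
#'   binders.
#' @param split a [binder_split()].
#' @param cutoff contact cutoff in Angstrom.
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(pose, reference, split, cutoff = 5.0) {
  ref <- .contact_keys(reference, split, cutoff)
  if (!length(ref)) stop("reference structure has no cross-binder contacts")
  pos <- .contact_keys(pose, split, cutoff)
  length(intersect(pos, ref)) / length(ref)
}

#' Write a per-frame interface report as TSV
#'
#' One row per trajectory frame: frame time, BSA, residue and atom counts
#' per binder, counts per hydrophobicity class, and HBS.
#'
#' @param traj a `pp_trajectory` (heavy atoms, radii assigned).
#' @param split a [binder_split()].
#' @param path output TSV path.
#' @param params a [surface_params()].
#' @param ... passed to [interface_analysis()].
#' @return the report data.frame, invisibly.
#' @export
write_interface_report <- function(traj, split, path,
                                   params = surface_params(), ...) {
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    ia <- interface_analysis(get_frame(traj, i), split, params, ...)
    data.frame(frame = i, time_ps = traj$times[i], bsa = round(ia$bsa, 2),
               n_res_a = sum(ia$residues$binder == "A"),
               n_res_b = sum(ia$residues$binder == "B"),
               n_atoms_a = sum(ia$atoms$binder == "A"),
               n_atoms_b = sum(ia$atoms$binder == "B"),
               res_hydrophobic = sum(ia$residues$class == "hydrophobic"),
               res_neutral = sum(ia$residues$class == "neutral"),
               res_hydrophilic = sum(ia$residues$class == "hydrophilic"),
               hbs = ia$hbs)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
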