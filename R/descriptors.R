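# Kabsch superposition, interface RMSD, per-trajectory descriptor series.

#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (weighted) RMSD between `reference` and `mobile %*% t(R) + t`.
#'
#' @param reference,mobile n x 3 coordinate matrices, n >= 3.
#' @param weights optional non-negative per-atom weights.
#' @return list of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (unweighted RMSD after the
#'   transform).
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n != nrow(mobile)) stop("coordinate sets differ in size")
  if (n < 3) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  mu_r <- colSums(reference * w)
  mu_m <- colSums(mobile * w)
  X <- sweep(mobile, 2, mu_m)
  Y <- sweep(reference, 2, mu_r)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  if (min(sv$d) < 1e-12 && n > 3 && sv$d[2] < 1e-12)
    stop("degenerate (collinear) geometry, superposition is not unique")
  translation <- mu_r - as.vector(R %*% mu_m)
  fitted <- mobile %*% t(R) + matrix(translation, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition`.
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  xyz <- as.matrix(xyz)
  xyz %*% t(sp$rotation) + matrix(sp$translation, nrow(xyz), 3, byrow = TRUE)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

# Match the reference's interface atoms in a frame by identity key.
# Missing atoms are tolerated (and dropped pairwise) up to `max_missing`
# of the set, otherwise an error lists them.
.matched_interface_xyz <- function(frame, reference, interface_keys, mode,
                                   max_missing = 0.05) {
  keys_ref <- residue_keys(reference)
  sel <- keys_ref %in% interface_keys
  if (mode == "backbone")
    sel <- sel & reference$atoms$name %in% BACKBONE_NAMES
  if (!any(sel)) stop("no reference atoms in the interface selection")
  id_ref <- paste(keys_ref, reference$atoms$name)[sel]
  id_frame <- paste(residue_keys(frame), frame$atoms$name)
  pos <- match(id_ref, id_frame)
  if (anyNA(pos)) {
    frac <- mean(is.na(pos))
    if (frac > max_missing)
      stop("frame lacks ", round(100 * frac, 1),
           "% of the interface atom set: ",
           paste(head(id_ref[is.na(pos)], 5), collapse = ", "), " ...")
    warning(sum(is.na(pos)), " interface atom(s) missing from frame; ",
            "excluded pairwise")
  }
  keep <- !is.na(pos)
  list(ref = reference$xyz[which(sel)[keep], , drop = FALSE],
       frame = frame$xyz[pos[keep], , drop = FALSE])
}

#' Interface root-mean-square deviation of a frame
#'
#' Superposes the frame onto the reference over the interface atom set
#' and returns the RMSD over that same set.  `mode = "heavy"` uses all
#' heavy atoms of the interface residues (iRMSD); `mode = "backbone"`
#' restricts to N, CA, C, O (the backbone variant used for pairwise pose
#' clustering).
#'
#' @param frame,reference `pp_structure`s sharing the interface atoms.
#' @param interface_keys character vector of `chain:resid:icode` residue
#'   keys (typically frozen from the initial pose).
#' @param mode `"heavy"` or `"backbone"`.
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(frame, reference, interface_keys,
                  mode = c("heavy", "backbone")) {
  mode <- match.arg(mode)
  m <- .matched_interface_xyz(frame, reference, interface_keys, mode)
  kabsch_superpose(m$ref, m$frame)$rmsd
}

#' Frozen interface residue keys of an initial pose
#'
#' @param structure initial pose (`pp_structure`).
#' @param split a [binder_split()].
#' @param params a [surface_params()].
#' @param residue_threshold residue delta-SASA threshold, Angstrom^2.
#' @return character vector of residue keys (both binders pooled).
#' @export
interface_keys <- function(structure, split, params = surface_params(),
                           residue_threshold = 1.0) {
  res <- interface_residues(structure, split, params, residue_threshold)
  paste(res$chain, res$resid, res$icode, sep = ":")
}

# Frame indices retained on the analysis grid: grid times are
# spacing * (1:n_target); each grid time takes its nearest frame (ties
# resolved to the earlier frame); duplicates collapse.  A trajectory with
# no more frames than requested is used as is.
subsample_indices <- function(times, n_target, spacing) {
  n <- length(times)
  if (n <= n_target) {
    if (n < n_target)
      warning("trajectory has ", n, " frames, fewer than the ", n_target,
              " requested; using all frames")
    return(seq_len(n))
  }
  grid <- spacing * seq_len(n_target)
  idx <- vapply(grid, function(g) {
    d <- abs(times - g)
    which(d == min(d))[1]  # earliest frame on a tie
  }, integer(1))
  sort(unique(idx))
}

#' Per-trajectory descriptor series
#'
#' Subsamples the trajectory to the analysis grid (default 100 frames
#' spaced by 100 ps) and computes, per retained frame: iRMSD and backbone
#' iRMSD against the initial pose over the frozen interface residue set,
#' BSA, and HBS (interface recomputed each frame).  Means and standard
#' deviations of each trace are attached, along with the ratio of the
#' HBS and iRMSD means.
#'
#' @param traj a `pp_trajectory` (heavy atoms, radii assigned).
#' @param split a [binder_split()].
#' @param reference initial pose; defaults to the trajectory's first
#'   frame.
#' @param keys frozen interface residue keys; computed from `reference`
#'   when `NULL`.
#' @param params a [surface_params()].
#' @param n_frames_target frames on the analysis grid (default 100).
#' @param spacing_ps grid spacing in ps (default 100).
#' @param residue_threshold,atom_epsilon interface thresholds, Angstrom^2.
#' @param hbs_mode see [interface_analysis()].
#' @return object of class `descriptor_series`: list with `frames`
#'   (data.frame time_ps, irmsd, irmsd_b, bsa, hbs) and `summary`.
#' @export
analyze_trajectory <- function(traj, split, reference = NULL, keys = NULL,
                               params = surface_params(),
                               n_frames_target = 100, spacing_ps = 100,
                               residue_threshold = 1.0, atom_epsilon = 0.1,
                               hbs_mode = "interface_atoms") {
  if (is.null(reference)) reference <- get_frame(traj, 1)
  if (is.null(keys))
    keys <- interface_keys(reference, split, params, residue_threshold)
  if (!length(keys))
    stop("initial pose has an empty interface; nothing to track")
  idx <- subsample_indices(traj$times, n_frames_target, spacing_ps)
  ir <- vapply(idx, function(i) {
    fr <- get_frame(traj, i)
    c(irmsd(fr, reference, keys, "heavy"),
      irmsd(fr, reference, keys, "backbone"))
  }, numeric(2))
  if (hbs_mode == "interface_atoms") {
    # fast path: the per-frame BSA/HBS loop runs in compiled code on
    # binder bookkeeping precomputed once (the roster is frame-invariant)
    bidx <- split_binders(get_frame(traj, 1), split)
    if (!length(bidx$a) || !length(bidx$b)) stop("empty binder")
    if (anyNA(traj$atoms$radius)) stop("assign radii before analysis")
    keys_all <- paste(traj$atoms$chain, traj$atoms$resid, traj$atoms$icode,
                      sep = ":")
    fac <- function(ii) match(keys_all[ii], unique(keys_all[ii]))
    hydro <- classify_residue(traj$atoms$resname,
                              default = "hydrophilic") == "hydrophobic"
    dh <- traj_interface_descriptors(
      traj$coords[idx], traj$atoms$radius,
      as.integer(bidx$a), as.integer(bidx$b),
      as.integer(fac(bidx$a)), as.integer(fac(bidx$b)),
      hydro[bidx$a], hydro[bidx$b],
      params$probe_radius, params$n_sphere_points,
      residue_threshold, atom_epsilon)
    frames <- data.frame(time_ps = traj$times[idx],
                         irmsd = ir[1, ], irmsd_b = ir[2, ],
                         bsa = dh$bsa, hbs = dh$hbs)
  } else {
    rows <- lapply(seq_along(idx), function(k) {
      ia <- interface_analysis(get_frame(traj, idx[k]), split, params,
                               residue_threshold = residue_threshold,
                               atom_epsilon = atom_epsilon,
                               hbs_mode = hbs_mode)
      data.frame(time_ps = traj$times[idx[k]],
                 irmsd = ir[1, k], irmsd_b = ir[2, k],
                 bsa = ia$bsa, hbs = ia$hbs)
    })
    frames <- do.call(rbind, rows)
  }
  descriptor_series(frames, keys = keys)
}

#' Build a descriptor series from a per-frame table
#'
#' @param frames data.frame with columns `time_ps`, `irmsd`, `irmsd_b`,
#'   `bsa`, `hbs`.
#' @param keys interface residue keys the iRMSD trace was computed over.
#' @return object of class `descriptor_series`.
#' @export
descriptor_series <- function(frames, keys = character(0)) {
  need <- c("time_ps", "irmsd", "irmsd_b", "bsa", "hbs")
  stopifnot(all(need %in% names(frames)), nrow(frames) >= 1)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  s <- list(n_frames = nrow(frames),
            mean_irmsd = mean(frames$irmsd), sd_irmsd = sd0(frames$irmsd),
            mean_irmsd_b = mean(frames$irmsd_b),
            sd_irmsd_b = sd0(frames$irmsd_b),
            mean_bsa = mean(frames$bsa), sd_bsa = sd0(frames$bsa),
            mean_hbs = mean(frames$hbs), sd_hbs = sd0(frames$hbs))
  s$hbs_over_irmsd <- .ratio_descriptor(s$mean_hbs, s$mean_irmsd)
  structure(list(frames = frames, summary = s, keys = keys),
            class = "descriptor_series")
}

# HBS/iRMSD with the degenerate limits pinned: no buried hydrophobic
# atoms -> 0; a perfectly conserved pose (mean iRMSD 0) -> +Inf, which
# sorts first under descending ranking.
.ratio_descriptor <- function(mean_hbs, mean_irmsd) {
  if (mean_hbs == 0) return(0)
  # below superposition round-off the pose is perfectly conserved
  if (mean_irmsd < 1e-9) return(Inf)
  mean_hbs / mean_irmsd
}

#' @export
print.descriptor_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "descriptor_series: %d frames | iRMSD %.2f +/- %.2f A | BSA %.0f +/- %.0f A^2 | HBS %.1f | HBS/iRMSD %.2f\n",
    s$n_frames, s$mean_irmsd, s$sd_irmsd, s$mean_bsa, s$sd_bsa,
    s$mean_hbs, s$hbs_over_irmsd))
  invisible(x)
}

#' Pool replica descriptor series of one pose
#'
#' Pooled means are taken over all retained frames of all replicas
#' (frame-weighted, so replicas of unequal length contribute in
#' proportion to their frame counts); the pooled ratio descriptor is the
#' pooled HBS mean over the pooled iRMSD mean.
#'
#' @param series_list list of `descriptor_series` (one per replica).
#' @return list of class `pooled_descriptors` with the pooled summary
#'   statistics and `n_frames_total`.
#' @export
pool_replicas <- function(series_list) {
  if (!length(series_list)) stop("no replica series to pool")
  stopifnot(all(vapply(series_list, inherits, logical(1),
                       "descriptor_series")))
  all_frames <- do.call(rbind, lapply(series_list, `[[`, "frames"))
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  out <- list(n_replicas = length(series_list),
              n_frames_total = nrow(all_frames),
              mean_irmsd = mean(all_frames$irmsd),
              sd_irmsd = sd0(all_frames$irmsd),
              mean_irmsd_b = mean(all_frames$irmsd_b),
              mean_bsa = mean(all_frames$bsa),
              sd_bsa = sd0(all_frames$bsa),
              mean_hbs = mean(all_frames$hbs),
              sd_hbs = sd0(all_frames$hbs))
  out$hbs_over_irmsd <- .ratio_descriptor(out$mean_hbs, out$mean_irmsd)
  class(out) <- "pooled_descriptors"
  out
}

#' Ratio descriptor HBS/iRMSD from pooled values
#'
#' @param pooled a `pooled_descriptors` (or any list carrying `mean_hbs`
#'   and `mean_irmsd`).
#' @return HBS/iRMSD in 1/Angstrom; `Inf` flags a perfectly conserved
#'   pose (zero mean iRMSD), 0 an interface without buried hydrophobic
#'   atoms.
#' @export
hbs_over_irmsd <- function(pooled) {
  .ratio_descriptor(pooled$mean_hbs, pooled$mean_irmsd)
}

#' Write per-trajectory descriptor traces as TSV
#'
#' @param series a `descriptor_series`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_series <- function(series, path) {
  write.table(series$frames, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
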