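# Synthetic dimers and replica trajectories with controlled ground truth.
#
# The generator emulates the study conditions the descriptor protocol is
# built for: per-pose triplicate trajectories of 100 frames spaced by
# 100 ps, with three behaviors (conserved interface, drift to a new
# interface, progressive unbinding) and a controllable hydrophobic
# interface composition so that a designated near-native pose carries the
# designed best descriptors.

# Side-chain heavy-atom counts of the canonical residues; pseudo side
# chains carry one centroid atom per real side-chain heavy atom so HBS
# arithmetic matches real residues.
SIDECHAIN_HEAVY <- c(
  GLY = 0L, ALA = 1L, SER = 2L, CYS = 2L, THR = 3L, VAL = 3L, PRO = 3L,
  ILE = 4L, LEU = 4L, ASP = 4L, ASN = 4L, MET = 4L, GLN = 5L, GLU = 5L,
  LYS = 5L, HIS = 6L, ARG = 7L, PHE = 7L, TYR = 8L, TRP = 10L)

.chain_atoms <- function(n_res, composition, chain, contact_res, reach,
                         toward = +1) {
  composition <- rep(composition, length.out = n_res)
  bad <- setdiff(toupper(composition), names(SIDECHAIN_HEAVY))
  if (length(bad)) stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (i in seq_len(n_res)) {
    x0 <- 3.8 * (i - 1)
    resname <- toupper(composition[i])
    bb <- data.frame(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = x0 + c(-1.2, 0, 1.2, 1.3),
      y = c(0.6, 0, 0.5, 1.7),
      z = 0)
    ns <- SIDECHAIN_HEAVY[[resname]]
    sc <- NULL
    if (ns > 0) {
      in_contact <- i %in% contact_res
      r_sc <- if (in_contact) reach else min(1.0 + 0.5 * ns, 3.2)
      dirz <- if (in_contact) toward else -toward
      k <- seq_len(ns)
      sc <- data.frame(
        name = sprintf("SC%d", k),
        element = "C",
        x = x0 + 0.35 * cos(2.4 * k),
        y = 0.35 * sin(2.4 * k),
        z = dirz * r_sc * k / ns)
    }
    res <- rbind(bb, sc)
    res$resname <- resname
    res$chain <- chain
    res$resid <- i
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}

#' Build a rigid toy dimer with a designed binding interface
#'
#' Two mini-chains of idealized backbone plus pseudo side-chain heavy
#' atoms (one atom per real side-chain heavy atom of the residue type),
#' placed so that exactly the requested residue pairs are in heavy-atom
#' contact (< 5 A) and all others are not.  Contacting residues extend
#' their side chains toward the partner to meet at `contact_gap`; all
#' other side chains point away from the interface.  The construction is
#' validated against [residue_contact_pairs()]; an infeasible request is
#' a placement error.
#'
#' @param n_res_a,n_res_b residues per chain.
#' @param composition_a,composition_b 3-letter residue names, recycled
#'   along each chain.
#' @param contact_pairs two-column integer matrix (or list of length-2
#'   vectors) of (residue in A, residue in B) contact requests; contact
#'   residues need at least one side-chain atom (so not GLY).
#' @param seed integer; a small seeded coordinate jitter (sd
#'   `coord_jitter`) makes distinct seeds give distinct rigid geometries.
#' @param contact_gap designed tip-to-tip distance of contacting side
#'   chains (A).
#' @param backbone_sep backbone-plane separation of the two chains (A).
#' @param coord_jitter sd of the seeded coordinate jitter (A).
#' @param radii_table radii assigned to the result.
#' @return list with `structure` (a `pp_structure`, heavy atoms, radii
#'   assigned) and `split` (a [binder_split()], chains A and B).
#' @export
make_toy_dimer <- function(n_res_a = 6, n_res_b = 6,
                           composition_a = "ALA", composition_b = "ALA",
                           contact_pairs = cbind(2, 2), seed = 1,
                           contact_gap = 4.0, backbone_sep = 8.5,
                           coord_jitter = 0.05,
                           radii_table = default_radii_table()) {
  cp <- if (is.null(contact_pairs)) matrix(integer(0), 0, 2)
        else if (is.list(contact_pairs)) do.call(rbind, contact_pairs)
        else as.matrix(contact_pairs)
  if (length(cp) && (ncol(cp) != 2 ||
                     any(cp[, 1] < 1) || any(cp[, 1] > n_res_a) ||
                     any(cp[, 2] < 1) || any(cp[, 2] > n_res_b)))
    stop("contact_pairs must be (residue in A, residue in B) pairs in range")
  reach <- (backbone_sep - contact_gap) / 2
  a <- .chain_atoms(n_res_a, composition_a, "A",
                    contact_res = cp[, 1], reach = reach, toward = +1)
  b <- .chain_atoms(n_res_b, composition_b, "B",
                    contact_res = cp[, 2], reach = reach, toward = +1)
  if (length(cp)) {
    no_sc <- SIDECHAIN_HEAVY[toupper(rep(composition_a,
                                         length.out = n_res_a))[cp[, 1]]] == 0 |
             SIDECHAIN_HEAVY[toupper(rep(composition_b,
                                         length.out = n_res_b))[cp[, 2]]] == 0
    if (any(no_sc))
      stop("placement error: contact residues need a side chain (not GLY)")
  }
  # mirror chain B onto the opposite face and align requested pairs in x
  b$z <- backbone_sep - b$z
  if (length(cp)) b$x <- b$x + 3.8 * mean(cp[, 1] - cp[, 2])
  at <- rbind(a, b)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (coord_jitter > 0)
    xyz <- xyz + with_seed(seed, matrix(rnorm(length(xyz), 0, coord_jitter),
                                        ncol = 3))
  atoms <- data.frame(serial = seq_len(nrow(at)), name = at$name,
                      element = at$element, resname = at$resname,
                      chain = at$chain, resid = at$resid, icode = "",
                      stringsAsFactors = FALSE)
  st <- assign_radii(pp_structure(atoms, xyz), radii_table)
  split <- binder_split("A", "B")
  got <- residue_contact_pairs(st, split, cutoff = 5.0)
  want <- if (length(cp)) sort(paste0("A:", cp[, 1], ":|B:", cp[, 2], ":"))
          else character(0)
  have <- sort(paste(got$res_a, got$res_b, sep = "|"))
  if (!identical(want, have))
    stop("placement error: requested contacts ",
         paste(want, collapse = " "), " but realized ",
         paste(have, collapse = " "))
  list(structure = st, split = split)
}

#' Trajectory behavior specification
#'
#' @param behavior `"conserved"` (rigid-body jitter of binder B around
#'   the initial pose), `"drift"` (binder B slides around the interface
#'   normal until a new contact set forms, then jitters there) or
#'   `"unbind"` (binder B translates along the separation axis at a
#'   constant rate).
#' @param n_frames frames (default 100).
#' @param dt frame spacing in ps (default 100).
#' @param jitter_sigma rms rigid-body displacement per frame (A).
#' @param drift_angle_per_frame degrees of drift rotation per frame.
#' @param separation_rate unbinding translation per frame (A/frame).
#' @param seed integer RNG seed; generation is a pure function of it.
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(behavior = c("conserved", "drift", "unbind"),
                            n_frames = 100, dt = 100, jitter_sigma = 0.3,
                            drift_angle_per_frame = 8,
                            separation_rate = 0.6, seed = 1) {
  behavior <- match.arg(behavior)
  stopifnot(n_frames >= 2, jitter_sigma >= 0, separation_rate >= 0,
            drift_angle_per_frame >= 0)
  structure(list(behavior = behavior, n_frames = as.integer(n_frames),
                 dt = dt, jitter_sigma = jitter_sigma,
                 drift_angle_per_frame = drift_angle_per_frame,
                 separation_rate = separation_rate,
                 seed = as.integer(seed)), class = "trajectory_spec")
}

.rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)),
    nrow = 3, byrow = TRUE)
}

#' Generate a synthetic rigid-body trajectory of a pose
#'
#' Binder A stays fixed; binder B undergoes the behavior's rigid-body
#' motion plus a per-frame Gaussian jitter (translation with rms
#' magnitude `jitter_sigma`, applied independently per frame so the pose
#' fluctuates around its behavior path rather than random-walking away).
#' Frame 1 carries zero behavior displacement, so an unbinding run of n
#' frames ends at `separation_rate * (n - 1)` A extra separation.  The
#' drift rotation (about the separation axis through binder B's
#' centroid) accumulates per frame until the cross-binder residue
#' contact set is non-empty and differs from the initial one, or 185
#' degrees at most, then holds.
#'
#' @param pose a `pp_structure`.
#' @param split a [binder_split()].
#' @param spec a [trajectory_spec()].
#' @return a `pp_trajectory` (times `dt * (0:(n-1))`).
#' @export
synthesize_trajectory <- function(pose, split, spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  idx <- split_binders(pose, split)
  xyz0 <- pose$xyz
  com_a <- colMeans(xyz0[idx$a, , drop = FALSE])
  com_b <- colMeans(xyz0[idx$b, , drop = FALSE])
  axis <- com_b - com_a
  axis <- axis / sqrt(sum(axis^2))
  n <- spec$n_frames
  jit <- with_seed(spec$seed,
                   matrix(rnorm(3L * n, 0, spec$jitter_sigma / sqrt(3)),
                          ncol = 3))
  init_contacts <- .contact_keys(pose, split, 5.0)
  coords <- vector("list", n)
  angle <- 0
  drift_locked <- FALSE
  for (t in seq_len(n)) {
    xyzB <- xyz0[idx$b, , drop = FALSE]
    if (spec$behavior == "unbind") {
      shift <- spec$separation_rate * (t - 1)
      xyzB <- xyzB + matrix(axis * shift, nrow(xyzB), 3, byrow = TRUE)
    } else if (spec$behavior == "drift") {
      if (t > 1 && !drift_locked)
        angle <- min(angle + spec$drift_angle_per_frame, 185)
      R <- .rotation_about_axis(axis, angle)
      xyzB <- sweep(xyzB, 2, com_b)
      xyzB <- xyzB %*% t(R)
      xyzB <- sweep(xyzB, 2, com_b, "+")
    }
    if (spec$jitter_sigma > 0)
      xyzB <- xyzB + matrix(jit[t, ], nrow(xyzB), 3, byrow = TRUE)
    frame <- xyz0
    frame[idx$b, ] <- xyzB
    coords[[t]] <- frame
    if (spec$behavior == "drift" && !drift_locked && angle > 0) {
      fr <- structure(list(atoms = pose$atoms, xyz = frame),
                      class = "pp_structure")
      now <- .contact_keys(fr, split, 5.0)
      if (length(setdiff(now, init_contacts))) drift_locked <- TRUE
    }
  }
  pp_trajectory(pose$atoms, coords, times = spec$dt * (seq_len(n) - 1))
}

# Deterministic seed fan-out for (base seed, pose, replica) tuples;
# kept below 2^31 - 1.
fanout_seed <- function(base_seed, pose, replica = 0) {
  as.integer(((as.numeric(base_seed) %% 1e6) * 1009 +
                pose * 101 + replica * 13) %% 2147483647)
}

#' Benchmark ensemble specification
#'
#' @param n_poses candidate poses (default 20, the per-system pose count
#'   the rescoring benchmark uses).
#' @param near_native_index which pose is the constructed near-native
#'   one; `NULL` samples it from the base seed.
#' @param n_res residues per chain of every toy dimer.
#' @param replicas trajectories per pose (default 3).
#' @param base_seed master seed; everything derives from it.
#' @param hydrophobic_bonus extra hydrophobic contact pairs granted to
#'   the near-native pose on top of the decoys' two contacts.
#' @param jitter_sigma,drift_angle_per_frame,separation_rate,n_frames,dt
#'   forwarded to [trajectory_spec()].
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_poses = 20, near_native_index = NULL,
                          n_res = 6, replicas = 3, base_seed = 1,
                          hydrophobic_bonus = 1, jitter_sigma = 0.3,
                          drift_angle_per_frame = 8, separation_rate = 0.6,
                          n_frames = 100, dt = 100) {
  stopifnot(n_poses >= 2, replicas >= 1,
            is.null(near_native_index) ||
              (near_native_index >= 1 && near_native_index <= n_poses))
  structure(list(n_poses = as.integer(n_poses),
                 near_native_index = near_native_index,
                 n_res = as.integer(n_res), replicas = as.integer(replicas),
                 base_seed = as.integer(base_seed),
                 hydrophobic_bonus = as.integer(hydrophobic_bonus),
                 jitter_sigma = jitter_sigma,
                 drift_angle_per_frame = drift_angle_per_frame,
                 separation_rate = separation_rate,
                 n_frames = as.integer(n_frames), dt = dt),
            class = "ensemble_spec")
}

#' Generate a benchmark pose ensemble with ground truth
#'
#' One designated near-native pose gets a conserved-interface behavior
#' and the largest, most hydrophobic interface (bulky hydrophobic
#' contact residues, plus `hydrophobic_bonus` extra contact pairs);
#' decoys get smaller polar/neutral interfaces and cycle through drift,
#' conserved (a stable but poorly packed decoy) and unbind behaviors.
#' Synthetic external docking scores are drawn uninformatively, mimicking
#' a scoring function with no discrimination power on this set.
#'
#' @param spec an [ensemble_spec()].
#' @return list of class `pose_ensemble`: `poses` (list of
#'   `pp_structure`), `split`, `trajectories` (list over poses of lists
#'   of `pp_trajectory`), `ground_truth` (data.frame pose_id, label,
#'   behavior, seed), `external_scores` (named), `near_native_id`,
#'   `spec`.
#' @export
make_benchmark_ensemble <- function(spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_poses
  nn <- spec$near_native_index
  drawn <- with_seed(spec$base_seed, {
    list(nn = if (is.null(nn)) sample.int(n, 1) else as.integer(nn),
         scores = round(runif(n, -120, -80), 1))
  })
  nn <- drawn$nn
  hydrophobic_set <- c("PHE", "LEU", "ILE", "MET")
  polar_set <- c("SER", "THR", "LYS", "GLU", "ASN")
  decoy_behaviors <- rep(c("drift", "conserved", "unbind"), length.out = n)
  poses <- vector("list", n)
  trajectories <- vector("list", n)
  gt <- vector("list", n)
  split <- NULL
  for (p in seq_len(n)) {
    pose_seed <- fanout_seed(spec$base_seed, p, 0)
    is_nn <- p == nn
    if (is_nn) {
      n_pairs <- min(2L + spec$hydrophobic_bonus, spec$n_res - 2L)
      contact_cols <- seq(2L, length.out = n_pairs)
      comp <- rep("ALA", spec$n_res)
      comp[contact_cols] <- rep(hydrophobic_set,
                                length.out = length(contact_cols))
      behavior <- "conserved"
    } else {
      # decoys keep a partly hydrophobic interface so the ranking test
      # is not trivially decided by a zero HBS
      contact_cols <- c(2L, spec$n_res - 1L)
      comp <- rep("ALA", spec$n_res)
      comp[contact_cols[1]] <- c("LEU", "VAL", "MET", "CYS")[((p - 1) %% 4) + 1]
      comp[contact_cols[2]] <- polar_set[((p - 1) %% length(polar_set)) + 1]
      behavior <- decoy_behaviors[p]
    }
    dimer <- make_toy_dimer(n_res_a = spec$n_res, n_res_b = spec$n_res,
                            composition_a = comp, composition_b = comp,
                            contact_pairs = cbind(contact_cols, contact_cols),
                            seed = pose_seed)
    split <- dimer$split
    poses[[p]] <- dimer$structure
    trajectories[[p]] <- lapply(seq_len(spec$replicas), function(r) {
      synthesize_trajectory(dimer$structure, split, trajectory_spec(
        behavior = behavior, n_frames = spec$n_frames, dt = spec$dt,
        jitter_sigma = spec$jitter_sigma,
        drift_angle_per_frame = spec$drift_angle_per_frame,
        separation_rate = spec$separation_rate,
        seed = fanout_seed(spec$base_seed, p, r)))
    })
    gt[[p]] <- data.frame(pose_id = sprintf("pose_%02d", p),
                          label = if (is_nn) "near_native" else "decoy",
                          behavior = behavior, seed = pose_seed,
                          stringsAsFactors = FALSE)
  }
  ids <- sprintf("pose_%02d", seq_len(n))
  names(poses) <- names(trajectories) <- ids
  structure(list(poses = poses, split = split,
                 trajectories = trajectories,
                 ground_truth = do.call(rbind, gt),
                 external_scores = setNames(drawn$scores, ids),
                 near_native_id = ids[nn], spec = spec),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat("pose_ensemble:", length(x$poses), "poses x",
      length(x$trajectories[[1]]), "replica trajectories; near-native =",
      x$near_native_id, "\n")
  invisible(x)
}

#' Write an ensemble to disk
#'
#' Emits one PDB per pose, one multi-MODEL PDB per replica trajectory,
#' the ground-truth TSV (pose_id, label, behavior, seed) and the
#' external scores TSV.
#'
#' @param ensemble a `pose_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(ensemble$poses)) {
    write_structure(ensemble$poses[[id]], file.path(dir, paste0(id, ".pdb")))
    for (r in seq_along(ensemble$trajectories[[id]]))
      write_structure(ensemble$trajectories[[id]][[r]],
                      file.path(dir, sprintf("%s_rep%d.pdb", id, r)))
  }
  write.table(ensemble$ground_truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(pose_id = names(ensemble$external_scores),
                         external_score = ensemble$external_scores),
              file.path(dir, "external_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
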