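# End-to-end rescoring: descriptor analysis -> pooling -> classification
# -> ranking -> (benchmark mode) figures of merit.

#' Rescore a set of candidate poses from their replica trajectories
#'
#' For every pose: each replica trajectory is reduced to a descriptor
#' series against the pose's initial conformation (interface residue set
#' frozen from the initial pose), replicas are classified and pooled,
#' and poses are ranked on each pooled descriptor.  Descriptor sigmas
#' are calibrated from the interface-conserving trajectories ([compute_sigma()]).
#' When the nearest-native pose id is known (benchmark mode) the three
#' figures of merit are evaluated.
#'
#' @param poses named list of `pp_structure`s (heavy atoms, radii
#'   assigned).
#' @param trajectories named list (same names) of lists of
#'   `pp_trajectory` replicas.
#' @param split a [binder_split()].
#' @param external_scores optional named numeric vector of docking
#'   scores (lower is better).
#' @param nearest_native optional pose id enabling benchmark mode.
#' @param params a [surface_params()].
#' @param cls_params a [classifier_params()].
#' @param n_frames_target,spacing_ps analysis grid, see
#'   [analyze_trajectory()].
#' @param residue_threshold,atom_epsilon interface thresholds (A^2).
#' @return list of class `ranking_report`: `pose_table` (descriptors,
#'   class, per-descriptor rank columns `rank_*`), `replica_classes`,
#'   `series` (list over poses of replica `descriptor_series`), `sigma`,
#'   `merit` (a `merit_report` or `NULL`).
#' @export
rescore_poses <- function(poses, trajectories, split,
                          external_scores = NULL, nearest_native = NULL,
                          params = surface_params(),
                          cls_params = classifier_params(),
                          n_frames_target = 100, spacing_ps = 100,
                          residue_threshold = 1.0, atom_epsilon = 0.1) {
  ids <- names(poses)
  if (is.null(ids) || is.null(names(trajectories)) ||
      !setequal(ids, names(trajectories)))
    stop("poses and trajectories must be named lists over the same ids")
  all_series <- list()
  all_classes <- character(0)
  rows <- list()
  replica_classes <- list()
  series_by_pose <- list()
  for (id in ids) {
    ref <- poses[[id]]
    keys <- interface_keys(ref, split, params, residue_threshold)
    reps <- trajectories[[id]]
    series <- lapply(reps, analyze_trajectory, split = split,
                     reference = ref, keys = keys, params = params,
                     n_frames_target = n_frames_target,
                     spacing_ps = spacing_ps,
                     residue_threshold = residue_threshold,
                     atom_epsilon = atom_epsilon)
    cls <- vapply(series, function(s)
      as.character(classify_trajectory(s, cls_params)), character(1))
    pooled <- pool_replicas(series)
    rows[[id]] <- data.frame(
      pose_id = id, class = classify_pose(cls),
      external_score = if (is.null(external_scores)) NA_real_
                       else unname(external_scores[id]),
      mean_irmsd = pooled$mean_irmsd, mean_bsa = pooled$mean_bsa,
      mean_hbs = pooled$mean_hbs, hbs_over_irmsd = pooled$hbs_over_irmsd,
      stringsAsFactors = FALSE)
    replica_classes[[id]] <- cls
    series_by_pose[[id]] <- series
    all_series <- c(all_series, series)
    all_classes <- c(all_classes, cls)
  }
  pose_table <- do.call(rbind, rows)
  rownames(pose_table) <- NULL
  if (is.null(external_scores)) pose_table$external_score <- NULL
  sigma <- suppressWarnings(compute_sigma(all_series, all_classes))
  ranks <- rank_pose_table(pose_table)
  for (cn in setdiff(names(ranks), "pose_id"))
    pose_table[[paste0("rank_", cn)]] <- ranks[[cn]]
  merit <- NULL
  if (!is.null(nearest_native)) {
    if (!nearest_native %in% ids)
      stop("nearest_native id '", nearest_native, "' is not a pose id")
    merit <- figures_of_merit(
      pose_tables = list(system = pose_table),
      nearest_native = c(system = nearest_native), sigma = sigma)
  }
  structure(list(pose_table = pose_table,
                 replica_classes = replica_classes,
                 series = series_by_pose, sigma = sigma, merit = merit),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("ranking_report:", nrow(x$pose_table), "poses\n")
  ord <- order(x$pose_table$rank_hbs_over_irmsd)
  print(head(x$pose_table[ord, c("pose_id", "class", "mean_irmsd",
                                 "mean_bsa", "mean_hbs", "hbs_over_irmsd")],
             10), row.names = FALSE)
  invisible(x)
}

#' Read and validate a run configuration
#'
#' Plain YAML mapping.  Recognized keys: `poses` (directory of `*.pdb`
#' initial poses, or explicit list), `trajectories` (mapping pose id ->
#' list of multi-MODEL PDB paths; defaults to files named
#' `<pose>_rep<k>.pdb` next to each pose), `binder_a`/`binder_b` (chain
#' id lists), `external_scores` (TSV with columns pose_id,
#' external_score), `nearest_native`, `probe_radius`,
#' `n_sphere_points`, `interface_threshold`, `atom_epsilon`, `frames`,
#' `spacing_ps`, `out`, `seed`.  Every referenced path must exist; this
#' is checked before any computation.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(probe_radius = 1.4, n_sphere_points = 960,
                   interface_threshold = 1.0, atom_epsilon = 0.1,
                   frames = 100, spacing_ps = 100, cutoff = 4.0,
                   out = "rescore_out", seed = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$binder_a) || is.null(config$binder_b))
    stop("config needs binder_a and binder_b chain lists")
  if (is.null(config$poses)) stop("config needs 'poses'")
  if (length(config$poses) == 1 && dir.exists(config$poses[[1]])) {
    files <- list.files(config$poses[[1]], pattern = "\\.pdb$",
                        full.names = TRUE)
    files <- files[!grepl("_rep[0-9]+\\.pdb$", files)]
    if (!length(files)) stop("no pose PDB files in ", config$poses[[1]])
    config$pose_files <- setNames(files,
                                  sub("\\.pdb$", "", basename(files)))
  } else {
    files <- unlist(config$poses)
    config$pose_files <- setNames(files,
                                  sub("\\.pdb$", "", basename(files)))
  }
  missing <- config$pose_files[!file.exists(config$pose_files)]
  if (length(missing))
    stop("pose file(s) not found: ", paste(missing, collapse = ", "))
  if (is.null(config$trajectories)) {
    config$traj_files <- lapply(names(config$pose_files), function(id) {
      dir <- dirname(config$pose_files[[id]])
      list.files(dir, pattern = paste0("^", id, "_rep[0-9]+\\.pdb$"),
                 full.names = TRUE)
    })
    names(config$traj_files) <- names(config$pose_files)
  } else {
    config$traj_files <- lapply(config$trajectories, unlist)
  }
  for (id in names(config$pose_files)) {
    tf <- config$traj_files[[id]]
    if (is.null(tf) || !length(tf))
      stop("no trajectories for pose ", id)
    if (!all(file.exists(tf)))
      stop("trajectory file(s) not found for pose ", id, ": ",
           paste(tf[!file.exists(tf)], collapse = ", "))
  }
  if (!is.null(config$external_scores) &&
      is.character(config$external_scores) &&
      !file.exists(config$external_scores))
    stop("external_scores file not found: ", config$external_scores)
  class(config) <- c("run_config", "list")
  config
}

#' Run the full rescoring pipeline from a configuration
#'
#' Reads poses and replica trajectories, strips hydrogens, assigns
#' radii, runs [rescore_poses()], and writes the stage reports under the
#' configured output directory: `pose_table.tsv`, `merit.tsv` (benchmark
#' mode) and `summary.json`.  Deterministic given inputs and seed.
#'
#' @param config see [read_run_config()].
#' @return the `ranking_report`, invisibly.
#' @export
run_rescoring <- function(config) {
  config <- read_run_config(config)
  params <- surface_params(probe_radius = config$probe_radius,
                           n_sphere_points = config$n_sphere_points)
  prep <- function(x) assign_radii(strip_hydrogens(x))
  poses <- lapply(config$pose_files, function(p)
    prep(get_frame(read_structure(p, dt = config$spacing_ps), 1)))
  trajectories <- lapply(config$traj_files, function(fs)
    lapply(fs, function(f) prep(read_structure(f, dt = config$spacing_ps))))
  split <- binder_split(unlist(config$binder_a), unlist(config$binder_b))
  scores <- NULL
  if (!is.null(config$external_scores)) {
    sc <- if (is.character(config$external_scores)) {
      read.table(config$external_scores, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
    } else config$external_scores
    scores <- setNames(sc$external_score, sc$pose_id)
  }
  report <- rescore_poses(poses, trajectories, split,
                          external_scores = scores,
                          nearest_native = config$nearest_native,
                          params = params,
                          n_frames_target = config$frames,
                          spacing_ps = config$spacing_ps,
                          residue_threshold = config$interface_threshold,
                          atom_epsilon = config$atom_epsilon)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write.table(report$pose_table, file.path(config$out, "pose_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$merit))
    write.table(report$merit$per_system,
                file.path(config$out, "merit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_poses = nrow(report$pose_table),
    classes = as.list(table(report$pose_table$class)),
    sigma = as.list(report$sigma),
    best_by_hbs_over_irmsd =
      report$pose_table$pose_id[which.min(report$pose_table$rank_hbs_over_irmsd)])
  if (!is.null(report$merit))
    summary$merit <- report$merit$counts
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
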