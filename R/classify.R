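# Stability classification, descriptor ranking, figures of merit.

#' Trajectory stability classifier thresholds
#'
#' Defaults follow standard practice in evaluating docked pose stability
#' under a destabilizing potential: mean iRMSD at or below 4 A means the
#' initial interface is conserved; above 5.5 A the initial binding
#' conformation is considered lost; a trajectory with mean iRMSD above
#' 14 A *and* mean BSA below 200 A^2 is unstable (the partners separate).
#' The 4.0-5.5 A band is reported as `ambiguous` and left to human
#' review.  "Stabilizes before the end" is quantified as: standard
#' deviation of the final `tail_fraction` of the iRMSD trace at or below
#' `tail_std_max`.
#'
#' @param conserved_max,lost_min,unstable_irmsd iRMSD thresholds (A).
#' @param unstable_bsa BSA threshold (A^2).
#' @param tail_fraction fraction of the trace used for the tail test.
#' @param tail_std_max max tail standard deviation (A) to call the tail
#'   stabilized.
#' @return list of class `classifier_params`.
#' @export
classifier_params <- function(conserved_max = 4.0, lost_min = 5.5,
                              unstable_irmsd = 14.0, unstable_bsa = 200.0,
                              tail_fraction = 0.2, tail_std_max = 1.0) {
  stopifnot(conserved_max < lost_min, lost_min < unstable_irmsd,
            tail_fraction > 0, tail_fraction <= 1)
  structure(list(conserved_max = conserved_max, lost_min = lost_min,
                 unstable_irmsd = unstable_irmsd,
                 unstable_bsa = unstable_bsa,
                 tail_fraction = tail_fraction,
                 tail_std_max = tail_std_max),
            class = "classifier_params")
}

STABILITY_CLASSES <- c("unstable", "new_interface", "ambiguous", "conserved")

#' Classify the stability of one trajectory
#'
#' Branches, in order: mean iRMSD <= `conserved_max` -> `conserved`;
#' mean iRMSD > `unstable_irmsd` and mean BSA < `unstable_bsa` ->
#' `unstable`; mean iRMSD > `lost_min` -> `new_interface` (with
#' `confidence` attribute `"high"` when the iRMSD tail has stabilized,
#' `"low"` otherwise); remaining band (`conserved_max`, `lost_min`] ->
#' `ambiguous` (requires visual review, never silently coerced).
#'
#' @param series a `descriptor_series`.
#' @param params a [classifier_params()].
#' @return character class with attribute `confidence`.
#' @export
classify_trajectory <- function(series, params = classifier_params()) {
  stopifnot(inherits(series, "descriptor_series"))
  s <- series$summary
  tr <- series$frames$irmsd
  n_tail <- max(2L, ceiling(params$tail_fraction * length(tr)))
  tail_sd <- if (length(tr) >= 2) {
    sd(tr[(length(tr) - n_tail + 1):length(tr)])
  } else 0
  stabilized <- tail_sd <= params$tail_std_max
  cls <- if (s$mean_irmsd <= params$conserved_max) {
    "conserved"
  } else if (s$mean_irmsd > params$unstable_irmsd &&
             s$mean_bsa < params$unstable_bsa) {
    "unstable"
  } else if (s$mean_irmsd > params$lost_min) {
    "new_interface"
  } else {
    "ambiguous"
  }
  confidence <- if (cls == "new_interface" && !stabilized) "low" else "high"
  structure(cls, confidence = confidence)
}

#' Pose-level class from replica classes
#'
#' Majority vote over the replica trajectory classes; ties resolve to the
#' worst class in the order unstable < new_interface < ambiguous <
#' conserved.
#'
#' @param classes character vector of replica classes.
#' @return single class string.
#' @export
classify_pose <- function(classes) {
  classes <- as.character(classes)
  if (!length(classes)) stop("no replica classes")
  bad <- setdiff(classes, STABILITY_CLASSES)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  tab <- table(factor(classes, levels = STABILITY_CLASSES))
  top <- names(tab)[tab == max(tab)]
  top[1]  # STABILITY_CLASSES is ordered worst-first
}

#' Default descriptor standard deviations (sigma)
#'
#' The within-sigma figure of merit measures whether the nearest-native
#' pose's descriptor value lies within one descriptor standard deviation
#' of the best-ranked pose's value.  These defaults are the benchmark
#' calibration: 10 (external docking score), 0.5 A (iRMSD), 50 A^2
#' (BSA), 1.5 atoms (HBS) and 1.6 1/A (HBS/iRMSD).
#'
#' @return named numeric vector keyed by descriptor column name.
#' @export
sigma_defaults <- function() {
  c(external_score = 10, mean_irmsd = 0.5, mean_bsa = 50,
    mean_hbs = 1.5, hbs_over_irmsd = 1.6)
}

#' Calibrate descriptor sigmas from trajectories
#'
#' sigma(descriptor) = the maximum per-frame standard deviation of that
#' descriptor over the trajectories whose binding interface showed some
#' stability (class `conserved` by default).  The external score has no
#' per-frame trace, so its sigma always comes from `fallback`.  With no
#' qualifying trajectory, all values fall back to [sigma_defaults()] with
#' a warning.
#'
#' @param series_list list of `descriptor_series`.
#' @param classes character vector of classes, parallel to `series_list`.
#' @param include classes considered interface-conserving.
#' @param fallback see [sigma_defaults()].
#' @return named numeric vector like [sigma_defaults()].
#' @export
compute_sigma <- function(series_list, classes,
                          include = "conserved",
                          fallback = sigma_defaults()) {
  stopifnot(length(series_list) == length(classes))
  keep <- classes %in% include
  if (!any(keep)) {
    warning("no interface-conserving trajectory; using fallback sigmas")
    return(fallback)
  }
  sel <- series_list[keep]
  per_traj <- function(f) max(vapply(sel, f, numeric(1)))
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  out <- fallback
  out["mean_irmsd"] <- per_traj(function(s) s$summary$sd_irmsd)
  out["mean_bsa"] <- per_traj(function(s) s$summary$sd_bsa)
  out["mean_hbs"] <- per_traj(function(s) s$summary$sd_hbs)
  out["hbs_over_irmsd"] <- per_traj(function(s) {
    ok <- s$frames$irmsd > 0
    if (!any(ok)) return(0)
    sd0(s$frames$hbs[ok] / s$frames$irmsd[ok])
  })
  out
}

#' Ranking directions of the descriptors
#'
#' Lower-is-better (`"asc"`): external docking score, mean iRMSD.
#' Higher-is-better (`"desc"`): mean BSA, mean HBS, HBS/iRMSD.
#'
#' @return named character vector.
#' @export
descriptor_directions <- function() {
  c(external_score = "asc", mean_irmsd = "asc", mean_bsa = "desc",
    mean_hbs = "desc", hbs_over_irmsd = "desc")
}

#' Competition-rank poses on one descriptor
#'
#' Rank 1 is best; ties share the lowest applicable rank and the next
#' rank is skipped ("1-1-3").  Infinite values are allowed (an infinite
#' HBS/iRMSD ranks first under descending direction).  Missing values
#' rank last, with a warning.
#'
#' @param values numeric vector, one per pose.
#' @param direction `"asc"` (lower is better) or `"desc"`.
#' @return integer ranks.
#' @export
rank_poses <- function(values, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  v <- as.numeric(values)
  if (anyNA(v)) {
    warning(sum(is.na(v)), " missing descriptor value(s); ranked last")
    v[is.na(v)] <- if (direction == "asc") Inf else -Inf
  }
  key <- if (direction == "asc") v else -v
  as.integer(rank(key, ties.method = "min"))
}

#' Rank a pose descriptor table on every descriptor
#'
#' @param pose_df data.frame with a `pose_id` column and any of the
#'   descriptor columns named in [descriptor_directions()].
#' @return data.frame of integer ranks (same rows, `pose_id` kept).
#' @export
rank_pose_table <- function(pose_df) {
  dirs <- descriptor_directions()
  cols <- intersect(names(dirs), names(pose_df))
  if (!length(cols)) stop("no descriptor columns found")
  out <- data.frame(pose_id = pose_df$pose_id, stringsAsFactors = FALSE)
  for (cn in cols) out[[cn]] <- rank_poses(pose_df[[cn]], dirs[[cn]])
  out
}

#' First-quartile rank threshold
#'
#' `floor(n / 4)`: with 20 poses a rank of at most 5 counts as first
#' quartile; with 14 poses, at most 3.
#'
#' @param n number of poses.
#' @return integer threshold.
#' @export
first_quartile_rank <- function(n) as.integer(floor(n / 4))

#' Figures of merit from per-system pose descriptor tables
#'
#' For every system and descriptor: `min_to_min` - the nearest-native
#' pose is ranked first; `within_sigma` - its descriptor value lies
#' within one sigma of the best-ranked pose's value; `first_quartile` -
#' its rank is at most `floor(n/4)`.
#'
#' @param pose_tables named list of per-system data.frames, each with
#'   `pose_id` plus descriptor columns (see [descriptor_directions()]).
#' @param nearest_native named character vector: nearest-native pose id
#'   per system.
#' @param sigma named numeric vector, see [sigma_defaults()].
#' @return list of class `merit_report`: `per_system` (long data.frame)
#'   and `counts` (per descriptor).
#' @export
figures_of_merit <- function(pose_tables, nearest_native,
                             sigma = sigma_defaults()) {
  systems <- names(pose_tables)
  if (is.null(systems)) stop("pose_tables must be a named list")
  missing <- setdiff(systems, names(nearest_native))
  if (length(missing))
    stop("nearest_native missing for: ", paste(missing, collapse = ", "))
  rows <- list()
  for (sys in systems) {
    df <- pose_tables[[sys]]
    nn <- nearest_native[[sys]]
    if (!nn %in% df$pose_id)
      stop("nearest-native pose '", nn, "' not in system ", sys)
    ranks <- rank_pose_table(df)
    n <- nrow(df)
    q1 <- first_quartile_rank(n)
    for (cn in setdiff(names(ranks), "pose_id")) {
      rk <- ranks[[cn]]
      i_nn <- match(nn, df$pose_id)
      i_best <- which.min(rk)
      gap <- abs(df[[cn]][i_nn] - df[[cn]][i_best])
      if (!is.finite(gap)) gap <- if (rk[i_nn] == 1) 0 else Inf
      sg <- if (cn %in% names(sigma)) sigma[[cn]] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        system = sys, descriptor = cn, n_poses = n,
        rank_nearest_native = rk[i_nn],
        min_to_min = rk[i_nn] == 1L,
        within_sigma = if (is.na(sg)) NA else gap <= sg,
        first_quartile = rk[i_nn] <= q1,
        stringsAsFactors = FALSE)
    }
  }
  per_system <- do.call(rbind, rows)
  .merit_report(per_system)
}

#' Figures of merit from nearest-native ranks alone
#'
#' Tally mode for published benchmark tables that report only the rank
#' of the nearest-native pose per system and descriptor: computes
#' `min_to_min` and `first_quartile`; `within_sigma` needs descriptor
#' values and is reported as `NA`.
#'
#' @param rank_df data.frame with columns `system`, `n_poses`, plus one
#'   column of nearest-native ranks per descriptor.
#' @return a `merit_report`.
#' @export
merit_from_ranks <- function(rank_df) {
  stopifnot(all(c("system", "n_poses") %in% names(rank_df)))
  desc_cols <- setdiff(names(rank_df), c("system", "n_poses"))
  rows <- list()
  for (i in seq_len(nrow(rank_df))) {
    q1 <- first_quartile_rank(rank_df$n_poses[i])
    for (cn in desc_cols) {
      rk <- rank_df[[cn]][i]
      rows[[length(rows) + 1L]] <- data.frame(
        system = rank_df$system[i], descriptor = cn,
        n_poses = rank_df$n_poses[i], rank_nearest_native = rk,
        min_to_min = rk == 1L, within_sigma = NA,
        first_quartile = rk <= q1, stringsAsFactors = FALSE)
    }
  }
  .merit_report(do.call(rbind, rows))
}

.merit_report <- function(per_system) {
  counts <- do.call(rbind, lapply(split(per_system, per_system$descriptor),
                                  function(d) {
    data.frame(descriptor = d$descriptor[1], n_systems = nrow(d),
               min_to_min = sum(d$min_to_min),
               within_sigma = if (all(is.na(d$within_sigma))) NA_integer_
                              else sum(d$within_sigma, na.rm = TRUE),
               first_quartile = sum(d$first_quartile),
               first_quartile_pct = 100 * mean(d$first_quartile),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  structure(list(per_system = per_system, counts = counts),
            class = "merit_report")
}

#' @export
print.merit_report <- function(x, ...) {
  cat("merit_report over", length(unique(x$per_system$system)),
      "system(s):\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Summarize per-system run stability counts
#'
#' @param counts data.frame with columns `system`, `runs`, `conserved`,
#'   `new_interface`, `unstable` (runs per class must sum to `runs`).
#' @return list with `total_runs`, `unstable_runs`, `conserved_pct`
#'   (named per system), `conserved_pct_min`, `conserved_pct_max`.
#' @export
summarize_stability_counts <- function(counts) {
  need <- c("system", "runs", "conserved", "new_interface", "unstable")
  stopifnot(all(need %in% names(counts)))
  tot <- counts$conserved + counts$new_interface + counts$unstable
  if (any(tot != counts$runs))
    stop("class counts do not sum to runs for: ",
         paste(counts$system[tot != counts$runs], collapse = ", "))
  pct <- setNames(100 * counts$conserved / counts$runs, counts$system)
  list(total_runs = sum(counts$runs),
       unstable_runs = sum(counts$unstable),
       conserved_pct = pct,
       conserved_pct_min = min(pct),
       conserved_pct_max = max(pct))
}

#' Bundled eight-system benchmark tables
#'
#' Transcribed summary tables from a published eight-system
#' protein-protein docking rescoring benchmark (systems named by the PDB
#' code of the native complex): the per-system rank of the nearest-native
#' pose under each descriptor, and the per-system stability counts of
#' the SMD runs.  Used as worked-example inputs for the tallying and
#' figure-of-merit operations.
#'
#' @return data.frame (ranks: columns `system`, `n_poses`,
#'   `external_score`, `mean_bsa`, `mean_irmsd`, `mean_hbs`,
#'   `hbs_over_irmsd`; stability: columns `system`, `runs`, `conserved`,
#'   `new_interface`, `unstable`).
#' @export
load_benchmark_ranks <- function() {
  read.table(system.file("extdata", "benchmark_ranks.tsv",
                         package = "smdrescore", mustWork = TRUE),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname load_benchmark_ranks
#' @export
load_benchmark_stability <- function() {
  read.table(system.file("extdata", "benchmark_stability.tsv",
                         package = "smdrescore", mustWork = TRUE),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
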