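# Pairwise backbone interface RMSD matrix, Daura clustering, selection.

#' Pairwise backbone interface RMSD matrix of a pose set
#'
#' Entry (i, j) is the backbone iRMSD between poses i and j over the
#' union of the two poses' interface residue sets, after superposition on
#' that set.  Each pose's interface set is computed once from its own
#' conformation.
#'
#' @param poses list of `pp_structure`s sharing residue keys.
#' @param split a [binder_split()].
#' @param params a [surface_params()].
#' @param residue_threshold interface residue threshold, Angstrom^2.
#' @return list of class `distance_matrix` with `matrix` (n x n,
#'   symmetric, zero diagonal) and `ids`.
#' @export
irmsdb_matrix <- function(poses, split, params = surface_params(),
                          residue_threshold = 1.0) {
  n <- length(poses)
  ids <- names(poses)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sets <- lapply(poses, interface_keys, split = split, params = params,
                 residue_threshold = residue_threshold)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        keys <- union(sets[[i]], sets[[j]])
        if (!length(keys))
          stop("poses ", ids[i], " and ", ids[j],
               " have an empty union interface")
        m[i, j] <- m[j, i] <- irmsd(poses[[j]], poses[[i]], keys, "backbone")
      }
    }
  }
  structure(list(matrix = m, ids = ids), class = "distance_matrix")
}

#' Daura neighbor clustering on a distance matrix
#'
#' Greedy neighbor-count clustering: repeatedly take the pose with the
#' most neighbors within `cutoff` (a pose is its own neighbor) as the
#' next cluster center (medoid), remove the cluster, and iterate until no
#' pose remains.  Ties on the neighbor count go to the lowest pose index,
#' fixing a deterministic order.  Empty clusters cannot arise (every
#' cluster contains at least its medoid).
#'
#' @param dm a `distance_matrix` (see [irmsdb_matrix()]) or a plain
#'   symmetric matrix.
#' @param cutoff neighbor cutoff in Angstrom (default 4, the standard
#'   pose-clustering cutoff).
#' @return list of class `daura_clustering`: `clusters` (list of member
#'   id vectors, in formation order), `medoids` (id per cluster),
#'   `cutoff`.
#' @export
daura_cluster <- function(dm, cutoff = 4.0) {
  if (inherits(dm, "distance_matrix")) {
    m <- dm$matrix
    ids <- dm$ids
  } else {
    m <- as.matrix(dm)
    ids <- rownames(m)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  }
  if (nrow(m) != ncol(m) || any(m < 0) || any(abs(m - t(m)) > 1e-9))
    stop("need a symmetric non-negative distance matrix")
  remaining <- seq_len(nrow(m))
  clusters <- list()
  medoids <- character(0)
  while (length(remaining)) {
    nb <- vapply(remaining,
                 function(i) sum(m[i, remaining] <= cutoff), integer(1))
    center <- remaining[which.max(nb)]  # which.max takes the first maximum
    members <- remaining[m[center, remaining] <= cutoff]
    clusters[[length(clusters) + 1L]] <- ids[members]
    medoids <- c(medoids, ids[center])
    remaining <- setdiff(remaining, members)
  }
  structure(list(clusters = clusters, medoids = medoids, cutoff = cutoff),
            class = "daura_clustering")
}

#' @export
print.daura_clustering <- function(x, ...) {
  cat("daura_clustering:", length(x$clusters), "cluster(s) at cutoff",
      x$cutoff, "A; sizes:",
      paste(vapply(x$clusters, length, integer(1)), collapse = " "), "\n")
  invisible(x)
}

#' Select candidate poses from a clustering and score the selection
#'
#' Returns the medoids of the `k` best-scored clusters and, when medoid
#' backbone iRMSDs against a reference are supplied, the two benchmark
#' admission verdicts: (1) some medoid lies below `near_native_cutoff`,
#' and (2) some such medoid is among the selected top-`k` clusters.
#'
#' @param clustering a `daura_clustering`.
#' @param scores numeric external score per pose id (named vector
#'   covering every clustered pose; lower is better).
#' @param k number of best-scored clusters to keep (default 20); capped
#'   at the cluster count with a warning.
#' @param medoid_irmsdb optional named numeric vector: backbone iRMSD of
#'   each medoid against the reference structure.
#' @param near_native_cutoff Angstrom (default 4).
#' @param cluster_score `"best"` (default, lowest member score) or
#'   `"mean"`.
#' @return list of class `pose_selection`: `table` (data.frame with
#'   cluster, medoid, size, score, rank, selected, irmsdb_vs_reference),
#'   `criterion1`, `criterion2` (logical or NA when no reference data).
#' @export
select_candidate_poses <- function(clustering, scores, k = 20,
                                   medoid_irmsdb = NULL,
                                   near_native_cutoff = 4.0,
                                   cluster_score = c("best", "mean")) {
  cluster_score <- match.arg(cluster_score)
  stopifnot(inherits(clustering, "daura_clustering"))
  all_members <- unlist(clustering$clusters)
  missing <- setdiff(all_members, names(scores))
  if (length(missing))
    stop("scores missing for pose(s): ", paste(head(missing, 5),
                                               collapse = ", "))
  cs <- vapply(clustering$clusters, function(mem) {
    v <- scores[mem]
    if (cluster_score == "best") min(v) else mean(v)
  }, numeric(1))
  nclust <- length(clustering$clusters)
  if (k > nclust) {
    warning("k = ", k, " exceeds the ", nclust,
            " cluster(s); using all clusters")
    k <- nclust
  }
  rk <- rank(cs, ties.method = "first")
  sel <- rk <= k
  tab <- data.frame(cluster = seq_len(nclust),
                    medoid = clustering$medoids,
                    size = vapply(clustering$clusters, length, integer(1)),
                    score = cs, rank = rk, selected = sel,
                    stringsAsFactors = FALSE)
  crit1 <- crit2 <- NA
  if (!is.null(medoid_irmsdb)) {
    v <- medoid_irmsdb[tab$medoid]
    if (anyNA(v)) stop("medoid_irmsdb does not cover every medoid")
    tab$irmsdb_vs_reference <- unname(v)
    crit1 <- any(v < near_native_cutoff)
    crit2 <- any(v[sel] < near_native_cutoff)
  }
  structure(list(table = tab, criterion1 = crit1, criterion2 = crit2,
                 k = k), class = "pose_selection")
}

#' Write a distance matrix as TSV
#' @param dm a `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  write.table(dm$matrix, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a distance matrix from TSV
#' @param path TSV written by [write_distance_matrix()].
#' @return a `distance_matrix`.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE))
  structure(list(matrix = m, ids = rownames(m)), class = "distance_matrix")
}
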