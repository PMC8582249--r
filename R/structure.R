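#' @useDynLib smdrescore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd setNames rnorm runif aggregate
#' @importFrom utils read.table write.table head
NULL

# ---- containers ------------------------------------------------------------

#' Construct a single-frame structure
#'
#' A `pp_structure` is the package's frame container: an atom table plus an
#' n x 3 coordinate matrix.  Atom identity is the PDB triple
#' (chain, resid, insertion code) together with the atom name; 1-based PDB
#' residue numbering is preserved and never renumbered.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resid`, `icode` (empty string when absent) and
#'   optionally `radius` (NA until assigned).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `pp_structure`.
#' @export
pp_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  need <- c("serial", "name", "element", "resname", "chain", "resid", "icode")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"radius" %in% names(atoms)) atoms$radius <- rep(NA_real_, nrow(atoms))
  if (any(!is.finite(xyz)))
    stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, icode, name) atom identity: ",
         key[duplicated(key)][1])
  dimnames(xyz) <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "pp_structure")
}

#' @export
print.pp_structure <- function(x, ...) {
  cat("pp_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s) [",
      paste(sort(unique(x$atoms$chain)), collapse = " "), "]\n")
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

#' Residue keys of a structure
#'
#' @param structure a `pp_structure`.
#' @return Character vector, one `chain:resid:icode` key per atom.
#' @export
residue_keys <- function(structure) {
  with(structure$atoms, paste(chain, resid, icode, sep = ":"))
}

#' Construct a trajectory
#'
#' Ordered frames over an identical atom roster.  The default potential
#' scaling factor metadata (`lambda = 0.6`) records the SMD setting the
#' descriptor thresholds were tuned for; it is carried, not applied.
#'
#' @param atoms atom table shared by all frames (see [pp_structure()]).
#' @param coords list of n x 3 coordinate matrices, one per frame.
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @param lambda potential-energy scaling factor metadata.
#' @return An object of class `pp_trajectory`.
#' @export
pp_trajectory <- function(atoms, coords, times = NULL, lambda = 0.6) {
  stopifnot(is.list(coords), length(coords) >= 1)
  n <- nrow(atoms)
  for (f in coords)
    if (nrow(f) != n) stop("all frames must share the atom roster")
  if (is.null(times)) times <- seq_len(length(coords)) - 1
  if (length(times) != length(coords))
    stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  ref <- pp_structure(atoms, coords[[1]])  # validates atoms/coords once
  structure(list(atoms = ref$atoms, coords = lapply(coords, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  }), times = as.numeric(times), lambda = lambda), class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat("pp_trajectory:", length(x$coords), "frames x", nrow(x$atoms),
      "atoms; t =", x$times[1], "..", x$times[length(x$times)],
      "ps; lambda =", x$lambda, "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `pp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame of a trajectory as a structure
#'
#' @param traj a `pp_trajectory`.
#' @param i frame index (1-based).
#' @return A `pp_structure`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  structure(list(atoms = traj$atoms, xyz = traj$coords[[i]]),
            class = "pp_structure")
}

# ---- PDB I/O (bio3d backend) ----------------------------------------------

#' Read a structure or multi-MODEL trajectory from a PDB file
#'
#' One frame per MODEL record (a single frame when no MODEL records are
#' present); atom order is preserved.  Alternate locations other than
#' `''`/`'A'` are dropped.  Frame times default to `dt * (0:(nframes-1))`.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ps used when the file carries no time
#'   annotation (PDB has none); defaults to 100 ps, the analysis grid the
#'   descriptor protocol assumes.
#' @param lambda scaling-factor metadata stored on the trajectory.
#' @return A `pp_trajectory`.
#' @export
read_structure <- function(path, dt = 100, lambda = 0.6) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  nmodels <- nrow(pdb$xyz)
  xyz_all <- matrix(pdb$xyz, nrow = nmodels)
  ele <- at$elesy
  bad <- is.na(ele) | !nzchar(trimws(ele))
  if (any(bad))
    ele[bad] <- suppressWarnings(bio3d::atom2ele(at$elety[bad]))
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = toupper(trimws(ele)),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resid = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[keep, , drop = FALSE]
  coords <- lapply(seq_len(nmodels), function(m) {
    xyz <- matrix(xyz_all[m, ], ncol = 3, byrow = TRUE)
    xyz[keep, , drop = FALSE]
  })
  pp_trajectory(atoms, coords, times = dt * (seq_len(nmodels) - 1),
                lambda = lambda)
}

#' Write a structure or trajectory as a (multi-MODEL) PDB file
#'
#' @param x a `pp_structure` or `pp_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "pp_structure"))
    x <- pp_trajectory(x$atoms, list(x$xyz))
  stopifnot(inherits(x, "pp_trajectory"))
  at <- x$atoms
  xyz <- do.call(rbind, lapply(x$coords, function(m) as.vector(t(m))))
  bio3d::write.pdb(
    file = path,
    xyz = if (nrow(xyz) == 1) as.vector(xyz) else xyz,
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$name,
    resid = at$resname,
    chain = at$chain,
    resno = at$resid,
    insert = ifelse(nzchar(at$icode), at$icode, ""),
    elesy = at$element
  )
  invisible(path)
}

# ---- hydrogens, radii, splits ----------------------------------------------

#' Remove hydrogen atoms
#'
#' All downstream surface and descriptor calculations operate on heavy
#' atoms only; this is the canonical first preprocessing step.
#'
#' @param x a `pp_structure` or `pp_trajectory`.
#' @return Object of the same class containing heavy atoms only.
#' @export
strip_hydrogens <- function(x) {
  is_h <- function(atoms) atoms$element %in% c("H", "D")
  if (inherits(x, "pp_structure")) {
    keep <- !is_h(x$atoms)
    return(structure(list(atoms = x$atoms[keep, , drop = FALSE],
                          xyz = x$xyz[keep, , drop = FALSE]),
                     class = "pp_structure"))
  }
  stopifnot(inherits(x, "pp_trajectory"))
  keep <- !is_h(x$atoms)
  structure(list(atoms = x$atoms[keep, , drop = FALSE],
                 coords = lapply(x$coords, function(m) m[keep, , drop = FALSE]),
                 times = x$times, lambda = x$lambda),
            class = "pp_trajectory")
}

#' Default atomic radii table
#'
#' An AMBER-style heavy-atom radii set (plus a hydrogen radius for files
#' that retain protons), shipped as plain text in
#' `inst/extdata/radii_default.txt`.  Rows are `resname atom radius` with
#' `*` wildcards; element fallbacks are wildcard rows keyed by element
#' symbol.
#'
#' @return data.frame with columns `resname`, `name`, `radius`.
#' @export
default_radii_table <- function() {
  read_radii_table(system.file("extdata", "radii_default.txt",
                               package = "smdrescore", mustWork = TRUE))
}

#' Read a radii table from a plain-text file
#'
#' @param path whitespace-separated file with columns resname, atom name
#'   and radius (Angstrom); `*` acts as a wildcard in the first two
#'   columns.  Lines starting with `#` are comments.
#' @return data.frame with columns `resname`, `name`, `radius`.
#' @export
read_radii_table <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("resname", "name", "radius"),
                    colClasses = c("character", "character", "numeric"))
  if (any(!is.finite(tab$radius)) || any(tab$radius <= 0))
    stop("radii must be positive finite numbers")
  tab
}

#' Assign per-atom radii from a radii table
#'
#' Lookup order: exact (resname, atom name), then (`*`, atom name), then
#' the element fallback row (`*`, element symbol).
#'
#' @param x a `pp_structure` or `pp_trajectory`.
#' @param table radii table, see [read_radii_table()]; defaults to the
#'   shipped table.
#' @return `x` with `atoms$radius` filled.
#' @export
assign_radii <- function(x, table = default_radii_table()) {
  atoms <- x$atoms
  r <- rep(NA_real_, nrow(atoms))
  exact <- paste(table$resname, table$name)
  idx <- match(paste(atoms$resname, atoms$name), exact)
  r <- table$radius[idx]
  miss <- is.na(r)
  if (any(miss)) {
    idx <- match(paste("*", atoms$name[miss]), exact)
    r[miss] <- table$radius[idx]
  }
  miss <- is.na(r)
  if (any(miss)) {
    idx <- match(paste("*", atoms$element[miss]), exact)
    r[miss] <- table$radius[idx]
  }
  if (anyNA(r)) {
    bad <- unique(with(atoms[is.na(r), , drop = FALSE],
                       paste0(resname, "/", name, " (element ", element, ")")))
    stop("no radius for atom type(s): ", paste(bad, collapse = ", "))
  }
  x$atoms$radius <- r
  x
}

#' Define which chains form each binder
#'
#' @param binder_a,binder_b character vectors of chain identifiers; must
#'   be disjoint and non-empty.
#' @return An object of class `binder_split`.
#' @export
binder_split <- function(binder_a, binder_b) {
  binder_a <- unique(as.character(binder_a))
  binder_b <- unique(as.character(binder_b))
  if (!length(binder_a) || !length(binder_b))
    stop("both binders need at least one chain")
  if (length(intersect(binder_a, binder_b)))
    stop("binder chain sets overlap: ",
         paste(intersect(binder_a, binder_b), collapse = ", "))
  structure(list(binder_a = binder_a, binder_b = binder_b),
            class = "binder_split")
}

#' Partition atoms of a structure into the two binders
#'
#' @param structure a `pp_structure`.
#' @param split a [binder_split()].
#' @return list with integer atom index vectors `a` and `b` (atoms of
#'   chains outside the split belong to neither).
#' @export
split_binders <- function(structure, split) {
  stopifnot(inherits(split, "binder_split"))
  chains <- structure$atoms$chain
  absent <- setdiff(c(split$binder_a, split$binder_b), unique(chains))
  if (length(absent))
    stop("chain(s) not present in structure: ", paste(absent, collapse = ", "))
  list(a = which(chains %in% split$binder_a),
       b = which(chains %in% split$binder_b))
}

subset_structure <- function(structure, idx) {
  structure(list(atoms = structure$atoms[idx, , drop = FALSE],
                 xyz = structure$xyz[idx, , drop = FALSE]),
            class = "pp_structure")
}

# ---- xyzr ------------------------------------------------------------------

#' Write coordinates plus radii in xyzr format
#'
#' One line per atom: `x y z radius`, fixed three-decimal formatting, the
#' input format of grid-based molecular surfacers.
#'
#' @param structure a `pp_structure` with radii assigned.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyzr <- function(structure, path) {
  r <- structure$atoms$radius
  if (anyNA(r)) stop("assign radii before writing xyzr")
  lines <- sprintf("%.3f %.3f %.3f %.3f",
                   structure$xyz[, 1], structure$xyz[, 2],
                   structure$xyz[, 3], r)
  writeLines(lines, path)
  invisible(path)
}

#' Read an xyzr file
#'
#' @param path whitespace-separated file with columns x, y, z, radius.
#' @return data.frame with columns `x`, `y`, `z`, `radius`.
#' @export
read_xyzr <- function(path) {
  read.table(path, header = FALSE, col.names = c("x", "y", "z", "radius"),
             colClasses = "numeric")
}

# ---- misc helpers ----------------------------------------------------------

# Evaluate expr with a temporary RNG state seeded from `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
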