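# Independent oracles used to validate the package's own implementations.
# Each one is written against the definition, not against the code paths
# it checks.

# Monte-Carlo SASA: sample uniform random directions on each atom's
# probe-inflated sphere and count the samples outside every neighbouring
# inflated sphere.
mc_sasa_oracle <- function(xyz, radii, probe = 1.4, n_samples = 1e5) {
  n <- nrow(xyz)
  ext <- radii + probe
  vapply(seq_len(n), function(i) {
    dirs <- matrix(rnorm(3 * n_samples), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs * ext[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= ext[j]^2
    }
    4 * pi * ext[i]^2 * mean(free)
  }, numeric(1))
}

# Horn's quaternion method for the optimal superposition RMSD; an
# algebraic route fully independent of the SVD-based Kabsch fit.
quaternion_rmsd_oracle <- function(reference, mobile) {
  n <- nrow(reference)
  Yc <- scale(reference, scale = FALSE)
  Xc <- scale(mobile, scale = FALSE)
  S <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lmax) / n
  sqrt(max(0, msd))
}

# Literal greedy neighbor-count clustering, re-derived from the
# definition: most neighbors within the cutoff wins (self included),
# lowest index on ties, members removed, repeat.
brute_daura_oracle <- function(m, cutoff) {
  left <- seq_len(nrow(m))
  clusters <- list()
  medoids <- integer(0)
  while (length(left)) {
    counts <- sapply(left, function(i) sum(m[i, left] <= cutoff))
    best <- left[counts == max(counts)]
    center <- min(best)
    members <- left[m[center, left] <= cutoff]
    clusters[[length(clusters) + 1]] <- members
    medoids <- c(medoids, center)
    left <- setdiff(left, members)
  }
  list(clusters = clusters, medoids = medoids)
}

# O(n^2) all-pairs residue contact scan from the definition.
brute_contacts_oracle <- function(structure, split, cutoff) {
  idx <- split_binders(structure, split)
  keys <- residue_keys(structure)
  out <- character(0)
  for (ra in unique(keys[idx$a])) {
    for (rb in unique(keys[idx$b])) {
      xa <- structure$xyz[idx$a[keys[idx$a] == ra], , drop = FALSE]
      xb <- structure$xyz[idx$b[keys[idx$b] == rb], , drop = FALSE]
      dmin <- min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                         2 * xa %*% t(xb)))
      if (dmin <= cutoff) out <- c(out, paste(ra, rb, sep = "|"))
    }
  }
  sort(out)
}

# Minimal hand-built structure: one chain per element of `chains`,
# one CA-only residue per row of coordinates.
ca_only_structure <- function(xyz, chains, resids = seq_along(chains),
                              resnames = "ALA", radius = 1.7) {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resname = rep(resnames, length.out = n),
                      chain = chains, resid = resids, icode = "",
                      radius = radius, stringsAsFactors = FALSE)
  pp_structure(atoms, xyz)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
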