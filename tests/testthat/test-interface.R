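# Interface detection, residue classes, HBS, contacts, FNAT.

test_that("the Kyte-Doolittle tri-classification covers all 20 residues", {
  tab <- residue_class_table()
  hydrophobic <- c("CYS", "MET", "PHE", "ILE", "LEU", "ALA", "VAL", "GLY")
  neutral <- c("SER", "THR", "TYR", "PRO", "TRP")
  hydrophilic <- c("LYS", "ASP", "GLN", "ASN", "HIS", "ARG", "GLU")
  expect_setequal(setdiff(names(tab), "MSE"),
                  c(hydrophobic, neutral, hydrophilic))
  expect_true(all(classify_residue(hydrophobic) == "hydrophobic"))
  expect_true(all(classify_residue(neutral) == "neutral"))
  expect_true(all(classify_residue(hydrophilic) == "hydrophilic"))
  expect_equal(classify_residue("MSE"), "hydrophobic")  # MET alias
  expect_error(classify_residue("XYZ"), "unknown")
  expect_equal(classify_residue("XYZ", default = "neutral"), "neutral")
})

test_that("interface residues are exactly the constructed contacts", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 4), c(2, 4)),
                      composition_a = c("ALA", "LEU", "ALA", "PHE", "ALA", "ALA"),
                      composition_b = "LEU", seed = 3)
  res <- interface_residues(d$structure, d$split)
  expect_setequal(paste(res$binder, res$resid), c("A 2", "A 4", "B 2", "B 4"))
  expect_true(all(res$dsasa > 1.0))
  # far apart: no interface at all
  apart <- d$structure
  bidx <- split_binders(apart, d$split)$b
  apart$xyz[bidx, 3] <- apart$xyz[bidx, 3] + 100
  expect_equal(nrow(interface_residues(apart, d$split)), 0)
  expect_equal(compute_bsa(apart, d$split), 0)
})

test_that("the residue delta-SASA threshold is strict and monotone", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "LEU", seed = 5)
  res <- interface_residues(d$structure, d$split)
  dmax <- max(res$dsasa)
  # threshold exactly equal to a residue's dSASA excludes it (strict >)
  res_hi <- interface_residues(d$structure, d$split, residue_threshold = dmax)
  expect_false(dmax %in% res_hi$dsasa)
  # raising the threshold can only shrink the set
  sizes <- vapply(c(0.5, 1, 5, 20, 1e6), function(th)
    nrow(interface_residues(d$structure, d$split, residue_threshold = th)),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0)
})

test_that("interface atoms require both residue and atom-level burial", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "LEU", seed = 5)
  ia <- interface_atoms(d$structure, d$split)
  expect_gt(length(ia$a), 0)
  keys <- residue_keys(d$structure)
  expect_true(all(keys[ia$a] == "A:2:"))
  expect_true(all(keys[ia$b] == "B:2:"))
  none <- interface_atoms(d$structure, d$split, atom_epsilon = Inf)
  expect_length(none$a, 0)
  expect_length(none$b, 0)
})

test_that("HBS counts pooled interface heavy atoms of hydrophobic residues", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 4), c(2, 4)),
                      composition_a = c("ALA", "LEU", "ALA", "SER", "ALA", "ALA"),
                      composition_b = c("ALA", "LEU", "ALA", "SER", "ALA", "ALA"),
                      seed = 7)
  ia <- interface_analysis(d$structure, d$split)
  # definition: hydrophobic interface atoms out of the atom table
  expect_equal(ia$hbs, sum(ia$atoms$class == "hydrophobic"))
  expect_lte(ia$hbs, nrow(ia$atoms))
  # SER (neutral) contributes interface atoms but not HBS
  expect_gt(sum(ia$atoms$resname == "SER"), 0)
  expect_false(any(ia$atoms$resname[ia$atoms$class == "hydrophobic"] == "SER"))
  # an all-hydrophobic interface puts every interface atom in the count
  d2 <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                       composition_b = "VAL", seed = 8)
  ia2 <- interface_analysis(d2$structure, d2$split)
  expect_equal(ia2$hbs, nrow(ia2$atoms))
  # alternate mode counts all heavy atoms of hydrophobic interface residues
  ia3 <- interface_analysis(d2$structure, d2$split, hbs_mode = "all_atoms")
  expect_gte(ia3$hbs, ia2$hbs)
})

test_that("residue contact tables match a brute-force scan", {
  # two CA-only residues 4 A apart -> one row at exactly 4
  st <- ca_only_structure(rbind(c(0, 0, 0), c(4, 0, 0)), chains = c("A", "B"))
  tab <- residue_contact_pairs(st, binder_split("A", "B"), cutoff = 5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$dist, 4)
  expect_true(is.na(tab$polar_dist))  # CA atoms are carbon
  far <- ca_only_structure(rbind(c(0, 0, 0), c(50, 0, 0)), chains = c("A", "B"))
  expect_equal(nrow(residue_contact_pairs(far, binder_split("A", "B"), 5)), 0)
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 3, 5), c(2, 3, 5)),
                      composition_a = "LEU", composition_b = "THR", seed = 9)
  got <- residue_contact_pairs(d$structure, d$split, cutoff = 6.5)
  expect_identical(sort(paste(got$res_a, got$res_b, sep = "|")),
                   brute_contacts_oracle(d$structure, d$split, 6.5))
  # polar-polar distances come from N/O atoms only
  expect_true(all(is.na(got$polar_dist) | got$polar_dist >= got$dist - 1e-9 |
                    got$polar_dist > 0))
})

test_that("FNAT is 1 on the reference, 0 when separated, 1/2 by construction", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 5), c(2, 5)),
                      composition_a = "LEU", composition_b = "LEU", seed = 11)
  expect_equal(fnat(d$structure, d$structure, d$split), 1.0)
  apart <- d$structure
  bidx <- split_binders(apart, d$split)$b
  apart$xyz[bidx, 3] <- apart$xyz[bidx, 3] + 100
  expect_equal(fnat(apart, d$structure, d$split), 0.0)
  expect_error(fnat(d$structure, apart, d$split), "no cross-binder contacts")
  # break exactly one of the two reference contacts
  half <- d$structure
  keys <- residue_keys(half)
  tip <- which(keys == "B:5:" & half$atoms$name != "N" &
                 half$atoms$name != "CA" & half$atoms$name != "C" &
                 half$atoms$name != "O")
  half$xyz[tip, 3] <- half$xyz[tip, 3] + 10
  expect_equal(fnat(half, d$structure, d$split), 0.5)
  # rigid motion of the whole pose leaves FNAT unchanged
  set.seed(12)
  moved <- d$structure
  moved$xyz <- moved$xyz %*% random_rotation() + 5
  expect_equal(fnat(moved, d$structure, d$split), 1.0)
})

test_that("per-frame interface reports tabulate counts and classes", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "SER", seed = 13)
  tr <- synthesize_trajectory(d$structure, d$split,
                              trajectory_spec("conserved", n_frames = 3,
                                              jitter_sigma = 0, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- write_interface_report(tr, d$split, path)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$bsa == rep$bsa[1]))
  expect_true(all(rep$hbs <= rep$n_atoms_a + rep$n_atoms_b))
  expect_true(file.exists(path))
})
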