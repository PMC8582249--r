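# Toy dimer and trajectory generators: construction guarantees and
# calibration of the three behaviors.

test_that("single-residue chains in contact are exactly the interface", {
  d <- make_toy_dimer(n_res_a = 1, n_res_b = 1, composition_a = "LEU",
                      composition_b = "LEU", contact_pairs = cbind(1, 1),
                      seed = 1)
  res <- interface_residues(d$structure, d$split)
  expect_setequal(paste(res$binder, res$resid), c("A 1", "B 1"))
})

test_that("a contact-free dimer has zero BSA", {
  d <- make_toy_dimer(contact_pairs = NULL, seed = 2)
  expect_equal(compute_bsa(d$structure, d$split), 0)
  expect_equal(nrow(interface_residues(d$structure, d$split)), 0)
})

test_that("dimers are pure functions of their seed", {
  a <- make_toy_dimer(seed = 33)
  b <- make_toy_dimer(seed = 33)
  expect_identical(a$structure$xyz, b$structure$xyz)
  c <- make_toy_dimer(seed = 34)
  expect_false(identical(a$structure$xyz, c$structure$xyz))
})

test_that("infeasible contact requests are placement errors", {
  expect_error(make_toy_dimer(composition_a = "GLY", composition_b = "LEU",
                              contact_pairs = cbind(2, 2), seed = 1),
               "placement error")
  # incompatible offsets cannot both be realized
  expect_error(make_toy_dimer(contact_pairs = cbind(c(1, 1), c(1, 6)),
                              composition_a = "LEU", composition_b = "LEU",
                              seed = 1),
               "placement error")
})

test_that("trajectories are deterministic and honor the jitter limit", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "LEU", seed = 3)
  spec <- trajectory_spec("conserved", n_frames = 10, jitter_sigma = 0.4,
                          seed = 9)
  t1 <- synthesize_trajectory(d$structure, d$split, spec)
  t2 <- synthesize_trajectory(d$structure, d$split, spec)
  expect_identical(t1$coords, t2$coords)
  frozen <- synthesize_trajectory(d$structure, d$split,
                                  trajectory_spec("conserved", n_frames = 5,
                                                  jitter_sigma = 0, seed = 9))
  for (i in 2:5) expect_identical(frozen$coords[[i]], frozen$coords[[1]])
})

test_that("unbinding translates binder B linearly along the axis", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "LEU", seed = 4)
  tr <- synthesize_trajectory(d$structure, d$split,
                              trajectory_spec("unbind", n_frames = 100,
                                              separation_rate = 0.5,
                                              jitter_sigma = 0, seed = 1))
  idx <- split_binders(d$structure, d$split)
  sep <- function(xyz) sqrt(sum((colMeans(xyz[idx$b, ]) -
                                   colMeans(xyz[idx$a, ]))^2))
  expect_equal(sep(tr$coords[[100]]) - sep(tr$coords[[1]]), 49.5,
               tolerance = 1e-9)
})

test_that("behavior calibration gives the intended stability classes", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 5), c(2, 5)),
                      composition_a = c("ALA", "LEU", "ALA", "ALA", "SER", "ALA"),
                      composition_b = c("ALA", "LEU", "ALA", "ALA", "SER", "ALA"),
                      seed = 5)
  sp <- surface_params(n_sphere_points = 144)
  for (seed in c(1, 17)) {
    cons <- analyze_trajectory(
      synthesize_trajectory(d$structure, d$split,
                            trajectory_spec("conserved", jitter_sigma = 0.5,
                                            seed = seed)),
      d$split, params = sp)
    expect_lt(cons$summary$mean_irmsd, 4)
    expect_equal(as.character(classify_trajectory(cons)), "conserved")
    unb <- analyze_trajectory(
      synthesize_trajectory(d$structure, d$split,
                            trajectory_spec("unbind", separation_rate = 0.6,
                                            seed = seed)),
      d$split, params = sp)
    expect_equal(as.character(classify_trajectory(unb)), "unstable")
  }
  drift <- analyze_trajectory(
    synthesize_trajectory(d$structure, d$split,
                          trajectory_spec("drift", seed = 1)),
    d$split, params = sp)
  expect_gt(drift$summary$mean_irmsd, 4)
  # the drifted pose settles on a genuinely different contact set
  last <- get_frame(synthesize_trajectory(
    d$structure, d$split, trajectory_spec("drift", seed = 1)), 100)
  new_contacts <- residue_contact_pairs(last, d$split, 5)
  old_contacts <- residue_contact_pairs(d$structure, d$split, 5)
  expect_false(setequal(paste(new_contacts$res_a, new_contacts$res_b),
                        paste(old_contacts$res_a, old_contacts$res_b)))
})

test_that("ensembles designate one near-native pose with the top HBS", {
  ens <- make_benchmark_ensemble(ensemble_spec(n_poses = 8, base_seed = 77))
  gt <- ens$ground_truth
  expect_equal(sum(gt$label == "near_native"), 1)
  expect_equal(gt$pose_id[gt$label == "near_native"], ens$near_native_id)
  sp <- surface_params(n_sphere_points = 240)
  hbs0 <- vapply(ens$poses, function(p)
    interface_analysis(p, ens$split, sp)$hbs, integer(1))
  nn <- ens$near_native_id
  expect_gt(hbs0[[nn]], max(hbs0[names(hbs0) != nn]))
  # regenerating from the same base seed is bit-identical
  ens2 <- make_benchmark_ensemble(ensemble_spec(n_poses = 8, base_seed = 77))
  expect_identical(ens$poses[[1]]$xyz, ens2$poses[[1]]$xyz)
  expect_identical(ens$trajectories[[3]][[2]]$coords,
                   ens2$trajectories[[3]][[2]]$coords)
})

test_that("ensembles serialize to PDB plus ground-truth tables", {
  ens <- make_benchmark_ensemble(ensemble_spec(n_poses = 3, replicas = 2,
                                               n_frames = 5, base_seed = 5))
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "pose_01.pdb")))
  expect_true(file.exists(file.path(dir, "pose_03_rep2.pdb")))
  gt <- read.table(file.path(dir, "ground_truth.tsv"), header = TRUE,
                   sep = "\t")
  expect_equal(nrow(gt), 3)
  back <- read_structure(file.path(dir, "pose_02_rep1.pdb"))
  expect_equal(n_frames(back), 5)
})
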