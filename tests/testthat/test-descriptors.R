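# Superposition, iRMSD, descriptor series, replica pooling.

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(41)
  X <- matrix(rnorm(30), ncol = 3)
  same <- kabsch_superpose(X, X)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  moved <- X %*% R + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(X, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(fit, moved), X, tolerance = 1e-9)
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches the quaternion oracle on random clouds", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    X <- matrix(rnorm(3 * n), ncol = 3)
    Y <- matrix(rnorm(3 * n), ncol = 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, quaternion_rmsd_oracle(X, Y),
                 tolerance = 1e-8)
  }
})

test_that("iRMSD is zero on the reference and under global rigid motion", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 4), c(2, 4)),
                      composition_a = "LEU", composition_b = "LEU", seed = 15)
  keys <- interface_keys(d$structure, d$split)
  expect_setequal(keys, c("A:2:", "A:4:", "B:2:", "B:4:"))
  expect_equal(irmsd(d$structure, d$structure, keys), 0, tolerance = 1e-12)
  set.seed(16)
  moved <- d$structure
  moved$xyz <- moved$xyz %*% random_rotation() + 10
  expect_equal(irmsd(moved, d$structure, keys), 0, tolerance = 1e-9)
  expect_equal(irmsd(moved, d$structure, keys, "backbone"), 0,
               tolerance = 1e-9)
})

test_that("iRMSD equals a brute-force oracle when one binder moves", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "LEU", n_res_a = 2, n_res_b = 2,
                      seed = 17)
  keys <- interface_keys(d$structure, d$split)
  frame <- d$structure
  bidx <- split_binders(frame, d$split)$b
  frame$xyz[bidx, 1] <- frame$xyz[bidx, 1] + 2
  sel <- residue_keys(d$structure) %in% keys
  want <- quaternion_rmsd_oracle(d$structure$xyz[sel, ], frame$xyz[sel, ])
  expect_equal(irmsd(frame, d$structure, keys, "heavy"), want,
               tolerance = 1e-8)
  # backbone mode uses the N/CA/C/O subset
  selb <- sel & d$structure$atoms$name %in% c("N", "CA", "C", "O")
  wantb <- quaternion_rmsd_oracle(d$structure$xyz[selb, ], frame$xyz[selb, ])
  expect_equal(irmsd(frame, d$structure, keys, "backbone"), wantb,
               tolerance = 1e-8)
})

test_that("frame subsampling picks the nearest frame per grid time", {
  # 1001 frames at 10 ps: the 100 ps grid keeps every 10th frame and
  # drops the t = 0 frame
  times <- 10 * (0:1000)
  idx <- subsample_indices(times, 100, 100)
  expect_length(idx, 100)
  expect_equal(idx, seq(11, 1001, by = 10))
  expect_false(1 %in% idx)
  # short trajectories are used whole, with a warning
  expect_warning(idx2 <- subsample_indices(0:49, 100, 100), "fewer")
  expect_equal(idx2, 1:50)
  # exact-length trajectories pass through untouched
  expect_equal(subsample_indices(100 * (0:99), 100, 100), 1:100)
})

test_that("a constant trajectory yields flat descriptor traces", {
  d <- make_toy_dimer(contact_pairs = cbind(2, 2), composition_a = "LEU",
                      composition_b = "LEU", seed = 19)
  tr <- synthesize_trajectory(d$structure, d$split,
                              trajectory_spec("conserved", n_frames = 20,
                                              jitter_sigma = 0, seed = 1))
  sp <- surface_params(n_sphere_points = 240)
  ds <- analyze_trajectory(tr, d$split, params = sp, n_frames_target = 20)
  expect_equal(ds$summary$mean_irmsd, 0, tolerance = 1e-9)
  expect_equal(ds$summary$sd_irmsd, 0, tolerance = 1e-9)
  expect_equal(ds$summary$mean_bsa,
               compute_bsa(d$structure, d$split, sp), tolerance = 1e-6)
  expect_equal(ds$summary$hbs_over_irmsd, Inf)
})

test_that("an unbinding trajectory shows rising iRMSD and vanishing BSA", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 4), c(2, 4)),
                      composition_a = "LEU", composition_b = "LEU", seed = 20)
  tr <- synthesize_trajectory(d$structure, d$split,
                              trajectory_spec("unbind", n_frames = 40,
                                              separation_rate = 0.5,
                                              jitter_sigma = 0, seed = 1))
  ds <- analyze_trajectory(tr, d$split, n_frames_target = 40,
                           params = surface_params(n_sphere_points = 240))
  expect_true(all(diff(ds$frames$irmsd) > -1e-9))
  expect_gt(ds$frames$irmsd[40], ds$frames$irmsd[2])
  expect_equal(ds$frames$bsa[40], 0)
})

test_that("the compiled per-frame descriptor path matches the reference path", {
  d <- make_toy_dimer(contact_pairs = cbind(c(2, 4), c(2, 4)),
                      composition_a = c("ALA", "LEU", "ALA", "SER", "ALA", "ALA"),
                      composition_b = "LEU", seed = 21)
  tr <- synthesize_trajectory(d$structure, d$split,
                              trajectory_spec("drift", n_frames = 12, seed = 2))
  sp <- surface_params(n_sphere_points = 144)
  fast <- analyze_trajectory(tr, d$split, params = sp, n_frames_target = 12)
  for (i in c(1, 6, 12)) {
    ia <- interface_analysis(get_frame(tr, i), d$split, sp)
    expect_equal(fast$frames$bsa[i], ia$bsa, tolerance = 1e-9)
    expect_equal(fast$frames$hbs[i], ia$hbs)
  }
})

test_that("descriptor means are invariant to frame order", {
  set.seed(22)
  frames <- data.frame(time_ps = 100 * (1:30),
                       irmsd = runif(30, 0, 5), irmsd_b = runif(30, 0, 4),
                       bsa = runif(30, 100, 900), hbs = rpois(30, 40))
  a <- descriptor_series(frames)
  shuffled <- frames[sample(30), ]
  shuffled$time_ps <- frames$time_ps
  b <- descriptor_series(shuffled)
  expect_equal(a$summary$mean_irmsd, b$summary$mean_irmsd)
  expect_equal(a$summary$sd_bsa, b$summary$sd_bsa)
  expect_equal(a$summary$hbs_over_irmsd, b$summary$hbs_over_irmsd)
})

test_that("replica pooling is frame-weighted", {
  mk <- function(n, irmsd, hbs) descriptor_series(data.frame(
    time_ps = 100 * seq_len(n), irmsd = irmsd, irmsd_b = irmsd,
    bsa = 500, hbs = hbs))
  one <- mk(10, 2, 40)
  expect_equal(pool_replicas(list(one))$mean_irmsd, 2)
  eq <- pool_replicas(list(mk(10, 1, 30), mk(10, 2, 40), mk(10, 3, 50)))
  expect_equal(eq$mean_irmsd, 2)
  expect_equal(eq$mean_hbs, 40)
  # unequal lengths: direct summation oracle
  r1 <- mk(100, 1, 30); r2 <- mk(100, 2, 40); r3 <- mk(50, 5, 60)
  pooled <- pool_replicas(list(r1, r2, r3))
  all_irmsd <- c(rep(1, 100), rep(2, 100), rep(5, 50))
  expect_equal(pooled$mean_irmsd, mean(all_irmsd))
  expect_equal(pooled$n_frames_total, 250)
  expect_equal(pooled$hbs_over_irmsd, pooled$mean_hbs / pooled$mean_irmsd)
  expect_error(pool_replicas(list()), "no replica")
})

test_that("the ratio descriptor handles its degenerate limits", {
  expect_equal(hbs_over_irmsd(list(mean_hbs = 60, mean_irmsd = 2)), 30)
  expect_equal(hbs_over_irmsd(list(mean_hbs = 0, mean_irmsd = 2)), 0)
  expect_equal(hbs_over_irmsd(list(mean_hbs = 10, mean_irmsd = 0)), Inf)
  # an infinite ratio ranks first under descending ranking
  expect_equal(rank_poses(c(3, Inf, 10), "desc"), c(3L, 1L, 2L))
})
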