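test_that("face-resolved distances equal the planted blocking distances exactly", {
  for (d in list(c(3.5, 6.0), c(2.5, 2.5), c(6.5, 3.0))) {
    tp <- build_template(generator_spec(d_block_re = d[1], d_block_si = d[2]))
    lcd <- ligand_carbene_distances(tp$frame, tp$topology)
    expect_equal(lcd$d_re, d[1], tolerance = 1e-9)
    expect_equal(lcd$d_si, d[2], tolerance = 1e-9)
    expect_true(lcd$closest_arm_re %in% 1:2)
    expect_true(lcd$closest_arm_si %in% 3:4)
  }
})

test_that("a face with no blocking ring yields a missing distance", {
  tp <- build_template(generator_spec(d_block_re = 3.5, d_block_si = 6.0))
  fr <- tp$frame
  # push the Re-side blocking rings across the carbene plane (y -> -y) so
  # all four rings sit on the Si face; distances to the donor centroid
  # (which lies at y = 0) are unchanged
  for (k in 1:2) {
    idx <- tp$topology$arms[[k]]$blocking_ring_idx
    fr$xyz[idx, 2] <- -fr$xyz[idx, 2]
  }
  lcd <- ligand_carbene_distances(fr, tp$topology)
  expect_true(is.na(lcd$d_re))
  expect_equal(lcd$d_si, 3.5, tolerance = 1e-9)
})

test_that("mirror reflection swaps d(Re) and d(Si) exactly", {
  gs <- generator_spec(d_block_re = 3.2, d_block_si = 5.1, noise_sigma = 0.1,
                       n_frames = 5, seed = 3)
  sim <- simulate_trajectory(gs)
  for (fr in sim$trajectory$frames) {
    lcd <- ligand_carbene_distances(fr, sim$topology)
    lcdm <- ligand_carbene_distances(reflect_frame(fr, "y"), sim$topology)
    expect_equal(lcd$d_re, lcdm$d_si, tolerance = 1e-12)
    expect_equal(lcd$d_si, lcdm$d_re, tolerance = 1e-12)
  }
})

test_that("distances are invariant to global rotation and translation", {
  set.seed(21)
  gs <- generator_spec(noise_sigma = 0.1, n_frames = 3, seed = 4)
  sim <- simulate_trajectory(gs)
  R <- random_rotation()
  shift <- c(12, -3, 7)
  for (fr in sim$trajectory$frames) {
    ref <- ligand_carbene_distances(fr, sim$topology)
    moved <- apply_rotation(fr, R, shift)
    got <- ligand_carbene_distances(moved, sim$topology)
    expect_equal(got$d_re, ref$d_re, tolerance = 1e-9)
    expect_equal(got$d_si, ref$d_si, tolerance = 1e-9)
    expect_equal(got$closest_arm_re, ref$closest_arm_re)
  }
})

test_that("face-resolved distances match a brute-force arms-by-faces oracle", {
  gs <- generator_spec(d_block_re = 3.5, d_block_si = 6.0, noise_sigma = 0.05,
                       n_frames = 20, seed = 5)
  sim <- simulate_trajectory(gs)
  for (fr in sim$trajectory$frames) {
    lcd <- ligand_carbene_distances(fr, sim$topology)
    orc <- oracle_ligand_distances(fr, sim$topology)
    expect_equal(lcd$d_re, orc$Re, tolerance = 1e-9)
    expect_equal(lcd$d_si, orc$Si, tolerance = 1e-9)
  }
})

test_that("descriptor series preserves frame order and repeats static geometry", {
  gs <- generator_spec(noise_sigma = 0, n_frames = 20, seed = 6)
  sim <- simulate_trajectory(gs)
  ser <- descriptor_series(sim$trajectory, sim$topology)
  expect_s3_class(ser, "DescriptorSeries")
  expect_equal(nrow(ser), 20L)
  expect_equal(ser$frame, 0:19)
  expect_true(all(ser$d_re == ser$d_re[1]))
  expect_true(all(ser$d_si == ser$d_si[1]))

  # alternating two geometries -> alternating records
  tp1 <- build_template(generator_spec(d_block_re = 3.0, d_block_si = 6.0))
  tp2 <- build_template(generator_spec(d_block_re = 4.0, d_block_si = 6.0))
  frames <- rep(list(tp1$frame, tp2$frame), 5)
  ser2 <- descriptor_series(trajectory(frames), tp1$topology)
  expect_equal(ser2$d_re, rep(c(3.0, 4.0), 5), tolerance = 1e-9)
})

test_that("planted Re blocking produces shorter mean d(Re) than d(Si)", {
  gs <- generator_spec(d_block_re = 3.5, d_block_si = 6.0, noise_sigma = 0.15,
                       n_frames = 200, seed = 7)
  sim <- simulate_trajectory(gs)
  ser <- descriptor_series(sim$trajectory, sim$topology)
  expect_lt(mean(ser$d_re), mean(ser$d_si))
})

test_that("buried volume reproduces the analytic single-sphere case with monotone mesh convergence", {
  fr <- new_frame(c("Rh", "Rh", "C"),
                  rbind(c(0, 0, 5), c(0, 0, -5), c(0, 0, 0)))
  analytic <- (1.70 * 1.17 / 3.5)^3 * 100
  errs <- vapply(c(0.2, 0.1, 0.05), function(m) {
    v <- buried_volume(fr, sphere_radius = 3.5, mesh = m,
                       center_xyz = c(0, 0, 0), exclude_idx = 1:2)
    abs(v - analytic)
  }, numeric(1))
  expect_lt(errs[2], 0.5)
  expect_true(all(diff(errs) < 0))
})

test_that("buried volume saturates at 0 and 100 in the degenerate limits", {
  bare <- new_frame(c("Rh", "Rh"), rbind(c(0, 0, 1.2), c(0, 0, -1.2)))
  expect_equal(buried_volume(bare, center_xyz = c(0, 0, 1.2), exclude_idx = 1:2), 0)
  giant <- new_frame(c("Rh", "Rh", "C"),
                     rbind(c(0, 0, 9), c(0, 0, -9), c(0, 0, 0)))
  expect_equal(buried_volume(giant, sphere_radius = 1.0, mesh = 0.1,
                             center_xyz = c(0, 0, 0), exclude_idx = 1:2), 100)
})

test_that("buried volume validates its sphere and mesh and excludes the Rh core", {
  fr <- new_frame(c("Rh", "Rh", "C"),
                  rbind(c(0, 0, 0), c(0, 0, 2.4), c(1, 0, 0)))
  expect_error(buried_volume(fr, sphere_radius = -1, center_xyz = c(0, 0, 0)),
               "sphere_radius")
  expect_error(buried_volume(fr, mesh = 1.0, center_xyz = c(0, 0, 0)),
               "mesh")
  tp <- build_template(generator_spec())
  v <- buried_volume(tp$frame, tp$topology)
  expect_gt(v, 0)
  expect_lt(v, 100)
  # the two Rh atoms themselves never count as buried volume
  core <- new_frame(c("Rh", "Rh"), rbind(c(0, 0, 0), c(0, 0, 2.4)))
  topo_stub <- structure(list(rh_carbene_idx = 1L, rh_distal_idx = 2L,
                              carbene_c_idx = 1L, ester_c_idx = 1L,
                              aryl_ring_idx = 1L, arms = list()),
                         class = "TopologyMap")
  expect_equal(buried_volume(core, topo_stub), 0)
})
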