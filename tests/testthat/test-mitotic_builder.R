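test_that("derived geometry evaluates the five relations", {
  p <- geometry_params(100, 400, 80, P_nm = 400, l_turn_Mb = 17,
                       rho_V_Mb_per_um3 = 44, mode = "cylinder_helix")
  g <- derive_geometry(p)
  # rho_L reconstructed from pitch: 17 Mb / 400 nm = 42.5 Mb/um
  expect_equal(p$rho_L_Mb_per_um, 42.5, tolerance = 1e-12)
  expect_equal(g$P_nm, 400, tolerance = 1e-9)
  expect_equal(g$L_cyl_nm, 100 / 42.5 * 1000, tolerance = 1e-9)
  expect_equal(g$R_cyl_nm, sqrt((100 / 44) / (100 / 42.5) / pi) * 1000,
               tolerance = 1e-9)
  expect_equal(g$R_cyl_nm, 554, tolerance = 0.002)
  expect_equal(g$N_loops, 250)

  # condensin I-only stretch: 100 Mb at 25 Mb/um -> 4 um
  p2 <- geometry_params(100, 100, 20, rho_L_Mb_per_um = 25,
                        rho_V_Mb_per_um3 = 77, mode = "stretched_periodic")
  g2 <- derive_geometry(p2)
  expect_equal(g2$L_cyl_nm, 4000, tolerance = 1e-9)
  expect_equal(g2$box_nm[3], 4000, tolerance = 1e-9)
  # box volume satisfies the volume density within 1e-9
  expect_equal(prod(g2$box_nm) / 1e9, 100 / 77, tolerance = 1e-9)

  # mutual consistency: recompute rho_L from returned P and l_turn
  expect_equal(p$l_turn_Mb / (g$P_nm / 1000), p$rho_L_Mb_per_um,
               tolerance = 1e-12)
  # volume conservation of the cylinder
  vol <- pi * (g$R_cyl_nm / 1000)^2 * (g$L_cyl_nm / 1000)
  expect_equal(vol, 100 / 44, tolerance = 0.02)
  expect_error(geometry_params(100, 400, 80, rho_V_Mb_per_um3 = 44),
               "exactly one")
})

test_that("consecutive loop arrays tile the chromosome exactly", {
  arr <- sample_consecutive_loops(100, 400, n_gap = 2, bp_per_bead = 2000,
                                  seed = 4)
  sizes <- arr$loops$end_bp - arr$loops$start_bp
  n <- nrow(arr$loops)
  expect_gt(n, 200)  # ~250 expected at 100 Mb / 400 kb
  expect_lt(n, 310)
  # sampled mean within 5% of l_loop (>= 500 loops for the SE)
  big <- sample_consecutive_loops(200, 100, n_gap = 0, bp_per_bead = 2000,
                                  seed = 4)
  big_sizes <- big$loops$end_bp - big$loops$start_bp
  expect_gte(nrow(big$loops), 500)
  expect_lt(abs(mean(big_sizes) / 1e5 - 1), 0.05)
  # coverage conservation in beads: loops + gaps == l_chrom
  gap_bp <- arr$n_gap * arr$bp_per_bead
  expect_equal(sum(sizes) + (n - 1) * gap_bp, arr$l_chrom_bp)
  # non-crossing by construction
  expect_equal(count_crossing_loops(arr), 0L)
  expect_error(sample_consecutive_loops(100, 0.1, bp_per_bead = 2000),
               "smaller than one bead")
})

test_that("nested subdivision respects root anchors", {
  root <- sample_consecutive_loops(20, 400, n_gap = 1, bp_per_bead = 2000,
                                   seed = 6)
  nest <- subdivide_nested(root, 100, n_gap_nested = 0, seed = 7)
  nested <- nest$loops[nest$loops$layer == "nested", ]
  roots <- nest$loops[nest$loops$layer == "root", ]
  # every nested loop inside exactly one root loop
  for (q in seq_len(nrow(nested))) {
    hit <- roots$start_bp <= nested$start_bp[q] &
      nested$end_bp[q] <= roots$end_bp
    expect_true(any(hit))
  }
  # mean ~4 nested loops per root
  ratio <- nrow(nested) / nrow(roots)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 5.5)
  # zero nested gaps -> nested loops exactly tile each root loop
  for (q in seq_len(nrow(roots))) {
    inside <- nested[nested$start_bp >= roots$start_bp[q] &
                       nested$end_bp <= roots$end_bp[q], ]
    expect_equal(sum(inside$end_bp - inside$start_bp),
                 roots$end_bp[q] - roots$start_bp[q])
  }
  expect_warning(subdivide_nested(root, 1000, seed = 8), "degenerate")
})

test_that("overlapping arrays cross; consecutive arrays never do", {
  ov <- sample_overlapping_loops(40, 900, 360, bp_per_bead = 4000, seed = 9)
  expect_true(ov$overlap_allowed)
  expect_gte(count_crossing_loops(ov), 1L)
  cons <- sample_consecutive_loops(40, 900, n_gap = 0, bp_per_bead = 4000,
                                   seed = 9)
  expect_equal(count_crossing_loops(cons), 0L)
})

test_that("force specs carry the advertised bonds, pins and ghosts", {
  arr <- sample_consecutive_loops(51, 400, n_gap = 2, bp_per_bead = 4000,
                                  seed = 10)
  gp <- geometry_params(51, 400, 80, P_nm = 400, l_turn_Mb = 17,
                        rho_V_Mb_per_um3 = 44, mode = "cylinder_helix")
  spec <- build_force_spec(arr, derive_geometry(gp))
  n_loops <- nrow(arr$loops)
  # chain bonds + one anchor bond per multi-bead loop + one gap bond
  # per junction (single-bead loops have coincident anchors, no bond)
  sizes <- arr$loops$end_bp - arr$loops$start_bp
  n_multi <- sum(sizes > arr$bp_per_bead)
  expect_equal(nrow(spec$bonds),
               (spec$n_beads - 1) + n_multi + (n_loops - 1))
  # 4 ghost particles, 2 terminal torsion quadruplets
  expect_equal(nrow(spec$ghosts), 4)
  expect_equal(length(spec$quadruplets), 2)
  # angular pins: 2 terminals + one anchor per helical turn
  expect_equal(nrow(spec$pins), 2 + floor(51 / 17))
  expect_true(all(spec$pins$kappa == 100))
  # anchor and gap bonds keep their nm geometry at any coarse-graining
  unit <- spec$unit_nm
  anchor_bonds <- spec$bonds[spec$bonds$L0 == 10 / unit, ]
  expect_equal(nrow(anchor_bonds), n_multi)
  gap_bonds <- spec$bonds[abs(spec$bonds$L0 - 90 / unit) < 1e-9, ]
  expect_equal(nrow(gap_bonds), n_loops - 1)
  # wall-overshoot compensation: potential is 0.3 kT at the target radius
  delta <- spec$cylinder$R - spec$cylinder$R_target
  expect_equal(spec$cylinder$eps * exp(-delta^2 / (2 * spec$cylinder$sigma^2)),
               0.3, tolerance = 1e-9)

  # overlapping mode: one pin per anchor at theta = pi (x_l + x_r) / l_turn
  ov <- sample_overlapping_loops(35, 900, 360, bp_per_bead = 4000, seed = 11)
  gpo <- geometry_params(35, 900, 0, P_nm = 400, l_turn_Mb = 17.5,
                         rho_V_Mb_per_um3 = 44, mode = "overlapping_helix")
  spo <- build_force_spec(ov, derive_geometry(gpo))
  expect_equal(nrow(spo$pins), 2 * nrow(ov$loops))
  expect_equal(unique(spo$pins$kappa), 1 / (1 - cos(1.2)), tolerance = 1e-9)
  root <- ov$loops
  expect_equal(spo$pins$theta0[seq_len(nrow(root))],
               pi * (root$start_bp + root$end_bp) / 17.5e6,
               tolerance = 1e-12)
  # architecture mismatch errors
  expect_error(build_force_spec(ov, derive_geometry(gp),
                                mode = "cylinder_helix"),
               "overlapping")

  # stretched mode: periodic box plus fixed ends
  gps <- geometry_params(40, 100, 20, rho_L_Mb_per_um = 25,
                         rho_V_Mb_per_um3 = 77, mode = "stretched_periodic")
  arrs <- sample_consecutive_loops(40, 100, n_gap = 0, bp_per_bead = 4000,
                                   seed = 12)
  sps <- build_force_spec(arrs, derive_geometry(gps))
  expect_equal(length(sps$box), 3)
  expect_equal(sps$fixed, c(1L, sps$n_beads))
})

test_that("cohesion sites are Poisson-sampled loop midpoints", {
  arr <- sample_consecutive_loops(100, 400, n_gap = 1, bp_per_bead = 2000,
                                  seed = 13)
  coh <- plant_cohesion(arr, f_coh_per_Mb = 1, seed = 14)
  # ~100 sites, within a generous Poisson interval
  expect_gt(nrow(coh), 100 - 4 * 10)
  expect_lt(nrow(coh), 100 + 4 * 10)
  # every site is the midpoint bead of its containing loop
  root <- arr$loops
  for (q in seq_len(nrow(coh))) {
    hit <- which(root$start_bp <= coh$site_bp[q] &
                   coh$site_bp[q] < root$end_bp)[1]
    mid_bead <- floor((root$start_bp[hit] + root$end_bp[hit]) / 2 /
                        arr$bp_per_bead) + 1L
    expect_equal(coh$bead[q], mid_bead)
  }
  expect_equal(nrow(plant_cohesion(arr, 0)), 0)
})

test_that("bead diameter scales with the cube root of DNA content", {
  expect_equal(bead_diameter_nm(200), 10)
  expect_equal(bead_diameter_nm(1600), 20)
  expect_equal(bead_diameter_nm(4000), 10 * 20^(1 / 3), tolerance = 1e-12)
})
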