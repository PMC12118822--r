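test_that("random-walk initialization has unit steps and RW statistics", {
  c2 <- init_conformation(2, "random_walk", seed = 1)
  expect_equal(sqrt(sum((c2$pos[2, ] - c2$pos[1, ])^2)), 1.0,
               tolerance = 1e-12)
  # <R^2> = n b^2 within 3 SE over 100 seeds
  n <- 2000
  r2 <- vapply(1:100, function(s) {
    cc <- init_conformation(n, "random_walk", seed = s)
    sum((cc$pos[n, ] - cc$pos[1, ])^2)
  }, numeric(1))
  steps <- n - 1
  se <- sqrt(2 / 3) * steps * sqrt(2) / sqrt(100)  # sd(R^2) ~ sqrt(2/3)*2*n/..
  expect_lt(abs(mean(r2) - steps), 3 * 0.82 * steps / sqrt(100))
})

test_that("zero forces at zero temperature leave positions unchanged", {
  spec <- basic_force_spec(5, rep_A = 0, bond_k = 0)
  conf <- generate_fixture("rw_conformation", list(n = 5), seed = 2)
  out <- integrate_brownian(conf, spec, n_steps = 100, temperature = 0,
                            seed = 3)
  expect_equal(out$pos, conf$pos, tolerance = 1e-12)
})

test_that("the integrator is deterministic under a fixed seed", {
  spec <- basic_force_spec(50)
  conf <- generate_fixture("rw_conformation", list(n = 50), seed = 4)
  a <- integrate_brownian(conf, spec, n_steps = 500, seed = 9)
  b <- integrate_brownian(conf, spec, n_steps = 500, seed = 9)
  expect_identical(a$pos, b$pos)
})

test_that("bond statistics match the Boltzmann oracle", {
  # two beads, k = 10, L0 = 1, T = 1: <r> from the 1D radial integral
  f <- function(r) r^2 * exp(-5 * (r - 1)^2)
  mean_th <- integrate(function(r) r * f(r), 0, 10)$value /
    integrate(f, 0, 10)$value
  spec <- basic_force_spec(2, rep_A = 0)
  conf <- smcsim:::new_conformation(rbind(c(0, 0, 0), c(1, 0, 0)), 200)
  res <- integrate_brownian(conf, spec, n_steps = 1.5e5, dt = 0.02,
                            seed = 5, save_every = 50)
  fr <- attr(res, "frames")
  bl <- vapply(fr, function(m) sqrt(sum((m[1, ] - m[2, ])^2)), numeric(1))
  expect_equal(mean(bl[-(1:100)]), mean_th, tolerance = 0.02)
})

test_that("a confined bead stays inside the cylinder wall", {
  spec <- basic_force_spec(2, rep_A = 0, bond_k = 0)
  spec$cylinder <- list(R = 4, L = 10, eps = 1, sigma = 0.5)
  conf <- smcsim:::new_conformation(rbind(c(0, 0, 0), c(1, 0, 0)), 200)
  res <- integrate_brownian(conf, spec, n_steps = 2e5, seed = 6,
                            save_every = 40)
  fr <- attr(res, "frames")
  r <- unlist(lapply(fr, function(m) sqrt(m[, 1]^2 + m[, 2]^2)))
  # 99% of samples inside the radius where the wall potential is 3 kT
  # (wall eps = 1 inside, harmonic outside: U = 3 at R + 2*sigma)
  r3 <- 4 + 2 * 0.5
  expect_gte(mean(r < r3), 0.99)
  z <- unlist(lapply(fr, function(m) abs(m[, 3])))
  expect_gte(mean(z < 5 + 2 * 0.5), 0.99)
})

test_that("soft-core repulsion lets interlinked rings unlink", {
  m <- 24
  th <- 2 * pi * seq_len(m) / m
  r0 <- 1.9
  ring1 <- cbind(r0 * cos(th), r0 * sin(th), 0)
  ring2 <- cbind(r0 + r0 * cos(th), 0 * th, r0 * sin(th))
  pos <- rbind(ring1, ring2)
  spec <- basic_force_spec(2 * m, chains = list(c(1L, m), c(m + 1L, 2L * m)),
                           rep_A = 3)
  spec$bonds <- rbind(spec$bonds,
                      data.frame(i = c(1L, m + 1L), j = c(m, 2L * m),
                                 k = 10, L0 = 1))  # close both rings
  conf <- smcsim:::new_conformation(pos, 200)
  lk0 <- linking_number(conf$pos[1:m, ], conf$pos[(m + 1):(2 * m), ])
  expect_equal(abs(lk0), 1, tolerance = 0.1)
  res <- integrate_brownian(conf, spec, n_steps = 2e5, seed = 7,
                            save_every = 5000)
  lks <- vapply(attr(res, "frames"), function(p)
    linking_number(p[1:m, ], p[(m + 1):(2 * m), ]), numeric(1))
  expect_true(any(abs(lks - lk0) > 0.5))  # a strand passage occurred
})

test_that("LEF bonds replay the 1D state exactly", {
  lat <- lattice(100)
  st <- initialize_state(lat, extrusive_cohesin_species(n = 3,
                                                        step_interval = 1L),
                         seed = 8)
  spec <- basic_force_spec(100, bp_per_bead = 1000)
  for (u in 1:5) {
    run_epochs(st, 3)
    spec <- update_lef_bonds(spec, st)
    tab <- lef_table(st)
    bound <- tab[tab$bound & tab$left_kb != tab$right_kb, ]
    expect_equal(nrow(spec$lef_bonds), nrow(bound))
    expect_setequal(paste(spec$lef_bonds$i, spec$lef_bonds$j),
                    paste(bound$left_kb + 1, bound$right_kb + 1))
  }
  # legs at 10 kb and 30 kb (0-based) with 1 kb beads -> beads 11, 31
  st2 <- initialize_state(lat, condensin_species(n = 1), seed = 9)
  st2$left[1] <- 11L; st2$right[1] <- 31L
  spec2 <- update_lef_bonds(basic_force_spec(100, bp_per_bead = 1000), st2)
  expect_equal(c(spec2$lef_bonds$i, spec2$lef_bonds$j), c(11L, 31L))
  # a leg outside the polymer errors
  st2$right[1] <- 300L
  expect_error(update_lef_bonds(basic_force_spec(100, bp_per_bead = 1000),
                                st2), "outside")
})

test_that("helix-backbone initialization follows the prescribed geometry", {
  arr <- sample_consecutive_loops(20, 400, n_gap = 2, bp_per_bead = 4000,
                                  seed = 10)
  gp <- geometry_params(20, 400, 80, P_nm = 400, l_turn_Mb = 10,
                        rho_V_Mb_per_um3 = 44, mode = "cylinder_helix")
  geom <- derive_geometry(gp)
  spec <- build_force_spec(arr, geom)
  conf <- init_conformation(mode = "helix_backbone", spec = spec, seed = 11)
  bb <- spec$backbone_beads
  unit <- spec$unit_nm
  # backbone z extent approximates the cylinder length (= n_turns * P)
  zr <- diff(range(conf$pos[bb, 3])) * unit
  expect_equal(zr, geom$L_cyl_nm, tolerance = 0.1)
  expect_equal(geom$n_turns * geom$P_nm, geom$L_cyl_nm, tolerance = 1e-9)
  # anchors wind 2 pi per turn: total winding = 2 pi l_chrom / l_turn
  th <- atan2(conf$pos[bb, 2], conf$pos[bb, 1])
  wind <- sum(diff(th) - 2 * pi * round(diff(th) / (2 * pi))) / (2 * pi)
  expect_equal(abs(wind), 20 / 10, tolerance = 0.2)
  expect_error(init_conformation(mode = "helix_backbone", seed = 1),
               "force spec")
})

test_that("conformations round-trip through text serialization", {
  conf <- generate_fixture("rw_conformation", list(n = 40), seed = 12)
  conf$category[5:10] <- "condensin"
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_conformation(conf, p1)
  back <- read_conformation(p1)
  expect_equal(back$pos, conf$pos, tolerance = 1e-6)
  expect_equal(back$category, conf$category)
  expect_equal(back$bp_per_bead, conf$bp_per_bead)
  write_conformation(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
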