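# deterministic helper: place complex i at given legs, clearing its old site
place_lef <- function(st, i, left, right) {
  for (s in unique(c(st$left[i], st$right[i]))) if (st$occ[s] == i) st$occ[s] <- 0L
  st$left[i] <- as.integer(left); st$right[i] <- as.integer(right)
  st$occ[left] <- i; st$occ[right] <- i
  st
}

test_that("initialization derives complex counts and placements", {
  # one condensin on a 1000-site lattice (d = lattice size), loop size 0
  st <- initialize_state(lattice(1000), condensin_species(separation_d = 1000),
                         seed = 1)
  expect_equal(sum(st$bound), 1)
  expect_equal(loop_size_stats(st)$sizes_kb, 0)

  # 20 Mb lattice, cohesin d = 300 kb: floor(20000/300) = 66 (floor rule)
  st2 <- initialize_state(lattice(20000), extrusive_cohesin_species(),
                          seed = 2)
  expect_equal(length(st2$sp), 66L)

  # identical seeds give identical placements
  a <- initialize_state(lattice(500), extrusive_cohesin_species(n = 5), seed = 7)
  b <- initialize_state(lattice(500), extrusive_cohesin_species(n = 5), seed = 7)
  expect_identical(lef_table(a), lef_table(b))

  # over-dense request errors
  expect_error(initialize_state(lattice(10),
                                condensin_species(n = 11), seed = 1),
               "over-dense")
})

test_that("a free two-sided extruder grows its loop by 2 sites per epoch", {
  st <- initialize_state(lattice(501), condensin_species(n = 1), seed = 3)
  run_epochs(st, 1)  # burn epoch 0 before manual placement
  st <- place_lef(st, 1L, 251L, 251L)
  run_epochs(st, 10)
  expect_equal(loop_size_stats(st)$sizes_kb, 20)
  run_epochs(st, 15)
  expect_equal(loop_size_stats(st)$sizes_kb, 50)
})

test_that("stalling keeps converging legs on adjacent, distinct sites", {
  st <- initialize_state(lattice(60), condensin_species(n = 2), seed = 5)
  st <- place_lef(st, 1L, 15L, 15L)
  st <- place_lef(st, 2L, 45L, 45L)
  run_epochs(st, 100)
  tab <- lef_table(st)
  sites <- c(st$left, st$right)
  expect_equal(anyDuplicated(sites), 0)
  # inner legs adjacent: right leg of 1 and left leg of 2
  expect_equal(st$left[2] - st$right[1], 1L)
  expect_equal(count_interleaved(st), 0L)
})

test_that("push displaces the contacted leg site by site", {
  # two-chain lattice; the cohesive cohesin never self-steps
  # (step_interval large), so its displacement is purely condensin push
  lat <- lattice(100, chains = list(c(0L, 50L), c(50L, 100L)))
  cond <- condensin_species(n = 1)
  coh <- cohesive_cohesin_species(n = 1, step_interval = 10000L)
  pol <- collision_policy(c("condensin", "cohesive_cohesin"),
                          "condensin>cohesive_cohesin" = "push")
  st <- initialize_state(lat, list(cond, coh), pol, seed = 11)
  run_epochs(st, 1)  # burn epoch 0 (every species is due then)
  st <- place_lef(st, 2L, 30L, 80L)  # cohesin legs on both chains
  st <- place_lef(st, 1L, 28L, 29L)  # condensin right leg adjacent
  run_epochs(st, 5)
  expect_equal(st$left[2], 35L)   # pushed 5 sites in extrusion direction
  expect_equal(st$right[1], 34L)  # condensin right leg trails by one
})

test_that("unload removes the blocking complex; no_rebind depletes the pool", {
  lat <- lattice(200)
  cond <- condensin_species(n = 1)
  coh <- extrusive_cohesin_species(n = 3, step_interval = 10000L)
  pol <- collision_policy(c("condensin", "extrusive_cohesin"),
                          "condensin>extrusive_cohesin" = "unload")
  st <- initialize_state(lat, list(cond, coh), pol, seed = 13,
                         no_rebind = TRUE)
  st <- place_lef(st, 1L, 100L, 100L)
  st <- place_lef(st, 2L, 60L, 80L)
  st <- place_lef(st, 3L, 110L, 130L)
  st <- place_lef(st, 4L, 20L, 40L)
  run_epochs(st, 60)
  expect_lt(sum(st$bound[2:4]), 3)          # at least one unloaded for good
  expect_true(st$bound[1])                  # condensin unaffected
  expect_gte(loop_size_stats(st, "condensin")$sizes_kb, 100)  # passed through
})

test_that("bypass steps over a blocking leg", {
  lat <- lattice(100)
  cond <- condensin_species(n = 1)
  coh <- extrusive_cohesin_species(n = 1, step_interval = 10000L)
  pol <- collision_policy(c("condensin", "extrusive_cohesin"),
                          "condensin>extrusive_cohesin" = "bypass")
  st <- initialize_state(lat, list(cond, coh), pol, seed = 17)
  run_epochs(st, 1)  # burn epoch 0
  st <- place_lef(st, 1L, 50L, 50L)
  st <- place_lef(st, 2L, 40L, 60L)
  run_epochs(st, 30)
  # condensin extruded past both cohesin legs without displacing them
  expect_equal(c(st$left[2], st$right[2]), c(40L, 60L))
  expect_gt(loop_size_stats(st, "condensin")$sizes_kb, 40)
  expect_equal(count_interleaved(st), 0L)  # nested, not interleaved
})

test_that("CTCF barriers capture capturable legs until unbinding", {
  lat <- lattice(101, barriers = c(30L, 70L), capture_prob = 1)
  coh <- extrusive_cohesin_species(n = 1, processivity_lambda = 1e9,
                                   step_interval = 1L)
  st <- initialize_state(lat, list(coh), seed = 19)
  run_epochs(st, 1)
  st <- place_lef(st, 1L, 51L, 51L)
  run_epochs(st, 60)
  # both legs captured exactly at the barrier sites (1-based: 31, 71)
  expect_true(st$cap_l[1] && st$cap_r[1])
  expect_equal(c(st$left[1], st$right[1]), c(31L, 71L))
  expect_equal(n_ctcf_anchored(st), 1L)
  # transparent species pass straight through
  cond <- condensin_species(n = 1)
  st2 <- initialize_state(lat, list(cond), seed = 19)
  run_epochs(st2, 1)
  st2 <- place_lef(st2, 1L, 51L, 51L)
  run_epochs(st2, 60)
  expect_false(st2$cap_l[1] || st2$cap_r[1])
  expect_equal(c(st2$left[1], st2$right[1]), c(1L, 101L))
})

test_that("gap fraction and loop sizes follow their definitions", {
  st <- initialize_state(lattice(100), condensin_species(n = 1), seed = 1)
  st <- place_lef(st, 1L, 26L, 76L)  # covers 50 of 100 sites half-open
  expect_equal(gap_fraction(st), 0.5)
  expect_equal(loop_size_stats(st)$sizes_kb, 50)

  # no complexes of the class -> gap fraction 1, undefined mean
  expect_equal(gap_fraction(st, "nonexistent"), 1.0)
  stats <- loop_size_stats(st, "nonexistent")
  expect_false(stats$defined)
  expect_true(is.na(stats$mean_kb))

  # theoretical formula
  expect_equal(theoretical_gap_fraction(0, 300), 1.0)
  expect_equal(theoretical_gap_fraction(100, 100), exp(-1))
  expect_equal(theoretical_gap_fraction(100, 300), exp(-1 / 3))
  expect_error(theoretical_gap_fraction(100, 0), "d_kb")
})

test_that("trajectories are deterministic under a fixed seed", {
  mk <- function() {
    lat <- lattice(2000, barriers = c(100L, 900L))
    st <- initialize_state(lat, list(extrusive_cohesin_species(n = 6,
                                       step_interval = 1L),
                                     condensin_species(n = 2)),
                           collision_policy(c("extrusive_cohesin",
                                              "condensin"),
                                            "condensin>extrusive_cohesin" =
                                              "push"),
                           seed = 23)
    run_epochs(st, 80)
    lef_table(st)
  }
  expect_identical(mk(), mk())
})

test_that("LEF tables serialize round-trip", {
  st <- initialize_state(lattice(300), extrusive_cohesin_species(n = 3),
                         seed = 29)
  run_epochs(st, 10)
  path <- tempfile(fileext = ".tsv")
  write_lef_table(st, path)
  back <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$left_kb, lef_table(st)$left_kb)
  expect_equal(back$species, lef_table(st)$species)
})
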