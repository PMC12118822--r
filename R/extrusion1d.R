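#' 1D lattice simulation of SMC loop extrusion
#'
#' The chromatin fiber is a 1D lattice (1 site = 1 kb by default). A
#' loop-extruding factor (LEF) is a walker with two legs that move in
#' opposite directions, so the legs delimit the extruded loop. Cohesive
#' cohesins are two-legged walkers whose legs live on the two sister
#' chains and diffuse rather than extrude. Barriers (CTCF sites) capture
#' the legs of capturable species with a per-site probability; captured
#' legs stay put until the complex unbinds. Collisions between legs of
#' different complexes are resolved by a species-pair policy: stall,
#' bypass, push, or unload.
#'
#' @name extrusion1d
NULL

# ---------------------------------------------------------------- lattice

#' Create a 1D extrusion lattice
#'
#' @param n_sites number of lattice sites (1 site = `kb_per_site` kb).
#' @param kb_per_site genomic length of one site in kb.
#' @param barriers integer vector of barrier positions, 0-based, in
#'   `[0, n_sites)` (BED-style, as barrier coordinate lists are usually
#'   given). May be empty.
#' @param capture_prob per-barrier capture probability in `[0, 1]`,
#'   recycled; default 0.9.
#' @param chains optional list of `c(start, end)` 0-based half-open
#'   intervals partitioning the lattice into chains (two chains model a
#'   pair of sister chromatids). Default: one chain covering everything.
#' @return an object of class `smc_lattice`.
#' @export
lattice <- function(n_sites, kb_per_site = 1, barriers = integer(0),
                    capture_prob = 0.9, chains = NULL) {
  stopifnot(n_sites >= 1, kb_per_site > 0)
  barriers <- as.integer(barriers)
  if (length(barriers) && (any(barriers < 0) || any(barriers >= n_sites)))
    stop("barrier sites must lie in [0, n_sites)")
  capture_prob <- rep_len(capture_prob, max(length(barriers), 1L))
  if (any(capture_prob < 0 | capture_prob > 1))
    stop("capture_prob must be in [0, 1]")
  if (is.null(chains)) chains <- list(c(0L, as.integer(n_sites)))
  chains <- lapply(chains, function(ch) as.integer(ch))
  ends <- vapply(chains, `[`, integer(1), 2L)
  starts <- vapply(chains, `[`, integer(1), 1L)
  o <- order(starts)
  chains <- chains[o]; starts <- starts[o]; ends <- ends[o]
  if (starts[1] != 0L || ends[length(ends)] != n_sites ||
      (length(chains) > 1 && any(starts[-1] != ends[-length(ends)])))
    stop("chains must be disjoint contiguous intervals covering the lattice")
  structure(
    list(n_sites = as.integer(n_sites), kb_per_site = kb_per_site,
         barriers = barriers,
         capture_prob = if (length(barriers)) capture_prob else numeric(0),
         chains = chains),
    class = "smc_lattice"
  )
}

#' @export
print.smc_lattice <- function(x, ...) {
  cat(sprintf("<smc_lattice> %d sites x %g kb, %d barrier(s), %d chain(s)\n",
              x$n_sites, x$kb_per_site, length(x$barriers), length(x$chains)))
  invisible(x)
}

# ---------------------------------------------------------------- species

#' Define a LEF species
#'
#' @param name species tag, e.g. `"extrusive_cohesin"`, `"condensin"`,
#'   `"condensin_I"`, `"condensin_II"`, `"cohesive_cohesin"`.
#' @param processivity_lambda mean chromatin (kb) extruded before
#'   unbinding in the absence of obstacles; `Inf` together with
#'   `lifetime = "infinite"` gives stable binding.
#' @param separation_d mean genomic spacing between complexes in kb; the
#'   loaded number is `floor(lattice kb / separation_d)` (per chain for
#'   two-chain species).
#' @param n explicit complex count overriding `separation_d`.
#' @param step_interval the species attempts moves every `step_interval`
#'   epochs (realizes relative speeds, e.g. cohesin:condensin 10:120
#'   kb/min as interval 12:1).
#' @param lifetime `"finite"` (turnover with rebinding, pool conserved) or
#'   `"infinite"`.
#' @param loading `"stochastic"` or `"synchronous"`; both place complexes
#'   at random free sites at initialization, `"stochastic"` additionally
#'   implies rebinding after unbinding events.
#' @param barrier_mode `"capturable"` or `"transparent"`.
#' @param motion `"extruding"` (legs step outward) or `"diffusing"` (each
#'   leg steps +-1 with equal probability).
#' @param two_chain `TRUE` for cohesive cohesin: the two legs live on the
#'   two chains of a two-chain lattice.
#' @return an object of class `lef_species`.
#' @export
lef_species <- function(name,
                        processivity_lambda = Inf,
                        separation_d = NULL,
                        n = NULL,
                        step_interval = 1L,
                        lifetime = c("finite", "infinite"),
                        loading = c("stochastic", "synchronous"),
                        barrier_mode = c("transparent", "capturable"),
                        motion = c("extruding", "diffusing"),
                        two_chain = FALSE) {
  lifetime <- match.arg(lifetime)
  motion <- match.arg(motion)
  if (motion == "extruding" && !(processivity_lambda > 0))
    stop("extruding species need processivity_lambda > 0")
  if (is.null(n) && is.null(separation_d))
    stop("give either separation_d or n")
  structure(
    list(name = name, processivity_lambda = processivity_lambda,
         separation_d = separation_d, n = n,
         step_interval = as.integer(step_interval),
         lifetime = lifetime, loading = match.arg(loading),
         barrier_mode = match.arg(barrier_mode), motion = motion,
         two_chain = isTRUE(two_chain)),
    class = "lef_species"
  )
}

#' Preset species with commonly used parameters
#'
#' `extrusive_cohesin_species()`: lambda = 100 kb, d = 300 kb, capturable
#' at CTCF, finite lifetime, steps every 12 epochs (10 kb/min against the
#' condensin 120 kb/min reference).
#' `condensin_species()`: infinite lifetime, synchronous loading,
#' d = 700 kb, transparent to CTCF, steps every epoch.
#' `cohesive_cohesin_species()`: diffusing two-chain walker, d = 300 kb,
#' bound stably.
#'
#' @param ... overrides passed to [lef_species()].
#' @name species_presets
NULL

#' @rdname species_presets
#' @export
extrusive_cohesin_species <- function(...) {
  args <- utils::modifyList(
    list(name = "extrusive_cohesin", processivity_lambda = 100,
         separation_d = 300, step_interval = 12L, lifetime = "finite",
         loading = "stochastic", barrier_mode = "capturable",
         motion = "extruding"),
    list(...))
  do.call(lef_species, args)
}

#' @rdname species_presets
#' @export
condensin_species <- function(...) {
  args <- utils::modifyList(
    list(name = "condensin", processivity_lambda = Inf,
         separation_d = 700, step_interval = 1L, lifetime = "infinite",
         loading = "synchronous", barrier_mode = "transparent",
         motion = "extruding"),
    list(...))
  do.call(lef_species, args)
}

#' @rdname species_presets
#' @export
cohesive_cohesin_species <- function(...) {
  args <- utils::modifyList(
    list(name = "cohesive_cohesin", processivity_lambda = Inf,
         separation_d = 300, step_interval = 1L, lifetime = "infinite",
         loading = "synchronous", barrier_mode = "transparent",
         motion = "diffusing", two_chain = TRUE),
    list(...))
  do.call(lef_species, args)
}

# ---------------------------------------------------------------- policy

#' Collision policy matrix
#'
#' Outcome applied when a leg of `moving` species attempts to step onto a
#' site occupied by a leg of `blocking` species. Same-species collisions
#' default to `"stall"` (two condensins, two cohesins stall until one
#' unbinds); any pair can be overridden to `"stall"`, `"bypass"`,
#' `"push"`, or `"unload"`.
#'
#' @param species_names character vector of species tags.
#' @param ... named overrides of the form
#'   `"moving>blocking" = "outcome"`, e.g.
#'   `"condensin>extrusive_cohesin" = "unload"`.
#' @return square character matrix with `dimnames = species_names`.
#' @export
collision_policy <- function(species_names, ...) {
  m <- matrix("stall", length(species_names), length(species_names),
              dimnames = list(moving = species_names,
                              blocking = species_names))
  overrides <- list(...)
  for (key in names(overrides)) {
    parts <- strsplit(key, ">", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% species_names))
      stop("policy override keys must look like 'moving>blocking'")
    outcome <- match.arg(overrides[[key]],
                         c("stall", "bypass", "push", "unload"))
    m[parts[1], parts[2]] <- outcome
  }
  m
}

# ---------------------------------------------------------------- state

with_state_rng <- function(state, expr) {
  # each state owns an RNG stream, so simulations are reproducible
  # independent of the global seed
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", state$rng, envir = globalenv())
  on.exit({
    state$rng <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

chain_of_site <- function(lat, site1) {
  # site1 is 1-based; chains stored 0-based half-open
  for (k in seq_along(lat$chains)) {
    ch <- lat$chains[[k]]
    if (site1 > ch[1] && site1 <= ch[2]) return(k)
  }
  stop("site outside lattice")
}

#' Initialize an extrusion state
#'
#' Loads each species at random unoccupied sites with both legs on the
#' same site (loop size 0). The complex count is
#' `floor(lattice_kb / separation_d)` (floor is the documented rounding
#' rule), unless the species carries an explicit `n`. Two-chain species
#' load their two legs at the same offset within chain 1 and chain 2.
#'
#' @param lat an [lattice()] object.
#' @param species list of [lef_species()] objects.
#' @param policy collision-policy matrix from [collision_policy()];
#'   default all-stall.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param no_rebind if `TRUE`, complexes removed by the `unload` collision
#'   outcome leave the pool for good instead of rebinding (models net
#'   cohesin loss rather than continuous reloading).
#' @return an `extrusion_state` environment (modified in place by
#'   [step_epoch()]).
#' @export
initialize_state <- function(lat, species, policy = NULL, seed = 1L,
                             no_rebind = FALSE) {
  stopifnot(inherits(lat, "smc_lattice"))
  if (inherits(species, "lef_species")) species <- list(species)
  sp_names <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names)) stop("duplicated species names")
  if (is.null(policy)) policy <- collision_policy(sp_names)
  if (!all(sp_names %in% rownames(policy)))
    stop("policy matrix must cover all species")

  state <- new.env(parent = emptyenv())
  state$lat <- lat
  state$species <- species
  state$sp_names <- sp_names
  state$policy <- policy
  state$no_rebind <- isTRUE(no_rebind)
  state$epoch <- 0L
  state$seed <- as.integer(seed)

  # barrier lookup (1-based)
  state$barrier_p <- numeric(lat$n_sites)
  if (length(lat$barriers))
    state$barrier_p[lat$barriers + 1L] <- lat$capture_prob

  # chain bounds per site (1-based inclusive)
  state$chain_lo <- integer(0)
  state$chain_hi <- integer(0)
  for (ch in lat$chains) {
    state$chain_lo <- c(state$chain_lo, ch[1] + 1L)
    state$chain_hi <- c(state$chain_hi, ch[2])
  }

  counts <- integer(length(species))
  for (k in seq_along(species)) {
    sp <- species[[k]]
    if (!is.null(sp$n)) {
      counts[k] <- as.integer(sp$n)
    } else if (sp$two_chain) {
      if (length(lat$chains) != 2)
        stop("two-chain species require a two-chain lattice")
      chain_kb <- (lat$chains[[1]][2] - lat$chains[[1]][1]) * lat$kb_per_site
      counts[k] <- floor(chain_kb / sp$separation_d)
    } else {
      counts[k] <- floor(lat$n_sites * lat$kb_per_site / sp$separation_d)
    }
  }
  n_lef <- sum(counts)
  if (n_lef > lat$n_sites)
    stop("over-dense configuration: requested LEF count exceeds sites")

  state$occ <- integer(lat$n_sites)
  state$sp <- rep.int(rep(seq_along(species), counts), 1L)
  state$left <- integer(n_lef)
  state$right <- integer(n_lef)
  state$cap_l <- logical(n_lef)
  state$cap_r <- logical(n_lef)
  state$stall_l <- logical(n_lef)
  state$stall_r <- logical(n_lef)
  state$bound <- rep(TRUE, n_lef)

  set.seed(seed)
  for (i in seq_len(n_lef)) {
    sp <- species[[state$sp[i]]]
    if (sp$two_chain) {
      ch1 <- lat$chains[[1]]; ch2 <- lat$chains[[2]]
      w <- ch1[2] - ch1[1]
      repeat {
        off <- sample.int(min(w, ch2[2] - ch2[1]), 1L)
        s1 <- ch1[1] + off; s2 <- ch2[1] + off
        if (state$occ[s1] == 0L && state$occ[s2] == 0L) break
      }
      state$left[i] <- s1; state$right[i] <- s2
      state$occ[s1] <- i; state$occ[s2] <- i
    } else {
      free <- which(state$occ == 0L)
      s <- free[sample.int(length(free), 1L)]
      state$left[i] <- s; state$right[i] <- s
      state$occ[s] <- i
    }
  }
  state$rng <- get(".Random.seed", globalenv())
  class(state) <- "extrusion_state"
  state
}

#' @export
print.extrusion_state <- function(x, ...) {
  cat(sprintf("<extrusion_state> epoch %d, %d/%d LEFs bound on %d sites\n",
              x$epoch, sum(x$bound), length(x$bound), x$lat$n_sites))
  invisible(x)
}

# internal: unload complex i (clear occupancy and flags)
.unload_lef <- function(state, i) {
  for (s in unique(c(state$left[i], state$right[i]))) {
    if (s >= 1L && state$occ[s] == i) state$occ[s] <- 0L
  }
  state$bound[i] <- FALSE
  state$cap_l[i] <- state$cap_r[i] <- FALSE
  state$stall_l[i] <- state$stall_r[i] <- FALSE
}

# internal: rebind complex i at a random free site (loop size 0)
.rebind_lef <- function(state, i) {
  sp <- state$species[[state$sp[i]]]
  if (sp$two_chain) {
    ch1 <- state$lat$chains[[1]]; ch2 <- state$lat$chains[[2]]
    w <- min(ch1[2] - ch1[1], ch2[2] - ch2[1])
    for (try in 1:200) {
      off <- sample.int(w, 1L)
      s1 <- ch1[1] + off; s2 <- ch2[1] + off
      if (state$occ[s1] == 0L && state$occ[s2] == 0L) {
        state$left[i] <- s1; state$right[i] <- s2
        state$occ[s1] <- i; state$occ[s2] <- i
        state$bound[i] <- TRUE
        return(invisible(TRUE))
      }
    }
    return(invisible(FALSE))
  }
  free <- which(state$occ == 0L)
  if (!length(free)) return(invisible(FALSE))
  s <- free[sample.int(length(free), 1L)]
  state$left[i] <- s; state$right[i] <- s
  state$occ[s] <- i
  state$bound[i] <- TRUE
  invisible(TRUE)
}

# internal: handle an unload-type removal honoring pool/rebind rules
.unload_and_maybe_rebind <- function(state, i) {
  .unload_lef(state, i)
  sp <- state$species[[state$sp[i]]]
  if (!state$no_rebind && sp$lifetime == "finite") .rebind_lef(state, i)
}

# internal: move one leg of complex i; leg is "l" or "r"; dir is +-1.
# Returns nothing; mutates state.
.move_leg <- function(state, i, leg, dir) {
  lat <- state$lat
  cap <- if (leg == "l") state$cap_l[i] else state$cap_r[i]
  if (cap) return(invisible(NULL))
  s <- if (leg == "l") state$left[i] else state$right[i]
  t <- s + dir
  chk <- chain_of_site(lat, s)
  if (t < state$chain_lo[chk] || t > state$chain_hi[chk]) {
    if (leg == "l") state$stall_l[i] <- TRUE else state$stall_r[i] <- TRUE
    return(invisible(NULL))
  }
  sp <- state$species[[state$sp[i]]]
  # same-chain diffusers must keep left <= right
  if (sp$motion == "diffusing" && !sp$two_chain) {
    if (leg == "l" && t > state$right[i]) return(invisible(NULL))
    if (leg == "r" && t < state$left[i]) return(invisible(NULL))
  }

  do_move <- function(target) {
    # barrier capture tested on the step onto the barrier site
    captured <- FALSE
    if (sp$barrier_mode == "capturable" && state$barrier_p[target] > 0 &&
        stats::runif(1) < state$barrier_p[target]) {
      captured <- TRUE
    }
    other <- if (leg == "l") state$right[i] else state$left[i]
    if (state$occ[s] == i && other != s) state$occ[s] <- 0L
    state$occ[target] <- i
    if (leg == "l") {
      state$left[i] <- target
      state$stall_l[i] <- FALSE
      if (captured) state$cap_l[i] <- TRUE
    } else {
      state$right[i] <- target
      state$stall_r[i] <- FALSE
      if (captured) state$cap_r[i] <- TRUE
    }
  }

  j <- state$occ[t]
  if (j == 0L || j == i) {
    do_move(t)
    return(invisible(NULL))
  }

  outcome <- state$policy[sp$name, state$sp_names[state$sp[j]]]
  if (outcome == "stall") {
    if (leg == "l") state$stall_l[i] <- TRUE else state$stall_r[i] <- TRUE
  } else if (outcome == "bypass") {
    t2 <- t + dir
    if (t2 >= state$chain_lo[chk] && t2 <= state$chain_hi[chk] &&
        (state$occ[t2] == 0L || state$occ[t2] == i)) {
      do_move(t2)
    } else {
      if (leg == "l") state$stall_l[i] <- TRUE else state$stall_r[i] <- TRUE
    }
  } else if (outcome == "unload") {
    .unload_and_maybe_rebind(state, j)
    if (state$occ[t] == 0L) do_move(t)
  } else if (outcome == "push") {
    for (attempt in 1:10) {
      # maximal run of occupied sites from t in direction dir
      u <- t
      while (u + dir >= state$chain_lo[chk] && u + dir <= state$chain_hi[chk] &&
             state$occ[u + dir] != 0L && state$occ[u + dir] != i) {
        u <- u + dir
      }
      v <- u + dir
      run <- if (dir > 0) seq.int(t, u) else seq.int(t, u, by = -1L)
      ids <- state$occ[run]
      if (v >= state$chain_lo[chk] && v <= state$chain_hi[chk] &&
          (state$occ[v] == 0L || state$occ[v] == i)) {
        # shift all legs in the run one site outward, far end first;
        # a barrier-captured leg is displaced off its barrier (pushing
        # applies regardless of CTCF trapping) and loses its capture
        for (q in rev(seq_along(run))) {
          jj <- ids[q]; sq <- run[q]; tq <- sq + dir
          if (state$occ[sq] == jj) state$occ[sq] <- 0L
          state$occ[tq] <- jj
          if (state$left[jj] == sq) {
            state$left[jj] <- tq
            state$cap_l[jj] <- FALSE
          }
          if (state$right[jj] == sq && !(state$left[jj] == tq &&
                                         state$left[jj] == state$right[jj])) {
            state$right[jj] <- tq
            state$cap_r[jj] <- FALSE
          }
        }
        do_move(t)
        break
      }
      # pushed into a chain end: the end-most complex unloads
      .unload_and_maybe_rebind(state, ids[length(ids)])
      if (state$occ[t] == 0L) do_move(t)
      if (state$occ[t] == 0L || state$occ[t] == i) break
    }
  }
  invisible(NULL)
}

#' Advance the simulation by one epoch
#'
#' Every species whose `step_interval` divides the current epoch attempts
#' one move per leg: extruders step both legs outward by one site,
#' diffusers step each leg +-1 with equal probability. Complexes are
#' updated sequentially in a freshly shuffled order each epoch. Collisions
#' are resolved by the state's policy matrix; barrier capture is tested
#' per crossing leg; finally, finite-lifetime species undergo turnover
#' with per-complex unbinding probability `(kb moved per epoch) / lambda`
#' and immediate rebinding at a random free site (pool conserved).
#'
#' @param state an `extrusion_state`; modified in place and returned.
#' @return the state, invisibly.
#' @export
step_epoch <- function(state) {
  stopifnot(inherits(state, "extrusion_state"))
  due <- which(vapply(state$species, function(sp) {
    state$epoch %% sp$step_interval == 0L
  }, logical(1)))
  if (length(due)) {
    with_state_rng(state, {
      idx <- which(state$bound & state$sp %in% due)
      if (length(idx)) {
        idx <- idx[sample.int(length(idx))]
        for (i in idx) {
          if (!state$bound[i]) next
          sp <- state$species[[state$sp[i]]]
          if (sp$motion == "extruding") {
            .move_leg(state, i, "l", -1L)
            if (state$bound[i]) .move_leg(state, i, "r", +1L)
          } else {
            .move_leg(state, i, "l", if (stats::runif(1) < 0.5) -1L else 1L)
            if (state$bound[i])
              .move_leg(state, i, "r", if (stats::runif(1) < 0.5) -1L else 1L)
          }
        }
      }
      # turnover of finite-lifetime species due this epoch
      for (k in due) {
        sp <- state$species[[k]]
        if (sp$lifetime != "finite" || !is.finite(sp$processivity_lambda))
          next
        p <- 2 * state$lat$kb_per_site / sp$processivity_lambda
        for (i in which(state$bound & state$sp == k)) {
          if (stats::runif(1) < p) {
            .unload_lef(state, i)
            .rebind_lef(state, i)
          }
        }
      }
    })
  }
  state$epoch <- state$epoch + 1L
  invisible(state)
}

#' Run many epochs
#'
#' @param state an `extrusion_state`.
#' @param n number of epochs.
#' @return the state, invisibly.
#' @export
run_epochs <- function(state, n) {
  for (k in seq_len(n)) step_epoch(state)
  invisible(state)
}

# ---------------------------------------------------------------- queries

sp_class_idx <- function(state, species_class) {
  if (is.null(species_class)) return(seq_along(state$species))
  which(state$sp_names %in% species_class)
}

#' Fraction of chromatin outside loops
#'
#' Fraction of lattice sites not covered by any loop of the given species
#' class, using half-open coverage `[left, right)`. Two-chain (cohesive)
#' complexes do not form loops and are excluded.
#'
#' @param state an `extrusion_state`.
#' @param species_class character vector of species names, or `NULL` for
#'   all single-chain species.
#' @return a fraction in `[0, 1]`.
#' @export
gap_fraction <- function(state, species_class = NULL) {
  ks <- sp_class_idx(state, species_class)
  ks <- ks[!vapply(state$species[ks], `[[`, logical(1), "two_chain")]
  idx <- which(state$bound & state$sp %in% ks)
  if (!length(idx)) return(1.0)
  l <- state$left[idx]; r <- state$right[idx]
  keep <- r > l
  if (!any(keep)) return(1.0)
  l <- l[keep]; r <- r[keep]
  o <- order(l)
  l <- l[o]; r <- r[o]
  covered <- 0L; cur_l <- l[1]; cur_r <- r[1]
  if (length(l) > 1) {
    for (q in 2:length(l)) {
      if (l[q] <= cur_r) {
        cur_r <- max(cur_r, r[q])
      } else {
        covered <- covered + (cur_r - cur_l)
        cur_l <- l[q]; cur_r <- r[q]
      }
    }
  }
  covered <- covered + (cur_r - cur_l)
  1 - covered / state$lat$n_sites
}

#' Theoretical steady-state gap fraction
#'
#' `g = exp(-lambda / d)`: the fraction of chromatin left in gaps when
#' extruders of processivity `lambda` are spaced `d` apart.
#'
#' @param lambda_kb processivity in kb (>= 0).
#' @param d_kb separation in kb (> 0).
#' @return `exp(-lambda_kb / d_kb)`.
#' @export
theoretical_gap_fraction <- function(lambda_kb, d_kb) {
  stopifnot(lambda_kb >= 0)
  if (!is.numeric(d_kb) || any(d_kb <= 0)) stop("d_kb must be > 0")
  exp(-lambda_kb / d_kb)
}

#' Loop sizes of bound complexes
#'
#' @param state an `extrusion_state`.
#' @param species_class species names or `NULL` for all single-chain
#'   species.
#' @return list with `sizes_kb` (per bound complex) and `mean_kb` (`NA`
#'   with a `defined = FALSE` flag when no complex is bound).
#' @export
loop_size_stats <- function(state, species_class = NULL) {
  ks <- sp_class_idx(state, species_class)
  ks <- ks[!vapply(state$species[ks], `[[`, logical(1), "two_chain")]
  idx <- which(state$bound & state$sp %in% ks)
  sizes <- (state$right[idx] - state$left[idx]) * state$lat$kb_per_site
  list(sizes_kb = sizes,
       mean_kb = if (length(sizes)) mean(sizes) else NA_real_,
       defined = length(sizes) > 0)
}

#' Count interleaved (crossing) loop pairs
#'
#' A pair of loops (a,b), (c,d) is interleaved when `a < c < b < d`.
#' Under a stall-only policy loops are consecutive or nested, never
#' interleaved; bypass makes interleaving possible.
#'
#' @param state an `extrusion_state`.
#' @param species_class species names or `NULL`.
#' @return integer count of interleaved pairs.
#' @export
count_interleaved <- function(state, species_class = NULL) {
  ks <- sp_class_idx(state, species_class)
  ks <- ks[!vapply(state$species[ks], `[[`, logical(1), "two_chain")]
  idx <- which(state$bound & state$sp %in% ks)
  l <- state$left[idx]; r <- state$right[idx]
  keep <- r > l
  l <- l[keep]; r <- r[keep]
  n <- length(l)
  if (n < 2) return(0L)
  cnt <- 0L
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    lo1 <- l[a]; hi1 <- r[a]; lo2 <- l[b]; hi2 <- r[b]
    if (lo1 > lo2) { tmp <- lo1; lo1 <- lo2; lo2 <- tmp
                     tmp <- hi1; hi1 <- hi2; hi2 <- tmp }
    if (lo2 < hi1 && hi1 < hi2 && lo1 < lo2) cnt <- cnt + 1L
  }
  cnt
}

#' Count complexes captured at barriers on both legs
#'
#' CTCF-CTCF anchored complexes are the 1D proxy for Hi-C dots: a
#' cohesin whose two legs are both captured at barrier sites corresponds
#' to a positioned CTCF-CTCF loop.
#'
#' @param state an `extrusion_state`.
#' @param species_class species names or `NULL`.
#' @return integer count.
#' @export
n_ctcf_anchored <- function(state, species_class = NULL) {
  ks <- sp_class_idx(state, species_class)
  sum(state$bound & state$sp %in% ks & state$cap_l & state$cap_r)
}

#' Snapshot of all complexes as a data frame
#'
#' @param state an `extrusion_state`.
#' @return data.frame with one row per complex: epoch, id, species,
#'   bound, left/right positions in kb (0-based genomic), capture and
#'   stall flags.
#' @export
lef_table <- function(state) {
  kb <- state$lat$kb_per_site
  data.frame(
    epoch = state$epoch,
    lef_id = seq_along(state$sp),
    species = state$sp_names[state$sp],
    bound = state$bound,
    left_kb = (state$left - 1L) * kb,
    right_kb = (state$right - 1L) * kb,
    captured_left = state$cap_l,
    captured_right = state$cap_r,
    stalled_left = state$stall_l,
    stalled_right = state$stall_r,
    stringsAsFactors = FALSE
  )
}
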