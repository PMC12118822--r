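#' Coarse-grained polymer engine
#'
#' Chromatin is a chain of beads (one bead = `bp_per_bead` bp, diameter
#' one reduced length unit = [bead_diameter_nm()] nm). The reference
#' integrator is overdamped Langevin (Brownian) dynamics at T = 1 with
#' friction 1: it reproduces the same equilibrium ensembles as a DPD
#' thermostat (which differs only in kinetics) and is sized for desk-scale
#' systems of up to a few 10^4 beads. Excluded volume is the soft
#' DPD-style repulsion `F = A (1 - r) rhat` (A = 3 kT, cutoff 1), which
#' permits occasional strand passage and hence topological equilibration.
#'
#' @name polymer3d
NULL

new_conformation <- function(pos, bp_per_bead, category = NULL,
                             seed = NA_integer_, step = 0L) {
  pos <- unname(as.matrix(pos))
  n <- nrow(pos)
  stopifnot(n >= 2, ncol(pos) == 3, all(is.finite(pos)))
  if (is.null(category)) category <- rep("generic", n)
  structure(
    list(pos = pos, bp_per_bead = bp_per_bead,
         category = category, seed = seed, step = step),
    class = "conformation"
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads, %g bp/bead, step %d\n",
              nrow(x$pos), x$bp_per_bead, x$step))
  invisible(x)
}

# unit-step random walk; bridge = TRUE pins the end at `to`
rw_path <- function(n, from = c(0, 0, 0), to = NULL, step_len = 1) {
  if (n == 1) return(matrix(from, 1, 3))
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * step_len
  steps <- apply(dirs, 2, cumsum)
  if (is.null(dim(steps))) steps <- matrix(steps, nrow = 1)
  path <- rbind(from, sweep(steps, 2, from, "+"))
  dimnames(path) <- NULL
  if (!is.null(to)) {
    # Brownian-bridge correction: subtract the fraction of the end error
    err <- path[n, ] - to
    frac <- (seq_len(n) - 1) / (n - 1)
    path <- path - outer(frac, err)
  }
  path
}

#' Initialize a conformation
#'
#' `random_walk` mode draws unit-length steps in uniformly random
#' directions. `helix_backbone` mode needs a `force_spec`: backbone beads
#' (loop anchors and gap beads) are placed on a regular helix with the
#' geometry's pitch and turn content (or, in `stretched_periodic` mode,
#' on a Brownian bridge between the fixed ends), and loop interiors are
#' laid down as random-walk bridges between their anchors.
#'
#' @param n_beads number of beads (ignored in helix mode, which takes it
#'   from the spec).
#' @param mode `"random_walk"` or `"helix_backbone"`.
#' @param seed integer seed.
#' @param spec a [build_force_spec()] object (required for helix mode).
#' @param bp_per_bead coarse-graining for random-walk mode.
#' @return a `conformation`.
#' @export
init_conformation <- function(n_beads = NULL,
                              mode = c("random_walk", "helix_backbone"),
                              seed = 1L, spec = NULL, bp_per_bead = 200) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "random_walk") {
    stopifnot(!is.null(n_beads), n_beads >= 2)
    pos <- rw_path(n_beads)
    return(new_conformation(pos, bp_per_bead, seed = seed))
  }
  if (is.null(spec)) stop("helix_backbone mode requires a force spec")
  n <- spec$n_beads
  bp <- spec$bp_per_bead
  geom <- spec$geom
  pos <- matrix(NA_real_, n, 3)
  unit <- spec$unit_nm
  root <- spec$loops[spec$loops$layer == "root", , drop = FALSE]
  anc <- spec$anchors

  if (spec$mode == "stretched_periodic") {
    L <- spec$box[3]
    ends <- rbind(c(0, 0, -L / 2 + 0.5), c(0, 0, L / 2 - 0.5))
    bb <- spec$backbone_beads
    # backbone step sized to the equilibrium bond lengths: per loop the
    # path crosses one gap bond (L_gap + 10 nm) and one 10 nm anchor
    # bond (the backbone is stiff enough that brush tension barely
    # stretches them)
    L_gap_nm <- geom$params$L_gap_nm
    if (is.null(L_gap_nm)) L_gap_nm <- 0
    step_bb <- sqrt((((L_gap_nm + 10) / unit)^2 + (10 / unit)^2) / 2)
    path <- rw_path(length(bb), from = ends[1, ], to = ends[2, ],
                    step_len = step_bb)
    pos[bb, ] <- path
    pos[1, ] <- ends[1, ]; pos[n, ] <- ends[2, ]
  } else {
    # regular helix for the backbone: angle advances with genomic
    # position at 2*pi per turn, z advances linearly along the cylinder
    turn_bp <- geom$params$l_turn_Mb * 1e6
    l_chrom_bp <- geom$params$l_chrom_Mb * 1e6
    Lc <- geom$L_cyl_nm / unit
    r_bb <- if (!is.null(spec$spool)) spec$spool$R + 1.5
            else max(1.5, geom$R_cyl_nm / unit * 0.25)
    helix_at <- function(g_bp, theta = NULL) {
      th <- if (is.null(theta)) 2 * pi * g_bp / turn_bp else theta
      c(r_bb * cos(th), r_bb * sin(th),
        -Lc / 2 + Lc * g_bp / l_chrom_bp)
    }
    if (spec$mode == "cylinder_helix") {
      bb <- spec$backbone_beads
      g_bp <- (bb - 0.5) * bp
      pos[bb, ] <- t(vapply(g_bp, helix_at, numeric(3))) +
        matrix(stats::rnorm(3 * length(bb), 0, 0.2), ncol = 3)
    } else {
      # overlapping mode: anchors at their pinned angles
      theta <- pi * (root$start_bp + root$end_bp) / turn_bp
      mid <- (root$start_bp + root$end_bp) / 2
      for (q in seq_len(nrow(root))) {
        p <- helix_at(mid[q], theta[q])
        pos[anc[q, 1], ] <- p
        pos[anc[q, 2], ] <- p + stats::rnorm(3, 0, 0.1)
      }
    }
  }
  # loop interiors: random-walk bridges between their anchor positions;
  # in confined (cylinder) modes each loop is additionally fanned
  # radially outward so the initial density is near the target instead
  # of piling the whole brush onto the backbone helix
  spread_R <- if (spec$mode %in% c("cylinder_helix", "overlapping_helix"))
    max(0, geom$R_cyl_nm / unit - 3) else 0
  for (q in seq_len(nrow(anc))) {
    i0 <- anc[q, 1]; i1 <- anc[q, 2]
    if (i1 - i0 < 2) next
    if (any(is.na(pos[i0, ])) || any(is.na(pos[i1, ]))) next
    idx <- i0:i1
    fill <- idx[is.na(pos[idx, 1])]
    path <- rw_path(i1 - i0 + 1, from = pos[i0, ], to = pos[i1, ],
                    step_len = 0.7)
    if (spread_R > 0) {
      er <- c(pos[i0, 1], pos[i0, 2], 0)
      nrm <- sqrt(sum(er^2))
      if (nrm > 1e-9) {
        er <- er / nrm
        amp <- stats::runif(1, 0, spread_R)
        m <- i1 - i0 + 1
        tent <- sin(pi * (seq_len(m) - 1) / (m - 1))
        path <- path + outer(amp * tent, er)
      }
    }
    pos[fill, ] <- path[fill - i0 + 1, , drop = FALSE]
  }
  # any leftover beads (chain ends, uncovered chromatin): diffuse from
  # the nearest placed bead
  left <- which(is.na(pos[, 1]))
  if (length(left)) {
    placed <- which(!is.na(pos[, 1]))
    for (i in left) {
      ref <- placed[which.min(abs(placed - i))]
      pos[i, ] <- pos[ref, ] + stats::rnorm(3, 0, 0.5)
    }
  }
  new_conformation(pos, bp, category = rep("generic", n), seed = seed)
}

#' Advance a conformation with the reference Brownian integrator
#'
#' @param conf a `conformation`.
#' @param spec a `force_spec` (from [build_force_spec()] or
#'   [basic_force_spec()]); LEF bonds attached by [update_lef_bonds()]
#'   are included automatically.
#' @param n_steps number of time steps of size `dt`.
#' @param dt time step in reduced units (default 0.05).
#' @param temperature reduced temperature (default 1).
#' @param seed integer seed for the thermal noise.
#' @param save_every save a frame every this many steps (0 = none).
#' @return the advanced `conformation`; saved frames (list of matrices)
#'   in attribute `"frames"`.
#' @export
integrate_brownian <- function(conf, spec, n_steps, dt = 0.05,
                               temperature = 1, seed = 1L,
                               save_every = 0L) {
  stopifnot(inherits(conf, "conformation"), n_steps >= 0, dt > 0)
  bonds <- spec$bonds
  if (!is.null(spec$lef_bonds) && nrow(spec$lef_bonds))
    bonds <- rbind(bonds, spec$lef_bonds[, c("i", "j", "k", "L0")])
  lateral_bead <- integer(0); lateral_force <- 0
  if (!is.null(spec$cohesion) && nrow(spec$cohesion)) {
    lateral_bead <- spec$cohesion$bead
    # kT/nm -> kT/length-unit
    lateral_force <- spec$cohesion$force_kT_per_nm[1] * spec$unit_nm
  }
  pins <- spec$pins
  res <- cpp_brownian(
    conf$pos,
    as.integer(bonds$i), as.integer(bonds$j),
    as.numeric(bonds$k), as.numeric(bonds$L0),
    if (is.null(spec$angle_k)) 0 else spec$angle_k,
    spec$repulsion$A, spec$repulsion$cutoff,
    if (is.null(spec$box)) numeric(0) else as.numeric(spec$box),
    as.integer(spec$fixed),
    spec$cylinder, spec$spool,
    if (is.null(spec$spool)) integer(0) else as.integer(spec$spool$beads),
    if (is.null(spec$tethers)) 0 else spec$tethers$force,
    if (is.null(spec$tethers)) 0L else as.integer(spec$tethers$bead_lo),
    if (is.null(spec$tethers)) 0L else as.integer(spec$tethers$bead_hi),
    if (is.null(pins)) integer(0) else as.integer(pins$bead),
    if (is.null(pins)) numeric(0) else as.numeric(pins$theta0),
    if (is.null(pins)) numeric(0) else as.numeric(pins$kappa),
    as.integer(lateral_bead), lateral_force,
    dt, as.integer(n_steps), temperature, as.integer(seed),
    as.integer(save_every))
  out <- conf
  out$pos <- res$pos
  out$step <- conf$step + n_steps
  attr(out, "frames") <- res$frames
  out
}

#' Minimal force spec for free chains
#'
#' Chain-connectivity bonds plus soft repulsion, with no confinement;
#' used for random-walk controls, two-chain cohesion simulations and
#' tests. Multiple chains are given as a list of bead index ranges.
#'
#' @param n_beads total bead count.
#' @param chains list of `c(first, last)` bead ranges (1-based); default
#'   one chain.
#' @param bp_per_bead coarse-graining.
#' @param rep_A repulsion amplitude in kT (0 disables).
#' @param angle_k bending stiffness in kT (0 disables).
#' @param bond_k harmonic bond stiffness (kT/unit^2).
#' @return a `force_spec`.
#' @export
basic_force_spec <- function(n_beads, chains = NULL, bp_per_bead = 1000,
                             rep_A = 3, angle_k = 0, bond_k = 10) {
  if (is.null(chains)) chains <- list(c(1L, as.integer(n_beads)))
  bonds <- do.call(rbind, lapply(chains, function(ch) {
    if (ch[2] - ch[1] < 1) return(NULL)
    data.frame(i = ch[1]:(ch[2] - 1L), j = (ch[1] + 1L):ch[2],
               k = bond_k, L0 = 1)
  }))
  structure(
    list(n_beads = as.integer(n_beads), bp_per_bead = bp_per_bead,
         unit_nm = bead_diameter_nm(bp_per_bead),
         bonds = bonds, repulsion = list(A = rep_A, cutoff = 1),
         angle_k = angle_k, mode = "free", chains = chains,
         backbone_beads = integer(0), cylinder = NULL, spool = NULL,
         tethers = NULL, pins = NULL, fixed = integer(0), box = NULL),
    class = "force_spec"
  )
}

#' Synchronize LEF bonds with a 1D extrusion state
#'
#' Every bound LEF becomes one harmonic bond (L0 = 1, k = 10) between the
#' beads holding its two legs; stale bonds from previous updates are
#' replaced. Bead categories (`condensin` / `cohesin` at leg beads) are
#' refreshed at the same time for downstream fluorescence profiling.
#'
#' @param spec a `force_spec`.
#' @param state an `extrusion_state` whose lattice covers the same
#'   chromatin as the spec's beads (lattice kb mapped through
#'   `bp_per_bead`).
#' @param condensin_species,cohesin_species species names contributing to
#'   the respective bead categories.
#' @return the spec with `lef_bonds` and `lef_category` replaced.
#' @export
update_lef_bonds <- function(spec, state,
                             condensin_species = c("condensin",
                                                   "condensin_I",
                                                   "condensin_II"),
                             cohesin_species = c("extrusive_cohesin",
                                                 "cohesive_cohesin")) {
  kb_per_bead <- spec$bp_per_bead / 1000
  idx <- which(state$bound)
  # lattice site 1 covers [0, kb_per_site) kb
  site_to_bead <- function(site) {
    bead <- floor((site - 1L) * state$lat$kb_per_site / kb_per_bead) + 1L
    if (any(bead < 1L | bead > spec$n_beads))
      stop("LEF leg outside polymer range")
    as.integer(bead)
  }
  bi <- site_to_bead(state$left[idx])
  bj <- site_to_bead(state$right[idx])
  keep <- bi != bj
  sp_name <- state$sp_names[state$sp[idx]]
  spec$lef_bonds <- data.frame(i = bi[keep], j = bj[keep], k = 10, L0 = 1,
                               species = sp_name[keep],
                               stringsAsFactors = FALSE)
  cat_vec <- rep("generic", spec$n_beads)
  for (nm in intersect(sp_name, cohesin_species)) {
    sel <- sp_name == nm
    cat_vec[c(bi[sel], bj[sel])] <- "cohesin"
  }
  for (nm in intersect(sp_name, condensin_species)) {
    sel <- sp_name == nm
    cat_vec[c(bi[sel], bj[sel])] <- "condensin"
  }
  spec$lef_category <- cat_vec
  spec
}

# ------------------------------------------------------------------- I/O

#' Write / read conformations as plain text
#'
#' XYZ-style TSV with `#`-prefixed metadata header lines (bp_per_bead,
#' seed, step) and columns bead, x, y, z, category. Write-read-write
#' round trips are byte-identical.
#'
#' @param conf a `conformation`.
#' @param path file path.
#' @return `read_conformation` returns a `conformation`.
#' @export
write_conformation <- function(conf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# bp_per_bead\t%g", conf$bp_per_bead),
    sprintf("# seed\t%d", as.integer(conf$seed)),
    sprintf("# step\t%d", as.integer(conf$step)),
    "bead\tx\ty\tz\tcategory"), con)
  df <- data.frame(bead = seq_len(nrow(conf$pos)),
                   x = sprintf("%.6f", conf$pos[, 1]),
                   y = sprintf("%.6f", conf$pos[, 2]),
                   z = sprintf("%.6f", conf$pos[, 3]),
                   category = conf$category)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_conformation
#' @export
read_conformation <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- lapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, 2)
  df <- utils::read.table(path, sep = "\t", skip = 3, header = TRUE,
                          stringsAsFactors = FALSE)
  new_conformation(as.matrix(df[, c("x", "y", "z")]),
                   bp_per_bead = as.numeric(meta[[1]]),
                   category = df$category,
                   seed = as.integer(meta[[2]]),
                   step = as.integer(meta[[3]]))
}

#' Gauss linking number of two closed rings
#'
#' Used by the topological-equilibration smoke test: the soft-core
#' repulsion must allow two interlinked rings to unlink.
#'
#' @param posA,posB N x 3 coordinate matrices of the two rings (closed:
#'   last bead bonds to first).
#' @return numeric linking number (integer up to discretization error).
#' @export
linking_number <- function(posA, posB) {
  segs <- function(p) {
    nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
    list(mid = (p + nxt) / 2, d = nxt - p)
  }
  a <- segs(posA); b <- segs(posB)
  total <- 0
  for (q in seq_len(nrow(posA))) {
    r <- sweep(b$mid, 2, a$mid[q, ], "-")
    cross_ab <- cbind(
      a$d[q, 2] * b$d[, 3] - a$d[q, 3] * b$d[, 2],
      a$d[q, 3] * b$d[, 1] - a$d[q, 1] * b$d[, 3],
      a$d[q, 1] * b$d[, 2] - a$d[q, 2] * b$d[, 1])
    rn <- sqrt(rowSums(r^2))^3
    total <- total + sum(rowSums(r * cross_ab) / rn)
  }
  total / (4 * pi)
}
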