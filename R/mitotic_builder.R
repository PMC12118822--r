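#' Builders for mitotic chromatid models
#'
#' Mitotic chromatids are modeled as a bottlebrush: the chromatin fiber is
#' folded by condensins into an array of loops whose anchors form a
#' backbone, the bottlebrush is packed into a cylinder at a measured
#' volume density, and the backbone is weakly nudged onto a helical path.
#' Three architectures are supported: `cylinder_helix` (consecutive
#' loops, helical backbone in a confining cylinder), `stretched_periodic`
#' (consecutive loops, ends fixed in a periodic box - no helix), and
#' `overlapping_helix` (independently placed, overlapping loops with
#' per-anchor angular pins and no continuous backbone).
#'
#' Genomic coordinates are 0-based, half-open, in bp on a synthetic
#' chromosome. Spatial lengths are in reduced units of one bead diameter;
#' [bead_diameter_nm()] gives the nm equivalent at a given coarse-graining.
#'
#' @name mitotic_builder
NULL

#' Bead diameter at a given coarse-graining
#'
#' The reference fiber is 10 nm beads of 200 bp (one nucleosome). Coarser
#' beads conserve volume density, so the diameter scales with the cube
#' root of the DNA content.
#'
#' @param bp_per_bead DNA per bead in bp.
#' @return diameter in nm.
#' @export
bead_diameter_nm <- function(bp_per_bead) {
  stopifnot(bp_per_bead > 0)
  10 * (bp_per_bead / 200)^(1 / 3)
}

# --------------------------------------------------------------- geometry

#' Free geometric parameters of a chromatid model
#'
#' @param l_chrom_Mb chromosome length in Mb.
#' @param l_loop_kb average loop size in kb (root layer).
#' @param L_gap_nm gap between consecutive loop anchors in nm.
#' @param rho_L_Mb_per_um linear chromatin density along the cylinder axis
#'   (give this or `P_nm`).
#' @param P_nm helical pitch in nm (interconvertible with `rho_L` through
#'   `P = l_turn / rho_L`).
#' @param l_turn_Mb genomic content of one helical turn in Mb.
#' @param rho_V_Mb_per_um3 volume density in Mb/um^3.
#' @param sigma_C_nm Hi-C contact radius in nm.
#' @param mode `"cylinder_helix"`, `"stretched_periodic"` or
#'   `"overlapping_helix"`.
#' @param l_loop_nested_kb,L_gap_nested_nm optional nested-layer loop and
#'   gap sizes (condensin I inside condensin II loops).
#' @return object of class `geometry_params`.
#' @export
geometry_params <- function(l_chrom_Mb, l_loop_kb, L_gap_nm,
                            rho_L_Mb_per_um = NULL, P_nm = NULL,
                            l_turn_Mb = NA_real_, rho_V_Mb_per_um3,
                            sigma_C_nm = 48,
                            mode = c("cylinder_helix", "stretched_periodic",
                                     "overlapping_helix"),
                            l_loop_nested_kb = NULL,
                            L_gap_nested_nm = NULL) {
  mode <- match.arg(mode)
  if (is.null(rho_L_Mb_per_um) == is.null(P_nm))
    stop("give exactly one of rho_L_Mb_per_um or P_nm")
  if (is.null(rho_L_Mb_per_um)) {
    if (!is.finite(l_turn_Mb)) stop("P_nm given: l_turn_Mb required")
    rho_L_Mb_per_um <- l_turn_Mb / (P_nm / 1000)
  }
  stopifnot(l_chrom_Mb > 0, l_loop_kb > 0, L_gap_nm >= 0,
            rho_L_Mb_per_um > 0, rho_V_Mb_per_um3 > 0, sigma_C_nm >= 0)
  structure(
    list(l_chrom_Mb = l_chrom_Mb, l_loop_kb = l_loop_kb,
         L_gap_nm = L_gap_nm, rho_L_Mb_per_um = rho_L_Mb_per_um,
         l_turn_Mb = l_turn_Mb, rho_V_Mb_per_um3 = rho_V_Mb_per_um3,
         sigma_C_nm = sigma_C_nm, mode = mode,
         l_loop_nested_kb = l_loop_nested_kb,
         L_gap_nested_nm = L_gap_nested_nm),
    class = "geometry_params"
  )
}

#' Derive cylinder/helix geometry from free parameters
#'
#' Evaluates the model's five relations:
#' `L_cyl = l_chrom / rho_L`,
#' `R_cyl = sqrt(l_chrom / rho_V / L_cyl / pi)`,
#' `P = l_turn / rho_L`,
#' `N_loops = l_chrom / l_loop`,
#' `L_bb = N_loops * (L_gap + L_loopbond)`.
#' In `stretched_periodic` mode the periodic box has length
#' `L_stretch = l_chrom / rho_L` and a square cross-section sized to
#' satisfy the volume density.
#'
#' @param params a [geometry_params()] object.
#' @return object of class `derived_geometry` with lengths in nm.
#' @examples
#' p <- geometry_params(100, 400, 80, P_nm = 400, l_turn_Mb = 17,
#'                      rho_V_Mb_per_um3 = 44)
#' derive_geometry(p)
#' @export
derive_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  with(params, {
    L_cyl_um <- l_chrom_Mb / rho_L_Mb_per_um
    vol_um3 <- l_chrom_Mb / rho_V_Mb_per_um3
    R_cyl_um <- sqrt(vol_um3 / L_cyl_um / pi)
    P_nm <- if (is.finite(l_turn_Mb)) l_turn_Mb / rho_L_Mb_per_um * 1000
            else NA_real_
    N_loops <- l_chrom_Mb * 1000 / l_loop_kb
    # L_loopbond is one bead diameter; its nm value depends on the
    # coarse-graining chosen downstream, recorded as 1 reduced unit
    box <- NULL
    if (mode == "stretched_periodic") {
      # long (stretch) axis is z, square cross-section sized to rho_V
      w_um <- sqrt(vol_um3 / L_cyl_um)
      box <- c(w_um, w_um, L_cyl_um) * 1000
    }
    structure(
      list(L_cyl_nm = L_cyl_um * 1000, R_cyl_nm = R_cyl_um * 1000,
           P_nm = P_nm, N_loops = N_loops,
           L_bb_units_per_loop = NA_real_,  # filled by build_force_spec
           n_turns = if (is.finite(l_turn_Mb)) l_chrom_Mb / l_turn_Mb
                     else NA_real_,
           box_nm = box, params = params),
      class = "derived_geometry"
    )
  })
}

#' @export
print.derived_geometry <- function(x, ...) {
  cat(sprintf(paste0("<derived_geometry> L_cyl=%.0f nm R_cyl=%.0f nm ",
                     "P=%.0f nm N_loops=%.0f n_turns=%.2f\n"),
              x$L_cyl_nm, x$R_cyl_nm, x$P_nm, x$N_loops, x$n_turns))
  invisible(x)
}

# ------------------------------------------------------------ loop arrays

new_loop_array <- function(loops, l_chrom_bp, bp_per_bead, n_gap,
                           overlap_allowed = FALSE) {
  structure(
    list(loops = loops, l_chrom_bp = l_chrom_bp, bp_per_bead = bp_per_bead,
         n_gap = n_gap, overlap_allowed = overlap_allowed),
    class = "loop_array"
  )
}

#' @export
print.loop_array <- function(x, ...) {
  cat(sprintf("<loop_array> %d loops (%s) on %.1f Mb, %g bp/bead\n",
              nrow(x$loops), paste(unique(x$loops$layer), collapse = "+"),
              x$l_chrom_bp / 1e6, x$bp_per_bead))
  invisible(x)
}

#' Sample a consecutive (tiling) loop array
#'
#' Loop sizes are drawn independently from an exponential distribution
#' with mean `l_loop_kb`, quantized to whole beads (minimum one bead),
#' and laid end to end separated by `n_gap`-bead gaps until the
#' chromosome is consumed; the final loop is truncated at the chromosome
#' end, so loop and gap beads tile the chromosome exactly.
#'
#' @param l_chrom_Mb chromosome length in Mb.
#' @param l_loop_kb mean loop size in kb.
#' @param n_gap gap size between consecutive loops, in beads.
#' @param bp_per_bead coarse-graining in bp per bead.
#' @param seed integer seed.
#' @return a `loop_array` whose `loops` data.frame has columns
#'   `start_bp`, `end_bp` (0-based half-open) and `layer` (`"root"`).
#' @export
sample_consecutive_loops <- function(l_chrom_Mb, l_loop_kb, n_gap = 0L,
                                     bp_per_bead = 200, seed = 1L) {
  stopifnot(l_loop_kb > 0, n_gap >= 0)
  if (l_loop_kb * 1000 < bp_per_bead)
    stop("l_loop_kb smaller than one bead")
  l_chrom_bp <- round(l_chrom_Mb * 1e6)
  gap_bp <- n_gap * bp_per_bead
  set.seed(seed)
  starts <- ends <- numeric(0)
  pos <- 0
  repeat {
    size_bp <- max(1, round(stats::rexp(1, 1 / (l_loop_kb * 1000)) /
                              bp_per_bead)) * bp_per_bead
    end <- min(pos + size_bp, l_chrom_bp)
    if (end > pos) { starts <- c(starts, pos); ends <- c(ends, end) }
    pos <- end + gap_bp
    if (pos >= l_chrom_bp) break
  }
  loops <- data.frame(start_bp = starts, end_bp = ends,
                      layer = "root", stringsAsFactors = FALSE)
  new_loop_array(loops, l_chrom_bp, bp_per_bead, n_gap)
}

#' Subdivide root loops into a nested layer
#'
#' Each root loop is partitioned into smaller loops with exponentially
#' distributed sizes (mean `l_loop_nested_kb`) separated by
#' `n_gap_nested`-bead gaps; nested loops never cross root anchors.
#'
#' @param root a consecutive `loop_array`.
#' @param l_loop_nested_kb mean nested loop size in kb.
#' @param n_gap_nested nested gap in beads.
#' @param seed integer seed.
#' @return a `loop_array` containing both layers.
#' @export
subdivide_nested <- function(root, l_loop_nested_kb, n_gap_nested = 0L,
                             seed = 1L) {
  stopifnot(inherits(root, "loop_array"), !root$overlap_allowed)
  if (l_loop_nested_kb * 1000 >= mean(root$loops$end_bp - root$loops$start_bp))
    warning("nested mean >= root mean: degenerate nesting")
  bp <- root$bp_per_bead
  gap_bp <- n_gap_nested * bp
  set.seed(seed)
  out <- vector("list", nrow(root$loops))
  for (q in seq_len(nrow(root$loops))) {
    lo <- root$loops$start_bp[q]; hi <- root$loops$end_bp[q]
    pos <- lo
    starts <- ends <- numeric(0)
    repeat {
      size_bp <- max(1, round(stats::rexp(1, 1 / (l_loop_nested_kb * 1000)) /
                                bp)) * bp
      end <- min(pos + size_bp, hi)
      if (end > pos) { starts <- c(starts, pos); ends <- c(ends, end) }
      pos <- end + gap_bp
      if (pos >= hi) break
    }
    out[[q]] <- data.frame(start_bp = starts, end_bp = ends,
                           layer = "nested", stringsAsFactors = FALSE)
  }
  loops <- rbind(root$loops, do.call(rbind, out))
  res <- new_loop_array(loops, root$l_chrom_bp, bp, root$n_gap)
  res$n_gap_nested <- n_gap_nested
  res
}

#' Sample independently positioned (overlapping) loops
#'
#' Models complete extruder-extruder bypassing: `l_chrom / spacing_kb`
#' loops are placed with uniformly random starts and exponential sizes,
#' so loops overlap and interleave freely and no continuous backbone
#' exists.
#'
#' @param l_chrom_Mb chromosome length in Mb.
#' @param l_loop_kb mean loop size in kb (e.g. 900).
#' @param spacing_kb chromatin per loop in kb (e.g. 360).
#' @param bp_per_bead coarse-graining.
#' @param seed integer seed.
#' @return a `loop_array` with `overlap_allowed = TRUE`.
#' @export
sample_overlapping_loops <- function(l_chrom_Mb, l_loop_kb = 900,
                                     spacing_kb = 360, bp_per_bead = 200,
                                     seed = 1L) {
  l_chrom_bp <- round(l_chrom_Mb * 1e6)
  n <- floor(l_chrom_Mb * 1000 / spacing_kb)
  set.seed(seed)
  sizes <- pmax(bp_per_bead,
                round(stats::rexp(n, 1 / (l_loop_kb * 1000)) /
                        bp_per_bead) * bp_per_bead)
  starts <- floor(stats::runif(n, 0, pmax(1, l_chrom_bp - sizes)) /
                    bp_per_bead) * bp_per_bead
  loops <- data.frame(start_bp = starts, end_bp = pmin(starts + sizes,
                                                       l_chrom_bp),
                      layer = "root", stringsAsFactors = FALSE)
  loops <- loops[order(loops$start_bp), , drop = FALSE]
  rownames(loops) <- NULL
  new_loop_array(loops, l_chrom_bp, bp_per_bead, n_gap = 0L,
                 overlap_allowed = TRUE)
}

#' Count crossing (interleaved) loop pairs in an array
#'
#' @param arr a `loop_array`.
#' @return integer count of pairs (a,b),(c,d) with a < c < b < d.
#' @export
count_crossing_loops <- function(arr) {
  l <- arr$loops$start_bp; r <- arr$loops$end_bp
  n <- length(l)
  if (n < 2) return(0L)
  cnt <- 0L
  o <- order(l)
  l <- l[o]; r <- r[o]
  for (a in 1:(n - 1)) {
    b <- which(l[(a + 1):n] < r[a] & r[(a + 1):n] > r[a] &
                 l[(a + 1):n] > l[a])
    cnt <- cnt + length(b)
  }
  cnt
}

# ------------------------------------------------------- force-field spec

loop_anchor_beads <- function(loops, bp_per_bead) {
  # anchor bead = bead containing the anchor bp (floor division), 1-based
  i0 <- floor(loops$start_bp / bp_per_bead) + 1L
  i1 <- floor((loops$end_bp - 1) / bp_per_bead) + 1L
  cbind(i0, i1)
}

#' Build the force-field specification for a chromatid model
#'
#' Emits, depending on `mode`:
#' \itemize{
#' \item loop-anchor harmonic bonds (L0 = 1, k = 10) for every loop;
#' \item gap-stretch bonds (L0 = n_gap + 1, k = 10) between consecutive
#'   root anchors (consecutive arrays only);
#' \item soft DPD-style repulsion (A = 3 kT, cutoff 1) and chain
#'   connectivity bonds;
#' \item `cylinder_helix`: confining cylinder wall (eps = 1 kT,
#'   sigma = 0.5, dimensions inflated so the wall potential is 0.3 kT at
#'   the target radius/length), axial end tethers (force 1.0), a spool
#'   wall (eps = 6 kT, sigma = 1, radius 2) excluding backbone beads from
#'   the axial core, 4 ghost particles with 2 terminal torsion
#'   quadruplets (realized as azimuthal pins of the terminal beads,
#'   k = 100 kT), and one angular pin per helical turn;
#' \item `stretched_periodic`: terminal beads fixed at distance
#'   `L_stretch` inside a periodic box;
#' \item `overlapping_helix`: per-anchor azimuthal pins at
#'   `theta_i = pi (x_left + x_right) / l_turn` with stiffness such that
#'   the pin energy is 1 kT at 1.2 rad.
#' }
#'
#' @param arr a `loop_array`.
#' @param geom a `derived_geometry`.
#' @param mode model architecture; defaults to the mode recorded in the
#'   geometry parameters.
#' @return object of class `force_spec` consumed by [integrate_brownian()].
#' @export
build_force_spec <- function(arr, geom, mode = NULL) {
  stopifnot(inherits(arr, "loop_array"), inherits(geom, "derived_geometry"))
  if (is.null(mode)) mode <- geom$params$mode
  if (mode %in% c("cylinder_helix", "stretched_periodic") &&
      arr$overlap_allowed)
    stop("overlapping arrays require mode = 'overlapping_helix'")
  bp <- arr$bp_per_bead
  unit_nm <- bead_diameter_nm(bp)
  n_beads <- as.integer(ceiling(arr$l_chrom_bp / bp))

  # chain connectivity
  chain_bonds <- data.frame(i = seq_len(n_beads - 1L),
                            j = seq_len(n_beads - 1L) + 1L,
                            k = 10, L0 = 1)
  # Backbone geometry keeps its physical (nm) dimensions regardless of
  # bead coarse-graining: the anchor bond is one 10 nm fiber diameter
  # and the gap-stretch bond spans L_gap + 10 nm. This preserves the
  # fine model's backbone walk statistics (which set the large-scale
  # P(s)) when beads are coarser than 200 bp.
  L_gap_nm <- geom$params$L_gap_nm %||% 0
  anchor_L0 <- 10 / unit_nm
  gap_L0 <- (L_gap_nm + 10) / unit_nm
  # nm-faithful stiffness as well: 10 kT/(10 nm)^2 = 0.1 kT/nm^2, which
  # is k = 10 at fine scale and stiffer in reduced units for coarse
  # beads; soft coarse bonds would let brush tension stretch the
  # backbone several-fold in nm and corrupt the large-scale P(s)
  k_bb <- 0.1 * unit_nm^2
  root <- arr$loops[arr$loops$layer == "root", , drop = FALSE]
  anc_root <- loop_anchor_beads(root, bp)
  loop_bonds <- data.frame(i = anc_root[, 1], j = anc_root[, 2],
                           k = k_bb, L0 = anchor_L0)
  nested <- arr$loops[arr$loops$layer == "nested", , drop = FALSE]
  if (nrow(nested)) {
    anc_n <- loop_anchor_beads(nested, bp)
    loop_bonds <- rbind(loop_bonds,
                        data.frame(i = anc_n[, 1], j = anc_n[, 2],
                                   k = k_bb, L0 = anchor_L0))
  }
  gap_bonds <- NULL
  backbone_beads <- integer(0)
  if (!arr$overlap_allowed) {
    nr <- nrow(root)
    if (nr > 1) {
      gap_bonds <- data.frame(i = anc_root[-nr, 2], j = anc_root[-1, 1],
                              k = k_bb, L0 = gap_L0)
    }
    # backbone = anchors plus the gap beads between consecutive loops
    gaps <- unlist(lapply(seq_len(max(nr - 1, 0)), function(q) {
      a <- anc_root[q, 2]; b <- anc_root[q + 1, 1]
      if (b > a + 1) seq.int(a + 1L, b - 1L) else integer(0)
    }))
    backbone_beads <- sort(unique(c(anc_root[, 1], anc_root[, 2], gaps)))
  } else {
    backbone_beads <- sort(unique(c(anc_root[, 1], anc_root[, 2])))
  }

  bonds <- rbind(chain_bonds, loop_bonds, gap_bonds)
  bonds <- bonds[bonds$i != bonds$j, , drop = FALSE]

  spec <- list(
    n_beads = n_beads, bp_per_bead = bp, unit_nm = unit_nm,
    bonds = bonds, repulsion = list(A = 3, cutoff = 1),
    angle_k = 0, mode = mode,
    backbone_beads = backbone_beads,
    anchors = anc_root, loops = arr$loops, geom = geom,
    cylinder = NULL, spool = NULL, tethers = NULL,
    pins = NULL, fixed = integer(0), box = NULL,
    ghosts = NULL, quadruplets = NULL
  )

  if (mode == "cylinder_helix" || mode == "overlapping_helix") {
    R <- geom$R_cyl_nm / unit_nm
    L <- geom$L_cyl_nm / unit_nm
    eps <- 1; sig <- 0.5
    # inflate so confining potential reaches 0.3 kT at the target surface
    infl <- sig * sqrt(2 * log(eps / 0.3))
    spec$cylinder <- list(R = R + infl, L = L + 2 * infl,
                          R_target = R, L_target = L, eps = eps,
                          sigma = sig)
    spec$tethers <- list(force = 1, bead_lo = 1L, bead_hi = n_beads)
  }
  if (mode == "cylinder_helix") {
    spec$spool <- list(R = 2, eps = 6, sigma = 1, beads = backbone_beads)
    # ghost particles: A1/A2 on the axis at the cylinder caps, P1/P2 at
    # the initial angular positions of the terminal beads (phase 0)
    Lh <- (geom$L_cyl_nm / unit_nm) / 2
    spec$ghosts <- data.frame(
      name = c("A1", "A2", "P1", "P2"),
      x = c(0, 0, geom$R_cyl_nm / unit_nm / 2, geom$R_cyl_nm / unit_nm / 2),
      y = c(0, 0, 0, 0),
      z = c(-Lh, Lh, -Lh, Lh))
    spec$quadruplets <- list(c("T1", "A1", "A2", "P1"),
                             c("T2", "A1", "A2", "P2"))
    n_turns <- geom$n_turns
    turn_bp <- geom$params$l_turn_Mb * 1e6
    # terminal torsion quadruplets realized as azimuthal pins, k = 100
    pin_beads <- c(1L, n_beads)
    pin_theta <- c(0, 2 * pi * (arr$l_chrom_bp / turn_bp))
    pin_kappa <- c(100, 100)
    # one loop anchor per helical turn, same stiffness
    for (t in seq_len(max(floor(n_turns), 0))) {
      target_bp <- (t - 0.5) * turn_bp
      qi <- which.min(abs(root$start_bp - target_bp))
      b <- anc_root[qi, 1]
      pin_beads <- c(pin_beads, b)
      pin_theta <- c(pin_theta,
                     2 * pi * ((root$start_bp[qi] + 0.5) / turn_bp))
      pin_kappa <- c(pin_kappa, 100)
    }
    spec$pins <- data.frame(bead = pin_beads, theta0 = pin_theta,
                            kappa = pin_kappa)
  }
  if (mode == "overlapping_helix") {
    turn_bp <- geom$params$l_turn_Mb * 1e6
    theta <- pi * (root$start_bp + root$end_bp) / turn_bp
    kappa <- 1 / (1 - cos(1.2))  # U = kappa (1 - cos) is 1 kT at 1.2 rad
    spec$pins <- data.frame(
      bead = c(anc_root[, 1], anc_root[, 2]),
      theta0 = c(theta, theta), kappa = kappa)
  }
  if (mode == "stretched_periodic") {
    spec$box <- geom$box_nm / unit_nm
    spec$fixed <- c(1L, n_beads)
  }
  class(spec) <- "force_spec"
  spec
}

#' @export
print.force_spec <- function(x, ...) {
  cat(sprintf("<force_spec> %s: %d beads, %d bonds, %d pins%s%s\n",
              x$mode, x$n_beads, nrow(x$bonds),
              if (is.null(x$pins)) 0L else nrow(x$pins),
              if (!is.null(x$cylinder)) ", cylinder wall" else "",
              if (!is.null(x$box)) ", periodic box" else ""))
  invisible(x)
}

#' Plant cohesion sites at loop midpoints
#'
#' Sister-chromatid cohesion sites are sampled as a Poisson process at
#' `f_coh` sites per Mb, then each site is relocated to the midpoint bead
#' of the loop containing it (cohesins slide to loop tips, minimizing
#' tension). Each site carries a constant lateral pinning force toward
#' the virtual sister interface.
#'
#' @param arr a consecutive or nested `loop_array`.
#' @param f_coh_per_Mb cohesion site frequency per Mb; `<= 0` gives an
#'   empty spec.
#' @param seed integer seed.
#' @param force_kT_per_nm lateral pin force (default 0.1 kT/nm).
#' @return data.frame with columns `site_bp` (sampled position),
#'   `bead` (midpoint bead of containing loop), `force_kT_per_nm`.
#' @export
plant_cohesion <- function(arr, f_coh_per_Mb, seed = 1L,
                           force_kT_per_nm = 0.1) {
  stopifnot(inherits(arr, "loop_array"), !arr$overlap_allowed)
  empty <- data.frame(site_bp = numeric(0), bead = integer(0),
                      force_kT_per_nm = numeric(0))
  if (f_coh_per_Mb <= 0) return(empty)
  set.seed(seed)
  n <- stats::rpois(1, f_coh_per_Mb * arr$l_chrom_bp / 1e6)
  if (n == 0) return(empty)
  sites <- sort(stats::runif(n, 0, arr$l_chrom_bp))
  root <- arr$loops[arr$loops$layer == "root", , drop = FALSE]
  hit <- vapply(sites, function(s) {
    q <- which(root$start_bp <= s & s < root$end_bp)
    if (length(q)) q[1] else NA_integer_
  }, integer(1))
  keep <- !is.na(hit)
  sites <- sites[keep]; hit <- hit[keep]
  mid_bp <- (root$start_bp[hit] + root$end_bp[hit]) / 2
  data.frame(site_bp = sites,
             bead = floor(mid_bp / arr$bp_per_bead) + 1L,
             force_kT_per_nm = force_kT_per_nm)
}
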