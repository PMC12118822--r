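#' Synthetic microscopy observables from conformations
#'
#' To compare simulations of sister chromatids with fluorescence
#' microscopy, each chromatid is reduced to a spine (the graph-shortest
#' path through its bond network, with condensin loop-anchor bridges
#' added as shortcuts), spines of the two sisters are paired into
#' perpendicular section frames, and monomers are collapsed onto the
#' section lines to build per-category (DNA / condensin / cohesin)
#' density profiles across the sister-sister axis.
#'
#' @name imaging_profiles
NULL

#' Extract a chromatid spine
#'
#' Builds the bead graph from consecutive-bead polymer bonds of one
#' chain plus bridge bonds (beads bridged by a condensin LEF), and
#' returns the shortest path by edge count between the first and last
#' bead of the chain. Ties are broken deterministically by the graph's
#' vertex order (lowest bead index first).
#'
#' @param conf a `conformation` (positions unused, topology only).
#' @param chain `c(first, last)` bead range of the chromatid.
#' @param bridge_bonds data.frame with columns `i`, `j` of extra bonds
#'   (may be empty).
#' @return integer vector of bead indices along the spine.
#' @export
extract_spine <- function(conf, chain = NULL, bridge_bonds = NULL) {
  n <- nrow(conf$pos)
  if (is.null(chain)) chain <- c(1L, n)
  beads <- chain[1]:chain[2]
  edges <- cbind(beads[-length(beads)], beads[-1])
  if (!is.null(bridge_bonds) && nrow(bridge_bonds)) {
    bb <- bridge_bonds[bridge_bonds$i >= chain[1] &
                         bridge_bonds$j <= chain[2], , drop = FALSE]
    edges <- rbind(edges, cbind(bb$i, bb$j))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  sp <- igraph::shortest_paths(g, from = chain[1], to = chain[2],
                               output = "vpath")
  path <- as.integer(sp$vpath[[1]])
  if (!length(path)) stop("chromatid graph is disconnected")
  path
}

#' Pair two spines into section frames
#'
#' Each spine bead is paired with its 3D-nearest bead on the other
#' spine; only mutually nearest pairs are kept. Every retained pair
#' defines a section frame with origin at the pair midpoint and axis
#' along the line through the pair.
#'
#' @param spineA,spineB integer bead indices of the two spines.
#' @param conf a `conformation` holding the bead positions.
#' @return data.frame with one row per frame: bead_a, bead_b, origin
#'   (`ox,oy,oz`) and unit axis (`ax,ay,az`).
#' @export
pair_spines <- function(spineA, spineB, conf) {
  pa <- conf$pos[spineA, , drop = FALSE]
  pb <- conf$pos[spineB, , drop = FALSE]
  # all-pairs distances (spines are short relative to the polymer)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  near_ab <- max.col(-d2, ties.method = "first")
  near_ba <- max.col(-t(d2), ties.method = "first")
  mutual <- which(near_ba[near_ab] == seq_along(spineA))
  if (!length(mutual)) {
    warning("no mutually nearest spine pairs")
    return(data.frame(bead_a = integer(0), bead_b = integer(0),
                      ox = numeric(0), oy = numeric(0), oz = numeric(0),
                      ax = numeric(0), ay = numeric(0), az = numeric(0)))
  }
  a <- mutual
  b <- near_ab[mutual]
  origin <- (pa[a, , drop = FALSE] + pb[b, , drop = FALSE]) / 2
  axis <- pb[b, , drop = FALSE] - pa[a, , drop = FALSE]
  nrm <- sqrt(rowSums(axis^2))
  nrm[nrm < 1e-12] <- 1
  axis <- axis / nrm
  data.frame(bead_a = spineA[a], bead_b = spineB[b],
             ox = origin[, 1], oy = origin[, 2], oz = origin[, 3],
             ax = axis[, 1], ay = axis[, 2], az = axis[, 3])
}

#' Cross-section density profile
#'
#' Every bead of the requested category is assigned to the section
#' frame that minimizes its perpendicular distance (rejection) to the
#' section line; its signed projection along that frame's axis about
#' the frame origin is histogrammed.
#'
#' @param conf a `conformation`.
#' @param frames data.frame from [pair_spines()].
#' @param category `"generic"` (all beads), `"condensin"` or
#'   `"cohesin"` (uses `conf$category`).
#' @param bin_width histogram bin width in length units (default 0.5).
#' @param lim half-range of the histogram (default 30 units).
#' @return data.frame `(position, count)`; class `density_profile`.
#' @export
radial_profile <- function(conf, frames, category = "generic",
                           bin_width = 0.5, lim = 30) {
  breaks <- seq(-lim, lim, by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  empty <- structure(data.frame(position = mids,
                                count = rep(0, length(mids))),
                    class = c("density_profile", "data.frame"))
  if (!nrow(frames)) return(empty)
  sel <- if (category == "generic") seq_len(nrow(conf$pos))
         else which(conf$category == category)
  if (!length(sel)) return(empty)
  p <- conf$pos[sel, , drop = FALSE]
  o <- as.matrix(frames[, c("ox", "oy", "oz")])
  a <- as.matrix(frames[, c("ax", "ay", "az")])
  # projection of bead k on frame f: (p_k - o_f) . a_f
  proj <- p %*% t(a) - matrix(rowSums(o * a), nrow(p), nrow(frames),
                              byrow = TRUE)
  # rejection^2 = |p - o|^2 - proj^2
  d2 <- outer(rowSums(p^2), rowSums(o^2), "+") - 2 * p %*% t(o)
  rej2 <- pmax(d2 - proj^2, 0)
  fsel <- max.col(-rej2, ties.method = "first")
  x <- proj[cbind(seq_along(fsel), fsel)]
  h <- graphics::hist(x[x >= -lim & x <= lim], breaks = breaks,
                      plot = FALSE)
  structure(data.frame(position = mids, count = h$counts),
            class = c("density_profile", "data.frame"))
}

#' Sum density profiles over conformations
#'
#' @param profiles list of `density_profile` objects on identical bins.
#' @return aggregated `density_profile`.
#' @export
sum_profiles <- function(profiles) {
  out <- profiles[[1]]
  for (p in profiles[-1]) out$count <- out$count + p$count
  out
}

#' Full width at half maximum of a profile
#'
#' Distance between the outermost crossings of half the maximum value,
#' with linear interpolation between bins.
#'
#' @param profile a `density_profile` (or data.frame
#'   `(position, count)`).
#' @return width in the profile's position units (`NA` if flat).
#' @export
width_half_max <- function(profile) {
  x <- profile$position
  y <- profile$count
  if (max(y) <= 0 || max(y) == min(y)) return(NA_real_)
  half <- max(y) / 2
  above <- y >= half
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 == 1) x[1] else {
    x[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (x[i1] - x[i1 - 1])
  }
  right <- if (i2 == length(x)) x[length(x)] else {
    x[i2] + (y[i2] - half) / (y[i2] - y[i2 + 1]) * (x[i2 + 1] - x[i2])
  }
  right - left
}

#' Modality summary of a density profile
#'
#' Smooths the counts and reports the positions of local maxima with at
#' least `prom` relative prominence, used to distinguish a single
#' shared axis (unimodal) from two separated sister axes (bimodal).
#'
#' @param profile a `density_profile`.
#' @param smooth_bins Gaussian smoothing sd in bins (default 2).
#' @param prom minimum relative prominence (default 0.1).
#' @return list with `n_modes` and `positions`.
#' @export
profile_modes <- function(profile, smooth_bins = 2, prom = 0.1) {
  y <- gauss_smooth(profile$count, smooth_bins)
  y[is.na(y)] <- 0
  pk <- find_peaks(y, prom = prom)
  pk <- pk[y[pk] > 0.1 * max(y)]
  list(n_modes = length(pk), positions = profile$position[pk])
}

#' Radial dispersion of scaffold (condensin) beads
#'
#' Standard deviation of the radial distance of the masked beads about
#' the chromatid axis (the z axis through the centroid, as in
#' cylinder-mode models). Condensins concentrated on a central scaffold
#' give a small value; condensins spread across the chromatid width
#' (overlapping-loop models) give a large one.
#'
#' @param conf a `conformation`.
#' @param mask logical or integer selection of condensin beads.
#' @return standard deviation of radial distances (length units).
#' @export
scaffold_dispersion <- function(conf, mask) {
  p <- conf$pos[mask, , drop = FALSE]
  if (!nrow(p)) return(NA_real_)
  cx <- mean(conf$pos[, 1]); cy <- mean(conf$pos[, 2])
  r <- sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)
  stats::sd(r)
}

#' Write a density profile as TSV
#'
#' Positions are emitted both in length units and nm.
#'
#' @param profile a `density_profile`.
#' @param path file path.
#' @param unit_nm nm per length unit.
#' @export
write_profile <- function(profile, path, unit_nm = 10) {
  df <- data.frame(position = profile$position,
                   position_nm = profile$position * unit_nm,
                   count = profile$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
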