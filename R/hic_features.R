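#' Feature scores on binned contact matrices
#'
#' Observed/expected normalization, compartment eigenvector and saddle
#' strength, dot (focal loop) deduplication and pileup enrichment,
#' insulation/TAD analysis, and time-course normalization. Matrices are
#' dense, symmetric, nonnegative, with 0-based half-open bin coordinates
#' at a fixed resolution; all scores are invariant to global scaling of
#' the matrix.
#'
#' @name hic_features
NULL

check_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("matrix must be nonnegative")
  if (max(abs(mat - t(mat)), na.rm = TRUE) >
      1e-8 * max(abs(mat), 1, na.rm = TRUE))
    stop("matrix must be symmetric")
  invisible(TRUE)
}

#' Observed/expected normalization by diagonal
#'
#' Divides each diagonal by its mean (the distance-decay expectation),
#' i.e. normalizes out P(s).
#'
#' @param mat dense symmetric contact matrix.
#' @param mask optional logical vector of bins to exclude.
#' @return OE matrix (NA on masked rows/columns).
#' @export
oe_matrix <- function(mat, mask = NULL) {
  check_matrix(mat)
  n <- nrow(mat)
  m <- mat
  if (!is.null(mask)) m[mask, ] <- m[, mask] <- NA
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    ex <- mean(m[idx], na.rm = TRUE)
    if (is.finite(ex) && ex > 0) {
      oe[idx] <- m[idx] / ex
      oe[idx[, c(2, 1), drop = FALSE]] <- m[idx] / ex
    }
  }
  oe
}

#' Compartment eigenvector
#'
#' Leading eigenvector of (OE - 1) restricted to unmasked bins, sign-
#' oriented to correlate positively with a reference track (e.g. GC
#' content or the planted compartment labels).
#'
#' @param oe OE matrix from [oe_matrix()].
#' @param reference_track numeric per-bin track for sign orientation
#'   (optional).
#' @return numeric track (length = bins); attribute `"flat"` is TRUE if
#'   the eigenvector carries no variance.
#' @export
compartment_ev <- function(oe, reference_track = NULL) {
  n <- nrow(oe)
  ok <- which(apply(oe, 1, function(r) any(is.finite(r))))
  if (length(ok) < 2) stop("degenerate matrix")
  a <- oe[ok, ok, drop = FALSE] - 1
  a[!is.finite(a)] <- 0
  e <- eigen(a, symmetric = TRUE)
  lead <- which.max(abs(e$values))
  v <- e$vectors[, lead] * sqrt(abs(e$values[lead]))
  track <- rep(NA_real_, n)
  track[ok] <- v
  flat <- stats::sd(v) < 1e-12
  if (!is.null(reference_track) && !flat) {
    cc <- stats::cor(track[ok], reference_track[ok])
    if (is.finite(cc) && cc < 0) track <- -track
  }
  attr(track, "flat") <- flat
  track
}

#' Compartmentalization (saddle) strength
#'
#' Bins are ranked by eigenvector value (after trimming the given
#' percentiles), split into `n_groups` equal-occupancy groups, and the
#' group-averaged OE matrix is formed. The score is the ratio of corner
#' elements `(AA + BB) / (AB + BA)` using the single extreme group per
#' corner.
#'
#' @param oe OE matrix.
#' @param ev compartment eigenvector track.
#' @param n_groups number of EV groups (default 10).
#' @param trim percentile trim, default `c(2.5, 97.5)`.
#' @return saddle strength (1.0 for a uniform matrix).
#' @export
saddle_strength <- function(oe, ev, n_groups = 10, trim = c(2.5, 97.5)) {
  stopifnot(length(ev) == nrow(oe))
  ok <- which(is.finite(ev))
  if (length(ok) < n_groups) stop("fewer unmasked bins than groups")
  qs <- stats::quantile(ev[ok], trim / 100)
  ok <- ok[ev[ok] >= qs[1] & ev[ok] <= qs[2]]
  if (length(ok) < n_groups) stop("fewer bins than groups after trim")
  grp <- cut(rank(ev[ok], ties.method = "first"),
             breaks = n_groups, labels = FALSE)
  S <- matrix(NA_real_, n_groups, n_groups)
  for (a in seq_len(n_groups)) for (b in seq_len(a)) {
    vals <- oe[ok[grp == a], ok[grp == b], drop = FALSE]
    S[a, b] <- S[b, a] <- mean(vals, na.rm = TRUE)
  }
  g <- n_groups
  (S[1, 1] + S[g, g]) / (S[1, g] + S[g, 1])
}

#' Deduplicate dot calls
#'
#' Dots closer than `radius` (Euclidean distance in the 2D map plane)
#' are clustered by single linkage and one representative (the first by
#' input order) is kept per cluster.
#'
#' @param dots data.frame with columns `x_bp`, `y_bp`.
#' @param radius clustering radius in bp (default 30 kb).
#' @return deduplicated data.frame.
#' @export
dedup_dots <- function(dots, radius = 3e4) {
  n <- nrow(dots)
  if (n <= 1) return(dots)
  d <- as.matrix(stats::dist(dots[, c("x_bp", "y_bp")]))
  g <- igraph::graph_from_adjacency_matrix(d <= radius, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  dots[!duplicated(comp), , drop = FALSE]
}

#' Dot (focal loop) pileup strength
#'
#' Extracts OE snippets of `flank` on each side around every dot,
#' averages them into a pileup, and reports the mean of the centered
#' 3x3 pixel window. Dots too close to the matrix edge are excluded
#' with a warning.
#'
#' @param mat dense contact matrix.
#' @param dots data.frame with `x_bp`, `y_bp` dot centers.
#' @param res matrix resolution in bp.
#' @param flank flank in bp on each side (default 50 kb).
#' @return mean 3x3 OE enrichment, or `NA_real_` if no usable dots.
#' @export
dot_strength <- function(mat, dots, res, flank = 5e4) {
  check_matrix(mat)
  if (nrow(dots) == 0) return(NA_real_)
  oe <- oe_matrix(mat)
  n <- nrow(mat)
  w <- round(flank / res)
  acc <- matrix(0, 2 * w + 1, 2 * w + 1)
  used <- 0L
  for (q in seq_len(nrow(dots))) {
    i <- floor(dots$x_bp[q] / res) + 1L
    j <- floor(dots$y_bp[q] / res) + 1L
    if (i - w < 1 || j - w < 1 || i + w > n || j + w > n) next
    sn <- oe[(i - w):(i + w), (j - w):(j + w)]
    sn[!is.finite(sn)] <- NA
    acc <- acc + ifelse(is.na(sn), 0, sn)
    used <- used + 1L
  }
  if (used == 0L) {
    warning("all dots too close to the matrix edge")
    return(NA_real_)
  }
  if (used < nrow(dots))
    warning(sprintf("%d dot(s) excluded near the matrix edge",
                    nrow(dots) - used))
  pile <- acc / used
  c0 <- w + 1
  mean(pile[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)])
}

#' Insulation track
#'
#' Diamond-window insulation: for each bin, the mean contact frequency
#' between the `window/res` bins upstream and downstream, expressed as
#' log2 relative to the chromosome-wide mean of that quantity.
#'
#' @param mat dense contact matrix.
#' @param res resolution in bp (must divide `window`).
#' @param window window in bp on each side (default 200 kb).
#' @return numeric per-bin track (NA within `window` of the edges).
#' @export
insulation_track <- function(mat, res, window = 2e5) {
  check_matrix(mat)
  if (window %% res != 0) stop("resolution must divide window")
  w <- window / res
  if (w < 2) stop("window must span at least 2 bins")
  n <- nrow(mat)
  tr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    tr[i] <- mean(mat[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
  }
  log2(tr / mean(tr, na.rm = TRUE))
}

#' Call insulating boundaries
#'
#' Boundaries are local minima of the insulation track; boundary
#' strength is the prominence of the minimum (height of the lower of
#' the two flanking maxima above the minimum). Boundaries with strength
#' below `min_strength` are filtered out.
#'
#' @param track insulation track from [insulation_track()].
#' @param res resolution in bp.
#' @param min_strength minimum prominence (default 0.1).
#' @return data.frame with `bin` (1-based), `pos_bp` (bin start),
#'   `strength`.
#' @export
call_boundaries <- function(track, res, min_strength = 0.1) {
  ok <- which(!is.na(track))
  y <- track[ok]
  n <- length(y)
  out <- data.frame(bin = integer(0), pos_bp = numeric(0),
                    strength = numeric(0))
  if (n < 3) return(out)
  cand <- which(diff(sign(diff(y))) > 0) + 1L
  for (i in cand) {
    jl <- i
    ml <- y[i]
    while (jl > 1 && y[jl] >= y[i] - 1e-12) { ml <- max(ml, y[jl]); jl <- jl - 1 }
    ml <- max(y[max(1, jl):i])
    jr <- i
    while (jr < n && y[jr] >= y[i] - 1e-12) { jr <- jr + 1 }
    mr <- max(y[i:min(n, jr)])
    s <- min(ml, mr) - y[i]
    if (s >= min_strength) {
      out <- rbind(out, data.frame(bin = ok[i], pos_bp = (ok[i] - 1) * res,
                                   strength = s))
    }
  }
  out
}

# nearest-neighbour rescale of a matrix to out x out
rescale_matrix <- function(m, out) {
  n <- nrow(m)
  idx <- pmin(n, pmax(1, round(seq(1, n, length.out = out))))
  m[idx, idx]
}

#' Average TAD pileup
#'
#' TADs are the intervals between consecutive boundaries within the
#' size range. For each TAD, an OE snippet spanning +-1 TAD size around
#' the TAD is extracted, rescaled to `out x out` pixels, and all
#' snippets are averaged.
#'
#' @param mat dense contact matrix.
#' @param boundaries data.frame from [call_boundaries()].
#' @param res resolution in bp.
#' @param size_range TAD size range in bp (default 100-700 kb).
#' @param out output pixel size (default 100).
#' @return list with `pileup` (out x out matrix) and `n_tads`.
#' @export
tad_pileup <- function(mat, boundaries, res, size_range = c(1e5, 7e5),
                       out = 100) {
  check_matrix(mat)
  oe <- oe_matrix(mat)
  n <- nrow(mat)
  b <- sort(boundaries$bin)
  acc <- matrix(0, out, out)
  used <- 0L
  if (length(b) >= 2) {
    for (q in seq_len(length(b) - 1)) {
      lo <- b[q]; hi <- b[q + 1]
      size_bp <- (hi - lo) * res
      if (size_bp < size_range[1] || size_bp > size_range[2]) next
      w <- hi - lo
      i0 <- lo - w; i1 <- hi + w
      if (i0 < 1 || i1 > n) next
      sn <- oe[i0:i1, i0:i1]
      sn[!is.finite(sn)] <- NA
      sc <- rescale_matrix(sn, out)
      acc <- acc + ifelse(is.na(sc), 0, sc)
      used <- used + 1L
    }
  }
  list(pileup = if (used) acc / used else acc * NA, n_tads = used)
}

#' Normalize a feature time course to its G2 value
#'
#' @param values numeric vector of per-timepoint scores.
#' @param g2_value the G2 (reference) score, > 0.
#' @return `values / g2_value`.
#' @export
timecourse_norm <- function(values, g2_value) {
  if (!is.numeric(g2_value) || g2_value <= 0) stop("g2_value must be > 0")
  values / g2_value
}

# ------------------------------------------------------------------- I/O

#' Write / read dense matrices as TSV
#'
#' @param mat matrix.
#' @param path file path.
#' @param res resolution in bp (stored in a header line).
#' @export
write_matrix <- function(mat, path, res) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution\t%g", res), con)
  utils::write.table(format(mat, digits = 8, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  hdr <- readLines(path, n = 1)
  res <- as.numeric(strsplit(sub("^# ", "", hdr), "\t")[[1]][2])
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1,
                                   header = FALSE))
  dimnames(m) <- NULL
  attr(m, "resolution") <- res
  m
}
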