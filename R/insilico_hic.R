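#' In-silico Hi-C: contacts, P(s) curves and model-fit metric
#'
#' Conformations are converted to contact frequencies by perturbing every
#' bead with an isotropic Gaussian of sd `sigma_C` per axis and counting
#' pairs within a strict distance cutoff of 1.1 length units, repeated
#' over many perturbation replicates: the jitter turns the hard cutoff
#' into a smooth, distance-dependent contact probability with an
#' effective "contact radius" sigma_C. P(s) is the ratio of the observed
#' contact count (numerator) and the number of locus pairs (denominator)
#' per log-spaced separation bin (128 bins per decade over 1 kb - 1 Gb),
#' with both terms smoothed separately by a Gaussian kernel of width
#' 0.03 in log10(s).
#'
#' @name insilico_hic
NULL

#' Sample contacts from a conformation
#'
#' @param conf a `conformation`.
#' @param sigma_C_nm contact radius: Gaussian jitter sd per axis, nm.
#' @param cutoff contact distance cutoff in length units (default 1.1).
#' @param n_reps number of perturbation replicates (default 100).
#' @param seed integer seed.
#' @param box optional periodic box (length-3, reduced units) for
#'   minimum-image contact search.
#' @param min_sep minimum bead separation |i - j| counted (default 1).
#' @return a `contact_list`: data.frame `(i, j, freq)` with frequencies
#'   in [0, 1], plus metadata attributes.
#' @export
simulate_contacts <- function(conf, sigma_C_nm = 48, cutoff = 1.1,
                              n_reps = 100, seed = 1L, box = NULL,
                              min_sep = 1L) {
  stopifnot(inherits(conf, "conformation"), sigma_C_nm >= 0)
  if (cutoff <= 0) stop("cutoff must be > 0")
  unit_nm <- bead_diameter_nm(conf$bp_per_bead)
  df <- cpp_contacts(conf$pos, sigma_C_nm / unit_nm, cutoff,
                     as.integer(n_reps), as.integer(seed),
                     if (is.null(box)) numeric(0) else as.numeric(box),
                     as.integer(min_sep))
  structure(df, class = c("contact_list", "data.frame"),
            bp_per_bead = conf$bp_per_bead, n_reps = n_reps,
            n_beads = nrow(conf$pos))
}

#' Pool contacts from several conformations
#'
#' Averages per-pair frequencies over conformation replicates.
#'
#' @param contact_lists list of `contact_list` objects over the same
#'   bead range.
#' @return a pooled `contact_list`.
#' @export
pool_contacts <- function(contact_lists) {
  stopifnot(length(contact_lists) >= 1)
  all <- do.call(rbind, lapply(contact_lists, function(d)
    data.frame(i = d$i, j = d$j, freq = d$freq)))
  agg <- stats::aggregate(freq ~ i + j, all, sum)
  agg$freq <- agg$freq / length(contact_lists)
  structure(agg, class = c("contact_list", "data.frame"),
            bp_per_bead = attr(contact_lists[[1]], "bp_per_bead"),
            n_reps = attr(contact_lists[[1]], "n_reps"),
            n_beads = attr(contact_lists[[1]], "n_beads"))
}

# geometric separation bins: 128 per decade over [1 kb, 1 Gb]
ps_bin_edges <- function() 10^seq(3, 9, by = 1 / 128)

gauss_smooth <- function(v, sigma_bins) {
  n <- length(v)
  half <- max(1L, ceiling(4 * sigma_bins))
  kern <- stats::dnorm(-half:half, sd = sigma_bins)
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  num <- stats::filter(c(rep(0, half), v0, rep(0, half)), kern, sides = 2)
  den <- stats::filter(c(rep(0, half), as.numeric(ok), rep(0, half)),
                       kern, sides = 2)
  out <- (num / pmax(den, 1e-300))[(half + 1):(half + n)]
  out[den[(half + 1):(half + n)] < 1e-12] <- NA
  as.numeric(out)
}

#' Contact frequency versus genomic separation
#'
#' @param contacts a `contact_list` (or data.frame with `i`, `j`, `freq`
#'   plus a `bp_per_bead`/`n_beads` pair given explicitly).
#' @param bp_per_bead,n_beads overrides for plain data.frames.
#' @param log10_sigma Gaussian smoothing width in log10(s) (default 0.03).
#' @return a `ps_curve`: data.frame `(s_bp, P)` over the populated bins,
#'   with unsmoothed numerator/denominator kept as attributes.
#' @export
ps_from_contacts <- function(contacts, bp_per_bead = NULL, n_beads = NULL,
                             log10_sigma = 0.03) {
  if (is.null(bp_per_bead)) bp_per_bead <- attr(contacts, "bp_per_bead")
  if (is.null(n_beads)) n_beads <- attr(contacts, "n_beads")
  stopifnot(!is.null(bp_per_bead), !is.null(n_beads), nrow(contacts) > 0)
  edges <- ps_bin_edges()
  nbin <- length(edges) - 1L
  # numerator: observed contacts per separation bin
  s_pair <- abs(contacts$j - contacts$i) * bp_per_bead
  bin_pair <- findInterval(s_pair, edges, rightmost.closed = TRUE)
  keep <- bin_pair >= 1 & bin_pair <= nbin
  num <- numeric(nbin)
  if (any(keep)) {
    agg <- rowsum(contacts$freq[keep], bin_pair[keep])
    num[as.integer(rownames(agg))] <- agg[, 1]
  }
  # denominator: all locus pairs at each separation
  k <- seq_len(n_beads - 1L)
  s_off <- k * bp_per_bead
  bin_off <- findInterval(s_off, edges, rightmost.closed = TRUE)
  keep2 <- bin_off >= 1 & bin_off <= nbin
  den <- numeric(nbin)
  agg2 <- rowsum(as.numeric(n_beads - k[keep2]), bin_off[keep2])
  den[as.integer(rownames(agg2))] <- agg2[, 1]

  if (sum(num) == 0) warning("all-zero contact numerator")
  sigma_bins <- log10_sigma * 128
  num_s <- gauss_smooth(ifelse(den > 0, num, NA), sigma_bins)
  den_s <- gauss_smooth(ifelse(den > 0, den, NA), sigma_bins)
  P <- num_s / den_s
  mid <- sqrt(edges[-length(edges)] * edges[-1])
  ok <- den > 0 & !is.na(P)
  out <- data.frame(s_bp = mid[ok], P = P[ok])
  structure(out, class = c("ps_curve", "data.frame"),
            num = num[ok], den = den[ok], bp_per_bead = bp_per_bead,
            log10_sigma = log10_sigma)
}

#' P(s) directly from a conformation
#'
#' Convenience wrapper: [simulate_contacts()] then [ps_from_contacts()].
#'
#' @inheritParams simulate_contacts
#' @param ... passed to [simulate_contacts()].
#' @return a `ps_curve`.
#' @export
ps_from_conformation <- function(conf, sigma_C_nm = 48, ...) {
  ps_from_contacts(simulate_contacts(conf, sigma_C_nm = sigma_C_nm, ...))
}

#' Logarithmic derivative of a P(s) curve
#'
#' Central differences of log10 P against log10 s on the smoothed curve.
#'
#' @param ps a `ps_curve`.
#' @return data.frame `(s_bp, slope)`.
#' @export
log_derivative <- function(ps) {
  stopifnot(nrow(ps) >= 3)
  ls <- log10(ps$s_bp)
  lp <- log10(pmax(ps$P, 1e-300))
  n <- nrow(ps)
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (lp[3:n] - lp[1:(n - 2)]) / (ls[3:n] - ls[1:(n - 2)])
  data.frame(s_bp = ps$s_bp, slope = slope)
}

#' Mean P(s) slope over a separation range
#'
#' @param ps a `ps_curve`.
#' @param s_min,s_max range in bp.
#' @return mean of d log10 P / d log10 s over bins in the range.
#' @export
mean_log_slope <- function(ps, s_min, s_max) {
  d <- log_derivative(ps)
  sel <- d$s_bp >= s_min & d$s_bp <= s_max & !is.na(d$slope)
  if (!any(sel)) stop("no bins in requested range")
  mean(d$slope[sel])
}

# local maxima of y with relative prominence >= prom (fraction of the
# peak value, against the deepest valley separating it from higher
# ground on each side)
find_peaks <- function(y, prom = 0.02) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- vapply(cand, function(i) {
    jl <- i
    vl <- y[i]
    while (jl > 1 && y[jl] <= y[i]) { vl <- min(vl, y[jl]); jl <- jl - 1 }
    jr <- i
    vr <- y[i]
    while (jr < n && y[jr] <= y[i]) { vr <- min(vr, y[jr]); jr <- jr + 1 }
    min(y[i] - vl, y[i] - vr) >= prom * y[i]
  }, logical(1))
  cand[keep]
}

#' Estimate the average loop size from the P(s) derivative
#'
#' The derivative of P(s) peaks near the loop size; in dense mitotic
#' loop arrays the true loop size sits somewhat to the left of that
#' peak, so the peak position is multiplied by a fixed calibration
#' factor (determined once against chromatid models built with known
#' 100/200/400 kb loops; see the package vignette).
#'
#' @param ps a `ps_curve`.
#' @param s_range search range in bp (default 10 kb - 2 Mb).
#' @param calibration left-offset calibration factor (0.64, fixed once
#'   against a chromatid model built with known 400 kb loops).
#' @return estimated loop size in kb (`NA` if no peak).
#' @export
loop_size_estimate <- function(ps, s_range = c(1e4, 2e6),
                               calibration = 0.64, detect_sigma = 0.05) {
  d <- log_derivative(ps)
  sel <- which(d$s_bp >= s_range[1] & d$s_bp <= s_range[2] &
                 !is.na(d$slope))
  if (length(sel) < 3) return(NA_real_)
  sl <- gauss_smooth(d$slope[sel], detect_sigma * 128)
  i <- sel[which.max(sl)]
  d$s_bp[i] * calibration / 1000
}

#' Position of the second Hi-C diagonal
#'
#' The second diagonal of mitotic maps is the first local maximum of
#' P(s) beyond `s_min`; its position equals the genomic content of one
#' helical turn. Returns `NA` (none) when no peak with at least the
#' required prominence exists, as for non-helical (condensin I-only)
#' chromosomes.
#'
#' @param ps a `ps_curve`.
#' @param s_min lower bound of the search in bp (default 2 Mb).
#' @param prominence minimum relative prominence (default 0.02).
#' @return position in Mb, or `NA_real_`.
#' @export
second_diagonal_position <- function(ps, s_min = 2e6, prominence = 0.02,
                                     detect_sigma = 0.08) {
  pk <- ps_peaks(ps, s_min = s_min, prominence = prominence,
                 detect_sigma = detect_sigma)
  if (!length(pk)) return(NA_real_)
  pk[1]
}

#' All P(s) peak positions beyond a minimum separation
#'
#' Peaks are located on a detection-smoothed copy of the curve (wider
#' kernel than the construction smoothing, suppressing single-bin
#' sampling bumps) and their positions are then refined to the raw
#' local maximum near each smoothed peak, which removes the position
#' bias that smoothing an asymmetric peak introduces.
#'
#' @inheritParams second_diagonal_position
#' @return numeric vector of peak positions in Mb (possibly empty).
#' @export
ps_peaks <- function(ps, s_min = 2e6, prominence = 0.02,
                     detect_sigma = 0.08) {
  sel <- which(ps$s_bp >= s_min & !is.na(ps$P) & ps$P > 0)
  if (length(sel) < 5) return(numeric(0))
  y <- 10^gauss_smooth(log10(ps$P[sel]), detect_sigma * 128)
  pk <- find_peaks(y, prom = prominence)
  if (!length(pk)) return(numeric(0))
  refined <- vapply(pk, function(i) {
    win <- max(1, i - 6):min(length(sel), i + 6)
    win[which.max(ps$P[sel[win]])]
  }, numeric(1))
  ps$s_bp[sel[refined]] / 1e6
}

#' RMS deviation between two P(s) curves
#'
#' Both curves are normalized to 1.0 at s = 3 kb and compared as root
#' mean square of log10 differences over separation bins in
#' `[s_min, s_max]`.
#'
#' @param ps_model,ps_ref `ps_curve` objects.
#' @param s_min,s_max comparison range in bp (defaults 3 kb and 40 Mb).
#' @return RMS deviation (log10 units).
#' @export
fit_rms <- function(ps_model, ps_ref, s_min = 3e3, s_max = 4e7) {
  norm_at_3kb <- function(ps) {
    sel <- which(!is.na(ps$P) & ps$P > 0)
    if (!length(sel)) stop("empty P(s) curve")
    s <- ps$s_bp[sel]
    if (min(s) > 3e3 || max(s) < 3e3)
      stop("P(s) curve does not cover s = 3 kb")
    v <- exp(stats::approx(log(s), log(ps$P[sel]), xout = log(3e3))$y)
    data.frame(s_bp = s, P = ps$P[sel] / v)
  }
  a <- norm_at_3kb(ps_model)
  b <- norm_at_3kb(ps_ref)
  # interpolate the reference onto the model grid (log-log)
  sel <- a$s_bp >= s_min & a$s_bp <= s_max &
    a$s_bp >= min(b$s_bp) & a$s_bp <= max(b$s_bp)
  if (!any(sel)) stop("no overlapping separation bins")
  bi <- exp(stats::approx(log(b$s_bp), log(b$P), xout = log(a$s_bp[sel]))$y)
  sqrt(mean((log10(a$P[sel]) - log10(bi))^2))
}

# ------------------------------------------------------------------- I/O

#' Write / read contact lists as pairs-like text
#'
#' Columns: chrom1, pos1, chrom2, pos2, freq on the synthetic chromosome
#' `chrS` (positions are 0-based bead starts in bp).
#'
#' @param contacts a `contact_list`.
#' @param path file path.
#' @export
write_pairs <- function(contacts, path) {
  bp <- attr(contacts, "bp_per_bead")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bp_per_bead\t%g", bp),
               sprintf("# n_beads\t%d", attr(contacts, "n_beads")),
               sprintf("# n_reps\t%d", attr(contacts, "n_reps")),
               "chrom1\tpos1\tchrom2\tpos2\tfreq"), con)
  df <- data.frame(chrom1 = "chrS", pos1 = (contacts$i - 1) * bp,
                   chrom2 = "chrS", pos2 = (contacts$j - 1) * bp,
                   freq = sprintf("%.6g", contacts$freq))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- lapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, 2)
  bp <- as.numeric(meta[[1]])
  df <- utils::read.table(path, sep = "\t", skip = 3, header = TRUE,
                          stringsAsFactors = FALSE)
  out <- data.frame(i = df$pos1 / bp + 1, j = df$pos2 / bp + 1,
                    freq = df$freq)
  structure(out, class = c("contact_list", "data.frame"),
            bp_per_bead = bp, n_beads = as.integer(meta[[2]]),
            n_reps = as.integer(meta[[3]]))
}

#' Write / read a P(s) curve as TSV
#'
#' Columns `s_bp`, `P`, `slope` (central-difference log-log derivative).
#'
#' @param ps a `ps_curve`.
#' @param path file path.
#' @export
write_ps <- function(ps, path) {
  d <- log_derivative(ps)
  df <- data.frame(s_bp = sprintf("%.6g", ps$s_bp),
                   P = sprintf("%.6g", ps$P),
                   slope = sprintf("%.6g", d$slope))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ps
#' @export
read_ps <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(data.frame(s_bp = df$s_bp, P = df$P),
            class = c("ps_curve", "data.frame"))
}
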