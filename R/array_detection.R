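#' Configuration for particle-pair array analysis
#'
#' Defaults reproduce the published procedure for linear zRGα1a arrays:
#' neighbours within 170 px (214.2 A at 1.26 A/px), C2 folding of the
#' in-plane angle, a 2 A x 2.6 deg histogram and a peak threshold of 0.5 of
#' the maximum normalized frequency.
#'
#' @param cutoff_px neighbour cutoff between particle centroids, in pixels.
#' @param pixel_size_A pixel size in Angstrom per pixel (used to convert
#'   centroid distances; the cutoff itself is applied in pixel space).
#' @param symmetry_fold `n` of the complex's Cn point-group symmetry; psi is
#'   folded into `[0, 360/n)`.
#' @param dist_bin_A distance bin width in Angstrom.
#' @param dpsi_bin_deg delta-psi bin width in degrees.
#' @param peak_threshold normalized-frequency threshold in `(0, 1]` defining
#'   the peak component.
#' @param round_psi if `TRUE`, round psi angles to whole degrees before
#'   folding (reproduces integer-valued angle handling; off by default to
#'   keep sub-degree precision).
#' @param circular_dpsi if `TRUE`, fold the absolute angle difference
#'   circularly into `[0, 180/n]`; the default is the plain absolute
#'   difference of folded angles.
#'
#' @return A list of class `"array_config"`.
#' @export
array_config <- function(cutoff_px = 170, pixel_size_A = 1.26,
                         symmetry_fold = 2L, dist_bin_A = 2,
                         dpsi_bin_deg = 2.6, peak_threshold = 0.5,
                         round_psi = FALSE, circular_dpsi = FALSE) {
  stopifnot(cutoff_px > 0, pixel_size_A > 0, dist_bin_A > 0,
            dpsi_bin_deg > 0, symmetry_fold >= 1,
            peak_threshold > 0, peak_threshold <= 1)
  structure(list(cutoff_px = cutoff_px, pixel_size_A = pixel_size_A,
                 symmetry_fold = as.integer(symmetry_fold),
                 dist_bin_A = dist_bin_A, dpsi_bin_deg = dpsi_bin_deg,
                 peak_threshold = peak_threshold,
                 round_psi = isTRUE(round_psi),
                 circular_dpsi = isTRUE(circular_dpsi)),
            class = "array_config")
}

#' Fold an in-plane angle under Cn symmetry
#'
#' Maps psi first into `[0, 360)` and then into the symmetry-reduced range
#' `[0, 360/n)`, since a view rotated by `360/n` degrees is indistinguishable
#' for a Cn-symmetric particle.  Idempotent and vectorised.
#'
#' @param psi_deg angle(s) in degrees.
#' @param symmetry_fold Cn fold `n >= 1`.
#' @return Angle(s) in `[0, 360/n)`.
#' @export
#' @examples
#' fold_psi(-5, 2)   # 175
#' fold_psi(190, 2)  # 10
fold_psi <- function(psi_deg, symmetry_fold = 2L) {
  if (!all(is.finite(psi_deg))) stop("psi_deg must be finite")
  stopifnot(symmetry_fold >= 1)
  (psi_deg %% 360) %% (360 / symmetry_fold)
}

#' Folded in-plane angle difference between two particles
#'
#' The default follows the published procedure literally: both angles are
#' folded into `[0, 360/n)` and the absolute difference is taken.  With
#' `circular = TRUE` the difference is additionally folded to the shorter
#' arc, `min(d, 360/n - d)`.
#'
#' @param psi_a,psi_b angles in degrees.
#' @param symmetry_fold Cn fold.
#' @param circular use the circular (shorter-arc) difference.
#' @return Non-negative difference(s) in degrees.
#' @export
delta_psi <- function(psi_a, psi_b, symmetry_fold = 2L, circular = FALSE) {
  d <- abs(fold_psi(psi_a, symmetry_fold) - fold_psi(psi_b, symmetry_fold))
  if (circular) d <- pmin(d, 360 / symmetry_fold - d)
  d
}

#' Convert a pixel distance to Angstrom
#'
#' @param d_px distance in pixels.
#' @param pixel_size_A pixel size in Angstrom per pixel (positive).
#' @return Distance in Angstrom.
#' @export
#' @examples
#' px_to_angstrom(170, 1.26)  # 214.2
px_to_angstrom <- function(d_px, pixel_size_A) {
  if (!is.numeric(pixel_size_A) || pixel_size_A <= 0)
    stop("pixel_size_A must be positive")
  d_px * pixel_size_A
}

# Cell-list neighbour search within one micrograph: indices i < j with
# centroid separation <= cutoff (pixels).  Cells are cutoff-sized so only
# the 8-neighbourhood needs scanning.
.neighbour_pairs <- function(x, y, cutoff) {
  n <- length(x)
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  cx <- floor(x / cutoff)
  cy <- floor(y / cutoff)
  key <- paste(cx, cy, sep = ",")
  cells <- split(seq_len(n), key)
  ii <- integer(0); jj <- integer(0)
  coord <- do.call(rbind, strsplit(names(cells), ",", fixed = TRUE))
  ccx <- as.integer(coord[, 1]); ccy <- as.integer(coord[, 2])
  # forward half of the 8-neighbourhood avoids double visits
  offs <- rbind(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  for (k in seq_along(cells)) {
    a <- cells[[k]]
    if (length(a) > 1) {
      cmb <- utils::combn(a, 2L)
      ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
    }
    for (o in seq_len(nrow(offs))) {
      nk <- match(paste(ccx[k] + offs[o, 1], ccy[k] + offs[o, 2], sep = ","),
                  names(cells))
      if (!is.na(nk)) {
        b <- cells[[nk]]
        ii <- c(ii, rep(a, each = length(b)))
        jj <- c(jj, rep(b, times = length(a)))
      }
    }
  }
  d2 <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2
  keep <- d2 <= cutoff^2
  ii <- ii[keep]; jj <- jj[keep]
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  cbind(i = ii, j = jj)
}

#' Find within-micrograph particle pairs inside the centroid cutoff
#'
#' Every unordered pair of particles sharing a micrograph whose centroid
#' separation in pixels is at most `cutoff_px` is reported exactly once
#' (`id_a < id_b`), with the separation converted to Angstrom and the folded
#' angle difference attached.  Implemented as a cell-list neighbour search,
#' equivalent to the all-against-all enumeration.
#'
#' @param table a [particle_table()].
#' @param config an [array_config()]; its `pixel_size_A` is used unless the
#'   table carries its own.
#' @return A data frame of class `"particle_pairs"` with columns
#'   `micrograph`, `id_a`, `id_b`, `distance_A`, `dpsi_deg`.
#' @export
find_pairs <- function(table, config = array_config()) {
  stopifnot(inherits(table, "particle_table"), inherits(config, "array_config"))
  ps <- attr(table, "pixel_size_A")
  if (is.null(ps) || is.na(ps)) ps <- config$pixel_size_A
  psi <- if (config$round_psi) round(table$psi_deg) else table$psi_deg
  res <- lapply(split(seq_len(nrow(table)), table$micrograph), function(idx) {
    pr <- .neighbour_pairs(table$x_px[idx], table$y_px[idx], config$cutoff_px)
    if (!nrow(pr)) return(NULL)
    a <- idx[pr[, "i"]]; b <- idx[pr[, "j"]]
    d_px <- sqrt((table$x_px[a] - table$x_px[b])^2 +
                 (table$y_px[a] - table$y_px[b])^2)
    data.frame(
      micrograph = table$micrograph[a],
      id_a = pmin(table$particle_id[a], table$particle_id[b]),
      id_b = pmax(table$particle_id[a], table$particle_id[b]),
      distance_A = px_to_angstrom(d_px, ps),
      dpsi_deg = delta_psi(psi[a], psi[b], config$symmetry_fold,
                           config$circular_dpsi),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(micrograph = character(0), id_a = integer(0),
                      id_b = integer(0), distance_A = numeric(0),
                      dpsi_deg = numeric(0))
  rownames(out) <- NULL
  out <- out[order(out$micrograph, out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("particle_pairs", "data.frame")
  out
}

# Half-open bin index: edges[i] <= x < edges[i+1]; values on an edge go up.
.bin_index <- function(x, edges) findInterval(x, edges)

#' Bin particle pairs into a distance / delta-psi frequency grid
#'
#' Bins are half-open `[lo, hi)` (a value exactly on an edge falls in the
#' upper bin), anchored at zero, spanning `[0, cutoff]` in distance and
#' `[0, 360/n)` in delta-psi.  Counts are conserved and the normalized grid
#' divides by the maximum count, as in a surface plot of relative frequency.
#'
#' @param pairs a `"particle_pairs"` frame from [find_pairs()]; non-empty.
#' @param config an [array_config()].
#' @return A list of class `"distribution_grid"`: `dist_edges`, `dpsi_edges`,
#'   `counts` (distance x delta-psi integer matrix) and `normalized`.
#' @export
bin_pairs <- function(pairs, config = array_config()) {
  if (!nrow(pairs)) stop("no particle pairs to bin")
  cutoff_A <- config$cutoff_px * config$pixel_size_A
  nd <- floor(cutoff_A / config$dist_bin_A) + 1L
  dist_edges <- seq(0, by = config$dist_bin_A, length.out = nd + 1L)
  span <- 360 / config$symmetry_fold
  np <- ceiling(span / config$dpsi_bin_deg)
  dpsi_edges <- seq(0, by = config$dpsi_bin_deg, length.out = np + 1L)

  di <- .bin_index(pairs$distance_A, dist_edges)
  pi_ <- .bin_index(pairs$dpsi_deg, dpsi_edges)
  ok <- di >= 1 & di <= nd & pi_ >= 1 & pi_ <= np
  counts <- matrix(0L, nd, np)
  tab <- table(factor(di[ok], levels = seq_len(nd)),
               factor(pi_[ok], levels = seq_len(np)))
  counts[] <- as.integer(tab)
  structure(list(dist_edges = dist_edges, dpsi_edges = dpsi_edges,
                 counts = counts,
                 normalized = if (max(counts) > 0) counts / max(counts)
                              else counts * 0),
            class = "distribution_grid")
}

#' Extract the dominant peak of a distance / delta-psi distribution
#'
#' The peak is the 4-connected component of bins whose normalized frequency
#' is at least `peak_threshold` that contains the global maximum (on ties,
#' the first maximum in distance-major scan order).  Summary statistics are
#' computed over the raw pairs falling in the component's bins, not over bin
#' centres.
#'
#' @param grid a `"distribution_grid"` from [bin_pairs()].
#' @param pairs the pairs the grid was built from.
#' @param config the [array_config()] used.
#' @return A list of class `"peak_summary"`: `mean_distance_A`,
#'   `sd_distance_A`, `mean_dpsi_deg`, `sd_dpsi_deg`, `n_pairs_in_peak`,
#'   `peak_bins` (two-column index matrix).
#' @export
extract_peak <- function(grid, pairs, config = array_config()) {
  stopifnot(inherits(grid, "distribution_grid"))
  if (!nrow(pairs) || max(grid$counts) == 0)
    stop("empty distribution: no peak to extract")
  nd <- nrow(grid$counts); np <- ncol(grid$counts)
  # which.max scans column by column with the row index (distance) fastest:
  # the documented distance-major tie-break.
  start <- which.max(grid$normalized)
  above <- grid$normalized >= config$peak_threshold
  member <- matrix(FALSE, nd, np)
  queue <- start
  member[start] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    r <- ((cur - 1L) %% nd) + 1L
    c <- ((cur - 1L) %/% nd) + 1L
    for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
      if (d[1] >= 1 && d[1] <= nd && d[2] >= 1 && d[2] <= np) {
        idx <- (d[2] - 1L) * nd + d[1]
        if (above[idx] && !member[idx]) {
          member[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
    }
  }
  peak_bins <- which(member, arr.ind = TRUE)
  colnames(peak_bins) <- c("dist_bin", "dpsi_bin")

  di <- .bin_index(pairs$distance_A, grid$dist_edges)
  pi_ <- .bin_index(pairs$dpsi_deg, grid$dpsi_edges)
  inb <- di >= 1 & di <= nd & pi_ >= 1 & pi_ <= np
  in_peak <- inb & member[cbind(pmin(pmax(di, 1L), nd),
                                pmin(pmax(pi_, 1L), np))]
  d <- pairs$distance_A[in_peak]
  p <- pairs$dpsi_deg[in_peak]
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  structure(list(mean_distance_A = mean(d), sd_distance_A = sd0(d),
                 mean_dpsi_deg = mean(p), sd_dpsi_deg = sd0(p),
                 n_pairs_in_peak = sum(in_peak), peak_bins = peak_bins),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf(
    "Array peak: distance %.1f +/- %.1f A, delta-psi %.1f +/- %.1f deg (%d pairs, %d bins)\n",
    x$mean_distance_A, x$sd_distance_A, x$mean_dpsi_deg, x$sd_dpsi_deg,
    x$n_pairs_in_peak, nrow(x$peak_bins)))
  invisible(x)
}

#' Run the full array analysis on a STAR file
#'
#' Reads particles, finds within-cutoff pairs, bins them and extracts the
#' dominant peak; optionally writes a tab-separated pairs table, the grid as
#' a TSV matrix with bin-edge headers, and a JSON summary.
#'
#' @param star_path path to a particle STAR file.
#' @param config an [array_config()].
#' @param outdir output directory, or `NULL` to skip writing.
#' @param pixel_size_A pixel size override passed to [read_star()].
#' @return Invisibly, a list with `table`, `pairs`, `grid`, `peak`.
#' @export
run_array_analysis <- function(star_path, config = array_config(),
                               outdir = NULL, pixel_size_A = NULL) {
  table <- read_star(star_path, pixel_size_A = pixel_size_A)
  pairs <- find_pairs(table, config)
  if (!nrow(pairs)) stop("no particle pairs within the cutoff")
  grid <- bin_pairs(pairs, config)
  peak <- extract_peak(grid, pairs, config)
  message(sprintf("%d particles on %d micrographs -> %d pairs within %.1f A",
                  nrow(table), length(unique(table$micrograph)), nrow(pairs),
                  config$cutoff_px * config$pixel_size_A))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pairs, file.path(outdir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gm <- grid$counts
    dimnames(gm) <- list(
      sprintf("%.6g", grid$dist_edges[-length(grid$dist_edges)]),
      sprintf("%.6g", grid$dpsi_edges[-length(grid$dpsi_edges)]))
    utils::write.table(gm, file.path(outdir, "grid.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    jsonlite::write_json(
      list(mean_distance_A = peak$mean_distance_A,
           sd_distance_A = peak$sd_distance_A,
           mean_dpsi_deg = peak$mean_dpsi_deg,
           sd_dpsi_deg = peak$sd_dpsi_deg,
           n_pairs_in_peak = peak$n_pairs_in_peak,
           n_pairs = nrow(pairs), n_particles = nrow(table)),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(table = table, pairs = pairs, grid = grid, peak = peak))
}
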