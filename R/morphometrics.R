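#' Cell-to-cell distance profile (CCDP)
#'
#' Probability-normalised histogram of pairwise distances: the count in each
#' fixed-width bin divided by the total number of distances, so the profile
#' sums to one. The profile's peak (centre of the maximal bin) is the most
#' probable distance between two cells.
#'
#' @param distances numeric vector of pairwise distances (um).
#' @param bin_width histogram bin width (um), default 5.
#' @return An object of class `ccd_profile` with `bin_edges`,
#'   `probabilities` and `n_distances`.
#' @export
ccdp <- function(distances, bin_width = 5) {
  distances <- as.numeric(distances)
  if (length(distances) == 0) stop("at least one distance is required")
  if (any(distances < 0)) stop("distances must be >= 0")
  idx <- floor(distances / bin_width)
  nbin <- max(idx) + 1
  counts <- tabulate(idx + 1L, nbins = nbin)
  structure(list(bin_edges = seq(0, nbin * bin_width, by = bin_width),
                 probabilities = counts / length(distances),
                 n_distances = length(distances)),
            class = "ccd_profile")
}

#' @export
print.ccd_profile <- function(x, ...) {
  cat(sprintf("CCDP: %d distances, %d bins of %g um, peak at %g um\n",
              x$n_distances, length(x$probabilities),
              diff(x$bin_edges[1:2]), ccdp_peak(x)))
  invisible(x)
}

#' Peak of a CCDP
#'
#' Centre of the maximal bin; ties break toward the smaller distance.
#'
#' @param profile a [ccdp()] profile.
#' @return Peak distance (um).
#' @export
ccdp_peak <- function(profile) {
  stopifnot(inherits(profile, "ccd_profile"))
  i <- which.max(profile$probabilities) # first maximum = smaller distance
  (profile$bin_edges[i] + profile$bin_edges[i + 1]) / 2
}

# plain CCDP over all neuron pairs (3D distances); used when no cluster
# structure exists and the whole-culture profile is reported instead
ccdp_of_population <- function(population, bin_width = 5) {
  pos <- population$positions[population$types == "N", , drop = FALSE]
  if (nrow(pos) < 2) stop("need at least two neurons")
  ccdp(as.numeric(stats::dist(pos)), bin_width = bin_width)
}

local_minima_runs <- function(v) {
  # strict local minima with plateau handling: a run of equal values is a
  # minimum if both flanking values are larger; returns run-centre indices
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  if (length(r$values) >= 3) {
    for (q in 2:(length(r$values) - 1L)) {
      if (r$values[q] < r$values[q - 1L] && r$values[q] < r$values[q + 1L])
        out <- c(out, as.integer(round((starts[q] + ends[q]) / 2)))
    }
  }
  out
}

minimum_prominence <- function(v, i) {
  # height of the lower flanking peak above v[i]: walk each way until a
  # value below v[i] (or the end) and take the maximum passed en route
  vi <- v[i]
  side_bar <- function(idx) {
    bar <- -Inf
    for (j in idx) {
      if (v[j] < vi) return(bar)
      bar <- max(bar, v[j])
    }
    bar
  }
  lbar <- if (i > 1) side_bar((i - 1):1) else -Inf
  rbar <- if (i < length(v)) side_bar((i + 1):length(v)) else -Inf
  min(lbar, rbar) - vi
}

#' Segment neuron clusters along the culture long axis
#'
#' Neurons are binned at 10 um along x; the per-bin counts are smoothed with
#' a 3-bin moving average; the culture extent is the span between the first
#' and last bin whose smoothed count reaches 5% of the maximum; local minima
#' of the smoothed counts inside the extent mark cluster boundaries.
#'
#' To keep shot noise inside dense regions from fragmenting clusters, a
#' minimum only counts as a boundary when it dips at least
#' `min_prominence_frac` of the maximum bin count below its lower flanking
#' peak.
#'
#' @param population a [cell_population()] with at least one neuron.
#' @param bin_width_x x-bin width (um), default 10.
#' @param edge_threshold_frac occupancy threshold for the culture extent as
#'   a fraction of the maximum smoothed bin count.
#' @param min_prominence_frac minimum prominence of a boundary minimum,
#'   as a fraction of the maximum smoothed bin count.
#' @return An object of class `cluster_segmentation`: list with
#'   `cluster_intervals` (list of `c(start, end)` um), `culture_extent`,
#'   `bin_width_x`, and the smoothed count profile (`bin_centers`,
#'   `counts`).
#' @export
segment_clusters <- function(population, bin_width_x = 10,
                             edge_threshold_frac = 0.05,
                             min_prominence_frac = 0.2) {
  stopifnot(inherits(population, "cell_population"))
  x <- population$positions[population$types == "N", 1]
  if (length(x) == 0) stop("population contains no neurons")
  lo <- floor(min(x) / bin_width_x) * bin_width_x
  idx <- floor((x - lo) / bin_width_x)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  sm <- smooth3(counts)
  centers <- lo + (seq_along(sm) - 0.5) * bin_width_x
  occupied <- which(sm >= edge_threshold_frac * max(sm))
  ext_bins <- range(occupied)
  extent <- c(lo + (ext_bins[1] - 1) * bin_width_x,
              lo + ext_bins[2] * bin_width_x)
  inside <- seq(ext_bins[1], ext_bins[2])
  vin <- sm[inside]
  minima <- local_minima_runs(vin)
  prom <- min_prominence_frac * max(sm)
  minima <- minima[vapply(minima, function(i) minimum_prominence(vin, i),
                          numeric(1)) >= prom]
  bounds <- centers[inside][minima]
  edges <- c(extent[1], bounds, extent[2])
  intervals <- lapply(seq_len(length(edges) - 1L),
                      function(q) c(edges[q], edges[q + 1L]))
  structure(list(cluster_intervals = intervals,
                 culture_extent = extent,
                 bin_width_x = bin_width_x,
                 bin_centers = centers,
                 counts = sm),
            class = "cluster_segmentation")
}

smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(as.numeric(v))
  out <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
  out[1] <- mean(v[1:2])
  out[n] <- mean(v[(n - 1):n])
  out
}

#' @export
print.cluster_segmentation <- function(x, ...) {
  cat(sprintf("Cluster segmentation: %d clusters over [%.0f, %.0f] um\n",
              length(x$cluster_intervals), x$culture_extent[1],
              x$culture_extent[2]))
  invisible(x)
}

#' Per-cluster CCDP within depth bins
#'
#' Within each segmented cluster, the culture is sliced into z-bins
#' (default 10 um) and pairwise planar (x-y) distances are computed only
#' among neurons sharing a z-bin; distances from all z-bins of a cluster
#' are pooled into that cluster's CCDP. The mean profile averages the
#' per-cluster probability vectors.
#'
#' @param population a [cell_population()].
#' @param segmentation a [segment_clusters()] result.
#' @param z_bin depth slice thickness (um), default 10.
#' @param bin_width CCDP bin width (um), default 5.
#' @return List with `profiles` (per-cluster [ccdp()] objects),
#'   `mean_profile`, and `cluster_ids` of the retained clusters.
#' @export
cluster_ccdp <- function(population, segmentation, z_bin = 10,
                         bin_width = 5) {
  stopifnot(inherits(population, "cell_population"),
            inherits(segmentation, "cluster_segmentation"))
  neuron <- population$types == "N"
  pos <- population$positions[neuron, , drop = FALSE]
  profiles <- list()
  kept <- integer(0)
  for (ci in seq_along(segmentation$cluster_intervals)) {
    iv <- segmentation$cluster_intervals[[ci]]
    inside <- pos[, 1] >= iv[1] & pos[, 1] < iv[2]
    sub <- pos[inside, , drop = FALSE]
    dists <- numeric(0)
    if (nrow(sub) >= 2) {
      zb <- floor(sub[, 3] / z_bin)
      for (b in unique(zb)) {
        pts <- sub[zb == b, 1:2, drop = FALSE]
        if (nrow(pts) >= 2)
          dists <- c(dists, as.numeric(stats::dist(pts)))
      }
    }
    if (length(dists) == 0) {
      warning(sprintf("cluster %d has <2 neurons in every z-bin; excluded",
                      ci))
      next
    }
    profiles[[length(profiles) + 1L]] <- ccdp(dists, bin_width = bin_width)
    kept <- c(kept, ci)
  }
  if (length(profiles) == 0)
    stop("no cluster yields any within-z-bin pair")
  list(profiles = profiles,
       mean_profile = mean_ccdp(profiles),
       cluster_ids = kept)
}

#' Average several CCDPs
#'
#' Profiles are zero-padded to a common length and their probability
#' vectors averaged; the result still sums to one.
#'
#' @param profiles list of [ccdp()] profiles with equal bin width.
#' @return A `ccd_profile`.
#' @export
mean_ccdp <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  bw <- vapply(profiles, function(p) diff(p$bin_edges[1:2]), numeric(1))
  if (length(unique(bw)) != 1) stop("profiles must share a bin width")
  nb <- max(vapply(profiles, function(p) length(p$probabilities), integer(1)))
  mat <- vapply(profiles, function(p) {
    c(p$probabilities, rep(0, nb - length(p$probabilities)))
  }, numeric(nb))
  probs <- rowMeans(matrix(mat, nrow = nb))
  structure(list(bin_edges = seq(0, nb * bw[1], by = bw[1]),
                 probabilities = probs,
                 n_distances = sum(vapply(profiles, `[[`, numeric(1),
                                          "n_distances"))),
            class = "ccd_profile")
}

culture_length <- function(population, probs = c(0.005, 0.995)) {
  # whole-culture extent: contraction is read from whole-aggregate images,
  # and astrocyte-rich cultures keep an astrocyte rim beyond the neuron core
  diff(stats::quantile(population$positions[, 1], probs, names = FALSE))
}

#' Percent contraction between two states
#'
#' Culture length is the robust x-extent (span between the 0.5th and 99.5th
#' percentile of all cell x-coordinates, mirroring whole-culture imaging);
#' contraction is `100 * (L0 - Lf) / L0`.
#'
#' @param initial,final [cell_population()] states.
#' @return Contraction percentage.
#' @export
contraction <- function(initial, final) {
  stopifnot(inherits(initial, "cell_population"),
            inherits(final, "cell_population"))
  L0 <- culture_length(initial)
  if (L0 <= 0) stop("initial extent is zero")
  100 * (L0 - culture_length(final)) / L0
}

#' Contraction normalised to a reference condition
#'
#' Divides each condition's contraction by the mean contraction of a
#' designated reference condition.
#'
#' @param values contraction percentages.
#' @param reference_values contraction percentages of the reference
#'   condition.
#' @return `values / mean(reference_values)`.
#' @export
normalized_contraction <- function(values, reference_values) {
  m <- mean(reference_values)
  if (!is.finite(m) || m == 0) stop("reference mean contraction is zero")
  values / m
}

#' Depth-resolved astrocyte ratio
#'
#' Depth is measured from the local aggregate surface: the (x, y) plane is
#' tiled into columns (default 10 um pitch) and each column's surface is
#' the maximum cell z over the column and its 8 neighbours; a cell's depth
#' is that surface minus its own z. Two scalars summarise sorting: the
#' astrocyte fraction within the top 10 um (`superficial_ratio`) and the
#' maximum per-bin astrocyte fraction in the interior reference window
#' below it (`deep_max_ratio`: bins between `superficial_depth` and
#' `max_deep_depth`, holding at least `min_bin_count` cells). The window
#' mirrors how deep layers are measured in stained stacks (a band just
#' below the sheath, e.g. 15-25 um), and keeps the underside of a
#' fully-enveloping shell from masquerading as "deep" cells.
#'
#' @param population a [cell_population()].
#' @param depth_bin depth bin width (um), default 5.
#' @param column_pitch surface-column pitch (um), default 10.
#' @param superficial_depth boundary of the superficial layer (um).
#' @param min_bin_count minimum cells for a deep bin to enter the maximum.
#' @param max_deep_depth lower edge of the deep reference window (um).
#' @return An object of class `depth_profile`: `depth_bin_edges`,
#'   `astrocyte_ratio`, `total_count`, `superficial_ratio`,
#'   `deep_max_ratio`, and per-cell `depths`.
#' @export
depth_profile <- function(population, depth_bin = 5, column_pitch = 10,
                          superficial_depth = 10, min_bin_count = 10,
                          max_deep_depth = 50) {
  stopifnot(inherits(population, "cell_population"))
  pos <- population$positions
  if (nrow(pos) == 0) stop("population is empty")
  astro <- population$types == "A"
  cx <- floor(pos[, 1] / column_pitch)
  cy <- floor(pos[, 2] / column_pitch)
  key <- paste(cx, cy)
  top <- tapply(pos[, 3], key, max)
  # neighbourhood maximum over the 3x3 surrounding columns
  ux <- as.integer(sub(" .*", "", names(top)))
  uy <- as.integer(sub(".* ", "", names(top)))
  lut <- new.env(hash = TRUE, size = length(top))
  for (q in seq_along(top)) assign(names(top)[q], top[[q]], envir = lut)
  surf <- vapply(seq_along(top), function(q) {
    m <- -Inf
    for (ox in -1:1) for (oy in -1:1) {
      v <- get0(paste(ux[q] + ox, uy[q] + oy), envir = lut,
                ifnotfound = NULL)
      if (!is.null(v) && v > m) m <- v
    }
    m
  }, numeric(1))
  names(surf) <- names(top)
  depths <- surf[key] - pos[, 3]
  nb <- max(1L, floor(max(depths) / depth_bin) + 1L)
  bin <- pmin(floor(depths / depth_bin), nb - 1L) + 1L
  total <- tabulate(bin, nbins = nb)
  astro_n <- tabulate(bin[astro], nbins = nb)
  ratio <- ifelse(total > 0, astro_n / total, NA_real_)
  superficial <- depths <= superficial_depth
  sup_ratio <- if (any(superficial)) mean(astro[superficial]) else NA_real_
  edges <- seq(0, nb * depth_bin, by = depth_bin)
  deep_bins <- which(edges[-length(edges)] >= superficial_depth &
                       edges[-1] <= max_deep_depth &
                       total >= min_bin_count)
  deep_max <- if (length(deep_bins)) max(ratio[deep_bins]) else NA_real_
  structure(list(depth_bin_edges = edges,
                 astrocyte_ratio = ratio,
                 total_count = total,
                 superficial_ratio = sup_ratio,
                 deep_max_ratio = deep_max,
                 depths = unname(depths)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "Depth profile: superficial astrocyte ratio %.3f, deep max %.3f\n",
    x$superficial_ratio, x$deep_max_ratio))
  invisible(x)
}

#' Correlation between attraction constants and superficial sorting
#'
#' Pearson correlation of each type-pair attraction column (`AS_NN`,
#' `AS_NA`, `AS_AN`, `AS_AA`) against the superficial astrocyte ratio
#' across sweep configurations.
#'
#' @param sweep_table a data frame as returned by [sweep_simulations()]
#'   (needs the four `AS_*` columns and `superficial_astro_ratio`).
#' @return Named numeric vector of four correlations; a zero-variance
#'   column yields `NA`.
#' @export
force_morphology_correlation <- function(sweep_table) {
  need <- c("AS_NN", "AS_NA", "AS_AN", "AS_AA", "superficial_astro_ratio")
  missing <- setdiff(need, names(sweep_table))
  if (length(missing))
    stop("sweep_table lacks columns: ", paste(missing, collapse = ", "))
  ok <- stats::complete.cases(sweep_table[, need])
  tab <- sweep_table[ok, ]
  if (nrow(tab) < 3) stop("need at least three configurations")
  y <- tab$superficial_astro_ratio
  out <- vapply(c("AS_NN", "AS_NA", "AS_AN", "AS_AA"),
                function(col) {
                  xcol <- tab[[col]]
                  if (stats::sd(xcol) == 0 || stats::sd(y) == 0)
                    return(NA_real_)
                  stats::cor(xcol, y)
                }, numeric(1))
  stats::setNames(out, c("NN", "NA", "AN", "AA"))
}

#' Radial neuron-density profile of a disk culture
#'
#' Neuron counts per concentric annulus divided by annulus area.
#'
#' @param population a [cell_population()] in disk coordinates (origin at
#'   the disk centre).
#' @param bin_width radial bin width (um), default 20.
#' @return Data frame with `r_center` (um) and `density` (neurons/um^2,
#'   projected).
#' @export
radial_density_profile <- function(population, bin_width = 20) {
  stopifnot(inherits(population, "cell_population"))
  pos <- population$positions[population$types == "N", , drop = FALSE]
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  nb <- floor(max(r) / bin_width) + 1L
  bin <- pmin(floor(r / bin_width), nb - 1L) + 1L
  counts <- tabulate(bin, nbins = nb)
  edges <- seq(0, nb * bin_width, by = bin_width)
  area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  data.frame(r_center = (edges[-1] + edges[-length(edges)]) / 2,
             density = counts / area)
}
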