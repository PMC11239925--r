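## smFISH spot quantification and colocalization.
##
## Spot-to-protein distances: a binary structure mask (Otsu threshold of the
## protein channel) is turned into a Euclidean distance map; each spot's
## subpixel distance is read off by bilinear interpolation. RNA-RNA
## colocalization: mutual-nearest-neighbor (MNN) distances between two spot
## fields, with significance from uniform re-placement of the second species
## within a region mask.

#' Construct a binary structure mask
#'
#' @param grid logical (or 0/1) matrix; `TRUE` marks structure pixels.
#' @param pixel_size physical pixel size, um/px. The package default of
#'   0.215 um/px corresponds to the smFISH imaging scale (100 px = 21.5 um).
#' @return list of class `structure_mask`.
#' @export
structure_mask <- function(grid, pixel_size = 0.215) {
  grid <- .as_mask_grid(grid)
  .assert(pixel_size > 0, "pixel_size must be > 0")
  structure(list(grid = grid, pixel_size = pixel_size),
            class = "structure_mask")
}

#' Threshold an intensity image into a structure mask by Otsu's method
#'
#' The threshold maximizes the between-class variance of the full-image
#' histogram (256 bins); the mask is the set of pixels strictly above it.
#'
#' @param image 2-D numeric intensity matrix with at least two distinct
#'   values.
#' @param pixel_size um/px, stored on the mask.
#' @return a [structure_mask()].
#' @export
otsu_mask <- function(image, pixel_size = 0.215) {
  .assert(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  rng <- range(image)
  if (rng[1] == rng[2]) stop("no threshold separable: constant image")
  thr <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256)
  structure_mask(image > thr, pixel_size = pixel_size)
}

#' Euclidean distance map of a structure mask
#'
#' Each pixel's value is the Euclidean distance (px) to the nearest true-mask
#' pixel; exactly 0 on true pixels.
#'
#' @param mask a [structure_mask()] or logical matrix (>= 1 true pixel).
#' @return list of class `distance_map` with `grid` (numeric matrix, px),
#'   `pixel_size` and `units = "px"`.
#' @export
distance_map <- function(mask) {
  ps <- if (inherits(mask, "structure_mask")) mask$pixel_size else 0.215
  grid <- .as_mask_grid(mask)
  if (!any(grid)) stop("empty mask: distance map undefined")
  d <- EBImage::distmap(1 - grid)   # distance to nearest zero of (1 - mask)
  structure(list(grid = matrix(as.numeric(d), nrow(grid), ncol(grid)),
                 pixel_size = ps, units = "px"),
            class = "distance_map")
}

#' Subpixel spot-to-structure distances by bilinear interpolation
#'
#' The distance at subpixel `(x, y)` is the bilinear interpolation of the
#' surrounding distance-map pixel-center values (1, 2 or 4 pixels depending
#' on whether the coordinates are integral), converted to um via the map's
#' pixel size. Order of the input spots is preserved.
#'
#' @param spots a [spot_field()] (or data.frame with `spot_id`, `x`, `y`).
#' @param dmap a [distance_map()].
#' @return numeric vector of distances in um, one per spot.
#' @export
spot_structure_distances <- function(spots, dmap) {
  .assert(inherits(dmap, "distance_map"), "dmap must be a distance_map")
  g <- dmap$grid
  h <- nrow(g); w <- ncol(g)
  x <- spots$x; y <- spots$y
  bad <- which(x < 0 | x > w - 1 | y < 0 | y > h - 1)
  if (length(bad))
    stop("spot outside map extent: spot_id ",
         paste(spots$spot_id[bad], collapse = ", "))
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  # grid[row, col] with row = y + 1, col = x + 1 (0-based pixel centers)
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- (1 - fx) * (1 - fy) * g[i00] +
       fx * (1 - fy) * g[i00 + cbind(0, rep(1, length(x)))] +
       (1 - fx) * fy * g[i00 + cbind(rep(1, length(x)), 0)] +
       fx * fy * g[i00 + cbind(1, rep(1, length(x)))]
  v * dmap$pixel_size
}

#' Summarize a spot-distance distribution
#'
#' @param distances non-empty numeric vector; px if `pixel_size` given,
#'   already-um otherwise.
#' @param pixel_size conversion factor applied to `distances` (use 1 if the
#'   distances are already in um).
#' @param probs quantiles to report.
#' @param breaks histogram break specification (passed to [graphics::hist()]
#'   machinery via [hist()]'s algorithm, computed without plotting).
#' @return list with `median`, `quantiles`, `n` and `histogram`
#'   (data.frame of bin edges and counts), all in um.
#' @export
distance_summary <- function(distances, pixel_size = 1,
                             probs = c(0.25, 0.5, 0.75, 0.9),
                             breaks = "Sturges") {
  .assert(length(distances) > 0 && all(is.finite(distances)),
          "distances must be non-empty and finite")
  d <- distances * pixel_size
  hh <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(median = median(d), quantiles = quantile(d, probs), n = length(d),
       histogram = data.frame(lower = head(hh$breaks, -1),
                              upper = hh$breaks[-1], count = hh$counts))
}

## internal: MNN pairing on raw coordinate vectors.
## Ties broken toward the lowest index (inputs are ordered by spot_id).
.mnn_pairs <- function(ax, ay, bx, by) {
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  nn_ab <- max.col(-d2, ties.method = "first")         # per A row, best B
  nn_ba <- max.col(-t(d2), ties.method = "first")      # per B row, best A
  ia <- which(nn_ba[nn_ab] == seq_along(ax))
  list(a = ia, b = nn_ab[ia],
       distance = sqrt(d2[cbind(ia, nn_ab[ia])]))
}

#' Mutual nearest neighbors between two spot fields
#'
#' Returns exactly the pairs `(i, j)` where `j` is `i`'s nearest neighbor in
#' B and `i` is `j`'s nearest neighbor in A; distance ties are broken toward
#' the lowest `spot_id`. Each spot appears in at most one pair.
#'
#' @param a,b [spot_field()]s from the same image frame.
#' @return data.frame `spot_a`, `spot_b`, `distance` (px).
#' @export
mutual_nearest_neighbors <- function(a, b) {
  .assert(nrow(a) > 0 && nrow(b) > 0, "both spot fields must be non-empty")
  wa <- attr(a, "width"); wb <- attr(b, "width")
  ha <- attr(a, "height"); hb <- attr(b, "height")
  if (!is.null(wa) && !is.null(wb) && (wa != wb || ha != hb))
    stop("frame mismatch between spot fields")
  a <- a[order(a$spot_id), , drop = FALSE]
  b <- b[order(b$spot_id), , drop = FALSE]
  m <- .mnn_pairs(a$x, a$y, b$x, b$y)
  data.frame(spot_a = a$spot_id[m$a], spot_b = b$spot_id[m$b],
             distance = m$distance)
}

#' Colocalization significance by randomization of the second species
#'
#' The observed statistic is the fraction of mutual-nearest-neighbor pairs
#' with distance at or below `threshold` (the median MNN distance is also
#' reported). The null re-places the B spots uniformly at random within the
#' region mask `n_random` times; the p-value is
#' `(1 + #(null >= observed)) / (1 + n_random)` for the fraction statistic.
#'
#' @param a,b [spot_field()]s.
#' @param region a [structure_mask()] covering all spots (the admissible
#'   area for re-placement).
#' @param n_random number of random re-placements (>= 100).
#' @param threshold colocalization distance threshold in um.
#' @param seed integer seed.
#' @return list of class `mnn_result`: `pairs`, `observed`
#'   (`fraction_below`, `median_um`), `null_fraction` (vector),
#'   `p_value`, `cdf` (sorted observed and pooled null MNN distances, um),
#'   `threshold`, `n_random`.
#' @export
coloc_significance <- function(a, b, region, n_random = 1000, threshold = 0.5,
                               seed = 1) {
  .assert(n_random >= 100, "n_random must be >= 100")
  region <- if (inherits(region, "structure_mask")) region else structure_mask(region)
  grid <- region$grid; ps <- region$pixel_size
  h <- nrow(grid); w <- ncol(grid)
  covered <- function(f) {
    if (any(f$x < 0 | f$x > w - 1 | f$y < 0 | f$y > h - 1)) return(FALSE)
    all(grid[cbind(round(f$y) + 1, round(f$x) + 1)])
  }
  if (!covered(a) || !covered(b))
    stop("region smaller than spot extent")
  a <- a[order(a$spot_id), , drop = FALSE]
  b <- b[order(b$spot_id), , drop = FALSE]
  obs <- .mnn_pairs(a$x, a$y, b$x, b$y)
  obs_um <- obs$distance * ps
  obs_frac <- mean(obs_um <= threshold)
  set.seed(seed)
  true_idx <- which(grid)
  nb <- nrow(b)
  null_frac <- numeric(n_random)
  null_d <- vector("list", n_random)
  for (r in seq_len(n_random)) {
    pix <- sample(true_idx, nb, replace = TRUE)
    rx <- ((pix - 1) %/% h) + runif(nb, -0.5, 0.5)
    ry <- ((pix - 1) %% h) + runif(nb, -0.5, 0.5)
    m <- .mnn_pairs(a$x, a$y, rx, ry)
    dm <- m$distance * ps
    null_frac[r] <- mean(dm <= threshold)
    null_d[[r]] <- dm
  }
  structure(list(
    pairs = data.frame(spot_a = a$spot_id[obs$a], spot_b = b$spot_id[obs$b],
                       distance = obs$distance),
    observed = list(fraction_below = obs_frac, median_um = median(obs_um)),
    null_fraction = null_frac,
    p_value = (1 + sum(null_frac >= obs_frac)) / (1 + n_random),
    cdf = list(test = sort(obs_um), null = sort(unlist(null_d))),
    threshold = threshold, n_random = n_random
  ), class = "mnn_result")
}

#' Per-compartment spot counts and densities
#'
#' Counts spots per (cell, compartment) and normalizes by area (or, when a
#' `length_px` column is supplied instead of `area_px2`, by length, giving
#' spots per um along e.g. a neurite).
#'
#' @param spots a [spot_field()].
#' @param compartment_areas data.frame with `cell_id`, `compartment` and
#'   either `area_px2` or `length_px`.
#' @param pixel_size um/px (default 0.215, i.e. 100 px = 21.5 um).
#' @return data.frame `cell_id`, `compartment`, `n_spots`, and
#'   `density_per_um2` (or `density_per_um` in length mode).
#' @export
spot_density <- function(spots, compartment_areas, pixel_size = 0.215) {
  by_len <- "length_px" %in% names(compartment_areas)
  .assert(by_len || "area_px2" %in% names(compartment_areas),
          "compartment_areas needs an area_px2 or length_px column")
  size <- compartment_areas[[if (by_len) "length_px" else "area_px2"]]
  if (any(size <= 0)) stop("zero or negative compartment area")
  key <- function(d) paste(d$cell_id, d$compartment, sep = "\r")
  have <- key(compartment_areas)
  need <- unique(key(spots))
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing area entry for: ", paste(gsub("\r", "/", missing), collapse = ", "))
  counts <- table(factor(key(spots), levels = have))
  dens <- if (by_len) as.vector(counts) / (size * pixel_size)
          else as.vector(counts) / (size * pixel_size^2)
  out <- data.frame(cell_id = compartment_areas$cell_id,
                    compartment = compartment_areas$compartment,
                    n_spots = as.vector(counts))
  out[[if (by_len) "density_per_um" else "density_per_um2"]] <- dens
  out
}
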