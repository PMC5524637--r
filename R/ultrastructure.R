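# Dyad-distance, T-tubule-orientation and cluster-overlap quantification
# on 2-D binary masks.

#' Pair of jSR / T-tubule boundary masks on a common grid
#'
#' @param jsr_mask,tt_mask Binary matrices of identical shape; the jSR
#'   and T-tubule membrane masks of one dyad.
#' @param pixel_size_nm Pixel edge length (nm), > 0.
#' @return A `mask_pair` object.
#' @export
new_mask_pair <- function(jsr_mask, tt_mask, pixel_size_nm) {
  stopifnot(is.matrix(jsr_mask), is.matrix(tt_mask),
            all(dim(jsr_mask) == dim(tt_mask)), pixel_size_nm > 0)
  structure(list(jsr_mask = jsr_mask > 0, tt_mask = tt_mask > 0,
                 pixel_size_nm = pixel_size_nm),
            class = "mask_pair")
}

#' Ordered boundaries of the connected components of a binary mask
#'
#' Labels the 8-connected components and traces one ordered closed
#' contour per component (Moore-neighbor tracing), in pixel coordinates.
#'
#' @param mask Binary matrix.
#' @return A list of integer matrices with columns `row`, `col`, one per
#'   component; the trace starts at the uppermost-leftmost pixel and
#'   proceeds clockwise.
#' @export
#' @examples
#' m <- matrix(0, 7, 7); m[2:6, 2:6] <- 1
#' nrow(unique(trace_boundaries(m)[[1]]))  # 16 boundary pixels
trace_boundaries <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) stop("mask is empty", call. = FALSE)
  lab <- label_components(mask)
  lapply(seq_len(max(lab)), function(id) trace_contour(lab == id))
}

#' Nearest-boundary distances between T-tubule and jSR membranes
#'
#' For every boundary point of the T-tubule mask, the Euclidean distance
#' to the nearest boundary point of the jSR mask, scaled to nm.
#' Distances are between boundary pixel centres; the per-dyad summary is
#' their mean and minimum.
#'
#' @param pair A `mask_pair`.
#' @return A `dyad_distance_report`: `distances_nm` (one per T-tubule
#'   boundary point), `mean_nm`, `min_nm`, `n_points`.
#' @export
dyad_distances <- function(pair) {
  stopifnot(inherits(pair, "mask_pair"))
  if (!any(pair$jsr_mask) || !any(pair$tt_mask))
    stop("both masks must be non-empty", call. = FALSE)
  bt <- boundary_points(pair$tt_mask)
  bj <- boundary_points(pair$jsr_mask)
  d <- nn_distances(bt, bj) * pair$pixel_size_nm
  structure(list(distances_nm = d, mean_nm = mean(d), min_nm = min(d),
                 n_points = length(d)),
            class = "dyad_distance_report")
}

boundary_points <- function(mask) {
  b <- trace_boundaries(mask)
  unique(do.call(rbind, b))
}

# nearest-neighbour distances from each row of a to the point set b
nn_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Orientation histogram of a skeletonized T-tubule network
#'
#' Skeletonizes the projected network mask (Zhang-Suen thinning),
#' estimates the local tangent orientation at every skeleton pixel from
#' the structure tensor of the Gaussian-smoothed skeleton, and histograms
#' the orientations relative to the cell long axis over \[-90, 90)
#' degrees.  Angles are counterclockwise-positive; 0 degrees is the long
#' axis.
#'
#' @param mask Binary matrix (projected T-tubule network).
#' @param long_axis_deg Orientation of the cell long axis (degrees).
#' @param bin_width_deg Histogram bin width (degrees).
#' @param sigma Structure-tensor smoothing scale (pixels).
#' @return An `orientation_histogram`: `breaks`, `counts`, `weights`
#'   (normalized), `angles_deg` (per skeleton pixel).
#' @export
skeleton_orientation <- function(mask, long_axis_deg = 0,
                                 bin_width_deg = 2, sigma = 2) {
  stopifnot(is.matrix(mask))
  sk <- skeletonize(mask)
  if (!any(sk)) stop("skeleton is empty", call. = FALSE)
  sm <- gaussian_smooth(sk * 1, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  # math convention: x = column, y = -row (counterclockwise positive)
  gx <- gc; gy <- -gr
  jxx <- gaussian_smooth(gx * gx, sigma)
  jyy <- gaussian_smooth(gy * gy, sigma)
  jxy <- gaussian_smooth(gx * gy, sigma)
  idx <- which(sk)
  phi <- 0.5 * atan2(2 * jxy[idx], jxx[idx] - jyy[idx]) * 180 / pi
  ang <- fold_angle(phi + 90 - long_axis_deg)   # tangent = normal + 90
  breaks <- seq(-90, 90, by = bin_width_deg)
  counts <- hist(ang, breaks = breaks, plot = FALSE, right = FALSE)$counts
  structure(list(breaks = breaks, counts = counts,
                 weights = counts / sum(counts), angles_deg = ang),
            class = "orientation_histogram")
}

# fold an angle into [-90, 90)
fold_angle <- function(a) ((a + 90) %% 180) - 90

#' Detect labeled clusters in a grayscale image
#'
#' Smooth, threshold (Otsu by default), label 8-connected components and
#' keep those with at least `min_area` pixels, mirroring particle
#' analysis of thresholded super-resolution reconstructions.
#'
#' @param image Numeric matrix.
#' @param threshold Intensity threshold; `NULL` uses Otsu's method on the
#'   smoothed image.
#' @param smooth_sigma Gaussian smoothing scale (pixels); 0 disables.
#' @param min_area Minimum cluster area (pixels).
#' @param region_mask Optional binary matrix marking the lateral-membrane
#'   region; clusters whose centroid falls inside are tagged `"lateral"`,
#'   the rest `"midsection"`.
#' @param pixel_size_nm Pixel edge length (nm).
#' @return A `cluster_set`: `labels` (label matrix) and `clusters` (data
#'   frame with id, area_px, area_nm2, centroid_row, centroid_col,
#'   region).
#' @export
detect_clusters <- function(image, threshold = NULL, smooth_sigma = 1,
                            min_area = 4, region_mask = NULL,
                            pixel_size_nm = 1) {
  stopifnot(is.matrix(image))
  sm <- if (smooth_sigma > 0) gaussian_smooth(image, smooth_sigma) else image
  if (is.null(threshold)) threshold <- otsu_threshold(sm)
  bw <- sm > threshold
  lab <- label_components(bw)
  n <- max(lab)
  keep_rows <- list()
  out_lab <- matrix(0L, nrow(image), ncol(image))
  new_id <- 0L
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n)
    for (id in which(areas >= min_area)) {
      px <- which(lab == id, arr.ind = TRUE)
      new_id <- new_id + 1L
      out_lab[lab == id] <- new_id
      cr <- mean(px[, 1]); cc <- mean(px[, 2])
      region <- NA_character_
      if (!is.null(region_mask)) {
        region <- if (region_mask[round(cr), round(cc)] > 0)
          "lateral" else "midsection"
      }
      keep_rows[[new_id]] <- data.frame(
        id = new_id, area_px = nrow(px),
        area_nm2 = nrow(px) * pixel_size_nm^2,
        centroid_row = cr, centroid_col = cc, region = region)
    }
  }
  clusters <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    data.frame(id = integer(0), area_px = integer(0), area_nm2 = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               region = character(0))
  structure(list(labels = out_lab, clusters = clusters,
                 pixel_size_nm = pixel_size_nm, threshold = threshold),
            class = "cluster_set")
}

#' Pairwise overlap areas between two cluster sets
#'
#' Pixel-intersection area of every touching pair of clusters from two
#' channels on the same grid, plus the total overlap per cluster of the
#' first channel.
#'
#' @param a,b `cluster_set` objects on the same grid.
#' @return A list: `pairs` (data frame id_a, id_b, overlap_px,
#'   overlap_nm2) and `per_cluster_a` (total overlap per a-cluster, nm2).
#' @export
overlap_area <- function(a, b) {
  stopifnot(inherits(a, "cluster_set"), inherits(b, "cluster_set"))
  if (!all(dim(a$labels) == dim(b$labels)) ||
      a$pixel_size_nm != b$pixel_size_nm)
    stop("cluster sets are not on the same grid", call. = FALSE)
  both <- a$labels > 0 & b$labels > 0
  if (!any(both)) {
    pairs <- data.frame(id_a = integer(0), id_b = integer(0),
                        overlap_px = integer(0), overlap_nm2 = numeric(0))
  } else {
    tab <- table(a$labels[both], b$labels[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    pairs <- data.frame(id_a = as.integer(df[[1]]),
                        id_b = as.integer(df[[2]]),
                        overlap_px = as.integer(df$Freq),
                        overlap_nm2 = df$Freq * a$pixel_size_nm^2)
  }
  tot <- setNames(rep(0, nrow(a$clusters)), a$clusters$id)
  if (nrow(pairs)) {
    agg <- tapply(pairs$overlap_nm2, pairs$id_a, sum)
    tot[names(agg)] <- agg
  }
  list(pairs = pairs, per_cluster_a = tot)
}
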