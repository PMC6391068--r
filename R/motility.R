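#' Construct a spatiotemporal diameter map
#'
#' @param D `P x T` matrix of gut diameters (mm) by longitudinal position
#'   (rows, oral at row 1) and time (columns).
#' @param dx_mm Axial resolution (mm per row).
#' @param dt_s Temporal resolution (s per column).
#' @return A `diameter_map` object.
#' @export
diameter_map <- function(D, dx_mm, dt_s) {
  if (!is.matrix(D) || nrow(D) < 1 || ncol(D) < 1) stop("D must be a P x T matrix")
  if (any(D < 0)) stop("diameters must be >= 0")
  if (dx_mm <= 0 || dt_s <= 0) stop("resolutions must be > 0")
  structure(list(D = D, dx_mm = dx_mm, dt_s = dt_s), class = "diameter_map")
}

#' @export
print.diameter_map <- function(x, ...) {
  cat(sprintf("<diameter_map> %d positions x %d frames (%.3g mm, %.3g s resolution)\n",
              nrow(x$D), ncol(x$D), x$dx_mm, x$dt_s))
  invisible(x)
}

#' Intensity threshold by the histogram-valley rule
#'
#' Picks the valley between the two dominant modes of a (near-)bimodal
#' intensity distribution: the minimum of a kernel density estimate between
#' the two highest density peaks. Falls back to the midpoint of the range if
#' no interior valley exists.
#'
#' @param x Numeric intensities.
#' @return Threshold value.
#' @export
valley_threshold <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) return(mean(range(x)))
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  d$x[seg[which.min(y[seg])]]
}

#' Diameter map from a gut-silhouette video
#'
#' For each frame and each column along the gut axis, the diameter is the
#' count of silhouette pixels in that column times the pixel size. The
#' silhouette is darker than the background by default; the intensity
#' threshold is chosen once per video by the histogram-valley rule and held
#' fixed across frames.
#'
#' @param frames `H x W x T` array of video frames; the gut axis runs along
#'   columns unless `axis = "rows"`.
#' @param pixel_size_mm Pixel pitch (mm).
#' @param dt_s Seconds per frame.
#' @param axis `"cols"` (default) or `"rows"`: the longitudinal direction.
#' @param invert Set `TRUE` when the gut is brighter than the background.
#' @param threshold Optional manual override of the intensity threshold.
#' @return A [diameter_map()].
#' @export
build_diameter_map <- function(frames, pixel_size_mm, dt_s, axis = "cols",
                               invert = FALSE, threshold = NULL) {
  if (length(dim(frames)) != 3) stop("frames must be an H x W x T array")
  thr <- threshold %||% valley_threshold(as.numeric(frames))
  tn <- dim(frames)[3]
  cols <- vector("list", tn)
  for (t in seq_len(tn)) {
    fr <- frames[, , t]
    sil <- if (invert) fr > thr else fr < thr
    if (!any(sil)) stop("empty silhouette in frame ", t)
    counts <- if (axis == "cols") colSums(sil) else rowSums(sil)
    cols[[t]] <- counts * pixel_size_mm
  }
  diameter_map(do.call(cbind, cols), dx_mm = pixel_size_mm, dt_s = dt_s)
}

label_components_8 <- function(mask) {
  # 8-connected components on a logical matrix, via igraph
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  pos <- arrayInd(idx, dim(mask))
  id_of <- integer(length(mask)); id_of[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  for (s in shifts) {
    r2 <- pos[, 1] + s[1]; c2 <- pos[, 2] + s[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    nb <- r2[ok] + (c2[ok] - 1L) * nr
    ok2 <- mask[nb]
    edges[[length(edges) + 1]] <- cbind(id_of[idx[ok]][ok2], id_of[nb[ok2]])
  }
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Detect propagating contraction (CMMC-like) events
#'
#' A contraction is any map cell whose diameter falls below
#' `(1 - depth_threshold)` times the per-position baseline (temporal median).
#' Contraction cells are grouped into 8-connected components in the
#' (position, time) grid; components spanning at least `min_extent_mm`
#' longitudinally become events. Each event reports its onset time, its
#' initiation position (the most oral contracted position at onset), its
#' longitudinal extent, its mean relative depth, and its propagation speed
#' (least-squares slope of the leading front; aboral positive).
#'
#' @param map A [diameter_map()].
#' @param depth_threshold Fractional diameter decrease (default 0.3).
#' @param min_extent_mm Minimum longitudinal span (mm, default 5).
#' @return Tibble: `onset_s`, `init_mm`, `extent_mm`, `depth`, `speed_mm_s`.
#' @export
detect_cmmc_events <- function(map, depth_threshold = 0.3, min_extent_mm = 5) {
  stopifnot(inherits(map, "diameter_map"))
  base <- apply(map$D, 1, stats::median)
  rel <- 1 - map$D / base
  mask <- map$D < (1 - depth_threshold) * base
  lab <- label_components_8(mask)
  k <- max(lab)
  if (k == 0) return(empty_events())
  out <- vector("list", k)
  for (i in seq_len(k)) {
    cells <- which(lab == i, arr.ind = TRUE)
    extent <- (max(cells[, 1]) - min(cells[, 1]) + 1) * map$dx_mm
    if (extent < min_extent_mm) next
    onset_col <- min(cells[, 2])
    init_row <- min(cells[cells[, 2] == onset_col, 1])
    # leading front: earliest contracted time at each position
    front <- stats::aggregate(cells[, 2], list(pos = cells[, 1]), min)
    speed <- if (nrow(front) > 1) {
      stats::coef(stats::lm(I(front$pos * map$dx_mm) ~ I(front$x * map$dt_s)))[2]
    } else {
      NA_real_
    }
    out[[i]] <- tibble::tibble(
      onset_s = (onset_col - 1) * map$dt_s,
      init_mm = (init_row - 1) * map$dx_mm,
      extent_mm = extent,
      depth = mean(rel[cells]),
      speed_mm_s = unname(speed)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_events() else res[order(res$onset_s), ]
}

empty_events <- function() {
  tibble::tibble(onset_s = numeric(), init_mm = numeric(), extent_mm = numeric(),
                 depth = numeric(), speed_mm_s = numeric())
}

#' CMMC frequency in a longitudinal region
#'
#' Counts events whose initiation position lies inside `region_window` and
#' divides by the recording duration.
#'
#' @param events Output of [detect_cmmc_events()].
#' @param duration_min Recording duration (min, > 0).
#' @param region_window Length-2 mm range of initiation positions to count
#'   (default: all).
#' @return Events per minute.
#' @export
cmmc_frequency <- function(events, duration_min, region_window = c(-Inf, Inf)) {
  if (duration_min <= 0) stop("duration_min must be > 0")
  n <- sum(events$init_mm >= region_window[1] & events$init_mm <= region_window[2])
  n / duration_min
}
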