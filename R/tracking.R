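# Body-part tracking tables -> occupancy maps and distance-to-target
# series aligned with behavior and calcium.

#' Read a pose table in the two-header tracking-export layout
#'
#' First header row: body part per column triplet; second: `x`, `y`,
#' `likelihood`. Optional `# key=value` comment lines (e.g.
#' `frame_rate_hz`) may precede the headers. Frames whose likelihood falls
#' below `min_confidence` are masked for that part (coordinates kept,
#' flagged unusable).
#'
#' @param path Path to the CSV file.
#' @param min_confidence Per-frame confidence threshold in `[0, 1]`.
#' @param frame_rate_hz Frame rate; overrides any value in the file header.
#' @return A `pose_track` with a logical `masked` column in `$data`.
#' @export
read_pose <- function(path, min_confidence = 0.6, frame_rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- read_commented(path)
  body <- parsed$body
  if (length(body) < 2)
    stop("unknown pose file layout: need two header rows", call. = FALSE)
  h1 <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(body[2], ",", fixed = TRUE)[[1]]
  if (length(h1) != length(h2) || length(h1) < 4 ||
      !all(h2[-1] %in% c("x", "y", "likelihood")))
    stop("unknown pose file layout: expected bodypart/coord header rows",
         call. = FALSE)
  parts <- unique(h1[-1])
  dat <- utils::read.csv(text = paste(body[-(1:2)], collapse = "\n"),
                         header = FALSE)
  names(dat) <- c("frame", paste(h1[-1], h2[-1], sep = "."))
  n <- nrow(dat)
  rows <- lapply(parts, function(p) {
    data.frame(frame = dat$frame,
               part = p,
               x = dat[[paste0(p, ".x")]],
               y = dat[[paste0(p, ".y")]],
               likelihood = dat[[paste0(p, ".likelihood")]],
               stringsAsFactors = FALSE)
  })
  data <- do.call(rbind, rows)
  rate <- frame_rate_hz %||%
    (if (!is.null(parsed$meta$frame_rate_hz))
       as.numeric(parsed$meta$frame_rate_hz) else 30)
  data$time_s <- data$frame / rate
  data$masked <- data$likelihood < min_confidence
  if (all(data$masked))
    warning("all frames fall below min_confidence; track fully masked",
            call. = FALSE)
  structure(list(frame_rate_hz = rate, parts = parts,
                 meta = list(mouse = parsed$meta$mouse %||% NA_character_,
                             phase = parsed$meta$phase %||% NA_character_,
                             day = as.integer(parsed$meta$day %||% NA),
                             test = as.integer(parsed$meta$test %||% NA)),
                 min_confidence = min_confidence,
                 data = data[, c("frame", "time_s", "part", "x", "y",
                                 "likelihood", "masked")]),
            class = "pose_track")
}

part_frames <- function(track, part, unmasked_only = TRUE) {
  d <- track$data[track$data$part == part, , drop = FALSE]
  if (!nrow(d)) stop("unknown body part: ", part, call. = FALSE)
  if (unmasked_only && !is.null(d$masked)) d <- d[!d$masked, , drop = FALSE]
  d
}

#' Spatial occupancy map for one body part
#'
#' Normalized 2D histogram of the part's position over all unmasked frames:
#' every bin value is the fraction of frames spent there, so the map sums
#' to 1.
#'
#' @param track A `pose_track`.
#' @param part Body part name.
#' @param bins Integer `c(nx, ny)` bin counts.
#' @param geometry A [box_geometry()] fixing the histogram extent; defaults
#'   to the data range.
#' @return An `occupancy_map`: list with the normalized `density` matrix
#'   (nx x ny), bin `xbreaks`/`ybreaks`, `part`, `n_frames`.
#' @export
occupancy_map <- function(track, part = "head", bins = c(20L, 15L),
                          geometry = NULL) {
  stopifnot(inherits(track, "pose_track"))
  d <- part_frames(track, part)
  if (!nrow(d))
    stop("no unmasked frames for part '", part, "'", call. = FALSE)
  if (is.null(geometry)) {
    xr <- range(d$x); yr <- range(d$y)
  } else {
    xr <- c(0, geometry$width_mm); yr <- c(0, geometry$height_mm)
  }
  xb <- seq(xr[1], xr[2], length.out = bins[1] + 1L)
  yb <- seq(yr[1], yr[2], length.out = bins[2] + 1L)
  ix <- pmin(pmax(findInterval(d$x, xb, all.inside = TRUE), 1L), bins[1])
  iy <- pmin(pmax(findInterval(d$y, yb, all.inside = TRUE), 1L), bins[2])
  counts <- matrix(0, bins[1], bins[2])
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  structure(list(density = counts / nrow(d), xbreaks = xb, ybreaks = yb,
                 part = part, n_frames = nrow(d)),
            class = "occupancy_map")
}

#' Distance from a body part to a fixed target
#'
#' Per-frame Euclidean distance from the part to `target_xy` (e.g. the
#' spout or the lever from the box geometry); masked frames yield `NA`.
#'
#' @param track A `pose_track`.
#' @param part Body part name.
#' @param target_xy Numeric `c(x, y)` target coordinates.
#' @return Data frame with `frame`, `time_s`, `distance` (`NA` when
#'   masked).
#' @export
distance_to_target <- function(track, part = "head", target_xy) {
  stopifnot(inherits(track, "pose_track"), length(target_xy) == 2)
  d <- part_frames(track, part, unmasked_only = FALSE)
  dist <- sqrt((d$x - target_xy[1])^2 + (d$y - target_xy[2])^2)
  if (!is.null(d$masked)) dist[d$masked] <- NA_real_
  data.frame(frame = d$frame, time_s = d$time_s, distance = dist)
}

#' Correlate a distance series with calcium activity
#'
#' Interpolates the distance series onto the calcium trace's grid over the
#' overlapping span and computes a correlation coefficient (rank-based by
#' default). Significance is assessed against a circular-time-shift null:
#' the distance series is rotated by random offsets, which preserves the
#' autocorrelation of both series, unlike naive i.i.d. shuffling.
#'
#' @param dist Data frame from [distance_to_target()].
#' @param trace A `norm_trace`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_null Number of circular shifts for the null distribution.
#' @param seed Seed for the shift draws.
#' @return List with `r`, `p_value`, `n`, `method`. A constant input
#'   (undefined correlation) yields `r = NA`, not 0.
#' @export
correlate_with_calcium <- function(dist, trace, method = c("spearman",
                                                           "pearson"),
                                   n_null = 199L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "norm_trace"))
  ok <- !is.na(dist$distance)
  t0 <- max(min(dist$time_s[ok]), min(trace$time_s))
  t1 <- min(max(dist$time_s[ok]), max(trace$time_s))
  sel <- trace$time_s >= t0 & trace$time_s <= t1
  if (sum(sel) < 10)
    stop("fewer than 10 overlapping samples between distance and calcium",
         call. = FALSE)
  d_on_grid <- stats::approx(dist$time_s[ok], dist$distance[ok],
                             xout = trace$time_s[sel])$y
  ca <- trace$dff[sel]
  keep <- !is.na(d_on_grid)
  d_on_grid <- d_on_grid[keep]; ca <- ca[keep]
  n <- length(ca)
  if (stats::sd(d_on_grid) == 0 || stats::sd(ca) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, method = method))
  r <- stats::cor(d_on_grid, ca, method = method)
  set.seed(seed)
  shifts <- sample.int(n - 1L, n_null, replace = TRUE)
  r_null <- vapply(shifts, function(s) {
    stats::cor(c(d_on_grid[(s + 1L):n], d_on_grid[1:s]), ca,
               method = method)
  }, numeric(1))
  p <- (1 + sum(abs(r_null) >= abs(r))) / (n_null + 1)
  list(r = r, p_value = p, n = n, method = method)
}
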