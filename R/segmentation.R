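#' Segmentation parameters
#'
#' Controls for the maximally-stable-extremal-regions (MSER) bead detector
#' and the validity filters. Area bounds default to circle areas at the
#' radius bounds, tying the detector directly to bead geometry.
#'
#' @param delta stability window: region area variation is measured across
#'   +/- `delta` threshold levels.
#' @param min_radius,max_radius accepted bead radius range, pixels.
#' @param min_area,max_area accepted region area range, pixels; default
#'   `pi * min_radius^2` / `pi * max_radius^2`.
#' @param max_variation maximum relative area variation for a region to
#'   count as stable.
#' @param n_levels number of threshold levels swept over the (relative)
#'   intensity range.
#' @param min_shape_score minimum region-area / circle-area ratio.
#' @param edge_margin detections with centres within this many pixels of the
#'   image border are invalidated.
#' @param min_fill minimum bounding-box fill (region area / bounding-box
#'   area) for a region to be a candidate; a disc fills ~0.79 of its box
#'   while two diagonally merged discs fill ~0.5.
#' @param max_aspect maximum bounding-box aspect ratio for a candidate; an
#'   axis-aligned merged doublet has aspect ~2 while a disc has ~1. The two
#'   compactness limits together stop the detector from preferring regions
#'   that merged with a neighbour at low thresholds.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(delta = 2, min_radius = 3, max_radius = 20,
                                min_area = NULL, max_area = NULL,
                                max_variation = 0.5, n_levels = 24,
                                min_shape_score = 0.55, edge_margin = 2,
                                min_fill = 0.65, max_aspect = 1.4) {
  if (min_radius >= max_radius) stop_domain("min_radius must be < max_radius")
  min_area <- min_area %||% (pi * min_radius^2 * 0.5)
  max_area <- max_area %||% (pi * max_radius^2 * 1.5)
  if (min_area >= max_area) stop_domain("min_area must be < max_area")
  if (delta < 1 || n_levels < 2 * delta + 3)
    stop_domain("need n_levels >= 2*delta + 3")
  structure(list(delta = as.integer(delta), min_radius = min_radius,
                 max_radius = max_radius, min_area = min_area,
                 max_area = max_area, max_variation = max_variation,
                 n_levels = as.integer(n_levels),
                 min_shape_score = min_shape_score,
                 edge_margin = edge_margin, min_fill = min_fill,
                 max_aspect = max_aspect),
            class = "segmentation_params")
}

#' Detect candidate bead regions by threshold-stability (MSER)
#'
#' Sweeps `n_levels` intensity thresholds across the image's relative
#' intensity range and labels the bright connected components at each level.
#' Each extremal region is tracked across levels by its seed pixel (the
#' component's brightest pixel); a region is emitted at the level where its
#' relative area variation across `+/- delta` levels is minimal and below
#' `max_variation`, provided its area lies within the configured bounds.
#' Because thresholds are placed relative to the image's own range, the
#' detector is invariant to positive rescaling of the intensities, and it is
#' fully deterministic.
#'
#' @param image intensity matrix (rows = y, columns = x).
#' @param params a [segmentation_params()].
#' @return list of regions, each a list with `pixels` (linear indices into
#'   the image), `area`, `level` and `seed`; empty list for degenerate
#'   (constant or empty) images.
#' @export
detect_regions <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  if (length(image) == 0 || !all(is.finite(image)))
    if (length(image) == 0) return(list()) else stop_domain("image must be finite")
  rng <- range(image)
  if (rng[1] == rng[2]) return(list())
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  L <- params$n_levels
  # ascending thresholds strictly inside (0, 1)
  levels <- seq(1 / (L + 1), L / (L + 1), length.out = L)
  labmaps <- vector("list", L)
  recs <- vector("list", L)
  for (k in seq_len(L)) {
    mask <- norm >= levels[k]
    lab <- EBImage::bwlabel(mask)
    labmaps[[k]] <- lab
    idx <- which(mask)
    if (length(idx) == 0) { recs[[k]] <- NULL; next }
    lv <- lab[idx]
    area <- tabulate(lv)
    # seed = brightest pixel of each component (ties -> lowest index)
    ord <- order(lv, -norm[idx], idx)
    first <- ord[!duplicated(lv[ord])]
    seeds <- idx[first]
    labs <- lv[first]
    # bounding-box fill per component (compactness proxy)
    h <- nrow(image)
    rows_px <- (idx - 1) %% h
    cols_px <- (idx - 1) %/% h
    bw <- tapply(cols_px, lv, function(v) diff(range(v)) + 1)
    bh <- tapply(rows_px, lv, function(v) diff(range(v)) + 1)
    bwl <- as.numeric(bw[as.character(labs)])
    bhl <- as.numeric(bh[as.character(labs)])
    recs[[k]] <- data.frame(level = k, label = labs, seed = seeds,
                            area = area[labs], fill = area[labs] / (bwl * bhl),
                            aspect = pmax(bwl, bhl) / pmin(bwl, bhl))
  }
  track <- do.call(rbind, recs)
  if (is.null(track) || nrow(track) == 0) return(list())
  d <- params$delta
  out <- list()
  track <- track[order(track$seed, track$level), ]
  for (tr in split(track, track$seed)) {
    seed <- tr$seed[1]
    if (nrow(tr) < 2 * d + 1) next
    ks <- tr$level
    area_at <- function(k) tr$area[match(k, ks)]
    cand <- ks[(ks - d) %in% ks & (ks + d) %in% ks]
    if (length(cand) == 0) next
    variation <- (area_at(cand - d) - area_at(cand + d)) / area_at(cand)
    ok <- variation <= params$max_variation &
      area_at(cand) >= params$min_area & area_at(cand) <= params$max_area &
      tr$fill[match(cand, ks)] >= params$min_fill &
      tr$aspect[match(cand, ks)] <= params$max_aspect
    if (!any(ok)) next
    cand <- cand[ok]; variation <- variation[ok]
    kstar <- cand[which.min(variation)]
    lab <- labmaps[[kstar]]
    pix <- which(lab == lab[seed])
    out[[length(out) + 1]] <- list(pixels = pix, area = length(pix),
                                   level = kstar, seed = seed)
  }
  # dedupe regions that resolved to the identical pixel set
  if (length(out) > 1) {
    key <- vapply(out, function(r) paste(r$level, r$pixels[1], r$area), "")
    out <- out[!duplicated(key)]
  }
  out[order(vapply(out, function(r) r$seed, numeric(1)))]
}

# --- minimal enclosing circle (Welzl on the convex hull) ------------------

circle_from2 <- function(p, q) {
  c <- (p + q) / 2
  list(c = c, r = sqrt(sum((p - q)^2)) / 2)
}

circle_from3 <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(dd) < 1e-12) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / dd
  ctr <- c(ux, uy)
  list(c = ctr, r = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ$c)^2)) <= circ$r + tol
}

mec_welzl <- function(pts) {
  n <- nrow(pts)
  circ <- list(c = pts[1, ], r = 0)
  for (i in seq_len(n)) {
    if (in_circle(circ, pts[i, ])) next
    circ <- list(c = pts[i, ], r = 0)
    for (j in seq_len(i - 1)) {
      if (in_circle(circ, pts[j, ])) next
      circ <- circle_from2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1)) {
        if (in_circle(circ, pts[k, ])) next
        c3 <- circle_from3(pts[i, ], pts[j, ], pts[k, ])
        if (!is.null(c3)) circ <- c3
      }
    }
  }
  circ
}

#' Fit the minimal enclosing circle of a pixel region
#'
#' Returns the smallest circle containing all pixel centres of the region —
#' the circle that defines the outer boundary of a detected bead. Image
#' coordinates are 0-based with x = column, y = row and pixel centres at
#' integers. A single pixel yields radius 0.5 by convention; degenerate
#' (collinear) regions are flagged and fall back to the half-diagonal of the
#' bounding box.
#'
#' @param region region as returned by [detect_regions()], or a two-column
#'   matrix/data frame of (x, y) pixel coordinates.
#' @param dim image dimensions `c(nrow, ncol)`; required when `region` is a
#'   list of linear pixel indices.
#' @details The circle is computed over pixel centres and then grown by half
#'   a pixel so that it encloses the full extent of the boundary pixels;
#'   this makes a lone pixel a circle of radius 0.5 rather than a point.
#' @return list with `x`, `y`, `radius` and logical `degenerate`.
#' @export
fit_circle <- function(region, dim = NULL) {
  if (is.list(region) && !is.null(region$pixels)) {
    if (is.null(dim)) stop_domain("dim required for index regions")
    idx <- region$pixels
    pts <- cbind(x = (idx - 1) %/% dim[1], y = (idx - 1) %% dim[1])
  } else {
    pts <- as.matrix(region)
    colnames(pts) <- c("x", "y")
  }
  pts <- unique(pts)
  if (nrow(pts) == 1)
    return(list(x = unname(pts[1, 1]), y = unname(pts[1, 2]), radius = 0.5,
                degenerate = FALSE))
  hull <- if (nrow(pts) > 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  circ <- mec_welzl(hull)
  degenerate <- FALSE
  if (nrow(pts) >= 3) {
    # collinear region: all hull points within numerical tolerance of a line
    v <- hull[2, ] - hull[1, ]
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      d <- abs((hull[, 1] - hull[1, 1]) * v[2] - (hull[, 2] - hull[1, 2]) * v[1]) / nv
      if (all(d < 1e-9)) {
        degenerate <- TRUE
        bb <- c(diff(range(pts[, 1])), diff(range(pts[, 2])))
        circ <- list(c = c(mean(range(pts[, 1])), mean(range(pts[, 2]))),
                     r = sqrt(sum(bb^2)) / 2)
      }
    }
  }
  list(x = unname(circ$c[1]), y = unname(circ$c[2]),
       radius = unname(circ$r) + 0.5, degenerate = degenerate)
}

#' Representative bead intensity from the spherical fluorescence model
#'
#' A uniformly fluorescent sphere projects to the chord-length profile
#' `I(r) = A * sqrt(1 - (r/R)^2) + background`. The amplitude `A` (peak
#' intensity above background) is estimated by least squares over the pixels
#' inside the circle, with the local background taken as the median
#' intensity in the annulus `r in [1.1 R, 1.5 R]`. If the annulus falls
#' entirely outside the image the global median is used and the result is
#' flagged.
#'
#' @param image intensity matrix.
#' @param circle list with `x`, `y`, `radius` (e.g. from [fit_circle()]).
#' @return list with `intensity` (A), `background`, and `background_global`
#'   flag.
#' @export
representative_intensity <- function(image, circle) {
  h <- nrow(image); w <- ncol(image)
  x <- circle$x; y <- circle$y; R <- circle$radius
  if (R <= 0) stop_domain("circle radius must be > 0")
  Rout <- 1.5 * R
  c0 <- max(1L, floor(x - Rout) + 1L); c1 <- min(w, ceiling(x + Rout) + 1L)
  r0 <- max(1L, floor(y - Rout) + 1L); r1 <- min(h, ceiling(y + Rout) + 1L)
  cols <- c0:c1; rows <- r0:r1
  d2 <- outer(((rows - 1) - y)^2, ((cols - 1) - x)^2, `+`)
  patch <- image[rows, cols, drop = FALSE]
  rr <- sqrt(d2)
  ann <- rr >= 1.1 * R & rr <= 1.5 * R
  flag <- FALSE
  if (sum(ann) < 8) {
    bg <- stats::median(image)
    flag <- TRUE
  } else bg <- stats::median(patch[ann])
  inside <- rr < R
  wgt <- sqrt(pmax(1 - (rr[inside] / R)^2, 0))
  A <- sum(wgt * (patch[inside] - bg)) / sum(wgt^2)
  list(intensity = A, background = bg, background_global = flag)
}

# area of the intersection of two circles
circle_overlap_area <- function(x1, y1, r1, x2, y2, r2) {
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

#' Apply validity filters to bead detections
#'
#' Marks each detection valid or invalid with a single primary reason, in
#' this priority order: `size` (radius outside the configured bounds),
#' `shape` (region area / circle area below the threshold — rejects
#' eccentric optical artifacts), `edge` (centre within the edge margin of
#' the image border), `overlap` (circle overlaps an already accepted circle
#' by more than 50% of the smaller circle's area; the larger region is
#' kept).
#'
#' @param detections data frame with columns `x`, `y`, `radius`, `area`,
#'   `shape_score` (as produced by [segment_well()]).
#' @param params a [segmentation_params()].
#' @param img_dim image dimensions `c(nrow, ncol)` for the edge filter.
#' @return the data frame with logical `valid` and character `reason`
#'   columns (`reason` is `""` for valid detections).
#' @export
apply_validity_filters <- function(detections, params, img_dim = NULL) {
  n <- nrow(detections)
  valid <- rep(TRUE, n); reason <- rep("", n)
  bad_size <- detections$radius < params$min_radius |
              detections$radius > params$max_radius
  valid[bad_size] <- FALSE; reason[bad_size] <- "size"
  bad_shape <- valid & detections$shape_score < params$min_shape_score
  valid[bad_shape] <- FALSE; reason[bad_shape] <- "shape"
  if (!is.null(img_dim)) {
    m <- params$edge_margin
    bad_edge <- valid & (detections$x < m | detections$y < m |
                         detections$x > img_dim[2] - 1 - m |
                         detections$y > img_dim[1] - 1 - m)
    valid[bad_edge] <- FALSE; reason[bad_edge] <- "edge"
  }
  # overlap: consider detections in decreasing region-area order so the
  # larger region wins doublet conflicts
  ord <- order(-detections$area)
  xs <- detections$x; ys <- detections$y; rs <- detections$radius
  accepted <- integer(0)
  for (i in ord) {
    if (!valid[i]) next
    clash <- FALSE
    if (length(accepted)) {
      # only circles whose centres are closer than the radius sum can overlap
      d2 <- (xs[accepted] - xs[i])^2 + (ys[accepted] - ys[i])^2
      for (j in accepted[d2 < (rs[accepted] + rs[i])^2]) {
        ov <- circle_overlap_area(xs[i], ys[i], rs[i], xs[j], ys[j], rs[j])
        if (ov > 0.5 * pi * min(rs[i], rs[j])^2) { clash <- TRUE; break }
      }
    }
    if (clash) { valid[i] <- FALSE; reason[i] <- "overlap" }
    else accepted <- c(accepted, i)
  }
  detections$valid <- valid
  detections$reason <- reason
  detections
}

#' Segment one well image into bead detections
#'
#' Runs the full image-analysis step: MSER region detection on the
#' bead-marker channel, minimal-enclosing-circle fitting, spherical-model
#' representative intensity on both channels, shape scoring and validity
#' filtering. Bead detection uses the marker channel because every bead —
#' PCR-positive or not — fluoresces there; the detection-channel intensity
#' is then measured inside the same circles.
#'
#' @param marker marker-channel intensity matrix or image file path.
#' @param detect optional detection-channel matrix or path (same geometry).
#' @param params a [segmentation_params()].
#' @return data frame with one row per detection: `bead_id`, `x`, `y`,
#'   `radius`, `area`, `shape_score`, `intensity_marker`, `intensity_detect`
#'   (NA if no detection channel), `valid`, `reason`.
#' @export
segment_well <- function(marker, detect = NULL, params = segmentation_params()) {
  if (is.character(marker)) marker <- read_well_image(marker)
  if (is.character(detect)) detect <- read_well_image(detect)
  regions <- detect_regions(marker, params)
  n <- length(regions)
  empty <- data.frame(bead_id = integer(0), x = numeric(0), y = numeric(0),
                      radius = numeric(0), area = numeric(0),
                      shape_score = numeric(0), intensity_marker = numeric(0),
                      intensity_detect = numeric(0), valid = logical(0),
                      reason = character(0))
  if (n == 0) return(empty)
  dims <- dim(marker)
  rows <- lapply(seq_len(n), function(i) {
    reg <- regions[[i]]
    circ <- fit_circle(reg, dims)
    im <- representative_intensity(marker, circ)
    id_ <- if (!is.null(detect)) representative_intensity(detect, circ)
    data.frame(bead_id = i, x = circ$x, y = circ$y, radius = circ$radius,
               area = reg$area,
               shape_score = min(reg$area / (pi * circ$radius^2), 1),
               intensity_marker = im$intensity,
               intensity_detect = if (is.null(detect)) NA_real_ else id_$intensity)
  })
  det <- do.call(rbind, rows)
  apply_validity_filters(det, params, img_dim = dims)
}

#' Count beads across well images
#'
#' Counts valid bead detections over one or more well images and, when the
#' input volume they represent is known, converts the count into a bead
#' concentration. This is the bead-count protocol used to characterise each
#' bead batch.
#'
#' @param images a single image (matrix or path) or a list of them; two-
#'   channel renders from [render_well_image()] are accepted (marker used).
#' @param params a [segmentation_params()].
#' @param input_volume total bead suspension volume represented, uL.
#' @return list with `count`, per-image `counts`, and `concentration`
#'   (beads/uL, NA without a volume).
#' @export
count_beads <- function(images, params = segmentation_params(),
                        input_volume = NULL) {
  if (is.matrix(images) || (is.character(images) && length(images) == 1) ||
      (is.list(images) && !is.null(images$marker)))
    images <- list(images)
  if (length(images) < 1) stop_domain("need at least one image")
  counts <- vapply(images, function(im) {
    if (is.list(im) && !is.null(im$marker)) im <- im$marker
    det <- segment_well(im, params = params)
    sum(det$valid)
  }, numeric(1))
  total <- sum(counts)
  list(count = total, counts = counts,
       concentration = if (is.null(input_volume)) NA_real_
                       else total / input_volume)
}
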