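#' Bead population specification
#'
#' Describes a batch of hydrogel nanoreactor beads by count, mean diameter and
#' diameter coefficient of variation. The mean bead volume in nL is derived
#' from the diameter assuming spherical beads. Defaults correspond to the
#' bead batch characterised in the study this package models: 94.8 um mean
#' diameter, CV 0.07, i.e. a 0.446 nL average compartment.
#'
#' @param n_beads number of beads (>= 1 for placement; 0 allowed for blanks).
#' @param mean_diameter mean bead diameter in micrometres.
#' @param diameter_cv coefficient of variation of the diameter (>= 0).
#' @return an object of class `bead_population`.
#' @export
bead_population <- function(n_beads, mean_diameter = 94.8, diameter_cv = 0.07) {
  if (n_beads < 0) stop_domain("n_beads must be >= 0")
  if (mean_diameter <= 0) stop_domain("mean_diameter must be > 0")
  if (diameter_cv < 0) stop_domain("diameter_cv must be >= 0")
  structure(list(
    n_beads = as.integer(n_beads),
    mean_diameter = mean_diameter,
    diameter_cv = diameter_cv,
    mean_volume = sphere_volume(mean_diameter)
  ), class = "bead_population")
}

#' @export
print.bead_population <- function(x, ...) {
  cat(sprintf("bead population: %d beads, diameter %.1f um (CV %.2f), mean volume %.3f nL\n",
              x$n_beads, x$mean_diameter, x$diameter_cv, x$mean_volume))
  invisible(x)
}

#' Image rendering specification
#'
#' Parameters of the synthetic fluorescence well image: geometry, background,
#' pixel noise, and the representative-intensity distributions of
#' PCR-negative and PCR-positive beads in the detection channel. Intensities
#' are on a 16-bit scale (0-65535). Default mode parameters separate the
#' negative and positive populations by roughly five to six pooled standard
#' deviations, emulating the clearly bimodal endpoint fluorescence of
#' amplified bead monolayers.
#'
#' @param width,height image size in pixels.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param background_level mean background intensity.
#' @param noise_sd Gaussian pixel noise standard deviation (>= 0).
#' @param negative_intensity,negative_sd mean/SD of PCR-negative bead
#'   representative intensities (detection channel).
#' @param positive_intensity,positive_sd mean/SD of PCR-positive bead
#'   representative intensities; must exceed `negative_intensity`.
#' @param marker_intensity,marker_sd mean/SD of the bead-marker channel
#'   intensity (all beads fluoresce there).
#' @param artifact_rate expected number of spurious bright blobs per bead.
#' @return an object of class `image_spec`.
#' @export
image_spec <- function(width = 512, height = 512, pixel_size = 9.48,
                       background_level = 500, noise_sd = 20,
                       negative_intensity = 2000, negative_sd = 600,
                       positive_intensity = 8000, positive_sd = 1400,
                       marker_intensity = 6000, marker_sd = 800,
                       artifact_rate = 0) {
  if (width < 1 || height < 1) stop_domain("image dimensions must be >= 1")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (negative_intensity < 0) stop_domain("negative_intensity must be >= 0")
  if (positive_intensity <= negative_intensity)
    stop_domain("positive_intensity must exceed negative_intensity")
  if (artifact_rate < 0) stop_domain("artifact_rate must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, background_level = background_level,
                 noise_sd = noise_sd,
                 negative_intensity = negative_intensity, negative_sd = negative_sd,
                 positive_intensity = positive_intensity, positive_sd = positive_sd,
                 marker_intensity = marker_intensity, marker_sd = marker_sd,
                 artifact_rate = artifact_rate),
            class = "image_spec")
}

#' Draw per-bead target counts
#'
#' Distributes target molecules over beads as independent Poisson draws with
#' mean `lam` targets per bead, the partitioning assumption underlying
#' digital PCR quantification.
#'
#' @param n_beads number of beads.
#' @param lam mean targets per bead (>= 0).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return integer vector of length `n_beads`.
#' @export
draw_target_counts <- function(n_beads, lam, seed = NULL) {
  if (lam < 0) stop_domain("lam must be >= 0")
  if (n_beads == 0) return(integer(0))
  with_seed(seed, stats::rpois(n_beads, lam))
}

# Non-overlapping 2-D bead placement inside a circular well.
#
# Beads self-assemble into a dense monolayer, so placement uses a jittered
# hexagonal lattice: sites with spacing set by the largest bead are laid out
# inside the well, jittered by less than the spacing slack (so circles can
# never overlap), shuffled, and the first n taken. This reaches monolayer
# densities (area fraction ~0.6 at the study geometry) that purely random
# sequential placement cannot.
place_beads <- function(n, radii, well_radius, gap_frac = 0.05) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  rmax <- max(radii)
  s <- 2 * rmax * (1 + gap_frac)       # lattice spacing
  jit <- gap_frac * rmax * 0.9         # jitter half-width, < slack/2
  reach <- well_radius - rmax
  if (reach <= 0) stop_domain("well too small for bead radius")
  sites <- NULL
  for (attempt in 1:6) {
    dy <- s * sqrt(3) / 2
    rows <- seq(-reach, reach, by = dy)
    pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      xs <- seq(-reach + off, reach, by = s)
      cbind(xs, rows[i])
    }))
    keep <- pts[, 1]^2 + pts[, 2]^2 <= (reach - jit * sqrt(2))^2
    sites <- pts[keep, , drop = FALSE]
    if (nrow(sites) >= n) break
    s <- s / (1 + gap_frac)            # tighten towards contact
    gap_frac <- gap_frac / 2
    jit <- gap_frac * rmax * 0.9
  }
  if (nrow(sites) < n)
    stop_domain(sprintf("infeasible packing: %d sites available for %d beads",
                        nrow(sites), n))
  pick <- sample.int(nrow(sites), n)
  x <- sites[pick, 1] + stats::runif(n, -jit, jit)
  y <- sites[pick, 2] + stats::runif(n, -jit, jit)
  data.frame(x = x, y = y)
}

# Additive render of one projected uniform-fluorescence sphere: pixel
# intensity A * sqrt(1 - (r/R)^2) for r < R (chord-length profile), peak A at
# the centre. img is a height x width matrix; x,y are 0-based pixel coords.
render_sphere <- function(img, x, y, R, A) {
  h <- nrow(img); w <- ncol(img)
  c0 <- max(1L, floor(x - R) + 1L); c1 <- min(w, ceiling(x + R) + 1L)
  r0 <- max(1L, floor(y - R) + 1L); r1 <- min(h, ceiling(y + R) + 1L)
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1; rows <- r0:r1
  dx <- (cols - 1) - x; dy <- (rows - 1) - y
  d2 <- outer(dy^2, dx^2, `+`)
  prof <- 1 - d2 / R^2
  prof[prof < 0] <- 0
  img[rows, cols] <- img[rows, cols] + A * sqrt(prof)
  img
}

# Flat elliptical blob used for optical artifacts (flat profile and small /
# eccentric shape so downstream validity filters can reject them).
render_blob <- function(img, x, y, a, b, theta, A) {
  h <- nrow(img); w <- ncol(img)
  R <- max(a, b)
  c0 <- max(1L, floor(x - R) + 1L); c1 <- min(w, ceiling(x + R) + 1L)
  r0 <- max(1L, floor(y - R) + 1L); r1 <- min(h, ceiling(y + R) + 1L)
  if (c0 > c1 || r0 > r1) return(img)
  cols <- c0:c1; rows <- r0:r1
  dx <- (cols - 1) - x; dy <- (rows - 1) - y
  u <- outer(dy * sin(theta), dx * cos(theta), `+`)
  v <- outer(dy * cos(theta), -dx * sin(theta), `+`)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[rows, cols][inside] <- img[rows, cols][inside] + A
  img
}

#' Render a synthetic two-channel well image with ground truth
#'
#' Places beads in a circular well as a non-overlapping monolayer, assigns
#' each bead a Poisson target count, and renders two grayscale channels: a
#' bead-marker channel in which every bead fluoresces, and a detection
#' channel in which PCR-positive beads (>= 1 target) are bright and negative
#' beads dim. Each bead is drawn as a projected uniform sphere whose pixel
#' intensity follows the chord length through the bead, so the peak central
#' pixel equals the bead's representative intensity above background.
#' Optionally adds flat elliptical artifact blobs, Gaussian pixel noise and a
#' constant background.
#'
#' @param pop a [bead_population()]; diameters are drawn log-normal with the
#'   stated mean and CV.
#' @param img an [image_spec()].
#' @param lam mean targets per bead.
#' @param seed integer seed for placement, sizes, counts and noise.
#' @param well_radius_px well radius in pixels; default fills the image.
#' @return list with `marker` and `detect` (height x width intensity
#'   matrices), `truth` (data frame: bead_id, x_px, y_px, radius_px, targets,
#'   positive, edge, marker_intensity, detect_intensity), `artifacts`
#'   (data frame of rendered blob positions) and `manifest` (parameters).
#' @export
render_well_image <- function(pop, img, lam = 0, seed = NULL,
                              well_radius_px = NULL) {
  stopifnot(inherits(pop, "bead_population"), inherits(img, "image_spec"))
  with_seed(seed, {
    w <- img$width; h <- img$height
    wr <- well_radius_px %||% (min(w, h) / 2 - 1)
    n <- pop$n_beads
    mean_r <- pop$mean_diameter / img$pixel_size / 2
    if (n > 0 && pop$diameter_cv > 0) {
      sdlog <- sqrt(log(1 + pop$diameter_cv^2))
      radii <- stats::rlnorm(n, log(mean_r) - sdlog^2 / 2, sdlog)
    } else radii <- rep(mean_r, max(n, 0))
    pos <- place_beads(n, radii, wr)
    # centre well in image, 0-based pixel coordinates
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    x <- pos$x + cx; y <- pos$y + cy
    targets <- draw_target_counts(n, lam)
    positive <- targets >= 1L
    marker_A <- pmax(stats::rnorm(n, img$marker_intensity, img$marker_sd), 0)
    detect_A <- ifelse(positive,
                       stats::rnorm(n, img$positive_intensity, img$positive_sd),
                       stats::rnorm(n, img$negative_intensity, img$negative_sd))
    detect_A <- pmax(detect_A, 0)
    marker <- matrix(0, h, w); detect <- matrix(0, h, w)
    for (i in seq_len(n)) {
      marker <- render_sphere(marker, x[i], y[i], radii[i], marker_A[i])
      detect <- render_sphere(detect, x[i], y[i], radii[i], detect_A[i])
    }
    # artifacts: small or eccentric flat blobs on the marker channel
    n_art <- if (img$artifact_rate > 0 && n > 0)
      stats::rpois(1, img$artifact_rate * n) else 0L
    artifacts <- data.frame(x = numeric(0), y = numeric(0),
                            a = numeric(0), b = numeric(0))
    if (n_art > 0) {
      th <- stats::runif(n_art, 0, 2 * pi)
      rr <- wr * sqrt(stats::runif(n_art))
      ax <- rr * cos(th) + cx; ay <- rr * sin(th) + cy
      a <- stats::runif(n_art, 0.15, 0.4) * mean_r
      b <- a * stats::runif(n_art, 1, 3)
      ang <- stats::runif(n_art, 0, pi)
      A <- stats::runif(n_art, 0.8, 1.5) * img$marker_intensity
      for (i in seq_len(n_art)) {
        marker <- render_blob(marker, ax[i], ay[i], a[i], b[i], ang[i], A[i])
        detect <- render_blob(detect, ax[i], ay[i], a[i], b[i], ang[i], A[i])
      }
      artifacts <- data.frame(x = ax, y = ay, a = a, b = b)
    }
    marker <- marker + img$background_level
    detect <- detect + img$background_level
    if (img$noise_sd > 0) {
      marker <- marker + matrix(stats::rnorm(h * w, 0, img$noise_sd), h, w)
      detect <- detect + matrix(stats::rnorm(h * w, 0, img$noise_sd), h, w)
    }
    clip <- function(m, ch) {
      if (any(m < 0) || any(m > 65535)) {
        warning(sprintf("%s channel clipped to 16-bit range", ch), call. = FALSE)
        m[m < 0] <- 0; m[m > 65535] <- 65535
      }
      m
    }
    marker <- clip(marker, "marker"); detect <- clip(detect, "detect")
    edge <- (x - radii < 0) | (x + radii > w - 1) |
            (y - radii < 0) | (y + radii > h - 1)
    truth <- data.frame(bead_id = seq_len(n), x_px = x, y_px = y,
                        radius_px = radii, targets = targets,
                        positive = positive, edge = edge,
                        marker_intensity = marker_A,
                        detect_intensity = detect_A)
    list(marker = marker, detect = detect, truth = truth, artifacts = artifacts,
         manifest = list(pop = unclass(pop), img = unclass(img), lam = lam,
                         seed = seed, well_radius_px = wr,
                         n_targets_total = sum(targets),
                         n_positive = sum(positive)))
  })
}

#' Simulate per-bead detection-channel intensities without rendering images
#'
#' Fast path for statistical studies: draws Poisson target counts and then
#' representative intensities from the negative/positive modes of an
#' [image_spec()], skipping image synthesis and segmentation.
#'
#' @inheritParams draw_target_counts
#' @param img an [image_spec()] providing the two intensity modes.
#' @return data frame with columns `targets`, `positive`, `intensity`.
#' @export
simulate_well_intensities <- function(n_beads, lam, img = image_spec(),
                                      seed = NULL) {
  with_seed(seed, {
    targets <- draw_target_counts(n_beads, lam)
    positive <- targets >= 1L
    intensity <- ifelse(positive,
                        stats::rnorm(n_beads, img$positive_intensity, img$positive_sd),
                        stats::rnorm(n_beads, img$negative_intensity, img$negative_sd))
    data.frame(targets = targets, positive = positive,
               intensity = pmax(intensity, 0))
  })
}

#' Simulate a Langmuir adsorption kinetics assay
#'
#' Generates a supernatant-depletion time course: bound DNA follows the
#' integrated finite-bath Langmuir rate law (see [langmuir_kinetics()]) with
#' capacity `b_max = n_beads * q_max / volume`, and the free (supernatant)
#' concentration is obtained by mass balance `C0 - bound`. Gaussian noise is
#' added to the supernatant readout. An absorbance column can be emitted
#' using the dsDNA conversion of 50 ng/uL per absorbance unit at 260 nm.
#'
#' @param q_max per-bead binding capacity, ng/bead.
#' @param K_D dissociation constant, ng/uL. Retained for interface parity
#'   with the isotherm simulator; the kinetic trajectory is capacity-limited
#'   and does not involve `K_D`.
#' @param k_a adsorption rate constant, 1/s.
#' @param C0 initial free DNA concentration, ng/uL.
#' @param n_beads bead count in the assay.
#' @param volume assay volume, uL.
#' @param times sampling times in seconds, ascending.
#' @param noise_sd additive Gaussian noise SD on the supernatant readout.
#' @param seed integer seed.
#' @param absorbance also report absorbance (supernatant / 50).
#' @return data frame with columns `time_s`, `bound`, `supernatant`
#'   (and `a260` if requested); attribute `params` records the inputs.
#' @export
simulate_kinetics_assay <- function(q_max, K_D = 0.0011 * 1000, k_a, C0,
                                    n_beads, volume, times,
                                    noise_sd = 0, seed = NULL,
                                    absorbance = FALSE) {
  if (any(c(q_max, K_D, k_a, C0, n_beads, volume) < 0))
    stop_domain("rates and concentrations must be >= 0")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (is.unsorted(times)) stop_domain("times must be sorted ascending")
  b_max <- n_beads * q_max / volume
  bound <- langmuir_kinetics(times, k_a, b_max, C0)
  sup <- C0 - bound
  if (noise_sd > 0)
    sup <- with_seed(seed, pmax(sup + stats::rnorm(length(sup), 0, noise_sd), 0))
  out <- data.frame(time_s = times, bound = C0 - sup, supernatant = sup)
  if (absorbance) out$a260 <- out$supernatant / 50
  attr(out, "params") <- list(q_max = q_max, K_D = K_D, k_a = k_a, C0 = C0,
                              n_beads = n_beads, volume = volume,
                              b_max = b_max, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a Langmuir isotherm assay
#'
#' For each input concentration, solves the equilibrium mass balance between
#' free DNA in solution and DNA bound to `n_beads` beads of capacity `q_max`
#' and dissociation constant `K_D`, then reports the equilibrium free
#' concentration and the bound amount per bead, optionally with relative
#' Gaussian noise on the bound values. The default input ladder is the
#' study's: 10, 63, 127, 199, 297, 401 ng/uL.
#'
#' @param q_max per-bead capacity, ng/bead.
#' @param K_D dissociation constant, ng/uL.
#' @param input_concs input DNA concentrations, ng/uL.
#' @param n_beads,volume assay size (beads, uL).
#' @param rel_noise relative noise SD applied to bound values.
#' @param seed integer seed.
#' @return data frame with columns `input`, `free`, `bound` (ng/bead);
#'   attribute `params` records the inputs.
#' @export
simulate_isotherm_assay <- function(q_max, K_D,
                                    input_concs = c(10, 63, 127, 199, 297, 401),
                                    n_beads = 13900, volume = 100,
                                    rel_noise = 0, seed = NULL) {
  if (any(input_concs < 0)) stop_domain("input_concs must be >= 0")
  if (rel_noise < 0) stop_domain("rel_noise must be >= 0")
  free <- vapply(input_concs, function(C0) {
    if (C0 == 0) return(0)
    fr <- capture_fraction(q_max, K_D, n_beads, C0 * volume, volume)
    attr(fr, "free")
  }, numeric(1))
  bound <- langmuir_isotherm(free, q_max, K_D)
  if (rel_noise > 0)
    bound <- with_seed(seed,
      pmax(bound * (1 + stats::rnorm(length(bound), 0, rel_noise)), 0))
  out <- data.frame(input = input_concs, free = free, bound = bound)
  attr(out, "params") <- list(q_max = q_max, K_D = K_D, n_beads = n_beads,
                              volume = volume, rel_noise = rel_noise,
                              seed = seed)
  out
}

#' Simulate paired concentration measurements from two methods
#'
#' Perturbs true concentrations on the log10 scale to produce paired
#' measurements from a reference method (x) and a test method (y), the test
#' method optionally carrying a constant log10 bias. Used to exercise the
#' method-comparison statistics.
#'
#' @param true_concs true concentrations, copies/uL (> 0).
#' @param bias constant offset added to log10(y).
#' @param sd_x,sd_y log10-scale noise SDs of the two methods.
#' @param seed integer seed.
#' @return data frame with columns `level`, `truth`, `method_x`, `method_y`.
#' @export
simulate_paired_measurements <- function(true_concs, bias = 0,
                                         sd_x = 0.02, sd_y = 0.02,
                                         seed = NULL) {
  if (any(true_concs <= 0)) stop_domain("true_concs must be > 0")
  if (sd_x < 0 || sd_y < 0) stop_domain("noise SDs must be >= 0")
  with_seed(seed, {
    n <- length(true_concs)
    lx <- log10(true_concs) + stats::rnorm(n, 0, sd_x)
    ly <- log10(true_concs) + bias + stats::rnorm(n, 0, sd_y)
    data.frame(level = paste0("V", seq_len(n)), truth = true_concs,
               method_x = 10^lx, method_y = 10^ly)
  })
}

#' Write a rendered well to disk
#'
#' Writes both channels as 16-bit grayscale TIFF, the ground truth as CSV and
#' the generator manifest as JSON.
#'
#' @param render result of [render_well_image()].
#' @param dir output directory (created if missing).
#' @param basename file name stem.
#' @return invisibly, the named vector of paths written.
#' @export
write_well_image <- function(render, dir, basename = "well") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    marker = file.path(dir, paste0(basename, "_marker.tif")),
    detect = file.path(dir, paste0(basename, "_detect.tif")),
    truth = file.path(dir, paste0(basename, "_truth.csv")),
    manifest = file.path(dir, paste0(basename, "_manifest.json"))
  )
  tiff::writeTIFF(render$marker / 65535, paths["marker"], bits.per.sample = 16)
  tiff::writeTIFF(render$detect / 65535, paths["detect"], bits.per.sample = 16)
  utils::write.csv(render$truth, paths["truth"], row.names = FALSE)
  jsonlite::write_json(render$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a grayscale well image from TIFF or PNG
#'
#' @param path image file path.
#' @return intensity matrix on the 16-bit scale (0-65535).
#' @export
read_well_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop_domain("package 'png' required to read PNG images")
      png::readPNG(path)
    },
    stop_domain("unsupported image format: ", ext)
  )
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * 65535
}
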