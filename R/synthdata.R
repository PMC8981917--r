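#' Constitutive parameters for a synthetic ring specimen
#'
#' Defines a minimal C1 "J-shaped" stress-strain law with an exactly
#' known linear-region slope, used to generate traces with ground truth
#' for testing the analysis pipeline: a quadratic toe region (crimp
#' straightening) joining the linear region continuously in value and
#' slope, linear loading to rupture, and a single-sample load drop at
#' rupture.
#'
#' The toe stress is `E * eps^2 / (2 * toe_strain)` for strains up to
#' `toe_strain`, after which stress rises at slope `linear_modulus`
#' until it reaches `uts`; the implied failure strain is
#' `uts / E + toe_strain / 2`.  If `failure_strain` is supplied it must
#' be consistent with that value.
#'
#' @param linear_modulus Target tangent modulus E, MPa (> 0).
#' @param uts Peak engineering stress at rupture, MPa (> 0, and
#'   > E * toe_strain / 2 so rupture falls beyond the toe).
#' @param toe_strain Strain extent of the toe region (>= 0).
#' @param failure_strain Optional; derived from `uts` when NULL.
#' @param post_peak_drop_fraction Fraction of peak load lost at rupture
#'   (default 0.6; must be >= the 0.40 termination rule to trigger it).
#' @param noise_sd Load noise standard deviation, mN (>= 0).
#' @param drag_amplitude Hydrodynamic drag amplitude, mN (>= 0).
#' @param seed Integer RNG seed.
#' @return Object of class `constitutive_params`.
#' @export
constitutive_params <- function(linear_modulus, uts, toe_strain = 0.05,
                                failure_strain = NULL,
                                post_peak_drop_fraction = 0.6,
                                noise_sd = 0, drag_amplitude = 0,
                                seed = 1L) {
  if (linear_modulus <= 0) stop("linear_modulus must be positive")
  if (uts <= 0) stop("uts must be positive")
  if (toe_strain < 0) stop("toe_strain must be non-negative")
  if (post_peak_drop_fraction < 0 || post_peak_drop_fraction > 1)
    stop("post_peak_drop_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (drag_amplitude < 0) stop("drag_amplitude must be non-negative")
  sigma_toe <- linear_modulus * toe_strain / 2
  if (uts <= sigma_toe)
    stop("uts must exceed the toe-end stress E*toe_strain/2 (rupture within toe)")
  ef <- uts / linear_modulus + toe_strain / 2
  if (!is.null(failure_strain)) {
    if (abs(failure_strain - ef) > 1e-8 * max(1, ef))
      stop(sprintf("failure_strain %.6f inconsistent with uts/E + toe/2 = %.6f",
                   failure_strain, ef))
  }
  if (toe_strain >= ef) stop("toe_strain must be below failure_strain")
  structure(list(linear_modulus = linear_modulus, uts = uts,
                 toe_strain = toe_strain, failure_strain = ef,
                 post_peak_drop_fraction = post_peak_drop_fraction,
                 noise_sd = noise_sd, drag_amplitude = drag_amplitude,
                 seed = as.integer(seed)),
            class = "constitutive_params")
}

# model engineering stress (MPa) at engineering strain eps
model_stress <- function(params, eps) {
  E <- params$linear_modulus
  t <- params$toe_strain
  s <- numeric(length(eps))
  pos <- eps > 0
  if (t > 0) {
    toe <- pos & eps <= t
    s[toe] <- E * eps[toe]^2 / (2 * t)
    lin <- pos & eps > t
    s[lin] <- E * t / 2 + E * (eps[lin] - t)
  } else {
    s[pos] <- E * eps[pos]
  }
  s
}

# smooth monotone drag load (N) as a function of extension (mm),
# saturating at amplitude_mN; e_ref sets how fast drag develops
drag_load <- function(extension, amplitude_mN, e_ref = 0.5) {
  amplitude_mN / 1000 * (1 - exp(-extension / e_ref))
}

#' Generate a synthetic pull-to-failure trace
#'
#' Samples the constitutive model along the protocol's constant-speed
#' crosshead ramp at the acquisition rate.  Before `slack_mm` of
#' extension the specimen carries no tension (only drag and noise);
#' beyond it, load = drag + 2 * A0 * sigma(strain) + noise, where
#' strain is referenced to the tension-onset gauge length.  At the
#' first sample past the model failure strain the specimen load drops
#' by `post_peak_drop_fraction` and holds there for a few samples, so
#' the trace ends in violation of the termination rule.
#'
#' @param params A [constitutive_params()].
#' @param geometry A [specimen_geometry()]; its mean elliptical area is
#'   taken as the physical cross-section A0 (the ring's two limbs give
#'   the factor 2).
#' @param protocol A [test_protocol()].
#' @param slack_mm Extension travelled before the ring engages (default
#'   0.05 mm).
#' @param n_post_rupture Samples held at the post-rupture load level.
#' @return A [tensile_trace()] whose `"ground_truth"` attribute stores
#'   the generating parameters and onset extension.
#' @export
gen_trace <- function(params, geometry, protocol, slack_mm = 0.05,
                      n_post_rupture = 5L) {
  stopifnot(inherits(params, "constitutive_params"),
            inherits(geometry, "specimen_geometry"),
            inherits(protocol, "test_protocol"))
  a0 <- geometry$a0_mean
  if (a0 <= 0) stop("geometry area must be positive")
  if (slack_mm < 0) stop("slack_mm must be non-negative")

  v <- crosshead_speed(protocol)          # mm/s
  dt <- 1 / protocol$sampling_rate
  gauge <- protocol$initial_grip_distance + slack_mm
  # extension at rupture, then a short post-rupture tail
  e_fail <- slack_mm + params$failure_strain * gauge
  n_ramp <- ceiling(e_fail / (v * dt)) + 1L
  n <- n_ramp + as.integer(n_post_rupture)
  tm <- (seq_len(n) - 1) * dt
  ext <- tm * v
  eps <- pmax(0, ext - slack_mm) / gauge

  sig <- model_stress(params, eps)
  pre <- eps < params$failure_strain
  r <- which(!pre)[1]                      # rupture sample
  peak <- sig[r - 1L]
  sig[r:n] <- (1 - params$post_peak_drop_fraction) * peak

  load <- drag_load(ext, params$drag_amplitude) + 2 * a0 * sig
  if (params$noise_sd > 0) {
    load <- load + withr::with_seed(params$seed,
      stats::rnorm(n, 0, params$noise_sd / 1000))
  }
  tr <- tensile_trace(tm, ext, load,
                      specimen_id = sprintf("synth_seed%d", params$seed))
  attr(tr, "ground_truth") <- list(params = params, slack_mm = slack_mm,
                                   gauge_length = gauge, a0 = a0,
                                   rupture_index = r)
  tr
}

#' Generate a specimen-free drag baseline trace
#'
#' The same protocol ramp with no specimen: load is a smooth monotone
#' saturating function of extension scaled by `drag_amplitude`, plus
#' optional noise.
#'
#' @param protocol A [test_protocol()].
#' @param drag_amplitude mN (>= 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param max_extension_mm Extension range to cover (must span the
#'   specimen traces it will correct).
#' @param noise_sd Load noise sd, mN.
#' @return A baseline [tensile_trace()].
#' @export
gen_drag_baseline <- function(protocol, drag_amplitude, seed = 1L,
                              max_extension_mm = 4, noise_sd = 0) {
  stopifnot(inherits(protocol, "test_protocol"))
  if (drag_amplitude < 0) stop("drag_amplitude must be non-negative")
  v <- crosshead_speed(protocol)
  dt <- 1 / protocol$sampling_rate
  n <- ceiling(max_extension_mm / (v * dt)) + 1L
  tm <- (seq_len(n) - 1) * dt
  ext <- tm * v
  load <- drag_load(ext, drag_amplitude)
  if (noise_sd > 0)
    load <- load + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd / 1000))
  tensile_trace(tm, ext, load, specimen_id = sprintf("baseline_seed%d", seed),
                is_baseline = TRUE)
}

#' Generate a synthetic annulus image
#'
#' Rasterizes a ring of foreground intensity centred in the frame whose
#' radial thickness at polar angle theta is `thickness_fn(theta)`
#' pixels, for testing the morphometry module against known ground
#' truth.
#'
#' @param inner_radius_px Inner (lumen) radius in pixels.
#' @param thickness_fn Either a single number (constant thickness, px)
#'   or a function of angle (radians in `[0, 2*pi)`) returning px.
#' @param image_size Side of the square frame in pixels (default 256).
#' @param seed Seed for pixel noise / speckles.
#' @param fg,bg Foreground and background intensities in `[0, 1]`.
#' @param noise_sd Additive Gaussian pixel noise sd.
#' @param n_speckles Number of small (2 px radius) foreground speckles
#'   scattered outside the ring, to exercise segmentation filtering.
#' @return `image_size` x `image_size` numeric matrix in `[0, 1]`; the
#'   `"ground_truth"` attribute records centre, radius and the
#'   thickness function.
#' @export
gen_ring_image <- function(inner_radius_px, thickness_fn, image_size = 256L,
                           seed = 1L, fg = 0.9, bg = 0.1, noise_sd = 0.02,
                           n_speckles = 0L) {
  if (inner_radius_px <= 0) stop("inner_radius_px must be positive")
  tf <- if (is.function(thickness_fn)) thickness_fn
        else { th <- as.numeric(thickness_fn); function(a) rep(th, length(a)) }
  probe <- tf(seq(0, 2 * pi, length.out = 720L))
  if (any(probe <= 0)) stop("thickness_fn must be strictly positive at all angles")
  if (inner_radius_px + max(probe) >= image_size / 2)
    stop("ring exceeds the image frame: inner_radius + max thickness must be < image_size/2")

  cx <- (image_size + 1) / 2
  idx <- seq_len(image_size)
  dx <- matrix(idx - cx, image_size, image_size)        # rows: x
  dy <- t(dx)                                           # cols: y
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  thick <- matrix(tf(as.vector(theta)), image_size, image_size)
  img <- matrix(bg, image_size, image_size)
  img[r >= inner_radius_px & r < inner_radius_px + thick] <- fg

  withr::with_seed(seed, {
    if (n_speckles > 0) {
      # speckles in the background corners, away from the ring
      for (k in seq_len(n_speckles)) {
        repeat {
          px <- stats::runif(1, 3, image_size - 3)
          py <- stats::runif(1, 3, image_size - 3)
          rr <- sqrt((px - cx)^2 + (py - cx)^2)
          if (rr > inner_radius_px + max(probe) + 6 || rr < inner_radius_px - 6) break
        }
        spk <- ((dx - (px - cx))^2 + (dy - (py - cx))^2) <= 4
        img[spk] <- fg
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                          image_size, image_size)
  })
  img[] <- pmin(pmax(img, 0), 1)
  attr(img, "ground_truth") <- list(center = c(cx, cx),
                                    inner_radius_px = inner_radius_px,
                                    thickness_fn = tf)
  img
}

#' Write a grayscale image matrix as 8-bit PNG
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_ring_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Generate a long-format dose-response measurement table
#'
#' Samples `n_per_group` normal values per group with the stated means
#' and SDs, producing the long table the statistics battery consumes.
#'
#' @param group_means Numeric vector of group means.
#' @param group_sds Numeric vector of group SDs (same length).
#' @param n_per_group Specimens per group (>= 3 for downstream tests;
#'   smaller tables are produced but rejected by the statistics module).
#' @param seed Integer seed.
#' @param group_labels Optional labels (default "g1", "g2", ...).
#' @param day Integer day stamp (default 14).
#' @param endpoint Endpoint name (default "mtm_mpa").
#' @return data.frame with columns
#'   `specimen_id, group, day, endpoint, value`.
#' @export
gen_dose_response <- function(group_means, group_sds, n_per_group,
                              seed = 1L, group_labels = NULL,
                              day = 14L, endpoint = "mtm_mpa") {
  k <- length(group_means)
  if (length(group_sds) != k) stop("group_means and group_sds must have equal length")
  if (any(group_sds < 0)) stop("group_sds must be non-negative")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.null(group_labels)) group_labels <- paste0("g", seq_len(k))
  vals <- withr::with_seed(seed, {
    unlist(lapply(seq_len(k), function(i)
      stats::rnorm(n_per_group, group_means[i], group_sds[i])))
  })
  data.frame(
    specimen_id = paste0(rep(group_labels, each = n_per_group), "_",
                         rep(seq_len(n_per_group), k)),
    group = rep(group_labels, each = n_per_group),
    day = as.integer(day),
    endpoint = endpoint,
    value = vals,
    stringsAsFactors = FALSE)
}
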