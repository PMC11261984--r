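# Synthetic tomogram scenes with known ground truth.
#
# The generator emulates what the pipeline needs from a tomogram: a noisy
# 3D volume containing many roughly spherical particles of two (or more)
# distinguishable classes, differing in size and texture frequency, with
# ground-truth centers and voxel masks. It makes no attempt at physical
# cryo-ET realism (no missing wedge, CTF or tilt artifacts).

#' Synthetic scene parameters
#'
#' @param dim volume dimension `c(D, H, W)`.
#' @param classes data frame with one row per particle class: columns
#'   `label`, `count`, `r_min`, `r_max` (voxel radii), `contrast` (peak
#'   intensity above the base level, in noise-sigma units when
#'   `noise_sigma = 1`), `texture_period` (voxels; 0 = untextured) and
#'   `texture_amp` (relative modulation amplitude).
#' @param noise_sigma Gaussian noise standard deviation.
#' @param base_level background density level.
#' @param min_separation minimum pairwise center distance (voxels).
#' @param edge_width width of the particle's soft inner edge: the radial
#'   profile is 1 up to `radius - edge_width` and falls linearly to 0 at
#'   `radius` (so particle support ends exactly at `radius`).
#' @param polarity `"bright"` (particles above background, the default the
#'   mock segmenter expects) or `"dark"`.
#' @return A `scene_params` list.
#' @export
scene_params <- function(dim = c(96L, 96L, 96L),
                         classes = data.frame(
                           label = c("A", "B"),
                           count = c(12L, 8L),
                           r_min = c(6, 10),
                           r_max = c(8, 12),
                           contrast = c(3, 3),
                           texture_period = c(3, 12),
                           texture_amp = c(0.5, 0.5)
                         ),
                         noise_sigma = 1,
                         base_level = 0,
                         min_separation = 24,
                         edge_width = 1.5,
                         polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  structure(list(dim = as.integer(dim), classes = classes,
                 noise_sigma = noise_sigma, base_level = base_level,
                 min_separation = min_separation, edge_width = edge_width,
                 polarity = polarity),
            class = "scene_params")
}

#' Named scene presets
#'
#' `"standard"` is the reference study condition: a 96^3 volume with 12
#' class-A spheres (radius 6-8, fine texture) and 8 class-B spheres (radius
#' 10-12, coarse texture), both at 3-sigma contrast over unit Gaussian
#' noise, minimum center separation 24. `"sparse"` halves the counts;
#' `"noisy"` doubles the noise.
#'
#' @param name preset name.
#' @return A `scene_params`.
#' @export
scene_preset <- function(name = c("standard", "sparse", "noisy")) {
  name <- match.arg(name)
  p <- scene_params()
  if (name == "sparse") p$classes$count <- c(6L, 4L)
  if (name == "noisy") p$noise_sigma <- 2
  p
}

#' Generate a synthetic tomogram scene
#'
#' Particle centers are placed by rejection sampling at integer coordinates
#' (respecting the separation constraint and a boundary margin of the
#' particle radius); each particle adds
#' `contrast * prof(r) * (1 + amp * sin(2*pi*(z+y+x)/period + phase))`
#' to the background, where `prof` is the soft-edged radial profile. The
#' ground-truth mask of a particle is its support `prof > 0`. Uses a private
#' RNG stream: the caller's `.Random.seed` is untouched, and the same
#' `(params, seed)` pair regenerates the volume bit-exactly.
#'
#' @param params a `scene_params`.
#' @param seed integer RNG seed.
#' @param max_attempts placement attempt budget per particle.
#' @return A `synthetic_scene`: list with `tomogram`, `particles` (data frame
#'   `id, class, z, y, x, radius, peak_intensity`, coordinates 1-based),
#'   `masks` (per-particle voxel index vectors into the volume), `snr`
#'   (RMS of the clean particle signal over the realized noise RMS; `Inf`
#'   when noiseless), `params`, `seed`.
#' @export
generate_scene <- function(params, seed = 0L, max_attempts = 2000L) {
  stopifnot(inherits(params, "scene_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  d <- params$dim
  cls <- params$classes
  # sample radii/centers class by class, in table order
  particles <- NULL
  for (ci in seq_len(nrow(cls))) {
    for (j in seq_len(cls$count[ci])) {
      radius <- stats::runif(1, cls$r_min[ci], cls$r_max[ci])
      margin <- ceiling(radius)
      if (any(d - 2 * margin < 1)) {
        stop("volume too small for a particle of radius ", radius,
             call. = FALSE)
      }
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cen <- vapply(d, function(n) sample((margin + 1):(n - margin), 1L),
                      integer(1))
        if (is.null(particles) ||
            all(sqrt((particles$z - cen[1])^2 + (particles$y - cen[2])^2 +
                     (particles$x - cen[3])^2) >= params$min_separation)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("placement budget exhausted: cannot fit ", cls$count[ci],
             " particles of class ", cls$label[ci], " at separation ",
             params$min_separation, " in a ",
             paste(d, collapse = "x"), " volume", call. = FALSE)
      }
      particles <- rbind(particles, data.frame(
        id = if (is.null(particles)) 1L else nrow(particles) + 1L,
        class = cls$label[ci], z = cen[1], y = cen[2], x = cen[3],
        radius = radius, phase = stats::runif(1, 0, 2 * pi),
        texture_period = cls$texture_period[ci],
        texture_amp = cls$texture_amp[ci],
        contrast = cls$contrast[ci]))
    }
  }

  clean <- array(0, d)
  masks <- vector("list", nrow(particles))
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    m <- ceiling(p$radius)
    zr <- (p$z - m):(p$z + m); yr <- (p$y - m):(p$y + m)
    xr <- (p$x - m):(p$x + m)
    dz <- zr - p$z; dy <- yr - p$y; dx <- xr - p$x
    r <- sqrt(outer(outer(dz^2, dy^2, "+"), dx^2, "+"))
    prof <- pmin(pmax((p$radius - r) / params$edge_width, 0), 1)
    sig <- p$contrast * prof
    if (p$texture_period > 0) {
      s <- outer(outer(zr, yr, "+"), xr, "+")
      sig <- sig * (1 + p$texture_amp *
                      sin(2 * pi * s / p$texture_period + p$phase))
    }
    clean[zr, yr, xr] <- clean[zr, yr, xr] + sig
    local_idx <- which(prof > 0, arr.ind = TRUE)
    masks[[i]] <- as.integer(
      (zr[local_idx[, 1]]) +
        (yr[local_idx[, 2]] - 1L) * d[1] +
        (xr[local_idx[, 3]] - 1L) * d[1] * d[2])
  }

  noise <- if (params$noise_sigma > 0)
    array(stats::rnorm(prod(d), 0, params$noise_sigma), d) else array(0, d)
  sign <- if (params$polarity == "bright") 1 else -1
  vox <- params$base_level + sign * clean + noise

  snr <- if (params$noise_sigma > 0)
    sqrt(mean(clean^2)) / sqrt(mean(noise^2)) else Inf

  particles$peak_intensity <- params$base_level + sign * particles$contrast
  structure(list(
    tomogram = tomogram(vox),
    particles = particles[, c("id", "class", "z", "y", "x", "radius",
                              "peak_intensity")],
    masks = masks, snr = snr, params = params, seed = seed
  ), class = "synthetic_scene")
}

# Dense logical volume for one ground-truth particle mask.
scene_mask_volume <- function(scene, i) {
  m <- array(FALSE, scene$params$dim)
  m[scene$masks[[i]]] <- TRUE
  m
}

#' Write a scene's ground truth
#'
#' Writes the particle table as a coordinates CSV (`z,y,x` 0-based, plus
#' `class`, `radius`, `id`) and, optionally, the per-particle masks as a
#' labeled MRC volume (voxel value = particle id, 0 = background).
#'
#' @param scene a `synthetic_scene`.
#' @param path CSV output path.
#' @param labels_path optional labeled-mask MRC output path.
#' @export
write_truth <- function(scene, path, labels_path = NULL) {
  df <- scene$particles
  out <- data.frame(z = df$z - 1L, y = df$y - 1L, x = df$x - 1L,
                    class = df$class, radius = df$radius, id = df$id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path)) {
    lab <- array(0, scene$params$dim)
    for (i in seq_along(scene$masks)) lab[scene$masks[[i]]] <- df$id[i]
    write_mrc_volume(labels_path, lab, mode = 1L)
  }
  invisible(NULL)
}

#' Read a ground-truth coordinates CSV
#'
#' @param path CSV written by [write_truth()] (0-based coordinates).
#' @return Data frame with 1-based `z, y, x` plus any extra columns.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path)
  df$z <- df$z + 1L; df$y <- df$y + 1L; df$x <- df$x + 1L
  df
}
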