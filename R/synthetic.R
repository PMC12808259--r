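#' Generator constants for synthetic scenes
#'
#' All "magic" intensities and texture frequencies of the synthetic scene
#' generator in one place. They encode only ordinal facts about the imaged
#' materials — denim reflects more infrared than visible light, dried blood is
#' lighter than wet blood in IR, residue particles are dark in both modalities
#' — not measured reflectances. Frequencies are in cycles per image.
#'
#' @return Named list of generator constants; pass a modified copy to
#'   [scene_params()] to alter the forward model.
#' @export
scene_defaults <- function() {
  list(
    white_base = 0.85,        # bright cotton, either modality
    white_gradient_amp = 0.05, # smooth illumination falloff
    white_weave_amp = 0.02,   # fine weave periodicity
    white_weave_freq = 180,
    denim_base_ir = 0.55,     # denim is mid-bright in IR ...
    denim_base_vl = 0.30,     # ... but dark to the eye
    denim_twill_amp = 0.15,   # diagonal twill ridges
    denim_twill_freq = 85,
    denim_patch_amp = 0.06,   # coarse wash/shade patches (per component)
    denim_patch_maxfreq = 4,
    denim_gradient_amp = 0.05,
    particle_intensity = c(0.05, 0.15), # dark residue, both modalities
    defect_intensity = 0.02,  # bullet defect, near-black
    blood_vl_wet = 0.10,
    blood_vl_dry = 0.15,
    blood_ir_wet = 0.35,
    blood_ir_dry = 0.55,      # dry > wet in IR
    blood_highlight = 0.95,   # specular flash reflections on wet blood (VL)
    tape_base = c(0.93, 0.91, 0.88),   # pale scanned tape, RGB
    tape_spot = c(0.38, 0.12, 0.45)    # violet lead-reaction spots, RGB
  )
}

#' Parameters of a synthetic ground-truthed scene
#'
#' Describes a simulated trace carrier: fabric texture, a radially dispersed
#' cloud of dark residue particles around a central (optional) bullet defect,
#' and optional blood. Rendering is fully deterministic under `seed`.
#'
#' @param fabric `"WHITE_COTTON"`, `"DENIM"` or `"TAPE"`.
#' @param height,width Image size in pixels.
#' @param n_particles Number of particles to plant, `>= 0`.
#' @param particle_radius_range `c(min, max)` particle radius in pixels,
#'   `min >= 1`.
#' @param dispersion Standard deviation (pixels) of the isotropic bivariate
#'   normal scatter of particle centres around the frame centre; defaults to
#'   a quarter of the smaller image dimension.
#' @param defect_radius Radius (pixels) of the central bullet defect, or
#'   `NULL` for none. Particles never intersect the defect.
#' @param blood `NULL`, or `list(state = "wet"|"dry", coverage = fraction of
#'   the frame in [0, 0.9], droplets = satellite droplet count)`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param allow_overlap If `FALSE` (default) particles are rejection-sampled
#'   to be pairwise disjoint with a 2 px guard band, so ground-truth counts
#'   are exact; `TRUE` permits overlaps to study under-counting.
#' @param seed Integer RNG seed; all stages derive their streams from it.
#' @param constants Generator constants, see [scene_defaults()].
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(fabric = c("WHITE_COTTON", "DENIM", "TAPE"),
                         height = 512, width = 512, n_particles = 0,
                         particle_radius_range = c(1, 3), dispersion = NULL,
                         defect_radius = NULL, blood = NULL, noise_sd = 0.02,
                         allow_overlap = FALSE, seed = 1,
                         constants = scene_defaults()) {
  fabric <- match.arg(fabric)
  if (is.null(dispersion)) dispersion <- min(height, width) / 4
  stopifnot(height >= 8, width >= 8, n_particles >= 0,
            length(particle_radius_range) == 2,
            particle_radius_range[1] >= 1,
            particle_radius_range[2] >= particle_radius_range[1],
            dispersion > 0, noise_sd >= 0)
  if (!is.null(blood)) {
    if (is.null(blood$state) || !blood$state %in% c("wet", "dry")) {
      stop("blood$state must be \"wet\" or \"dry\"", call. = FALSE)
    }
    if (is.null(blood$coverage) || blood$coverage < 0 || blood$coverage > 0.9) {
      stop("blood$coverage must lie in [0, 0.9]: larger coverages produce an
           uninterpretable scene", call. = FALSE)
    }
    if (is.null(blood$droplets)) blood$droplets <- 0L
  }
  structure(
    list(fabric = fabric, height = height, width = width,
         n_particles = as.integer(n_particles),
         particle_radius_range = particle_radius_range,
         dispersion = dispersion, defect_radius = defect_radius,
         blood = blood, noise_sd = noise_sd,
         allow_overlap = isTRUE(allow_overlap), seed = as.integer(seed),
         constants = constants),
    class = "scene_params"
  )
}

# Independent deterministic substream per generation stage; keeps every stage
# reproducible whether called standalone or from simulate_scene(). Restores
# the caller's RNG state on exit.
with_stage_seed <- function(seed, stage, expr) {
  offset <- c(texture = 11L, particles = 23L, blood = 37L, tape = 53L)[[stage]]
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 48271 + offset) %% 2147483629)
  expr
}

default_modality <- function(fabric) {
  switch(fabric, WHITE_COTTON = "VL", DENIM = "IR", TAPE = "TAPE_SCAN")
}

#' Generate a bare fabric texture
#'
#' Renders the background the residue will be planted on. White cotton: bright
#' base with a smooth low-frequency illumination gradient and a fine periodic
#' weave. Denim: mid-bright base (brighter in IR than VL) with coarse
#' low-frequency wash patches and a diagonal twill whose energy sits at a
#' known high spatial frequency, so the band-pass preset provably removes it.
#' Tape: pale near-uniform base. Gaussian pixel noise of `noise_sd` is added
#' and intensities clamped to `[0, 1]`.
#'
#' @param params A [scene_params()].
#' @param modality `"VL"` or `"IR"`; default is the fabric's usual one (VL for
#'   white cotton, IR for denim).
#' @return A [gsr_image()] background.
#' @export
generate_fabric_texture <- function(params, modality = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(modality)) modality <- default_modality(params$fabric)
  k <- params$constants
  h <- params$height; w <- params$width
  rr <- matrix(seq_len(h), h, w) / h
  cc <- matrix(rep(seq_len(w), each = h), h, w) / w
  with_stage_seed(params$seed, "texture", {
    if (params$fabric == "WHITE_COTTON") {
      base <- k$white_base
      grad <- k$white_gradient_amp *
        cos(2 * pi * (sample(1:2, 1) * rr + sample(1:2, 1) * cc) +
              stats::runif(1, 0, 2 * pi))
      f <- k$white_weave_freq
      weave <- k$white_weave_amp *
        (sin(2 * pi * f * cc + stats::runif(1, 0, 2 * pi)) +
           sin(2 * pi * f * rr + stats::runif(1, 0, 2 * pi))) / 2
      pix <- base + grad + weave
    } else if (params$fabric == "DENIM") {
      base <- if (modality == "IR") k$denim_base_ir else k$denim_base_vl
      grad <- k$denim_gradient_amp *
        cos(2 * pi * (rr + cc) + stats::runif(1, 0, 2 * pi))
      patch <- 0
      for (j in 1:3) {
        u <- sample(0:k$denim_patch_maxfreq, 1)
        v <- sample(seq_len(k$denim_patch_maxfreq), 1)
        patch <- patch + k$denim_patch_amp *
          cos(2 * pi * (u * rr + v * cc) + stats::runif(1, 0, 2 * pi))
      }
      f <- k$denim_twill_freq
      twill <- k$denim_twill_amp * sin(2 * pi * f * (rr + cc) +
                                         stats::runif(1, 0, 2 * pi))
      pix <- base + grad + patch + twill
    } else { # TAPE, greyscale view of the pale base
      pix <- matrix(max(k$tape_base), h, w)
    }
    if (params$noise_sd > 0) {
      pix <- pix + stats::rnorm(h * w, 0, params$noise_sd)
    }
    gsr_image(pmin(pmax(pix, 0), 1), modality = modality,
              fabric = if (params$fabric == "TAPE") "TAPE" else params$fabric)
  })
}

disc_offsets <- function(r) {
  d <- floor(r)
  dr <- rep(-d:d, times = 2 * d + 1)
  dc <- rep(-d:d, each = 2 * d + 1)
  keep <- dr^2 + dc^2 <= r^2
  cbind(dr[keep], dc[keep])
}

paint_disc <- function(pix, row, col, r, value) {
  off <- disc_offsets(r)
  rr <- round(row) + off[, 1]
  cc <- round(col) + off[, 2]
  keep <- rr >= 1 & rr <= nrow(pix) & cc >= 1 & cc <= ncol(pix)
  pix[cbind(rr[keep], cc[keep])] <- value
  pix
}

sample_particle_centres <- function(params) {
  n <- params$n_particles
  h <- params$height; w <- params$width
  rmin <- params$particle_radius_range[1]
  rmax <- params$particle_radius_range[2]
  ctr <- c(h, w) / 2
  guard <- 2 # px kept clear between discs so components never touch
  def <- if (is.null(params$defect_radius)) 0 else params$defect_radius
  rows <- cols <- radii <- numeric(n)
  placed <- 0L
  max_prop <- max(2000L, 600L * n)
  prop <- 0L
  while (placed < n && prop < max_prop) {
    prop <- prop + 1L
    r <- stats::runif(1, rmin, rmax)
    y <- stats::rnorm(1, ctr[1], params$dispersion)
    x <- stats::rnorm(1, ctr[2], params$dispersion)
    if (y < r + 1 || y > h - r || x < r + 1 || x > w - r) next
    if (def > 0 && sqrt((y - ctr[1])^2 + (x - ctr[2])^2) < def + r + guard) next
    if (!params$allow_overlap && placed > 0L) {
      i <- seq_len(placed)
      if (any((rows[i] - y)^2 + (cols[i] - x)^2 <
                (radii[i] + r + guard)^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- y; cols[placed] <- x; radii[placed] <- r
  }
  if (placed < n) {
    stop(sprintf(
      "could only place %d of %d non-overlapping particles; reduce n_particles or increase dispersion/frame size",
      placed, n), call. = FALSE)
  }
  tibble::tibble(row = rows, col = cols, radius = radii)
}

#' Plant dark residue particles on a background
#'
#' Particle centres are drawn from an isotropic bivariate normal of scale
#' `dispersion` around the frame centre (the entry site), rejection-sampled to
#' the frame, away from the defect, and (by default) to pairwise non-overlap.
#' Each particle darkens a disc to an intensity drawn from the generator's
#' particle range.
#'
#' @param bg A [gsr_image()] background from [generate_fabric_texture()].
#' @param params The same [scene_params()] used for the background.
#' @return List of `image` (a `gsr_image`) and `truth` (a `scene_truth`:
#'   particle table with `row`, `col`, `radius`, `intensity`; logical `mask`;
#'   `defect_mask`; `blood_mask`).
#' @export
plant_particles <- function(bg, params) {
  stopifnot(inherits(bg, "gsr_image"), inherits(params, "scene_params"))
  k <- params$constants
  h <- bg$height; w <- bg$width
  pix <- bg$pixels
  mask <- matrix(FALSE, h, w)
  defect_mask <- matrix(FALSE, h, w)
  if (!is.null(params$defect_radius)) {
    defect_mask <- paint_disc(defect_mask, h / 2, w / 2,
                              params$defect_radius, TRUE)
    pix[defect_mask] <- k$defect_intensity
  }
  with_stage_seed(params$seed, "particles", {
    if (params$n_particles > 0L) {
      tab <- sample_particle_centres(params)
      tab$intensity <- stats::runif(params$n_particles,
                                    k$particle_intensity[1],
                                    k$particle_intensity[2])
    } else {
      tab <- tibble::tibble(row = numeric(), col = numeric(),
                            radius = numeric(), intensity = numeric())
    }
    for (i in seq_len(nrow(tab))) {
      pix <- paint_disc(pix, tab$row[i], tab$col[i], tab$radius[i],
                        tab$intensity[i])
      mask <- paint_disc(mask, tab$row[i], tab$col[i], tab$radius[i], TRUE)
    }
    mask <- mask & !defect_mask
    truth <- structure(
      list(particles = tab, mask = mask, defect_mask = defect_mask,
           blood_mask = matrix(FALSE, h, w)),
      class = "scene_truth"
    )
    list(image = gsr_image(pix, l_pixel = bg$l_pixel, modality = bg$modality,
                           fabric = bg$fabric),
         truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d particles, %d truth px, blood px = %d\n",
              nrow(x$particles), sum(x$mask), sum(x$blood_mask)))
  invisible(x)
}

#' Overlay blood on a scene
#'
#' Renders an irregular central bloodstain (accreted overlapping discs along a
#' random walk) plus satellite droplets. The rendered darkness depends on
#' modality and state: in visible light blood is near-black whether wet or dry
#' (wet additionally carries sparse specular flash highlights); in infrared
#' blood is distinctly lighter, and dried blood lighter than wet. Residue
#' particles are left untouched so they remain visible on top of the stain.
#'
#' @param img A [gsr_image()] scene.
#' @param truth The scene's `scene_truth` (particle pixels are preserved).
#' @param params A [scene_params()] whose `blood` element is non-`NULL`.
#' @return List of `image` and updated `truth` (with `blood_mask` filled).
#' @export
add_blood <- function(img, truth, params) {
  stopifnot(inherits(img, "gsr_image"), inherits(truth, "scene_truth"),
            inherits(params, "scene_params"))
  bl <- params$blood
  if (is.null(bl) || bl$coverage == 0) return(list(image = img, truth = truth))
  k <- params$constants
  h <- img$height; w <- img$width
  lvl <- if (img$modality == "IR") {
    if (bl$state == "dry") k$blood_ir_dry else k$blood_ir_wet
  } else {
    if (bl$state == "dry") k$blood_vl_dry else k$blood_vl_wet
  }
  with_stage_seed(params$seed, "blood", {
    target <- bl$coverage * h * w
    bmask <- matrix(FALSE, h, w)
    pos <- c(h / 2 + stats::rnorm(1, 0, h / 10),
             w / 2 + stats::rnorm(1, 0, w / 10))
    guard_iter <- 0L
    while (sum(bmask) < target && guard_iter < 100000L) {
      guard_iter <- guard_iter + 1L
      r <- stats::runif(1, min(h, w) / 40, min(h, w) / 12)
      bmask <- paint_disc(bmask, pos[1], pos[2], r, TRUE)
      step <- r * 0.8
      pos <- pmin(pmax(pos + stats::rnorm(2, 0, step), 1), c(h, w))
    }
    # satellite droplets
    for (i in seq_len(bl$droplets)) {
      bmask <- paint_disc(bmask,
                          pos[1] + stats::rnorm(1, 0, h / 6),
                          pos[2] + stats::rnorm(1, 0, w / 6),
                          stats::runif(1, 1, 3), TRUE)
    }
    pix <- img$pixels
    paintable <- bmask & !truth$mask & !truth$defect_mask
    pix[paintable] <- pmin(pmax(
      lvl + stats::rnorm(sum(paintable), 0, params$noise_sd / 2), 0), 1)
    if (img$modality == "VL" && bl$state == "wet" && bl$droplets > 0) {
      idx <- which(paintable)
      hi <- sample(idx, min(length(idx), max(1L, bl$droplets * 3L)))
      pix[hi] <- k$blood_highlight
    }
    truth$blood_mask <- bmask
    list(image = gsr_image(pix, l_pixel = img$l_pixel,
                           modality = img$modality, fabric = img$fabric),
         truth = truth)
  })
}

#' Render a complete synthetic scene
#'
#' Texture, optional defect, particles, optional blood, in that order; fully
#' deterministic under `params$seed`.
#'
#' @param params A [scene_params()].
#' @param modality `"VL"`, `"IR"`, or `NULL` for the fabric's default.
#' @return List of `image` ([gsr_image()]), `truth` (`scene_truth`), `params`.
#' @export
simulate_scene <- function(params, modality = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(modality)) modality <- default_modality(params$fabric)
  bg <- generate_fabric_texture(params, modality = modality)
  sc <- plant_particles(bg, params)
  sc <- add_blood(sc$image, sc$truth, params)
  c(sc, list(params = params))
}

#' Render the same scene under visible light and infrared
#'
#' Identical geometry (particle positions, defect, blood shape) rendered
#' twice; only material intensities change with modality. Denim backgrounds
#' come out brighter in IR than in VL, residue particles stay dark in both.
#'
#' @param params A [scene_params()] for a fabric scene.
#' @return List of `vl` and `ir`, each as returned by [simulate_scene()].
#' @export
render_pair <- function(params) {
  list(vl = simulate_scene(params, modality = "VL"),
       ir = simulate_scene(params, modality = "IR"))
}

#' Render a synthetic developed-tape scan
#'
#' A pale near-uniform RGB background with violet lead-reaction spots planted
#' by the same scatter model as fabric particles. Spot colour varies slightly
#' per spot; a global hue rotation of the scan leaves the HSV value channel —
#' and therefore the tape pipeline's counts — unchanged.
#'
#' @param params A [scene_params()] with `fabric = "TAPE"`.
#' @return List of `image` ([gsr_rgb()]), `truth` (`scene_truth`), `params`.
#' @export
simulate_tape_scan <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (params$fabric != "TAPE") {
    stop("simulate_tape_scan() needs fabric = \"TAPE\"", call. = FALSE)
  }
  k <- params$constants
  h <- params$height; w <- params$width
  with_stage_seed(params$seed, "tape", {
    pix <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      pix[, , ch] <- k$tape_base[ch] + stats::rnorm(h * w, 0, params$noise_sd)
    }
    mask <- matrix(FALSE, h, w)
    if (params$n_particles > 0L) {
      tab <- sample_particle_centres(params)
      tab$intensity <- rep(max(k$tape_spot), nrow(tab))
      for (i in seq_len(nrow(tab))) {
        jit <- stats::runif(1, -0.05, 0.05)
        for (ch in 1:3) {
          pix[, , ch] <- paint_disc(pix[, , ch], tab$row[i], tab$col[i],
                                    tab$radius[i],
                                    min(max(k$tape_spot[ch] + jit, 0), 1))
        }
        mask <- paint_disc(mask, tab$row[i], tab$col[i], tab$radius[i], TRUE)
      }
    } else {
      tab <- tibble::tibble(row = numeric(), col = numeric(),
                            radius = numeric(), intensity = numeric())
    }
    truth <- structure(
      list(particles = tab, mask = mask,
           defect_mask = matrix(FALSE, h, w),
           blood_mask = matrix(FALSE, h, w)),
      class = "scene_truth"
    )
    list(image = gsr_rgb(pmin(pmax(pix, 0), 1)), truth = truth,
         params = params)
  })
}
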