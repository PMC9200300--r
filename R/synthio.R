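#' Specify one synthetic MP object
#'
#' Three shape archetypes mirror the circularity classes used in MP
#' morphometry: `particle` (near-circular ellipse), `fragment` (irregular
#' perturbed polygon) and `fiber` (thin thickened random-walk polyline).
#'
#' @param archetype `"particle"`, `"fragment"` or `"fiber"`.
#' @param center Length-2 numeric `(row, col)` in pixels.
#' @param size Characteristic length in px (diameter for particles/fragments,
#'   path length for fibers).
#' @param orientation Orientation in radians.
#' @param brightness 8-bit peak intensity of the object.
#' @param irregularity Shape perturbation in `[0, 1]` (fragments: radial
#'   vertex jitter; fibers: walk curvature).
#' @return An `object_spec` list.
#' @export
object_spec <- function(archetype = c("particle", "fragment", "fiber"),
                        center, size, orientation = 0, brightness = 230,
                        irregularity = 0.5) {
  archetype <- match.arg(archetype)
  stopifnot(length(center) == 2L, size >= 1, brightness >= 0, brightness <= 255,
            irregularity >= 0, irregularity <= 1)
  structure(list(archetype = archetype, center = as.numeric(center),
                 size = as.numeric(size), orientation = as.numeric(orientation),
                 brightness = as.numeric(brightness),
                 irregularity = as.numeric(irregularity)),
            class = "object_spec")
}

#' Specify a synthetic fluorescence scene
#'
#' A scene is a dark noisy background carrying bright fluorescent objects.
#' Two deliberate imaging artefacts emulate the failure modes of global
#' thresholding: a Gaussian halo around bright objects is added to the
#' *image only* (never the mask), baiting false positives, and a fraction of
#' objects get a darkened core inside the mask footprint, baiting false
#' negatives.
#'
#' @param canvas Length-2 `(h, w)` in pixels.
#' @param objects List of [object_spec()]s.
#' @param background_level Mean background intensity (8-bit).
#' @param background_noise_sd Gaussian background noise SD (intensity units).
#' @param halo_strength Halo peak as a fraction of object brightness, in
#'   `[0, 1]`; 0 disables halos.
#' @param dark_core_fraction Fraction of objects rendered with a dark core,
#'   in `[0, 1]`.
#' @param seed Integer; fully determines the rendered scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(canvas, objects, background_level = 20,
                       background_noise_sd = 6, halo_strength = 0,
                       dark_core_fraction = 0, seed = 1L) {
  stopifnot(length(canvas) == 2L, all(canvas >= 1),
            background_level >= 0, background_level <= 255,
            background_noise_sd >= 0,
            halo_strength >= 0, halo_strength <= 1,
            dark_core_fraction >= 0, dark_core_fraction <= 1)
  if (!all(vapply(objects, inherits, TRUE, "object_spec"))) {
    stopf("objects must be a list of object_spec")
  }
  structure(list(canvas = as.integer(canvas), objects = objects,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 halo_strength = halo_strength,
                 dark_core_fraction = dark_core_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# ---- footprint rendering -------------------------------------------------

# Each renderer returns integer pixel indices (row, col matrix) of the
# object footprint on an h x w canvas. Randomized shape details draw from
# the current RNG stream.
render_footprint <- function(obj, h, w) {
  switch(obj$archetype,
    particle = render_particle(obj),
    fragment = render_fragment(obj),
    fiber    = render_fiber(obj)
  )
}

pixel_grid <- function(r0, r1, c0, c1) {
  cbind(row = rep(r0:r1, times = c1 - c0 + 1L),
        col = rep(c0:c1, each = r1 - r0 + 1L))
}

render_particle <- function(obj) {
  a <- obj$size / 2
  # eccentricity < 0.3 => axis ratio > sqrt(1 - 0.09) ~ 0.954
  b <- a * stats::runif(1, 0.955, 1)
  th <- obj$orientation
  r0 <- floor(obj$center[1] - a); r1 <- ceiling(obj$center[1] + a)
  c0 <- floor(obj$center[2] - a); c1 <- ceiling(obj$center[2] + a)
  g <- pixel_grid(r0, r1, c0, c1)
  dy <- g[, 1] - obj$center[1]; dx <- g[, 2] - obj$center[2]
  u <- dy * cos(th) + dx * sin(th)
  v <- -dy * sin(th) + dx * cos(th)
  g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
}

# even-odd point-in-polygon, vectorized over points
point_in_poly <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

render_fragment <- function(obj) {
  # perturbed elongated polygon: aspect 3.5-5.5 keeps the measured
  # circularity of mid-sized fragments inside the 0.3-0.6 band
  k <- sample(10:14, 1)
  aspect <- stats::runif(1, 3.5, 5.5)
  a <- obj$size / 2; b <- a / aspect
  ang <- sort(stats::runif(k, 0, 2 * pi))
  jit <- 1 + obj$irregularity * stats::runif(k, -0.35, 0.35)
  ey <- a * sin(ang) * jit; ex <- b * cos(ang) * jit
  th <- obj$orientation
  vy <- obj$center[1] + ey * cos(th) - ex * sin(th)
  vx <- obj$center[2] + ey * sin(th) + ex * cos(th)
  r0 <- floor(min(vy)); r1 <- ceiling(max(vy))
  c0 <- floor(min(vx)); c1 <- ceiling(max(vx))
  g <- pixel_grid(r0, r1, c0, c1)
  g[point_in_poly(g[, 1], g[, 2], vy, vx), , drop = FALSE]
}

render_fiber <- function(obj) {
  len <- obj$size
  width <- if (len < 24) 1 else sample(1:3, 1) # keep thin: circularity < 0.3
  width <- min(width, max(1, floor(len / 12)))
  n_seg <- max(3L, round(len / 4))
  step <- len / n_seg
  th <- obj$orientation
  # centred random walk with persistent heading
  py <- numeric(n_seg + 1L); px <- numeric(n_seg + 1L)
  for (i in seq_len(n_seg)) {
    th <- th + obj$irregularity * stats::rnorm(1, 0, 0.25)
    py[i + 1L] <- py[i] + step * sin(th)
    px[i + 1L] <- px[i] + step * cos(th)
  }
  py <- py - mean(py) + obj$center[1]
  px <- px - mean(px) + obj$center[2]
  hw <- width / 2
  r0 <- floor(min(py) - hw); r1 <- ceiling(max(py) + hw)
  c0 <- floor(min(px) - hw); c1 <- ceiling(max(px) + hw)
  g <- pixel_grid(r0, r1, c0, c1)
  dmin <- rep(Inf, nrow(g))
  for (i in seq_len(n_seg)) {
    dmin <- pmin(dmin, dist_point_segment(g[, 1], g[, 2],
                                          py[i], px[i], py[i + 1L], px[i + 1L]))
  }
  g[dmin <= hw, , drop = FALSE]
}

dist_point_segment <- function(py, px, ay, ax, by, bx) {
  vy <- by - ay; vx <- bx - ax
  L2 <- vy^2 + vx^2
  t <- if (L2 == 0) rep(0, length(py)) else
    pmin(1, pmax(0, ((py - ay) * vy + (px - ax) * vx) / L2))
  sqrt((py - (ay + t * vy))^2 + (px - (ax + t * vx))^2)
}

# ---- scene assembly ------------------------------------------------------

#' Render a synthetic scene
#'
#' Deterministic given `spec$seed`: produces the fluorescence image, the
#' exact ground-truth mask (union of object footprints; halos excluded), and
#' a per-object table.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` ([mp_image()]), `mask` ([mp_mask()]) and
#'   `objects` (data.frame: index, archetype, center, size, brightness,
#'   area_px, dark_core).
#' @examples
#' sc <- generate_scene(scene_spec(c(48, 48), list(
#'   object_spec("particle", c(24, 24), 10)), seed = 7))
#' sum(sc$mask) == sc$objects$area_px
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$canvas[1]; w <- spec$canvas[2]
  with_seed(spec$seed, {
    img <- matrix(stats::rnorm(h * w, spec$background_level,
                               spec$background_noise_sd), h, w)
    mask <- matrix(0L, h, w)
    n_obj <- length(spec$objects)
    dark <- if (n_obj > 0) stats::runif(n_obj) < spec$dark_core_fraction else logical(0)
    areas <- integer(n_obj)
    for (k in seq_len(n_obj)) {
      obj <- spec$objects[[k]]
      fp <- render_footprint(obj, h, w)
      if (nrow(fp) == 0L) stopf("object %d rendered an empty footprint", k)
      if (min(fp) < 1L || max(fp[, 1]) > h || max(fp[, 2]) > w) {
        stopf("object %d footprint exceeds the %d x %d canvas", k, h, w)
      }
      idx <- fp[, 1] + (fp[, 2] - 1L) * h
      mask[idx] <- 1L
      areas[k] <- nrow(fp)
      img[idx] <- obj$brightness + stats::rnorm(length(idx), 0, 4)
      if (spec$halo_strength > 0) {
        img <- add_halo(img, fp, spec$halo_strength * obj$brightness, h, w)
      }
      if (dark[k]) {
        img <- darken_core(img, fp, spec$background_level, h, w)
      }
    }
    px <- pmax(0, pmin(255, round(img)))
    rgb <- array(0L, c(h, w, 3L))
    # Nile-red-like colour: signal strongest in red, weaker green, faint blue
    rgb[, , 1] <- px
    rgb[, , 2] <- round(px * 0.55)
    rgb[, , 3] <- round(px * 0.25)
    list(image = mp_image(rgb, id = sprintf("synth_seed%d", spec$seed)),
         mask = mp_mask(mask),
         objects = data.frame(
           index = seq_len(n_obj),
           archetype = vapply(spec$objects, `[[`, "", "archetype"),
           center_row = vapply(spec$objects, function(o) o$center[1], 0),
           center_col = vapply(spec$objects, function(o) o$center[2], 0),
           size = vapply(spec$objects, `[[`, 0, "size"),
           brightness = vapply(spec$objects, `[[`, 0, "brightness"),
           area_px = areas,
           dark_core = dark))
  })
}

# Gaussian-profile halo just outside the footprint; image only, never mask.
add_halo <- function(img, fp, peak, h, w, reach = 4L, sigma = 1.6) {
  r0 <- max(1L, min(fp[, 1]) - reach); r1 <- min(h, max(fp[, 1]) + reach)
  c0 <- max(1L, min(fp[, 2]) - reach); c1 <- min(w, max(fp[, 2]) + reach)
  g <- pixel_grid(r0, r1, c0, c1)
  gi <- g[, 1] + (g[, 2] - 1L) * h
  fpi <- fp[, 1] + (fp[, 2] - 1L) * h
  outside <- !(gi %in% fpi)
  if (!any(outside)) return(img)
  go <- g[outside, , drop = FALSE]
  # distance to nearest footprint pixel (brute force on the local box)
  d <- vapply(seq_len(nrow(go)), function(i) {
    sqrt(min((go[i, 1] - fp[, 1])^2 + (go[i, 2] - fp[, 2])^2))
  }, 0)
  add <- peak * exp(-d^2 / (2 * sigma^2))
  ii <- gi[outside]
  img[ii] <- img[ii] + add
  img
}

# Interior pixels far from the boundary drop to near-background level,
# emulating thick MP photographed dark at the centre.
darken_core <- function(img, fp, background_level, h, w) {
  fpi <- fp[, 1] + (fp[, 2] - 1L) * h
  inside <- matrix(FALSE, h, w); inside[fpi] <- TRUE
  # 8-neighbour boundary test
  on_boundary <- vapply(seq_len(nrow(fp)), function(i) {
    r <- fp[i, 1]; c <- fp[i, 2]
    nb <- pixel_grid(max(1L, r - 1L), min(h, r + 1L),
                     max(1L, c - 1L), min(w, c + 1L))
    r == 1L || r == h || c == 1L || c == w ||
      !all(inside[nb[, 1] + (nb[, 2] - 1L) * h])
  }, TRUE)
  bd <- fp[on_boundary, , drop = FALSE]
  if (nrow(bd) == 0L || all(on_boundary)) return(img)
  interior <- fp[!on_boundary, , drop = FALSE]
  d <- vapply(seq_len(nrow(interior)), function(i) {
    sqrt(min((interior[i, 1] - bd[, 1])^2 + (interior[i, 2] - bd[, 2])^2))
  }, 0)
  core <- interior[d >= max(1, max(d) * 0.4), , drop = FALSE]
  if (nrow(core) == 0L) return(img)
  ci <- core[, 1] + (core[, 2] - 1L) * h
  img[ci] <- background_level + stats::rnorm(length(ci), 5, 2)
  img
}

#' Sample a random scene specification
#'
#' Draws object archetypes, centres (rejection-sampled to a minimum
#' separation), sizes and brightnesses, returning a fully determined
#' [scene_spec()].
#'
#' @param canvas `(h, w)` canvas in px.
#' @param n_objects Number of objects.
#' @param archetypes Archetypes to draw from.
#' @param size_range Length-2 size range in px.
#' @param brightness_range Length-2 8-bit peak intensity range.
#' @param min_separation Minimum centre-to-centre clearance beyond the two
#'   object radii, px.
#' @param seed Integer seed (also becomes the scene seed).
#' @param ... Passed to [scene_spec()] (background, halo, dark-core
#'   parameters).
#' @return A [scene_spec()].
#' @export
sample_scene_spec <- function(canvas, n_objects,
                              archetypes = c("particle", "fragment", "fiber"),
                              size_range = c(8, 18),
                              brightness_range = c(200, 250),
                              min_separation = 4, seed = 1L, ...) {
  with_seed(seed, {
    h <- canvas[1]; w <- canvas[2]
    # fibers extend up to ~their doubled path length / 2 from the centre
    margin <- if ("fiber" %in% archetypes) size_range[2] + 5
              else size_range[2] * 0.75 + 2
    if (2 * margin >= min(h, w)) stopf("canvas too small for the size range")
    centers <- matrix(0, 0, 2)
    sizes <- numeric(0)
    archs <- character(0)
    tries <- 0L
    while (nrow(centers) < n_objects) {
      tries <- tries + 1L
      if (tries > 2000L * max(1L, n_objects)) {
        stopf("could not place %d objects with min_separation %.1f", n_objects,
              min_separation)
      }
      ctr <- c(stats::runif(1, margin, h - margin),
               stats::runif(1, margin, w - margin))
      arch <- sample(archetypes, 1)
      sz <- stats::runif(1, size_range[1], size_range[2])
      # a fiber's size is its path length; lengths below ~14 px cannot fall
      # in the fiber circularity band (a true 8x1 bar already measures 0.31)
      if (arch == "fiber") sz <- max(2 * sz, 16)
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
        if (any(dd < (sizes + sz) / 2 + min_separation)) next
      }
      centers <- rbind(centers, ctr)
      sizes <- c(sizes, sz)
      archs <- c(archs, arch)
    }
    objs <- lapply(seq_len(n_objects), function(k) {
      object_spec(archs[k], centers[k, ], sizes[k],
                  orientation = stats::runif(1, 0, pi),
                  brightness = stats::runif(1, brightness_range[1],
                                            brightness_range[2]))
    })
    scene_spec(canvas, objs, seed = seed, ...)
  })
}

#' Generate a synthetic image/mask dataset on disk
#'
#' Writes `img_NNN.png` / `mask_NNN.png` pairs plus a `manifest.csv`
#' (columns: id, n_objects, mp_pixels, seed). Filenames and content are
#' deterministic given `seed`.
#'
#' @param dir Output directory.
#' @param n_images Number of image/mask pairs.
#' @param sampler Function `(seed) -> scene_spec`; defaults to
#'   [sample_scene_spec()] on a 128 x 128 canvas with 1-8 objects.
#' @param seed Master seed; image k uses derived seed `seed * 1000 + k`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param polarity Mask serialization polarity (see [write_mask()]).
#' @return The manifest data.frame, invisibly.
#' @export
generate_dataset <- function(dir, n_images, sampler = NULL, seed = 1L,
                             overwrite = FALSE, polarity = "mp_white") {
  stopifnot(n_images >= 1)
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stopf("output directory %s is not empty (use overwrite = TRUE)", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sampler)) {
    sampler <- function(s) {
      n <- with_seed(s + 500000L, sample(1:8, 1))
      sample_scene_spec(c(128, 128), n, seed = s)
    }
  }
  rows <- vector("list", n_images)
  for (k in seq_len(n_images)) {
    s <- seed * 1000L + k
    sc <- generate_scene(sampler(s))
    id <- sprintf("img_%03d", k)
    write_image(sc$image, file.path(dir, paste0(id, ".png")))
    write_mask(sc$mask, file.path(dir, paste0("mask_", sprintf("%03d", k), ".png")),
               polarity = polarity)
    rows[[k]] <- data.frame(id = id, n_objects = nrow(sc$objects),
                            mp_pixels = sum(sc$mask), seed = s)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
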