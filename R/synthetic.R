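# Synthetic H&E-like nucleus scenes with exact instance ground truth.
#
# The generator emulates hematoxylin-and-eosin histology patches: many
# touching, roughly elliptical nuclei in purple-ish hematoxylin tones over
# a pink-ish textured eosin background. Each nucleus is a rotated ellipse
# whose boundary radius is modulated by a smooth low-frequency harmonic
# perturbation; overlap is resolved by draw order so every pixel belongs to
# at most one instance. Everything is a pure function of (parameters, seed).

default_shape_ranges <- function() {
  list(
    axis_major = c(6, 14),      # semi-axis a, px
    axis_ratio = c(0.55, 0.95), # b = ratio * a
    boundary_amp = c(0.03, 0.1),# radial perturbation amplitude
    intensity = c(0.75, 1.25),  # hematoxylin stain intensity multiplier
    min_sep = 0.8               # centers at least min_sep * (a1 + a2) apart
  )
}

# smooth low-frequency noise field in [-1, 1], coarse grid upsampled
smooth_noise <- function(h, w, coarse = 8L) {
  g <- array(stats::runif(coarse * coarse, -1, 1), dim = c(1, 1, coarse, coarse))
  drop(cpp_resize_fwd(g, as.integer(h), as.integer(w)))
}

#' Generate a synthetic nucleus scene
#'
#' Renders `n_nuclei` elliptical nuclei with smoothly perturbed boundaries
#' in hematoxylin-like tones over a textured eosin-like background.
#' Centers are placed by dart throwing with a minimum-separation rule so
#' nuclei touch but rarely engulf one another; residual overlaps are
#' resolved by draw order (the earlier nucleus keeps contested pixels), so
#' the per-pixel instance map has at most one id per pixel.
#'
#' @param width,height image size in px (>= 64).
#' @param n_nuclei number of nuclei (>= 0).
#' @param shape_ranges parameter ranges, see `default_shape_ranges()`:
#'   `axis_major`, `axis_ratio`, `boundary_amp`, `intensity`, `min_sep`.
#' @param seed integer RNG seed; regeneration with the same arguments is
#'   bit-for-bit identical.
#' @return object of class `synthetic_scene`: list with `image`
#'   (H x W x 3 integer array, 0..255), `label_map` (H x W integer matrix,
#'   0 = background), `nucleus_params` (data.frame: id, cy, cx, a, b, phi,
#'   amp, intensity), `seed`, `width`, `height`.
#' @export
generate_scene <- function(width, height, n_nuclei,
                           shape_ranges = default_shape_ranges(),
                           seed = 1L) {
  assert_that(width >= 64 && height >= 64, "width and height must be >= 64")
  assert_that(n_nuclei >= 0, "n_nuclei must be >= 0")
  sr <- utils::modifyList(default_shape_ranges(), shape_ranges)
  with_seed(seed, {
    # ---- sample nucleus parameters with separation-aware placement
    params <- data.frame(id = integer(0), cy = numeric(0), cx = numeric(0),
                         a = numeric(0), b = numeric(0), phi = numeric(0),
                         amp = numeric(0), intensity = numeric(0))
    if (n_nuclei > 0) {
      for (i in seq_len(n_nuclei)) {
        a <- stats::runif(1, sr$axis_major[1], sr$axis_major[2])
        b <- a * stats::runif(1, sr$axis_ratio[1], sr$axis_ratio[2])
        placed <- FALSE
        for (try in seq_len(50)) {
          cy <- stats::runif(1, 2, height - 3)
          cx <- stats::runif(1, 2, width - 3)
          if (nrow(params) == 0) { placed <- TRUE; break }
          dd <- sqrt((params$cy - cy)^2 + (params$cx - cx)^2)
          if (all(dd >= sr$min_sep * (params$a + a))) { placed <- TRUE; break }
        }
        # keep the last candidate even if crowded: density wins over purity
        params <- rbind(params, data.frame(
          id = i, cy = cy, cx = cx, a = a, b = b,
          phi = stats::runif(1, 0, pi),
          amp = stats::runif(1, sr$boundary_amp[1], sr$boundary_amp[2]),
          intensity = stats::runif(1, sr$intensity[1], sr$intensity[2])))
      }
    }
    # ---- rasterize: first-drawn nucleus keeps contested pixels
    label <- matrix(0L, height, width)
    harmonics <- vector("list", n_nuclei)
    if (n_nuclei > 0) for (i in seq_len(n_nuclei)) {
      p <- params[i, ]
      harmonics[[i]] <- list(ac = stats::rnorm(3), bc = stats::rnorm(3))
      rmax <- max(p$a, p$b) * (1 + 3 * p$amp) + 1
      y0 <- max(1, floor(p$cy - rmax)); y1 <- min(height, ceiling(p$cy + rmax))
      x0 <- max(1, floor(p$cx - rmax)); x1 <- min(width, ceiling(p$cx + rmax))
      ys <- y0:y1; xs <- x0:x1
      dy <- outer(ys - 1 - p$cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - 1 - p$cx)
      u <- (cos(p$phi) * dx + sin(p$phi) * dy) / p$a
      v <- (-sin(p$phi) * dx + cos(p$phi) * dy) / p$b
      rho <- sqrt(u^2 + v^2)
      th <- atan2(v, u)
      pert <- matrix(0, nrow(th), ncol(th))
      for (h in 1:3)
        pert <- pert + harmonics[[i]]$ac[h] * cos((h + 1) * th) +
                       harmonics[[i]]$bc[h] * sin((h + 1) * th)
      inside <- rho <= 1 + p$amp * pert / sqrt(3)
      sub <- label[ys, xs]
      sub[inside & sub == 0L] <- i
      label[ys, xs] <- sub
    }
    # drop fully occluded nuclei (rare): every retained mask is non-empty
    present <- sort(unique(label[label > 0L]))
    if (n_nuclei > 0 && length(present) < n_nuclei) {
      relab <- integer(n_nuclei)
      relab[present] <- seq_along(present)
      label[label > 0L] <- relab[label[label > 0L]]
      params <- params[present, , drop = FALSE]
      params$id <- seq_len(nrow(params))
    }
    # ---- render H&E-like colours
    bg_base <- c(0.93, 0.80, 0.88)   # eosin pink
    nuc_base <- c(0.42, 0.26, 0.58)  # hematoxylin purple
    tex <- smooth_noise(height, width)
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3)
      img[, , ch] <- bg_base[ch] * (1 + 0.05 * tex) +
        matrix(stats::rnorm(height * width, sd = 0.015), height, width)
    if (nrow(params) > 0) {
      ntex <- smooth_noise(height, width, coarse = 16L)
      idx <- which(label > 0L)
      inten <- params$intensity[label[idx]]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- nuc_base[ch] / inten * (1 + 0.08 * ntex[idx])
        img[, , ch] <- plane
      }
    }
    img <- array(as.integer(pmin(255, pmax(0, round(img * 255)))),
                 dim = dim(img))
    structure(list(image = img, label_map = label, nucleus_params = params,
                   seed = seed, width = width, height = height),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %dx%d, %d nuclei>\n", x$width, x$height,
              max(0L, x$label_map)))
  invisible(x)
}

#' Extract the instance masks of a scene
#'
#' @param scene a `synthetic_scene`.
#' @return an [instance_set()] with one full-size binary mask per nucleus.
#' @export
scene_instances <- function(scene) {
  n <- max(0L, scene$label_map)
  masks <- lapply(seq_len(n), function(i) (scene$label_map == i) * 1L)
  instance_set(masks)
}

# ----------------------------------------------------------- augmentation --

#' Photometric augmentation specification
#'
#' Five photometric operators, each applied independently with its own
#' probability and a factor sampled from its range: multiplicative
#' brightness gain, contrast reduction (blend toward the image mean),
#' additive Gaussian noise (sd), impulse (salt-and-pepper) noise (pixel
#' fraction) and Poisson noise in linear intensity (photon scale).
#'
#' @param brightness,contrast,gaussian,impulse,poisson lists with elements
#'   `p` (probability in `[0, 1]`) and `range` (non-degenerate numeric
#'   length 2).
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(
    brightness = list(p = 0.3, range = c(1.1, 1.5)),
    contrast = list(p = 0.3, range = c(0.5, 0.9)),
    gaussian = list(p = 0.3, range = c(0.01, 0.05)),
    impulse = list(p = 0.3, range = c(0.004, 0.02)),
    poisson = list(p = 0.3, range = c(40, 120))) {
  spec <- list(brightness = brightness, contrast = contrast,
               gaussian = gaussian, impulse = impulse, poisson = poisson)
  for (nm in names(spec)) {
    op <- spec[[nm]]
    assert_that(op$p >= 0 && op$p <= 1,
                sprintf("%s probability must lie in [0, 1]", nm))
    assert_that(length(op$range) == 2 && op$range[2] > op$range[1],
                sprintf("%s factor range must be non-degenerate", nm))
  }
  structure(spec, class = "augmentation_spec")
}

#' Apply the photometric augmentation channel to a scene
#'
#' Each operator fires independently with its probability, in the fixed
#' order brightness, contrast, Gaussian, impulse, Poisson. All operators
#' are photometric: the label map and nucleus parameters are returned
#' untouched.
#'
#' @param scene a `synthetic_scene`.
#' @param spec an [augmentation_spec()].
#' @param seed integer RNG seed.
#' @return a new `synthetic_scene` with the transformed image.
#' @export
augment_scene <- function(scene, spec = augmentation_spec(), seed = 1L) {
  assert_that(inherits(spec, "augmentation_spec"),
              "spec must be an augmentation_spec")
  img <- scene$image / 255
  with_seed(seed, {
    if (stats::runif(1) < spec$brightness$p) {
      f <- stats::runif(1, spec$brightness$range[1], spec$brightness$range[2])
      img <- img * f
    }
    if (stats::runif(1) < spec$contrast$p) {
      f <- stats::runif(1, spec$contrast$range[1], spec$contrast$range[2])
      img <- mean(img) + f * (img - mean(img))
    }
    if (stats::runif(1) < spec$gaussian$p) {
      sd_ <- stats::runif(1, spec$gaussian$range[1], spec$gaussian$range[2])
      img <- img + array(stats::rnorm(length(img), sd = sd_), dim = dim(img))
    }
    if (stats::runif(1) < spec$impulse$p) {
      fr <- stats::runif(1, spec$impulse$range[1], spec$impulse$range[2])
      npix <- dim(img)[1] * dim(img)[2]
      hit <- which(stats::runif(npix) < fr)
      salt <- stats::runif(length(hit)) < 0.5
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[hit] <- ifelse(salt, 1, 0)
        img[, , ch] <- plane
      }
    }
    if (stats::runif(1) < spec$poisson$p) {
      q <- stats::runif(1, spec$poisson$range[1], spec$poisson$range[2])
      img <- array(stats::rpois(length(img), lambda = pmax(0, img) * q) / q,
                   dim = dim(img))
    }
  })
  out <- scene
  out$image <- array(as.integer(pmin(255, pmax(0, round(img * 255)))),
                     dim = dim(scene$image))
  out
}

# ----------------------------------------------------------------- tiling --

#' Tile a scene into non-overlapping square patches
#'
#' Splits the scene into (H/patch) x (W/patch) patches in row-major order.
#' Instance masks are clipped to each patch; clipped fragments smaller than
#' `min_fragment` pixels are dropped. The number of foreground pixels lost
#' to dropped fragments is recorded in the `dropped_pixels` attribute of
#' the returned list.
#'
#' @param scene a `synthetic_scene`.
#' @param patch_size patch side in px; must divide both dimensions.
#' @param min_fragment minimum fragment area kept after clipping (px).
#' @return list of `synthetic_scene` patches with attributes
#'   `grid` (rows, cols), `dropped_pixels`; each patch carries `scene_seed`
#'   and `grid_pos` (0-based row, col).
#' @export
tile_scene <- function(scene, patch_size, min_fragment = 10L) {
  H <- scene$height; W <- scene$width
  if (H %% patch_size != 0)
    stop(sprintf("height %d is not divisible by patch_size %d", H, patch_size),
         call. = FALSE)
  if (W %% patch_size != 0)
    stop(sprintf("width %d is not divisible by patch_size %d", W, patch_size),
         call. = FALSE)
  nr <- H %/% patch_size; nc <- W %/% patch_size
  patches <- vector("list", nr * nc)
  dropped <- 0L
  idx <- 1L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    ys <- ((r - 1) * patch_size + 1):(r * patch_size)
    xs <- ((cc - 1) * patch_size + 1):(cc * patch_size)
    lab <- scene$label_map[ys, xs]
    ids <- sort(unique(lab[lab > 0L]))
    keep <- ids[vapply(ids, function(i) sum(lab == i), numeric(1)) >= min_fragment]
    dropped <- dropped + sum(lab > 0L) - sum(lab %in% keep)
    relab <- matrix(0L, patch_size, patch_size)
    for (j in seq_along(keep)) relab[lab == keep[j]] <- j
    pp <- scene$nucleus_params[match(keep, scene$nucleus_params$id), , drop = FALSE]
    if (nrow(pp) > 0) {
      pp$cy <- pp$cy - (r - 1) * patch_size
      pp$cx <- pp$cx - (cc - 1) * patch_size
      pp$id <- seq_len(nrow(pp))
    }
    patches[[idx]] <- structure(
      list(image = scene$image[ys, xs, , drop = FALSE], label_map = relab,
           nucleus_params = pp, seed = scene$seed,
           width = patch_size, height = patch_size,
           scene_seed = scene$seed, grid_pos = c(r - 1L, cc - 1L)),
      class = "synthetic_scene")
    idx <- idx + 1L
  }
  attr(patches, "grid") <- c(rows = nr, cols = nc)
  attr(patches, "dropped_pixels") <- dropped
  patches
}

# --------------------------------------------------------------- manifest --

#' Assign patches to train/val/test splits by source scene
#'
#' Source scenes are shuffled under the seed and assigned to splits by the
#' given counts; every patch inherits its scene's split, so no scene leaks
#' across splits.
#'
#' @param patches list of patches; each must carry a `scene_id` attribute
#'   or element (as produced by [synth_dataset()]), plus `grid_pos`.
#' @param split_scene_counts integer c(train, val, test) scene counts; must
#'   sum to the number of distinct source scenes.
#' @param seed shuffle seed.
#' @return `dataset_manifest`: data.frame with columns `file_name`,
#'   `scene_id`, `row`, `col`, `split`, `patch_index`.
#' @export
make_manifest <- function(patches, split_scene_counts, seed = 1L) {
  scene_ids <- vapply(patches, function(p) p$scene_id %||% p$scene_seed,
                      numeric(1))
  scenes <- sort(unique(scene_ids))
  assert_that(sum(split_scene_counts) == length(scenes),
              sprintf("split counts sum to %d but there are %d source scenes",
                      sum(split_scene_counts), length(scenes)))
  shuffled <- with_seed(seed, sample(scenes))
  split_of <- rep(c("train", "val", "test"), times = split_scene_counts)
  names(split_of) <- as.character(shuffled)
  df <- data.frame(
    file_name = vapply(seq_along(patches), function(i) {
      p <- patches[[i]]
      sprintf("scene%03d_r%dc%d.png", scene_ids[i], p$grid_pos[1], p$grid_pos[2])
    }, character(1)),
    scene_id = scene_ids,
    row = vapply(patches, function(p) p$grid_pos[1], numeric(1)),
    col = vapply(patches, function(p) p$grid_pos[2], numeric(1)),
    split = unname(split_of[as.character(scene_ids)]),
    patch_index = seq_along(patches))
  class(df) <- c("dataset_manifest", class(df))
  df
}

#' Generate a complete synthetic dataset
#'
#' Generates `n_scenes` scenes, tiles each into patches and builds the
#' split manifest (per-scene split assignment).
#'
#' @param n_scenes number of source scenes.
#' @param scene_size scene side in px.
#' @param nuclei_per_scene nuclei per scene.
#' @param patch_size patch side in px.
#' @param splits integer c(train, val, test) scene counts.
#' @param seed master seed; scene i uses seed `seed * 1000 + i`.
#' @param shape_ranges forwarded to [generate_scene()].
#' @return list with `patches` (each carrying `scene_id`) and `manifest`.
#' @export
synth_dataset <- function(n_scenes, scene_size = 1000L, nuclei_per_scene = 400L,
                          patch_size = 250L, splits = c(22L, 2L, 6L),
                          seed = 1L, shape_ranges = default_shape_ranges()) {
  patches <- list()
  for (s in seq_len(n_scenes)) {
    sc <- generate_scene(scene_size, scene_size, nuclei_per_scene,
                         shape_ranges, seed = seed * 1000L + s)
    ps <- tile_scene(sc, patch_size)
    for (p in ps) {
      p$scene_id <- s
      patches[[length(patches) + 1L]] <- p
    }
  }
  manifest <- make_manifest(patches, splits, seed = seed)
  list(patches = patches, manifest = manifest)
}
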