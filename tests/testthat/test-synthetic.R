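# Synthetic scene generation, augmentation channel, tiling and manifests.

test_that("scene generation is deterministic, bounded and exclusive per pixel", {
  s0 <- generate_scene(256, 256, 0, seed = 7)
  expect_equal(nrow(s0$nucleus_params), 0)
  expect_true(all(s0$label_map == 0))
  expect_equal(dim(s0$image), c(256, 256, 3))

  s1 <- generate_scene(256, 256, 30, seed = 7)
  s2 <- generate_scene(256, 256, 30, seed = 7)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$label_map, s2$label_map)
  expect_identical(s1$nucleus_params, s2$nucleus_params)

  s3 <- generate_scene(256, 256, 30, seed = 8)
  expect_false(identical(s1$label_map, s3$label_map))

  inst <- scene_instances(s1)
  areas <- vapply(inst$masks, sum, numeric(1))
  expect_true(all(areas > 0))
  expect_equal(length(inst$masks), nrow(s1$nucleus_params))
  # exclusivity: mask areas sum to the labeled pixel count
  expect_equal(sum(areas), sum(s1$label_map > 0))

  expect_error(generate_scene(32, 256, 5), "width")
  expect_error(generate_scene(256, 256, -1), "n_nuclei")
})

test_that("rendered nucleus areas track the sampled ellipse axes", {
  s <- generate_scene(1000, 1000, 400, seed = 1)
  p <- s$nucleus_params
  areas <- vapply(seq_len(nrow(p)), function(i) sum(s$label_map == i), numeric(1))
  expected <- pi * p$a * p$b
  rel <- abs(areas - expected) / expected
  # boundary perturbation, pixelation and residual occlusion each shave a
  # little area; the ellipse term must still dominate for nearly all nuclei
  expect_gt(mean(rel < 0.35), 0.97)
  expect_lt(median(rel), 0.15)
})

test_that("augmentation is photometric only and reproducible", {
  s <- generate_scene(128, 128, 12, seed = 3)
  noop <- augmentation_spec(
    brightness = list(p = 0, range = c(1.1, 1.5)),
    contrast = list(p = 0, range = c(0.5, 0.9)),
    gaussian = list(p = 0, range = c(0.01, 0.05)),
    impulse = list(p = 0, range = c(0.004, 0.02)),
    poisson = list(p = 0, range = c(40, 120)))
  expect_identical(augment_scene(s, noop, seed = 1)$image, s$image)

  full <- augmentation_spec(
    brightness = list(p = 1, range = c(1.1, 1.5)),
    contrast = list(p = 1, range = c(0.5, 0.9)),
    gaussian = list(p = 1, range = c(0.01, 0.05)),
    impulse = list(p = 1, range = c(0.004, 0.02)),
    poisson = list(p = 1, range = c(40, 120)))
  a1 <- augment_scene(s, full, seed = 5)
  a2 <- augment_scene(s, full, seed = 5)
  expect_identical(a1$image, a2$image)
  expect_false(identical(a1$image, s$image))
  # geometry untouched
  expect_identical(a1$label_map, s$label_map)
  expect_identical(a1$nucleus_params, s$nucleus_params)

  # brightness alone: every pixel is the clipped f-scaled input
  bright <- augmentation_spec(
    brightness = list(p = 1, range = c(1.25, 1.25 + 1e-9)),
    contrast = list(p = 0, range = c(0.5, 0.9)),
    gaussian = list(p = 0, range = c(0.01, 0.05)),
    impulse = list(p = 0, range = c(0.004, 0.02)),
    poisson = list(p = 0, range = c(40, 120)))
  ab <- augment_scene(s, bright, seed = 2)
  manual <- array(as.integer(pmin(255, pmax(0, round(s$image / 255 * 1.25 * 255)))),
                  dim = dim(s$image))
  expect_lte(max(abs(ab$image - manual)), 1L)  # factor is sampled within 1e-9

  expect_error(augmentation_spec(brightness = list(p = 2, range = c(1, 2))),
               "probability")
  expect_error(augmentation_spec(gaussian = list(p = 0.5, range = c(0.05, 0.05))),
               "range")
})

test_that("tiling splits scenes conservatively and validates divisibility", {
  s <- generate_scene(1000, 1000, 80, seed = 2)
  patches <- tile_scene(s, 250)
  expect_length(patches, 16)
  expect_equal(unname(attr(patches, "grid")), c(4, 4))
  # row-major order
  expect_equal(patches[[2]]$grid_pos, c(0L, 1L))
  expect_equal(patches[[5]]$grid_pos, c(1L, 0L))
  # conservation: foreground pixels across patches + dropped = scene total
  fg <- sum(vapply(patches, function(p) sum(p$label_map > 0), numeric(1)))
  expect_equal(fg + attr(patches, "dropped_pixels"), sum(s$label_map > 0))
  # image content is an exact crop
  expect_identical(patches[[1]]$image, s$image[1:250, 1:250, , drop = FALSE])

  s2 <- generate_scene(250, 250, 10, seed = 4)
  one <- tile_scene(s2, 250)
  expect_length(one, 1)
  expect_identical(one[[1]]$image, s2$image)
  expect_identical(one[[1]]$label_map, s2$label_map)

  expect_error(tile_scene(s2, 240), "not divisible")
})

test_that("small clipped fragments are dropped at patch borders", {
  s <- generate_scene(128, 128, 0, seed = 1)
  # a nucleus straddling the tile border at x = 64 with a 2-px sliver
  s$label_map[60:70, 63:64] <- 1L   # 22 px in left tile
  s$label_map[60:61, 65] <- 2L      # synthetic 2-px fragment in right tile
  patches <- tile_scene(s, 64, min_fragment = 10)
  right <- patches[[2]]
  expect_equal(sum(right$label_map > 0), 0)   # sliver dropped
  expect_equal(attr(patches, "dropped_pixels"), 2L)
})

test_that("manifest splits by source scene with the published patch counts", {
  ds <- synth_dataset(n_scenes = 4, scene_size = 128, nuclei_per_scene = 5,
                      patch_size = 64, splits = c(2, 1, 1), seed = 9)
  m <- ds$manifest
  expect_equal(nrow(m), 4 * 4)
  expect_equal(sum(m$split == "train"), 8)
  expect_equal(sum(m$split == "val"), 4)
  expect_equal(sum(m$split == "test"), 4)
  # all patches of a scene share its split
  expect_true(all(tapply(m$split, m$scene_id, function(x) length(unique(x))) == 1))
  # determinism
  m2 <- make_manifest(ds$patches, c(2, 1, 1), seed = 9)
  expect_equal(m$split, m2$split)
  # every patch appears exactly once
  expect_equal(anyDuplicated(m$file_name), 0)
  expect_error(make_manifest(ds$patches, c(3, 1, 1)), "sum")
})
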