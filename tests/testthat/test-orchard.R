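# Synthetic orchard scene generator and augmentation pipeline.

test_that("scene rendering is deterministic with exact ground truth", {
  sp <- scene_spec(image_size = 160, n_fruits = 8, seed = 7)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$boxes, b$truth$boxes)
  expect_identical(a$truth$occluded_fraction, b$truth$occluded_fraction)
  c <- render_scene(scene_spec(image_size = 160, n_fruits = 8, seed = 8))
  expect_false(identical(a$image, c$image))

  expect_equal(dim(a$image), c(160, 160, 3))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_equal(nrow(a$truth$boxes), 8)
  expect_true(all(a$truth$occluded_fraction >= 0 & a$truth$occluded_fraction <= 1))
  # boxes within image and small-object sized (radius_range default < 16 px)
  expect_true(all(a$truth$boxes$cx > 0 & a$truth$boxes$cx < 1))
  expect_true(all(a$truth$boxes$w * 160 < 32))

  # empty scene
  e <- render_scene(scene_spec(image_size = 64, n_fruits = 0, seed = 1))
  expect_equal(nrow(e$truth$boxes), 0)
  expect_error(render_scene(scene_spec(image_size = 32, n_fruits = 500, seed = 1)),
               "infeasible")
})

test_that("unoccluded fruits round-trip through the colorimetric classifier", {
  hits <- 0; total <- 0
  for (s in 1:6) {
    sp <- scene_spec(image_size = 200, n_fruits = 6, occluder_density = 0,
                     cluster_spread = 40, seed = 100 + s)
    sc <- render_scene(sp)
    for (i in seq_len(nrow(sc$truth$boxes))) {
      if (sc$truth$occluded_fraction[i] > 0) next
      got <- classify_box(sc$image, sc$truth$boxes[i, ])
      total <- total + 1
      if (got$class == sc$truth$class[i]) hits <- hits + 1
    }
  }
  expect_gt(total, 20)
  expect_equal(hits, total)   # 100% of unoccluded fruits recover their class
})

test_that("ground-truth density maps peak at fruit centers when kernels are separate", {
  # default sigma_max is 15 px, kernels truncate at 4 sigma; fruits from a
  # scattered scene, keeping only those > 130 px from every neighbour so
  # kernels cannot overlap
  sp <- scene_spec(image_size = 640, n_fruits = 8, occluder_density = 0,
                   cluster_fraction = 0, seed = 17)
  sc <- render_scene(sp)
  den <- generate_density_map(sc$truth$boxes, 640, 640)
  plane <- matrix(den[1, , ], 640, 640)
  ctr <- sc$truth$centers_px
  dmat <- as.matrix(stats::dist(ctr)); diag(dmat) <- Inf
  tested <- 0
  for (i in seq_len(nrow(ctr))) {
    if (min(dmat[i, ]) < 130) next
    tested <- tested + 1
    x0 <- max(1, round(ctr[i, 1]) - 5); x1 <- min(640, round(ctr[i, 1]) + 5)
    y0 <- max(1, round(ctr[i, 2]) - 5); y1 <- min(640, round(ctr[i, 2]) + 5)
    loc <- plane[y0:y1, x0:x1]
    am <- which(loc == max(loc), arr.ind = TRUE)[1, ]
    peak_x <- x0 + am[2] - 1 - 0.5   # pixel center, 0-based coords
    peak_y <- y0 + am[1] - 1 - 0.5
    expect_lt(abs(peak_x - ctr[i, 1]), 1.01)
    expect_lt(abs(peak_y - ctr[i, 2]), 1.01)
  }
  expect_gt(tested, 0)
})

test_that("identity augmentation changes nothing and flips mirror boxes", {
  sp <- scene_spec(image_size = 96, n_fruits = 4, seed = 3)
  sc <- render_scene(sp)
  idn <- augment(sc$image, sc$truth$boxes, identity_policy(), seed = 5)
  expect_equal(idn$image, sc$image, tolerance = 0)
  expect_equal(idn$boxes$cx, sc$truth$boxes$cx, tolerance = 1e-12)

  flip_pol <- augment_policy(hflip = 1, vflip = 0, rotation = c(0, 0), crop = 0,
                             scale = c(1, 1), brightness = c(0, 0),
                             contrast = c(0, 0), hue = c(0, 0), saturation = c(0, 0))
  fl <- augment(sc$image, sc$truth$boxes, flip_pol, seed = 5)
  expect_equal(fl$boxes$cx, 1 - sc$truth$boxes$cx, tolerance = 1e-9)
  expect_equal(fl$boxes$cy, sc$truth$boxes$cy, tolerance = 1e-9)
  expect_equal(fl$image[, 96:1, ], sc$image, tolerance = 0)
})

test_that("rotation by +15 degrees moves box centers per the rotation matrix", {
  img <- array(0.5, c(100, 100, 3))
  boxes <- data.frame(class = 0L, cx = 0.7, cy = 0.4, w = 0.1, h = 0.1)
  rot_pol <- augment_policy(hflip = 0, vflip = 0, rotation = c(15, 15), crop = 0,
                            scale = c(1, 1), brightness = c(0, 0),
                            contrast = c(0, 0), hue = c(0, 0), saturation = c(0, 0))
  out <- augment(img, boxes, rot_pol, seed = 2)
  th <- 15 * pi / 180
  # hand-computed rotation of the center about (0.5, 0.5)
  dx <- 0.7 - 0.5; dy <- 0.4 - 0.5
  exp_cx <- 0.5 + cos(th) * dx - sin(th) * dy
  exp_cy <- 0.5 + sin(th) * dx + cos(th) * dy
  expect_equal(out$boxes$cx, exp_cx, tolerance = 1e-9)
  expect_equal(out$boxes$cy, exp_cy, tolerance = 1e-9)
  # rotated square's axis-aligned hull is enlarged by cos+sin
  expect_equal(out$boxes$w, 0.1 * (cos(th) + sin(th)), tolerance = 1e-9)

  # photometric-only transforms leave boxes untouched
  photo <- augment_policy(hflip = 0, vflip = 0, rotation = c(0, 0), crop = 0,
                          scale = c(1, 1))
  ph <- augment(img, boxes, photo, seed = 9)
  expect_equal(ph$boxes, boxes, tolerance = 1e-12)
})

test_that("write_dataset splits 70/15/15 with disjoint round-tripping files", {
  scenes <- lapply(1:20, function(s) {
    render_scene(scene_spec(image_size = 64, n_fruits = 3, seed = s,
                            radius_range = c(4, 7)))
  })
  out <- file.path(tempdir(), "orchard_ds")
  unlink(out, recursive = TRUE)
  man <- write_dataset(scenes, out)
  expect_equal(nrow(man), 20)
  expect_equal(as.numeric(table(man$split)[c("train", "val", "test")]), c(14, 3, 3))
  expect_true(all(file.exists(man$image)))
  expect_true(all(file.exists(man$labels)))
  expect_true(all(file.exists(man$occlusion)))
  # no stem in two splits
  expect_equal(anyDuplicated(man$stem), 0)
  # labels round-trip to the boxes that produced them
  for (i in c(1, 10, 20)) {
    back <- read_yolo_labels(man$labels[i])
    expect_equal(back$cx, scenes[[i]]$truth$boxes$cx, tolerance = 1e-5)
    expect_equal(back$class, scenes[[i]]$truth$boxes$class)
  }
  # images round-trip losslessly through PNG
  img <- png::readPNG(man$image[1])
  expect_equal(img, scenes[[1]]$image, tolerance = 1 / 255)
  expect_error(write_dataset(list(), out), "empty")
  unlink(out, recursive = TRUE)
})

test_that("the default regime yields the expected occlusion and clustering statistics", {
  # small-n replicate of the regime check (the acceptance suite runs the
  # 200-scene version); default spec at full 640x640 resolution
  fr <- numeric(0); nn15 <- logical(0)
  for (s in 1:15) {
    sc <- render_scene(scene_spec(seed = 9000 + s))
    fr <- c(fr, sc$truth$occluded_fraction)
    dm <- as.matrix(stats::dist(sc$truth$centers_px)); diag(dm) <- Inf
    nn15 <- c(nn15, apply(dm, 1, min) < 15)
  }
  share <- mean(fr > 0.3)
  expect_gt(share, 0.25)
  expect_lt(share, 0.55)
  # a substantial minority of fruits sit in sub-15 px clusters
  expect_gt(mean(nn15), 0.15)
})
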