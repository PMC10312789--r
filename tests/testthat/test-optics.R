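test_that("synthesized PSF planes are normalized and respect the geometry", {
  # degenerate geometry: one lens, one depth, no parallax
  lay1 <- lens_layout(matrix(c(16, 16), 1), 8)
  p1 <- synthesize_psf(lay1, 1, 2, 0, c(32, 32))
  pl <- grid_of(p1)[, , 1]
  expect_equal(sum(pl), 1, tolerance = 1e-6)
  expect_equal(which(pl == max(pl), arr.ind = TRUE)[1, ],
               c(row = 16, col = 16))

  # central depth plane of a multi-lens PSF: spots exactly on the centers
  psf <- tiny_psf(depth = 5)
  central <- grid_of(psf)[, , 3]
  lay <- tiny_layout()
  for (k in 1:3) {
    win <- central[lay$centers[k, 1] + (-2:2), lay$centers[k, 2] + (-2:2)]
    expect_equal(unname(which(win == max(win), arr.ind = TRUE)[1, ]),
                 c(3, 3))
  }

  # every plane sums to one, any configuration
  for (z in 1:5) expect_equal(sum(grid_of(psf)[, , z]), 1, tolerance = 1e-6)

  # centers outside the image are a geometry error
  expect_error(synthesize_psf(lens_layout(matrix(c(40, 10), 1), 8),
                              3, 1, 0, c(32, 32)),
               "geometry")
})

test_that("forward projection is linear and sifts a delta voxel", {
  psf <- tiny_psf()
  zero <- forward_project(array(0, c(16, 16, 6)), psf)
  expect_true(all(zero$data == 0))

  # unit voxel at the volume center reproduces the matching PSF plane
  vol <- array(0, c(32, 32, 6))
  vol[17, 17, 4] <- 1
  img <- forward_project(vol, psf)
  expect_lt(max(abs(img$data - grid_of(psf)[, , 4])), 1e-12)

  # additivity and homogeneity on random 8 x 16 x 16 volumes
  set.seed(2)
  for (rep in 1:3) {
    a <- array(runif(16 * 16 * 6), c(16, 16, 6))
    b <- array(runif(16 * 16 * 6), c(16, 16, 6))
    fa <- forward_project(a, psf)$data
    fb <- forward_project(b, psf)$data
    fab <- forward_project(a + b, psf)$data
    expect_lt(max(abs(fab - fa - fb)), 1e-10)
    f2a <- forward_project(2.5 * a, psf)$data
    expect_lt(max(abs(f2a - 2.5 * fa)), 1e-10)
  }

  expect_error(forward_project(array(0, c(16, 16, 3)), psf), "depth")
})

test_that("lens centers are recovered exactly from a synthetic PSF", {
  centers <- rbind(c(10, 10), c(10, 50), c(30, 30), c(50, 12), c(52, 52))
  lay <- lens_layout(centers, 16)
  psf <- synthesize_psf(lay, 7, 1.8, 0.5, c(64, 64))
  det <- detect_lens_centers(psf, 5, min_separation = 8)
  # same set of centers (detection orders by peak value)
  expect_equal(det$centers[order(det$centers[, 1], det$centers[, 2]), ],
               centers[order(centers[, 1], centers[, 2]), ])

  # single-spot argmax
  one <- synthesize_psf(lens_layout(matrix(c(20, 44), 1), 8), 3, 2, 0,
                        c(64, 64))
  d1 <- detect_lens_centers(one, 1, 4)
  expect_equal(unname(d1$centers[1, ]), c(20, 44))

  # a flat plane has no strict local maxima
  flat <- psf_stack(array(1 / (32 * 32), c(32, 32, 1)))
  expect_error(detect_lens_centers(flat, 1, 4), "detection error")

  # asking for more peaks than exist reports the count found
  expect_error(detect_lens_centers(one, 3, 4), "found 1")
})

test_that("view cropping windows, zero-fills and round-trips", {
  lay <- tiny_layout(crop = 12L)
  zero <- crop_views(lf_image(matrix(0, 32, 32)), lay)
  expect_equal(dim(zero$data), c(12, 12, 3))
  expect_true(all(zero$data == 0))

  # a bright pixel at center k lands at the crop center of view k
  img <- matrix(0, 32, 32)
  img[lay$centers[1, 1], lay$centers[1, 2]] <- 7
  vs <- crop_views(lf_image(img), lay)
  ctr <- 12L %/% 2L + 1L
  expect_equal(vs$data[ctr, ctr, 1], 7)

  # crop then re-embed reproduces the masked image on a
  # non-overlapping layout
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  lay2 <- lens_layout(rbind(c(6, 6), c(6, 26), c(26, 6), c(26, 26)), 8)
  vs2 <- crop_views(lf_image(img), lay2)
  re <- matrix(0, 32, 32)
  mask <- matrix(FALSE, 32, 32)
  half <- 8L %/% 2L
  for (k in 1:4) {
    rs <- lay2$centers[k, 1] - half + 0:7
    cs <- lay2$centers[k, 2] - half + 0:7
    re[rs, cs] <- vs2$data[, , k]
    mask[rs, cs] <- TRUE
  }
  expect_identical(re[mask], img[mask])
  expect_true(all(re[!mask] == 0))

  # out-of-bounds windows zero-fill
  lay3 <- lens_layout(matrix(c(2, 2), 1), 8)
  vs3 <- crop_views(lf_image(img), lay3)
  expect_true(all(vs3$data[1, , 1] == 0))  # rows above the image edge
  expect_equal(dim(vs3$data), c(8, 8, 1))
})
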