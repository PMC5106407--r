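test_that("circular Hough transform recovers a planted bright disc", {
  spec <- synthetic_fundus_spec(height = 600, width = 900, od_radius = 45,
                                macula_dist_dd = 200.5 / 90, seed = 2)
  out <- generate_fundus(spec)
  tr <- out$truth$od
  od <- detect_optic_disc(fsm_filter(extract_green_channel(out$image)))
  err <- sqrt((od$circle$row - tr$circle$row)^2 +
                (od$circle$col - tr$circle$col)^2)
  expect_lte(err, 3)
  expect_lte(abs(od$circle$radius - tr$circle$radius) / tr$circle$radius, 0.1)
  expect_equal(od$dd, 2 * od$circle$radius)
})

test_that("disc detection fails cleanly on a blank image", {
  expect_error(detect_optic_disc(matrix(100, 200, 300)), "no optic disc")
})

test_that("of two planted discs the bright one is returned", {
  img <- matrix(100, 300, 450)
  rr <- row(img) - 1; cc <- col(img) - 1
  img[(rr - 150)^2 + (cc - 120)^2 <= 20^2] <- 30    # dark distractor
  img[(rr - 150)^2 + (cc - 330)^2 <= 20^2] <- 220   # bright disc
  od <- detect_optic_disc(img)
  expect_lte(sqrt((od$circle$row - 150)^2 + (od$circle$col - 330)^2), 3)
})

test_that("vessel segmentation handles blank images and small specks", {
  blank <- matrix(100, 60, 60)
  expect_false(any(segment_vessels(blank)))

  ## isolated 3-px speck, removed by the area rule
  img <- matrix(50, 80, 80)
  img[40, 40:42] <- 200
  expect_false(any(segment_vessels(img, se_radius = 3, min_object = 30)))
  ## and kept when the rule allows it
  expect_true(any(segment_vessels(img, se_radius = 3, min_object = 2)))
})

test_that("vessel segmentation with Otsu is invariant to a constant shift", {
  out <- generate_fundus(synthetic_fundus_spec(seed = 6, noise_density = 0))
  enh <- bpdfhe(fsm_filter(complement(extract_green_channel(out$image))))
  ## rescale into [0, 235] so that the +20 shift is clip-free
  enh <- round(enh * (235 / 255))
  v1 <- segment_vessels(enh)
  v2 <- segment_vessels(enh + 20)
  expect_identical(v1, v2)
})

test_that("planted vessel tree is recovered with Dice overlap >= 0.6", {
  out <- generate_fundus(synthetic_fundus_spec(seed = 3))
  enh <- bpdfhe(fsm_filter(complement(extract_green_channel(out$image))))
  v <- segment_vessels(enh)
  tr <- out$truth$vessels
  dice <- 2 * sum(v & tr) / (sum(v) + sum(tr))
  expect_gte(dice, 0.6)
})

test_that("vessel removal inpaints only the masked pixels", {
  img <- rand_gray(40, 40, seed = 9)
  expect_identical(remove_vessels(img, matrix(FALSE, 40, 40)), img)

  all_mask <- matrix(TRUE, 40, 40)
  sm <- remove_vessels(img, all_mask)
  expect_true(all(abs(dim(sm) == dim(img))))
  expect_gt(sd(img), sd(sm))           # fully smoothed image

  ## single vertical vessel line on a constant background: the filled
  ## values come from clean neighbours only, so the output is constant
  flat <- matrix(100, 50, 50)
  corrupted <- flat; corrupted[, 25] <- 40
  mask <- matrix(FALSE, 50, 50); mask[, 25] <- TRUE
  fixed <- remove_vessels(corrupted, mask, sigma = 4)
  expect_lte(max(abs(fixed - flat)), 1)

  expect_error(remove_vessels(img, matrix(FALSE, 10, 10)), "shape")
})

test_that("geometric macula search honours the 2DD / 37 degree geometry", {
  out <- generate_fundus(synthetic_fundus_spec(seed = 8, noise_density = 0))
  g <- extract_green_channel(out$image)
  od <- out$truth$od
  mac <- locate_macula_geometric(fsm_filter(g), od)
  ## radius definition: 1.3 DD diameter
  expect_equal(mac$circle$radius, 0.65 * od$dd)
  ## fovea planted at exactly 2DD along the horizontal
  err <- sqrt(sum((mac$fovea - out$truth$macula$fovea)^2))
  expect_lte(err, 5)
  ## returned geometry satisfies the search-band invariants
  d <- sqrt((mac$fovea[1] - od$circle$row)^2 +
              (mac$fovea[2] - od$circle$col)^2)
  expect_gte(d, 1.5 * od$dd)
  expect_lte(d, 2.5 * od$dd)
  expect_lte(abs(mac$angle_deg), 37)
})

test_that("a dark distractor outside the 37 degree wedge is rejected", {
  ## flat retina with a dark pit at 10 degrees (true macula) and a much
  ## darker one at 55 degrees above the horizontal (outside the wedge)
  h <- 240; w <- 360
  img <- matrix(150, h, w)
  rr <- row(img) - 1; cc <- col(img) - 1
  od <- optic_disc(circle(120, 280, 20))
  place <- function(angle_deg, depth) {
    a <- angle_deg * pi / 180
    r0 <- 120 - 80 * sin(a); c0 <- 280 - 80 * cos(a)
    d2 <- (rr - r0)^2 + (cc - c0)^2
    list(pos = c(r0, c0), dip = depth * exp(-d2 / (2 * 8^2)))
  }
  true_mac <- place(10, 60)
  distract <- place(55, 120)
  img <- pmin(pmax(img - true_mac$dip - distract$dip, 0), 255)
  mac <- locate_macula_geometric(img, od, side = "left")
  expect_lte(sqrt(sum((mac$fovea - true_mac$pos)^2)), 6)
  expect_lte(abs(mac$angle_deg), 37)
})

test_that("macula search errors when the wedge misses the image", {
  img <- matrix(100, 60, 60)
  od <- optic_disc(circle(30, 55, 25))   # 2DD band entirely off-frame
  expect_error(locate_macula_geometric(img, od, side = "right"),
               "out of frame")
})

test_that("image-centre macula method uses the raster centre", {
  img <- matrix(100, 600, 900)
  mac <- locate_macula_image_centre(img, radius = 80)
  expect_equal(unname(mac$fovea), c(300, 450))
  ## mask area equals the per-pixel distance count
  m <- crop_circular_roi(matrix(1, 600, 900), mac$circle)
  rr <- row(img) - 1; cc <- col(img) - 1
  expect_equal(sum(m > 0), sum((rr - 300)^2 + (cc - 450)^2 <= 80^2))
  expect_error(locate_macula_image_centre(img, radius = 301), "radius")
  expect_error(circle(10, 10, 0), "positive")
})

test_that("morphological macula enhancement finds a planted dark blob", {
  flat <- matrix(120, 40, 40)
  ## constant image: top-hat and bottom-hat vanish
  m <- locate_macula_morphological(flat, se_radius = 5)
  expect_true(is.logical(m))

  img <- matrix(200, 120, 160)
  rr <- row(img) - 1; cc <- col(img) - 1
  img[(rr - 69)^2 + (cc - 89)^2 <= 12^2] <- 60
  mask <- locate_macula_morphological(img)
  ctr <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(ctr[, 1]) - 1, mean(ctr[, 2]) - 1)
  expect_lte(sqrt(sum((centroid - c(69, 89))^2)), 5)

  ## clipping contract on a random image
  x <- rand_gray(50, 50, seed = 2)
  tophat <- x - fundusscreen:::disc_open(x, 5)
  bothat <- fundusscreen:::disc_close(x, 5) - x
  enhanced <- fundusscreen:::clip255(x + tophat - bothat)
  expect_true(all(enhanced >= 0 & enhanced <= 255))
})

test_that("circular crop preserves the interior bit-exactly", {
  img <- rand_gray(40, 60, seed = 13)
  whole <- crop_circular_roi(img, circle(20, 30, 100))
  expect_identical(whole, img)

  tiny <- crop_circular_roi(img, circle(20, 30, 1))
  expect_lte(sum(tiny > 0), 5)

  circ <- circle(15, 40, 9)
  out <- crop_circular_roi(img, circ)
  rr <- row(img) - 1; cc <- col(img) - 1
  inside <- (rr - 15)^2 + (cc - 40)^2 <= 9^2
  expect_identical(out[inside], img[inside])     # bit-exact interior
  expect_true(all(out[!inside] == 0))

  expect_warning(res <- crop_circular_roi(img, circle(500, 500, 3)),
                 "intersect")
  expect_true(all(res == 0))
})

test_that("disc recovery holds across many generator seeds", {
  ok <- vapply(1:12, function(s) {
    out <- generate_fundus(synthetic_fundus_spec(seed = s))
    od <- detect_optic_disc(fsm_filter(extract_green_channel(out$image)))
    tr <- out$truth$od
    err <- sqrt((od$circle$row - tr$circle$row)^2 +
                  (od$circle$col - tr$circle$col)^2)
    err <= 3 &&
      abs(od$circle$radius - tr$circle$radius) / tr$circle$radius <= 0.1
  }, logical(1))
  expect_gte(mean(ok), 11 / 12)
})
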