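test_that("DCT matrix is orthonormal with the stated entries", {
  for (S in c(2, 4, 8, 16, 32)) {
    C <- dct_matrix(S)
    expect_lt(max(abs(C %*% t(C) - diag(S))), 1e-10)
    expect_equal(C[1, ], rep(1 / sqrt(S), S))
  }
  C2 <- dct_matrix(2)
  expect_equal(C2, matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2, byrow = TRUE))
  expect_equal(dct_matrix(8)[2, 1], sqrt(2 / 8) * cos(pi / 16), tolerance = 1e-12)
  expect_error(dct_matrix(1), "integer >= 2")
})

test_that("zigzag enumeration follows the JPEG Z pattern and is a bijection", {
  zz <- zigzag_index(8)
  expect_equal(nrow(zz), 64)
  expect_equal(unlist(zz[zz$k == 0, c("i", "j")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(zz[zz$k == 1, c("i", "j")], use.names = FALSE), c(0, 1))
  expect_equal(unlist(zz[zz$k == 2, c("i", "j")], use.names = FALSE), c(1, 0))
  expect_equal(unlist(zz[zz$k == 63, c("i", "j")], use.names = FALSE), c(7, 7))
  for (S in c(4, 8, 16)) {
    zz <- zigzag_index(S)
    expect_equal(sort(zz$i * S + zz$j), 0:(S^2 - 1)) # bijection onto the grid
    # anti-diagonal sums never decrease along the walk
    expect_true(all(diff(zz$i + zz$j) >= 0))
  }
})

test_that("block DCT matches the brute-force double-sum oracle", {
  set.seed(20)
  worst <- 0
  for (r in 1:100) {
    x <- matrix(runif(64, -128, 127), 8, 8)
    z <- block_dct(x, 8)[, , 1, 1]
    worst <- max(worst, max(abs(z - dct2_bruteforce(x))))
  }
  expect_lt(worst, 1e-8)
})

test_that("block DCT conserves energy and concentrates constants in DC", {
  set.seed(21)
  plane <- matrix(runif(32 * 32, 0, 255), 32, 32)
  z <- block_dct(plane, 8)
  expect_equal(sum(z^2), sum(plane^2), tolerance = 1e-8)
  const <- matrix(3.5, 8, 8)
  zc <- block_dct(const, 8)[, , 1, 1]
  expect_equal(zc[1, 1], 8 * 3.5, tolerance = 1e-10)
  expect_lt(max(abs(zc[-1])), 1e-10)
  expect_lt(max(abs(zc[1, -1])), 1e-10)
  expect_error(block_dct(matrix(0, 10, 10), 8), "not divisible")
})

test_that("inverse block DCT is the exact round-trip inverse", {
  set.seed(22)
  worst <- 0
  for (r in 1:100) {
    p <- matrix(rnorm(16 * 16, sd = 50), 16, 16)
    S <- sample(c(2, 4, 8), 1)
    worst <- max(worst, max(abs(inverse_block_dct(block_dct(p, S)) - p)))
  }
  expect_lt(worst, 1e-8)
  zeros <- array(0, c(4, 4, 2, 2))
  expect_equal(inverse_block_dct(zeros), matrix(0, 8, 8))
  dc <- array(0, c(4, 4, 1, 1))
  dc[1, 1, 1, 1] <- 4
  expect_equal(inverse_block_dct(dc), matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("frequency cubes group same-frequency coefficients in zigzag order", {
  plane <- matrix(runif(256 * 256, 0, 255), 256, 256)
  cube <- build_cube(block_dct(plane, 8), "Y")
  expect_equal(dim(cube), c(32, 32, 64))
  # channel k at (p, q) is the zigzag-k coefficient of block (p, q)
  blocks <- block_dct(plane, 8)
  zz <- zigzag_index(8)
  for (k in c(0, 1, 5, 63)) {
    ij <- zz[zz$k == k, ]
    expect_equal(cube[, , k + 1], blocks[ij$i + 1, ij$j + 1, , ])
  }
  const_cube <- build_cube(block_dct(matrix(2, 16, 16), 4), "Cb")
  expect_equal(as.numeric(const_cube[, , 1]), rep(8, 16), tolerance = 1e-12)
  expect_lt(max(abs(const_cube[, , -1])), 1e-10)
})

test_that("YCbCr conversion uses the full-range convention", {
  gray <- array(rep(c(77, 77, 77), each = 4), c(2, 2, 3))
  p <- rgb_to_ycbcr(gray)
  expect_equal(as.numeric(p$Y), rep(77, 4))
  expect_equal(as.numeric(p$Cb), rep(128, 4))
  expect_equal(as.numeric(p$Cr), rep(128, 4))
  black <- array(0, c(2, 2, 3))
  pb <- rgb_to_ycbcr(black)
  expect_equal(as.numeric(pb$Y), rep(0, 4))
  expect_equal(as.numeric(pb$Cb), rep(128, 4))
  red <- array(rep(c(255, 0, 0), each = 4), c(2, 2, 3))
  pr <- rgb_to_ycbcr(red)
  expect_equal(pr$Y[1, 1], 76.245, tolerance = 1e-9)
  expect_equal(pr$Cb[1, 1], 84.97232, tolerance = 1e-6)
  expect_equal(pr$Cr[1, 1], 255) # 255.5 clamped to range
})

test_that("4:2:0 subsampling halves chroma by 2x2 averaging", {
  img <- random_rgb(256, 256, seed = 30)
  sub <- chroma_subsample_420(rgb_to_ycbcr(img))
  expect_equal(dim(sub$Y), c(256, 256))
  expect_equal(dim(sub$Cb), c(128, 128))
  expect_equal(dim(sub$Cr), c(128, 128))
  const <- list(Y = matrix(9, 4, 4), Cb = matrix(7, 4, 4), Cr = matrix(3, 4, 4))
  expect_equal(chroma_subsample_420(const)$Cb, matrix(7, 2, 2))
  blk <- list(Y = matrix(0, 2, 2), Cb = matrix(c(0, 2, 0, 2), 2, 2), Cr = matrix(0, 2, 2))
  expect_equal(chroma_subsample_420(blk)$Cb, matrix(1, 1, 1))
  odd <- list(Y = matrix(0, 3, 4), Cb = matrix(0, 3, 4), Cr = matrix(0, 3, 4))
  expect_error(chroma_subsample_420(odd), "even")
})

test_that("chroma cube upsampling doubles each sub-channel", {
  cube <- build_cube(block_dct(matrix(runif(64 * 64), 64, 64), 4), "Cr")
  up <- upsample_chroma_cube(cube)
  expect_equal(dim(up), c(32, 32, 16))
  expect_equal(up[1:2, 1:2, 3], matrix(cube[1, 1, 3], 2, 2)) # nearest: 2x2 copies
  const <- build_cube(array(0, c(2, 2, 2, 2)) + 0, "Cb")
  expect_true(all(upsample_chroma_cube(const) == 0))
})

test_that("preprocessing yields the square side the DCT geometry needs", {
  img <- random_rgb(500, 400, seed = 31)
  out <- preprocess_image(img, 8, 32)
  expect_equal(dim(out), c(256, 256, 3)) # resize shorter side to 294, crop 256
  out2 <- preprocess_image(random_rgb(256, 256, seed = 32), 8, 32)
  expect_equal(dim(out2), c(256, 256, 3))
  expect_equal(dim(preprocess_image(img, 4, 32)), c(128, 128, 3))
  expect_error(preprocess_image(array(0, c(1, 5, 3)), 8, 32), "2 px")
})

test_that("assembled representations honor the selection contract", {
  img <- random_rgb(80, 80, seed = 33)
  full <- transform_image(img, fixed_selection("full", 8), filter_size = 8, image_size = 8)
  expect_equal(dim(full)[3], 192)
  sel24 <- fixed_selection("explicit", 8, entries = top24_entries)
  rep24 <- transform_image(img, sel24, filter_size = 8, image_size = 8)
  expect_equal(dim(rep24), c(8, 8, 24))
  expect_equal(table(attr(rep24, "channels")$plane)[c("Y", "Cb", "Cr")],
    table(factor(c(rep("Y", 11), rep("Cb", 7), rep("Cr", 6)), c("Y", "Cb", "Cr"))),
    ignore_attr = TRUE
  )
  # stats = NULL leaves coefficients untouched; stats standardizes them
  stats <- channel_norm_stats(list(rep24))
  norm <- transform_image(img, sel24, filter_size = 8, image_size = 8, stats = stats)
  expect_equal(mean(norm[, , 1]), 0, tolerance = 1e-9)
  # out-of-range index errors name the plane
  bad <- channel_selection("Cb", 3, filter_size = 2)
  planes <- chroma_subsample_420(rgb_to_ycbcr(preprocess_image(img, 8, 8)))
  cubes <- lapply(
    stats::setNames(c("Y", "Cb", "Cr"), c("Y", "Cb", "Cr")),
    function(p) build_cube(block_dct(planes[[p]], 8), p)
  )
  bad2 <- channel_selection("Cr", 60, filter_size = 8)
  attr(bad2, "filter_size") <- 8
  bad2$index <- 70L # forged out-of-range index
  expect_error(assemble_representation(cubes, bad2), "Cr")
})

test_that("per-channel normalization stats pool mean and spread across images", {
  reps <- lapply(1:4, function(i) {
    structure(array(i, c(2, 2, 3)), class = c("freq_rep", "array"))
  })
  st <- channel_norm_stats(reps)
  expect_equal(st$mean, rep(2.5, 3))
  expect_equal(st$sd, rep(sqrt(mean((1:4 - 2.5)^2)), 3))
  # constant channels get unit sd so they pass through unscaled
  st1 <- channel_norm_stats(reps[1])
  expect_equal(st1$sd, rep(1, 3))
})
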