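test_that("fixed selections match their closed-form channel counts", {
  for (S in c(4, 8, 16)) {
    expect_equal(nrow(fixed_selection("full", S)), 3 * S^2)
    expect_equal(nrow(fixed_selection("upper_tri_incl_diag", S)), 3 * S * (S + 1) / 2)
    expect_equal(nrow(fixed_selection("upper_tri_excl_diag", S)), 3 * S * (S - 1) / 2)
  }
  expect_equal(nrow(fixed_selection("upper_tri_incl_diag", 8)), 108)
  expect_equal(nrow(fixed_selection("upper_tri_excl_diag", 8)), 84)
})

test_that("triangular selections keep exactly the low anti-diagonals", {
  sel <- fixed_selection("upper_tri_incl_diag", 8)
  zz <- zigzag_index(8)
  kept <- zz[zz$k %in% sel$index[sel$plane == "Y"], ]
  expect_true(all(kept$i + kept$j <= 7))
  dropped <- zz[!zz$k %in% sel$index[sel$plane == "Y"], ]
  expect_true(all(dropped$i + dropped$j > 7))
  sel2 <- fixed_selection("upper_tri_excl_diag", 8)
  kept2 <- zz[zz$k %in% sel2$index[sel2$plane == "Y"], ]
  expect_true(all(kept2$i + kept2$j <= 6))
})

test_that("explicit selections reproduce the published top-24 combination", {
  sel <- fixed_selection("explicit", 8, entries = top24_entries)
  expect_equal(nrow(sel), 24)
  expect_equal(sum(sel$plane == "Y"), 11)
  expect_equal(sum(sel$plane == "Cb"), 7)
  expect_equal(sum(sel$plane == "Cr"), 6)
  expect_error(
    fixed_selection("explicit", 8, entries = list(Y = 64)),
    "indices"
  )
})

test_that("selection construction validates entries", {
  expect_error(channel_selection("Y", -1, 8), "indices")
  expect_error(channel_selection(c("Y", "Y"), c(1, 1), 8), "unique")
  expect_error(channel_selection("Q", 0, 8), "planes")
})

test_that("top-N selection keeps the heaviest channels with deterministic ties", {
  full <- fixed_selection("full", 8)
  n_ch <- nrow(full)
  equal <- channel_weights(full$plane, full$index, rep(0.5, n_ch))
  sel24 <- select_top_n(equal, 24, filter_size = 8)
  expect_equal(sel24$plane, rep("Y", 24)) # tie-break: Y first, ascending index
  expect_equal(sel24$index, 0:23)
  expect_equal(nrow(select_top_n(equal, n_ch)), n_ch)

  w <- rep(0.1, n_ch)
  w[which(full$plane == "Cr" & full$index == 5)] <- 0.9
  one <- select_top_n(channel_weights(full$plane, full$index, w), 1, 8)
  expect_equal(one$plane, "Cr")
  expect_equal(one$index, 5L)
  expect_error(select_top_n(equal, n_ch + 1), "exceeds")
})

test_that("top-N agrees with a brute-force sort-and-slice oracle", {
  full <- fixed_selection("full", 4)
  set.seed(55)
  plane_ord <- match(full$plane, c("Y", "Cb", "Cr"))
  for (r in 1:1000) {
    w <- round(runif(nrow(full)), 2) # coarse grid to force ties
    n <- sample(1:48, 1)
    got <- select_top_n(channel_weights(full$plane, full$index, w), n, 4)
    ord <- order(-w, plane_ord, full$index)[1:n]
    want <- paste(full$plane[ord], full$index[ord])
    expect_setequal(paste(got$plane, got$index), want)
  }
})

test_that("SE gates are sigmoid-bounded and symmetric for symmetric inputs", {
  params <- se_init(8, reduction = 2, seed = 3)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  g <- se_gate(x, params)
  expect_length(g, 8)
  expect_true(all(g > 0 & g < 1))
  # zero input with zero biases lands exactly at sigmoid(0)
  expect_equal(se_gate(array(0, c(4, 4, 8)), params), rep(0.5, 8))
  # identical channel maps + tied excitation weights give equal gates
  tied <- list(
    W1 = matrix(0.3, 2, 8), b1 = rep(0, 2),
    W2 = matrix(0.2, 8, 2), b2 = rep(0, 8)
  )
  same <- array(rep(rnorm(16), 8), c(4, 4, 8))
  gt <- se_gate(same, tied)
  expect_equal(gt, rep(gt[1], 8))
  expect_warning(se_init(4, reduction = 16), "falling back")
})

test_that("weight aggregation is the per-channel arithmetic mean", {
  w1 <- channel_weights(c("Y", "Cb"), c(0, 1), c(0.2, 0.6))
  w2 <- channel_weights(c("Y", "Cb"), c(0, 1), c(0.8, 0.6))
  agg <- aggregate_weights(list(w1, w2))
  expect_equal(agg$weight[agg$plane == "Y"], 0.5)
  expect_equal(agg$weight[agg$plane == "Cb"], 0.6)
  agg1 <- aggregate_weights(list(w1))
  expect_equal(
    agg1$weight[match(paste(w1$plane, w1$index), paste(agg1$plane, agg1$index))],
    w1$weight
  )
  # mean of identical vectors is that vector
  agg3 <- aggregate_weights(list(w1, w1, w1))
  expect_equal(sort(agg3$weight), sort(w1$weight))
  w3 <- channel_weights("Cr", 2, 0.5)
  expect_error(aggregate_weights(list(w1, w3)), "different channel sets")
})

test_that("selections survive a JSON round trip with normalization stats", {
  sel <- fixed_selection("explicit", 8, entries = top24_entries)
  attr(sel, "norm_stats") <- list(mean = rnorm(24), sd = runif(24, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_equal(back$plane, sel$plane)
  expect_equal(back$index, sel$index)
  expect_equal(attr(back, "filter_size"), 8L)
  expect_equal(attr(back, "norm_stats")$mean, attr(sel, "norm_stats")$mean)
  expect_equal(attr(back, "norm_stats")$sd, attr(sel, "norm_stats")$sd)
})

test_that("selection and weight plots build without error", {
  sel <- fixed_selection("upper_tri_incl_diag", 4)
  p1 <- ggplot2::autoplot(sel)
  expect_s3_class(p1, "ggplot")
  full <- fixed_selection("full", 4)
  w <- channel_weights(full$plane, full$index, runif(nrow(full)))
  p2 <- ggplot2::autoplot(w, filter_size = 4)
  expect_s3_class(p2, "ggplot")
})
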