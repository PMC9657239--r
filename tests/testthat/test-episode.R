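test_that("episode sampling produces the requested support/query structure", {
  df <- toy_features(n_classes = 10, per_class = 20)
  set.seed(10)
  ep <- sample_episode(df, n_way = 5, k_shot = 1, n_query = 15)
  expect_equal(nrow(ep$support), 5)
  expect_equal(nrow(ep$query), 75)
  expect_setequal(unique(ep$query$class), ep$classes)
  expect_setequal(unique(ep$support$class), ep$classes)
  expect_equal(as.numeric(table(ep$query$class)), rep(15, 5))
  # support and query never share a sample (features are continuous, so
  # identical rows would mean a shared draw)
  key <- function(d) apply(feat <- d[vapply(d, is.numeric, TRUE)], 1, paste, collapse = ",")
  expect_length(intersect(key(ep$support), key(ep$query)), 0)

  set.seed(77)
  a <- sample_episode(df, 5, 3, 10)
  set.seed(77)
  b <- sample_episode(df, 5, 3, 10)
  expect_identical(a, b)

  expect_error(sample_episode(df, n_way = 11), "11 classes")
  expect_error(sample_episode(df, 5, 10, 15), "fewer than")
})

test_that("centroids are per-class means, invariant to sample order", {
  sup <- tibble::tibble(class = c("a", "a", "b"), V1 = c(0, 2, 5), V2 = c(0, 2, 7))
  cen <- compute_centroids(sup)
  expect_equal(cen$V1[cen$class == "a"], 1)
  expect_equal(cen$V2[cen$class == "a"], 1)
  expect_equal(cen$V1[cen$class == "b"], 5) # K = 1: the support vector itself
  shuffled <- compute_centroids(sup[c(3, 1, 2), ])
  expect_equal(shuffled, cen)
})

test_that("cosine similarity matches its closed-form cases", {
  a <- c(1, 2, 3)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosine_similarity(a, 10 * a), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(2, 0), c(3, 4)), 0.6)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("class probabilities are a softmax over raw cosines", {
  cen <- tibble::tibble(class = c("p", "q"), V1 = c(1, 0), V2 = c(0, 1))
  pr <- class_probabilities(c(1, 0), cen) # similarities 1 and 0
  expect_equal(pr$probability, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # equal similarities give the uniform distribution
  cen4 <- tibble::tibble(class = letters[1:4], V1 = rep(1, 4), V2 = rep(2, 4))
  pr4 <- class_probabilities(c(3, 1), cen4)
  expect_equal(pr4$probability, rep(0.25, 4))
  # a query equal to a centroid wins when centroids are distinct
  cen3 <- tibble::tibble(class = c("a", "b", "c"), V1 = c(1, 0, 1), V2 = c(0, 1, 1))
  pr3 <- class_probabilities(c(1, 1), cen3)
  expect_equal(pr3$class[which.max(pr3$probability)], "c")
  expect_error(class_probabilities(c(1, 2, 3), cen), "dimensions")
})

test_that("probabilities match a hand-computed softmax-over-cosines oracle", {
  # a printed 3-way toy episode with d = 4, worked independently below
  c1 <- c(1, 0, 2, 1)
  c2 <- c(0, 3, 1, 0)
  c3 <- c(2, 1, 0, 2)
  q <- c(1, 0, 2, 3)
  cen <- tibble::tibble(
    class = c("c1", "c2", "c3"),
    V1 = c(c1[1], c2[1], c3[1]), V2 = c(c1[2], c2[2], c3[2]),
    V3 = c(c1[3], c2[3], c3[3]), V4 = c(c1[4], c2[4], c3[4])
  )
  sims <- c(
    sum(q * c1) / (sqrt(sum(q^2)) * sqrt(sum(c1^2))),
    sum(q * c2) / (sqrt(sum(q^2)) * sqrt(sum(c2^2))),
    sum(q * c3) / (sqrt(sum(q^2)) * sqrt(sum(c3^2)))
  )
  expected <- exp(sims) / sum(exp(sims))
  got <- class_probabilities(q, cen)
  expect_equal(got$probability, expected, tolerance = 1e-9)
  # and the calibrated route agrees with calibrating by hand
  cfg <- calibrator_config()
  gq <- calibrate(q, cfg)
  gc1 <- calibrate(c1, cfg); gc2 <- calibrate(c2, cfg); gc3 <- calibrate(c3, cfg)
  sims_g <- c(
    sum(gq * gc1) / (sqrt(sum(gq^2)) * sqrt(sum(gc1^2))),
    sum(gq * gc2) / (sqrt(sum(gq^2)) * sqrt(sum(gc2^2))),
    sum(gq * gc3) / (sqrt(sum(gq^2)) * sqrt(sum(gc3^2)))
  )
  expected_g <- exp(sims_g) / sum(exp(sims_g))
  got_g <- class_probabilities(q, cen, calibrator = cfg)
  expect_equal(got_g$probability, expected_g, tolerance = 1e-9)
})

test_that("probability vectors always lie on the simplex", {
  set.seed(12)
  for (r in 1:1000) {
    n <- sample(2:8, 1)
    d <- sample(2:16, 1)
    cen <- matrix(rnorm(n * d), n, d)
    pr <- class_probabilities(rnorm(d), cen)
    expect_equal(sum(pr$probability), 1, tolerance = 1e-9)
    expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  }
})

test_that("episode scoring and cross-entropy satisfy their identities", {
  df <- toy_features(n_classes = 6, per_class = 20, sep = 50)
  set.seed(13)
  ep <- sample_episode(df, 5, 5, 10)
  sc <- score_episode(ep)
  expect_equal(nrow(sc), 50)
  expect_true(all(vapply(sc$probabilities, function(p) abs(sum(p) - 1) < 1e-9, TRUE)))
  # widely separated clusters: every query correct, tiny loss
  expect_true(all(sc$correct))
  expect_gte(cross_entropy_loss(sc), 0)
  # uniform probabilities give loss log(N)
  uni <- tibble::tibble(p_true = rep(1 / 5, 10))
  expect_equal(cross_entropy_loss(uni), log(5), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(uni[sample(1:10), , drop = FALSE]), log(5))
  expect_warning(
    lo <- cross_entropy_loss(tibble::tibble(p_true = c(0.5, 0))),
    "clamped"
  )
  expect_true(is.finite(lo))
})

test_that("episodic evaluation recovers well-separated synthetic classes", {
  df <- generate_feature_clusters(synthetic_feature_spec(
    n_classes = 8, dim = 64, per_class = 25, separation = 10,
    noise = "gaussian", sigma = 1, seed = 5
  ))
  ev <- evaluate_episodes(df, n_way = 5, k_shot = 5, n_query = 15, episodes = 200, seed = 6)
  expect_gte(glance(ev)$mean_accuracy, 99)
  # reproducible under the same seed
  ev2 <- evaluate_episodes(df, n_way = 5, k_shot = 5, n_query = 15, episodes = 200, seed = 6)
  expect_identical(tidy(ev), tidy(ev2))
})

test_that("unseparated features score at chance", {
  df <- generate_feature_clusters(synthetic_feature_spec(
    n_classes = 8, dim = 32, per_class = 25, separation = 0,
    noise = "gaussian", seed = 7
  ))
  ev <- evaluate_episodes(df, n_way = 5, k_shot = 1, n_query = 15, episodes = 600, seed = 8)
  expect_equal(glance(ev)$mean_accuracy, 20, tolerance = 0.1) # 20% +/- 2 points
})

test_that("tidy, glance and autoplot expose the evaluation results", {
  df <- toy_features()
  ev <- evaluate_episodes(df, 5, 1, 10, episodes = 10, epochs = 2, seed = 9)
  td <- tidy(ev)
  expect_equal(nrow(td), 20)
  expect_named(td, c("epoch", "episode", "accuracy", "loss"))
  g <- glance(ev)
  expect_equal(g$n_episodes, 20)
  expect_equal(g$chance, 20)
  expect_equal(g$mean_accuracy, mean(td$accuracy))
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})

test_that("spatial and frequency embeddings concatenate in order", {
  expect_equal(concat_spatial_frequency(c(1, 2), 3), c(1, 2, 3))
  expect_length(concat_spatial_frequency(rnorm(5), rnorm(7)), 12)
  expect_equal(concat_spatial_frequency(c(1, 2), numeric(0)), c(1, 2))
})
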