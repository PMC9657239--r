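# Desk-scale synthetic fixtures carrying the statistical structure the
# method assumes: leaf-like images whose classes differ in lesion color and
# texture spatial frequency, and skewed feature-vector clusters.

#' Specification of a synthetic leaf-image dataset
#'
#' Each image is a uniform "clean board" background, an elliptical leaf
#' mask, and a class-specific sinusoidal lesion texture (one hue and one
#' spatial-frequency band per class) plus Gaussian pixel noise — a stylized
#' stand-in for single-leaf, single-disease, controlled-background plant
#' photographs. Lesion frequencies and hues are assigned by interleaving, so
#' the source and target class parameter sets are disjoint (as the training
#' and novel-class splits must be).
#'
#' @param n_source,n_target Number of source (training) and target (novel,
#'   test-only) classes.
#' @param per_class Images per class; must cover `k_shot + n_query` for the
#'   intended episodes.
#' @param side Image side length in pixels.
#' @param freq_range Range of lesion texture frequencies (cycles per image)
#'   spread across classes.
#' @param noise_sd Gaussian pixel noise standard deviation (0–255 scale).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `synthetic_image_spec` list including the per-class `classes`
#'   tibble (name, split, frequency, hue).
#' @export
synthetic_image_spec <- function(n_source = 8, n_target = 5, per_class = 20,
                                 side = 64, freq_range = c(3, 24),
                                 noise_sd = 8, seed = 0) {
  stopifnot(n_source >= 1, n_target >= 1, per_class >= 1, side >= 16)
  n <- n_source + n_target
  freqs <- seq(freq_range[1], freq_range[2], length.out = n)
  hues <- (seq_len(n) - 1) / n # evenly spaced on the color wheel
  # interleave so neither split monopolizes low or high frequencies
  split <- rep("target", n)
  split[seq(1, n, length.out = n_source) |> round()] <- "source"
  if (sum(split == "source") != n_source) { # guard against rounding collisions
    split <- c(rep("source", n_source), rep("target", n_target))
  }
  classes <- tibble::tibble(
    name = sprintf("class_%02d", seq_len(n)),
    split = split,
    frequency = freqs,
    hue = hues
  )
  structure(
    list(
      n_source = n_source, n_target = n_target, per_class = per_class,
      side = as.integer(side), noise_sd = noise_sd, seed = seed,
      classes = classes
    ),
    class = "synthetic_image_spec"
  )
}

hue_to_rgb <- function(hue, s = 0.85, v = 0.45) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue %% 1, s, v)))
}

# One synthetic leaf image as an H x W x 3 array in [0, 255]. The board
# color is matched to the mean leaf color so the luma spectrum is dominated
# by the lesion texture rather than the leaf outline, keeping the
# frequency-selection behavior of the classes analytically predictable; the
# boundary is softened over ~2 px for the same reason (a hard edge spreads
# 1/f^2 energy across every band).
render_leaf_image <- function(side, frequency, hue, noise_sd) {
  xs <- matrix(rep(seq_len(side), each = side), side, side) # column coord
  ys <- matrix(rep(seq_len(side), times = side), side, side) # row coord
  cx <- side / 2 + stats::runif(1, -2, 2)
  cy <- side / 2 + stats::runif(1, -2, 2)
  ax <- side * stats::runif(1, 0.38, 0.44)
  ay <- side * stats::runif(1, 0.26, 0.32)
  r <- sqrt(((xs - cx) / ax)^2 + ((ys - cy) / ay)^2)
  leaf <- 1 / (1 + exp((r - 1) * side / 2)) # soft elliptical mask
  theta <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  f <- frequency + stats::runif(1, -0.5, 0.5)
  wave <- sin(2 * pi * f * (xs * cos(theta) + ys * sin(theta)) / side + phase)
  texture <- 0.5 + 0.5 * wave # lesion modulation in [0, 1]
  leaf_rgb <- c(60, 140, 60) * stats::runif(1, 0.9, 1.1)
  lesion_rgb <- hue_to_rgb(hue)
  alpha <- 0.85
  img <- array(0, c(side, side, 3))
  for (ch in 1:3) {
    leaf_plane <- leaf_rgb[ch] * (1 - alpha * texture) + lesion_rgb[ch] * alpha * texture
    bg <- leaf_rgb[ch] * (1 - alpha * 0.5) + lesion_rgb[ch] * alpha * 0.5
    plane <- bg * (1 - leaf) + leaf_plane * leaf
    plane <- plane + stats::rnorm(side^2, sd = noise_sd)
    img[, , ch] <- pmin(pmax(plane, 0), 255)
  }
  img
}

#' Generate a directory-per-class synthetic image dataset
#'
#' Writes `per_class` PNG images for every class of the spec into
#' `out_dir/<class_name>/`, plus a `manifest.json` recording the class
#' parameters and the source/target split. Byte-identical across runs with
#' the same spec.
#'
#' @param spec A [synthetic_image_spec()].
#' @param out_dir Output directory (created if missing).
#' @return A tibble manifest: `path`, `class`, `split`, one row per image.
#' @export
#' @examples
#' \donttest{
#' spec <- synthetic_image_spec(n_source = 2, n_target = 2, per_class = 3, side = 32)
#' manifest <- generate_image_dataset(spec, tempfile())
#' nrow(manifest) # 12
#' }
generate_image_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  rows <- list()
  for (ci in seq_len(nrow(spec$classes))) {
    cls <- spec$classes[ci, ]
    cls_dir <- file.path(out_dir, cls$name)
    dir.create(cls_dir, showWarnings = FALSE)
    for (im in seq_len(spec$per_class)) {
      img <- render_leaf_image(spec$side, cls$frequency, cls$hue, spec$noise_sd)
      path <- file.path(cls_dir, sprintf("img_%03d.png", im))
      png::writePNG(img / 255, path)
      rows[[length(rows) + 1]] <- tibble::tibble(
        path = path, class = cls$name, split = cls$split
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(
    list(
      seed = spec$seed, side = spec$side, per_class = spec$per_class,
      noise_sd = spec$noise_sd,
      classes = spec$classes
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  manifest
}

#' Generate synthetic images in memory
#'
#' Same generator as [generate_image_dataset()] without touching disk:
#' returns the images as arrays together with their labels and split.
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list with `images` (list of `side x side x 3` arrays), and a
#'   `labels` tibble (`class`, `split`).
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  images <- list()
  labels <- list()
  for (ci in seq_len(nrow(spec$classes))) {
    cls <- spec$classes[ci, ]
    for (im in seq_len(spec$per_class)) {
      images[[length(images) + 1]] <-
        render_leaf_image(spec$side, cls$frequency, cls$hue, spec$noise_sd)
      labels[[length(labels) + 1]] <- tibble::tibble(class = cls$name, split = cls$split)
    }
  }
  list(images = images, labels = dplyr::bind_rows(labels))
}

#' Specification of synthetic feature-vector clusters
#'
#' Class `c`'s centroid sits at `separation` times an orthonormal direction
#' (a unit basis vector when `n_classes <= dim`, otherwise random
#' orthonormal directions); samples add i.i.d. noise per dimension —
#' Gaussian, or log-normal to produce the right-skewed marginals that the
#' Gaussian-like calibrator targets.
#'
#' @param n_classes Number of classes.
#' @param dim Feature dimensionality (`>= 2`).
#' @param per_class Samples per class.
#' @param separation Distance of each centroid from the origin; 0 makes all
#'   classes statistically identical.
#' @param noise `"gaussian"` or `"lognormal"`.
#' @param sigma Gaussian noise standard deviation.
#' @param meanlog,sdlog Log-normal noise parameters.
#' @param seed Integer seed.
#' @return A `synthetic_feature_spec` list.
#' @export
synthetic_feature_spec <- function(n_classes = 5, dim = 64, per_class = 100,
                                   separation = 10, noise = c("gaussian", "lognormal"),
                                   sigma = 1, meanlog = 0, sdlog = 1, seed = 0) {
  noise <- match.arg(noise)
  stopifnot(n_classes >= 2, dim >= 2, per_class >= 1, separation >= 0)
  structure(
    list(
      n_classes = n_classes, dim = dim, per_class = per_class,
      separation = separation, noise = noise, sigma = sigma,
      meanlog = meanlog, sdlog = sdlog, seed = seed
    ),
    class = "synthetic_feature_spec"
  )
}

#' Generate labeled synthetic feature clusters
#'
#' @param spec A [synthetic_feature_spec()].
#' @return A tibble with a `class` column and feature columns `V1..Vdim`,
#'   `n_classes * per_class` rows.
#' @export
#' @examples
#' df <- generate_feature_clusters(synthetic_feature_spec(n_classes = 3, dim = 8))
#' dim(df)
generate_feature_clusters <- function(spec) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  k <- spec$n_classes
  dirs <- if (k <= d) {
    diag(1, k, d)
  } else {
    # more classes than dimensions: random directions (orthonormal rows
    # are impossible; use unit-norm random directions instead)
    m <- matrix(stats::rnorm(k * d), k, d)
    m / sqrt(rowSums(m^2))
  }
  n <- k * spec$per_class
  noise <- if (spec$noise == "gaussian") {
    matrix(stats::rnorm(n * d, sd = spec$sigma), n, d)
  } else {
    matrix(stats::rlnorm(n * d, meanlog = spec$meanlog, sdlog = spec$sdlog), n, d)
  }
  cls_idx <- rep(seq_len(k), each = spec$per_class)
  centers <- spec$separation * dirs[cls_idx, , drop = FALSE]
  m <- centers + noise
  colnames(m) <- paste0("V", seq_len(d))
  dplyr::bind_cols(
    tibble::tibble(class = sprintf("class_%02d", cls_idx)),
    tibble::as_tibble(m)
  )
}
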