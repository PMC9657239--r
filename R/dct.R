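#' The orthonormal type-II DCT matrix
#'
#' Builds the `S x S` discrete cosine transform matrix `C` used to transform
#' each image patch: row 0 is the constant `1/sqrt(S)`, row `i > 0` is
#' `sqrt(2/S) * cos((2j + 1) * i * pi / (2S))`. `C` is orthonormal, so the
#' block transform `Z = C X t(C)` conserves energy and is exactly invertible.
#'
#' @param S Integer filter side length (the DCT filter is `S x S`), `S >= 2`.
#'   Standard JPEG uses 8; 4 and 16 are the other sizes commonly explored.
#' @return An `S x S` numeric matrix.
#' @export
#' @examples
#' C <- dct_matrix(8)
#' max(abs(C %*% t(C) - diag(8))) < 1e-10
dct_matrix <- function(S) {
  S <- check_filter_size(S)
  idx <- 0:(S - 1)
  C <- sqrt(2 / S) * cos(outer(idx, idx, function(i, j) (2 * j + 1) * i * pi / (2 * S)))
  C[1, ] <- 1 / sqrt(S)
  C
}

check_filter_size <- function(S) {
  if (!is.numeric(S) || length(S) != 1 || is.na(S) || S < 2 || S != round(S)) {
    stop("`S` must be a single integer >= 2", call. = FALSE)
  }
  as.integer(S)
}

#' JPEG zigzag enumeration of block frequencies
#'
#' Enumerates the `S^2` frequency positions of an `S x S` DCT block in the
#' JPEG "Z" order, from the DC coefficient at the top-left corner to the
#' highest-frequency coefficient at the bottom-right. Anti-diagonals are
#' traversed in alternating direction, so `k = 0` is `(0, 0)`, `k = 1` is
#' `(0, 1)`, `k = 2` is `(1, 0)`, and so on. All frequency-channel indices in
#' this package (selection files, tables of retained channels) refer to this
#' numbering.
#'
#' @param S Filter side length.
#' @return A tibble with columns `k` (zigzag index, 0-based), `i` (row) and
#'   `j` (column), both 0-based, one row per frequency in zigzag order.
#' @export
#' @examples
#' zigzag_index(8)[1:3, ] # k = 0, 1, 2 at (0,0), (0,1), (1,0)
zigzag_index <- function(S) {
  S <- check_filter_size(S)
  rows <- vector("list", 2L * S - 1L)
  for (s in 0:(2L * S - 2L)) {
    lo <- max(0L, s - S + 1L)
    hi <- min(s, S - 1L)
    i <- if (s %% 2 == 0) hi:lo else lo:hi
    rows[[s + 1L]] <- cbind(i = i, j = s - i)
  }
  m <- do.call(rbind, rows)
  tibble::tibble(k = 0:(S^2 - 1L), i = as.integer(m[, "i"]), j = as.integer(m[, "j"]))
}

#' Blockwise 2-D DCT of an image plane
#'
#' Partitions a real plane into non-overlapping `S x S` patches `X[p, q]` and
#' transforms each one as `Z[p, q] = C X[p, q] t(C)` with the orthonormal DCT
#' matrix from [dct_matrix()]. The plane dimensions must be divisible by `S`;
#' nothing is padded silently (the preprocessing step guarantees
#' divisibility for pipeline inputs).
#'
#' @param plane Numeric matrix (`H x W`), e.g. a Y, Cb or Cr plane.
#' @param S Filter side length.
#' @return A 4-D array with dimensions `(S, S, H/S, W/S)`; element
#'   `[i, j, p, q]` is coefficient `(i-1, j-1)` of block `(p-1, q-1)`.
#' @export
block_dct <- function(plane, S) {
  S <- check_filter_size(S)
  check_divisible(plane, S)
  apply_blockwise(plane, dct_matrix(S))
}

#' Inverse blockwise DCT
#'
#' Exact inverse of [block_dct()]: `X[p, q] = t(C) Z[p, q] C`. Used for
#' round-trip verification of the transform.
#'
#' @param blocks 4-D coefficient array as returned by [block_dct()].
#' @return The reconstructed plane, a numeric matrix.
#' @export
inverse_block_dct <- function(blocks) {
  stopifnot(length(dim(blocks)) == 4)
  S <- dim(blocks)[1]
  C <- dct_matrix(S)
  Hb <- dim(blocks)[3]
  Wb <- dim(blocks)[4]
  # undo the block transform, then reassemble the plane from patches
  x <- apply_to_blocks(blocks, t(C))
  x <- aperm(x, c(1, 3, 2, 4)) # (S, Hb, S, Wb)
  dim(x) <- c(S * Hb, S * Wb)
  x
}

# split plane into S x S patches and apply M . patch . t(M) to each
apply_blockwise <- function(plane, M) {
  S <- nrow(M)
  H <- nrow(plane)
  W <- ncol(plane)
  x <- plane
  dim(x) <- c(S, H / S, S, W / S)
  x <- aperm(x, c(1, 3, 2, 4)) # (S, S, Hb, Wb)
  apply_to_blocks(x, M)
}

# x: (S, S, Hb, Wb) blocks; returns M . block . t(M) for every block
apply_to_blocks <- function(x, M) {
  S <- dim(x)[1]
  d <- dim(x)
  a <- M %*% matrix(x, nrow = S) # act on row index
  dim(a) <- d
  a <- aperm(a, c(2, 1, 3, 4))
  b <- M %*% matrix(a, nrow = S) # act on column index
  dim(b) <- d
  aperm(b, c(2, 1, 3, 4))
}

check_divisible <- function(plane, S) {
  if (!is.matrix(plane) || !is.numeric(plane)) {
    stop("`plane` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(plane) %% S != 0 || ncol(plane) %% S != 0) {
    stop(sprintf(
      "plane dimensions %d x %d are not divisible by the filter size %d; crop or resize first",
      nrow(plane), ncol(plane), S
    ), call. = FALSE)
  }
  invisible(plane)
}

#' Assemble a frequency cube from block-DCT coefficients
#'
#' Groups coefficients with the same frequency across all blocks of a plane
#' into one sub-channel: sub-channel `k` holds, at spatial position
#' `(p, q)`, the zigzag-`k` coefficient of block `(p, q)`. An `S x S` filter
#' therefore yields `S^2` sub-channels of size `(H/S) x (W/S)`; sub-channel 0
#' is the DC frequency.
#'
#' @param blocks 4-D coefficient array from [block_dct()].
#' @param plane One of `"Y"`, `"Cb"`, `"Cr"` — recorded as cube provenance.
#' @return A `freq_cube`: a 3-D array `(H/S, W/S, S^2)` with attributes
#'   `plane` and `S`, channels in zigzag frequency order.
#' @export
build_cube <- function(blocks, plane = c("Y", "Cb", "Cr")) {
  plane <- match.arg(plane)
  stopifnot(length(dim(blocks)) == 4)
  S <- dim(blocks)[1]
  Hb <- dim(blocks)[3]
  Wb <- dim(blocks)[4]
  zz <- zigzag_index(S)
  lin <- zz$i + 1L + zz$j * S # column-major position of (i, j) within a block
  x <- blocks
  dim(x) <- c(S * S, Hb, Wb)
  cube <- aperm(x[lin, , , drop = FALSE], c(2, 3, 1))
  structure(cube, plane = plane, S = S, class = c("freq_cube", "array"))
}

#' @export
print.freq_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<freq_cube> plane %s, filter %d: %d sub-channels of %d x %d\n",
    attr(x, "plane"), attr(x, "S"), d[3], d[1], d[2]
  ))
  invisible(x)
}

#' Convert an RGB image to YCbCr planes
#'
#' Full-range JPEG (ITU-R BT.601) conversion: `Y` in `[0, 255]` carries
#' brightness, `Cb`/`Cr` carry color and are centred at 128. An achromatic
#' pixel `(g, g, g)` maps to `Y = g`, `Cb = Cr = 128`. Outputs are clamped to
#' `[0, 255]`.
#'
#' @param img Numeric `H x W x 3` array of RGB intensities in `[0, 255]`.
#' @return Named list with numeric matrices `Y`, `Cb`, `Cr`, all `H x W`.
#' @export
rgb_to_ycbcr <- function(img) {
  check_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  list(Y = clamp255(y), Cb = clamp255(cb), Cr = clamp255(cr))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("`img` must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(img)[1] < 2 || dim(img)[2] < 2) {
    stop("image must be at least 2 px per side", call. = FALSE)
  }
  invisible(img)
}

#' 4:2:0 chroma subsampling
#'
#' Keeps the Y plane at full resolution and halves Cb and Cr in both axes by
#' 2x2 block averaging, mirroring JPEG's 4:2:0 ratio (the human visual
#' system is more sensitive to brightness than to color, so chroma detail can
#' be reduced). A 256x256 input yields Y 256x256 and Cb/Cr 128x128.
#'
#' @param planes Named list `Y`, `Cb`, `Cr` of full-resolution matrices with
#'   even dimensions.
#' @return Named list with `Y` unchanged and `Cb`, `Cr` at half resolution.
#' @export
chroma_subsample_420 <- function(planes) {
  stopifnot(is.list(planes), all(c("Y", "Cb", "Cr") %in% names(planes)))
  h <- nrow(planes$Y); w <- ncol(planes$Y)
  if (h %% 2 != 0 || w %% 2 != 0) {
    stop("plane dimensions must be even for 4:2:0 subsampling", call. = FALSE)
  }
  list(Y = planes$Y, Cb = halve2x2(planes$Cb), Cr = halve2x2(planes$Cr))
}

halve2x2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  a <- (m[seq(1, h, 2), , drop = FALSE] + m[seq(2, h, 2), , drop = FALSE]) / 2
  (a[, seq(1, w, 2), drop = FALSE] + a[, seq(2, w, 2), drop = FALSE]) / 2
}

#' Upsample a chroma frequency cube to luma resolution
#'
#' Cb/Cr sub-channels are half the spatial size of Y sub-channels after 4:2:0
#' subsampling; they are doubled here (nearest-neighbour by default, bilinear
#' optionally) so all planes can be concatenated into one representation.
#'
#' @param cube A `freq_cube` from a chroma plane.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return A `freq_cube` with each sub-channel doubled in both axes.
#' @export
upsample_chroma_cube <- function(cube, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  d <- dim(cube)
  out <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- upsample2(cube[, , k], method)
  }
  structure(out,
    plane = attr(cube, "plane"), S = attr(cube, "S"),
    class = c("freq_cube", "array")
  )
}

upsample2 <- function(m, method) {
  if (method == "nearest") {
    m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  } else {
    resize_plane(m, 2L * nrow(m), 2L * ncol(m))
  }
}

# bilinear resize of an H x W matrix (EBImage stores width-first, so transpose)
resize_plane <- function(m, new_h, new_w) {
  t(EBImage::resize(t(m), w = new_w, h = new_h, filter = "bilinear"))
}

# bilinear resize of an H x W x C array
resize_rgb <- function(img, new_h, new_w) {
  out <- EBImage::resize(aperm(img, c(2, 1, 3)), w = new_w, h = new_h, filter = "bilinear")
  aperm(out, c(2, 1, 3))
}

#' Resize and centre-crop an image for the DCT pipeline
#'
#' Resizes the shorter side to `floor(filter_size * image_size * 1.15)`
#' preserving aspect ratio, then centre-crops to a square of side
#' `filter_size * image_size`. After the block DCT each sub-channel is then
#' exactly `image_size x image_size`, and both dimensions are divisible by
#' `2 * filter_size` so 4:2:0 subsampling and blocking never need padding.
#'
#' @param img Numeric `H x W x 3` RGB array, intensities in `[0, 255]`.
#' @param filter_size DCT filter side `S` (8 standard; 4–32 supported).
#' @param image_size Target sub-channel side length in pixels.
#' @return A square `filter_size*image_size` RGB array.
#' @export
preprocess_image <- function(img, filter_size, image_size) {
  check_rgb(img)
  filter_size <- check_filter_size(filter_size)
  stopifnot(image_size >= 1)
  target <- filter_size * image_size
  enlarged <- as.integer(filter_size * image_size * 1.15)
  h <- dim(img)[1]; w <- dim(img)[2]
  scale <- enlarged / min(h, w)
  img <- resize_rgb(img, max(round(h * scale), enlarged), max(round(w * scale), enlarged))
  center_crop(img, target)
}

center_crop <- function(img, side) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < side || w < side) stop("image smaller than crop size", call. = FALSE)
  r0 <- (h - side) %/% 2
  c0 <- (w - side) %/% 2
  img[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
}

#' Concatenate selected frequency channels into one representation
#'
#' Takes the Y, Cb and Cr frequency cubes of an image, upsamples the chroma
#' cubes to Y resolution, extracts the channels named by a
#' [channel_selection()] in order, and optionally standardizes each retained
#' channel with stored per-channel statistics (the "Normalize (after DCT)"
#' step; statistics are computed once from the training split).
#'
#' @param cubes Named list of `freq_cube`s for `Y`, `Cb`, `Cr`.
#' @param sel A [channel_selection()].
#' @param stats Optional per-channel normalization: a list with numeric
#'   vectors `mean` and `sd`, one entry per selected channel in selection
#'   order. `NULL` returns raw coefficients.
#' @param upsample Chroma upsampling method, `"nearest"` or `"bilinear"`.
#' @return A `freq_rep`: 3-D array `(image_size, image_size, n)` with a
#'   `channels` attribute recording the selection.
#' @export
assemble_representation <- function(cubes, sel, stats = NULL,
                                    upsample = c("nearest", "bilinear")) {
  upsample <- match.arg(upsample)
  stopifnot(is.list(cubes), all(c("Y", "Cb", "Cr") %in% names(cubes)))
  sel <- as_channel_selection(sel)
  for (p in c("Cb", "Cr")) {
    if (nrow(cubes[[p]]) < nrow(cubes$Y)) {
      cubes[[p]] <- upsample_chroma_cube(cubes[[p]], method = upsample)
    }
  }
  hw <- dim(cubes$Y)[1:2]
  n <- nrow(sel)
  out <- array(0, c(hw[1], hw[2], n))
  for (r in seq_len(n)) {
    cube <- cubes[[sel$plane[r]]]
    k <- sel$index[r]
    if (k < 0 || k >= dim(cube)[3]) {
      stop(sprintf("selection index %d out of range for plane %s", k, sel$plane[r]),
        call. = FALSE
      )
    }
    out[, , r] <- cube[, , k + 1L]
  }
  if (!is.null(stats)) {
    stopifnot(length(stats$mean) == n, length(stats$sd) == n)
    for (r in seq_len(n)) {
      out[, , r] <- (out[, , r] - stats$mean[r]) / stats$sd[r]
    }
  }
  structure(out, channels = sel, class = c("freq_rep", "array"))
}

#' @export
print.freq_rep <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<freq_rep> %d frequency channels of %d x %d\n", d[3], d[1], d[2]))
  invisible(x)
}

#' Full frequency transform of one RGB image
#'
#' Runs the whole frontend: resize + centre-crop, YCbCr conversion, 4:2:0
#' chroma subsampling, blockwise DCT per plane, zigzag cube assembly, chroma
#' upsampling, channel selection and optional per-channel normalization.
#'
#' @inheritParams preprocess_image
#' @inheritParams assemble_representation
#' @param image_size Side of each output channel; defaults to 32.
#' @return A `freq_rep` array `(image_size, image_size, n_selected)`.
#' @export
#' @examples
#' img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
#' sel <- fixed_selection("full", S = 4)
#' rep <- transform_image(img, sel, filter_size = 4, image_size = 8)
#' dim(rep) # 8 x 8 x 48
transform_image <- function(img, sel, filter_size = 8, image_size = 32,
                            stats = NULL, upsample = c("nearest", "bilinear")) {
  img <- preprocess_image(img, filter_size, image_size)
  planes <- chroma_subsample_420(rgb_to_ycbcr(img))
  cubes <- lapply(
    stats::setNames(c("Y", "Cb", "Cr"), c("Y", "Cb", "Cr")),
    function(p) build_cube(block_dct(planes[[p]], filter_size), plane = p)
  )
  assemble_representation(cubes, sel, stats = stats, upsample = upsample)
}

#' Per-channel normalization statistics over a set of representations
#'
#' Computes the mean and standard deviation of every retained frequency
#' channel across a list of (unnormalized) representations, for reuse as the
#' `stats` argument of [assemble_representation()] / [transform_image()].
#' Computed from the training (source) split once and stored alongside the
#' channel selection.
#'
#' @param reps List of `freq_rep` arrays sharing one selection.
#' @return List with numeric vectors `mean` and `sd` (zero spread is
#'   replaced by 1 so constant channels pass through unscaled).
#' @export
channel_norm_stats <- function(reps) {
  stopifnot(length(reps) >= 1)
  n <- dim(reps[[1]])[3]
  per_channel <- vapply(reps, function(r) {
    apply(r, 3, function(ch) c(mean(ch), mean(ch^2)))
  }, matrix(0, 2, n))
  m1 <- rowMeans(per_channel[1, , , drop = FALSE], dims = 2)[1, ]
  m2 <- rowMeans(per_channel[2, , , drop = FALSE], dims = 2)[1, ]
  sds <- sqrt(pmax(m2 - m1^2, 0))
  sds[sds < 1e-12] <- 1
  list(mean = as.numeric(m1), sd = as.numeric(sds))
}
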