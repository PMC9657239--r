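PLANES <- c("Y", "Cb", "Cr")

#' An ordered set of retained frequency channels
#'
#' A channel selection is a tibble with one row per retained channel:
#' `plane` (one of `"Y"`, `"Cb"`, `"Cr"`) and `index` (0-based zigzag
#' frequency index, see [zigzag_index()]). Row order is the channel order of
#' the assembled representation. The filter size and, optionally, the
#' per-channel normalization statistics of the training split travel with
#' the selection.
#'
#' @param plane Character vector of plane names.
#' @param index Integer vector of zigzag indices, same length.
#' @param filter_size The DCT filter side the indices refer to.
#' @param norm_stats Optional list with `mean` and `sd` vectors (one per
#'   channel, selection order).
#' @return A tibble of class `channel_selection`.
#' @export
#' @examples
#' channel_selection(c("Y", "Cb"), c(0, 2), filter_size = 8)
channel_selection <- function(plane, index, filter_size, norm_stats = NULL) {
  filter_size <- check_filter_size(filter_size)
  plane <- as.character(plane)
  index <- as.integer(index)
  stopifnot(length(plane) == length(index))
  if (!all(plane %in% PLANES)) stop("planes must be Y, Cb or Cr", call. = FALSE)
  if (any(index < 0 | index >= filter_size^2)) {
    stop(sprintf("indices must lie in [0, %d)", filter_size^2), call. = FALSE)
  }
  if (anyDuplicated(paste(plane, index))) {
    stop("selection entries must be unique", call. = FALSE)
  }
  out <- tibble::tibble(plane = plane, index = index)
  attr(out, "filter_size") <- filter_size
  attr(out, "norm_stats") <- norm_stats
  class(out) <- c("channel_selection", class(out))
  out
}

as_channel_selection <- function(x) {
  if (!inherits(x, "channel_selection")) {
    stop("expected a `channel_selection`; build one with channel_selection() or fixed_selection()",
      call. = FALSE
    )
  }
  x
}

#' Rule-based channel selections
#'
#' Builds a selection without learned weights. Modes: `"full"` keeps all
#' `3 * S^2` channels; `"upper_tri_incl_diag"` keeps, per plane, the
#' low-frequency triangle `i + j <= S - 1` including the minor diagonal
#' (`3 * S(S+1)/2` channels, 108 for `S = 8`); `"upper_tri_excl_diag"` drops
#' the diagonal as well (`3 * S(S-1)/2`, 84 for `S = 8`); `"explicit"` keeps
#' user-supplied per-plane zigzag index lists verbatim (e.g. a published
#' top-N combination). Channels are ordered plane-major (Y, Cb, Cr) by
#' ascending zigzag index, except for `"explicit"` which preserves the given
#' order.
#'
#' Because the zigzag order walks anti-diagonals, the two triangular modes
#' are simply the first `S(S+1)/2` (resp. `S(S-1)/2`) zigzag indices of each
#' plane.
#'
#' @param mode Selection rule.
#' @param S Filter side length.
#' @param entries For `"explicit"`: named list of integer vectors, e.g.
#'   `list(Y = c(0, 1, 3), Cb = 0, Cr = c(0, 1))`.
#' @return A [channel_selection()].
#' @export
#' @examples
#' nrow(fixed_selection("upper_tri_incl_diag", 8)) # 108
fixed_selection <- function(mode = c("full", "upper_tri_incl_diag", "upper_tri_excl_diag", "explicit"),
                            S = 8, entries = NULL) {
  mode <- match.arg(mode)
  S <- check_filter_size(S)
  per_plane <- switch(mode,
    full = rep(list(0:(S^2 - 1L)), 3),
    upper_tri_incl_diag = rep(list(0:(S * (S + 1L) / 2L - 1L)), 3),
    upper_tri_excl_diag = rep(list(0:(S * (S - 1L) / 2L - 1L)), 3),
    explicit = {
      if (is.null(entries) || !all(names(entries) %in% PLANES)) {
        stop("`entries` must be a named list over Y/Cb/Cr", call. = FALSE)
      }
      lapply(PLANES, function(p) as.integer(entries[[p]]))
    }
  )
  plane <- rep(PLANES, times = lengths(per_plane))
  channel_selection(plane, unlist(per_plane), filter_size = S)
}

#' Per-channel squeeze-and-excitation gates for one sample
#'
#' The squeeze step global-average-pools each frequency channel to a scalar;
#' the excitation step passes the pooled vector through a two-layer
#' bottleneck (reduce by `reduction`, ReLU, expand, sigmoid), yielding one
#' gate in `(0, 1)` per channel. During frequency-mode pre-training the
#' gates both rescale the input channels and, aggregated over samples, rank
#' the channels by informativeness.
#'
#' @param x 3-D array `(h, w, n_channels)` (a `freq_rep` works).
#' @param params SE parameters from [se_init()].
#' @return Numeric vector of `n_channels` gate values in `(0, 1)`.
#' @export
se_gate <- function(x, params) {
  stopifnot(length(dim(x)) == 3)
  pooled <- apply(x, 3, mean)
  se_excite(pooled, params)
}

se_excite <- function(pooled, params) {
  h <- pmax(params$W1 %*% pooled + params$b1, 0)
  as.numeric(1 / (1 + exp(-(params$W2 %*% h + params$b2))))
}

#' Initialize a squeeze-and-excitation block
#'
#' @param n_channels Number of input channels.
#' @param reduction Bottleneck reduction ratio (default 16, the conventional
#'   setting). If `n_channels < reduction` the block falls back to
#'   `reduction = 1` with a warning.
#' @param seed Optional integer seed for reproducible initialization.
#' @return List of parameters (`W1`, `b1`, `W2`, `b2`); biases start at zero
#'   so an all-zero input yields gates of exactly 0.5.
#' @export
se_init <- function(n_channels, reduction = 16, seed = NULL) {
  stopifnot(n_channels >= 1, reduction >= 1)
  if (n_channels < reduction) {
    warning(sprintf(
      "n_channels (%d) < reduction (%d); falling back to reduction = 1",
      n_channels, reduction
    ))
    reduction <- 1
  }
  if (!is.null(seed)) set.seed(seed)
  hidden <- max(1L, n_channels %/% reduction)
  list(
    W1 = matrix(stats::rnorm(hidden * n_channels, sd = sqrt(2 / n_channels)), hidden, n_channels),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(n_channels * hidden, sd = sqrt(2 / hidden)), n_channels, hidden),
    b2 = rep(0, n_channels)
  )
}

#' Aggregate per-sample channel weights
#'
#' Averages squeeze-and-excitation gate vectors over samples into a single
#' per-channel ranking. All inputs must describe the same channel set.
#'
#' @param weights A `channel_weights` tibble with repeated `(plane, index)`
#'   rows, or a list of such tibbles; see [channel_weights()].
#' @return A [channel_weights()] tibble with one averaged row per channel
#'   and an `n_samples` attribute.
#' @export
aggregate_weights <- function(weights) {
  if (is.list(weights) && !is.data.frame(weights)) {
    keys <- lapply(weights, function(w) sort(paste(w$plane, w$index)))
    if (!all(vapply(keys, identical, logical(1), y = keys[[1]]))) {
      stop("samples cover different channel sets; cannot aggregate", call. = FALSE)
    }
    weights <- dplyr::bind_rows(weights)
  }
  stopifnot(nrow(weights) > 0)
  counts <- dplyr::count(weights, .data$plane, .data$index)
  if (length(unique(counts$n)) != 1) {
    stop("samples cover different channel sets; cannot aggregate", call. = FALSE)
  }
  out <- weights |>
    dplyr::group_by(.data$plane, .data$index) |>
    dplyr::summarise(weight = mean(.data$weight), .groups = "drop")
  channel_weights(out$plane, out$index, out$weight, n_samples = counts$n[1])
}

#' Per-channel attention weights
#'
#' @param plane,index Channel identity (see [channel_selection()]).
#' @param weight Nonnegative weights in `[0, 1]` (sigmoid gates).
#' @param n_samples Number of samples the weights aggregate.
#' @return Tibble of class `channel_weights`.
#' @export
channel_weights <- function(plane, index, weight, n_samples = 1L) {
  stopifnot(all(weight >= 0), all(weight <= 1))
  out <- tibble::tibble(
    plane = as.character(plane), index = as.integer(index),
    weight = as.numeric(weight)
  )
  attr(out, "n_samples") <- n_samples
  class(out) <- c("channel_weights", class(out))
  out
}

#' Select the top-N channels by learned weight
#'
#' Keeps the `n` channels with the largest aggregated weights. Ties are
#' broken deterministically: plane order Y < Cb < Cr, then ascending zigzag
#' index. The result is ordered plane-major by ascending index, the
#' convention used for published channel tables.
#'
#' @param weights A [channel_weights()] tibble (one row per channel).
#' @param n Number of channels to keep, `n <=` number of channels.
#' @param filter_size Filter side the indices refer to.
#' @return A [channel_selection()] of exactly `n` channels.
#' @export
select_top_n <- function(weights, n, filter_size = 8) {
  stopifnot(nrow(weights) >= 1)
  if (n > nrow(weights)) {
    stop(sprintf("n = %d exceeds the %d available channels", n, nrow(weights)), call. = FALSE)
  }
  ranked <- weights |>
    dplyr::mutate(.plane_ord = match(.data$plane, PLANES)) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$.plane_ord, .data$index) |>
    dplyr::slice_head(n = n) |>
    dplyr::arrange(.data$.plane_ord, .data$index)
  channel_selection(ranked$plane, ranked$index, filter_size = filter_size)
}

#' Write / read a channel selection as JSON
#'
#' Serializes the selection (filter size, ordered entries, optional
#' normalization statistics) to the interchange schema
#' `{"filter_size": 8, "entries": [["Y", 0], ...], "norm_stats": ...}`.
#'
#' @param sel A [channel_selection()].
#' @param path File path.
#' @return `write_selection()` returns `path` invisibly; `read_selection()`
#'   returns a [channel_selection()].
#' @export
write_selection <- function(sel, path) {
  sel <- as_channel_selection(sel)
  obj <- list(
    filter_size = attr(sel, "filter_size"),
    entries = purrr::map2(sel$plane, sel$index, ~ list(.x, .y))
  )
  ns <- attr(sel, "norm_stats")
  if (!is.null(ns)) obj$norm_stats <- list(mean = ns$mean, sd = ns$sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path)
  ns <- NULL
  if (!is.null(obj$norm_stats)) {
    ns <- list(
      mean = as.numeric(unlist(obj$norm_stats$mean)),
      sd = as.numeric(unlist(obj$norm_stats$sd))
    )
  }
  channel_selection(
    plane = vapply(obj$entries, function(e) as.character(e[[1]]), ""),
    index = vapply(obj$entries, function(e) as.integer(e[[2]]), 0L),
    filter_size = obj$filter_size,
    norm_stats = ns
  )
}

#' Plot learned channel weights or a selection on the zigzag grid
#'
#' Draws one `S x S` tile grid per plane with the zigzag-indexed frequencies;
#' for weights the fill encodes the learned gate, for selections the fill
#' marks retained channels.
#'
#' @param object A `channel_weights` or `channel_selection`.
#' @param filter_size Filter side (taken from the selection when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_weights <- function(object, filter_size = 8, ...) {
  zz <- zigzag_index(filter_size)
  df <- dplyr::left_join(object, zz, by = c(index = "k")) |>
    dplyr::mutate(plane = factor(.data$plane, PLANES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$weight)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "horizontal frequency", y = "vertical frequency",
      fill = "gate", title = "Learned frequency-channel weights"
    )
}

#' @rdname autoplot.channel_weights
#' @export
autoplot.channel_selection <- function(object, filter_size = NULL, ...) {
  S <- filter_size %||% attr(object, "filter_size")
  zz <- zigzag_index(S)
  grid <- tidyr::expand_grid(plane = factor(PLANES, PLANES), zz)
  df <- grid |>
    dplyr::left_join(
      dplyr::mutate(tibble::as_tibble(object),
        plane = factor(.data$plane, PLANES), selected = TRUE
      ),
      by = c("plane", k = "index")
    ) |>
    dplyr::mutate(selected = !is.na(.data$selected))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$selected)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "#2c7fb8")) +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "horizontal frequency", y = "vertical frequency",
      fill = "kept", title = "Retained frequency channels"
    )
}
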