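#' Sample one N-way/K-shot episode from a feature table
#'
#' Draws `n_way` classes without replacement, then for each class `k_shot +
#' n_query` distinct samples, split into a support set (which defines the
#' class centroids) and a query set (to be classified). Deterministic given
#' the R random seed.
#'
#' @param data Data frame with a `class` column and numeric feature columns,
#'   one row per sample.
#' @param n_way Number of classes per episode (5 is the standard setting).
#' @param k_shot Support samples per class.
#' @param n_query Query samples per class (default 15).
#' @return A list of class `episode` with tibbles `support` and `query` and
#'   the drawn `classes`.
#' @export
#' @examples
#' df <- generate_feature_clusters(synthetic_feature_spec(n_classes = 6, per_class = 25))
#' set.seed(1)
#' ep <- sample_episode(df, n_way = 5, k_shot = 1, n_query = 10)
#' nrow(ep$support) # 5
sample_episode <- function(data, n_way = 5, k_shot = 1, n_query = 15) {
  stopifnot(is.data.frame(data), "class" %in% names(data))
  classes <- unique(as.character(data$class))
  if (length(classes) < n_way) {
    stop(sprintf("need %d classes but only %d available", n_way, length(classes)),
      call. = FALSE
    )
  }
  need <- k_shot + n_query
  sizes <- table(as.character(data$class))
  too_small <- names(sizes)[sizes < need]
  if (length(too_small) > 0) {
    stop(sprintf(
      "classes with fewer than k_shot + n_query = %d samples: %s",
      need, paste(too_small, collapse = ", ")
    ), call. = FALSE)
  }
  drawn <- sample(classes, n_way)
  support <- vector("list", n_way)
  query <- vector("list", n_way)
  for (c_i in seq_along(drawn)) {
    rows <- which(as.character(data$class) == drawn[c_i])
    picked <- sample(rows, need)
    support[[c_i]] <- data[picked[seq_len(k_shot)], , drop = FALSE]
    query[[c_i]] <- data[picked[k_shot + seq_len(n_query)], , drop = FALSE]
  }
  structure(
    list(
      support = dplyr::bind_rows(support),
      query = dplyr::bind_rows(query),
      classes = drawn
    ),
    class = "episode"
  )
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf(
    "<episode> %d-way, %d support + %d query samples\n",
    length(x$classes), nrow(x$support), nrow(x$query)
  ))
  invisible(x)
}

feature_matrix <- function(data) {
  num <- vapply(data, is.numeric, logical(1))
  as.matrix(data[num])
}

#' Class centroids of a support set
#'
#' The centroid (prototype) of each class is the arithmetic mean of its
#' embedded support vectors; with `k_shot = 1` the centroid is the single
#' support vector itself.
#'
#' @param support Data frame with a `class` column and numeric feature
#'   columns.
#' @return A tibble with one row per class: `class` plus mean feature
#'   columns.
#' @export
compute_centroids <- function(support) {
  stopifnot(is.data.frame(support), "class" %in% names(support), nrow(support) >= 1)
  support |>
    dplyr::group_by(class = as.character(.data$class)) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean), .groups = "drop")
}

#' Cosine similarity of two vectors
#'
#' `sum(a * b) / (||a|| ||b||)`: the cosine of the angle between two
#' non-zero vectors, in `[-1, 1]`, invariant to positive rescaling of
#' either argument.
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector is undefined", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Class membership probabilities for one query vector
#'
#' Applies the Gaussian-like calibration to the query embedding and to every
#' centroid, computes cosine similarities, and converts them to a
#' probability vector with a softmax over the raw similarities (no
#' temperature: the exponent is the cosine itself).
#'
#' @param query Numeric query embedding.
#' @param centroids Tibble from [compute_centroids()], or a numeric matrix
#'   with one centroid per row.
#' @param calibrator A [calibrator_config()], or `NULL` to skip calibration.
#' @return A tibble with columns `class` and `probability` (summing to 1),
#'   ordered as the centroids.
#' @export
class_probabilities <- function(query, centroids, calibrator = NULL) {
  if (is.data.frame(centroids)) {
    cls <- as.character(centroids$class)
    cm <- feature_matrix(centroids)
  } else {
    cm <- as.matrix(centroids)
    cls <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  }
  if (length(query) != ncol(cm)) {
    stop(sprintf(
      "query has %d dimensions but centroids have %d",
      length(query), ncol(cm)
    ), call. = FALSE)
  }
  if (!is.null(calibrator)) {
    query <- calibrate(query, calibrator)
    cm <- t(apply(cm, 1, calibrate, config = calibrator))
  }
  sims <- apply(cm, 1, cosine_similarity, a = query)
  p <- exp(sims - max(sims))
  p <- p / sum(p)
  tibble::tibble(class = cls, probability = as.numeric(p))
}

#' Score every query of an episode
#'
#' @param episode An [sample_episode()] result (features already embedded).
#' @param calibrator Optional [calibrator_config()] applied to queries and
#'   centroids before distance measurement.
#' @return A tibble with one row per query: `true_class`, `predicted`,
#'   `correct`, `p_true` (probability assigned to the true class) and a
#'   list-column `probabilities`.
#' @export
score_episode <- function(episode, calibrator = NULL) {
  stopifnot(inherits(episode, "episode"))
  centroids <- compute_centroids(episode$support)
  cm <- feature_matrix(centroids)
  qm <- feature_matrix(episode$query)
  truth <- as.character(episode$query$class)
  if (!is.null(calibrator)) {
    cm <- t(apply(cm, 1, calibrate, config = calibrator))
    qm <- t(apply(qm, 1, calibrate, config = calibrator))
  }
  cn <- cm / sqrt(rowSums(cm^2))
  qn <- qm / sqrt(rowSums(qm^2))
  sims <- qn %*% t(cn) # cosine similarities, queries x classes
  p <- exp(sims - apply(sims, 1, max))
  p <- p / rowSums(p)
  colnames(p) <- centroids$class
  best <- max.col(p, ties.method = "first")
  tibble::tibble(
    true_class = truth,
    predicted = centroids$class[best],
    correct = centroids$class[best] == truth,
    p_true = p[cbind(seq_along(truth), match(truth, centroids$class))],
    probabilities = lapply(seq_along(truth), function(r) p[r, ])
  )
}

#' Mean cross-entropy loss over an episode's queries
#'
#' Average negative log-probability of the true class over all `N * W`
#' queries. Probabilities below `1e-12` are clamped (with a warning) to keep
#' the loss finite.
#'
#' @param scores Tibble from [score_episode()] (uses the `p_true` column).
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(scores) {
  p <- scores$p_true
  if (any(p < 1e-12)) {
    warning("true-class probabilities below 1e-12 were clamped")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

#' Episodic evaluation of a feature table
#'
#' Repeatedly samples N-way/K-shot episodes from pre-embedded features and
#' reports query accuracy per episode, grouped into epochs (the headline
#' number of an evaluation is the mean accuracy over all episodes of all
#' epochs).
#'
#' @inheritParams sample_episode
#' @param episodes Episodes per epoch (600 is the community convention for
#'   a full evaluation; use fewer at desk scale).
#' @param epochs Number of evaluation epochs (10 for a full evaluation).
#' @param calibrator Optional [calibrator_config()].
#' @param seed Optional integer seed; the evaluation is reproducible given
#'   the seed.
#' @return An object of class `fewshot_eval`: per-episode results plus the
#'   configuration. Use [tidy()] for per-episode rows, [glance()] for the
#'   one-row summary, and [autoplot()] for an accuracy histogram.
#' @export
#' @examples
#' df <- generate_feature_clusters(synthetic_feature_spec())
#' ev <- evaluate_episodes(df, n_way = 5, k_shot = 5, episodes = 20, seed = 1)
#' glance(ev)
evaluate_episodes <- function(data, n_way = 5, k_shot = 1, n_query = 15,
                              episodes = 100, epochs = 1, calibrator = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- tidyr::expand_grid(epoch = seq_len(epochs), episode = seq_len(episodes))
  res$accuracy <- NA_real_
  res$loss <- NA_real_
  for (r in seq_len(nrow(res))) {
    ep <- sample_episode(data, n_way = n_way, k_shot = k_shot, n_query = n_query)
    sc <- score_episode(ep, calibrator = calibrator)
    res$accuracy[r] <- mean(sc$correct)
    res$loss[r] <- suppressWarnings(cross_entropy_loss(sc))
  }
  structure(
    list(
      results = res,
      config = list(
        n_way = n_way, k_shot = k_shot, n_query = n_query,
        episodes = episodes, epochs = epochs,
        calibrated = !is.null(calibrator), seed = seed
      )
    ),
    class = "fewshot_eval"
  )
}

#' @export
print.fewshot_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fewshot_eval> %d-way %d-shot, %d episodes x %d epochs%s\n  mean accuracy %.2f%% (95%% CI +/- %.2f)\n",
    x$config$n_way, x$config$k_shot, x$config$episodes, x$config$epochs,
    if (x$config$calibrated) ", calibrated" else "",
    g$mean_accuracy, g$ci95
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-episode results of an episodic evaluation
#'
#' @param x A `fewshot_eval` object.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `episode`, `accuracy` (in percent)
#'   and `loss`.
#' @export
tidy.fewshot_eval <- function(x, ...) {
  dplyr::mutate(x$results, accuracy = 100 * .data$accuracy)
}

#' One-row summary of an episodic evaluation
#'
#' @param x A `fewshot_eval` object.
#' @param ... Unused.
#' @return A tibble with the overall mean accuracy (percent), its 95%
#'   confidence half-width over episodes, the mean loss, episode counts and
#'   the chance level `100 / n_way`.
#' @export
glance.fewshot_eval <- function(x, ...) {
  acc <- 100 * x$results$accuracy
  n <- length(acc)
  tibble::tibble(
    mean_accuracy = mean(acc),
    ci95 = 1.96 * stats::sd(acc) / sqrt(n),
    mean_loss = mean(x$results$loss),
    n_episodes = n,
    n_way = x$config$n_way,
    k_shot = x$config$k_shot,
    chance = 100 / x$config$n_way
  )
}

#' Histogram of per-episode accuracies
#'
#' @param object A `fewshot_eval` object.
#' @param ... Unused.
#' @return A ggplot object with the chance level marked.
#' @export
autoplot.fewshot_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2c7fb8", color = "white") +
    ggplot2::geom_vline(
      xintercept = 100 / object$config$n_way,
      linetype = "dashed", color = "grey40"
    ) +
    ggplot2::labs(
      x = "episode accuracy (%)", y = "episodes",
      title = sprintf(
        "%d-way %d-shot episodic accuracy",
        object$config$n_way, object$config$k_shot
      )
    )
}

#' Concatenate spatial and frequency embeddings
#'
#' Joins the two domain embeddings of one sample into a single
#' representation, spatial first.
#'
#' @param v_spatial,v_freq Numeric vectors (either may be empty).
#' @return The concatenated vector.
#' @export
concat_spatial_frequency <- function(v_spatial, v_freq) {
  c(v_spatial, v_freq)
}
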