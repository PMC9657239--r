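#' Read an RGB image as an intensity array
#'
#' Loads PNG directly and other formats (JPEG, TIFF) through EBImage,
#' returning the `H x W x 3` array of intensities in `[0, 255]` the rest of
#' the pipeline expects. Grayscale images are expanded to three channels.
#'
#' @param path Image file path.
#' @return Numeric `H x W x 3` array.
#' @export
load_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] == 1) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE] # drop alpha
  img * 255
}

#' List a directory-per-class image dataset
#'
#' @param dir Dataset root: one subdirectory per class containing images.
#' @return A tibble with `path` and `class` columns.
#' @export
image_manifest <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE)
  if (length(classes) == 0) stop("no class subdirectories in ", dir, call. = FALSE)
  purrr::map_dfr(classes, function(d) {
    files <- list.files(d, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE, full.names = TRUE)
    tibble::tibble(path = files, class = basename(d))
  })
}

#' Transform a batch of images to frequency representations
#'
#' @param images List of `H x W x 3` arrays.
#' @param sel A [channel_selection()].
#' @inheritParams transform_image
#' @return List of `freq_rep` arrays.
#' @export
transform_images <- function(images, sel, filter_size = 8, image_size = 32,
                             stats = NULL, upsample = "nearest") {
  lapply(images, transform_image,
    sel = sel, filter_size = filter_size,
    image_size = image_size, stats = stats, upsample = upsample
  )
}

#' Learn a top-N frequency-channel selection with SE attention
#'
#' Pre-trains a small encoder on the full channel set of the source split
#' with a squeeze-and-excitation block in front; the per-channel gates,
#' averaged over every sample of the final epoch, rank the channels, and the
#' top `n` are kept. The encoder trained here is discarded — after selection
#' a fresh encoder is built for the reduced channel count and retrained,
#' since its first-layer shape changes.
#'
#' @param reps List of full-channel `freq_rep` arrays (source split).
#' @param labels Class labels, one per representation.
#' @param n Number of channels to keep.
#' @param filter_size DCT filter side the representations used.
#' @param reduction SE bottleneck reduction ratio (default 16).
#' @param epochs Pre-training epochs for the selection pass; the gate
#'   ranking needs several epochs to separate informative channels from the
#'   sigmoid's 0.5 starting point (default 12).
#' @param seed Integer seed.
#' @param embedding_dim Embedding width of the throwaway selection encoder.
#' @return A list: `selection` (a [channel_selection()]), `weights` (the
#'   aggregated [channel_weights()]), and the selection-pass `loss` history.
#' @export
learn_channel_selection <- function(reps, labels, n = 24, filter_size = 8,
                                    reduction = 16, epochs = 12, seed = 0,
                                    embedding_dim = 64) {
  stopifnot(length(reps) == length(labels), length(reps) > 0)
  full_sel <- attr(reps[[1]], "channels")
  n_channels <- dim(reps[[1]])[3]
  se <- se_init(n_channels, reduction = reduction, seed = seed)
  enc <- build_encoder(
    encoder_spec("tiny_cnn", in_channels = n_channels, embedding_dim = embedding_dim),
    seed = seed
  )
  fit <- pretrain(enc, reps, labels,
    epochs = epochs, seed = seed,
    se = se, channels = full_sel
  )
  list(
    selection = select_top_n(fit$se_gates, n, filter_size = filter_size),
    weights = fit$se_gates,
    loss = fit$loss
  )
}

#' Embed a set of representations into a feature table
#'
#' @param reps List of 3-D arrays matching the encoder's input channels.
#' @param labels Class labels, one per representation.
#' @param encoder An `fs_encoder` (typically the encoder of a [pretrain()]
#'   fit).
#' @return A tibble with `class` and embedding columns `V1..Vd`.
#' @export
embed_dataset <- function(reps, labels, encoder) {
  stopifnot(length(reps) == length(labels))
  m <- t(vapply(
    reps, function(r) encoder_embed(encoder, r),
    numeric(encoder$spec$embedding_dim)
  ))
  colnames(m) <- paste0("V", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(class = as.character(labels)), tibble::as_tibble(m))
}

#' Configuration of a full episodic experiment
#'
#' Collects every knob of the end-to-end pipeline. `domains` and `gc` define
#' the comparison grid (the canonical ablation is spatial vs. frequency,
#' each with and without Gaussian-like calibration). With `data = NULL` a
#' synthetic leaf dataset is generated from `image_spec`.
#'
#' @param domains Subset of `c("spatial", "freq")`.
#' @param gc Logical vector: evaluate with calibration on, off, or both.
#' @param filter_size,image_size DCT frontend geometry.
#' @param selection `"learned"`, `"full"`, `"upper_tri_incl_diag"`,
#'   `"upper_tri_excl_diag"`, or a [channel_selection()] used verbatim.
#' @param top_n Channels kept when `selection = "learned"`.
#' @param beta Power-transform exponent of the calibrator.
#' @param n_way,k_shot,n_query,episodes,eval_epochs Episodic evaluation
#'   parameters.
#' @param pretrain_epochs,lr,batch_size Encoder pre-training parameters.
#' @param selection_epochs Epochs of the SE selection pass (the gate ranking
#'   needs longer than the downstream encoder to stabilize; default 12).
#' @param architecture Encoder backbone (see [encoder_spec()]).
#' @param embedding_dim Embedding width.
#' @param spatial_size Input side for the spatial-domain branch.
#' @param data Dataset directory (directory-per-class with a
#'   `manifest.json` naming the source/target split), or `NULL` for
#'   synthetic data.
#' @param image_spec [synthetic_image_spec()] used when `data` is `NULL`.
#' @param seed Master seed; all randomness (generation, training,
#'   episodes) derives from it.
#' @return A `run_config` list with a stable hash.
#' @export
run_config <- function(domains = c("spatial", "freq"), gc = c(FALSE, TRUE),
                       filter_size = 4, image_size = 16,
                       selection = "learned", top_n = 12, beta = 0.5,
                       n_way = 5, k_shot = 5, n_query = 15, episodes = 100,
                       eval_epochs = 1, pretrain_epochs = 5,
                       selection_epochs = 12, lr = 0.01,
                       batch_size = 16, architecture = "tiny_cnn",
                       embedding_dim = 64, spatial_size = 32,
                       data = NULL, image_spec = NULL, seed = 0) {
  domains <- match.arg(domains, c("spatial", "freq"), several.ok = TRUE)
  if (is.null(image_spec) && is.null(data)) {
    image_spec <- synthetic_image_spec(seed = seed)
  }
  if (is.character(selection)) {
    selection <- match.arg(
      selection,
      c("learned", "full", "upper_tri_incl_diag", "upper_tri_excl_diag")
    )
  } else {
    sel_fs <- attr(as_channel_selection(selection), "filter_size")
    if (sel_fs != filter_size) {
      stop(sprintf(
        "selection filter_size (%d) does not match transform filter_size (%d)",
        sel_fs, filter_size
      ), call. = FALSE)
    }
  }
  cfg <- list(
    domains = domains, gc = gc, filter_size = filter_size,
    image_size = image_size, selection = selection, top_n = top_n,
    beta = beta, n_way = n_way, k_shot = k_shot, n_query = n_query,
    episodes = episodes, eval_epochs = eval_epochs,
    pretrain_epochs = pretrain_epochs, selection_epochs = selection_epochs,
    lr = lr, batch_size = batch_size,
    architecture = architecture, embedding_dim = embedding_dim,
    spatial_size = spatial_size, data = data, image_spec = image_spec,
    seed = seed
  )
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Run the end-to-end episodic experiment grid
#'
#' Executes the full pipeline for every requested domain: (frequency)
#' DCT-transform the images, learn or fix a channel selection on the source
#' split, compute normalization statistics, pre-train an encoder, embed the
#' target split, and evaluate N-way/K-shot episodes with and/or without the
#' Gaussian-like calibrator; (spatial) the same with normalized RGB inputs
#' and crop/flip augmentation. Source and target class sets are disjoint by
#' construction, so the evaluation measures generalization to novel classes.
#'
#' @param cfg A [run_config()].
#' @param verbose Print progress lines.
#' @return A `fewshot_experiment`: a results tibble (one row per
#'   domain x calibration cell with accuracy, CI, channel count, config
#'   hash, seed) plus the per-domain evaluation objects.
#' @export
run_experiment <- function(cfg = run_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(cfg$seed)

  # ---- data ----
  if (is.null(cfg$data)) {
    say("generating synthetic dataset (%d classes)", nrow(cfg$image_spec$classes))
    ds <- generate_images(cfg$image_spec)
    images <- ds$images
    labels <- ds$labels
  } else {
    manifest <- image_manifest(cfg$data)
    meta <- jsonlite::read_json(file.path(cfg$data, "manifest.json"), simplifyVector = TRUE)
    split_map <- stats::setNames(meta$classes$split, meta$classes$name)
    images <- lapply(manifest$path, load_image)
    labels <- tibble::tibble(class = manifest$class, split = split_map[manifest$class])
  }
  src <- which(labels$split == "source")
  tgt <- which(labels$split == "target")
  if (length(intersect(unique(labels$class[src]), unique(labels$class[tgt]))) > 0) {
    stop("source and target class sets must be disjoint", call. = FALSE)
  }

  evals <- list()
  rows <- list()
  calib <- calibrator_config(beta = cfg$beta)

  for (domain in cfg$domains) {
    if (domain == "freq") {
      say("frequency branch: transform + selection")
      if (is.character(cfg$selection) && cfg$selection == "learned") {
        full_sel <- fixed_selection("full", S = cfg$filter_size)
        full_reps <- transform_images(images[src], full_sel,
          filter_size = cfg$filter_size, image_size = cfg$image_size
        )
        full_stats <- channel_norm_stats(full_reps)
        full_reps <- lapply(full_reps, function(r) {
          structure(sweep3(r, full_stats), channels = full_sel, class = class(r))
        })
        learned <- learn_channel_selection(full_reps, labels$class[src],
          n = cfg$top_n, filter_size = cfg$filter_size,
          epochs = cfg$selection_epochs, seed = cfg$seed
        )
        sel <- learned$selection
      } else if (is.character(cfg$selection)) {
        sel <- fixed_selection(cfg$selection, S = cfg$filter_size)
      } else {
        sel <- cfg$selection
      }
      raw_src <- transform_images(images[src], sel,
        filter_size = cfg$filter_size, image_size = cfg$image_size
      )
      stats <- channel_norm_stats(raw_src)
      reps_src <- lapply(raw_src, function(r) structure(sweep3(r, stats), channels = sel, class = class(r)))
      reps_tgt <- transform_images(images[tgt], sel,
        filter_size = cfg$filter_size, image_size = cfg$image_size, stats = stats
      )
      n_channels <- nrow(sel)
      augment <- NULL
    } else {
      say("spatial branch: resize + normalize")
      sel <- NULL
      n_channels <- 3L
      reps_src <- lapply(images[src], function(im) {
        normalize_rgb(resize_rgb(im, cfg$spatial_size, cfg$spatial_size))
      })
      reps_tgt <- lapply(images[tgt], function(im) {
        normalize_rgb(resize_rgb(im, cfg$spatial_size, cfg$spatial_size))
      })
      # crop/flip operates on the already-normalized arrays (range-agnostic)
      augment <- function(im) spatial_augment(im, cfg$spatial_size)
    }
    say("pre-training %s encoder (%d channels)", cfg$architecture, n_channels)
    enc <- build_encoder(
      encoder_spec(cfg$architecture, in_channels = n_channels, embedding_dim = cfg$embedding_dim),
      seed = cfg$seed
    )
    fit <- pretrain(enc, reps_src, labels$class[src],
      epochs = cfg$pretrain_epochs, batch_size = cfg$batch_size,
      lr = cfg$lr, seed = cfg$seed, augment = augment
    )
    say("embedding target split (%d images)", length(tgt))
    feats <- embed_dataset(reps_tgt, labels$class[tgt], fit$encoder)
    for (use_gc in cfg$gc) {
      ev <- evaluate_episodes(feats,
        n_way = cfg$n_way, k_shot = cfg$k_shot,
        n_query = cfg$n_query, episodes = cfg$episodes,
        epochs = cfg$eval_epochs,
        calibrator = if (use_gc) calib else NULL,
        seed = cfg$seed
      )
      g <- glance(ev)
      key <- paste0(domain, if (use_gc) "_gc")
      evals[[key]] <- ev
      rows[[key]] <- tibble::tibble(
        domain = domain, gc = use_gc,
        n_way = cfg$n_way, k_shot = cfg$k_shot,
        accuracy = g$mean_accuracy, ci95 = g$ci95,
        n_channels = n_channels, episodes = g$n_episodes,
        config_hash = cfg$hash, seed = cfg$seed
      )
      say("%s | gc %s: %.2f%%", domain, use_gc, g$mean_accuracy)
    }
  }
  structure(
    list(results = dplyr::bind_rows(rows), evals = evals, config = cfg),
    class = "fewshot_experiment"
  )
}

# standardize the channels of one 3-D representation
sweep3 <- function(r, stats) {
  for (k in seq_len(dim(r)[3])) {
    r[, , k] <- (r[, , k] - stats$mean[k]) / stats$sd[k]
  }
  r
}

#' @export
print.fewshot_experiment <- function(x, ...) {
  cat("<fewshot_experiment>\n")
  print(x$results[c("domain", "gc", "k_shot", "accuracy", "ci95", "n_channels")])
  invisible(x)
}

#' @export
tidy.fewshot_experiment <- function(x, ...) x$results

#' @export
autoplot.fewshot_experiment <- function(object, ...) {
  df <- object$results |>
    dplyr::mutate(setting = paste0(.data$domain, ifelse(.data$gc, " + GC", "")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setting, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$accuracy - .data$ci95,
        ymax = .data$accuracy + .data$ci95
      ),
      width = 0.2
    ) +
    ggplot2::geom_hline(
      yintercept = 100 / object$config$n_way,
      linetype = "dashed", color = "grey40"
    ) +
    ggplot2::labs(
      x = NULL, y = "accuracy (%)",
      title = sprintf(
        "%d-way %d-shot accuracy by domain and calibration",
        object$config$n_way, object$config$k_shot
      )
    )
}
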