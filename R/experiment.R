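#' Pipeline configuration
#'
#' Bundles every tunable of the annotation pipeline. The defaults are the
#' reference operating point: CLAHE 8x8 tiles / clip 0.01, non-local means
#' with radii 4 and h = 0.05, padding to 512, dense SIFT at step 4 on bin
#' sizes 4/6/8/10, a codebook of k = 1,000 words built with at most 20
#' ANN k-means iterations from up to 1,000 descriptors per image, 2x2
#' spatial histograms (4,000 dimensions at the default k), PCA to 100
#' dimensions, and bagged random forests with 1,000 deep trees.
#'
#' @param clahe,nlm,pad Enhancement parameter objects.
#' @param step,bin_sizes,contrast_threshold Dense-SIFT settings.
#' @param k Codebook size.
#' @param pool_cap Maximum descriptors contributed per image to the
#'   clustering pool.
#' @param kmeans_iter Maximum k-means iterations.
#' @param max_comparisons Quantization search budget (`Inf` = exact).
#' @param pca_dim Retained PCA dimensions.
#' @param normalize_hist L1-normalize spatial histograms.
#' @param n_trees,features_per_split Random-forest settings.
#' @param modes Input modes evaluated by [run_experiment()].
#' @param schemes Classification schemes evaluated.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(clahe = clahe_params(), nlm = nlm_params(),
                       pad = pad_params(),
                       step = 4, bin_sizes = c(4, 6, 8, 10),
                       contrast_threshold = 0.005,
                       k = 1000, pool_cap = 1000, kmeans_iter = 20,
                       max_comparisons = Inf, pca_dim = 100,
                       normalize_hist = FALSE,
                       n_trees = 1000, features_per_split = NULL,
                       modes = input_modes(), schemes = scheme_ids(),
                       seed = 1) {
  stopifnot(k >= 1, pool_cap >= 1, pca_dim >= 1, n_trees >= 1,
            all(modes %in% input_modes()), all(schemes %in% scheme_ids()))
  structure(list(clahe = clahe, nlm = nlm, pad = pad,
                 step = step, bin_sizes = bin_sizes,
                 contrast_threshold = contrast_threshold,
                 k = as.integer(k), pool_cap = as.integer(pool_cap),
                 kmeans_iter = as.integer(kmeans_iter),
                 max_comparisons = max_comparisons,
                 pca_dim = as.integer(pca_dim),
                 normalize_hist = isTRUE(normalize_hist),
                 n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 modes = modes, schemes = schemes,
                 seed = as.integer(seed)),
            class = "run_config")
}

# ---- internal: one-pass descriptor extraction with 8-bit caching -----------

# While a mode is processed, each image's multi-scale descriptor field is
# held in 8-bit fixed point (round(v * 255), the conventional SIFT storage
# format), keeping hundreds of images' descriptors within a couple of GB.
# The codebook pool is sampled from the full-precision descriptors at
# extraction time; quantization then reads the packed bytes directly.
extract_image_features <- function(img, mode, cfg, pool_n = 0, pool_seed = 1) {
  # layered modes feed the luminance of (original, CLAHE, NLM) to the
  # descriptor stage; computing the weighted sum directly avoids building
  # the 3-channel array and collapsing it again (same arithmetic as
  # luminance(stack_layers(...)))
  gray <- switch(mode,
    layered = {
      cl <- apply_clahe(img, cfg$clahe)
      nl <- apply_nl_means(img, cfg$nlm)
      0.299 * img + 0.587 * cl + 0.114 * nl
    },
    padded_layered = {
      p <- pad_with_repetition(img, cfg$pad)
      cl <- apply_clahe(p, cfg$clahe)
      nl <- apply_nl_means(p, cfg$nlm)
      0.299 * p + 0.587 * cl + 0.114 * nl
    },
    {
      prep <- prepare_input(img, mode, cfg$clahe, cfg$nlm, cfg$pad)
      if (is_layered(prep)) pmin(pmax(luminance(prep), 0), 1) else prep
    })
  gray <- pmin(pmax(gray, 0), 1)
  ds <- dense_sift(gray, step = cfg$step, bin_sizes = cfg$bin_sizes,
                   contrast_threshold = cfg$contrast_threshold)
  keep <- !ds$low_contrast
  pool <- NULL
  if (pool_n > 0 && any(keep)) {
    kept_idx <- which(keep)
    take <- min(pool_n, length(kept_idx))
    sel <- with_seed(pool_seed, sample.int(length(kept_idx), take))
    pool <- ds$descriptors[kept_idx[sort(sel)], , drop = FALSE]
  }
  list(desc_raw = pack_descriptors_cpp(ds$descriptors, keep),
       n = sum(keep),
       frames = ds$frames[keep, , drop = FALSE],
       size = dim(gray),
       pool = pool)
}

quantize_packed <- function(ex, book) {
  if (ex$n == 0) return(integer(0))
  quantize_packed_cpp(ex$desc_raw, ncol(book$centers), book$centers)$idx
}

#' Fit a multi-axial annotation model on a training table
#'
#' Runs the full Bag-of-Keypoints pipeline for one input mode: prepares every
#' training image, extracts multi-scale dense SIFT, builds the visual
#' codebook from a seeded per-image descriptor sample (training images only),
#' forms 2x2 spatial word histograms, fits the PCA reduction (training
#' features only) and trains one random forest per classification scheme.
#'
#' @param table Training label table.
#' @param image_dir Directory holding the training images.
#' @param mode One of [input_modes()].
#' @param config A [run_config()].
#' @param verbose Emit progress messages.
#' @return An object of class `irma_annotator` with `predict`, `print`
#'   methods.
#' @export
fit_annotator <- function(table, image_dir, mode, config = run_config(),
                          verbose = FALSE) {
  table <- validate_label_table(table)
  stopifnot(inherits(config, "run_config"), mode %in% input_modes())
  n <- nrow(table)
  if (n < 2) stop("training needs at least two images")
  say <- function(...) if (verbose) message(sprintf(...))

  say("[%s] extracting descriptors from %d training images", mode, n)
  cache <- vector("list", n)
  pool <- vector("list", n)
  for (i in seq_len(n)) {
    img <- read_gray_image(file.path(image_dir, table$image_id[i]))
    cache[[i]] <- extract_image_features(
      img, mode, config, pool_n = config$pool_cap,
      pool_seed = derive_seed(config$seed,
                              paste("pool", mode, table$image_id[i])))
    pool[[i]] <- cache[[i]]$pool
    cache[[i]]$pool <- NULL
  }
  pool <- do.call(rbind, pool[!vapply(pool, is.null, logical(1))])
  if (is.null(pool) || nrow(pool) < config$k)
    stop(sprintf("descriptor pool (%d) is smaller than k = %d",
                 if (is.null(pool)) 0L else nrow(pool), config$k))

  say("[%s] clustering %d pooled descriptors into %d words",
      mode, nrow(pool), config$k)
  book <- build_codebook(pool, k = config$k, max_iter = config$kmeans_iter,
                         seed = derive_seed(config$seed, paste("codebook", mode)),
                         max_comparisons = config$max_comparisons)

  say("[%s] quantizing and pooling spatial histograms", mode)
  feats <- matrix(0, n, 4 * config$k)
  for (i in seq_len(n)) {
    feats[i, ] <- spatial_histogram(cache[[i]]$frames,
                                    quantize_packed(cache[[i]], book),
                                    cache[[i]]$size, config$k,
                                    normalize = config$normalize_hist)
    cache[i] <- list(NULL)    # free the packed descriptors, keep indices
  }

  pca_dim <- min(config$pca_dim, n - 1, ncol(feats))
  pca <- fit_pca(feats, out_dim = pca_dim)
  reduced <- apply_pca(pca, feats)

  forests <- list()
  for (scheme in config$schemes) {
    labels <- project_codes(table$irma_code, scheme)
    say("[%s] training %d-tree forest for scheme %s (%d classes)",
        mode, config$n_trees, scheme, length(unique(labels)))
    forests[[scheme]] <- train_random_forest(
      reduced, labels,
      rf_config(n_trees = config$n_trees,
                features_per_split = config$features_per_split,
                seed = derive_seed(config$seed, paste("rf", mode, scheme))))
  }

  structure(list(mode = mode, config = config, codebook = book, pca = pca,
                 forests = forests,
                 train_ids = table$image_id,
                 train_features = reduced,
                 train_labels = table$irma_code),
            class = "irma_annotator")
}

#' @export
print.irma_annotator <- function(x, ...) {
  cat(sprintf(
    "<irma_annotator> mode '%s': k = %d words, PCA -> %d, forests: %s (%d training images)\n",
    x$mode, x$codebook$k, x$pca$out_dim,
    paste(names(x$forests), collapse = ", "), length(x$train_ids)))
  invisible(x)
}

#' Annotate images with a fitted model
#'
#' @param object An `irma_annotator`.
#' @param table Label table of the images to annotate (labels are not used
#'   for prediction, only carried through).
#' @param image_dir Directory holding the images.
#' @param ... Unused.
#' @return A list with `labels` (data.frame, one column per scheme),
#'   `features` (reduced feature matrix) and `image_id`.
#' @export
predict.irma_annotator <- function(object, table, image_dir, ...) {
  table <- validate_label_table(table)
  cfg <- object$config
  n <- nrow(table)
  feats <- matrix(0, n, 4 * object$codebook$k)
  for (i in seq_len(n)) {
    img <- read_gray_image(file.path(image_dir, table$image_id[i]))
    ex <- extract_image_features(img, object$mode, cfg)
    feats[i, ] <- spatial_histogram(ex$frames, quantize_packed(ex, object$codebook),
                                    ex$size, object$codebook$k,
                                    normalize = cfg$normalize_hist)
  }
  reduced <- apply_pca(object$pca, feats)
  out <- data.frame(row.names = seq_len(n))
  for (scheme in names(object$forests))
    out[[scheme]] <- predict(object$forests[[scheme]], reduced)$labels
  list(labels = out, features = reduced, image_id = table$image_id)
}

#' Run the full input-mode x scheme annotation experiment
#'
#' For every requested input mode the pipeline is fit on the training table
#' (codebook and PCA see training images only) and evaluated on the test
#' table, producing the accuracy matrix with input modes as rows and
#' classification schemes as columns.
#'
#' @param train_table,test_table Label tables.
#' @param train_dir,test_dir Image directories (may be the same directory).
#' @param config A [run_config()]; its `modes` and `schemes` select the
#'   matrix cells.
#' @param keep_features Keep the reduced train/test feature matrices per mode
#'   in the report (for downstream analyses).
#' @param verbose Emit progress messages.
#' @return An object of class `annotation_report`.
#' @export
run_experiment <- function(train_table, train_dir, test_table, test_dir,
                           config = run_config(), keep_features = FALSE,
                           verbose = FALSE) {
  train_table <- validate_label_table(train_table)
  test_table <- validate_label_table(test_table)
  modes <- config$modes
  schemes <- config$schemes
  if (length(modes) < 1 || length(schemes) < 1)
    stop("at least one input mode and one scheme are required")
  # canonical report row order
  modes <- input_modes()[input_modes() %in% modes]

  acc <- matrix(NA_real_, length(modes), length(schemes),
                dimnames = list(input_mode_labels(modes), schemes))
  n_classes <- acc
  timings <- stats::setNames(numeric(length(modes)), modes)
  features <- if (keep_features) list() else NULL
  unseen <- list()

  for (m in seq_along(modes)) {
    mode <- modes[m]
    t0 <- proc.time()[["elapsed"]]
    model <- withCallingHandlers(
      fit_annotator(train_table, train_dir, mode, config, verbose = verbose),
      error = function(e) stop(sprintf("stage 'fit' failed for mode '%s': %s",
                                       mode, conditionMessage(e))))
    pred <- tryCatch(
      predict(model, test_table, test_dir),
      error = function(e) stop(sprintf("stage 'predict' failed for mode '%s': %s",
                                       mode, conditionMessage(e))))
    for (s in seq_along(schemes)) {
      scheme <- schemes[s]
      truth <- project_codes(test_table$irma_code, scheme)
      train_classes <- unique(project_codes(train_table$irma_code, scheme))
      novel <- setdiff(unique(truth), train_classes)
      if (length(novel) > 0)
        unseen[[paste(mode, scheme)]] <- novel
      acc[m, s] <- evaluate_accuracy(pred$labels[[scheme]], truth)
      n_classes[m, s] <- length(train_classes)
    }
    timings[mode] <- proc.time()[["elapsed"]] - t0
    if (keep_features)
      features[[mode]] <- list(train = model$train_features,
                               train_labels = train_table$irma_code,
                               test = pred$features,
                               test_labels = test_table$irma_code)
  }

  structure(list(accuracy = acc, n_classes = n_classes,
                 modes = modes, schemes = schemes,
                 n_train = nrow(train_table), n_test = nrow(test_table),
                 unseen_test_classes = unseen,
                 config = config,
                 config_hash = object_hash(config),
                 seed = config$seed,
                 timings = timings,
                 features = features),
            class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("<annotation_report> %d train / %d test images, seed %d, config %s\n",
              x$n_train, x$n_test, x$seed, x$config_hash))
  print(round(x$accuracy, 4))
  if (length(x$unseen_test_classes) > 0)
    cat(sprintf("note: %d (mode, scheme) cells had test classes absent from training\n",
                length(x$unseen_test_classes)))
  invisible(x)
}

#' @export
as.data.frame.annotation_report <- function(x, ...) {
  data.frame(input_image = rownames(x$accuracy),
             as.data.frame(x$accuracy),
             check.names = FALSE, row.names = NULL)
}

#' Write an experiment report as CSV plus a JSON run manifest
#'
#' The CSV holds the accuracy matrix (rows = input modes under their display
#' names, columns = schemes) and is byte-reproducible for a fixed seed. The
#' JSON manifest carries seeds, the configuration, per-mode wall times and
#' class counts.
#'
#' @param report An `annotation_report`.
#' @param csv_path,json_path Output paths (`NULL` skips either file).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "annotation_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(json_path)) {
    manifest <- list(
      seed = report$seed,
      config_hash = report$config_hash,
      n_train = report$n_train, n_test = report$n_test,
      modes = report$modes, schemes = report$schemes,
      accuracy = as.data.frame(report),
      n_classes = report$n_classes,
      timings_sec = as.list(round(report$timings, 3)),
      config = unclass_config(report$config))
    jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csv = csv_path, json = json_path))
}

# strip S3 classes so a config serializes cleanly to JSON/YAML
unclass_config <- function(cfg) {
  out <- unclass(cfg)
  for (nm in c("clahe", "nlm", "pad")) out[[nm]] <- unclass(out[[nm]])
  out$max_comparisons <- if (is.finite(out$max_comparisons))
    out$max_comparisons else "exact"
  out
}
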