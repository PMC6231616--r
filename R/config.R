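#' Read and write pipeline configurations as YAML
#'
#' A configuration file mirrors the [run_config()] structure with nested
#' `clahe`, `nlm` and `pad` sections; omitted entries fall back to the
#' defaults, so a file only needs the settings it overrides. Configurations
#' round-trip: `read_run_config(write_run_config(cfg, path))` reproduces
#' `cfg`.
#'
#' @param path YAML file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config A [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass_config(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @param x A plain nested list (e.g. parsed YAML) with `run_config` fields.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  stopifnot(is.list(x))
  cl <- x$clahe %||% list()
  nl <- x$nlm %||% list()
  pd <- x$pad %||% list()
  mc <- x$max_comparisons %||% Inf
  if (identical(mc, "exact")) mc <- Inf
  run_config(
    clahe = clahe_params(
      num_tiles = cl$num_tiles %||% c(8, 8),
      clip_limit = cl$clip_limit %||% 0.01,
      n_bins = cl$n_bins %||% 256,
      distribution = cl$distribution %||% "uniform",
      alpha = cl$alpha %||% 0.4),
    nlm = nlm_params(
      kernel_radius = nl$kernel_radius %||% 4,
      window_radius = nl$window_radius %||% 4,
      filter_strength = nl$filter_strength %||% 0.05),
    pad = pad_params(target_side = pd$target_side %||% 512),
    step = x$step %||% 4,
    bin_sizes = x$bin_sizes %||% c(4, 6, 8, 10),
    contrast_threshold = x$contrast_threshold %||% 0.005,
    k = x$k %||% 1000,
    pool_cap = x$pool_cap %||% 1000,
    kmeans_iter = x$kmeans_iter %||% 20,
    max_comparisons = mc,
    pca_dim = x$pca_dim %||% 100,
    normalize_hist = x$normalize_hist %||% FALSE,
    n_trees = x$n_trees %||% 1000,
    features_per_split = x$features_per_split,
    modes = x$modes %||% input_modes(),
    schemes = x$schemes %||% scheme_ids(),
    seed = x$seed %||% 1)
}
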