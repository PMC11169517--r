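#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [dcrelm_train()] and
#' [run_pipeline()]. Any element can be overridden through `...` by passing
#' nested lists, e.g. `dcrelm_config(train = list(epochs = 300))`, which is
#' merged over the defaults. Presets bundle scaled problem sizes:
#' `"default"` keeps the full-size settings (2000 epochs, 500 ELM nodes),
#' `"easy"` is the synthetic benchmark setting (200 ELM nodes, 300 epochs),
#' `"smoke"` is a fast sanity setting for tiny inputs.
#'
#' @param preset `"default"`, `"easy"` or `"smoke"`.
#' @param ... nested list overrides.
#' @return A `RunConfig` list.
#' @export
dcrelm_config <- function(preset = c("default", "easy", "smoke"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    elm = list(n_nodes = 500L, activation = "tanh", weight_scale = "scaled"),
    graph = list(k = 15L, drop_fraction = 0.10, tau_ppr = 0.2,
                 literal_normalization = FALSE),
    aug = list(noise_mean = 1, noise_sd = 0.1, resample_each_epoch = TRUE),
    ae = list(layers = c(512L, 256L)),
    igae = list(layers = 256L),
    latent = list(d = 20L),
    fusion = list(tau = 0.5, gamma = 0.1),
    loss = list(epsilon = 0.01, lambda = 10),
    train = list(epochs = 2000L, lr = 1e-4, warmup = 50L, p_refresh = 1L,
                 nu = 1, seed = 0L, k = NULL),
    variant = "full"
  )
  if (preset == "easy") {
    cfg$elm$n_nodes <- 200L
    cfg$ae$layers <- c(128L, 64L)
    cfg$igae$layers <- 64L
    cfg$train$epochs <- 400L
    cfg$train$warmup <- 100L
    cfg$loss$lambda <- 500
  } else if (preset == "smoke") {
    cfg$elm$n_nodes <- 64L
    cfg$ae$layers <- c(32L, 16L)
    cfg$igae$layers <- 16L
    cfg$latent$d <- 10L
    cfg$graph$k <- 5L
    cfg$train$epochs <- 100L
    cfg$train$warmup <- 30L
    cfg$loss$lambda <- 500
  }
  cfg <- merge_config(cfg, list(...))
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_config`, a config list merged over defaults; for
#'   `write_config`, `path` invisibly.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(dcrelm_config, c(list(preset = "default"), over))
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
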