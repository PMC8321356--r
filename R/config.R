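#' Pipeline configuration
#'
#' All tunable parameters of the inspection pipeline in one object, with the
#' reference defaults: object threshold `m0 = 0.2`, normalization bin width
#' `delta = 0.1`, minimum cluster size 30 px, 8-connectivity, and the
#' detection-preset Chan-Vese parameters (`mu = 4, nu = 2`; see
#' [chanvese_config()]).
#'
#' @param m0 Object threshold on the high-voltage absorption.
#' @param delta Normalization bin width.
#' @param min_count Minimum pixels per normalization bin.
#' @param chanvese A [chanvese_config()].
#' @param min_cluster_size Cluster-size filter threshold, pixels.
#' @param connectivity Cluster connectivity, 4 or 8.
#' @param acquisition An [acquisition_config()] used by simulation commands.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(m0 = 0.2, delta = 0.1, min_count = 20,
                            chanvese = chanvese_config("detection"),
                            min_cluster_size = 30, connectivity = 8,
                            acquisition = NULL) {
  stopifnot(m0 > 0, delta > 0, min_count >= 1, min_cluster_size >= 1,
            connectivity %in% c(4, 8),
            inherits(chanvese, "chanvese_config"))
  structure(
    list(m0 = m0, delta = delta, min_count = min_count, chanvese = chanvese,
         min_cluster_size = min_cluster_size, connectivity = connectivity,
         acquisition = acquisition),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> m0=%g delta=%g min_count=%d min_cluster=%d conn=%d\n",
    x$m0, x$delta, x$min_count, x$min_cluster_size, x$connectivity))
  print(x$chanvese)
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `m0`, `delta`, `min_count`,
#' `min_cluster_size`, `connectivity`, and a `chanvese` block with any of
#' the [chanvese_config()] fields (including `preset`). Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("m0", "delta", "min_count", "min_cluster_size", "connectivity",
             "chanvese")
  extra <- setdiff(names(y), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  cv_args <- y$chanvese
  if (!is.null(cv_args)) {
    cv_known <- c("preset", "mu", "nu", "lambda1", "lambda2", "dt", "tol",
                  "n_max", "epsilon", "eta", "t_init")
    cv_extra <- setdiff(names(cv_args), cv_known)
    if (length(cv_extra))
      stop("unknown chanvese keys: ", paste(cv_extra, collapse = ", "))
    cv <- do.call(chanvese_config, cv_args)
  } else {
    cv <- chanvese_config("detection")
  }
  args <- y[setdiff(names(y), "chanvese")]
  args$chanvese <- cv
  do.call(pipeline_config, args)
}

#' Hash of a configuration for provenance logging
#'
#' @param cfg A [pipeline_config()].
#' @return Character MD5 hash of the serialized configuration.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp)   # deterministic serialization of the values
  unname(tools::md5sum(tmp))
}
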