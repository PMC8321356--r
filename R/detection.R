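#' Extract connected clusters from a segmentation mask
#'
#' Connected-component labeling of the defect phase. The default
#' 8-connectivity keeps diagonally touching fragments (e.g. pieces of a
#' shattered bone) in one cluster. Clusters are returned sorted by size
#' descending, ties broken by the top-left-most pixel in row-major order.
#'
#' @param mask Logical matrix or a `dexa_segmentation`.
#' @param intensity Optional matrix (typically the normalized image `N`) for
#'   per-cluster mean intensities.
#' @param connectivity 4 or 8.
#' @return An object of class `dexa_clusters`: a list of clusters, each with
#'   `pixels` (two-column row/col matrix), `size`, and `mean_intensity`.
#' @export
extract_clusters <- function(mask, intensity = NULL, connectivity = 8) {
  if (inherits(mask, "dexa_segmentation")) mask <- mask$mask
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- label_components_cpp(mask, as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0L)
    return(structure(list(), class = "dexa_clusters"))
  nc <- ncol(mask)
  clusters <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    idx <- which(lab == k)
    rows <- (idx - 1L) %% nrow(mask) + 1L
    cols <- (idx - 1L) %/% nrow(mask) + 1L
    clusters[[k]] <- list(
      pixels = cbind(row = rows, col = cols),
      size = length(idx),
      mean_intensity = if (is.null(intensity)) NA_real_
                       else mean(intensity[idx]),
      # row-major rank of the top-left-most pixel, for deterministic ties
      first_pixel = min((rows - 1L) * nc + cols)
    )
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               vapply(clusters, `[[`, numeric(1), "first_pixel"))
  structure(clusters[ord], class = "dexa_clusters")
}

#' @export
print.dexa_clusters <- function(x, ...) {
  cat(sprintf("<dexa_clusters> %d cluster(s)", length(x)))
  if (length(x))
    cat(": sizes", paste(vapply(x, `[[`, numeric(1), "size"),
                         collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Size-filter clusters and decide defected vs normal
#'
#' Clusters with fewer than `min_size` pixels are removed (a cluster of
#' exactly `min_size` pixels is kept). The sample is marked `"defected"` if
#' any cluster survives, `"normal"` otherwise. Cluster size is the only
#' decision criterion; the per-cluster mean intensity is carried along for
#' reporting.
#'
#' @param clusters A `dexa_clusters` list.
#' @param min_size Minimum surviving cluster size in pixels, default 30.
#' @param sample_id Optional identifier recorded in the result.
#' @return An object of class `dexa_detection`: `sample_id`,
#'   `clusters_kept`, `clusters_removed`, `verdict`.
#' @export
filter_and_decide <- function(clusters, min_size = 30, sample_id = NA) {
  stopifnot(min_size >= 1)
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  keep <- sizes >= min_size
  structure(
    list(sample_id = sample_id,
         clusters_kept = structure(clusters[keep], class = "dexa_clusters"),
         clusters_removed = structure(clusters[!keep],
                                      class = "dexa_clusters"),
         verdict = if (any(keep)) "defected" else "normal"),
    class = "dexa_detection"
  )
}

#' @export
print.dexa_detection <- function(x, ...) {
  cat(sprintf("<dexa_detection> %s: %s (%d cluster(s) kept)\n",
              if (is.na(x$sample_id)) "sample" else x$sample_id,
              x$verdict, length(x$clusters_kept)))
  invisible(x)
}

#' Run the full inspection pipeline on one projection pair
#'
#' Pre-processing (quotient, thickness correction, normalization), Chan-Vese
#' segmentation, cluster extraction and the size-filter verdict, in one call.
#'
#' @param pair A `dexa_projection`.
#' @param cfg A [pipeline_config()].
#' @param sample_id Optional identifier.
#' @return A `dexa_detection`; the segmentation and pre-processing results
#'   are attached as attributes `segmentation` and `preprocess`.
#' @export
#' @examples
#' ph <- generate_phantom(c(64, 64), "fan", seed = 3)
#' pr <- simulate_pair(ph, acquisition_config(seed = 3))
#' detect(pr)
detect <- function(pair, cfg = pipeline_config(), sample_id = NA) {
  pp <- preprocess(pair, m0 = cfg$m0, delta = cfg$delta,
                   min_count = cfg$min_count)
  seg <- segment(pp$norm, cfg$chanvese)
  cl <- extract_clusters(seg$mask, intensity = pp$norm$n,
                         connectivity = cfg$connectivity)
  res <- filter_and_decide(cl, min_size = cfg$min_cluster_size,
                           sample_id = sample_id)
  attr(res, "segmentation") <- seg
  attr(res, "preprocess") <- pp
  res
}
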