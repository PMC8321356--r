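#' Defect classes of the synthetic phantom generator
#'
#' Bone-fragment classes with their typical projected areas (pixels, at the
#' default 256x256 image size) and eccentricities. Fan bones are larger and
#' rounder; rib fragments are elongated. Areas follow the observed per-class
#' mean +/- sd bands for bone fragments in chicken-fillet scans
#' (fan 370 +/- 120 px, large rib 290 +/- 70 px, small rib 160 +/- 35 px).
#' @keywords internal
DEFECT_CLASSES <- list(
  fan       = list(area = c(250, 490), aspect = c(1.0, 2.0)),
  large_rib = list(area = c(220, 360), aspect = c(2.0, 4.0)),
  small_rib = list(area = c(125, 195), aspect = c(2.0, 4.0))
)

#' Generate a synthetic fillet phantom
#'
#' Builds a smooth random "meat" thickness map (a sum of smoothed random
#' bumps, zero outside the blob) and, for defect classes other than `"none"`,
#' plants one ellipsoidal bone inclusion fully inside the meat region. The
#' inclusion's projected area is drawn within its class band (see
#' `DEFECT_CLASSES`), scaled by `prod(shape) / 256^2` for other image sizes,
#' and its thickness profile is an ellipsoid cap with maximum drawn from
#' `bone_thickness` (cm). Deterministic given `seed`.
#'
#' @param shape Image dimensions `c(rows, cols)`, each `>= 64`.
#' @param defect_class One of `"none"`, `"fan"`, `"large_rib"`, `"small_rib"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param pixel_size Pixel pitch in cm.
#' @param peak_thickness Range (cm) from which the maximum meat thickness is
#'   drawn.
#' @param bone_thickness Range (cm) from which the maximum bone thickness is
#'   drawn.
#' @return An object of class `dexa_phantom` with fields `meat` and `bone`
#'   (thickness maps, cm), `truth` (logical mask, `bone > 0`), `pixel_size`,
#'   `defect_class`.
#' @export
#' @examples
#' ph <- generate_phantom(c(64, 64), "fan", seed = 1)
#' sum(ph$truth) # projected bone area in pixels
generate_phantom <- function(shape = c(256, 256),
                             defect_class = c("none", "fan", "large_rib",
                                              "small_rib"),
                             seed = NULL,
                             pixel_size = 0.1,
                             peak_thickness = c(1.5, 4),
                             bone_thickness = c(0.1, 0.4)) {
  defect_class <- match.arg(defect_class)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 64L))
    stop("shape must be two dimensions, each >= 64")
  if (!is.null(seed)) set.seed(seed)

  nr <- shape[1]; nc <- shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  # meat blob: sum of random Gaussian bumps, cut at a fraction of the peak
  k <- 6L
  cr <- runif(k, 0.3 * nr, 0.7 * nr)
  cc <- runif(k, 0.3 * nc, 0.7 * nc)
  sg <- runif(k, 0.12, 0.25) * min(nr, nc)
  am <- runif(k, 0.5, 1)
  field <- matrix(0, nr, nc)
  for (i in seq_len(k))
    field <- field + am[i] *
      exp(-((rows - cr[i])^2 + (cols - cc[i])^2) / (2 * sg[i]^2))
  cut <- 0.35 * max(field)
  meat <- pmax(field - cut, 0)
  peak <- runif(1, peak_thickness[1], peak_thickness[2])
  meat <- meat * (peak / max(meat))

  bone <- matrix(0, nr, nc)
  if (defect_class != "none") {
    cls <- DEFECT_CLASSES[[defect_class]]
    area_scale <- prod(shape) / (256 * 256)
    band <- cls$area * area_scale
    # candidate centers: anywhere in the blob with a small thickness margin,
    # so inclusions land in thin and thick parts alike (as real fragments do)
    core <- which(meat > 0.2 * peak)
    if (length(core) == 0) stop("phantom generation error: degenerate blob")
    placed <- FALSE
    for (try in 1:100) {
      target <- runif(1, band[1] + 0.1 * diff(band), band[2] - 0.1 * diff(band))
      aspect <- runif(1, cls$aspect[1], cls$aspect[2])
      b <- sqrt(target / (pi * aspect))
      a <- aspect * b
      idx <- core[sample.int(length(core), 1)]
      y0 <- (idx - 1) %% nr + 1
      x0 <- (idx - 1) %/% nr + 1
      th <- runif(1, 0, pi)
      u <- (((rows - y0) * cos(th) + (cols - x0) * sin(th)) / a)^2 +
           ((-(rows - y0) * sin(th) + (cols - x0) * cos(th)) / b)^2
      inside <- u < 1
      npx <- sum(inside)
      if (npx < band[1] || npx > band[2]) next
      if (any(meat[inside] <= 0)) next      # must lie fully inside the meat
      tmax <- runif(1, bone_thickness[1], bone_thickness[2])
      bone[inside] <- tmax * sqrt(1 - u[inside])
      # rasterized sqrt profile can give 0 exactly on the rim; truth = bone > 0
      placed <- TRUE
      break
    }
    if (!placed)
      stop("phantom generation error: could not place bone inside meat region")
  }

  structure(
    list(meat = meat, bone = bone, truth = bone > 0,
         pixel_size = pixel_size, defect_class = defect_class),
    class = "dexa_phantom"
  )
}

#' @export
print.dexa_phantom <- function(x, ...) {
  cat(sprintf("<dexa_phantom> %dx%d, class '%s', meat peak %.2f cm, bone area %d px\n",
              nrow(x$meat), ncol(x$meat), x$defect_class, max(x$meat),
              sum(x$truth)))
  invisible(x)
}

#' Acquisition configuration for dual-energy simulation
#'
#' @param spectra List of two [spectrum()] objects, low-kV first.
#' @param exposure Exposure time per projection, seconds. The short 0.5 s
#'   exposure is the high-noise regime in-line inspection operates in; longer
#'   exposures shrink the Poisson noise as `1/sqrt(t)`.
#' @param flux Photon flux per pixel per second incident on the detector.
#' @param seed Integer master seed for the noise (and dataset generation).
#' @param noise If `FALSE`, return noiseless expected absorption rates.
#' @param darkfield_offset Constant detector offset counts (default 0;
#'   flat-/dark-field correction is assumed already applied upstream).
#' @return An object of class `dexa_acquisition`.
#' @export
acquisition_config <- function(spectra = list(make_spectrum(40),
                                              make_spectrum(90)),
                               exposure = 0.5,
                               flux = 1e6,
                               seed = NULL,
                               noise = TRUE,
                               darkfield_offset = 0) {
  if (length(spectra) != 2L ||
      !all(vapply(spectra, inherits, logical(1), "dexa_spectrum")))
    stop("spectra must be a list of two dexa_spectrum objects")
  if (exposure <= 0) stop("exposure must be > 0")
  if (flux <= 0) stop("flux must be > 0")
  structure(
    list(spectra = spectra, exposure = exposure, flux = flux, seed = seed,
         noise = isTRUE(noise), darkfield_offset = darkfield_offset),
    class = "dexa_acquisition"
  )
}

#' Simulate a dual-energy projection pair of a phantom
#'
#' Ideal parallel-beam top view, one ray per pixel. Per pixel and voltage the
#' expected transmitted fraction is
#' `T = sum_E I(E) exp(-mu_meat(E) L_meat - mu_bone(E) L_bone) / sum_E I(E)`;
#' expected counts are `flux * exposure * T`. With noise enabled, projection
#' and flatfield counts are Poisson-sampled and the absorption rate is
#' `M = -ln(P / F)`, clipped below at 0. Zero-count pixels are flagged invalid
#' in the `valid` mask rather than producing infinities.
#'
#' @param phantom A [generate_phantom()] result.
#' @param acq An [acquisition_config()].
#' @param seed Optional seed overriding `acq$seed` (used by
#'   [generate_dataset()] for per-sample reproducibility).
#' @param meat_curve,bone_curve Attenuation curves; defaults are the packaged
#'   skeletal-muscle and cortical-bone tables.
#' @return An object of class `dexa_projection` with absorption matrices
#'   `m1` (low kV) and `m2` (high kV), a `valid` mask, and the phantom's
#'   `truth` mask carried along for evaluation.
#' @export
simulate_pair <- function(phantom, acq = acquisition_config(), seed = NULL,
                          meat_curve = muscle_attenuation(),
                          bone_curve = bone_attenuation()) {
  stopifnot(inherits(phantom, "dexa_phantom"),
            inherits(acq, "dexa_acquisition"))
  if (is.null(seed)) seed <- acq$seed
  if (!is.null(seed)) set.seed(seed)

  dims <- dim(phantom$meat)
  lmat <- cbind(as.vector(phantom$meat), as.vector(phantom$bone))
  curves <- list(meat_curve, bone_curve)
  n_counts <- acq$flux * acq$exposure

  channel <- function(spec) {
    tf <- transmitted_fraction(spec, curves, lmat)
    if (!acq$noise) {
      m <- -log(tf)
      return(list(m = matrix(m, dims[1], dims[2]),
                  valid = matrix(TRUE, dims[1], dims[2])))
    }
    p <- stats::rpois(length(tf), n_counts * tf) + acq$darkfield_offset
    f <- stats::rpois(length(tf), n_counts) + acq$darkfield_offset
    valid <- p > 0 & f > 0
    m <- numeric(length(tf))
    m[valid] <- pmax(-log(p[valid] / f[valid]), 0)
    list(m = matrix(m, dims[1], dims[2]),
         valid = matrix(valid, dims[1], dims[2]))
  }

  ch1 <- channel(acq$spectra[[1]])
  ch2 <- channel(acq$spectra[[2]])
  structure(
    list(m1 = ch1$m, m2 = ch2$m, valid = ch1$valid & ch2$valid,
         truth = phantom$truth, pixel_size = phantom$pixel_size,
         defect_class = phantom$defect_class),
    class = "dexa_projection"
  )
}

#' @export
print.dexa_projection <- function(x, ...) {
  cat(sprintf("<dexa_projection> %dx%d, M1 in [%.3f, %.3f], M2 in [%.3f, %.3f]\n",
              nrow(x$m1), ncol(x$m1), min(x$m1), max(x$m1), min(x$m2),
              max(x$m2)))
  invisible(x)
}

derive_sample_seed <- function(master, i) {
  # fixed arithmetic, kept well inside 32-bit integer range
  as.integer((as.numeric(master) * 10007 + 97 * i) %% 2147483647)
}

#' Generate a synthetic dual-energy dataset on disk
#'
#' Writes one low/high-kV absorption TIFF pair and a truth-mask PNG per
#' sample, plus a CSV manifest. Paths in the manifest are relative to
#' `out_dir`, so regenerating the dataset with the same master seed into any
#' directory yields a byte-identical manifest. Per-sample seeds are derived
#' from the master seed (`acq$seed`) by fixed arithmetic.
#'
#' @param n_per_class Named counts for classes `fan`, `large_rib`,
#'   `small_rib`, `none`.
#' @param acq An [acquisition_config()]; its `seed` is the master seed.
#' @param out_dir Output directory (created if needed).
#' @param shape Image dimensions passed to [generate_phantom()].
#' @return The manifest data frame (columns `sample_id`, `defect_class`,
#'   `has_defect`, `path_lo`, `path_hi`, `path_truth`, `seed`), invisibly;
#'   also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_per_class = c(fan = 100, large_rib = 100,
                                             small_rib = 96, none = 192),
                             acq = acquisition_config(seed = 1),
                             out_dir,
                             shape = c(256, 256)) {
  if (any(n_per_class < 0)) stop("counts must be >= 0")
  if (is.null(acq$seed)) stop("acq$seed (master seed) is required")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("unwritable output path: ", out_dir)

  classes <- rep(names(n_per_class), times = n_per_class)
  n <- length(classes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    sid <- sprintf("s%04d_%s", i, cls)
    sd_i <- derive_sample_seed(acq$seed, i)
    ph <- generate_phantom(shape, cls, seed = sd_i)
    pr <- simulate_pair(ph, acq, seed = derive_sample_seed(acq$seed, i + n))
    p_lo <- sprintf("%s_lo.tif", sid)
    p_hi <- sprintf("%s_hi.tif", sid)
    p_tr <- sprintf("%s_truth.png", sid)
    write_absorption_tiff(pr$m1, file.path(out_dir, p_lo))
    write_absorption_tiff(pr$m2, file.path(out_dir, p_hi))
    write_mask_png(ph$truth, file.path(out_dir, p_tr))
    rows[[i]] <- data.frame(
      sample_id = sid, defect_class = cls, has_defect = cls != "none",
      path_lo = p_lo, path_hi = p_hi, path_truth = p_tr, seed = sd_i,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read one manifest sample back as a projection pair
#'
#' @param dir Dataset directory containing the images.
#' @param row One row of the manifest data frame.
#' @return A `dexa_projection` (with `truth` loaded from the mask file).
#' @export
read_pair <- function(dir, row) {
  m1 <- read_absorption_tiff(file.path(dir, row$path_lo))
  m2 <- read_absorption_tiff(file.path(dir, row$path_hi))
  truth <- read_mask_png(file.path(dir, row$path_truth))
  structure(
    list(m1 = m1, m2 = m2, valid = matrix(TRUE, nrow(m1), ncol(m1)),
         truth = truth, pixel_size = NA_real_,
         defect_class = row$defect_class),
    class = "dexa_projection"
  )
}
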