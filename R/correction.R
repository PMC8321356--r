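#' Dual-energy quotient image
#'
#' Computes the pixelwise quotient `R = M1 / M2` over the object mask. A
#' pixel belongs to the object mask when its high-voltage absorption `m2` is
#' at least `m0`: near the object rim both absorption rates are ratios of
#' small numbers with large relative error, so those pixels are excluded from
#' every later stage (fit, binning, normalization).
#'
#' @param m1,m2 Absorption matrices for the low and high tube voltage.
#' @param m0 Object threshold on `m2` (absorption units), default 0.2.
#' @param valid Optional logical matrix of pixels with usable counts
#'   (e.g. from [simulate_pair()]); invalid pixels are excluded from the mask.
#' @return List with `r` (quotient matrix, 0 off-mask) and `mask` (logical).
#' @export
compute_quotient <- function(m1, m2, m0 = 0.2, valid = NULL) {
  stopifnot(is.matrix(m1), is.matrix(m2), all(dim(m1) == dim(m2)))
  if (m0 <= 0) stop("m0 must be > 0")
  mask <- m2 >= m0
  if (!is.null(valid)) mask <- mask & valid
  if (!any(mask)) stop("no object found: empty mask at threshold m0 = ", m0)
  r <- matrix(0, nrow(m1), ncol(m1))
  r[mask] <- m1[mask] / m2[mask]
  list(r = r, mask = mask)
}

#' Quadratic thickness-dependence fit of the quotient
#'
#' Beam hardening makes the dual-energy quotient drift smoothly with object
#' thickness; with the thickness profile unknown, the high-voltage absorption
#' `m2` serves as the thickness proxy. This fits
#' `R ~ a * m2^2 + b * m2 + c` by ordinary least squares over all masked
#' pixels simultaneously (unweighted: every object pixel votes equally).
#'
#' @param r Quotient matrix from [compute_quotient()].
#' @param m2 High-voltage absorption matrix.
#' @param mask Logical object mask.
#' @return An object of class `dexa_fit`: coefficients `a`, `b`, `c`,
#'   `residual_rms`, and `n_pixels`.
#' @export
fit_thickness_polynomial <- function(r, m2, mask) {
  stopifnot(all(dim(r) == dim(m2)), all(dim(r) == dim(mask)))
  x <- m2[mask]
  y <- r[mask]
  if (length(unique(x)) < 3L)
    stop("degenerate fit: need >= 3 distinct m2 values on the mask ",
         "(constant or near-constant thickness proxy)")
  X <- cbind(1, x, x^2)
  qr_x <- qr(X)
  if (qr_x$rank < 3L)
    stop("degenerate fit: rank-deficient design matrix (m2 values collinear)")
  beta <- qr.coef(qr_x, y)
  resid <- y - X %*% beta
  structure(
    list(a = unname(beta[3]), b = unname(beta[2]), c = unname(beta[1]),
         residual_rms = sqrt(mean(resid^2)), n_pixels = length(y)),
    class = "dexa_fit"
  )
}

#' @export
print.dexa_fit <- function(x, ...) {
  cat(sprintf("<dexa_fit> R ~ %.4g*m2^2 + %.4g*m2 + %.4g  (rms %.4g, n = %d)\n",
              x$a, x$b, x$c, x$residual_rms, x$n_pixels))
  invisible(x)
}

#' Apply the thickness correction
#'
#' Subtracts the fitted quadratic trend:
#' `R' = R - a * m2^2 - b * m2 - c` on the mask, 0 elsewhere. For a
#' homogeneous object `R'` is close to zero regardless of thickness; a
#' foreign inclusion with different spectral properties deviates from zero.
#' When the fit comes from the same data, `R'` has exactly zero mean over the
#' mask (least-squares orthogonality to the intercept).
#'
#' @inheritParams fit_thickness_polynomial
#' @param fit A `dexa_fit`.
#' @return Corrected quotient matrix `R'`.
#' @export
apply_correction <- function(r, m2, fit, mask) {
  stopifnot(inherits(fit, "dexa_fit"), all(dim(r) == dim(m2)))
  if (!all(is.finite(c(fit$a, fit$b, fit$c)))) stop("fit must be finite")
  rp <- matrix(0, nrow(r), ncol(r))
  rp[mask] <- r[mask] - fit$a * m2[mask]^2 - fit$b * m2[mask] - fit$c
  rp
}

#' Bin-wise noise normalization of the corrected quotient
#'
#' The noise variance of `R'` depends strongly on thickness (small
#' denominators near the rim), so a single global standard deviation would
#' over- or under-weight parts of the object. Masked pixels are binned by
#' `m2` into intervals `[m0 + i*delta, m0 + (i+1)*delta)` (half-open, last
#' bin closed); per bin, the mean and sample standard deviation of `R'` give
#' `N = (R' - mean_i) / sigma_i`. Bins with fewer than `min_count` pixels are
#' merged into the nearest populated bin (ties to the lower index) before the
#' statistics are taken, and `sigma` is floored at `sigma_floor`.
#'
#' @param rp Corrected quotient matrix from [apply_correction()].
#' @param m2 High-voltage absorption matrix (binning variable).
#' @param mask Logical object mask.
#' @param m0 Bin origin (the object threshold), default 0.2.
#' @param delta Bin width in absorption units, default 0.1.
#' @param min_count Minimum pixels per emitted bin, default 20.
#' @param sigma_floor Lower bound for the per-bin standard deviation.
#' @return An object of class `dexa_norm`: `n` (normalized image, 0
#'   off-mask), `mask`, `bins` (data frame of per-bin statistics:
#'   `bin_index`, `lower`, `upper`, `count`, `mean`, `sigma`), and
#'   `degenerate` (TRUE when a single zero-spread bin forced `N == 0`).
#' @export
normalize_quotient <- function(rp, m2, mask, m0 = 0.2, delta = 0.1,
                               min_count = 20, sigma_floor = 1e-6) {
  stopifnot(all(dim(rp) == dim(m2)), all(dim(rp) == dim(mask)))
  if (delta <= 0) stop("delta must be > 0")
  x <- m2[mask]
  y <- rp[mask]
  idx <- pmax(floor((x - m0) / delta), 0)   # m2 >= m0 on mask; guard rounding
  # merge under-populated bins into the nearest populated bin
  counts <- table(idx)
  levels_i <- as.numeric(names(counts))
  big <- levels_i[counts >= min_count]
  assign_bin <- idx
  if (length(big) == 0L) {
    assign_bin[] <- levels_i[1]           # single merged bin
  } else if (length(big) < length(levels_i)) {
    small <- levels_i[counts < min_count]
    for (s in small) {
      d <- abs(big - s)
      assign_bin[idx == s] <- big[which.min(d)]  # ties: lower index wins
    }
  }
  ub <- sort(unique(assign_bin))
  n_img <- matrix(0, nrow(rp), ncol(rp))
  nvec <- numeric(length(y))
  stats_rows <- vector("list", length(ub))
  degenerate <- FALSE
  for (k in seq_along(ub)) {
    sel <- assign_bin == ub[k]
    m <- mean(y[sel])
    s <- if (sum(sel) > 1L) stats::sd(y[sel]) else 0
    if (!is.finite(s)) s <- 0
    if (s < sigma_floor) {
      if (length(ub) == 1L) {
        degenerate <- TRUE
        warning("degenerate normalization: single bin with zero spread; N set to 0")
        nvec[sel] <- 0
        s <- sigma_floor
      } else {
        s <- sigma_floor
        nvec[sel] <- (y[sel] - m) / s
      }
    } else {
      nvec[sel] <- (y[sel] - m) / s
    }
    stats_rows[[k]] <- data.frame(
      bin_index = ub[k], lower = m0 + ub[k] * delta,
      upper = m0 + (ub[k] + 1) * delta, count = sum(sel), mean = m, sigma = s)
  }
  n_img[mask] <- nvec
  structure(
    list(n = n_img, mask = mask, bins = do.call(rbind, stats_rows),
         degenerate = degenerate),
    class = "dexa_norm"
  )
}

#' @export
print.dexa_norm <- function(x, ...) {
  cat(sprintf("<dexa_norm> %dx%d, %d mask px, %d bins, |N| max %.2f\n",
              nrow(x$n), ncol(x$n), sum(x$mask), nrow(x$bins),
              max(abs(x$n))))
  invisible(x)
}

#' Full thickness-correction pre-processing chain
#'
#' Composes [compute_quotient()], [fit_thickness_polynomial()],
#' [apply_correction()] and [normalize_quotient()], turning a dual-energy
#' projection pair into the normalized corrected quotient `N(x)` that the
#' segmentation stage consumes. All intermediates are returned for
#' inspection.
#'
#' @param pair A `dexa_projection` (from [simulate_pair()] or [read_pair()]).
#' @param m0 Object threshold, default 0.2.
#' @param delta Normalization bin width, default 0.1.
#' @param min_count Minimum pixels per bin, default 20.
#' @return An object of class `dexa_preprocess`: `norm` (a `dexa_norm`),
#'   `fit`, `r`, `rp`, `mask`.
#' @export
#' @examples
#' ph <- generate_phantom(c(64, 64), "fan", seed = 7)
#' pr <- simulate_pair(ph, acquisition_config(seed = 7))
#' pp <- preprocess(pr)
#' range(pp$norm$n[pp$mask])
preprocess <- function(pair, m0 = 0.2, delta = 0.1, min_count = 20) {
  stopifnot(inherits(pair, "dexa_projection"))
  q <- compute_quotient(pair$m1, pair$m2, m0 = m0, valid = pair$valid)
  fit <- fit_thickness_polynomial(q$r, pair$m2, q$mask)
  rp <- apply_correction(q$r, pair$m2, fit, q$mask)
  norm <- normalize_quotient(rp, pair$m2, q$mask, m0 = m0, delta = delta,
                             min_count = min_count)
  structure(
    list(norm = norm, fit = fit, r = q$r, rp = rp, mask = q$mask),
    class = "dexa_preprocess"
  )
}
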