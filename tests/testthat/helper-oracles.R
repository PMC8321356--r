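# Fixture builders and independent oracles used across the test files.

# Two-line spectrum hitting attenuation values ka at E = 30 and kb at E = 60.
toy_curve <- function(ka = 0.2, kb = 0.1) {
  attenuation_curve(c(30, 60), c(ka, kb), "toy")
}

two_line_spectrum <- function(w = c(1, 1), voltage = 90) {
  spectrum(c(30, 60), w, voltage)
}

delta_spectrum <- function(energy, voltage = max(energy, 90)) {
  spectrum(energy, 1, voltage)
}

# Hand evaluation of the polychromatic absorption rate for tabulated
# weights/attenuations: -log(sum(w exp(-k L)) / sum(w)). Independent of the
# package's quadrature path.
hand_absorption <- function(w, k, L) {
  -log(sum(w * exp(-k * L)) / sum(w))
}

# Uniform-slab phantom built directly (bypasses the random generator) for
# controlled simulation tests.
slab_phantom <- function(nr = 64, nc = 64, meat = 2, bone = 0,
                         bone_rows = NULL) {
  mb <- matrix(0, nr, nc)
  if (bone > 0) {
    if (is.null(bone_rows)) bone_rows <- seq_len(nr %/% 2)
    mb[bone_rows, ] <- bone
  }
  structure(
    list(meat = matrix(meat, nr, nc), bone = mb, truth = mb > 0,
         pixel_size = 0.1, defect_class = if (bone > 0) "fan" else "none"),
    class = "dexa_phantom"
  )
}

# Independent connected-component labeling by BFS over an R queue;
# deliberately naive, used only to cross-check the compiled implementation.
flood_label_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Exhaustive Chan-Vese energy minimum over all 2^(nr*nc) masks of a tiny
# image (vectorized over candidate masks). Energy definition mirrors the
# diagnostic: binary region means, 4-neighbor boundary-pair perimeter.
brute_force_min_energy <- function(n, lambda1 = 1, lambda2 = 1, mu = 1,
                                   nu = 1) {
  npix <- length(n)
  stopifnot(npix <= 16)
  nmask <- 2^npix
  M <- matrix(FALSE, nmask, npix)
  for (b in seq_len(npix))
    M[, b] <- bitwAnd(seq_len(nmask) - 1L, bitwShiftL(1L, b - 1L)) > 0
  nr <- nrow(n); nc <- ncol(n)
  # adjacency pairs (column-major pixel indices)
  pix <- function(i, j) (j - 1L) * nr + i
  pairs <- rbind(
    cbind(as.vector(pix(row(n)[-nr, ], col(n)[-nr, ])),
          as.vector(pix(row(n)[-1, ], col(n)[-1, ]))),
    cbind(as.vector(pix(row(n)[, -nc], col(n)[, -nc])),
          as.vector(pix(row(n)[, -1], col(n)[, -1]))))
  per <- rowSums(M[, pairs[, 1], drop = FALSE] != M[, pairs[, 2], drop = FALSE])
  v <- as.vector(n)
  cnt1 <- rowSums(M); cnt2 <- npix - cnt1
  S1 <- as.vector(M %*% v); Q1 <- as.vector(M %*% v^2)
  fit1 <- Q1 - ifelse(cnt1 > 0, S1^2 / cnt1, 0)
  S2 <- sum(v) - S1; Q2 <- sum(v^2) - Q1
  fit2 <- Q2 - ifelse(cnt2 > 0, S2^2 / cnt2, 0)
  min(lambda1 * fit1 + lambda2 * fit2 + mu * per + nu * cnt1)
}

# Noiseless two-valued blob image: value `hi` on a centered rectangle.
blob_image <- function(nr = 32, nc = 32, blob = 11:20, hi = 10) {
  n <- matrix(0, nr, nc)
  n[blob, blob] <- hi
  n
}
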