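#' Synthetic XLFM image formation
#'
#' In a Fourier light-field microscope every micro-lens acts as an individual
#' camera: a point source appears once behind each lens, displaced with depth
#' by a lens-dependent parallax. [synthesize_psf()] builds such a PSF stack
#' from a lens layout: each depth plane carries one Gaussian spot per lens,
#' shifted along the direction from the image center to that lens center by
#' \code{parallax_per_depth * (z - z_central)} pixels, and each plane is
#' normalized to sum exactly 1. The central depth plane (index
#' \code{(D + 1) \%/\% 2}) has zero parallax, so spots sit exactly on the
#' configured centers.
#'
#' @param layout a [lens_layout()]; all centers must lie inside
#'   \code{image_shape}
#' @param depth_count number of depth planes
#' @param spot_sigma Gaussian spot width in pixels
#' @param parallax_per_depth radial spot displacement per depth plane, pixels
#' @param image_shape integer length-2 \code{(H, W)} of the camera image
#' @return a [psf_stack()] of shape \code{(H, W, depth_count)}
#' @export
synthesize_psf <- function(layout, depth_count, spot_sigma,
                           parallax_per_depth, image_shape) {
  stopifnot(inherits(layout, "lens_layout"))
  depth_count <- as.integer(depth_count)
  if (depth_count < 1) stop("depth_count must be >= 1")
  if (spot_sigma <= 0) stop("spot_sigma must be > 0")
  h <- image_shape[1]; w <- image_shape[2]
  cs <- layout$centers
  if (any(cs[, 1] < 1 | cs[, 1] > h | cs[, 2] < 1 | cs[, 2] > w))
    stop("geometry error: lens centers do not fit in image_shape")
  z_central <- (depth_count + 1L) %/% 2L
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  planes <- array(0, c(h, w, depth_count))
  for (z in seq_len(depth_count)) {
    mag <- parallax_per_depth * (z - z_central)
    pl <- matrix(0, h, w)
    for (k in seq_len(nrow(cs))) {
      dir <- c(cs[k, 1], cs[k, 2]) - ctr
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm > 0) dir / nrm else c(0, 0)
      sr <- cs[k, 1] + mag * dir[1]
      sc <- cs[k, 2] + mag * dir[2]
      pl <- pl + exp(-((rr - sr)^2 + (cc - sc)^2) / (2 * spot_sigma^2))
    }
    s <- sum(pl)
    if (s <= 0) stop("degenerate PSF plane at depth ", z)
    planes[, , z] <- pl / s
  }
  psf_stack(planes)
}

# --- linear projector -------------------------------------------------------
#
# forward_project is same-size 2D convolution per depth, summed over depth:
#   image = sum_z conv2d(embed(volume[, , z]), psf[, , z])
# where embed() places the (possibly smaller) volume slice centered in the
# image grid. The convolution kernel center is the fixed pixel index
# dim %/% 2 + 1 (1-based), so a unit voxel at the volume center reproduces
# the PSF plane. Everything runs in a zero-padded Fourier domain large
# enough to make the circular convolution linear, and the adjoint (used by
# Richardson-Lucy) is the exact matrix transpose of the forward map.

make_projector <- function(psf, vol_lateral) {
  g <- grid_of(psf)
  hi <- dim(g)[1]; wi <- dim(g)[2]; d <- dim(g)[3]
  hv <- vol_lateral[1]; wv <- vol_lateral[2]
  if (hv > hi || wv > wi)
    stop("volume lateral extent exceeds the image size")
  nh <- stats::nextn(2L * hi - 1L, c(2, 3, 5))
  nw <- stats::nextn(2L * wi - 1L, c(2, 3, 5))
  fk <- array(complex(real = 0), c(nh, nw, d))
  for (z in seq_len(d)) {
    pad <- matrix(0, nh, nw)
    pad[seq_len(hi), seq_len(wi)] <- g[, , z]
    fk[, , z] <- stats::fft(pad)
  }
  list(fk = fk, d = d, hi = hi, wi = wi, hv = hv, wv = wv,
       nh = nh, nw = nw,
       ck_r = hi %/% 2L + 1L, ck_c = wi %/% 2L + 1L,
       er = (hi - hv) %/% 2L, ec = (wi - wv) %/% 2L)
}

proj_apply <- function(p, vol) {
  acc <- matrix(complex(real = 0), p$nh, p$nw)
  pad <- matrix(0, p$nh, p$nw)
  for (z in seq_len(p$d)) {
    pad[] <- 0
    pad[p$er + seq_len(p$hv), p$ec + seq_len(p$wv)] <- vol[, , z]
    acc <- acc + stats::fft(pad) * p$fk[, , z]
  }
  full <- Re(stats::fft(acc, inverse = TRUE)) / (p$nh * p$nw)
  full[p$ck_r - 1L + seq_len(p$hi), p$ck_c - 1L + seq_len(p$wi)]
}

proj_adjoint <- function(p, img) {
  pad <- matrix(0, p$nh, p$nw)
  pad[p$ck_r - 1L + seq_len(p$hi), p$ck_c - 1L + seq_len(p$wi)] <- img
  fu <- stats::fft(pad)
  out <- array(0, c(p$hv, p$wv, p$d))
  for (z in seq_len(p$d)) {
    full <- Re(stats::fft(fu * Conj(p$fk[, , z]), inverse = TRUE)) /
      (p$nh * p$nw)
    out[, , z] <- full[p$er + seq_len(p$hv), p$ec + seq_len(p$wv)]
  }
  out
}

#' Forward projection of a volume through a lenslet PSF stack
#'
#' Linear image formation: each depth plane of the volume is convolved
#' ("same" size, kernel center at pixel \code{dim \%/\% 2 + 1}) with the
#' matching PSF plane and the results are summed over depth. A volume whose
#' lateral extent is smaller than the image is embedded centered.
#'
#' @param vol a [volume()] or \code{(H, W, D)} array
#' @param psf a [psf_stack()] with the same number of depth planes
#' @return an [lf_image()] of the PSF's lateral size
#' @export
forward_project <- function(vol, psf) {
  v <- as_grid(vol, 3L, "volume")
  g <- grid_of(psf)
  if (dim(v)[3] != dim(g)[3])
    stop(sprintf("shape error: volume depth %d != psf depth %d",
                 dim(v)[3], dim(g)[3]))
  p <- make_projector(psf, dim(v)[1:2])
  lf_image(pmax(proj_apply(p, v), 0))
}

#' Detect lenslet centers from the central PSF plane
#'
#' Finds the \code{expected_count} strongest strict local maxima (8-neighbor)
#' of the central depth plane, greedily enforcing a minimum pairwise
#' separation. Candidates are ordered by descending peak value with row-major
#' tie-breaking, so the result is deterministic.
#'
#' @param psf a [psf_stack()]
#' @param expected_count number of lenses to locate
#' @param min_separation minimum Euclidean distance between accepted peaks,
#'   pixels
#' @param crop_size crop window side recorded in the returned layout
#' @return a [lens_layout()] with \code{expected_count} centers
#' @export
detect_lens_centers <- function(psf, expected_count, min_separation,
                                crop_size = 32L) {
  g <- grid_of(psf)
  if (expected_count < 1) stop("expected_count must be >= 1")
  z <- (dim(g)[3] + 1L) %/% 2L
  pl <- g[, , z]
  h <- nrow(pl); w <- ncol(pl)
  if (h < 3 || w < 3) stop("central PSF plane too small for peak detection")
  core <- pl[2:(h - 1), 2:(w - 1)]
  is_max <- core > pl[1:(h - 2), 2:(w - 1)] & core > pl[3:h, 2:(w - 1)] &
    core > pl[2:(h - 1), 1:(w - 2)] & core > pl[2:(h - 1), 3:w] &
    core > pl[1:(h - 2), 1:(w - 2)] & core > pl[1:(h - 2), 3:w] &
    core > pl[3:h, 1:(w - 2)] & core > pl[3:h, 3:w]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(sprintf("detection error: found 0 peaks, expected %d",
                 expected_count))
  idx <- idx + 1L  # back to full-plane coordinates
  vals <- pl[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  kept <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(idx))) {
    if (nrow(kept) == expected_count) break
    p <- idx[i, ]
    if (nrow(kept) == 0 ||
        all(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >=
            min_separation))
      kept <- rbind(kept, p)
  }
  if (nrow(kept) < expected_count)
    stop(sprintf("detection error: found %d qualifying peaks, expected %d",
                 nrow(kept), expected_count))
  lens_layout(unname(kept), crop_size)
}

#' Crop per-lens views from a light-field image
#'
#' Cuts a \code{crop_size x crop_size} window around every lens center and
#' stacks the crops (layout order). The center pixel lands at 1-based index
#' \code{crop_size \%/\% 2 + 1}; pixels falling outside the image are
#' zero-filled, and overlapping windows are allowed.
#'
#' @param image an [lf_image()]
#' @param layout a [lens_layout()]
#' @return a [view_stack()] of shape \code{(crop, crop, n_views)}
#' @export
crop_views <- function(image, layout) {
  img <- as_grid(image, 2L, "lf_image")
  stopifnot(inherits(layout, "lens_layout"))
  n <- nrow(layout$centers)
  cs <- layout$crop_size
  half <- cs %/% 2L
  out <- array(0, c(cs, cs, n))
  h <- nrow(img); w <- ncol(img)
  for (k in seq_len(n)) {
    r0 <- layout$centers[k, 1] - half
    c0 <- layout$centers[k, 2] - half
    rs <- max(1L, r0):min(h, r0 + cs - 1L)
    csr <- max(1L, c0):min(w, c0 + cs - 1L)
    if (length(rs) > 0 && length(csr) > 0 && rs[1] <= rs[length(rs)])
      out[rs - r0 + 1L, csr - c0 + 1L, k] <- img[rs, csr]
  }
  view_stack(out)
}
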