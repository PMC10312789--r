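#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peak^2 / MSE)} with the peak taken as the maximum of the
#' reference (appropriate for floating-point microscopy data with no fixed
#' bit depth). A perfect match (zero MSE) returns the declared cap of 100 dB.
#'
#' @param reference ground-truth [volume()] or array
#' @param estimate reconstructed [volume()] or array, same shape
#' @return PSNR in dB
#' @export
psnr <- function(reference, estimate) {
  r <- grid_of(reference); e <- grid_of(estimate)
  if (!identical(dim(r), dim(e))) stop("shape error: volume shapes differ")
  if (all(r == 0)) stop("value error: all-zero reference")
  mse <- mean((r - e)^2)
  if (mse == 0) return(100)
  min(10 * log10(max(r)^2 / mse), 100)
}

#' Masked mean absolute percentage error
#'
#' For highly sparse volumes a plain MAPE is dominated by empty voxels, so
#' the error is averaged over the union of non-zero voxels of reference and
#' estimate only:
#' \code{mean(|ref - est| / max(|ref|, eps))} over the mask, with
#' \code{eps = 1e-6 * max(ref)} guarding the division. An empty mask returns
#' 0. Reported as a fraction (0.1011 means 10.11\%).
#'
#' @inheritParams psnr
#' @return masked MAPE as a fraction
#' @export
mape_masked <- function(reference, estimate) {
  r <- grid_of(reference); e <- grid_of(estimate)
  if (!identical(dim(r), dim(e))) stop("shape error: volume shapes differ")
  mask <- r != 0 | e != 0
  if (!any(mask)) return(0)
  eps <- 1e-6 * max(abs(r))
  if (eps == 0) eps <- 1e-6
  mean(abs(r[mask] - e[mask]) / pmax(abs(r[mask]), eps))
}

#' Extract per-neuron activity traces from a volume sequence
#'
#' Neuron positions are the strongest local maxima of the per-voxel temporal
#' variance, greedily enforcing a pairwise separation (> \code{radius}), so
#' the procedure is a deterministic pure function of the data. The activity
#' of each neuron is the mean intensity in a cubic neighborhood of
#' half-width \code{radius} per frame.
#'
#' @param vols list of [volume()]s or arrays, identical shapes (the frames)
#' @param n_neurons number of neurons requested; if fewer qualifying maxima
#'   exist the result is shorter and carries \code{attr(, "short") = TRUE}
#' @param radius neighborhood half-width in voxels (also the separation
#'   scale)
#' @return list of \code{neuron_trace}: \code{position} (z, y, x order is
#'   \code{(row, col, depth)}) and \code{activity} (length = frames)
#' @export
extract_traces <- function(vols, n_neurons, radius = 2L) {
  if (length(vols) == 0) stop("data error: empty sequence")
  gs <- lapply(vols, function(v) as_grid(v, 3L, "frame"))
  d <- dim(gs[[1]])
  tfr <- length(gs)
  m1 <- Reduce(`+`, gs) / tfr
  m2 <- Reduce(`+`, lapply(gs, function(g) g^2)) / tfr
  vvar <- pmax(m2 - m1^2, 0)
  cand <- which(vvar > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    out <- list()
    attr(out, "short") <- n_neurons > 0
    return(out)
  }
  ord <- order(-vvar[cand], cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(0L, 0, 3)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == n_neurons) break
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        all(sqrt(rowSums(sweep(kept, 2, p)^2)) > radius))
      kept <- rbind(kept, p)
  }
  traces <- lapply(seq_len(nrow(kept)), function(k) {
    pos <- kept[k, ]
    act <- vapply(gs, function(g) box_mean(g, pos, radius), 0)
    structure(list(position = as.integer(pos), activity = act),
              class = "neuron_trace")
  })
  attr(traces, "short") <- nrow(kept) < n_neurons
  traces
}

box_mean <- function(g, pos, radius) {
  d <- dim(g)
  rs <- max(1L, pos[1] - radius):min(d[1], pos[1] + radius)
  cs <- max(1L, pos[2] - radius):min(d[2], pos[2] + radius)
  zs <- max(1L, pos[3] - radius):min(d[3], pos[3] + radius)
  mean(g[rs, cs, zs])
}

#' Mean temporal Pearson correlation of neuron traces
#'
#' Samples the estimated sequence at the reference neuron positions (the
#' positions always come from the reference, so every method is measured at
#' the same sites) and correlates each activity trace with its reference
#' counterpart. Traces with zero variance on either side contribute r = 0.
#'
#' @param ref_traces list of \code{neuron_trace} from [extract_traces()] on
#'   the reference sequence
#' @param est_vols list of estimated frames (same length and shape as the
#'   reference sequence)
#' @param radius neighborhood half-width used when sampling the estimate
#' @return mean Pearson r over neurons
#' @export
trace_pcc <- function(ref_traces, est_vols, radius = 2L) {
  if (length(est_vols) < 2) stop("value error: need at least 2 frames")
  if (length(ref_traces) == 0) stop("data error: no reference traces")
  gs <- lapply(est_vols, function(v) as_grid(v, 3L, "frame"))
  rs <- vapply(ref_traces, function(tr) {
    est <- vapply(gs, function(g) box_mean(g, tr$position, radius), 0)
    if (stats::sd(tr$activity) == 0 || stats::sd(est) == 0) return(0)
    stats::cor(tr$activity, est)
  }, 0)
  mean(rs)
}
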