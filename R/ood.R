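#' Per-level exact likelihood of a volume under the model
#'
#' Runs the axial Haar pyramid on the volume, pushes each level's detail
#' coefficients forward through that level's conditional flow (conditioned on
#' its features of \code{cond}), and reports the normalized per-element
#' negative log-likelihood per level together with their sum. The
#' deterministic low-resolution network defines no density, so it never
#' enters these scores.
#'
#' @param model a \code{cwfa_model}
#' @param vol a [volume()] or array at full resolution
#' @param cond a [condition_set()]
#' @param sample_id optional identifier carried through to the report
#' @return a \code{likelihood_report}: \code{per_level_nll} (one value per
#'   flow level), \code{total_nll}, \code{log_det} and \code{sample_id}
#' @export
likelihood_of <- function(model, vol, cond, sample_id = NA_character_) {
  g <- as_grid(vol, 3L, "volume")
  n <- length(model$levels)
  pyr <- haar_pyramid(g, n)
  per <- numeric(n)
  lds <- numeric(n)
  for (i in seq_len(n)) {
    feats <- condition_features(model, cond, i)
    # the level's flow models the details recentered on the
    # measurement-derived estimate (a fixed conditional translation with
    # zero log-determinant), so the likelihood stays exact
    di <- array(pyr$details[[i]], c(dim(pyr$details[[i]]), 1L)) -
      cwfa_level_center(model, cond, i)
    fw <- flow_apply(model$levels[[i]]$flow, di, feats, "forward")
    sc <- nll(fw$z, fw$log_det)
    per[i] <- sc$per_element
    lds[i] <- fw$log_det
  }
  structure(list(per_level_nll = per, total_nll = sum(per), log_det = lds,
                 sample_id = sample_id),
            class = "likelihood_report")
}

#' @export
print.likelihood_report <- function(x, ...) {
  cat(sprintf("<likelihood_report%s: per-level NLL [%s], total %.4f>\n",
              if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
              paste(sprintf("%.4f", x$per_level_nll), collapse = ", "),
              x$total_nll))
  invisible(x)
}

#' Calibrate an out-of-distribution threshold
#'
#' Out-of-distribution samples are the positive class and higher NLL means
#' more positive. The AUC is computed threshold-free from the score ranking
#' (equivalently, the Mann-Whitney U statistic divided by
#' \code{n_in * n_out}; ties count one half). Candidate thresholds are
#' \code{n_grid} linearly spaced values spanning the pooled score range,
#' together with the observed scores themselves (the operating points of the
#' ROC curve; without them a single extreme score can make the linear grid
#' too coarse to land inside a wide separation gap). The candidate
#' maximizing the F1-score is returned, ties resolved toward the lowest
#' threshold.
#'
#' @param scores_in NLL scores of in-distribution samples
#' @param scores_out NLL scores of out-of-distribution samples
#' @param n_grid number of candidate thresholds (default 1000)
#' @return list \code{(threshold, f1, auc)}
#' @export
select_threshold <- function(scores_in, scores_out, n_grid = 1000L) {
  if (length(scores_in) == 0 || length(scores_out) == 0)
    stop("data error: empty score list")
  pooled <- c(scores_in, scores_out)
  r <- rank(pooled)  # midranks: ties contribute 1/2
  n_i <- length(scores_in); n_o <- length(scores_out)
  auc <- (sum(r[n_i + seq_len(n_o)]) - n_o * (n_o + 1) / 2) / (n_i * n_o)
  grid <- sort(unique(c(seq(min(pooled), max(pooled), length.out = n_grid),
                        pooled)))
  f1s <- vapply(grid, function(thr) {
    tp <- sum(scores_out > thr)
    fp <- sum(scores_in > thr)
    fn <- n_o - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  best <- which.max(f1s)
  list(threshold = grid[best], f1 = f1s[best], auc = auc)
}

#' Classify a sample from its likelihood report
#'
#' Pure thresholding on one monitored level's NLL. Equality is
#' in-distribution (strict inequality flags out-of-distribution).
#'
#' @param report a \code{likelihood_report} from [likelihood_of()]
#' @param threshold calibrated NLL threshold
#' @param level 1-based flow level to monitor; by default the second level
#'   (the finest-but-one scale, which separates best in practice)
#' @return an \code{ood_decision}: \code{level_used}, \code{threshold},
#'   \code{score}, \code{is_ood}
#' @export
classify <- function(report, threshold, level = 2L) {
  if (level < 1 || level > length(report$per_level_nll))
    stop("value error: bad level index: ", level)
  score <- report$per_level_nll[level]
  structure(list(level_used = level, threshold = threshold,
                 score = score, is_ood = score > threshold),
            class = "ood_decision")
}

#' Fine-tune a trained model on newly detected samples
#'
#' Resumes training from the current parameters. \code{strategy = "replace"}
#' trains every component on the new pairs only (adapting the model to the
#' novel family); \code{strategy = "append"} trains on the union of old and
#' new pairs, retaining performance on the original family. With zero epochs
#' the model is returned unchanged.
#'
#' @param model a trained \code{cwfa_model}
#' @param new_pairs non-empty list of \code{list(v0, cond)} samples
#' @param strategy \code{"replace"} or \code{"append"}
#' @param old_pairs the original training samples (required for
#'   \code{"append"})
#' @param cfg a [train_config()]; its epoch counts control the fine-tuning
#'   budget
#' @return the adapted \code{cwfa_model}
#' @export
finetune <- function(model, new_pairs, strategy = c("replace", "append"),
                     old_pairs = NULL, cfg = train_config()) {
  strategy <- match.arg(strategy)
  if (length(new_pairs) == 0) stop("data error: new_pairs is empty")
  if (strategy == "append" && is.null(old_pairs))
    stop("usage error: strategy 'append' requires old_pairs")
  if (cfg$epochs_per_level == 0L && cfg$epochs_lr == 0L) return(model)
  dataset <- if (strategy == "replace") new_pairs else c(old_pairs, new_pairs)
  train_model(model, dataset, cfg)$model
}
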