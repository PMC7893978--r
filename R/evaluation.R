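#' Permutation-null significance threshold for prediction accuracy
#'
#' Destroys the correspondence between actual and predicted responses by
#' permuting the sample order of the predicted matrix, recomputes every
#' per-voxel Pearson correlation, and repeats `n_perm` times. By default all
#' permuted correlations are pooled into a single null distribution and the
#' `1 - alpha` quantile is returned as one global threshold; `mode =
#' "per_voxel"` instead returns one threshold per voxel. With 120 validation
#' samples and `alpha = 0.001` the pooled threshold is close to 0.27 (the
#' analytic t-quantile `r = t / sqrt(t^2 + n - 2)` gives about 0.279).
#'
#' @param actual,predicted Numeric matrices (samples x voxels) of equal shape,
#'   samples >= 3.
#' @param n_perm Number of permutations (>= 1/alpha, default 1000).
#' @param alpha Significance level in (0, 1) (default 0.001).
#' @param seed Optional integer seed for the permutations.
#' @param mode `"pooled"` (default) or `"per_voxel"`.
#' @return Scalar threshold (pooled) or a vector of per-voxel thresholds.
#' @export
permutation_threshold <- function(actual, predicted, n_perm = 1000L,
                                  alpha = 0.001, seed = NULL,
                                  mode = c("pooled", "per_voxel")) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!all(dim(actual) == dim(predicted))) stop("shape mismatch", call. = FALSE)
  n_s <- nrow(actual)
  if (n_s < 3) stop("need at least 3 samples", call. = FALSE)
  if (n_perm < 1 / alpha) {
    stop("n_perm too small to resolve the requested alpha", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # standardize columns once; a permuted correlation is then a plain column dot
  ac <- scale(actual)
  pc <- scale(predicted)
  ac[, attr(ac, "scaled:scale") == 0] <- 0
  pc[, attr(pc, "scaled:scale") == 0] <- 0
  null_r <- matrix(0, ncol(actual), n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n_s)
    null_r[, p] <- colSums(ac * pc[perm, , drop = FALSE]) / (n_s - 1)
  }
  if (mode == "pooled") {
    stats::quantile(null_r, 1 - alpha, names = FALSE)
  } else {
    apply(null_r, 1L, stats::quantile, probs = 1 - alpha, names = FALSE)
  }
}

# Analytic cross-check of the permutation threshold: the null quantile of a
# sample correlation at one-sided level alpha, from the t distribution with
# n - 2 degrees of freedom.
analytic_null_quantile <- function(n_samples, alpha = 0.001) {
  t <- stats::qt(1 - alpha, df = n_samples - 2)
  t / sqrt(t^2 + n_samples - 2)
}

#' Count and percentage of accurately predicted voxels
#'
#' A voxel counts as accurately predicted when its accuracy strictly exceeds
#' the significance threshold. The percentage is reported to 2 decimals.
#'
#' @param rho Per-voxel accuracy vector (NAs are never counted).
#' @param threshold Significance threshold.
#' @return List with `count`, `percentage` (rounded to 2 decimals) and
#'   `n_voxels`.
#' @export
#' @examples
#' accurate_fraction(c(rep(0.5, 548), rep(0, 746)), 0.27)$percentage # 42.35
accurate_fraction <- function(rho, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  count <- sum(rho > threshold, na.rm = TRUE)
  n <- length(rho)
  list(count = count,
       percentage = round(100 * count / n, 2),
       n_voxels = n)
}

#' Rank accurately predicted voxels by accuracy
#'
#' @param rho Per-voxel accuracy vector.
#' @param threshold Significance threshold; only voxels with `rho >
#'   threshold` are returned.
#' @return Data frame with columns `voxel` (index) and `rho`, sorted by
#'   non-increasing accuracy, ties kept in index order.
#' @export
rank_voxels <- function(rho, threshold = -Inf) {
  keep <- which(!is.na(rho) & rho > threshold)
  ord <- keep[order(-rho[keep])]
  data.frame(voxel = ord, rho = rho[ord], row.names = NULL)
}

#' Per-voxel prediction accuracy of a model on validation data
#'
#' Runs the model in evaluation mode on the validation stimuli and correlates
#' predicted with measured responses voxel by voxel. Validation responses
#' with a repeat dimension (repeats x samples x voxels) are averaged across
#' repeats first. Voxels whose measured response is constant are flagged and
#' excluded from the accurate-voxel count.
#'
#' @param model An `encoding_model`.
#' @param val_stimuli Validation stimuli, array `side x side x n`.
#' @param val_responses Matrix `n x n_voxels`, or array
#'   `repeats x n x n_voxels`.
#' @param threshold Significance threshold; when `NULL`, computed from the
#'   data by [permutation_threshold()] with `n_perm` and `alpha`.
#' @param n_perm,alpha,seed Passed to [permutation_threshold()].
#' @param roi Optional ROI label stored in the report.
#' @return An `accuracy_report`: list with `rho`, `roi`, `threshold`,
#'   `alpha`, `count`, `percentage`, `ranking` and `flagged` (constant-voxel
#'   indices).
#' @export
voxelwise_accuracy <- function(model, val_stimuli, val_responses,
                               threshold = NULL, n_perm = 1000L,
                               alpha = 0.001, seed = NULL, roi = NA_character_) {
  if (length(dim(val_responses)) == 3L) {
    val_responses <- apply(val_responses, c(2, 3), mean)
  }
  pred <- forward_pass(model, val_stimuli)
  if (!all(dim(pred) == dim(val_responses))) {
    stop("validation responses do not match the model output shape", call. = FALSE)
  }
  flagged <- which(apply(val_responses, 2L, stats::sd) == 0)
  if (length(flagged)) {
    message(sprintf("%d voxel(s) with constant measured response flagged and excluded",
                    length(flagged)))
  }
  rho <- colwise_pearson(pred, val_responses)
  rho[flagged] <- NA_real_
  if (is.null(threshold)) {
    threshold <- permutation_threshold(val_responses, pred, n_perm = n_perm,
                                       alpha = alpha, seed = seed)
  }
  af <- accurate_fraction(rho, threshold)
  structure(list(rho = rho, roi = roi, threshold = threshold, alpha = alpha,
                 count = af$count, percentage = af$percentage,
                 n_voxels = af$n_voxels,
                 ranking = rank_voxels(rho, threshold),
                 flagged = flagged),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy report%s: %d/%d voxels above rho = %.3f (%.2f%%)\n",
              if (is.na(x$roi)) "" else paste0(" [", x$roi, "]"),
              x$count, x$n_voxels, x$threshold, x$percentage))
  invisible(x)
}

#' Pairwise model dominance test
#'
#' Restricts to voxels accurately predicted by both models, measures the
#' fraction on which model A beats model B, and compares it with the
#' `1 - alpha` quantile of a fair-coin null (each shared voxel assigned to
#' either model with probability 0.5, `n_perm` replicates). Ties are broken
#' by independent fair coin flips. For shared-voxel counts in the several
#' hundreds the critical fraction is about 53%.
#'
#' @param rho_a,rho_b Matched per-voxel accuracy vectors.
#' @param threshold Accuracy threshold defining "accurately predicted".
#' @param n_perm Null replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed.
#' @return A `dominance_result`: list with `n_shared`, `fraction_a`,
#'   `critical_fraction`, `significant`, `alpha`; or with `no_test = TRUE`
#'   when no voxel passes both thresholds.
#' @export
dominance_test <- function(rho_a, rho_b, threshold, n_perm = 1000L,
                           alpha = 0.05, seed = NULL) {
  if (length(rho_a) != length(rho_b)) stop("length mismatch", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  shared <- which(rho_a > threshold & rho_b > threshold)
  if (length(shared) == 0L) {
    return(structure(list(no_test = TRUE, n_shared = 0L), class = "dominance_result"))
  }
  a <- rho_a[shared]; b <- rho_b[shared]
  wins <- a > b
  ties <- a == b
  if (any(ties)) wins[ties] <- stats::runif(sum(ties)) < 0.5
  frac <- mean(wins)
  null_frac <- stats::rbinom(n_perm, length(shared), 0.5) / length(shared)
  crit <- stats::quantile(null_frac, 1 - alpha, names = FALSE, type = 1)
  structure(list(no_test = FALSE, n_shared = length(shared),
                 fraction_a = frac, critical_fraction = crit,
                 significant = frac > crit, alpha = alpha),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  if (isTRUE(x$no_test)) {
    cat("Dominance test: no voxel accurately predicted by both models\n")
  } else {
    cat(sprintf("Dominance test: %d shared voxels, A wins %.1f%% (critical %.1f%%) -> %s\n",
                x$n_shared, 100 * x$fraction_a, 100 * x$critical_fraction,
                if (x$significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' Write an accuracy report to CSV and JSON
#'
#' @param report An `accuracy_report`.
#' @param csv_path Per-voxel CSV path (voxel, roi, rho, accurate flag).
#' @param json_path Optional JSON summary path (threshold, count, percentage).
#' @return Invisibly, the per-voxel data frame.
#' @export
write_accuracy_report <- function(report, csv_path, json_path = NULL) {
  df <- data.frame(voxel = seq_along(report$rho),
                   roi = report$roi,
                   rho = report$rho,
                   accurate = !is.na(report$rho) & report$rho > report$threshold)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(roi = report$roi, alpha = report$alpha,
                              threshold = report$threshold,
                              count = report$count,
                              n_voxels = report$n_voxels,
                              percentage = report$percentage),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
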