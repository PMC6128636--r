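#' Link-level confusion counts against a ground-truth wiring
#'
#' Evaluates every ordered off-diagonal pair. The positive set is the
#' ground-truth links of the requested sign class (SWM entry of matching sign
#' != 0); a predicted link is a true positive iff it sits on the same ordered
#' pair with the same polarity. A wrong-polarity prediction on a true link
#' therefore counts as a false positive for its own class while leaving the
#' true link a false negative. `TP + TN + FP + FN = n^2 - n` always.
#'
#' @param pred n x n signed prediction matrix (a TCM/FCM entity matrix or an
#'   `fcm` object).
#' @param truth n x n ground-truth synaptic weight matrix (SWM), or a
#'   `structural_network`.
#' @param sign_class `"excitatory"`, `"inhibitory"`, or `"all"`.
#' @return list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`,
#'   `accuracy` (`(TP+TN)/total`) and `mcc`.
#' @export
confusion <- function(pred, truth, sign_class = c("all", "excitatory", "inhibitory")) {
  sign_class <- match.arg(sign_class)
  if (inherits(pred, "fcm")) pred <- pred$fcm
  if (inherits(truth, "structural_network")) truth <- truth$swm
  if (!all(dim(pred) == dim(truth))) stop("dimension mismatch")
  off <- !diag(nrow = nrow(pred))
  p <- pred[off]; s <- truth[off]
  in_class <- function(x) switch(sign_class,
                                 excitatory = x > 0,
                                 inhibitory = x < 0,
                                 all = x != 0)
  P <- in_class(s)
  Q <- in_class(p)
  tp <- sum(Q & P & (sign(p) == sign(s)))
  fp <- sum(Q) - tp
  fn <- if (sign_class == "all") sum(P & p == 0) else sum(P) - tp
  tn <- length(p) - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(p),
                 mcc = mcc_value(tp, tn, fp, fn)),
            class = "confusion_counts")
}

# Matthews correlation coefficient; zero denominator -> 0 by convention
mcc_value <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# class scores and truth labels over ordered off-diagonal pairs
class_scores <- function(score_matrix, truth, sign_class) {
  if (inherits(score_matrix, "fcm")) score_matrix <- score_matrix$fcm
  if (inherits(truth, "structural_network")) truth <- truth$swm
  if (!all(dim(score_matrix) == dim(truth))) stop("dimension mismatch")
  off <- !diag(nrow = nrow(truth))
  m <- score_matrix[off]; s <- truth[off]
  sgn <- switch(sign_class, excitatory = 1, inhibitory = -1)
  list(scores = ifelse(sign(m) == sgn, abs(m), 0),
       labels = sign(s) == sgn)
}

# threshold sweep over unique score values, descending; returns cumulative
# TP/FP at each cut plus the (0, 0) start point
sweep_threshold <- function(scores, labels) {
  P <- sum(labels); N <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  sc <- scores[o]; y <- labels[o]
  last <- cumsum(rep(1, length(sc)))[!duplicated(sc, fromLast = TRUE)]
  tp <- c(0, cumsum(y)[last])
  fp <- c(0, cumsum(!y)[last])
  list(tp = tp, fp = fp, P = P, N = N,
       thresholds = c(Inf, sc[last]))
}

#' ROC curve and AUC for link detection
#'
#' Scores are the entity magnitudes of the requested sign class (entries of
#' the other sign score 0); the truth positives are the ground-truth links of
#' that sign. The threshold sweeps over the unique score values; the curve is
#' monotone from (0, 0) to (1, 1) and the AUC is computed by the trapezoid
#' rule.
#'
#' @param score_matrix signed score matrix (an `fcm` object or plain matrix).
#' @param truth ground-truth SWM or `structural_network`.
#' @param sign_class `"excitatory"` or `"inhibitory"`.
#' @return list of class `score_curve`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_auc <- function(score_matrix, truth, sign_class = c("excitatory", "inhibitory")) {
  sign_class <- match.arg(sign_class)
  cs <- class_scores(score_matrix, truth, sign_class)
  if (sum(cs$labels) == 0) stop("no ground-truth positives for class ", sign_class)
  sw <- sweep_threshold(cs$scores, cs$labels)
  tpr <- sw$tp / sw$P
  fpr <- if (sw$N > 0) sw$fp / sw$N else rep(0, length(sw$fp))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = sw$thresholds, auc = auc,
                 sign_class = sign_class), class = "score_curve")
}

#' Matthews-correlation-coefficient curve for link detection
#'
#' Same threshold sweep as [roc_auc()], evaluating the MCC of the implied
#' confusion at each cut; the curve is reported against the false positive
#' rate and its maximum summarizes detection precision. A zero denominator
#' yields MCC = 0.
#'
#' @inheritParams roc_auc
#' @return list of class `score_curve`: `fpr`, `mcc`, `thresholds`,
#'   `max_mcc`.
#' @export
mcc_curve <- function(score_matrix, truth, sign_class = c("excitatory", "inhibitory")) {
  sign_class <- match.arg(sign_class)
  cs <- class_scores(score_matrix, truth, sign_class)
  if (sum(cs$labels) == 0) stop("no ground-truth positives for class ", sign_class)
  sw <- sweep_threshold(cs$scores, cs$labels)
  mcc <- mapply(function(tp, fp) mcc_value(tp, sw$N - fp, fp, sw$P - tp),
                sw$tp, sw$fp)
  fpr <- if (sw$N > 0) sw$fp / sw$N else rep(0, length(sw$fp))
  structure(list(fpr = fpr, mcc = mcc, thresholds = sw$thresholds,
                 max_mcc = max(mcc), sign_class = sign_class),
            class = "score_curve")
}

fd_breaks <- function(x) {
  h <- 2 * stats::IQR(x) / length(x)^(1/3)
  if (h <= 0) h <- 1
  seq(floor(min(x)) - h / 2, max(x) + h, by = h)
}

#' In-degree distributions of a connectivity matrix, with fits
#'
#' Computes the functional in-degree (number of afferent links of the
#' requested sign per node) and fits either a Gaussian (closed-form
#' maximum-likelihood mean and SD) or a power law (linear regression on the
#' log-log binned histogram). R^2 is evaluated on the density-normalized
#' histogram: Freedman-Diaconis bins for the Gaussian fit, logarithmic bins
#' for the power law.
#'
#' @param tcm an `fcm` object or signed matrix.
#' @param sign_class `"excitatory"`, `"inhibitory"` or `"all"`.
#' @param fit `"gaussian"` or `"powerlaw"`.
#' @return list: `degrees`, `fit`, `params` (mean/sd or exponent/intercept),
#'   `r_squared`, `histogram`, `degenerate` (TRUE when the degree
#'   distribution has sd 0, e.g. a k-regular graph).
#' @export
degree_distributions <- function(tcm, sign_class = c("all", "excitatory", "inhibitory"),
                                 fit = c("gaussian", "powerlaw")) {
  sign_class <- match.arg(sign_class)
  fit <- match.arg(fit)
  m <- if (inherits(tcm, "fcm")) tcm$fcm else tcm
  sel <- switch(sign_class, excitatory = m > 0, inhibitory = m < 0, all = m != 0)
  if (!any(sel)) stop("no ", sign_class, " entries")
  deg <- colSums(sel)
  if (length(unique(deg)) < 3) {
    if (sd_pop(deg) == 0)
      return(list(degrees = deg, fit = fit, params = c(mean = mean(deg), sd = 0),
                  r_squared = NA_real_, histogram = NULL, degenerate = TRUE))
    stop("fewer than 3 distinct degrees: cannot fit")
  }
  if (fit == "gaussian") {
    mu <- mean(deg); sig <- sd_pop(deg)   # closed-form MLE
    h <- graphics::hist(deg, breaks = fd_breaks(deg), plot = FALSE)
    pred <- dnorm(h$mids, mu, sig)
    r2 <- 1 - sum((h$density - pred)^2) / sum((h$density - mean(h$density))^2)
    list(degrees = deg, fit = fit, params = c(mean = mu, sd = sig),
         r_squared = r2, histogram = h, degenerate = FALSE)
  } else {
    # heavy-tailed histograms call for logarithmic binning
    dpos <- deg[deg > 0]
    br <- unique(c(0, round(exp(seq(0, log(max(dpos) + 1), length.out = 16)))))
    h <- graphics::hist(dpos, breaks = br, plot = FALSE)
    ok <- h$density > 0 & h$mids > 0
    if (sum(ok) < 3) stop("too few occupied bins for a power-law fit")
    fitlm <- lm(log(h$density[ok]) ~ log(h$mids[ok]))
    r2 <- summary(fitlm)$r.squared
    cf <- coef(fitlm)
    list(degrees = deg, fit = fit,
         params = c(exponent = unname(cf[2]), intercept = unname(cf[1])),
         r_squared = r2, histogram = h, degenerate = FALSE)
  }
}

# box-plot summary convention: box 25th-75th, whiskers 5th-95th, mean marked
box_summary <- function(x) {
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  c(p5 = q[1], q25 = q[2], median = q[3], q75 = q[4], p95 = q[5],
    mean = mean(x))
}

#' Delay and connection-length distributions of detected links
#'
#' Per sign class, collects the peak delays (ms) and, when a layout is
#' supplied, the Euclidean link lengths (um) of the detected links, with
#' box-plot summaries (median, 25th-75th quartiles by linear interpolation,
#' 5th-95th percentile whiskers, mean).
#'
#' @param tcm an `fcm` object.
#' @param layout optional [electrode_layout()]; lengths are skipped without
#'   one (e.g. simulations with no spatial embedding).
#' @return nested list by class (`excitatory`, `inhibitory`) with `delays_ms`,
#'   `lengths_um`, and `summary` entries.
#' @export
delay_length_distributions <- function(tcm, layout = NULL) {
  stopifnot(inherits(tcm, "fcm"))
  dist_um <- if (!is.null(layout)) electrode_distances(layout, tcm$channel_ids)
  one <- function(sel) {
    idx <- which(sel, arr.ind = TRUE)
    delays <- tcm$delays_ms[sel]
    lengths <- if (!is.null(dist_um) && nrow(idx)) dist_um[idx] else NULL
    list(delays_ms = delays,
         lengths_um = lengths,
         summary = list(
           delays = if (length(delays)) box_summary(delays) else NULL,
           lengths = if (length(lengths)) box_summary(lengths) else NULL))
  }
  list(excitatory = one(tcm$fcm > 0), inhibitory = one(tcm$fcm < 0))
}

#' Detected inhibitory-link fraction versus recording length
#'
#' For each requested duration, the recording is truncated to its first `T`
#' seconds, the full inference pipeline (correlogram estimation, optional
#' spatio-temporal filter, hard threshold) is re-run, and the inhibitory
#' share of all detected links is reported. Inhibition detectability depends
#' on accumulating enough coincidences, so the fraction is expected to
#' degrade for short recordings.
#'
#' @param set a [spike_train_set()].
#' @param durations vector of truncation lengths in seconds (each
#'   `<= set$duration`).
#' @param W,delta correlogram parameters, see [build_fcm()].
#' @param layout optional [electrode_layout()]; when given, the
#'   spatio-temporal filter is applied before thresholding.
#' @param params a [pruning_params()].
#' @param ... further arguments to [build_fcm()].
#' @return data.frame with `duration_s`, `n_exc`, `n_inh`,
#'   `inhibitory_fraction`.
#' @export
inhibitory_fraction_vs_time <- function(set, durations, W = 25, delta = 1,
                                        layout = NULL,
                                        params = pruning_params(), ...) {
  stopifnot(all(durations > 0))
  durations <- durations[durations <= set$duration]
  rows <- lapply(durations, function(T) {
    sub <- truncate_recording(set, T)
    if (sum(spike_counts(sub) > 0) < 2) {
      warning("truncation to ", T, " s leaves < 2 active channels; skipped")
      return(NULL)
    }
    fc <- build_fcm(sub, W = W, delta = delta, ...)
    if (!is.null(layout)) fc <- spatiotemporal_filter(fc, layout, params)
    tc <- suppressWarnings(hard_threshold(fc, params))
    data.frame(duration_s = T, n_exc = sum(tc$fcm > 0), n_inh = sum(tc$fcm < 0),
               inhibitory_fraction = sum(tc$fcm < 0) / max(1, sum(tc$fcm != 0)))
  })
  do.call(rbind, rows)
}
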