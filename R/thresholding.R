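#' Global binarization of an intensity image
#'
#' A pixel is foreground (MP) iff its value is strictly greater than the
#' threshold `T`; pixels equal to `T` are background.
#'
#' @param intensity Integer matrix in `[0, 255]`.
#' @param T Threshold in `[0, 255]`.
#' @return An [mp_mask()].
#' @export
binarize <- function(intensity, T) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0 || T > 255) {
    stopf("threshold T must be a single value in [0, 255]")
  }
  mp_mask((intensity > T) * 1L)
}

#' Renyi entropy of a discrete distribution
#'
#' `H_alpha(q) = log(sum(q^alpha)) / (1 - alpha)` with natural logarithms;
#' zero-probability bins contribute nothing. The `alpha -> 1` limit is the
#' Shannon entropy, available as [shannon_entropy()].
#'
#' @param q Numeric vector of non-negative frequencies summing to 1.
#' @param alpha Positive order, `alpha != 1`.
#' @return Entropy in nats.
#' @export
renyi_entropy <- function(q, alpha) {
  check_distribution(q)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stopf("alpha must be a positive scalar")
  }
  if (alpha == 1) stopf("alpha = 1 is the Shannon limit; use shannon_entropy()")
  qq <- q[q > 0]
  log(sum(qq^alpha)) / (1 - alpha)
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum(q * log(q))` over occupied bins, in nats.
#'
#' @inheritParams renyi_entropy
#' @return Entropy in nats (non-negative).
#' @export
shannon_entropy <- function(q) {
  check_distribution(q)
  qq <- q[q > 0]
  -sum(qq * log(qq))
}

check_distribution <- function(q) {
  if (anyNA(q) || any(q < 0)) stopf("q must be non-negative with no NAs")
  if (abs(sum(q) - 1) > 1e-8) stopf("q must sum to 1 (got %.10f)", sum(q))
  invisible(q)
}

# Two-class entropy criterion curve over all 256 candidate thresholds.
# For each T the background class is bins [0, T] and the foreground class
# (T, 255]; each class is renormalized. Candidates leaving either class
# empty score -Inf. alpha = 1 gives the Kapur (max-entropy) criterion.
entropy_criterion <- function(q, alpha = 1) {
  P <- cumsum(q)
  crit <- rep(-Inf, 256L)
  for (Tv in 0:255) {
    pb <- P[Tv + 1L]
    pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    qb <- q[seq_len(Tv + 1L)] / pb
    qf <- q[seq.int(Tv + 2L, 256L)] / pf
    crit[Tv + 1L] <- if (alpha == 1) {
      shannon_entropy(qb) + shannon_entropy(qf)
    } else {
      renyi_entropy(qb, alpha) + renyi_entropy(qf, alpha)
    }
  }
  crit
}

entropy_argmax <- function(hist, alpha) {
  q <- hist_q(hist)
  if (sum(q > 0) < 2L) stopf("degenerate histogram: fewer than 2 occupied bins")
  crit <- entropy_criterion(q, alpha)
  which.max(crit) - 1L # ties -> smallest T (which.max takes the first)
}

hist_q <- function(hist) {
  if (inherits(hist, "mp_histogram")) return(hist$q)
  if (is.numeric(hist) && length(hist) == 256L) {
    s <- sum(hist)
    if (s <= 0) stopf("histogram is empty")
    return(hist / s)
  }
  stopf("expected an mp_histogram or a length-256 count/frequency vector")
}

#' Kapur maximum-entropy threshold
#'
#' Selects the threshold `T` maximizing the sum of Shannon entropies of the
#' renormalized background (`<= T`) and foreground (`> T`) classes, searched
#' exhaustively over all 256 candidate splits. Ties break to the smallest
#' `T`; splits leaving a class empty are skipped.
#'
#' @param hist An [intensity_histogram()] (or length-256 count vector).
#' @return Integer threshold in `[0, 255]`.
#' @export
max_entropy_threshold <- function(hist) {
  entropy_argmax(hist, alpha = 1)
}

#' Renyi-entropy threshold (three-order weighted rule)
#'
#' Computes three candidate thresholds by maximizing the two-class Renyi
#' criterion at orders `alpha = 0.5, 1, 2` (order 1 being the Kapur
#' criterion), then combines the sorted candidates `t1 <= t2 <= t3` with the
#' weighting rule of Sahoo et al. as implemented in the ImageJ auto-threshold
#' plugin: with cumulative probability `P`, spacing-dependent weights
#' `(b1, b2, b3)` and `omega = P(t3) - P(t1)`,
#' `T = floor(t1 * (P(t1) + 0.25 * omega * b1) + 0.25 * t2 * omega * b2 +
#'            t3 * (1 - P(t3) + 0.25 * omega * b3))`.
#'
#' @inheritParams max_entropy_threshold
#' @return Integer threshold in `[0, 255]`.
#' @export
renyi_threshold <- function(hist) {
  q <- hist_q(hist)
  t_cand <- sort(c(entropy_argmax(hist, 0.5),
                   entropy_argmax(hist, 1),
                   entropy_argmax(hist, 2)))
  t1 <- t_cand[1]; t2 <- t_cand[2]; t3 <- t_cand[3]
  if (abs(t1 - t3) <= 5) {
    if (abs(t2 - t3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(t2 - t3) <= 5) { b <- c(0, 3, 1) } else { b <- c(1, 2, 1) }
  }
  P <- cumsum(q)
  omega <- P[t3 + 1L] - P[t1 + 1L]
  as.integer(floor(
    t1 * (P[t1 + 1L] + 0.25 * omega * b[1]) +
      0.25 * t2 * omega * b[2] +
      t3 * (1 - P[t3 + 1L] + 0.25 * omega * b[3])
  ))
}

#' 3x3 median despeckle filter
#'
#' Median over each pixel's 3x3 neighbourhood with edge-replicated borders;
#' removes single-pixel noise before fixed-value thresholding.
#'
#' @param intensity Integer matrix.
#' @return Filtered integer matrix of the same shape.
#' @export
despeckle <- function(intensity) {
  h <- nrow(intensity); w <- ncol(intensity)
  ri <- c(1L, seq_len(h), h) # replicated border index
  ci <- c(1L, seq_len(w), w)
  p <- intensity[ri, ci, drop = FALSE]
  neigh <- array(0, c(h, w, 9L))
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1L
    neigh[, , k] <- p[di + seq_len(h), dj + seq_len(w)]
  }
  out <- apply(neigh, c(1, 2), stats::median)
  storage.mode(out) <- "integer"
  out
}

#' Remove small foreground components (outlier removal)
#'
#' Drops 8-connected foreground components whose pixel area is below
#' `min_size`. The companion step to [despeckle()] in fixed-threshold
#' pipelines; the published tooling does not state its parameters, so the
#' default (`min_size = 4`) is deliberately conservative and config-exposed.
#'
#' @param mask A binary mask.
#' @param min_size Minimum component area (px^2) to keep.
#' @return An [mp_mask()].
#' @export
remove_outliers <- function(mask, min_size = 4) {
  m <- as_mask_matrix(mask)
  lab <- .label8(m)
  if (max(lab) == 0L) return(mp_mask(m))
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_size)
  mp_mask(matrix(lab %in% keep, nrow(m), ncol(m)) * 1L)
}

#' Specify a classical thresholding (TR) segmenter
#'
#' The four published global-thresholding pipelines share a channel-reduction
#' step and a threshold rule:
#' \describe{
#'   \item{`mp_vat`}{grayscale + Kapur maximum-entropy threshold}
#'   \item{`mp_vat2`}{red channel + three-order Renyi-entropy threshold}
#'   \item{`c_vat`}{grayscale + despeckle + fixed threshold 222 + outlier
#'     removal}
#'   \item{`custom`}{user-supplied channel and fixed threshold (the
#'     batch-mode equivalent of interactive per-image thresholding)}
#' }
#'
#' @param name One of `"custom"`, `"mp_vat"`, `"mp_vat2"`, `"c_vat"`.
#' @param channel Channel reduction, `"gray"` or `"red"` (presets fix this).
#' @param threshold_rule `"fixed"`, `"max_entropy"` or `"renyi"` (presets fix
#'   this).
#' @param fixed_value Threshold for the fixed rule (`custom`; `c_vat`
#'   defaults to 222).
#' @param min_outlier_size Outlier-removal area for `c_vat`.
#' @return A `threshold_model` specification list.
#' @export
threshold_model <- function(name = c("custom", "mp_vat", "mp_vat2", "c_vat"),
                            channel = NULL, threshold_rule = NULL,
                            fixed_value = NULL, min_outlier_size = 4) {
  name <- match.arg(name)
  spec <- switch(name,
    mp_vat  = list(channel = "gray", rule = "max_entropy", fixed = NULL,
                   despeckle = FALSE, outliers = FALSE),
    mp_vat2 = list(channel = "red", rule = "renyi", fixed = NULL,
                   despeckle = FALSE, outliers = FALSE),
    c_vat   = list(channel = "gray", rule = "fixed",
                   fixed = if (is.null(fixed_value)) 222 else fixed_value,
                   despeckle = TRUE, outliers = TRUE),
    custom  = list(channel = if (is.null(channel)) "gray" else channel,
                   rule = if (is.null(threshold_rule)) "fixed" else threshold_rule,
                   fixed = fixed_value, despeckle = FALSE, outliers = FALSE)
  )
  if (spec$rule == "fixed" && is.null(spec$fixed)) {
    stopf("a fixed-threshold model needs fixed_value")
  }
  spec$name <- name
  spec$min_outlier_size <- min_outlier_size
  class(spec) <- "threshold_model"
  spec
}

#' Run a classical thresholding segmenter on an image
#'
#' Applies the model's channel reduction, optional despeckle, threshold rule
#' and optional outlier removal, returning the binary MP mask.
#'
#' @param image An [mp_image()].
#' @param spec A [threshold_model()] (or preset name string).
#' @return An [mp_mask()].
#' @examples
#' img <- mp_image(array(c(250, rep(10, 11)), c(2, 2, 3)))
#' sum(run_tr_model(img, "mp_vat"))
#' @export
run_tr_model <- function(image, spec = "mp_vat") {
  if (is.character(spec)) spec <- threshold_model(spec)
  stopifnot(inherits(spec, "threshold_model"))
  g <- switch(spec$channel,
    gray = to_gray(image),
    red  = red_channel(image),
    stopf("unknown channel '%s'", spec$channel)
  )
  if (isTRUE(spec$despeckle)) g <- despeckle(g)
  T <- switch(spec$rule,
    fixed       = spec$fixed,
    max_entropy = max_entropy_threshold(intensity_histogram(g)),
    renyi       = renyi_threshold(intensity_histogram(g)),
    stopf("unknown threshold rule '%s'", spec$rule)
  )
  m <- binarize(g, T)
  if (isTRUE(spec$outliers)) m <- remove_outliers(m, spec$min_outlier_size)
  m
}
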