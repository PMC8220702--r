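# Independent oracles used across the suite.

# Longest chord of a binary mask by brute force over boundary pixel centers
# (diameter of a point set equals the diameter of its convex hull).
mask_longest_chord_px <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  inner <- matrix(FALSE, n, m)
  inner[2:(n - 1), 2:(m - 1)] <-
    mask[2:(n - 1), 2:(m - 1)] & mask[1:(n - 2), 2:(m - 1)] &
    mask[3:n, 2:(m - 1)] & mask[2:(n - 1), 1:(m - 2)] & mask[2:(n - 1), 3:m]
  boundary <- which(mask & !inner, arr.ind = TRUE)
  if (nrow(boundary) < 2) return(0)
  hull <- grDevices::chull(boundary[, 1], boundary[, 2])
  pts <- boundary[hull, , drop = FALSE]
  dd <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(dd))
}

# Exact least-squares monotone (non-decreasing) step fit by exhaustive
# enumeration of all partitions of 1..n into consecutive blocks; each block
# takes its mean.  The unique minimizer equals the isotonic regression.
brute_force_isotonic <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      means[b] <- mean(y[starts[b]:ends[b]])
      fit[starts[b]:ends[b]] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# The flip-placement rule applied to a monotone fitted sequence: linear
# interpolation of the 0.5 crossing in log-magnification (midpoint of an
# exact-0.5 plateau), clamped at the ladder ends.
crossing_from_fit <- function(ladder, fit, eps = 1e-9) {
  x <- log(ladder)
  lo <- which(fit < 0.5 - eps)
  hi <- which(fit > 0.5 + eps)
  if (length(lo) == 0 && length(hi) == 0) return(exp(mean(range(x))))
  if (length(lo) == 0) return(ladder[1])
  if (length(hi) == 0) return(ladder[length(ladder)])
  i_lo <- max(lo); i_hi <- min(hi)
  xstar <- if (i_hi == i_lo + 1)
    x[i_lo] + (0.5 - fit[i_lo]) / (fit[i_hi] - fit[i_lo]) * (x[i_hi] - x[i_lo])
  else (x[i_lo + 1] + x[i_hi - 1]) / 2
  exp(xstar)
}

# ANOVA mean squares via stats::aov (independent route for the ICC oracle)
icc21_via_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# A toy, linearly separable frame pair: blank background vs a centred disc.
toy_frame <- function(disc, label, radius = 40) {
  patch <- matrix(0, 128, 128)
  if (disc) {
    dr <- matrix(seq_len(128) - 64.5, 128, 128)
    dc <- t(dr)
    patch[dr^2 + dc^2 <= radius^2] <- 1
  }
  lesion_frame(patch, magnification = 1,
               label = label,
               apparent_size_px = if (label == "LARGER") 2 * radius else 10)
}

toy_frame_set <- function(n_each, seed = 1) {
  set.seed(seed)
  frames <- c(lapply(seq_len(n_each), function(i) {
    f <- toy_frame(TRUE, "LARGER")
    f$patch <- f$patch + matrix(rnorm(128 * 128, 0, 0.02), 128, 128)
    f
  }), lapply(seq_len(n_each), function(i) {
    f <- toy_frame(FALSE, "SMALLER")
    f$patch <- f$patch + matrix(rnorm(128 * 128, 0, 0.02), 128, 128)
    f
  }))
  frames[sample(length(frames))]
}

# shared small fixtures (built once per suite run)
fixture_circle_case <- function() {
  synthesize_lesion(phantom_spec(true_diameter_cm = 3.2, aspect_ratio = 1,
                                 pixel_spacing_cm = 0.1, rng_seed = 7),
                    case_id = "circle32")
}
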