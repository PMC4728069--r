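#' Non-normalized Shannon entropy of a coefficient vector
#'
#' Computes \eqn{-\sum_i s_i^2 \ln(s_i^2)} over the raw (unnormalized)
#' coefficients, with the convention that zero coefficients contribute
#' zero. This is the node "impurity" used to choose the decomposition
#' depth: nodes dominated by noise spread energy over many small
#' coefficients and score high, while nodes that capture signal structure
#' concentrate energy and score low. The measure is additive over
#' concatenation, which is what makes per-level maxima comparable.
#'
#' @param coeffs Numeric vector of finite coefficients.
#' @return A single entropy value (0 for an empty vector).
#' @examples
#' node_entropy(c(0, 0, 0))              # 0
#' node_entropy(c(1, 1))                 # 0
#' node_entropy(rep(exp(-0.5), 2))       # 2 / e
#' @export
node_entropy <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) == 0L) {
    return(0)
  }
  if (!all(is.finite(coeffs))) {
    stop("coefficients must be finite")
  }
  s2 <- coeffs[coeffs != 0]^2
  -sum(s2 * log(s2))
}

#' Default configuration for wavelet packet denoising
#'
#' Bundles every knob of the denoising algorithm. The defaults are the
#' published operating point: the discrete Meyer wavelet, soft
#' thresholding at 4.5 standard deviations of the finest-scale detail
#' coefficients, an entropy-selected decomposition depth capped at 10,
#' and symmetric boundary extension.
#'
#' @param wavelet_name Wavelet identifier (see [wavelet_filters()]).
#' @param level_cap Maximum decomposition depth (>= 1). The effective
#'   depth is further capped at `floor(log2(n / filter_length))` so that
#'   every node retains at least one filter length of coefficients.
#' @param threshold_multiplier Threshold in units of the estimated noise
#'   standard deviation (> 0). 4.5 covers 99.99% of Gaussian noise.
#' @param threshold_mode `"soft"` (shrinkage, the default) or `"hard"`
#'   (keep-or-kill).
#' @param boundary_mode `"symmetric"` or `"periodic"` (see
#'   [wp_decompose()]).
#' @param exempt_approximation If `TRUE`, the level's approximation leaf
#'   (index 0) is left unthresholded. Default `FALSE`: all leaves are
#'   thresholded.
#' @param post_filter_band Optional numeric `c(low_hz, high_hz)` band for
#'   the conventional post-filter used by [denoise_and_filter()].
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(wavelet_name = "dmey",
                           level_cap = 10L,
                           threshold_multiplier = 4.5,
                           threshold_mode = c("soft", "hard"),
                           boundary_mode = c("symmetric", "periodic"),
                           exempt_approximation = FALSE,
                           post_filter_band = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  boundary_mode <- match.arg(boundary_mode)
  level_cap <- as.integer(level_cap)
  if (level_cap < 1L) stop("level_cap must be >= 1")
  if (!is.numeric(threshold_multiplier) || threshold_multiplier <= 0) {
    stop("threshold_multiplier must be > 0")
  }
  if (!is.null(post_filter_band)) {
    if (!is.numeric(post_filter_band) || length(post_filter_band) != 2L ||
        post_filter_band[1] < 0 || post_filter_band[2] <= post_filter_band[1]) {
      stop("post_filter_band must be c(low_hz, high_hz) with 0 <= low < high")
    }
  }
  structure(list(
    wavelet_name = wavelet_name,
    level_cap = level_cap,
    threshold_multiplier = threshold_multiplier,
    threshold_mode = threshold_mode,
    boundary_mode = boundary_mode,
    exempt_approximation = exempt_approximation,
    post_filter_band = post_filter_band
  ), class = "denoise_config")
}

#' @export
print.denoise_config <- function(x, ...) {
  cat(sprintf(
    "<denoise_config> %s, %s threshold %.2f sigma, level cap %d, %s boundary\n",
    x$wavelet_name, x$threshold_mode, x$threshold_multiplier, x$level_cap,
    x$boundary_mode))
  invisible(x)
}

# deepest level at which every node still holds at least one filter
# length of coefficients
max_feasible_level <- function(n, filter_length, level_cap) {
  feas <- floor(log2(n / filter_length))
  as.integer(min(level_cap, max(feas, 0L)))
}

# Grow the packet tree one level at a time until the maximum node entropy
# at level L drops below the maximum at level L+1 (ties keep deepening).
# Returns the selected level and the levels built so far, so denoise()
# does not decompose twice.
wp_grow_best <- function(x, w, config) {
  cap <- max_feasible_level(length(x), w$length, config$level_cap)
  if (cap < 1L) {
    stop("signal too short to decompose: need at least ",
         2 * w$length, " samples for ", w$name)
  }
  mode <- config$boundary_mode
  levels <- vector("list", cap + 2L)
  levels[[1L]] <- list(x)
  levels[[2L]] <- wp_split_level(levels[[1L]], w, mode)
  max_ent <- function(nodes) max(vapply(nodes, node_entropy, numeric(1)))
  ent_l <- max_ent(levels[[2L]])
  best <- cap
  for (l in seq_len(cap)) {
    if (l == cap) break
    levels[[l + 2L]] <- wp_split_level(levels[[l + 1L]], w, mode)
    ent_next <- max_ent(levels[[l + 2L]])
    if (ent_l < ent_next) {
      best <- l
      break
    }
    ent_l <- ent_next
  }
  list(level = best, levels = levels[seq_len(best + 1L)])
}

#' Entropy-based selection of the decomposition depth
#'
#' Grows the wavelet packet tree top-down, one full level at a time, and
#' stops at the first level \eqn{L} whose maximum node entropy is lower
#' than the maximum node entropy of its children at level \eqn{L + 1};
#' that \eqn{L} is returned. Equal maxima keep the decomposition going.
#' The depth is capped at `min(level_cap, floor(log2(n / filter_length)))`
#' so that no node shrinks below one filter length.
#'
#' @inheritParams wp_decompose
#' @param config A [denoise_config()].
#' @return The selected decomposition level (integer >= 1).
#' @export
best_level <- function(signal, wavelet = NULL, config = denoise_config()) {
  x <- as_samples(signal)
  w <- if (is.null(wavelet)) wavelet_filters(config$wavelet_name) else as_wavelet(wavelet)
  wp_grow_best(x, w, config)$level
}

#' Noise standard deviation from the finest-scale detail node
#'
#' Estimates the noise level as the population standard deviation of the
#' level-1 detail coefficients — the finest time scale, where (for
#' approximately Gaussian background noise) the coefficients are almost
#' entirely noise. The denoising threshold is a multiple of this value.
#'
#' @param tree A `wp_tree` of depth >= 1.
#' @return Estimated noise standard deviation.
#' @export
estimate_noise_sigma <- function(tree) {
  stopifnot(inherits(tree, "wp_tree"))
  if (tree$max_level < 1L || length(tree$levels) < 2L ||
      length(tree$levels[[2L]]) < 2L) {
    stop("corrupt tree: level-1 detail node missing")
  }
  d <- tree$levels[[2L]][[2L]]
  sqrt(mean((d - mean(d))^2))
}

#' Soft and hard thresholding
#'
#' `soft_threshold()` shrinks every coefficient towards zero by `thr`,
#' zeroing those whose magnitude is below it:
#' \eqn{\mathrm{sign}(x)\max(|x| - t, 0)}. It is continuous and
#' non-expansive, which is what avoids the ringing artifacts of hard
#' thresholding. `hard_threshold()` is the keep-or-kill alternative.
#'
#' @param values Numeric coefficients.
#' @param thr Threshold (>= 0).
#' @return Thresholded coefficients, same length.
#' @examples
#' soft_threshold(c(5, -1, -5), 2)  # 3, 0, -3
#' @export
soft_threshold <- function(values, thr) {
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) || thr < 0) {
    stop("threshold must be a single non-negative number")
  }
  sign(values) * pmax(abs(values) - thr, 0)
}

#' @rdname soft_threshold
#' @export
hard_threshold <- function(values, thr) {
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) || thr < 0) {
    stop("threshold must be a single non-negative number")
  }
  values * (abs(values) > thr)
}

#' Threshold the leaves of a wavelet packet tree
#'
#' Applies the configured threshold (soft by default) to the coefficients
#' of every leaf node at the deepest level of the tree. A single global
#' threshold is applied at each node. With `exempt_approximation` set in
#' the config, the approximation leaf (index 0) is left untouched.
#' Internal levels are not modified — reconstruction only reads the
#' leaves.
#'
#' @param tree A `wp_tree`.
#' @param thr Threshold value (>= 0).
#' @param config A [denoise_config()] (controls soft/hard and the
#'   approximation exemption).
#' @return A new `wp_tree` with thresholded leaves.
#' @export
threshold_tree <- function(tree, thr, config = denoise_config()) {
  stopifnot(inherits(tree, "wp_tree"))
  f <- if (config$threshold_mode == "hard") hard_threshold else soft_threshold
  leaves <- tree$levels[[tree$max_level + 1L]]
  start <- if (isTRUE(config$exempt_approximation)) 2L else 1L
  if (start <= length(leaves)) {
    for (i in seq(start, length(leaves))) {
      leaves[[i]] <- f(leaves[[i]], thr)
    }
  }
  tree$levels[[tree$max_level + 1L]] <- leaves
  tree
}

#' Wavelet packet denoising
#'
#' The complete denoising pipeline: select the decomposition depth by the
#' entropy criterion ([best_level()]), decompose, estimate the noise
#' standard deviation from the finest-scale detail coefficients
#' ([estimate_noise_sigma()]), soft-threshold every leaf at
#' `threshold_multiplier` times that estimate, and invert the transform.
#' Output has the same length and sample rate as the input.
#'
#' @param signal An [audio_signal()] or numeric vector.
#' @param config A [denoise_config()].
#' @return Denoised signal of the same class, length and sample rate.
#' @examples
#' set.seed(1)
#' x <- audio_signal(sin(2 * pi * 40 * (0:4095) / 4000) + rnorm(4096), 4000)
#' y <- denoise(x)
#' var(y$samples) < var(x$samples)
#' @export
denoise <- function(signal, config = denoise_config()) {
  x <- as_samples(signal)
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  w <- wavelet_filters(config$wavelet_name)
  grown <- wp_grow_best(x, w, config)
  level <- grown$level
  levels <- grown$levels
  # wp_grow_best may have stopped early; complete the tree to `level`
  while (length(levels) < level + 1L) {
    levels[[length(levels) + 1L]] <-
      wp_split_level(levels[[length(levels)]], w, config$boundary_mode)
  }
  tree <- structure(list(
    wavelet = w,
    mode = config$boundary_mode,
    max_level = level,
    original_length = length(x),
    sample_rate = if (inherits(signal, "audio_signal")) signal$sample_rate else NA_real_,
    levels = levels
  ), class = "wp_tree")
  thr <- config$threshold_multiplier * estimate_noise_sigma(tree)
  tree <- threshold_tree(tree, thr, config)
  out <- wp_reconstruct(tree)
  if (inherits(signal, "audio_signal") && !inherits(out, "audio_signal")) {
    out <- audio_signal(out, signal$sample_rate)
  }
  out
}

#' Data-driven mother wavelet selection
#'
#' Denoises the signal once per candidate wavelet and scores each
#' candidate by the Pearson correlation between the input and its
#' denoised output; the candidate with the highest correlation wins
#' (ties broken by candidate order). High correlation indicates that the
#' wavelet removed noise without distorting the underlying signal.
#'
#' @param signal An [audio_signal()] or numeric vector (non-constant).
#' @param candidates Character vector of wavelet names.
#' @param config A [denoise_config()]; its `wavelet_name` is overridden
#'   per candidate.
#' @return A list with `best` (the winning name) and `scores` (named
#'   numeric vector of correlations).
#' @export
select_wavelet <- function(signal, candidates = c("db2", "db6", "db10", "dmey"),
                           config = denoise_config()) {
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  x <- as_samples(signal)
  if (stats::sd(x) == 0) {
    stop("degenerate input: constant signal has no defined correlation")
  }
  scores <- vapply(candidates, function(nm) {
    cfg <- config
    cfg$wavelet_name <- nm
    y <- as_samples(denoise(signal, cfg))
    if (stats::sd(y) == 0) -Inf else stats::cor(x, y)
  }, numeric(1))
  names(scores) <- candidates
  list(best = candidates[[which.max(scores)]], scores = scores)
}
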