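#' @name wp_tree
#' @title Wavelet packet trees
#' @description
#' A wavelet packet decomposition recursively splits both the
#' approximation (low-pass) and the detail (high-pass) branch of a
#' two-channel filter bank, so level \eqn{L} of the tree holds \eqn{2^L}
#' equal-bandwidth coefficient nodes. The tree retains every level from
#' the root (the input samples) down to `max_level`, which is what makes
#' exact inversion possible after the leaves are modified.
#'
#' Nodes are indexed in natural (Paley) order: the children of node
#' `(level, i)` are `(level + 1, 2i)` (low-pass) and `(level + 1, 2i + 1)`
#' (high-pass), with indices counted from zero.
NULL

# supported boundary-extension modes; "periodic" is critically-sampled
# periodization, which keeps exactly ceil(n/2) coefficients per branch and
# makes orthonormal filter banks energy-preserving.
wp_modes <- c("symmetric", "periodic")

normalize_mode <- function(mode) {
  mode <- match.arg(tolower(mode), c(wp_modes, "periodization"))
  if (mode == "periodization") "periodic" else mode
}

# full linear convolution a * h (ascending index)
conv_full <- function(a, h) {
  stats::convolve(a, rev(h), type = "open")
}

# 1-based index mapping for half-point symmetric extension of 1..n;
# valid for arbitrarily long extensions (repeated reflection).
sym_idx <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# one analysis step: split x into approximation and detail coefficients
dwt_step <- function(x, w, mode) {
  L <- w$length
  n <- length(x)
  if (mode == "symmetric") {
    p <- L - 1
    ext <- x[sym_idx(seq(1 - p, n + p), n)]
    len_out <- (n + L - 1) %/% 2
    start <- L + 1
  } else {
    if (n %% 2 == 1) {          # pad odd lengths by repeating the edge
      x <- c(x, x[n])
      n <- n + 1
    }
    ext <- x[((seq(1 - L, n + L) - 1) %% n) + 1]
    len_out <- n %/% 2
    start <- 3 * L / 2 + 1
  }
  sel <- seq(start, by = 2, length.out = len_out)
  list(a = conv_full(ext, w$dec_lo)[sel],
       d = conv_full(ext, w$dec_hi)[sel])
}

# one synthesis step, trimmed to the parent node's length
idwt_step <- function(a, d, w, mode, out_len) {
  if (length(a) != length(d)) {
    stop("corrupt tree: sibling nodes have different lengths (",
         length(a), " vs ", length(d), ")")
  }
  L <- w$length
  La <- length(a)
  m <- 2 * La
  up_a <- numeric(m)
  up_d <- numeric(m)
  up_a[seq(1, by = 2, length.out = La)] <- a
  up_d[seq(1, by = 2, length.out = La)] <- d
  if (mode == "symmetric") {
    full <- conv_full(up_a, w$rec_lo) + conv_full(up_d, w$rec_hi)
    rec <- full[seq(L - 1, length.out = m - L + 2)]
  } else {
    ext_a <- up_a[((seq(1 - L, m + L) - 1) %% m) + 1]
    ext_d <- up_d[((seq(1 - L, m + L) - 1) %% m) + 1]
    full <- conv_full(ext_a, w$rec_lo) + conv_full(ext_d, w$rec_hi)
    rec <- full[seq(L + L / 2, length.out = m)]
  }
  if (length(rec) < out_len) {
    stop("corrupt tree: node too short to reconstruct parent of length ",
         out_len)
  }
  rec[seq_len(out_len)]
}

# grow one more level from a list of node coefficient vectors
wp_split_level <- function(nodes, w, mode) {
  out <- vector("list", 2L * length(nodes))
  for (i in seq_along(nodes)) {
    ad <- dwt_step(nodes[[i]], w, mode)
    out[[2L * i - 1L]] <- ad$a
    out[[2L * i]] <- ad$d
  }
  out
}

#' Wavelet packet decomposition
#'
#' Decomposes a signal into a complete wavelet packet tree of the given
#' depth. Every level from 0 (the input itself) to `level` is retained so
#' that [wp_reconstruct()] can invert the transform exactly, including
#' after the leaf coefficients have been thresholded.
#'
#' @param signal An [audio_signal()] or numeric vector.
#' @param wavelet A wavelet name or a `wavelet_spec` from
#'   [wavelet_filters()].
#' @param level Decomposition depth (>= 1).
#' @param mode Boundary extension: `"symmetric"` (half-point reflection,
#'   the default; fewest edge artifacts on audio) or `"periodic"`
#'   (critically-sampled periodization, under which orthonormal wavelets
#'   conserve energy exactly).
#' @return An object of class `wp_tree`.
#' @examples
#' x <- audio_signal(rnorm(512), 8000)
#' tr <- wp_decompose(x, "db4", level = 3)
#' length(wp_level(tr, 3))  # 8 leaf nodes
#' @export
wp_decompose <- function(signal, wavelet, level, mode = "symmetric") {
  x <- as_samples(signal)
  if (length(x) == 0L) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  level <- as.integer(level)
  if (level < 1L) stop("decomposition level must be >= 1")
  w <- as_wavelet(wavelet)
  mode <- normalize_mode(mode)
  if (mode == "periodic" && length(x) < 2^level) {
    stop("signal too short for level ", level,
         " decomposition: every node needs at least one coefficient")
  }
  levels <- vector("list", level + 1L)
  levels[[1L]] <- list(x)
  for (l in seq_len(level)) {
    levels[[l + 1L]] <- wp_split_level(levels[[l]], w, mode)
  }
  structure(list(
    wavelet = w,
    mode = mode,
    max_level = level,
    original_length = length(x),
    sample_rate = if (inherits(signal, "audio_signal")) signal$sample_rate else NA_real_,
    levels = levels
  ), class = "wp_tree")
}

#' @export
print.wp_tree <- function(x, ...) {
  cat(sprintf("<wp_tree> %s/%s, depth %d, %d leaves, input length %d\n",
              x$wavelet$name, x$mode, x$max_level, 2^x$max_level,
              x$original_length))
  invisible(x)
}

#' Access wavelet packet nodes
#'
#' `wp_level()` returns the list of coefficient vectors at one level of
#' the tree (in natural order); `wp_node()` returns a single node.
#'
#' @param tree A `wp_tree`.
#' @param level Level, 0 (root) to `tree$max_level`.
#' @param index Node position within the level, 0 to `2^level - 1`.
#' @return A list of numeric vectors, or one numeric vector.
#' @export
wp_level <- function(tree, level) {
  stopifnot(inherits(tree, "wp_tree"))
  level <- as.integer(level)
  if (level < 0L || level > tree$max_level) {
    stop("level must be between 0 and ", tree$max_level)
  }
  tree$levels[[level + 1L]]
}

#' @rdname wp_level
#' @export
wp_node <- function(tree, level, index) {
  nodes <- wp_level(tree, level)
  index <- as.integer(index)
  if (index < 0L || index >= length(nodes)) {
    stop("index must be between 0 and ", length(nodes) - 1L,
         " at level ", level)
  }
  nodes[[index + 1L]]
}

#' Invert a wavelet packet decomposition
#'
#' Reconstructs the time-domain signal from the leaf coefficients of a
#' wavelet packet tree, pairwise-merging siblings up the tree. Upper
#' levels supply only the node lengths needed for exact trimming, so the
#' reconstruction reflects any modification made to the leaves.
#'
#' @param tree A `wp_tree` from [wp_decompose()] (leaves possibly
#'   modified, e.g. by [threshold_tree()]).
#' @return An [audio_signal()] when the tree was built from one (sample
#'   rate preserved), otherwise a numeric vector, of the original length.
#' @export
wp_reconstruct <- function(tree) {
  stopifnot(inherits(tree, "wp_tree"))
  w <- tree$wavelet
  current <- tree$levels[[tree$max_level + 1L]]
  if (length(current) != 2^tree$max_level) {
    stop("corrupt tree: expected ", 2^tree$max_level, " leaf nodes")
  }
  for (l in seq(tree$max_level, 1L)) {
    parents <- tree$levels[[l]]
    merged <- vector("list", length(parents))
    for (i in seq_along(parents)) {
      merged[[i]] <- idwt_step(current[[2L * i - 1L]], current[[2L * i]],
                               w, tree$mode, length(parents[[i]]))
    }
    current <- merged
  }
  out <- current[[1L]]
  if (!is.na(tree$sample_rate)) audio_signal(out, tree$sample_rate) else out
}
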