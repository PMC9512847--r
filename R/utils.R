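#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold: the cut maximizing between-class variance.
#' Used for colony segmentation, nuclear foreground extraction and batch-level
#' EdU positivity.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) {
    stop("otsu_threshold: input is constant, no threshold separates classes",
         call. = FALSE)
  }
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bcv)]
}

# FNV-1a hash of a character string, returned as 8 hex digits. Deterministic,
# dependency-free; used only to fingerprint configs in manifests.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on the low byte only (b < 256); h may exceed .Machine integers
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit modular multiply, split to stay within double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * p) %% 65536 * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint a configuration object
#'
#' Deterministic 32-bit hash of the deparsed object; changes whenever any
#' field changes. Embedded in dataset manifests and pipeline reports.
#'
#' @param x any R object (typically a config list).
#' @return 8-character hex string.
#' @export
config_hash <- function(x) {
  fnv1a_hash(paste(deparse(x, control = "all"), collapse = "\n"))
}

# Derive a per-item 32-bit seed from a root seed (counter-based split so any
# subset of colonies is reproducible without generating the rest).
derive_seed <- function(root_seed, index) {
  as.integer((as.numeric(root_seed) * 100003 + as.numeric(index) * 7919 + 17) %%
               2147483647)
}

# Population standard deviation (divide by N, not N-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Spearman rank correlation without the cor.test machinery.
spearman <- function(x, y) stats::cor(rank(x), rank(y))

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to relabeling), approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Clamp helper.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
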