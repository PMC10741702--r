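#' Synthetic dataset container
#'
#' All test and demonstration inputs are generated in-package from a seed;
#' a `cp_dataset` bundles a pattern matrix in \[0, 1\], optional integer
#' labels and generator metadata, and regenerates bit-identically from the
#' same seed.
#'
#' @param patterns Numeric matrix in \[0, 1\], one pattern per row.
#' @param labels Optional integer labels, one per row.
#' @param meta Named list of generator metadata (name, seed, parameters).
#' @return An object of class `cp_dataset`.
#' @export
cp_dataset <- function(patterns, labels = NULL, meta = list()) {
  patterns <- as.matrix(patterns)
  check_unit(patterns, "patterns")
  if (!is.null(labels) && length(labels) != nrow(patterns))
    stop("'labels' length must match the number of patterns")
  structure(list(patterns = patterns, labels = labels, meta = meta),
            class = "cp_dataset")
}

#' @export
print.cp_dataset <- function(x, ...) {
  cat(sprintf("<cp_dataset> %d patterns x %d features%s (%s)\n",
              nrow(x$patterns), ncol(x$patterns),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", length(unique(x$labels))),
              if (is.null(x$meta$generator)) "?" else x$meta$generator))
  invisible(x)
}

#' The XOR truth table
#'
#' The four Boolean patterns with label `x1 XOR x2`: the canonical
#' linearly non-separable two-class problem.
#'
#' @return A [cp_dataset()] with 4 patterns and labels `0, 1, 1, 0`.
#' @export
xor_dataset <- function() {
  cp_dataset(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
             labels = c(0L, 1L, 1L, 0L),
             meta = list(generator = "xor"))
}

#' Correlated Bernoulli firing streams
#'
#' Draws `n` i.i.d. pairs of binary firing events `(I, O)` with
#' `P(I = 1) = p_i`, `P(O = 1 | I = 1) = p_o_given_i1` and
#' `P(O = 1 | I = 0) = p_o_given_i0`. Used to verify that the presynaptic
#' rule drives a synaptic weight towards the conditional firing probability
#' `P(O = 1 | I = 1)`.
#'
#' @param p_i Presynaptic firing probability.
#' @param p_o_given_i1,p_o_given_i0 Conditional postsynaptic probabilities.
#' @param n Number of pairs (>= 1).
#' @param seed Integer seed.
#' @return List with integer vectors `I` and `O` of length `n`.
#' @export
bernoulli_pair_stream <- function(p_i, p_o_given_i1, p_o_given_i0, n, seed) {
  check_unit(c(p_i, p_o_given_i1, p_o_given_i0), "probabilities")
  stopifnot(n >= 1)
  set.seed(seed)
  I <- as.integer(stats::runif(n) < p_i)
  O <- as.integer(stats::runif(n) < ifelse(I == 1, p_o_given_i1, p_o_given_i0))
  list(I = I, O = O)
}

#' Gaussian cluster sets
#'
#' `k` isotropic Gaussian clusters with deterministic means on a lattice
#' inside `[0.2, 0.8]^dim` (so cluster placement depends only on `(k, dim)`),
#' sampled with the given spread and clipped to \[0, 1\].
#'
#' @param k Number of clusters (>= 1).
#' @param n_per Patterns per cluster.
#' @param dim Dimensionality.
#' @param spread Standard deviation of each cluster.
#' @param seed Integer seed.
#' @return A labelled [cp_dataset()] with `k * n_per` patterns; labels are
#'   cluster indices `0 .. k-1`.
#' @export
gaussian_clusters <- function(k, n_per, dim = 2, spread = 0.05, seed = 1) {
  stopifnot(k >= 1, n_per >= 1, dim >= 1, spread >= 0)
  mu <- cluster_means(k, dim)
  set.seed(seed)
  pat <- matrix(NA_real_, k * n_per, dim)
  lab <- integer(k * n_per)
  for (c in seq_len(k)) {
    idx <- (c - 1) * n_per + seq_len(n_per)
    pat[idx, ] <- matrix(stats::rnorm(n_per * dim, 0, spread), n_per, dim,
                         byrow = TRUE) + matrix(mu[c, ], n_per, dim, byrow = TRUE)
    lab[idx] <- c - 1L
  }
  pat <- pmin(pmax(pat, 0), 1)
  cp_dataset(pat, labels = lab,
             meta = list(generator = "gaussian_clusters", seed = seed,
                         k = k, n_per = n_per, dim = dim, spread = spread))
}

# internal: deterministic cluster means on a {0.2, 0.5, 0.8}^dim lattice.
# Two levels (corners) are used while they suffice; three beyond that.
cluster_means <- function(k, dim) {
  levels <- if (k <= 2^dim) c(0.2, 0.8) else c(0.2, 0.5, 0.8)
  if (k > length(levels)^dim)
    stop("too many clusters for the deterministic mean lattice")
  mu <- matrix(NA_real_, k, dim)
  for (i in seq_len(k)) {
    digits <- integer(dim)
    v <- i - 1
    for (d in seq_len(dim)) {
      digits[d] <- v %% length(levels)
      v <- v %/% length(levels)
    }
    mu[i, ] <- levels[digits + 1]
  }
  mu
}

#' Frequency-skewed pattern stream
#'
#' Draws `n` patterns from a fixed set with prescribed presentation
#' frequencies; used to exercise artificial metaplasticity, which should
#' learn more from the rare patterns.
#'
#' @param patterns Matrix of candidate patterns (one per row).
#' @param freqs Probability vector over rows, summing to 1.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A [cp_dataset()] whose labels are the source row indices
#'   (0-based).
#' @export
skewed_frequency_dataset <- function(patterns, freqs, n, seed) {
  patterns <- as.matrix(patterns)
  if (length(freqs) != nrow(patterns)) stop("'freqs' must have one entry per pattern")
  if (abs(sum(freqs) - 1) > 1e-8) stop("'freqs' must sum to 1")
  stopifnot(n >= 1)
  set.seed(seed)
  idx <- sample.int(nrow(patterns), n, replace = TRUE, prob = freqs)
  cp_dataset(patterns[idx, , drop = FALSE], labels = as.integer(idx - 1),
             meta = list(generator = "skewed_frequency", seed = seed,
                         freqs = freqs, n = n))
}

#' Write / read a dataset in the package CSV dialect
#'
#' Comma-separated, header row, UTF-8, '.' decimal; feature columns `x1..xd`
#' and an optional `label` column. Floats are serialized with 17 significant
#' digits so a written dataset reads back bit-exactly.
#'
#' @param dataset A [cp_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cp_dataset"))
  cols <- lapply(seq_len(ncol(dataset$patterns)),
                 function(j) fmt17(dataset$patterns[, j]))
  names(cols) <- paste0("x", seq_along(cols))
  df <- as.data.frame(cols)
  if (!is.null(dataset$labels)) df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  feat <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (length(feat) == 0) stop("no feature columns 'x1..xd' found in ", path)
  pat <- as.matrix(df[, feat, drop = FALSE])
  dimnames(pat) <- NULL
  if (anyNA(pat)) stop("NA/NaN values in ", path)
  labels <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  cp_dataset(pat, labels = labels, meta = list(generator = "csv", path = path))
}

# internal: shortest 17-significant-digit decimal representation
fmt17 <- function(x) sprintf("%.17g", x)
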