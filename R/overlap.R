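#' Density-overlap index between two diameter distributions
#'
#' The overlap index is the integral of the pointwise minimum of two
#' kernel-density estimates: 1 for identical distributions, 0 for disjoint
#' ones. Each sample gets a Gaussian kernel with its own Silverman
#' bandwidth; both densities are evaluated on a common equispaced grid
#' spanning the union of the two ranges padded by three bandwidths, and the
#' minimum is integrated by the trapezoidal rule, clamped to `[0, 1]`.
#'
#' @param a,b Particle tibbles (column `diameter_um`) or numeric vectors;
#'   each needs at least 2 distinct values.
#' @param n_grid Number of grid points for the density evaluation.
#' @return The overlap index, a number in `[0, 1]`.
#' @examples
#' x <- rnorm(500); y <- rnorm(500, 2)
#' overlap_index(x, y)
#' @export
overlap_index <- function(a, b, n_grid = 1024) {
  xa <- .diameter_vector(a)
  xb <- .diameter_vector(b)
  for (v in list(xa, xb)) {
    if (length(unique(v)) < 2) {
      abort("Overlap needs samples with at least 2 distinct values.",
            class = "phenoswitch_degenerate_error")
    }
  }
  bw_a <- bw.nrd0(xa)
  bw_b <- bw.nrd0(xb)
  pad <- 3 * max(bw_a, bw_b)
  lo <- min(xa, xb) - pad
  hi <- max(xa, xb) + pad
  fa <- density(xa, bw = bw_a, from = lo, to = hi, n = n_grid)
  fb <- density(xb, bw = bw_b, from = lo, to = hi, n = n_grid)
  eta <- .trapz(fa$x, pmin(fa$y, fb$y))
  min(max(eta, 0), 1)
}

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Pairwise overlap matrix of a set of diameter samples
#'
#' Computes the overlap index for every unordered pair of samples (each
#' pair once, so the matrix is symmetric by construction) with the diagonal
#' set to 1.
#'
#' @param data A particle tibble covering several samples (grouped by the
#'   columns in `by`), or a named list of numeric diameter vectors.
#' @param by Grouping columns identifying a sample (defaults to
#'   `sample_id` and, if present, `time_h`).
#' @param n_grid Passed to [overlap_index()].
#' @return An object of class `overlap_matrix` with fields `labels` and
#'   `eta` (square numeric matrix). `as.matrix()` extracts the matrix.
#' @seealso [cluster_overlap()]
#' @export
overlap_matrix <- function(data, by = NULL, n_grid = 1024) {
  groups <- .sample_groups(data, by)
  k <- length(groups)
  if (k < 2) {
    abort("Overlap matrix needs at least 2 samples.",
          class = "phenoswitch_validation_error")
  }
  labels <- names(groups)
  eta <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      val <- tryCatch(
        overlap_index(groups[[i]], groups[[j]], n_grid = n_grid),
        error = function(e) {
          abort(sprintf("overlap_index failed for pair (%s, %s): %s",
                        labels[i], labels[j], conditionMessage(e)),
                class = "phenoswitch_degenerate_error")
        }
      )
      eta[i, j] <- val
      eta[j, i] <- val
    }
  }
  dimnames(eta) <- list(labels, labels)
  structure(list(labels = labels, eta = eta), class = "overlap_matrix")
}

.sample_groups <- function(data, by = NULL) {
  if (is.list(data) && !is.data.frame(data)) {
    stopifnot(!is.null(names(data)))
    return(lapply(data, as.numeric))
  }
  .require_columns(data, "diameter_um", "particle table")
  if (is.null(by)) by <- intersect(c("sample_id", "time_h"), names(data))
  if (length(by) == 0) {
    abort("No grouping columns found; supply `by`.",
          class = "phenoswitch_validation_error")
  }
  key <- do.call(paste, c(unname(data[by]), sep = "/"))
  split(data$diameter_um, factor(key, levels = unique(key)))
}

#' @export
as.matrix.overlap_matrix <- function(x, ...) x$eta

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix>", length(x$labels), "samples\n")
  print(round(x$eta, 3))
  invisible(x)
}

#' Tidy an overlap matrix into long pair form
#'
#' @param x An `overlap_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample_a`, `sample_b`, `eta`, one row per
#'   unordered pair (diagonal excluded).
#' @method tidy overlap_matrix
#' @export
tidy.overlap_matrix <- function(x, ...) {
  k <- length(x$labels)
  idx <- which(upper.tri(x$eta), arr.ind = TRUE)
  tibble(
    sample_a = x$labels[idx[, 1]],
    sample_b = x$labels[idx[, 2]],
    eta = x$eta[idx]
  )
}

#' Hierarchically cluster samples by their overlap profiles
#'
#' Agglomerative clustering of the rows of an overlap matrix, using
#' Euclidean distances between rows and Ward-D2 linkage, so samples whose
#' overlap profiles across the whole set are alike merge early. Merge
#' heights are non-decreasing.
#'
#' @param matrix An [overlap_matrix()] with at least 3 samples.
#' @return An object of class `overlap_clustering` wrapping the `hclust`
#'   tree; `tidy()` returns the flat merge table (parent/child/height).
#' @export
cluster_overlap <- function(matrix) {
  stopifnot(inherits(matrix, "overlap_matrix"))
  if (length(matrix$labels) < 3) {
    abort("Clustering needs at least 3 samples.",
          class = "phenoswitch_validation_error")
  }
  hc <- hclust(dist(matrix$eta, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc, labels = matrix$labels),
            class = "overlap_clustering")
}

#' @export
print.overlap_clustering <- function(x, ...) {
  cat("<overlap_clustering> Ward-D2 tree of", length(x$labels), "samples\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Flatten a clustering tree into a parent/child/height table
#'
#' @param x An `overlap_clustering`.
#' @param ... Unused.
#' @return A tibble with one row per child of each merge: `parent` (merge
#'   index, 1-based), `child` (a sample label or `"merge:<i>"` for an
#'   earlier merge) and the merge `height`.
#' @method tidy overlap_clustering
#' @export
tidy.overlap_clustering <- function(x, ...) {
  hc <- x$hclust
  m <- hc$merge
  child_label <- function(v) {
    out <- character(length(v))
    out[v < 0] <- hc$labels[-v[v < 0]]
    out[v > 0] <- paste0("merge:", v[v > 0])
    out
  }
  tibble(
    parent = rep(seq_len(nrow(m)), each = 2),
    child = child_label(as.vector(t(m))),
    height = rep(hc$height, each = 2)
  )
}
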