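#' Multi-class ReliefF feature weighting
#'
#' Scores each feature by how well it separates nearest neighbours of the
#' same class (hits) from nearest neighbours of every other class (misses).
#' For each of \code{m_samples} sampled instances \code{R} the weight of
#' feature \code{f} is updated by
#' \deqn{W_f \leftarrow W_f - \sum_{h} \mathrm{diff}(f, R, h)/(mk)
#'   + \sum_{C \ne cl(R)} \frac{P(C)}{1 - P(cl(R))}
#'     \sum_{m_C} \mathrm{diff}(f, R, m_C)/(mk)}
#' where \code{diff} is the absolute difference scaled by the feature's
#' observed range and neighbours are the \code{k} nearest by Manhattan
#' distance on the range-scaled features.
#'
#' @param X numeric matrix, n instances x p features (sentinel rows must be
#'   excluded beforehand).
#' @param y class labels, length n.
#' @param k_neighbors number of nearest hits/misses per class (default 10).
#' @param m_samples number of instances to sample; \code{NULL} (default) uses
#'   every instance once, in order.
#' @param seed integer seed controlling the instance sample (only used when
#'   \code{m_samples} is given).
#' @return list with \code{weights} (named numeric, length p) and
#'   \code{ranking} (feature names in descending weight order; ties broken by
#'   column order).
#' @export
relieff_rank <- function(X, y, k_neighbors = 10L, m_samples = NULL,
                         seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  y <- as.vector(y)
  stopifnot(length(y) == n, k_neighbors >= 1L)
  if (any(!is.finite(X))) stop("X contains non-finite values; drop sentinel rows first")

  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  small <- names(counts)[counts < k_neighbors + 1L]
  if (length(small) > 0L)
    stop("class(es) ", paste(small, collapse = ", "), " have fewer than k_neighbors + 1 = ",
         k_neighbors + 1L, " members")
  prior <- as.numeric(counts) / n
  names(prior) <- names(counts)

  rng <- apply(X, 2L, function(col) diff(range(col)))
  rng[rng == 0] <- 1  # constant features contribute no diff either way
  Xs <- sweep(X, 2L, rng, "/")

  if (is.null(m_samples)) {
    idx <- seq_len(n)
  } else {
    set.seed(as.integer(seed))
    idx <- sample.int(n, min(m_samples, n))
  }
  m <- length(idx)
  k <- as.integer(k_neighbors)

  by_class <- split(seq_len(n), factor(y, levels = classes))
  W <- numeric(p)
  for (i in idx) {
    d <- colSums(abs(t(Xs) - Xs[i, ]))  # Manhattan distances to all rows
    cl <- as.character(y[i])
    for (cname in names(by_class)) {
      members <- by_class[[cname]]
      if (cname == cl) members <- setdiff(members, i)
      nb <- members[order(d[members])[seq_len(k)]]
      contrib <- colSums(abs(Xs[nb, , drop = FALSE] -
                             matrix(Xs[i, ], k, p, byrow = TRUE)))
      if (cname == cl) {
        W <- W - contrib / (m * k)
      } else {
        W <- W + (prior[[cname]] / (1 - prior[[cl]])) * contrib / (m * k)
      }
    }
  }
  names(W) <- colnames(X)
  list(weights = W,
       ranking = colnames(X)[order(-W)])
}
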