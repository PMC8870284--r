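# Functional network construction: Pearson connectivity per epoch, then
# sparsity thresholding to a fixed edge density so all subjects' networks are
# compared at equal wiring cost.

#' Pearson correlation connectivity matrix of an epoch
#'
#' r[x, y] = cov(x, y) / sqrt(var(x) var(y)) over the epoch's samples, for
#' every channel pair. Symmetric with unit diagonal.
#'
#' @param epoch an \code{eeg_epoch} (or any channels-x-samples matrix).
#' @return object of class \code{connectivity_matrix}: the N x N correlation
#'   matrix with channel labels as dimnames and epoch tags as attributes.
#' @export
pearson_matrix <- function(epoch) {
  data <- if (inherits(epoch, "eeg_epoch")) epoch$data else as.matrix(epoch)
  if (ncol(data) < 2L) stop_input("need at least 2 samples per channel")
  v <- apply(data, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(data)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop_numeric("zero-variance channel(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(data))
  diag(r) <- 1
  attr(r, "epoch_index") <- if (inherits(epoch, "eeg_epoch")) epoch$epoch_index else NA
  class(r) <- c("connectivity_matrix", "matrix")
  r
}

#' Threshold a connectivity matrix to a fixed-density network
#'
#' Ranks the N(N-1)/2 channel pairs by absolute correlation (descending) and
#' retains the top \code{round(density * N(N-1)/2)} as edges. Retained edges
#' carry weight |r| (weighted mode) or 1 (binary mode); everything else,
#' including the diagonal, is 0. Ties crossing the cutoff are broken
#' deterministically by lexicographic (row, column) index order.
#'
#' @param cm a \code{connectivity_matrix} (or symmetric numeric matrix).
#' @param density fraction of possible edges to retain, in (0, 1].
#' @param mode \code{"weighted"} or \code{"binary"}.
#' @return object of class \code{eeg_network}: list with \code{w} (N x N
#'   adjacency), \code{density} (requested), \code{n_edges}, \code{mode}.
#' @export
sparsity_threshold <- function(cm, density = 0.3, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  r <- unclass(as.matrix(cm))
  n <- nrow(r)
  if (n != ncol(r)) stop_input("connectivity matrix must be square")
  if (!(density > 0 && density <= 1)) stop_input("'density' must be in (0, 1]")
  m <- round(density * n * (n - 1) / 2)
  if (m < 1) stop_input("density ", density, " yields zero edges for N = ", n)
  iu <- which(upper.tri(r), arr.ind = TRUE)
  absr <- abs(r[iu])
  ord <- order(-absr, iu[, 1], iu[, 2])
  keep <- ord[seq_len(m)]
  w <- matrix(0, n, n, dimnames = dimnames(r))
  vals <- if (mode == "weighted") absr[keep] else rep(1, m)
  w[iu[keep, , drop = FALSE]] <- vals
  w <- w + t(w)
  structure(list(w = w, density = density, n_edges = m, mode = mode),
            class = "eeg_network")
}

#' @export
print.eeg_network <- function(x, ...) {
  cat(sprintf("<eeg_network> %d nodes, %d edges (density %.3g, %s)\n",
              nrow(x$w), x$n_edges, x$density, x$mode))
  invisible(x)
}

#' Edge list of a thresholded network
#'
#' @param net an \code{eeg_network}.
#' @return data frame with columns i, j (1-based indices, i < j), from, to
#'   (labels) and weight.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "eeg_network"))
  iu <- which(upper.tri(net$w) & net$w > 0, arr.ind = TRUE)
  labs <- rownames(net$w)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(net$w)))
  data.frame(i = iu[, 1], j = iu[, 2],
             from = labs[iu[, 1]], to = labs[iu[, 2]],
             weight = net$w[iu], row.names = NULL)
}
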