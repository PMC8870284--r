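# Feature assembly: one vector per subject/state concatenating, epoch by
# epoch, the per-node values of the seven measures. Under the defaults
# (7 measures x 8 electrodes x 9 epochs) that is 504 features per subject per
# state. Three of the seven measures are network-level as usually defined;
# their per-electrode slots are filled with the nodal analogues (nodal
# efficiency for global efficiency, nodal mean distance for characteristic
# path length) and assortativity is broadcast to all electrodes, so every
# slot is well defined while the 7 x N x epochs layout is preserved. A
# "broadcast" layout using the network scalars for all three is available.

METRIC_ORDER <- c("loc_eff", "clustering", "strength", "betweenness",
                  "glob_eff", "char_path", "assortativity")

metric_block <- function(ms, layout) {
  n <- ms$n_nodes
  ge <- if (layout == "nodal") ms$glob_eff_node else rep(ms$glob_eff, n)
  cp <- if (layout == "nodal") ms$char_path_node else rep(ms$char_path, n)
  c(ms$loc_eff_node, ms$clustering_node, ms$strength_node,
    ms$betweenness_node, ge, cp, rep(ms$assortativity, n))
}

#' Assemble the feature vector for one subject/state
#'
#' Concatenates, for each epoch in order, per-node blocks of the seven
#' measures in the fixed order: local efficiency, clustering coefficient,
#' node strength, betweenness centrality, (nodal) global efficiency, (nodal)
#' characteristic path length, assortativity (broadcast to all nodes). Length
#' is always 7 x N x n_epochs. NaN entries (undefined assortativity on
#' degree-regular networks, or isolated-node path lengths) are imputed as 0
#' with a warning.
#'
#' @param metric_sets list of \code{\link{network_metrics}} results, one per
#'   epoch, in epoch order.
#' @param n_epochs expected epoch count (defaults to the list length; a
#'   mismatch is an error).
#' @param layout \code{"nodal"} (default) or \code{"broadcast"} (network
#'   scalars broadcast for global efficiency and characteristic path length).
#' @return named numeric vector of length \code{7 * N * n_epochs}; names are
#'   \code{e<epoch>_<measure>_<node>}.
#' @export
build_features <- function(metric_sets, n_epochs = length(metric_sets),
                           layout = c("nodal", "broadcast")) {
  layout <- match.arg(layout)
  if (length(metric_sets) != n_epochs)
    stop_input("expected ", n_epochs, " epoch metric sets, got ",
               length(metric_sets))
  ns <- vapply(metric_sets, `[[`, 0L, "n_nodes")
  if (length(unique(ns)) != 1L)
    stop_input("inconsistent node counts across epochs")
  n <- ns[1]
  labs <- names(metric_sets[[1]]$strength_node)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  v <- unlist(lapply(metric_sets, metric_block, layout = layout),
              use.names = FALSE)
  names(v) <- as.vector(vapply(seq_len(n_epochs), function(e)
    paste0("e", e, "_", rep(METRIC_ORDER, each = n), "_", rep(labs, 7)),
    character(7 * n)))
  if (anyNA(v)) {
    warning("imputing ", sum(is.na(v)), " undefined feature value(s) as 0 ",
            "(degenerate network measure)", call. = FALSE)
    v[is.na(v)] <- 0
  }
  v
}

# Network-level scalar summary of one epoch's metric set (used by the group
# statistics module; strength and betweenness summarised as node means).
scalar_row <- function(ms) {
  c(loc_eff = ms$loc_eff, clustering = ms$clustering, glob_eff = ms$glob_eff,
    char_path = ms$char_path, strength = mean(ms$strength_node),
    betweenness = mean(ms$betweenness_node), assortativity = ms$assortativity)
}
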