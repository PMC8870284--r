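# The central pipeline: recordings -> filtered epochs -> per-epoch
# fixed-density networks -> seven graph measures -> per-subject feature
# vectors. Returns one classed object holding everything the statistics and
# classification stages consume.

#' Fit the network-analysis pipeline to an EEG cohort
#'
#' For every recording: band-pass (0.5-45 Hz) and notch (50 Hz) filter, trim
#' the filter edge transients, cut \code{n_epochs} epochs of
#' \code{epoch_length_s} seconds, build the Pearson connectivity matrix of
#' each epoch, threshold it to a fixed edge density, and compute the seven
#' graph measures. Per-subject feature vectors (7 measures x N electrodes x
#' n_epochs; 504 under the defaults) and per-epoch network scalars are
#' assembled for the downstream group comparison and classification.
#'
#' @param cohort an \code{eeg_cohort} (see \code{\link{simulate_cohort}} /
#'   \code{\link{read_cohort_csv}}), or a plain list of \code{eeg_recording}s.
#' @param density retained edge fraction for sparsity thresholding
#'   (default 0.3).
#' @param mode network mode, \code{"weighted"} (default) or \code{"binary"}.
#' @param epoch_length_s epoch length in seconds (default 20).
#' @param n_epochs epochs per recording (default 9); recordings too short to
#'   tile use uniformly spaced overlapping windows.
#' @param band band-pass edges in Hz (default \code{c(0.5, 45)}); NULL skips.
#' @param notch_hz notch centre in Hz (default 50); NULL skips.
#' @param edge_trim_s seconds discarded from each end after filtering
#'   (default 2, filter settling).
#' @param layout feature layout, \code{"nodal"} or \code{"broadcast"}; see
#'   \code{\link{build_features}}.
#' @return object of class \code{eegnet_fit}:
#'   \describe{
#'     \item{features}{data frame, one row per (subject, state): subject_id,
#'       group, state, then the feature columns.}
#'     \item{epoch_features}{one row per (subject, state, epoch) with the
#'       7 x N per-epoch block (epochs-as-instances classification).}
#'     \item{scalars}{long data frame of network-level scalars per epoch.}
#'     \item{metric_sets}{nested list of \code{metric_set} objects.}
#'     \item{params}{resolved pipeline parameters.}
#'   }
#' @examples
#' cfg <- cohort_config(n_per_group = 2, states = "eyes_open",
#'                      duration_s = c(eyes_open = 65), seed = 7)
#' fit <- eegnet_fit(simulate_cohort(cfg), n_epochs = 3)
#' fit
#' @export
eegnet_fit <- function(cohort, density = 0.3, mode = c("weighted", "binary"),
                       epoch_length_s = 20, n_epochs = 9,
                       band = c(0.5, 45), notch_hz = 50, edge_trim_s = 2,
                       layout = c("nodal", "broadcast")) {
  mode <- match.arg(mode)
  layout <- match.arg(layout)
  recs <- if (inherits(cohort, "eeg_cohort")) cohort$recordings else cohort
  if (!length(recs)) stop_input("no recordings supplied")
  scalar_rows <- list(); feat_rows <- list(); epoch_rows <- list()
  metric_sets <- list()
  for (rec in recs) {
    r <- rec
    if (!is.null(band)) r <- eeg_bandpass(r, band[1], band[2])
    if (!is.null(notch_hz)) r <- eeg_notch(r, notch_hz)
    if (edge_trim_s > 0) r <- trim_edges(r, edge_trim_s)
    epochs <- epoch_split(r, epoch_length_s, n_epochs)
    ms_list <- lapply(epochs, function(ep) {
      net <- sparsity_threshold(pearson_matrix(ep), density, mode)
      network_metrics(net)
    })
    key <- paste(rec$subject_id, rec$state, sep = ".")
    metric_sets[[key]] <- ms_list
    for (e in seq_along(ms_list)) {
      scalar_rows[[paste(key, e)]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group, state = rec$state,
        epoch = e, t(scalar_row(ms_list[[e]])), stringsAsFactors = FALSE)
      epoch_rows[[paste(key, e)]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group, state = rec$state,
        epoch = e,
        t(suppressWarnings(build_features(ms_list[e], layout = layout))),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    feat_rows[[key]] <- data.frame(
      subject_id = rec$subject_id, group = rec$group, state = rec$state,
      t(suppressWarnings(build_features(ms_list, n_epochs, layout = layout))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  structure(list(
    features = do.call(rbind, c(feat_rows, make.row.names = FALSE)),
    epoch_features = do.call(rbind, c(epoch_rows, make.row.names = FALSE)),
    scalars = do.call(rbind, c(scalar_rows, make.row.names = FALSE)),
    metric_sets = metric_sets,
    params = list(density = density, mode = mode,
                  epoch_length_s = epoch_length_s, n_epochs = n_epochs,
                  band = band, notch_hz = notch_hz, edge_trim_s = edge_trim_s,
                  layout = layout)
  ), class = "eegnet_fit")
}

feature_cols <- function(df) setdiff(names(df), c("subject_id", "group",
                                                  "state", "epoch"))

#' Classify a fitted cohort for one state
#'
#' Cross-validated classification of middle-aged-like vs elderly-like
#' instances for a single recording state. Instances are epochs by default
#' (one 7 x N block per epoch, mirroring roughly-90-instance evaluations of
#' 40-subject cohorts); \code{instances = "subject"} uses one full-length
#' vector per subject instead.
#'
#' @param fit an \code{eegnet_fit}.
#' @param state which state to classify.
#' @param model classifier description, as in \code{\link{cross_validate}}.
#' @param instances \code{"subject"} (default) or \code{"epoch"}.
#' @param folds,seed cross-validation controls.
#' @return a \code{classification_report} (with \code{state} attached).
#' @export
classify_cohort <- function(fit, state, model = list(classifier = "knn", k = 3),
                            instances = c("subject", "epoch"),
                            folds = 10, seed = 1L) {
  stopifnot(inherits(fit, "eegnet_fit"))
  instances <- match.arg(instances)
  check_state(state)
  df <- if (instances == "epoch") fit$epoch_features else fit$features
  df <- df[df$state == state, , drop = FALSE]
  if (!nrow(df)) stop_input("no instances for state '", state, "'")
  rep <- cross_validate(as.matrix(df[feature_cols(df)]), df$group,
                        model = model, folds = folds, seed = seed,
                        group_ids = if (instances == "epoch") df$subject_id)
  rep$state <- state
  rep$instances <- instances
  rep
}

#' @export
print.eegnet_fit <- function(x, ...) {
  f <- x$features
  cat("<eegnet_fit>\n")
  cat(sprintf("  %d subjects x %d state(s); %d features/subject/state\n",
              length(unique(f$subject_id)), length(unique(f$state)),
              length(feature_cols(f))))
  cat(sprintf("  networks: density %.3g (%s), %d epochs of %g s\n",
              x$params$density, x$params$mode, x$params$n_epochs,
              x$params$epoch_length_s))
  invisible(x)
}

#' Summarise a fitted cohort: group medians and rank-sum tests
#'
#' @param object an \code{eegnet_fit}.
#' @param alpha significance level for \code{\link{compare_groups}}.
#' @param ... passed to \code{\link{compare_groups}}.
#' @return list of class \code{summary.eegnet_fit} with the comparison table
#'   and per-group median scalars.
#' @export
summary.eegnet_fit <- function(object, alpha = 0.05, ...) {
  cmp <- compare_groups(object$scalars, alpha = alpha, ...)
  med <- stats::aggregate(
    object$scalars[feature_cols(object$scalars)],
    by = list(group = object$scalars$group, state = object$scalars$state),
    FUN = stats::median, na.rm = TRUE)
  structure(list(comparison = cmp, medians = med, params = object$params),
            class = "summary.eegnet_fit")
}

#' @export
print.summary.eegnet_fit <- function(x, ...) {
  cat("Group comparison (Wilcoxon rank-sum, direction < 0 = elderly lower):\n")
  tab <- x$comparison
  tab$p_value <- signif(tab$p_value, 3)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Box plots of network scalars by group
#'
#' One panel per measure for a chosen state, middle-aged vs elderly, values
#' averaged over epochs per subject.
#'
#' @param x an \code{eegnet_fit}.
#' @param state state to plot (default: first present).
#' @param measures which scalar columns to plot.
#' @param ... passed to \code{\link[graphics]{boxplot}}.
#' @export
plot.eegnet_fit <- function(x, state = NULL,
                            measures = c("glob_eff", "loc_eff", "clustering",
                                         "char_path", "strength",
                                         "betweenness", "assortativity"),
                            ...) {
  sc <- x$scalars
  if (is.null(state)) state <- sc$state[1]
  sc <- sc[sc$state == state, , drop = FALSE]
  agg <- stats::aggregate(sc[measures],
                          by = list(subject_id = sc$subject_id,
                                    group = sc$group),
                          FUN = mean, na.rm = TRUE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(measures)),
                       mar = c(2.5, 4, 2, 0.5))
  on.exit(graphics::par(old))
  for (m in measures) {
    graphics::boxplot(agg[[m]] ~ factor(agg$group, GROUPS), ylab = m,
                      xlab = "", main = paste(m, "-", state), ...)
  }
  invisible(x)
}
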