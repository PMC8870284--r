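# Group-level statistics: two-sided Wilcoxon rank-sum comparisons of each
# network measure between the middle-aged-like and elderly-like groups, one
# test per (measure, state), uncorrected, significant at p < alpha.

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test with midrank ties: the exact
#' null distribution when \code{min(n_a, n_b) <= 8} and the pooled data are
#' tie-free, otherwise the normal approximation with tie correction. The
#' degenerate case of all values identical across both samples returns p = 1
#' with a warning.
#'
#' @param a,b numeric samples (elderly-like group conventionally second; the
#'   recorded direction is \code{sign(median(b) - median(a))}).
#' @param alpha significance level (default 0.05).
#' @param metric_name,state optional labels carried into the result.
#' @return one-row data frame of class \code{group_comparison}: metric, state,
#'   statistic (Mann-Whitney U of sample a), p_value, direction, significant.
#' @export
rank_sum_test <- function(a, b, alpha = 0.05, metric_name = NA_character_,
                          state = NA_character_) {
  if (!length(a) || !length(b)) stop_input("both samples must be nonempty")
  a <- as.numeric(a); b <- as.numeric(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical in both samples; p = 1", call. = FALSE)
    stat <- length(a) * length(b) / 2
    p <- 1
  } else {
    exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(pooled)
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    stat <- unname(ht$statistic)
    p <- min(ht$p.value, 1)
  }
  res <- data.frame(metric = metric_name, state = state, statistic = stat,
                    p_value = p,
                    direction = sign(stats::median(b) - stats::median(a)),
                    significant = p < alpha, stringsAsFactors = FALSE)
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' Compare network measures between groups
#'
#' Runs one rank-sum test per (measure, state) on a long table of per-subject
#' network scalars. By default the independent unit is the subject: epoch-level
#' values are averaged per subject before testing; set
#' \code{unit = "epoch"} to test epoch-level values directly. No
#' multiple-testing correction is applied (\code{p_adjust = "none"});
#' Benjamini-Hochberg is available via \code{p_adjust = "BH"}.
#'
#' @param scalars data frame with columns \code{subject_id}, \code{group},
#'   \code{state}, \code{epoch}, plus one numeric column per measure (as built
#'   by \code{\link{eegnet_fit}}, component \code{$scalars}).
#' @param alpha significance level (default 0.05).
#' @param unit \code{"subject"} (mean over epochs; default) or \code{"epoch"}.
#' @param p_adjust \code{"none"} (default) or any \code{\link[stats]{p.adjust}}
#'   method.
#' @return data frame of class \code{group_comparison}, one row per
#'   (measure, state). Direction < 0 means the elderly-like group is lower.
#' @export
compare_groups <- function(scalars, alpha = 0.05,
                           unit = c("subject", "epoch"), p_adjust = "none") {
  unit <- match.arg(unit)
  if (inherits(scalars, "eegnet_fit")) scalars <- scalars$scalars
  need <- c("subject_id", "group", "state")
  if (!all(need %in% names(scalars)))
    stop_input("'scalars' must have columns ", paste(need, collapse = ", "))
  if (!all(GROUPS %in% scalars$group))
    stop_input("both groups must be present; found: ",
               paste(unique(scalars$group), collapse = ", "))
  metrics <- setdiff(names(scalars), c(need, "epoch"))
  out <- list()
  for (st in unique(scalars$state)) {
    sub <- scalars[scalars$state == st, , drop = FALSE]
    for (m in metrics) {
      if (unit == "subject") {
        agg <- stats::aggregate(sub[[m]],
                                by = list(subject_id = sub$subject_id,
                                          group = sub$group),
                                FUN = mean, na.rm = TRUE)
        vals <- agg$x; grp <- agg$group
      } else {
        vals <- sub[[m]]; grp <- sub$group
      }
      out[[paste(st, m)]] <- rank_sum_test(vals[grp == "middle_aged"],
                                           vals[grp == "elderly"],
                                           alpha = alpha, metric_name = m,
                                           state = st)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- res$p_value < alpha
  class(res) <- c("group_comparison", "data.frame")
  res
}
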