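#' Standardized rank-sum statistic W
#'
#' `W = |z|` where `z` is the tie-corrected normal-approximation
#' standardization of the Mann-Whitney rank-sum statistic: ranks are
#' averaged over ties, no continuity correction is applied, and if all
#' pooled values are identical (standard deviation zero) `W = 0`. `W` is
#' invariant under any common strictly increasing transform of both
#' samples and under swapping the samples. The convention used throughout:
#' two samples are "indistinguishable" (stable) when `W < 1` and
#' "separated" (discriminative) when `W > 1`.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return List of class `wilcoxon_result` with `W`, `n_a`, `n_b`.
#' @export
wilcoxon_W <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2L || nb < 2L) stop("both samples need >= 2 values")
  if (any(!is.finite(c(sample_a, sample_b))))
    stop("samples must be finite")
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                       # average ranks for ties
  n <- na + nb
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  s2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  W <- if (s2 <= 0) 0 else abs((U - mu) / sqrt(s2))
  structure(list(W = W, n_a = na, n_b = nb), class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %.4f (n = %d, %d)\n", x$W, x$n_a,
              x$n_b))
  invisible(x)
}

feature_columns <- function(features) {
  intersect(feature_names(), names(features))
}

check_feature_table <- function(features) {
  need <- c("group", "roi", "tissue_class")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (!length(feature_columns(features)))
    stop("feature table has no recognised feature columns")
  invisible(features)
}

#' Per-feature stability percentage (intra-class)
#'
#' For each feature and each ROI, every pair of parameter-variation groups
#' is compared with [wilcoxon_W()] on the repeated values; a comparison is
#' successful (stable) when `W < 1`. The percentage is the fraction of
#' successful comparisons pooled over all ROIs and group pairs.
#'
#' @param features data.frame with metadata columns `group`, `roi`,
#'   `tissue_class` and the 86 feature columns; one row per (acquisition,
#'   ROI).
#' @param threshold stability threshold on W (default 1).
#' @return Named numeric vector (percent, in `[0, 100]`) per feature, with
#'   attribute `"n_comparisons"`.
#' @export
stability_percentage <- function(features, threshold = 1) {
  check_feature_table(features)
  fcols <- feature_columns(features)
  groups <- sort(unique(features$group))
  rois <- unique(features$roi)
  if (length(groups) < 2L) stop("need >= 2 groups")
  succ <- stats::setNames(numeric(length(fcols)), fcols)
  total <- 0L
  for (roi in rois) {
    sub <- features[features$roi == roi, , drop = FALSE]
    cells <- split(sub, sub$group)
    sizes <- vapply(cells, nrow, 0L)
    if (any(sizes < 2L)) {
      warning("ROI '", roi, "': groups with < 2 repetitions excluded: ",
              paste(names(cells)[sizes < 2L], collapse = ", "))
      cells <- cells[sizes >= 2L]
    }
    gs <- names(cells)
    if (length(gs) < 2L) next
    for (a in seq_len(length(gs) - 1L)) for (b in (a + 1L):length(gs)) {
      total <- total + 1L
      for (f in fcols) {
        W <- wilcoxon_W(cells[[a]][[f]], cells[[b]][[f]])$W
        if (W < threshold) succ[f] <- succ[f] + 1
      }
    }
  }
  if (total == 0L) stop("no valid group pairs")
  structure(100 * succ / total, n_comparisons = total)
}

#' Per-feature discriminative-power percentage (inter-class)
#'
#' For each feature and each parameter-variation group, every pair of
#' tissue classes is compared with [wilcoxon_W()] (values of a class pool
#' its ROIs); a comparison is successful (discriminative) when `W > 1`.
#'
#' @inheritParams stability_percentage
#' @return Named numeric vector (percent) per feature, with attribute
#'   `"n_comparisons"`.
#' @export
discriminative_percentage <- function(features, threshold = 1) {
  check_feature_table(features)
  fcols <- feature_columns(features)
  classes <- unique(features$tissue_class)
  if (length(classes) < 2L) stop("need >= 2 tissue classes")
  succ <- stats::setNames(numeric(length(fcols)), fcols)
  total <- 0L
  for (g in sort(unique(features$group))) {
    sub <- features[features$group == g, , drop = FALSE]
    cells <- split(sub, sub$tissue_class)
    sizes <- vapply(cells, nrow, 0L)
    if (any(sizes < 2L)) {
      warning("group '", g, "': classes with < 2 values excluded: ",
              paste(names(cells)[sizes < 2L], collapse = ", "))
      cells <- cells[sizes >= 2L]
    }
    ks <- names(cells)
    if (length(ks) < 2L) next
    for (a in seq_len(length(ks) - 1L)) for (b in (a + 1L):length(ks)) {
      total <- total + 1L
      for (f in fcols) {
        W <- wilcoxon_W(cells[[a]][[f]], cells[[b]][[f]])$W
        if (W > threshold) succ[f] <- succ[f] + 1
      }
    }
  }
  if (total == 0L) stop("no valid class pairs")
  structure(100 * succ / total, n_comparisons = total)
}

#' Stability / discriminative-power report
#'
#' Runs both analyses on a feature table and bundles per-feature
#' percentages plus rankings.
#'
#' @inheritParams stability_percentage
#' @return Object of class `stability_report`: data.frame `table` with
#'   columns `feature`, `stability`, `discriminative`, plus `ranking_stability`
#'   and `ranking_discriminative` character vectors.
#' @export
stability_report <- function(features, threshold = 1) {
  st <- stability_percentage(features, threshold)
  di <- discriminative_percentage(features, threshold)
  tab <- data.frame(feature = names(st), stability = unname(st),
                    discriminative = unname(di[names(st)]),
                    stringsAsFactors = FALSE)
  rep <- structure(list(table = tab,
                        n_stability_comparisons = attr(st, "n_comparisons"),
                        n_discriminative_comparisons = attr(di, "n_comparisons")),
                   class = "stability_report")
  rep$ranking_stability <- rank_features(rep, "stability")
  rep$ranking_discriminative <- rank_features(rep, "discriminative")
  rep
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d features; mean stability %.1f%%, mean discriminative %.1f%%\n",
              nrow(x$table), mean(x$table$stability),
              mean(x$table$discriminative)))
  cat("  top stable: ", paste(head(x$ranking_stability, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank features by stability or discriminative power
#'
#' Descending by percentage; ties broken by canonical feature-name order.
#'
#' @param report a [stability_report()].
#' @param axis `"stability"` or `"discriminative"`.
#' @return Character vector of feature names, best first.
#' @export
rank_features <- function(report, axis = c("stability", "discriminative")) {
  axis <- match.arg(axis)
  tab <- report$table
  canon <- match(tab$feature, feature_names())
  tab$feature[order(-tab[[axis]], canon)]
}

#' Top-k overlap curve between two rankings
#'
#' For each fraction `f`, the top group holds `k = round_half_up(f * N)`
#' features; the overlap is the percentage of the two top groups that is
#' shared (at 10% of 86 features the top group has 9 members). The
#' random-expectation baseline is `f * 100`.
#'
#' @param rank_a,rank_b character vectors ranking the same feature
#'   universe.
#' @param fractions fractions in (0, 1].
#' @return data.frame with `fraction`, `k`, `overlap_pct`, `baseline_pct`.
#' @export
topk_overlap <- function(rank_a, rank_b, fractions = seq(0.1, 1, by = 0.1)) {
  if (!setequal(rank_a, rank_b) || length(rank_a) != length(rank_b))
    stop("rankings must cover the same feature universe")
  N <- length(rank_a)
  k <- pmax(1L, as.integer(floor(fractions * N + 0.5)))   # round half up
  ov <- vapply(k, function(kk)
    100 * length(intersect(rank_a[seq_len(kk)], rank_b[seq_len(kk)])) / kk,
    0)
  data.frame(fraction = fractions, k = k, overlap_pct = ov,
             baseline_pct = 100 * fractions)
}
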