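#' Post-administration response histograms
#'
#' Per-unit histogram of spike counts in `binS`-second bins over the
#' `windowS`-second window after administration at `t0` (default: 100 x
#' 100 ms bins over 10 s), plus the equivalent rate profile in Hz.
#'
#' @param units a [NeuronUnitSet-class] or named list of spike trains (s)
#' @param t0 administration time, s
#' @param windowS response window, s (default 10)
#' @param binS bin width, s (default 0.1)
#' @param condition condition label attached to every vector
#' @return list with `counts` (units x bins matrix), `rate` (Hz),
#'   `binCenters` (s after t0), `condition`, `ids`
#' @export
responseHistograms <- function(units, t0, windowS = 10, binS = 0.1,
                               condition = "vehicle") {
  trains <- if (is(units, "NeuronUnitSet")) spikeTrains(units) else units
  nBins <- as.integer(round(windowS / binS))
  edges <- t0 + seq(0, windowS, by = binS)
  counts <- t(vapply(trains, function(tr) {
    inWin <- tr[tr >= t0 & tr < t0 + windowS]
    as.integer(table(cut(inWin, breaks = edges, right = FALSE)))
  }, integer(nBins)))
  rownames(counts) <- names(trains)
  list(counts = counts, rate = counts / binS,
       binCenters = seq(binS / 2, windowS - binS / 2, by = binS),
       condition = rep(condition, nrow(counts)),
       ids = names(trains))
}

#' Ward clustering of evoked-response vectors
#'
#' Agglomerative hierarchical clustering of the raw count vectors with
#' Euclidean distance and Ward linkage, cut at `k` clusters. Clustering
#' raw counts (not normalized profiles) keeps response magnitude part of
#' the distance; a `normalize` flag divides each vector by its total
#' count instead.
#'
#' @param counts numeric matrix, responses x bins
#' @param k number of clusters (default 5); alternatively give
#'   `cutHeight` to cut the dendrogram at a height
#' @param normalize divide vectors by their sums first (default FALSE)
#' @param cutHeight optional dendrogram cut height instead of `k`
#' @return list with `labels` (integer per response), `linkage`
#'   (data.frame id_left, id_right, height, size), `hclust`, `k`
#' @export
wardCluster <- function(counts, k = 5L, normalize = FALSE,
                        cutHeight = NULL) {
  if (nrow(counts) < k) stop("fewer response vectors than clusters")
  x <- counts
  if (normalize) {
    s <- rowSums(x); s[s == 0] <- 1
    x <- x / s
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  labels <- if (is.null(cutHeight)) stats::cutree(hc, k = k)
            else stats::cutree(hc, h = cutHeight)
  stepSize <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    stepSize[i] <- (if (l < 0) 1L else stepSize[l]) +
                   (if (r < 0) 1L else stepSize[r])
  }
  linkage <- data.frame(id_left = hc$merge[, 1], id_right = hc$merge[, 2],
                        height = hc$height, size = stepSize)
  list(labels = unname(labels), linkage = linkage, hclust = hc,
       k = max(labels))
}

#' Per-cluster summaries and per-condition proportions
#'
#' For each cluster: the mean rate profile, its peak rate (Hz), the peak
#' time (bin center, s) and the window-mean rate (Hz). The peak is read
#' off a centered `smoothBins`-bin moving average of the mean profile:
#' the raw argmax of a noisy profile is biased upward (the largest of a
#' hundred fluctuating bins), and light smoothing removes most of that
#' selection bias while hardly flattening genuine peaks. For each
#' condition label: the percentage of responses falling in each cluster
#' (summing to 100% per condition).
#'
#' @param labels integer cluster labels per response
#' @param hist output of [responseHistograms()] (or a compatible list
#'   with `rate`, `binCenters`, `condition`)
#' @param smoothBins odd width of the moving average used for the peak
#'   (default 3; 1 disables smoothing)
#' @return list with `clusterStats` data.frame (cluster, n, peakRate,
#'   peakTime, meanRate) and `conditionProportions` (conditions x
#'   clusters percentage matrix)
#' @export
clusterSummaries <- function(labels, hist, smoothBins = 3L) {
  ks <- sort(unique(labels))
  smooth <- function(p) {
    if (smoothBins <= 1L) return(p)
    h <- (smoothBins - 1L) %/% 2L
    vapply(seq_along(p), function(i)
      mean(p[max(1L, i - h):min(length(p), i + h)]), 0)
  }
  stats <- do.call(rbind, lapply(ks, function(kk) {
    prof <- colMeans(hist$rate[labels == kk, , drop = FALSE])
    sm <- smooth(prof)
    data.frame(cluster = kk, n = sum(labels == kk),
               peakRate = max(sm),
               peakTime = hist$binCenters[which.max(sm)],
               meanRate = mean(prof))
  }))
  conds <- unique(hist$condition)
  prop <- t(vapply(conds, function(cc) {
    sel <- hist$condition == cc
    100 * vapply(ks, function(kk) sum(labels[sel] == kk), 0) / sum(sel)
  }, numeric(length(ks))))
  rownames(prop) <- conds
  colnames(prop) <- paste0("cluster", ks)
  list(clusterStats = stats, conditionProportions = prop)
}
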