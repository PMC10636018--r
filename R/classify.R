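## Putative cell-class assignment: an anatomical gate (units below the
## pyramidal layer are excluded as putative dentate cells), a manual rule set
## (7 Hz firing-rate threshold with an autocorrelogram guard band around the
## boundary) and an automated k-means cross-check on standardized features.

#' Anatomical gate for unit classification
#'
#' Units recorded below the annotated CA1 pyramidal layer are putative
#' dentate granule cells, mossy cells or dentate interneurons and are
#' excluded before rate/waveform classification. Units with an unknown layer
#' cannot be gated and are flagged unclassifiable.
#'
#' @param metrics data.frame from \code{\link{unitMetricsTable}} (needs
#'   columns \code{unitId} and \code{layer}).
#' @return data.frame with columns \code{unitId} and \code{gate}
#'   (\code{"candidate"}, \code{"dentate_excluded"} or
#'   \code{"unclassifiable"}).
#' @export
anatomicalGate <- function(metrics) {
  gate <- rep("candidate", nrow(metrics))
  gate[metrics$layer == "below_pyr"] <- "dentate_excluded"
  unknown <- !(metrics$layer %in% c("ca1_pyr", "below_pyr"))
  if (any(unknown)) {
    warning(sum(unknown), " unit(s) without a layer label are unclassifiable")
    gate[unknown] <- "unclassifiable"
  }
  data.frame(unitId = metrics$unitId, gate = gate, stringsAsFactors = FALSE)
}

#' Manual rule-based classification
#'
#' Gated units with firing rate of 7 Hz or below are putative pyramidal
#' cells; units above 7 Hz are putative interneurons. Calls within the guard
#' band around the 7 Hz boundary whose autocorrelogram first moment falls on
#' the wrong side of the candidate-population median (a pyramidal call with a
#' tonic-looking, large first moment, or an interneuron call with a
#' bursty-looking, small one) are conservatively labeled unclassifiable.
#'
#' @param metrics data.frame from \code{\link{unitMetricsTable}}.
#' @param rateThreshold boundary rate, Hz (default 7; the boundary itself is
#'   pyramidal).
#' @param guardBand half-width of the rate band around the threshold in which
#'   the first-moment guard applies (default 1 Hz).
#' @return data.frame with columns \code{unitId}, \code{label}
#'   (\code{pyramidal}, \code{interneuron}, \code{dentate_excluded},
#'   \code{unclassifiable}) and \code{basis = "manual_rules"}.
#' @export
classifyManual <- function(metrics, rateThreshold = 7, guardBand = 1) {
  gate <- anatomicalGate(metrics)
  label <- gate$gate
  cand <- which(label == "candidate")
  incomplete <- cand[is.na(metrics$firingRate[cand]) |
                       is.na(metrics$acgFirstMoment[cand])]
  label[incomplete] <- "unclassifiable"
  cand <- setdiff(cand, incomplete)
  rate <- metrics$firingRate[cand]
  call <- ifelse(rate <= rateThreshold, "pyramidal", "interneuron")
  fmMedian <- stats::median(metrics$acgFirstMoment[cand])
  nearBoundary <- abs(rate - rateThreshold) <= guardBand
  wrongSide <- (call == "pyramidal" &
                  metrics$acgFirstMoment[cand] > fmMedian) |
               (call == "interneuron" &
                  metrics$acgFirstMoment[cand] < fmMedian)
  call[nearBoundary & wrongSide] <- "unclassifiable"
  label[cand] <- call
  data.frame(unitId = metrics$unitId, label = label, basis = "manual_rules",
             stringsAsFactors = FALSE)
}

#' Automated k-means classification (k = 2)
#'
#' k-means with k = 2 on z-scored features (log firing rate, spike width,
#' autocorrelogram first moment) of the gated candidate units. The cluster
#' with the higher mean firing rate is labeled interneuron. Initial centers
#' are the feature rows of the lowest- and highest-rate units and Lloyd
#' iterations are run from there, so the result is deterministic and
#' invariant to unit order.
#'
#' @param metrics data.frame from \code{\link{unitMetricsTable}} (>= 2 gated
#'   candidate units required).
#' @return list with \code{labels} (data.frame unitId, label,
#'   basis = "kmeans"), \code{centers} (feature-space centroids),
#'   \code{silhouette} (mean silhouette width over the candidates; low values
#'   flag a population without two real clusters).
#' @export
classifyKmeans <- function(metrics) {
  gate <- anatomicalGate(metrics)
  cand <- which(gate$gate == "candidate")
  if (length(cand) < 2) stop("k-means needs at least 2 gated units")
  feats <- cbind(logRate = log(metrics$firingRate[cand]),
                 width = metrics$spikeWidth[cand],
                 acgFirstMoment = metrics$acgFirstMoment[cand])
  z <- scale(feats)
  z[, apply(feats, 2, stats::sd) == 0] <- 0    # constant feature: no info
  init <- z[c(which.min(feats[, "logRate"]), which.max(feats[, "logRate"])), ,
            drop = FALSE]
  if (all(init[1, ] == init[2, ])) init[2, ] <- init[2, ] + 1e-6
  km <- stats::kmeans(z, centers = init, algorithm = "Lloyd",
                      iter.max = 100)
  meanRate <- tapply(metrics$firingRate[cand], km$cluster, mean)
  interCluster <- as.integer(names(which.max(meanRate)))
  call <- ifelse(km$cluster == interCluster, "interneuron", "pyramidal")
  label <- gate$gate
  label[cand] <- call
  ## mean silhouette width in the z-scored feature space
  d <- as.matrix(stats::dist(z))
  sil <- vapply(seq_along(cand), function(i) {
    own <- km$cluster == km$cluster[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(nrow(d)) != i]) else 0
    b <- mean(d[i, !own])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  list(labels = data.frame(unitId = metrics$unitId, label = label,
                           basis = "kmeans", stringsAsFactors = FALSE),
       centers = km$centers, silhouette = mean(sil))
}

#' Compare manual and automated classifications
#'
#' @param manual,kmeans label data.frames over the same unit set (columns
#'   \code{unitId}, \code{label}).
#' @param silhouetteFloor agreement on populations whose k-means silhouette
#'   is below this value is flagged as untrustworthy. The default 0.35 sits
#'   between the mean silhouette of a forced split of unimodal data (~0.25,
#'   the classical "no substantial structure" boundary) and that of genuinely
#'   bimodal populations (> 0.5).
#' @param silhouette optional silhouette value from
#'   \code{\link{classifyKmeans}}.
#' @return list with \code{confusion} (table), \code{agreement} (percent over
#'   all units), \code{disagreements} (unit ids) and \code{lowSeparation}
#'   (logical flag).
#' @export
compareClassifications <- function(manual, kmeans, silhouette = NA,
                                   silhouetteFloor = 0.35) {
  if (!setequal(manual$unitId, kmeans$unitId) ||
      nrow(manual) != nrow(kmeans))
    stop("manual and k-means classifications cover different unit sets")
  kmeans <- kmeans[match(manual$unitId, kmeans$unitId), ]
  confusion <- table(manual = manual$label, kmeans = kmeans$label)
  agree <- manual$label == kmeans$label
  list(confusion = confusion,
       agreement = 100 * mean(agree),
       disagreements = manual$unitId[!agree],
       lowSeparation = !is.na(silhouette) && silhouette < silhouetteFloor)
}
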