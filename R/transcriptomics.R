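#' Label expression samples against a hub mask
#'
#' Each sample coordinate is mapped to its nearest voxel through the grid
#' affine: samples landing on a hub voxel are labeled \code{hub}, on any
#' other gray voxel \code{nonhub}, and samples outside the gray mask (or
#' outside the array) \code{excluded}.
#'
#' @param coords numeric matrix, samples x 3 (MNI mm).
#' @param hubMask logical vector over gray voxels, or a logical
#'   \linkS4class{VoxelMap}, or a \linkS4class{HubResult}.
#' @param grid the session \linkS4class{VoxelGrid}.
#' @return character vector of labels.
#' @export
labelSamples <- function(coords, hubMask, grid) {
  if (is(hubMask, "HubResult")) hubMask <- hubMask@hubMask
  if (is(hubMask, "VoxelMap")) hubMask <- as.logical(mapValues(hubMask))
  pos <- .mmToMaskIndex(grid, coords)
  lab <- rep("excluded", length(pos))
  inGray <- !is.na(pos)
  lab[inGray] <- ifelse(hubMask[pos[inGray]], "hub", "nonhub")
  lab
}

#' Relabel a HubExpression from a hub mask
#'
#' @param expr a \linkS4class{HubExpression}.
#' @param hubMask,grid see \code{\link{labelSamples}}.
#' @return the container with updated labels.
#' @export
relabelExpression <- function(expr, hubMask, grid) {
  lab <- labelSamples(sampleCoords(expr), hubMask, grid)
  SummarizedExperiment::colData(expr)$label <-
    factor(lab, levels = c("hub", "nonhub", "excluded"))
  validObject(expr)
  expr
}

#' Balanced gradient-boosting classification of hubs vs non-hubs
#'
#' Per repetition: draw a balanced training set (\code{nTrainPerClass}
#' hub and non-hub samples each), choose the boosting round count by
#' cross-validation with early stopping (binary logistic loss), train a
#' gradient-boosted tree ensemble, and evaluate sensitivity, specificity
#' and accuracy on all held-out samples.  Per-gene importance (gain) and
#' each sample's held-out correct-classification rate are accumulated
#' across repetitions; the latter feeds the easiest/hardest task ranking
#' of \code{\link{svmTopnSweep}}.
#'
#' All counts default to the full protocol (300 per class, 1000
#' repetitions, 30-fold cross-validation, up to 1500 rounds, early
#' stopping patience 50, learning rate 0.05) and every one of them is a
#' parameter, so reduced versions run quickly.
#'
#' @param expr a \linkS4class{HubExpression} (labels hub/nonhub used;
#'   excluded samples are dropped).
#' @param nTrainPerClass training samples per class.
#' @param nRepetitions number of repetitions.
#' @param cvFolds cross-validation folds for the round search (0 skips
#'   the search and uses \code{maxRounds} directly).
#' @param maxRounds maximum boosting rounds.
#' @param patience early-stopping rounds.
#' @param learningRate boosting learning rate (eta).
#' @param seed integer RNG seed.
#' @param nthread xgboost threads (default 1 for reproducibility).
#' @return list with \code{perRepetition} (data.frame: sensitivity,
#'   specificity, accuracy, in %), \code{meanAccuracy},
#'   \code{meanSensitivity}, \code{meanSpecificity},
#'   \code{geneContribution} (mean gain per gene across repetitions),
#'   \code{sampleCorrectRate} (named, held-out correct rate per sample),
#'   \code{nRepetitions}, \code{seed}.
#' @export
trainBoostedProtocol <- function(expr, nTrainPerClass = 300L,
                                 nRepetitions = 1000L, cvFolds = 30L,
                                 maxRounds = 1500L, patience = 50L,
                                 learningRate = 0.05, seed = 1L,
                                 nthread = 1L) {
  X <- exprValues(expr)
  lab <- sampleLabels(expr)
  keep <- lab %in% c("hub", "nonhub")
  X <- X[keep, , drop = FALSE]
  lab <- lab[keep]
  hubIdx <- which(lab == "hub")
  nonIdx <- which(lab == "nonhub")
  if (length(hubIdx) <= nTrainPerClass || length(nonIdx) <= nTrainPerClass)
    stop("each class must exceed 'nTrainPerClass' samples")
  y <- as.numeric(lab == "hub")
  nGenes <- ncol(X)
  genes <- colnames(X)
  if (is.null(genes)) genes <- sprintf("g%05d", seq_len(nGenes))

  perf <- matrix(NA_real_, nRepetitions, 3,
                 dimnames = list(NULL, c("sensitivity", "specificity",
                                         "accuracy")))
  gain <- setNames(numeric(nGenes), genes)
  corr <- setNames(numeric(nrow(X)), rownames(X))
  seen <- setNames(numeric(nrow(X)), rownames(X))
  params <- list(objective = "binary:logistic", eta = learningRate,
                 nthread = nthread)

  withr_seed(seed, {
    for (rep in seq_len(nRepetitions)) {
      tr <- c(sample(hubIdx, nTrainPerClass),
              sample(nonIdx, nTrainPerClass))
      te <- setdiff(seq_len(nrow(X)), tr)
      dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                     label = y[tr], nthread = nthread)
      nrounds <- maxRounds
      if (cvFolds > 0L) {
        cv <- xgboost::xgb.cv(params = params, data = dtrain,
                              nrounds = maxRounds, nfold = cvFolds,
                              early_stopping_rounds = patience,
                              verbose = FALSE)
        best <- cv$early_stop$best_iteration
        if (is.null(best)) best <- cv$best_iteration
        if (!is.null(best) && is.finite(best)) nrounds <- best
      }
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
      pred <- as.numeric(
        stats::predict(fit, xgboost::xgb.DMatrix(X[te, , drop = FALSE],
                                                 nthread = nthread)) > 0.5)
      truth <- y[te]
      sens <- mean(pred[truth == 1] == 1)
      spec <- mean(pred[truth == 0] == 0)
      perf[rep, ] <- 100 * c(sens, spec, mean(pred == truth))
      ok <- pred == truth
      corr[te] <- corr[te] + ok
      seen[te] <- seen[te] + 1
      imp <- xgboost::xgb.importance(model = fit)
      gain[imp$Feature] <- gain[imp$Feature] + imp$Gain
      # booster handles live outside the R heap; collect them promptly so
      # long repetition runs keep a flat memory profile
      rm(fit, dtrain)
      if (rep %% 5L == 0L) gc(verbose = FALSE)
    }
  })
  rate <- corr / pmax(seen, 1)
  rate[seen == 0] <- NA_real_
  list(perRepetition = as.data.frame(perf),
       meanAccuracy = mean(perf[, "accuracy"]),
       meanSensitivity = mean(perf[, "sensitivity"]),
       meanSpecificity = mean(perf[, "specificity"]),
       geneContribution = gain / nRepetitions,
       sampleCorrectRate = rate,
       nRepetitions = nRepetitions, seed = as.integer(seed))
}

#' Support-vector sweep over the top-N key genes
#'
#' Non-hub samples are ranked by their held-out correct-classification
#' rate from the boosting protocol (ties broken by sample id); the
#' |hub| highest-rate ("easiest") or lowest-rate ("hardest") non-hubs are
#' paired with all hub samples.  For each N in \code{nRange}, a
#' radial-basis support-vector classifier on the top-N genes by
#' contribution (features standardized per gene) is scored by k-fold
#' cross-validation.
#'
#' @param expr a \linkS4class{HubExpression}.
#' @param contributions named per-gene contribution scores.
#' @param sampleCorrectRate named per-sample correct rates (from
#'   \code{\link{trainBoostedProtocol}}).
#' @param nRange integer vector of gene counts (default 100..300 by 25).
#' @param task "easiest" or "hardest".
#' @param cvFolds cross-validation folds (the full protocol uses one fold
#'   per hub sample; smaller values run faster).
#' @param seed integer RNG seed (fold assignment).
#' @return data.frame with columns n and accuracy (%).
#' @export
svmTopnSweep <- function(expr, contributions, sampleCorrectRate,
                         nRange = seq(100L, 300L, by = 25L),
                         task = c("easiest", "hardest"),
                         cvFolds = 10L, seed = 1L) {
  task <- match.arg(task)
  X <- exprValues(expr)
  lab <- sampleLabels(expr)
  if (max(nRange) > ncol(X))
    stop("'nRange' exceeds the gene count")
  hubs <- which(lab == "hub")
  nons <- which(lab == "nonhub")
  rate <- sampleCorrectRate[rownames(X)[nons]]
  ord <- if (task == "easiest") order(-rate, rownames(X)[nons])
         else order(rate, rownames(X)[nons])
  picked <- nons[ord[seq_len(min(length(hubs), length(nons)))]]
  idx <- c(hubs, picked)
  yy <- factor(c(rep("hub", length(hubs)), rep("nonhub", length(picked))))
  geneOrd <- names(sort(contributions, decreasing = TRUE))

  withr_seed(seed, {
    out <- lapply(nRange, function(n) {
      gsel <- geneOrd[seq_len(n)]
      Xs <- scale(X[idx, gsel, drop = FALSE])
      fit <- e1071::svm(Xs, yy, kernel = "radial", cost = 1,
                        scale = FALSE, cross = cvFolds)
      data.frame(n = n, accuracy = fit$tot.accuracy)
    })
    do.call(rbind, out)
  })
}

#' First principal component of a gene set's expression
#'
#' PC1 of the samples-by-set-genes submatrix (each gene centered),
#' sign-aligned to correlate positively with the set's mean expression,
#' and min-max scaled to [0, 1] across samples.
#'
#' @param expr a \linkS4class{HubExpression}.
#' @param geneSet character vector of gene identifiers.
#' @param name label for the set.
#' @return list with \code{name}, \code{score} (per sample, in [0, 1]),
#'   \code{explainedVariance} (share in [0, 1]), and \code{genesUsed}.
#' @export
genesetPc1 <- function(expr, geneSet, name = "geneset") {
  X <- exprValues(expr)
  present <- intersect(geneSet, colnames(X))
  if (!length(present))
    stop("no gene of the set is present in the expression matrix")
  if (nrow(X) < 3L) stop("at least 3 samples are required")
  sub <- X[, present, drop = FALSE]
  ctr <- scale(sub, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  score <- sv$u[, 1] * sv$d[1]
  if (length(present) > 1L) {
    mexpr <- rowMeans(sub)
    if (stats::sd(mexpr) > 0 && stats::cor(score, mexpr) < 0)
      score <- -score
  } else if (stats::cor(score, sub[, 1]) < 0) score <- -score
  ev <- sv$d[1]^2 / sum(sv$d^2)
  rng <- range(score)
  scaled <- if (diff(rng) > 0) (score - rng[1]) / diff(rng)
            else rep(0.5, length(score))
  list(name = name, score = setNames(scaled, rownames(X)),
       explainedVariance = ev, genesUsed = present)
}

#' Developmental trajectory of a transcription score
#'
#' Locally weighted regression (loess, locally quadratic) of per-sample
#' scores against log2(post-conceptional days), evaluated on a regular
#' grid.  Local quadratic fitting recovers curved developmental trends
#' without the flattening bias of locally linear smoothers.
#'
#' @param ageDays numeric, post-conceptional days (> 0).
#' @param scores numeric, one value per sample.
#' @param bandwidth smoother span (default 0.5).
#' @param nGrid grid resolution (default 100).
#' @return data.frame with columns log2Days and fit.
#' @export
trajectoryCurve <- function(ageDays, scores, bandwidth = 0.5,
                            nGrid = 100L) {
  if (length(scores) < 5L)
    stop("insufficient data: a trajectory needs >= 5 points")
  if (any(ageDays <= 0)) stop("ages must be positive (days)")
  x <- log2(ageDays)
  lo <- suppressWarnings(stats::loess(scores ~ x, span = bandwidth,
                                      degree = 2))
  grid <- seq(min(x), max(x), length.out = nGrid)
  fit <- suppressWarnings(
    as.numeric(stats::predict(lo, newdata = data.frame(x = grid))))
  data.frame(log2Days = grid, fit = fit)
}

#' Difference between two trajectories with a MAD band
#'
#' Interpolates both curves onto their common age range, reports the
#' difference, and compares its magnitude to the per-age median absolute
#' deviation (raw MAD, no consistency constant) of transcription level
#' across brain regions.  Ages where |difference| exceeds the MAD are
#' flagged.
#'
#' @param curveA,curveB data.frames from \code{\link{trajectoryCurve}}.
#' @param regionalValues numeric matrix, regions x ages, of transcription
#'   level used for the MAD band; its columns must correspond to
#'   \code{regionalAges}.
#' @param regionalAges numeric, log2(post-conceptional days) per column.
#' @param nGrid grid resolution.
#' @return data.frame with columns log2Days, difference, mad, exceeds.
#' @export
trajectoryDifference <- function(curveA, curveB, regionalValues,
                                 regionalAges, nGrid = 100L) {
  lo <- max(min(curveA$log2Days), min(curveB$log2Days))
  hi <- min(max(curveA$log2Days), max(curveB$log2Days))
  if (!(hi > lo)) stop("the trajectories do not overlap in age")
  grid <- seq(lo, hi, length.out = nGrid)
  fa <- stats::approx(curveA$log2Days, curveA$fit, xout = grid,
                      rule = 2, ties = mean)$y
  fb <- stats::approx(curveB$log2Days, curveB$fit, xout = grid,
                      rule = 2, ties = mean)$y
  madAge <- apply(regionalValues, 2L, function(v)
    stats::mad(v, constant = 1))
  madGrid <- stats::approx(regionalAges, madAge, xout = grid,
                           rule = 2, ties = mean)$y
  diff <- fa - fb
  data.frame(log2Days = grid, difference = diff, mad = madGrid,
             exceeds = abs(diff) > madGrid)
}

#' Assign parcels as hubs by majority coverage
#'
#' A parcel is a hub region when strictly more than 50% of its locations
#' fall inside the hub mask.
#'
#' @param parcelLabels integer/character per-location parcel labels (0 or
#'   NA locations are ignored).
#' @param hubIndicator logical per location.
#' @param threshold coverage threshold (default 0.5, exclusive).
#' @return character vector of hub parcel labels.
#' @export
assignParcelHubs <- function(parcelLabels, hubIndicator, threshold = 0.5) {
  keep <- !is.na(parcelLabels) & parcelLabels != 0
  if (!any(keep)) {
    warning("no non-empty parcels")
    return(character(0))
  }
  cov <- tapply(hubIndicator[keep], as.character(parcelLabels[keep]), mean)
  names(cov)[cov > threshold]
}

#' Export a ranked gene list
#'
#' Writes genes sorted by decreasing contribution, one identifier per
#' line, the format accepted by common enrichment services.
#'
#' @param contributions named per-gene scores.
#' @param path output file.
#' @param top optional count of top genes to keep.
#' @return the path, invisibly.
#' @export
exportRankedGenes <- function(contributions, path, top = NULL) {
  ord <- names(sort(contributions, decreasing = TRUE))
  if (!is.null(top)) ord <- ord[seq_len(top)]
  writeLines(ord, path)
  invisible(path)
}
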