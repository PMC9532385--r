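#' Generate spatial-autocorrelation-preserving surrogate maps
#'
#' Builds randomized copies of a spatial map that keep both its value
#' distribution (exactly, via final rank re-assignment) and its spatial
#' autocorrelation (approximately, via variogram matching).  Per
#' surrogate: (1) the source values are randomly permuted (twice,
#' independently); (2) each permuted field is smoothed with Gaussian
#' distance kernels over the \code{knn} nearest neighbors at every
#' bandwidth of a grid of fractions of the maximum pairwise distance;
#' (3) for each bandwidth pair, non-negative scale coefficients for the
#' two smoothed fields and a nugget are fit by least squares so the
#' candidate's binned variogram tracks the source's (a two-scale mixture
#' spans variogram shapes a single kernel cannot); (4) the source's exact
#' value multiset is re-assigned onto each candidate field by rank, and
#' the candidate whose finished variogram deviates least (mean relative
#' error across bins) from the source's is kept.
#'
#' @param values numeric per-location scalars (>= 10 locations).
#' @param coords numeric matrix, locations x 3 (mm), finite.
#' @param n number of surrogates.
#' @param seed integer RNG seed.
#' @param knn neighborhood size for the smoothing kernels (default 100,
#'   truncated to locations - 1).
#' @param nBins number of variogram distance bins (default 25).
#' @param bandwidthFractions kernel bandwidths as fractions of the
#'   maximum pairwise distance.
#' @param maxQuantile variogram pairs beyond this distance quantile are
#'   ignored when fitting (default 0.25).
#' @return a \linkS4class{SurrogateSet}.
#' @export
generateSurrogates <- function(values, coords, n = 1000L, seed = 1L,
                               knn = 100L, nBins = 25L,
                               bandwidthFractions =
                                 c(0.01, 0.02, 0.035, 0.05, 0.075, 0.1,
                                   0.15, 0.25),
                               maxQuantile = 0.25) {
  coords <- rbind(coords)
  nloc <- length(values)
  if (nloc < 10L) stop("at least 10 locations are required")
  if (nrow(coords) != nloc) stop("one coordinate triple per value")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (knn >= nloc) knn <- nloc - 1L
  if (knn < 1L) stop("invalid 'knn'")

  D <- as.matrix(stats::dist(coords))
  dmax <- max(D)
  hs <- bandwidthFractions * dmax

  sorted <- sort(values)
  surr <- matrix(NA_real_, n, nloc)
  if (stats::sd(values) == 0) {
    # a constant source has only one value arrangement
    surr[] <- rep(sorted, each = n)
    return(new("SurrogateSet", source = values, surrogates = surr,
               coords = coords, n = as.integer(n), seed = as.integer(seed),
               params = list(knn = knn, nBins = nBins, bandwidths = hs)))
  }

  # k nearest neighbors (excluding self) and per-bandwidth kernel weights
  nbr <- t(apply(D, 1L, function(dr) order(dr)[2:(knn + 1L)]))
  nbrD <- matrix(D[cbind(rep(seq_len(nloc), knn), as.vector(nbr))],
                 nloc, knn)
  kernels <- lapply(hs, function(h) {
    Wk <- exp(-nbrD^2 / (2 * h^2))
    Wk / rowSums(Wk)
  })

  bins <- .variogramBins(D, nBins, maxQuantile)
  gammaSrc <- .binnedVariogram(values, bins)

  nk <- length(kernels)
  withr_seed(seed, {
    for (s in seq_len(n)) {
      p1 <- sample(values)
      p2 <- sample(values)
      eps <- rnorm(nloc)
      sm1 <- lapply(kernels, function(kk)
        rowSums(kk * matrix(p1[as.vector(nbr)], nloc, knn)))
      sm2 <- lapply(kernels, function(kk)
        rowSums(kk * matrix(p2[as.vector(nbr)], nloc, knn)))
      g1 <- lapply(sm1, .binnedVariogram, bins = bins)
      g2 <- lapply(sm2, .binnedVariogram, bins = bins)
      best <- NULL; bestErr <- Inf
      for (i in seq_len(nk)) for (j in i:nk) {
        X <- cbind(g1[[i]], g2[[j]], 1)
        ok <- rowSums(!is.finite(X)) == 0 & is.finite(gammaSrc)
        if (sum(ok) < 3L) next
        co <- .nnls(X[ok, , drop = FALSE], gammaSrc[ok])
        # variogram of sqrt(b1)*sm1 + sqrt(b2)*sm2 + sqrt(a)*eps is
        # b1*gamma1 + b2*gamma2 + a (the components are independent):
        # mix the fields, restore the value multiset by rank, then judge
        # the finished surrogate's variogram against the source's
        cand <- sorted[rank(sqrt(co[1]) * sm1[[i]] +
                            sqrt(co[2]) * sm2[[j]] +
                            sqrt(co[3]) * eps, ties.method = "first")]
        gC <- .binnedVariogram(cand, bins)
        err <- mean(abs(gC - gammaSrc) / gammaSrc, na.rm = TRUE)
        if (is.finite(err) && err < bestErr) {
          bestErr <- err
          best <- cand
        }
      }
      if (is.null(best)) best <- sorted[rank(p1, ties.method = "first")]
      surr[s, ] <- best
    }
  })
  new("SurrogateSet", source = values, surrogates = surr, coords = coords,
      n = as.integer(n), seed = as.integer(seed),
      params = list(knn = knn, nBins = nBins, bandwidths = hs))
}

# non-negative least squares by active-set elimination (tiny designs)
.nnls <- function(X, y) {
  act <- seq_len(ncol(X))
  repeat {
    co <- rep(0, ncol(X))
    if (!length(act)) return(co)
    fit <- stats::lm.fit(X[, act, drop = FALSE], y)
    co[act] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    if (all(co[act] >= 0)) return(co)
    act <- act[co[act] > 0]
  }
}

# equal-width distance bins over (0, q(maxQuantile)]; longer pairs are
# ignored: only short-range autocorrelation is matched, which is what the
# generative surrogate model can and should reproduce
.variogramBins <- function(D, nBins, maxQuantile = 0.25) {
  nloc <- nrow(D)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ij]
  dcap <- stats::quantile(d, maxQuantile)
  keep <- d <= dcap
  ij <- ij[keep, , drop = FALSE]
  d <- d[keep]
  brk <- seq(0, dcap, length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(d, brk, left.open = TRUE), 1L), nBins)
  counts <- tabulate(bin, nBins)
  list(i = ij[, 1], j = ij[, 2], bin = bin, counts = counts,
       nBins = nBins, centers = (brk[-1] + brk[-length(brk)]) / 2)
}

# binned empirical semivariogram gamma(h) = mean of 0.5*(v_i - v_j)^2
.binnedVariogram <- function(values, bins) {
  dv <- 0.5 * (values[bins$i] - values[bins$j])^2
  sums <- numeric(bins$nBins)
  agg <- rowsum(dv, bins$bin)
  sums[as.integer(rownames(agg))] <- agg
  out <- sums / bins$counts
  out[bins$counts == 0] <- NA_real_
  out
}

#' Binned empirical variogram of a spatial map
#'
#' @param values numeric per-location scalars.
#' @param coords numeric matrix, locations x 3.
#' @param nBins number of equal-width distance bins.
#' @param maxQuantile distance-quantile cap on the pairs used.
#' @return data.frame with bin centers (mm) and semivariance.
#' @export
empiricalVariogram <- function(values, coords, nBins = 25L,
                               maxQuantile = 0.25) {
  D <- as.matrix(stats::dist(rbind(coords)))
  bins <- .variogramBins(D, nBins, maxQuantile)
  data.frame(distance = bins$centers,
             gamma = .binnedVariogram(values, bins))
}

#' @rdname accessors
#' @export
setMethod("surrogateValues", "SurrogateSet", function(x) x@surrogates)

setMethod("show", "SurrogateSet", function(object) {
  cat(sprintf("SurrogateSet: %d surrogates of a %d-location map (knn = %d)\n",
              object@n, length(object@source), object@params$knn))
})

# one-sided Wilcoxon rank-sum statistic W (Mann-Whitney U of group A)
.ranksumU <- function(values, isA) {
  r <- rank(values)
  nA <- sum(isA)
  sum(r[isA]) - nA * (nA + 1) / 2
}

#' Surrogate-null one-sided rank-sum test of hub vs non-hub values
#'
#' Compares the observed one-sided Wilcoxon rank-sum statistic (hub
#' locations vs the rest) against a null distribution obtained by
#' relabeling: for each surrogate of the hub-defining map, the top-|hub|
#' locations are assigned as surrogate hubs and the statistic is
#' recomputed.  Because the surrogates preserve the map's spatial
#' autocorrelation, the null respects the spatial structure that plain
#' permutation would destroy.  The p value is add-one corrected, then
#' Bonferroni-multiplied by \code{nTestsBonferroni} and capped at 1.
#'
#' @param values numeric per-location scalars under test (e.g. a gene-set
#'   score).
#' @param hubIndicator logical per location.
#' @param surrogates a \linkS4class{SurrogateSet} of the hub-defining map.
#' @param direction "greater" (hub values larger) or "less".
#' @param nTestsBonferroni number of tests in the family (default 1).
#' @return list with \code{statistic} (Mann-Whitney U), \code{p}
#'   (corrected) and \code{pRaw}.
#' @export
ranksumSurrogateTest <- function(values, hubIndicator, surrogates,
                                 direction = c("greater", "less"),
                                 nTestsBonferroni = 1L) {
  direction <- match.arg(direction)
  hubIndicator <- as.logical(hubIndicator)
  nHub <- sum(hubIndicator)
  if (nHub == 0L || nHub == length(hubIndicator))
    stop("both groups must be non-empty")
  if (length(values) != length(hubIndicator) ||
      length(values) != ncol(surrogateValues(surrogates)))
    stop("values, labels and surrogates must share locations")
  obs <- .ranksumU(values, hubIndicator)
  S <- surrogateValues(surrogates)
  null <- vapply(seq_len(nrow(S)), function(s) {
    top <- order(-S[s, ], seq_len(ncol(S)))[seq_len(nHub)]
    lab <- logical(ncol(S)); lab[top] <- TRUE
    .ranksumU(values, lab)
  }, numeric(1))
  pRaw <- if (direction == "greater")
    (1 + sum(null >= obs)) / (length(null) + 1)
  else (1 + sum(null <= obs)) / (length(null) + 1)
  list(statistic = obs, p = min(1, pRaw * nTestsBonferroni), pRaw = pRaw)
}

#' Surrogate-null test of a spatial correlation
#'
#' Pearson correlation between two per-region maps, with significance
#' judged against the correlations of map b with
#' autocorrelation-preserving surrogates of map a (add-one correction).
#'
#' @param mapA,mapB numeric per-region scalars (equal length >= 3).
#' @param surrogatesOfA a \linkS4class{SurrogateSet} of \code{mapA}.
#' @param alternative "two.sided" (on |r|), "greater" or "less".
#' @return list with \code{r} and \code{p}.
#' @export
correlateSurrogateTest <- function(mapA, mapB, surrogatesOfA,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  if (length(mapA) != length(mapB) || length(mapA) < 3L)
    stop("maps must have equal length >= 3")
  if (!(stats::sd(mapA) > 0) || !(stats::sd(mapB) > 0))
    stop("zero-variance input")
  r <- stats::cor(mapA, mapB)
  S <- surrogateValues(surrogatesOfA)
  null <- as.numeric(stats::cor(t(S), mapB))
  nn <- length(null)
  p <- switch(alternative,
    greater = (1 + sum(null >= r)) / (nn + 1),
    less = (1 + sum(null <= r)) / (nn + 1),
    two.sided = (1 + sum(abs(null) >= abs(r))) / (nn + 1)
  )
  list(r = r, p = p)
}
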