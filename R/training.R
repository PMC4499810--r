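## Random-restart hill climbing over feature weights and the Edge
## Alignment Weight, maximizing represented protein orthologies (RPO),
## plus the two-stage similarity-feature reduction.

#' Default hill-climbing step schedule
#'
#' Four increasingly precise step sizes; the coarsest is the fourth root
#' of the finest: \code{0.01^(1/4)} (about 0.32), then 0.1, 0.03, 0.01.
#'
#' @return decreasing numeric vector of step sizes.
#' @export
trainingSchedule <- function() c(0.01^(1 / 4), 0.1, 0.03, 0.01)

#' Hill climb a weight vector under an RPO objective
#'
#' For each step size in turn, parameters are visited in random order and
#' randomly incremented or decremented by the step (moves leaving [0,1]
#' are redirected or skipped).  A move is reverted only when the previous
#' alignment had strictly more RPOs; ties keep the new value, which lets
#' the climber drift across plateaus.  A coarser step is abandoned for the
#' next only when a full pass produces no strict improvement.
#'
#' @param initial named numeric vector of parameters in [0,1] (typically
#'   feature weights plus \code{"EAW"}).
#' @param objective function taking such a vector and returning a numeric
#'   vector with elements \code{rpo} and \code{ea}.
#' @param schedule strictly decreasing step sizes
#'   (default \code{\link{trainingSchedule}()}).
#' @return list with \code{weights} (the local optimum) and \code{value}
#'   (its objective).
#' @export
hillClimb <- function(initial, objective, schedule = trainingSchedule()) {
  if (any(initial < 0 | initial > 1)) stop("initial weights must lie in [0,1]")
  if (is.unsorted(rev(schedule), strictly = TRUE))
    stop("schedule must be strictly decreasing")
  cur <- initial
  curv <- objective(cur)
  for (step in schedule) {
    repeat {
      improved <- FALSE
      for (p in sample(names(cur))) {
        ## both directions are tried (random order) before concluding the
        ## parameter cannot improve; the first improving direction is
        ## followed as far as it keeps strictly improving
        for (dir in sample(c(-1, 1))) {
          p_improved <- FALSE
          repeat {
            val <- cur[[p]] + dir * step
            if (val < 0 || val > 1) break
            cand <- cur
            cand[[p]] <- val
            cv <- objective(cand)
            if (cv[["rpo"]] > curv[["rpo"]]) {
              cur <- cand; curv <- cv
              improved <- TRUE; p_improved <- TRUE
            } else if (cv[["rpo"]] == curv[["rpo"]]) {
              cur <- cand; curv <- cv; break  # tie: keep, stop stepping
            } else break                      # worse: revert
          }
          if (p_improved) break
        }
      }
      if (!improved) break
    }
  }
  list(weights = cur, value = curv)
}

#' Alignment-quality objective for weight training
#'
#' Builds the function optimized by \code{\link{hillClimb}}: weights
#' (including \code{"EAW"}) are assembled into base similarity matrices,
#' GreedyPlus is run, and the RPO/OVP/EA counts are returned.
#'
#' @param features list of \linkS4class{FeatureMatrix} objects.
#' @param net1,net2 the networks.
#' @param orth an \linkS4class{OrthologyMap}.
#' @return function: named weight vector -> c(rpo, ovp, ea).
#' @export
makeAlignmentObjective <- function(features, net1, net2, orth) {
  fnames <- unique(vapply(features, featureName, ""))
  function(params) {
    w <- params[setdiff(names(params), "EAW")]
    wv <- WeightVector(weights = w[fnames], eaw = params[["EAW"]])
    base <- assembleStack(features, wv)
    trace <- greedyPlusAlign(net1, net2, base, eaw = params[["EAW"]])
    .metrics_counts(trace, net1, net2, orth)
  }
}

#' Random-restart training of feature weights and the EAW
#'
#' Each restart draws all parameters (feature weights and the Edge
#' Alignment Weight) independently from U[0,1] and hill climbs them under
#' the RPO objective.  The best restart is the one with maximal RPO, ties
#' broken by EA and then by restart index.  Fully reproducible from
#' \code{seed}.
#'
#' @param features list of \linkS4class{FeatureMatrix} objects.
#' @param net1,net2 the networks.
#' @param orth an \linkS4class{OrthologyMap}.
#' @param restarts number of random restarts (desk-scale default 50;
#'   published-scale runs used thousands).
#' @param seed integer RNG seed.
#' @param schedule hill-climbing step sizes.
#' @return a \linkS4class{TrainingRun}.
#' @export
trainWeights <- function(features, net1, net2, orth, restarts = 50L,
                         seed = 1L, schedule = trainingSchedule()) {
  if (restarts < 1L) stop("restarts must be >= 1")
  fnames <- unique(vapply(features, featureName, ""))
  pnames <- c(fnames, "EAW")
  objective <- makeAlignmentObjective(features, net1, net2, orth)
  set.seed(seed)
  hist <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    init <- stats::setNames(stats::runif(length(pnames)), pnames)
    res <- hillClimb(init, objective, schedule)
    hist[[r]] <- c(restart = r, res$value[c("rpo", "ovp", "ea")],
                   res$weights)
  }
  history <- as.data.frame(do.call(rbind, hist))
  best_i <- order(-history$rpo, -history$ea, history$restart)[1]
  bw <- unlist(history[best_i, pnames])
  best <- WeightVector(weights = bw[fnames], eaw = bw[["EAW"]])
  methods::new("TrainingRun", seed = as.integer(seed),
               restarts = as.integer(restarts),
               schedule = as.numeric(schedule), best = best,
               history = history)
}

#' Remove mutually redundant similarity features
#'
#' Features of the same side are compared by Euclidean distance between
#' their vectorized normalized score matrices.  While any pair lies within
#' \code{threshold}, the member of the closest such pair with the smaller
#' summed distance to all remaining same-side features (i.e. the one most
#' similar to the rest) is dropped.
#'
#' @param features list of \linkS4class{FeatureMatrix} objects.
#' @param threshold redundancy distance cutoff (default 0.10).
#' @return the reduced feature list (order preserved).
#' @export
reduceRedundant <- function(features, threshold = 0.10) {
  if (length(features) < 2L) return(features)
  keep <- seq_along(features)
  sides <- vapply(features, featureSide, "")
  vecs <- lapply(features, function(f) as.vector(f@scores))
  repeat {
    if (length(keep) < 2L) break
    ## closest same-side pair within threshold
    best <- NULL
    for (a in seq_along(keep)[-length(keep)]) for (b in (a + 1L):length(keep)) {
      ia <- keep[a]; ib <- keep[b]
      if (sides[ia] != sides[ib]) next
      if (length(vecs[[ia]]) != length(vecs[[ib]])) next
      d <- sqrt(sum((vecs[[ia]] - vecs[[ib]])^2))
      if (d <= threshold && (is.null(best) || d < best$d))
        best <- list(ia = ia, ib = ib, d = d)
    }
    if (is.null(best)) break
    sum_dist <- function(i) {
      others <- setdiff(keep, i)
      others <- others[sides[others] == sides[i] &
                         lengths(vecs[others]) == length(vecs[[i]])]
      sum(vapply(others, function(o)
        sqrt(sum((vecs[[i]] - vecs[[o]])^2)), numeric(1)))
    }
    drop <- if (sum_dist(best$ia) <= sum_dist(best$ib)) best$ia else best$ib
    keep <- setdiff(keep, drop)
  }
  features[sort(keep)]
}

#' Iterative lowest-weight feature elimination
#'
#' Repeatedly trains the weights, averages each feature's weight over the
#' \code{topK} best parameter sets, and removes the feature with the
#' lowest mean weight - unless doing so would reduce the best achievable
#' RPO, in which case the procedure stops.  The Edge Alignment Weight is
#' never a removal candidate.
#'
#' @param features list of \linkS4class{FeatureMatrix} objects.
#' @param net1,net2 the networks.
#' @param orth an \linkS4class{OrthologyMap}.
#' @param topK number of best parameter sets averaged (default 50).
#' @param restarts restarts per training run.
#' @param seed base RNG seed (each round uses \code{seed + round - 1}).
#' @return list with \code{features} (the surviving list), \code{run}
#'   (the final \linkS4class{TrainingRun}) and \code{removed} (names in
#'   removal order).
#' @export
reduceIterative <- function(features, net1, net2, orth, topK = 50L,
                            restarts = 25L, seed = 1L) {
  if (!length(features)) stop("features must be nonempty")
  removed <- character()
  round <- 1L
  run <- trainWeights(features, net1, net2, orth, restarts = restarts,
                      seed = seed)
  repeat {
    fnames <- unique(vapply(features, featureName, ""))
    if (length(fnames) < 2L) break
    h <- run@history
    top <- h[order(-h$rpo, -h$ea, h$restart), , drop = FALSE]
    top <- utils::head(top, topK)
    mean_w <- vapply(fnames, function(f) mean(top[[f]]), numeric(1))
    cand <- names(which.min(mean_w))
    reduced <- Filter(function(f) featureName(f) != cand, features)
    round <- round + 1L
    run2 <- trainWeights(reduced, net1, net2, orth, restarts = restarts,
                         seed = seed + round - 1L)
    if (max(run2@history$rpo) < max(run@history$rpo)) break
    features <- reduced
    removed <- c(removed, cand)
    run <- run2
  }
  list(features = features, run = run, removed = removed)
}

#' Pairwise feature-distance structure (diagnostic)
#'
#' Euclidean distances between vectorized feature matrices of one side,
#' with the principal components of the feature vectors as a descriptive
#' aid for spotting redundant features.
#'
#' @param features list of \linkS4class{FeatureMatrix} objects.
#' @param side partition side to analyse.
#' @return list with \code{distances} (a dist object over feature names)
#'   and \code{pca} (a \code{prcomp} fit, or NULL for fewer than 3
#'   features).
#' @export
featureDistanceReport <- function(features, side) {
  fs <- Filter(function(f) featureSide(f) == side, features)
  if (length(fs) < 2L) stop("need at least two features on side ", side)
  m <- do.call(rbind, lapply(fs, function(f) as.vector(f@scores)))
  rownames(m) <- vapply(fs, featureName, "")
  pca <- if (nrow(m) >= 3L) stats::prcomp(m) else NULL
  list(distances = stats::dist(m), pca = pca)
}
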