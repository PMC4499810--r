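## Vertex similarity features: topological centralities, logarithmic
## pair normalization, Smith-Waterman peptide similarity, imported score
## tables, and assembly of weighted base-similarity matrices.

.topo_features <- c("degree", "avg_shortest_path", "betweenness", "closeness",
                    "eccentricity", "neighbourhood_connectivity", "radiality",
                    "stress", "topological_coefficient")

#' Per-vertex topological scores of an IIN
#'
#' Computes one of nine classical per-vertex measures, following the
#' NetworkAnalyzer conventions: distances are taken within connected
#' components; \code{closeness} is the reciprocal of the mean distance to
#' reachable vertices; \code{radiality} is (component diameter + 1 - mean
#' distance)/diameter; \code{betweenness} and \code{stress} use standard
#' unnormalized shortest-path counting; \code{topological_coefficient}
#' averages shared-neighbour fractions over partners sharing at least one
#' neighbour.  Isolated vertices score 0 on all distance-based measures.
#'
#' @param net an \linkS4class{IIN}.
#' @param feature one of \code{"degree"}, \code{"avg_shortest_path"},
#'   \code{"betweenness"}, \code{"closeness"}, \code{"eccentricity"},
#'   \code{"neighbourhood_connectivity"}, \code{"radiality"},
#'   \code{"stress"}, \code{"topological_coefficient"}.
#' @param side restrict the result to one partition side (default both).
#' @return named numeric vector over vertex ids.
#' @export
topoVertexScores <- function(net, feature = .topo_features,
                             side = c("both", "domain", "ligand")) {
  feature <- match.arg(feature)
  side <- match.arg(side)
  if (!nrow(net@vertices)) stop("network has no vertices")
  g <- asIgraph(net)
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)

  val <- switch(feature,
    degree = deg,
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE),
    neighbourhood_connectivity = {
      adj <- adjacencyList(net)
      vapply(ids, function(v) {
        nb <- adj[[v]]
        if (!length(nb)) 0 else mean(deg[nb])
      }, numeric(1))
    },
    topological_coefficient = {
      adj <- adjacencyList(net)
      vapply(ids, function(v) {
        nb <- adj[[v]]
        if (!length(nb)) return(0)
        shared <- vapply(setdiff(ids, v), function(w)
          length(intersect(nb, adj[[w]])), numeric(1))
        partners <- shared[shared > 0]
        if (!length(partners)) 0 else mean(partners / length(nb))
      }, numeric(1))
    },
    stress = .stress_centrality(net),
    {
      ## distance-based measures
      D <- igraph::distances(g)
      diag(D) <- Inf
      comp <- igraph::components(g)$membership
      comp_diam <- vapply(unique(comp), function(cmp) {
        sub <- D[comp == cmp, comp == cmp, drop = FALSE]
        fin <- sub[is.finite(sub)]
        if (length(fin)) max(fin) else 0
      }, numeric(1))
      names(comp_diam) <- unique(comp)
      vapply(seq_along(ids), function(i) {
        d <- D[i, ]
        d <- d[is.finite(d)]
        if (!length(d)) return(0)
        avg <- mean(d)
        switch(feature,
               avg_shortest_path = avg,
               closeness = 1 / avg,
               eccentricity = max(d),
               radiality = {
                 diam <- comp_diam[[as.character(comp[i])]]
                 if (diam == 0) 0 else (diam + 1 - avg) / diam
               })
      }, numeric(1))
    })
  names(val) <- ids
  if (side != "both") val <- val[vertexKinds(net)[ids] == side]
  val
}

## Stress centrality: for every vertex v, the number of shortest paths
## between other vertex pairs that pass through v (sigma counting).
.stress_centrality <- function(net) {
  adj <- adjacencyList(net)
  ids <- names(adj)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  D <- matrix(Inf, n, n); S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (w in idx[adj[[ids[u]]]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[u] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[u] + 1) sig[w] <- sig[w] + sig[u]
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist; S[s, ] <- sig
  }
  stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v || is.infinite(D[s, v])) next
      for (t in seq_len(n)) {
        if (t <= s || t == v || is.infinite(D[v, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
          stress[v] <- stress[v] + S[s, v] * S[v, t]
      }
    }
  }
  stats::setNames(stress, ids)
}

#' Turn two per-vertex score sets into a normalized similarity matrix
#'
#' For vertices i in network 1 and j in network 2 the raw similarity is
#' \code{raw = M - |score_i - score_j|} with M the maximum absolute
#' cross-network score difference, then normalized logarithmically as
#' \code{adj = log(raw + 1)/log(M + 1)}.  Equal scores map to 1, the most
#' dissimilar cross pair maps to 0; when all scores coincide (M = 0) every
#' pair maps to 1.  The result is invariant to shifting or negating all
#' scores.
#'
#' @param s1,s2 named numeric vectors of per-vertex raw scores (network 1
#'   and network 2, same feature and side).
#' @param name feature name for the result.
#' @param side partition side of the vertices.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
normalizeFeature <- function(s1, s2, name = "feature", side = "domain") {
  if (!length(s1) || !length(s2)) stop("score sets must be nonempty")
  if (any(!is.finite(s1)) || any(!is.finite(s2)))
    stop("vertex scores must be finite")
  diffs <- abs(outer(s1, s2, `-`))
  M <- max(diffs)
  adj <- if (M == 0) matrix(1, length(s1), length(s2))
         else log(M - diffs + 1) / log(M + 1)
  dimnames(adj) <- list(names(s1), names(s2))
  FeatureMatrix(name, side, adj, "computed")
}

#' Topological similarity feature between two networks
#'
#' Convenience wrapper: computes one topological score on both networks
#' and normalizes the cross-network differences for one side.
#'
#' @param net1,net2 the two \linkS4class{IIN}s.
#' @param feature a \code{\link{topoVertexScores}} feature name.
#' @param side "domain" or "ligand".
#' @return a \linkS4class{FeatureMatrix}.
#' @export
topoFeature <- function(net1, net2, feature, side) {
  s1 <- topoVertexScores(net1, feature, side = side)
  s2 <- topoVertexScores(net2, feature, side = side)
  normalizeFeature(s1, s2, name = paste(feature, side, sep = "_"), side = side)
}

#' Smith-Waterman local alignment score of two peptides
#'
#' Optimal local alignment with affine gap penalties under a substitution
#' matrix (BLOSUM62 by default, gap open 10, gap extend 0.5).  The score
#' is symmetric and never negative; an empty sequence scores 0.
#'
#' @param seq1,seq2 amino-acid strings (standard 20 letters plus X).
#' @param matrix substitution matrix name or matrix (default "BLOSUM62").
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @return the alignment score.
#' @export
smithWaterman <- function(seq1, seq2, matrix = "BLOSUM62",
                          gapOpen = 10, gapExtend = 0.5) {
  if (is.na(seq1) || is.na(seq2) || !nchar(seq1) || !nchar(seq2)) return(0)
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2), type = "local",
    substitutionMatrix = matrix, gapOpening = gapOpen,
    gapExtension = gapExtend, scoreOnly = TRUE)
  max(0, sc)
}

#' Smith-Waterman similarity feature over ligand sequences
#'
#' Scores every cross-network pair of same-side vertices that both carry a
#' sequence (pairs with a missing sequence score 0), then rescales to
#' [0,1] with \code{\link{pairwiseScoresToFeature}}.
#'
#' @param net1,net2 \linkS4class{IIN}s with vertex sequences attached.
#' @param side partition side (default "ligand").
#' @param mode normalization mode, see \code{\link{pairwiseScoresToFeature}}.
#' @param ... passed to \code{\link{smithWaterman}}.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
sequenceFeature <- function(net1, net2, side = "ligand",
                            mode = c("linear_max", "log"), ...) {
  mode <- match.arg(mode)
  v1 <- net1@vertices[net1@vertices$kind == side, ]
  v2 <- net2@vertices[net2@vertices$kind == side, ]
  raw <- matrix(0, nrow(v1), nrow(v2), dimnames = list(v1$id, v2$id))
  for (i in seq_len(nrow(v1))) for (j in seq_len(nrow(v2)))
    if (!is.na(v1$sequence[i]) && !is.na(v2$sequence[j]))
      raw[i, j] <- smithWaterman(v1$sequence[i], v2$sequence[j], ...)
  pairwiseScoresToFeature(raw, mode = mode,
                          name = paste("smith_waterman", side, sep = "_"),
                          side = side, provenance = "computed")
}

#' Rescale non-negative pairwise scores into a [0,1] feature
#'
#' \code{linear_max} divides by the global maximum (an all-zero input
#' stays all zero); \code{log} applies \code{log(s+1)/log(max+1)}.
#'
#' @param scores numeric matrix with id dimnames, or a data.frame with
#'   columns \code{id1}, \code{id2}, \code{score} (missing pairs become 0).
#' @param mode "linear_max" (default) or "log".
#' @param name,side,provenance metadata for the result.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
pairwiseScoresToFeature <- function(scores, mode = c("linear_max", "log"),
                                    name = "pairwise", side = "domain",
                                    provenance = "imported") {
  mode <- match.arg(mode)
  if (is.data.frame(scores)) {
    r <- sort(unique(scores$id1)); cc <- sort(unique(scores$id2))
    m <- matrix(0, length(r), length(cc), dimnames = list(r, cc))
    m[cbind(scores$id1, scores$id2)] <- scores$score
    scores <- m
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (any(scores < 0)) stop("scores must be non-negative")
  mx <- max(scores, 0)
  out <- if (mx == 0) scores
         else if (mode == "linear_max") scores / mx
         else log(scores + 1) / log(mx + 1)
  FeatureMatrix(name, side, out, provenance)
}

#' Broadcast protein-level pair scores to vertex pairs
#'
#' Every same-side cross-network vertex pair inherits the score of its
#' protein pair; protein pairs absent from the table score 0.
#'
#' @param proteinScores data.frame with columns \code{id1}, \code{id2}
#'   (protein names in networks 1 and 2) and \code{score} in [0,1].
#' @param net1,net2 the networks.
#' @param side partition side to cover.
#' @param name feature name.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
liftProteinFeature <- function(proteinScores, net1, net2, side,
                               name = "protein_feature") {
  if (any(proteinScores$score < 0 | proteinScores$score > 1))
    stop("protein scores must lie in [0,1]")
  v1 <- net1@vertices[net1@vertices$kind == side, ]
  v2 <- net2@vertices[net2@vertices$kind == side, ]
  lut <- stats::setNames(proteinScores$score,
                         paste(proteinScores$id1, proteinScores$id2, sep = "\t"))
  key <- outer(v1$protein, v2$protein, paste, sep = "\t")
  m <- matrix(unname(lut[key]), nrow(v1), nrow(v2),
              dimnames = list(v1$id, v2$id))
  m[is.na(m)] <- 0
  FeatureMatrix(name, side, m, "imported")
}

#' Combine weighted feature matrices into base similarity matrices
#'
#' The base similarity of a vertex pair is the weighted sum of its feature
#' scores, computed separately per partition side:
#' \code{base[i,j] = sum_f w_f * adj_f[i,j]}.
#'
#' @param features list of \linkS4class{FeatureMatrix} objects (or a
#'   \linkS4class{FeatureStack}, in which case \code{weights} defaults to
#'   its weight vector).
#' @param weights a \linkS4class{WeightVector}; every feature name must be
#'   weighted and every weighted name must exist among the features.
#' @return list with elements \code{domain} and \code{ligand}: numeric
#'   matrices (NULL when a side has no features).
#' @export
assembleStack <- function(features, weights = NULL) {
  if (methods::is(features, "FeatureStack")) {
    if (is.null(weights)) weights <- features@weights
    features <- features@features
  }
  if (is.null(weights)) stop("weights are required")
  w <- weights@weights
  fnames <- vapply(features, featureName, "")
  unknown <- setdiff(names(w), fnames)
  if (length(unknown))
    stop("weights name unknown feature(s): ", paste(unknown, collapse = ", "))
  missing_w <- setdiff(fnames, names(w))
  if (length(missing_w))
    stop("features missing a weight: ", paste(missing_w, collapse = ", "))
  out <- list(domain = NULL, ligand = NULL)
  for (f in features) {
    term <- w[[f@name]] * f@scores
    if (is.null(out[[f@side]])) out[[f@side]] <- term
    else {
      if (!identical(dimnames(out[[f@side]]), dimnames(f@scores)))
        stop("feature matrices on the ", f@side,
             " side cover different pair universes")
      out[[f@side]] <- out[[f@side]] + term
    }
  }
  out
}
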