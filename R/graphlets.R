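## Graphlet catalogue, per-vertex orbit counting and graphlet degree
## signature similarity, with a restriction to bipartite-compatible
## graphlets (odd-cycle-free), which are the only ones that can occur in
## an IIN.

.pkg_cache <- new.env(parent = emptyenv())

.perms <- function(n) {
  key <- paste0("perms", n)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  p <- if (n == 1) list(1L) else {
    sub <- .perms(n - 1L)
    out <- list()
    for (s in sub) for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(s, n, after = pos - 1L)
    out
  }
  ## normalize: each perm maps position -> vertex
  .pkg_cache[[key]] <- lapply(p, as.integer)
  .pkg_cache[[key]]
}

## Canonical form of a small adjacency matrix: the lexicographically
## smallest upper-triangle bit string over all vertex relabellings.
## Returns the string and one permutation achieving it.
.canon <- function(A) {
  n <- nrow(A)
  ut <- which(upper.tri(A))
  best <- NULL; best_p <- NULL
  for (p in .perms(n)) {
    s <- paste(A[p, p][ut], collapse = "")
    if (is.null(best) || s < best) { best <- s; best_p <- p }
  }
  list(str = paste0(n, ":", best), perm = best_p)
}

.is_connected_adj <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

.is_bipartite_adj <- function(A) {
  n <- nrow(A)
  colr <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (!is.na(colr[s])) next
    colr[s] <- 0L; frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (w in which(A[u, ] > 0)) {
        if (is.na(colr[w])) { colr[w] <- 1L - colr[u]; nxt <- c(nxt, w) }
        else if (colr[w] == colr[u]) return(FALSE)
      }
      frontier <- nxt
    }
  }
  TRUE
}

## Full graphlet catalogue on 2..maxNodes nodes.  Each entry: n, adj,
## edges, bipartite, canon string/perm, vertex orbits (local classes) and
## global orbit ids per vertex.  Entry order: node count, edge count,
## canonical string; orbit ids are assigned in that order with the 2-node
## edge orbit as index 0.
.graphlet_catalogue <- function(maxNodes = 5L) {
  key <- paste0("catalogue", maxNodes)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  entries <- list()
  for (n in 2:maxNodes) {
    pairs <- utils::combn(n, 2L)
    m <- ncol(pairs)
    seen <- character()
    found <- list()
    for (mask in 1:(2^m - 1L)) {
      on <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
      if (length(on) < n - 1L) next    # too few edges to connect
      A <- matrix(0L, n, n)
      for (e in on) { i <- pairs[1, e]; j <- pairs[2, e]; A[i, j] <- A[j, i] <- 1L }
      if (!.is_connected_adj(A)) next
      cn <- .canon(A)
      if (cn$str %in% seen) next
      seen <- c(seen, cn$str)
      found[[length(found) + 1L]] <-
        list(n = n, adj = A, edges = length(on), bipartite = .is_bipartite_adj(A),
             canon = cn$str, canon_perm = cn$perm)
    }
    ord <- order(vapply(found, `[[`, 0L, "edges"),
                 vapply(found, `[[`, "", "canon"))
    entries <- c(entries, found[ord])
  }
  ## automorphism orbits + global orbit indices
  next_orbit <- 0L
  lookup <- new.env(parent = emptyenv())
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    n <- e$n
    auto <- Filter(function(p) identical(e$adj[p, p], e$adj), .perms(n))
    orbit_local <- seq_len(n)
    for (p in auto) orbit_local <- pmin(orbit_local, orbit_local[p])
    ## iterate to closure
    repeat {
      prev <- orbit_local
      for (p in auto) orbit_local <- pmin(orbit_local, orbit_local[p])
      if (identical(prev, orbit_local)) break
    }
    classes <- sort(unique(orbit_local))
    orbit_global <- integer(n)
    for (cl in classes) {
      orbit_global[orbit_local == cl] <- next_orbit
      next_orbit <- next_orbit + 1L
    }
    e$orbit_of_vertex <- orbit_global
    e$orbit_ids <- unique(orbit_global)
    e$id <- k - 1L
    entries[[k]] <- e
    assign(e$canon, k, envir = lookup)
  }
  cat_obj <- list(entries = entries, lookup = lookup, n_orbits = next_orbit,
                  maxNodes = maxNodes)
  .pkg_cache[[key]] <- cat_obj
  cat_obj
}

#' Enumerate the connected graphlets on 3 to maxNodes nodes
#'
#' Exhaustively enumerates connected non-isomorphic graphs, recording for
#' each its automorphism orbits and whether it is bipartite (2-colourable,
#' i.e. odd-cycle-free).  For \code{maxNodes = 5} there are 29 such
#' graphlets; the additional 2-node edge graphlet (orbit index 0) is
#' included when \code{includeEdge = TRUE} and is always part of the orbit
#' index space used by \code{\link{orbitCounts}}.
#'
#' @param maxNodes largest graphlet size, between 3 and 5.
#' @param includeEdge also list the single 2-node graphlet.
#' @return data.frame with one row per graphlet: \code{graphlet} (0-based
#'   id), \code{nodes}, \code{edges}, \code{bipartite}, \code{n_orbits},
#'   \code{orbits} (comma-separated global orbit indices).
#' @export
enumerateGraphlets <- function(maxNodes = 5L, includeEdge = FALSE) {
  if (maxNodes < 3L || maxNodes > 5L) stop("maxNodes must be 3, 4 or 5")
  cat_obj <- .graphlet_catalogue(5L)
  keep <- vapply(cat_obj$entries, function(e)
    e$n <= maxNodes && (includeEdge || e$n >= 3L), TRUE)
  es <- cat_obj$entries[keep]
  data.frame(
    graphlet = vapply(es, `[[`, 0L, "id"),
    nodes = vapply(es, `[[`, 0L, "n"),
    edges = vapply(es, `[[`, 0L, "edges"),
    bipartite = vapply(es, `[[`, TRUE, "bipartite"),
    n_orbits = vapply(es, function(e) length(e$orbit_ids), 0L),
    orbits = vapply(es, function(e) paste(e$orbit_ids, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Adjacency matrices of the graphlet catalogue
#'
#' @param maxNodes largest graphlet size.
#' @return list of 0/1 adjacency matrices named by 0-based graphlet id,
#'   including the 2-node edge graphlet.
#' @export
graphletAdjacencies <- function(maxNodes = 5L) {
  cat_obj <- .graphlet_catalogue(5L)
  es <- Filter(function(e) e$n <= maxNodes, cat_obj$entries)
  stats::setNames(lapply(es, `[[`, "adj"),
                  vapply(es, `[[`, 0L, "id"))
}

## Orbit index space under a restriction: global orbit ids (0-based).
.orbit_space <- function(restriction = c("all", "bipartite_only"),
                         maxNodes = 5L) {
  restriction <- match.arg(restriction)
  cat_obj <- .graphlet_catalogue(5L)
  ids <- integer()
  for (e in cat_obj$entries) {
    if (e$n > maxNodes) next
    if (restriction == "bipartite_only" && !e$bipartite) next
    ids <- c(ids, e$orbit_ids)
  }
  sort(ids)
}

#' Graphlet orbit counts per vertex
#'
#' Counts, for every vertex, the connected induced subgraphs on 2--5
#' vertices it participates in, broken down by the vertex's automorphism
#' orbit (standard graphlet degree signature semantics).  Enumeration uses
#' the ESU scheme so each induced subgraph is visited exactly once.  Under
#' \code{restriction = "bipartite_only"} the orbit columns of graphlets
#' containing odd cycles - provably zero on a bipartite network - are
#' dropped.
#'
#' @param net an \linkS4class{IIN}.
#' @param restriction "all" or "bipartite_only".
#' @param maxNodes largest graphlet size to count (default 5).
#' @return integer matrix, rows = vertex ids, columns = orbit indices
#'   (named \code{"o<index>"}); attribute \code{restriction} records the
#'   flag.
#' @export
orbitCounts <- function(net, restriction = c("all", "bipartite_only"),
                        maxNodes = 5L) {
  restriction <- match.arg(restriction)
  cat_obj <- .graphlet_catalogue(5L)
  space <- .orbit_space(restriction, maxNodes)
  col_of <- stats::setNames(seq_along(space), space)
  adj <- adjacencyList(net)
  ids <- names(adj)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  nbrs <- lapply(adj, function(x) unname(idx[x]))
  counts <- matrix(0L, n, length(space),
                   dimnames = list(ids, paste0("o", space)))

  record <- function(sub) {
    k <- length(sub)
    A <- matrix(0L, k, k)
    for (a in 1:(k - 1L)) for (b in (a + 1L):k)
      if (sub[b] %in% nbrs[[sub[a]]]) A[a, b] <- A[b, a] <- 1L
    cn <- .canon(A)
    ek <- get0(cn$str, envir = cat_obj$lookup)
    if (is.null(ek)) return(invisible())
    entry <- cat_obj$entries[[ek]]
    ## A[cn$perm, cn$perm] == entry$adj[entry$canon_perm, entry$canon_perm]:
    ## subset vertex cn$perm[i] corresponds to entry vertex canon_perm[i]
    for (i in seq_len(k)) {
      orb <- entry$orbit_of_vertex[entry$canon_perm[i]]
      cname <- as.character(orb)
      if (!is.na(col_of[cname])) {
        v <- sub[cn$perm[i]]
        counts[v, col_of[[cname]]] <<- counts[v, col_of[[cname]]] + 1L
      }
    }
    invisible()
  }

  extend <- function(sub, ext, root, k) {
    if (length(sub) == k) { record(sub); return(invisible()) }
    while (length(ext)) {
      w <- ext[1]
      ext <- ext[-1]
      excl <- unique(c(sub, unlist(nbrs[sub])))
      new_ext <- unique(c(ext, setdiff(nbrs[[w]][nbrs[[w]] > root], excl)))
      extend(c(sub, w), new_ext, root, k)
    }
    invisible()
  }

  for (k in 2:maxNodes)
    for (v in seq_len(n))
      extend(v, nbrs[[v]][nbrs[[v]] > v], v, k)
  attr(counts, "restriction") <- restriction
  counts
}

## Programmatic orbit dependency counts: for orbit i, the number of
## distinct orbits (itself included) realizable as a connected subgraph of
## orbit i's graphlet through the focal vertex.  Used by the optional
## "dependency" weighting; the default weighting is uniform.
.orbit_dependencies <- function() {
  if (!is.null(.pkg_cache$orbit_deps)) return(.pkg_cache$orbit_deps)
  cat_obj <- .graphlet_catalogue(5L)
  deps <- integer(cat_obj$n_orbits)
  for (e in cat_obj$entries) {
    n <- e$n
    pairs <- if (n >= 2) utils::combn(n, 2L) else matrix(0L, 2, 0)
    reps <- vapply(unique(e$orbit_of_vertex), function(orb)
      which(e$orbit_of_vertex == orb)[1], 0L)
    for (r_i in seq_along(reps)) {
      focal <- reps[r_i]
      orb_id <- e$orbit_of_vertex[focal]
      seen_orbits <- integer()
      ## vertex subsets containing the focal vertex
      others <- setdiff(seq_len(n), focal)
      for (smask in 0:(2^length(others) - 1L)) {
        S <- c(focal, others[bitwAnd(smask, 2^(seq_along(others) - 1L)) > 0L])
        if (length(S) < 2L) next
        S <- sort(S)
        ep <- which(e$adj[cbind(pairs[1, ], pairs[2, ])] > 0 &
                      pairs[1, ] %in% S & pairs[2, ] %in% S)
        if (!length(ep)) next
        for (emask in 1:(2^length(ep) - 1L)) {
          on <- ep[bitwAnd(emask, 2^(seq_along(ep) - 1L)) > 0L]
          k <- length(S)
          A <- matrix(0L, k, k)
          pos <- stats::setNames(seq_len(k), S)
          for (eidx in on) {
            a <- pos[[as.character(pairs[1, eidx])]]
            b <- pos[[as.character(pairs[2, eidx])]]
            A[a, b] <- A[b, a] <- 1L
          }
          if (!.is_connected_adj(A)) next
          cn <- .canon(A)
          ek <- get0(cn$str, envir = cat_obj$lookup)
          if (is.null(ek)) next
          sub_entry <- cat_obj$entries[[ek]]
          fpos <- which(cn$perm == pos[[as.character(focal)]])
          sub_orb <- sub_entry$orbit_of_vertex[sub_entry$canon_perm[fpos]]
          seen_orbits <- union(seen_orbits, sub_orb)
        }
      }
      deps[orb_id + 1L] <- length(union(seen_orbits, orb_id))
    }
  }
  .pkg_cache$orbit_deps <- deps
  deps
}

#' Graphlet degree signature similarity of two orbit-count vectors
#'
#' Per-orbit distance \code{D_i = w_i |log(u_i+1) - log(v_i+1)| /
#' log(max(u_i, v_i) + 2)}; similarity is \code{1 - sum(D_i)/sum(w_i)}.
#' Symmetric, in [0,1], and equal to 1 exactly for identical vectors.
#' The default weighting is uniform; \code{"dependency"} down-weights
#' orbits by the (programmatically derived) number of orbits they depend
#' on, \code{w_i = 1 - log(o_i)/log(73)}.
#'
#' @param o1,o2 orbit-count vectors (rows of \code{\link{orbitCounts}}
#'   matrices) sharing the same restriction and index space.
#' @param orbitWeights "uniform" (default) or "dependency".
#' @return similarity in [0,1].
#' @export
signatureSimilarity <- function(o1, o2,
                                orbitWeights = c("uniform", "dependency")) {
  orbitWeights <- match.arg(orbitWeights)
  if (length(o1) != length(o2) ||
      (!is.null(names(o1)) && !is.null(names(o2)) &&
       !identical(names(o1), names(o2))))
    stop("orbit vectors must share the same index space (same restriction)")
  w <- if (orbitWeights == "uniform") rep(1, length(o1)) else {
    deps <- .orbit_dependencies()
    orb_idx <- as.integer(sub("^o", "", names(o1)))
    1 - log(deps[orb_idx + 1L]) / log(length(deps))
  }
  d <- w * abs(log(o1 + 1) - log(o2 + 1)) / log(pmax(o1, o2) + 2)
  1 - sum(d) / sum(w)
}

#' Graphlet-signature similarity feature between two networks
#'
#' @param net1,net2 \linkS4class{IIN}s.
#' @param side partition side to cover.
#' @param restriction orbit restriction passed to \code{\link{orbitCounts}}
#'   (default "bipartite_only", appropriate for IINs).
#' @param orbitWeights passed to \code{\link{signatureSimilarity}}.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
graphletFeature <- function(net1, net2, side,
                            restriction = "bipartite_only",
                            orbitWeights = "uniform") {
  c1 <- orbitCounts(net1, restriction)
  c2 <- orbitCounts(net2, restriction)
  ids1 <- net1@vertices$id[net1@vertices$kind == side]
  ids2 <- net2@vertices$id[net2@vertices$kind == side]
  m <- matrix(0, length(ids1), length(ids2), dimnames = list(ids1, ids2))
  for (i in ids1) for (j in ids2)
    m[i, j] <- signatureSimilarity(c1[i, ], c2[j, ], orbitWeights)
  FeatureMatrix(paste("graphlet", side, sep = "_"), side, m, "computed")
}
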