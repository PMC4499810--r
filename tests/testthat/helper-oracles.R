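## Independent brute-force oracles used to cross-check the package
## implementations.  Written deliberately from first principles (plain
## enumeration, no shared code paths with the package internals) and also
## sourced by scripts/acceptance.R.

## ---- Smith-Waterman: exhaustive enumeration of local alignments -------
## A local alignment with affine gaps is determined by its set of matched
## position pairs (i1<i2<..., j1<j2<...); every internal unmatched stretch
## of length L in either sequence costs open + ext*L.  Leading/trailing
## overhangs are free (local alignment).
oracle_sw <- function(s1, s2, submat, open = 10, ext = 0.5) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  if (!n || !m) return(0)
  gap <- function(len) if (len <= 0) 0 else open + ext * len
  best <- 0
  rec <- function(last_i, last_j, score) {
    best <<- max(best, score)
    if (last_i >= n || last_j >= m) return(invisible())
    for (i in (last_i + 1):n) for (j in (last_j + 1):m) {
      pen <- if (last_i > 0) gap(i - last_i - 1) + gap(j - last_j - 1) else 0
      rec(i, j, score + submat[a[i], b[j]] - pen)
    }
    invisible()
  }
  rec(0L, 0L, 0)
  best
}

## ---- shortest-path machinery by exhaustive simple-path enumeration ----
## Distances and shortest-path counts derived from a DFS over all simple
## paths (independent of the BFS/igraph routes used by the package).
oracle_paths <- function(net) {
  adj <- list()
  v <- vertexTable(net)
  for (id in v$id) adj[[id]] <- character()
  e <- iinEdges(net)
  for (k in seq_len(nrow(e))) {
    adj[[e$domain[k]]] <- c(adj[[e$domain[k]]], e$ligand[k])
    adj[[e$ligand[k]]] <- c(adj[[e$ligand[k]]], e$domain[k])
  }
  ids <- v$id
  n <- length(ids)
  paths <- list()  # paths[[s]][[t]] = list of shortest paths (vertex seqs)
  for (s in ids) {
    found <- list()
    dfs <- function(path) {
      tail <- path[length(path)]
      if (length(path) > 1L) {
        cur <- found[[tail]]
        if (is.null(cur) || length(cur[[1]]) > length(path))
          found[[tail]] <<- list(path)
        else if (length(cur[[1]]) == length(path))
          found[[tail]] <<- c(cur, list(path))
      }
      for (w in adj[[tail]]) if (!w %in% path) dfs(c(path, w))
    }
    dfs(s)
    paths[[s]] <- found
  }
  list(ids = ids, adj = adj, paths = paths)
}

oracle_topo <- function(net, feature) {
  pp <- oracle_paths(net)
  ids <- pp$ids
  deg <- vapply(ids, function(v) length(pp$adj[[v]]), numeric(1))
  dist_to <- function(s) {
    d <- vapply(ids, function(t)
      if (t == s) 0
      else if (is.null(pp$paths[[s]][[t]])) Inf
      else length(pp$paths[[s]][[t]][[1]]) - 1, numeric(1))
    names(d) <- ids
    d
  }
  D <- t(vapply(ids, dist_to, numeric(length(ids))))
  rownames(D) <- ids
  reach <- function(s) ids[ids != s & is.finite(D[s, ])]
  out <- switch(feature,
    degree = deg,
    avg_shortest_path = vapply(ids, function(s) {
      r <- reach(s); if (!length(r)) 0 else mean(D[s, r]) }, numeric(1)),
    closeness = vapply(ids, function(s) {
      r <- reach(s); if (!length(r)) 0 else 1 / mean(D[s, r]) }, numeric(1)),
    eccentricity = vapply(ids, function(s) {
      r <- reach(s); if (!length(r)) 0 else max(D[s, r]) }, numeric(1)),
    radiality = vapply(ids, function(s) {
      r <- reach(s)
      if (!length(r)) return(0)
      comp <- c(s, r)
      diam <- max(D[comp, comp][is.finite(D[comp, comp])])
      if (diam == 0) 0 else (diam + 1 - mean(D[s, r])) / diam
    }, numeric(1)),
    betweenness = vapply(ids, function(v) {
      tot <- 0
      for (si in seq_along(ids)) for (ti in seq_along(ids)) {
        if (ti <= si) next
        s <- ids[si]; t <- ids[ti]
        if (s == v || t == v) next
        ps <- pp$paths[[s]][[t]]
        if (is.null(ps)) next
        thru <- sum(vapply(ps, function(p) v %in% p[-c(1, length(p))], TRUE))
        tot <- tot + thru / length(ps)
      }
      tot
    }, numeric(1)),
    stress = vapply(ids, function(v) {
      tot <- 0
      for (si in seq_along(ids)) for (ti in seq_along(ids)) {
        if (ti <= si) next
        s <- ids[si]; t <- ids[ti]
        if (s == v || t == v) next
        ps <- pp$paths[[s]][[t]]
        if (is.null(ps)) next
        tot <- tot + sum(vapply(ps, function(p)
          v %in% p[-c(1, length(p))], TRUE))
      }
      tot
    }, numeric(1)),
    neighbourhood_connectivity = vapply(ids, function(v) {
      nb <- pp$adj[[v]]
      if (!length(nb)) 0 else mean(deg[nb]) }, numeric(1)),
    topological_coefficient = vapply(ids, function(v) {
      nb <- pp$adj[[v]]
      if (!length(nb)) return(0)
      fr <- c()
      for (w in setdiff(ids, v)) {
        sh <- length(intersect(nb, pp$adj[[w]]))
        if (sh > 0) fr <- c(fr, sh / length(nb))
      }
      if (!length(fr)) 0 else mean(fr)
    }, numeric(1)),
    stop("unknown feature"))
  names(out) <- ids
  out
}

## ---- graphlet orbit counts by combn enumeration -----------------------
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

oracle_orbit_classes <- function(A) {
  n <- nrow(A)
  cls <- seq_len(n)
  for (p in oracle_perms(n)) {
    if (identical(A[p, p], A)) {
      repeat {
        prev <- cls
        cls <- pmin(cls, cls[p])
        if (identical(prev, cls)) break
      }
    }
  }
  cls
}

oracle_orbit_counts <- function(net) {
  tab <- enumerateGraphlets(5, includeEdge = TRUE)
  adjs <- graphletAdjacencies(5)
  ## per graphlet: local class per vertex and global id per class (classes
  ## ordered by their smallest vertex label)
  ginfo <- lapply(seq_len(nrow(tab)), function(k) {
    A <- adjs[[as.character(tab$graphlet[k])]]
    cls <- oracle_orbit_classes(A)
    globals <- as.integer(strsplit(tab$orbits[k], ",")[[1]])
    stopifnot(length(globals) == length(unique(cls)))
    map <- stats::setNames(globals, sort(unique(cls)))
    list(n = nrow(A), adj = A, cls = cls, global = map)
  })
  v <- vertexTable(net)
  ids <- v$id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  e <- iinEdges(net)
  for (k in seq_len(nrow(e))) {
    A[e$domain[k], e$ligand[k]] <- 1L
    A[e$ligand[k], e$domain[k]] <- 1L
  }
  n_orb <- max(vapply(ginfo, function(g) max(g$global), 0L)) + 1L
  counts <- matrix(0L, n, n_orb, dimnames = list(ids, paste0("o", 0:(n_orb - 1L))))
  connected <- function(S) {
    seen <- S[1]; repeat {
      nxt <- unique(c(seen, S[colSums(A[seen, S, drop = FALSE]) > 0]))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == length(S)
  }
  for (k in 2:min(5L, n)) {
    for (S in utils::combn(seq_len(n), k, simplify = FALSE)) {
      if (!connected(S)) next
      As <- A[S, S, drop = FALSE]
      dimnames(As) <- NULL
      hit <- NULL
      for (g in ginfo) {
        if (g$n != k || sum(As) != sum(g$adj)) next
        for (p in oracle_perms(k)) {
          ## map subset position p[i] onto graphlet vertex i
          if (identical(As[p, p], g$adj)) { hit <- list(g = g, p = p); break }
        }
        if (!is.null(hit)) break
      }
      stopifnot(!is.null(hit))
      for (i in seq_len(k)) {
        orb <- hit$g$global[[as.character(hit$g$cls[i])]]
        vtx <- S[hit$p[i]]
        counts[vtx, orb + 1L] <- counts[vtx, orb + 1L] + 1L
      }
    }
  }
  counts
}

## ---- naive alignment simulator (full rescan each step) ----------------
oracle_greedyplus <- function(net1, net2, base, eaw) {
  v1 <- vertexTable(net1); v2 <- vertexTable(net2)
  e1 <- iinEdges(net1); e2 <- iinEdges(net2)
  nbr1 <- function(id) c(e1$ligand[e1$domain == id], e1$domain[e1$ligand == id])
  nbr2 <- function(id) c(e2$ligand[e2$domain == id], e2$domain[e2$ligand == id])
  aligned_u <- character(); aligned_v <- character()
  done <- c(domain = 0L, ligand = 0L)
  lim <- c(domain = min(sum(v1$kind == "domain"), sum(v2$kind == "domain")),
           ligand = min(sum(v1$kind == "ligand"), sum(v2$kind == "ligand")))
  rows <- list()
  while (any(done < lim)) {
    cands <- NULL
    for (side in c("domain", "ligand")) {
      if (done[[side]] >= lim[[side]]) next
      u_ids <- setdiff(v1$id[v1$kind == side], aligned_u)
      v_ids <- setdiff(v2$id[v2$kind == side], aligned_v)
      if (!length(u_ids) || !length(v_ids)) next
      grid <- expand.grid(u = u_ids, v = v_ids, stringsAsFactors = FALSE)
      grid$side <- side
      cands <- rbind(cands, grid)
    }
    if (is.null(cands) || !nrow(cands)) break
    cands$base <- mapply(function(u, v, side) base[[side]][u, v],
                         cands$u, cands$v, cands$side)
    cands$bonus <- mapply(function(u, v) {
      cnt <- 0L
      for (k in seq_along(aligned_u))
        if (aligned_u[k] %in% nbr1(u) && aligned_v[k] %in% nbr2(v))
          cnt <- cnt + 1L
      cnt
    }, cands$u, cands$v)
    if (is.infinite(eaw)) {
      key1 <- cands$bonus; key2 <- cands$base
    } else {
      key1 <- cands$base + eaw * cands$bonus; key2 <- rep(0, nrow(cands))
    }
    ord <- order(-key1, -key2, cands$side != "domain", cands$u, cands$v)
    top <- cands[ord[1], , drop = FALSE]
    aligned_u <- c(aligned_u, top$u); aligned_v <- c(aligned_v, top$v)
    done[[top$side]] <- done[[top$side]] + 1L
    rows[[length(rows) + 1L]] <- top
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- metrics oracles ---------------------------------------------------
oracle_ea <- function(trace, net1, net2) {
  p <- tracePairs(trace)
  e1 <- iinEdges(net1); e2 <- iinEdges(net2)
  partner <- stats::setNames(p$v, p$u)
  ea <- 0L
  for (i in seq_len(nrow(e1))) for (j in seq_len(nrow(e2))) {
    if (identical(unname(partner[e1$domain[i]]), e2$domain[j]) &&
        identical(unname(partner[e1$ligand[i]]), e2$ligand[j]))
      ea <- ea + 1L
  }
  ea
}

oracle_max_ovp <- function(net1, net2, orth) {
  v1 <- vertexTable(net1); v2 <- vertexTable(net2)
  allowed <- list()
  for (i in seq_len(nrow(v1))) {
    ok <- which(v2$kind == v1$kind[i] &
                  isOrthologous(orth, v1$protein[i], v2$protein))
    allowed[[i]] <- ok
  }
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (nrow(v1) - i + 1L) <= best) return(invisible())
    if (i > nrow(v1)) { best <<- max(best, count); return(invisible()) }
    rec(i + 1L, used, count)                       # leave vertex i unmatched
    for (j in setdiff(allowed[[i]], used))
      rec(i + 1L, c(used, j), count + 1L)
    invisible()
  }
  rec(1L, integer(), 0L)
  best
}
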