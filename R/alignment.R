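## The GreedyPlus aligner and its two baselines (pure greedy,
## seed-and-extend).  All aligners produce partition-respecting one-to-one
## alignments: domain vertices align only to domain vertices, ligands only
## to ligands, and alignment proceeds until the smaller side of each
## partition is exhausted.

## Validate and order the base matrices; returns per-side matrices with
## lexicographically sorted dimnames (the deterministic tie-break order).
.align_prepare <- function(net1, net2, base) {
  out <- list()
  for (side in c("domain", "ligand")) {
    ids1 <- sort(net1@vertices$id[net1@vertices$kind == side])
    ids2 <- sort(net2@vertices$id[net2@vertices$kind == side])
    if (!length(ids1) || !length(ids2)) { out[[side]] <- NULL; next }
    m <- base[[side]]
    if (is.null(m))
      stop("base matrix missing for the ", side, " side")
    if (!all(ids1 %in% rownames(m)) || !all(ids2 %in% colnames(m)))
      stop("base matrix for the ", side,
           " side does not cover all cross-network pairs")
    out[[side]] <- m[ids1, ids2, drop = FALSE]
  }
  out
}

## Best active cell of a matrix under lexicographic tie-break (rows and
## columns are pre-sorted); key = primary values, tiebreak by secondary.
.best_cell <- function(primary, secondary = NULL) {
  mx <- max(primary)
  if (!is.finite(mx)) return(NULL)
  cand <- which(primary == mx, arr.ind = TRUE)
  if (!is.null(secondary) && nrow(cand) > 1L) {
    sv <- secondary[cand]
    cand <- cand[sv == max(sv), , drop = FALSE]
  }
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  list(i = cand[1, 1], j = cand[1, 2], key = mx)
}

.new_trace <- function(rows, eaw) {
  p <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(), u = character(), v = character(),
               side = character(), base_score = numeric(),
               bonus_count = integer(), eaw_bonus = numeric(),
               stringsAsFactors = FALSE)
  rownames(p) <- NULL
  methods::new("AlignmentTrace", pairs = p, eaw = eaw)
}

#' Align two IINs with the GreedyPlus algorithm
#'
#' GreedyPlus iteratively commits the unaligned same-side vertex pair with
#' the highest working score.  The working score starts from the supplied
#' base similarity; whenever a pair (u, v) is aligned, every pair (n1, n2)
#' of still-unaligned neighbours of u and v (necessarily on the other
#' partition side) has its working score incremented by the Edge Alignment
#' Weight, since aligning (n1, n2) would now align an edge in each
#' network.  Bonuses accumulate across steps, so a candidate supported by
#' several aligned edges is boosted several times.  With \code{eaw = 0}
#' the algorithm reduces to the pure greedy baseline; with
#' \code{eaw = Inf} an edge-extending candidate always beats any
#' non-extending one (implemented as a (bonus count, base score) sort, so
#' alignment still continues when no extension exists).
#'
#' @param net1,net2 the two \linkS4class{IIN}s.
#' @param base list with per-side base similarity matrices (element
#'   \code{domain}: rows = net1 domain ids, columns = net2 domain ids;
#'   likewise \code{ligand}), e.g. from \code{\link{assembleStack}}.
#' @param eaw Edge Alignment Weight, >= 0 or \code{Inf}.
#' @param minScore optional floor: stop once the best working score drops
#'   below it (finite \code{eaw} only).
#' @return an \linkS4class{AlignmentTrace}.  Ties are broken
#'   deterministically: domain side before ligand side, then
#'   lexicographically by net1 id, then net2 id.
#' @export
greedyPlusAlign <- function(net1, net2, base, eaw = 0.5, minScore = -Inf) {
  if (is.na(eaw) || eaw < 0) stop("eaw must be non-negative")
  prep <- .align_prepare(net1, net2, base)
  sides <- names(prep)[!vapply(prep, is.null, TRUE)]
  if (!length(sides)) return(.new_trace(list(), eaw))
  infinite <- is.infinite(eaw)

  ## neighbour index lists: for a row (net1 vertex) of one side's matrix,
  ## the row indices of its neighbours in the opposite side's matrix;
  ## likewise for columns (net2).  Masked (-Inf) cells absorb bonuses
  ## harmlessly, so retired pairs need no extra bookkeeping.
  nbr_rows <- function(net, side) {
    ids <- rownames(prep[[side]])
    opp <- setdiff(c("domain", "ligand"), side)
    opp_ids <- rownames(prep[[opp]])
    adj <- adjacencyList(net)
    lapply(ids, function(u) match(intersect(adj[[u]], opp_ids), opp_ids))
  }
  nbr_cols <- function(net, side) {
    ids <- colnames(prep[[side]])
    opp <- setdiff(c("domain", "ligand"), side)
    opp_ids <- colnames(prep[[opp]])
    adj <- adjacencyList(net)
    lapply(ids, function(v) match(intersect(adj[[v]], opp_ids), opp_ids))
  }
  nb1 <- nb2 <- list()
  for (side in sides) {
    opp <- setdiff(c("domain", "ligand"), side)
    if (opp %in% sides) {
      nb1[[side]] <- nbr_rows(net1, side)
      nb2[[side]] <- nbr_cols(net2, side)
    }
  }

  ## per-side state as plain local matrices, stored TRANSPOSED
  ## (rows = net2 ids, columns = net1 ids): which.max's column-major
  ## first hit then realizes the (net1 id, net2 id) lexicographic
  ## tie-break without any allocation, which is the hot path
  has_d <- "domain" %in% sides
  has_l <- "ligand" %in% sides
  Wd <- if (has_d) t(prep$domain) else NULL
  Wl <- if (has_l) t(prep$ligand) else NULL
  Bd <- if (has_d) Wd * 0 else NULL
  Bl <- if (has_l) Wl * 0 else NULL
  D0 <- list(domain = Wd, ligand = Wl)
  rem_d <- if (has_d) min(dim(Wd)) else 0L
  rem_l <- if (has_l) min(dim(Wl)) else 0L
  total <- rem_d + rem_l
  out_step <- integer(total); out_u <- character(total)
  out_v <- character(total); out_side <- character(total)
  out_base <- numeric(total); out_bonus <- integer(total)
  step <- 0L

  ## returns i = row in the transposed matrix (net2), j = column (net1)
  scan <- function(m, base_m, bonus_m) {
    nr <- nrow(m)
    if (!infinite) {
      li <- which.max(m)
      mx <- m[li]
      if (!is.finite(mx)) return(NULL)
      i <- (li - 1L) %% nr + 1L
      j <- (li - 1L) %/% nr + 1L
      return(list(i = i, j = j, key = mx,
                  base = base_m[li], bonus = bonus_m[li]))
    }
    mx <- max(m)
    if (!is.finite(mx)) return(NULL)
    lin <- which(m == mx)
    if (length(lin) > 1L) {
      sb <- base_m[lin]
      lin <- lin[sb == max(sb)]
    }
    li <- lin[1]   # smallest linear index = (net1 id, net2 id) order
    list(i = (li - 1L) %% nr + 1L, j = (li - 1L) %/% nr + 1L, key = mx,
         base = base_m[li], bonus = bonus_m[li])
  }

  while (rem_d > 0L || rem_l > 0L) {
    cd <- if (rem_d > 0L) scan(if (infinite) Bd else Wd, D0$domain, Bd)
    cl <- if (rem_l > 0L) scan(if (infinite) Bl else Wl, D0$ligand, Bl)
    use_d <- if (is.null(cd)) FALSE
             else if (is.null(cl)) TRUE
             else if (infinite) {
               cd$bonus > cl$bonus ||
                 (cd$bonus == cl$bonus && cd$base >= cl$base)
             } else cd$key >= cl$key   # tie: domain side first
    pick <- if (use_d) cd else cl
    if (is.null(pick)) break
    if (!infinite && pick$key < minScore) break
    side <- if (use_d) "domain" else "ligand"

    step <- step + 1L
    out_step[step] <- step
    out_side[step] <- side
    out_base[step] <- pick$base
    out_bonus[step] <- as.integer(pick$bonus)
    ## transposed state: pick$i indexes net2 (rows), pick$j net1 (columns)
    if (use_d) {
      out_u[step] <- colnames(Wd)[pick$j]
      out_v[step] <- rownames(Wd)[pick$i]
      Wd[pick$i, ] <- -Inf; Wd[, pick$j] <- -Inf
      Bd[pick$i, ] <- -Inf; Bd[, pick$j] <- -Inf
      rem_d <- rem_d - 1L
      if (has_l) {
        n1 <- nb1$domain[[pick$j]]; n2 <- nb2$domain[[pick$i]]
        if (length(n1) && length(n2)) {
          if (!infinite) Wl[n2, n1] <- Wl[n2, n1] + eaw
          Bl[n2, n1] <- Bl[n2, n1] + 1
        }
      }
    } else {
      out_u[step] <- colnames(Wl)[pick$j]
      out_v[step] <- rownames(Wl)[pick$i]
      Wl[pick$i, ] <- -Inf; Wl[, pick$j] <- -Inf
      Bl[pick$i, ] <- -Inf; Bl[, pick$j] <- -Inf
      rem_l <- rem_l - 1L
      if (has_d) {
        n1 <- nb1$ligand[[pick$j]]; n2 <- nb2$ligand[[pick$i]]
        if (length(n1) && length(n2)) {
          if (!infinite) Wd[n2, n1] <- Wd[n2, n1] + eaw
          Bd[n2, n1] <- Bd[n2, n1] + 1
        }
      }
    }
  }
  keep <- seq_len(step)
  p <- data.frame(step = out_step[keep], u = out_u[keep], v = out_v[keep],
                  side = out_side[keep], base_score = out_base[keep],
                  bonus_count = out_bonus[keep],
                  eaw_bonus = ifelse(out_bonus[keep] == 0, 0,
                                     out_bonus[keep] * eaw),
                  stringsAsFactors = FALSE)
  methods::new("AlignmentTrace", pairs = p, eaw = eaw)
}

#' Pure greedy baseline aligner
#'
#' Aligns same-side vertex pairs strictly in descending order of base
#' similarity, ignoring edges entirely.  Uses the same tie-break as
#' \code{\link{greedyPlusAlign}} (which reduces to this algorithm at
#' \code{eaw = 0}).
#'
#' @inheritParams greedyPlusAlign
#' @return an \linkS4class{AlignmentTrace} (with \code{eaw = 0}).
#' @export
greedyAlign <- function(net1, net2, base) {
  prep <- .align_prepare(net1, net2, base)
  sides <- names(prep)[!vapply(prep, is.null, TRUE)]
  remaining <- vapply(prep, function(m) min(dim(m)), 0L)
  W <- prep
  rows <- list(); step <- 0L
  while (any(remaining[sides] > 0L)) {
    pick <- NULL
    for (side in sides) {
      if (remaining[[side]] == 0L) next
      cell <- .best_cell(W[[side]])
      if (is.null(cell)) next
      cell$side <- side
      if (is.null(pick) || cell$key > pick$key) pick <- cell
    }
    if (is.null(pick)) break
    side <- pick$side
    step <- step + 1L
    rows[[step]] <- data.frame(
      step = step, u = rownames(W[[side]])[pick$i],
      v = colnames(W[[side]])[pick$j], side = side,
      base_score = pick$key, bonus_count = 0L, eaw_bonus = 0,
      stringsAsFactors = FALSE)
    W[[side]][pick$i, ] <- -Inf; W[[side]][, pick$j] <- -Inf
    remaining[[side]] <- remaining[[side]] - 1L
  }
  .new_trace(rows, 0)
}

#' Seed-and-extend baseline aligner
#'
#' Seeds with the highest-scoring pair overall, then only aligns frontier
#' pairs: (u, v) such that u is adjacent to an already-aligned net1 vertex
#' whose partner is adjacent to v.  Every non-seed step therefore aligns
#' at least one edge pair.  The algorithm stops when the frontier is empty
#' (dead end) - it never restarts.
#'
#' @inheritParams greedyPlusAlign
#' @return an \linkS4class{AlignmentTrace} (with \code{eaw = 0}).
#' @export
seedExtendAlign <- function(net1, net2, base) {
  prep <- .align_prepare(net1, net2, base)
  sides <- names(prep)[!vapply(prep, is.null, TRUE)]
  if (!length(sides)) return(.new_trace(list(), 0))
  adj1 <- adjacencyList(net1)
  adj2 <- adjacencyList(net2)
  W <- prep
  Fr <- lapply(prep, function(m) matrix(FALSE, nrow(m), ncol(m),
                                        dimnames = dimnames(m)))
  remaining <- vapply(prep, function(m) min(dim(m)), 0L)
  rows <- list(); step <- 0L
  aligned1 <- aligned2 <- character()

  repeat {
    pick <- NULL
    for (side in sides) {
      if (remaining[[side]] == 0L) next
      m <- W[[side]]
      if (step > 0L) {
        m <- ifelse(Fr[[side]], m, -Inf)   # frontier only after the seed
        dimnames(m) <- dimnames(W[[side]])
      }
      cell <- .best_cell(m)
      if (is.null(cell)) next
      cell$side <- side
      if (is.null(pick) || cell$key > pick$key) pick <- cell
    }
    if (is.null(pick)) break
    side <- pick$side
    u <- rownames(W[[side]])[pick$i]
    v <- colnames(W[[side]])[pick$j]
    step <- step + 1L
    rows[[step]] <- data.frame(
      step = step, u = u, v = v, side = side, base_score = pick$key,
      bonus_count = 0L, eaw_bonus = 0, stringsAsFactors = FALSE)
    aligned1 <- c(aligned1, u); aligned2 <- c(aligned2, v)
    W[[side]][pick$i, ] <- -Inf; W[[side]][, pick$j] <- -Inf
    remaining[[side]] <- remaining[[side]] - 1L
    opp <- setdiff(c("domain", "ligand"), side)
    if (opp %in% sides) {
      n1 <- intersect(setdiff(adj1[[u]], aligned1), rownames(W[[opp]]))
      n2 <- intersect(setdiff(adj2[[v]], aligned2), colnames(W[[opp]]))
      if (length(n1) && length(n2)) Fr[[opp]][n1, n2] <- TRUE
    }
  }
  .new_trace(rows, 0)
}

#' Audit the edge-extension behaviour of an alignment trace
#'
#' Replays a trace and reports, for every step, whether the selected pair
#' extended at least one aligned edge (its accumulated bonus count was
#' positive) and whether any unaligned candidate pair could have done so.
#' Useful for checking the limiting \code{eaw = Inf} behaviour, where an
#' edge-extending candidate must be chosen whenever one exists.
#'
#' @param trace an \linkS4class{AlignmentTrace}.
#' @param net1,net2 the aligned networks.
#' @return data.frame with columns \code{step}, \code{selected_extending},
#'   \code{candidate_existed}.
#' @export
traceEdgeExtension <- function(trace, net1, net2) {
  p <- trace@pairs
  adj1 <- adjacencyList(net1)
  adj2 <- adjacencyList(net2)
  out <- data.frame(step = p$step, selected_extending = FALSE,
                    candidate_existed = FALSE)
  if (!nrow(p)) return(out)
  for (t in seq_len(nrow(p))) {
    before <- p[seq_len(t - 1L), , drop = FALSE]
    a1 <- before$u; a2 <- before$v
    ## bonus count of the selected pair, recomputed independently
    nb <- 0L
    for (k in seq_len(nrow(before)))
      if (before$u[k] %in% adj1[[p$u[t]]] && before$v[k] %in% adj2[[p$v[t]]])
        nb <- nb + 1L
    out$selected_extending[t] <- nb > 0L
    ## does any unaligned candidate extend an edge?
    exists <- FALSE
    for (k in seq_len(nrow(before))) {
      n1 <- setdiff(adj1[[before$u[k]]], a1)
      n2 <- setdiff(adj2[[before$v[k]]], a2)
      if (length(n1) && length(n2)) { exists <- TRUE; break }
    }
    out$candidate_existed[t] <- exists
  }
  out
}
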