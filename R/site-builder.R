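## Ligand-vertex construction: merge predicted 15-mer binding peptides on
## one protein into interface vertices spanning at most 30 amino acids.

#' Merge overlapping predicted binding sites into interface vertices
#'
#' Non-overlapping sites each become their own vertex.  A run of mutually
#' overlapping sites is merged into a single vertex while its span stays
#' within \code{maxLen}; longer runs are split into several vertices by an
#' exhaustive search over all contiguous partitions of the run, choosing
#' the cut that minimizes total pairwise residue overlap between the
#' resulting vertices (ties: fewest vertices, then leftmost cut).  Every
#' input site ends up wholly contained in exactly one output vertex.
#'
#' @param sites data.frame with columns \code{protein}, \code{start},
#'   \code{end} (1-based inclusive), all rows for the same protein.
#' @param maxLen maximum vertex span in amino acids (default 30).
#' @param kind vertex kind for the output interfaces (default "ligand").
#' @return data.frame of interface vertices: \code{id}, \code{protein},
#'   \code{kind}, \code{start}, \code{end}, plus a \code{members} list
#'   column with the row indices of the input sites each vertex contains.
#' @export
mergeSites <- function(sites, maxLen = 30L, kind = "ligand") {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!nrow(sites))
    return(data.frame(id = character(), protein = character(),
                      kind = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  if (length(unique(sites$protein)) != 1L)
    stop("mergeSites expects sites of a single protein")
  if (any(sites$end - sites$start + 1L > maxLen))
    stop("maxLen must be at least the site window length")
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)
  ord <- order(sites$start, sites$end)
  s <- sites[ord, , drop = FALSE]
  orig <- seq_len(nrow(sites))[ord]

  ## runs of transitively overlapping sites
  run_id <- integer(nrow(s))
  run_id[1] <- 1L
  run_max_end <- s$end[1]
  for (i in seq_len(nrow(s))[-1]) {
    if (s$start[i] <= run_max_end) {
      run_id[i] <- run_id[i - 1L]
      run_max_end <- max(run_max_end, s$end[i])
    } else {
      run_id[i] <- run_id[i - 1L] + 1L
      run_max_end <- s$end[i]
    }
  }

  out <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    groups <- .split_run(s$start[idx], s$end[idx], maxLen)
    for (g in groups) {
      out[[length(out) + 1L]] <- data.frame(
        protein = s$protein[idx[1]],
        start = min(s$start[idx[g]]), end = max(s$end[idx[g]]),
        members = I(list(orig[idx[g]])), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$kind <- kind
  out$id <- makeInterfaceId(out$protein, out$start, out$end)
  out[, c("id", "protein", "kind", "start", "end", "members")]
}

## All contiguous partitions of a sorted overlap run into groups whose
## spans stay within maxLen; returns the index groups of the best cut.
.split_run <- function(starts, ends, maxLen) {
  n <- length(starts)
  span_ok <- function(i, j) max(ends[i:j]) - starts[i] + 1L <= maxLen
  if (span_ok(1L, n)) return(list(seq_len(n)))

  best <- NULL
  best_key <- c(Inf, Inf)  # (total pairwise overlap, number of vertices)
  ## enumerate cut masks over the n-1 gaps (runs are short in practice)
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0L)
    bounds <- c(0L, cuts, n)
    ok <- TRUE
    groups <- vector("list", length(bounds) - 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      i <- bounds[k] + 1L; j <- bounds[k + 1L]
      if (!span_ok(i, j)) { ok <- FALSE; break }
      groups[[k]] <- i:j
    }
    if (!ok) next
    spans <- t(vapply(groups, function(g)
      c(starts[g[1]], max(ends[g])), numeric(2)))
    ov <- 0L
    if (nrow(spans) > 1L)
      for (a in 1:(nrow(spans) - 1L)) for (b in (a + 1L):nrow(spans))
        ov <- ov + max(0L, min(spans[a, 2], spans[b, 2]) -
                         max(spans[a, 1], spans[b, 1]) + 1L)
    key <- c(ov, length(groups))
    ## ties beyond (overlap, count) resolved by leftmost cut: masks are
    ## scanned in increasing order, i.e. earlier cut positions first
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- groups
      best_key <- key
    }
  }
  if (is.null(best)) stop("overlap run cannot be split within maxLen")
  best
}

#' Build an IIN from domain--peptide interactions
#'
#' Predicted target peptides are merged per protein with
#' \code{\link{mergeSites}}; each interaction becomes an edge from its
#' domain to the ligand vertex containing its site, with duplicate edges
#' collapsed.
#'
#' @param interactions data.frame with columns \code{domain_id} (interface
#'   id of the domain), \code{protein}, \code{start}, \code{end} (the
#'   predicted peptide site on the target protein).
#' @param domains data.frame declaring the domain vertices (\code{id} plus
#'   optionally \code{protein}, \code{start}, \code{end}); defaults to the
#'   ids appearing in \code{interactions}.
#' @param maxLen maximum ligand-vertex span (default 30).
#' @return an \linkS4class{IIN}.
#' @export
buildIIN <- function(interactions, domains = NULL, maxLen = 30L) {
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (is.null(domains))
    domains <- data.frame(id = sort(unique(interactions$domain_id)),
                          stringsAsFactors = FALSE)
  dv <- data.frame(id = domains$id, kind = "domain", stringsAsFactors = FALSE)

  lig <- list(); edges <- list()
  for (p in unique(interactions$protein)) {
    rows <- interactions[interactions$protein == p, , drop = FALSE]
    sites <- unique(rows[, c("protein", "start", "end")])
    merged <- mergeSites(sites, maxLen = maxLen)
    ## map each interaction's site to its containing vertex
    site_key <- paste(sites$start, sites$end)
    vertex_of_site <- character(nrow(sites))
    for (k in seq_len(nrow(merged)))
      vertex_of_site[merged$members[[k]]] <- merged$id[k]
    if (any(!nzchar(vertex_of_site)))
      stop("internal error: site not covered by any merged vertex")
    hit <- match(paste(rows$start, rows$end), site_key)
    lig[[p]] <- merged[, c("id", "protein", "kind", "start", "end")]
    edges[[p]] <- data.frame(domain = rows$domain_id,
                             ligand = vertex_of_site[hit],
                             stringsAsFactors = FALSE)
  }
  lv <- do.call(rbind, lig)
  ed <- do.call(rbind, edges)
  IIN(rbind(dv, lv[, c("id", "kind")]), ed)
}
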