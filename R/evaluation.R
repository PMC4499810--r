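## Orthology-recovery metrics: represented protein orthologies (RPO),
## orthologous vertex pairs (OVP), edges aligned (EA), and their
## data-dependent maxima.

#' Score an alignment against known orthology
#'
#' An orthologous vertex pair (OVP) is an aligned interface pair whose
#' parent proteins are known orthologs; a represented protein orthology
#' (RPO) is an orthologous protein pair with at least one such aligned
#' interface pair, so RPO <= OVP always.  Edges aligned (EA) counts edge
#' pairs, one per network, whose both endpoint pairs are aligned; since
#' alignments respect the partition and edges run domain--ligand, each
#' aligned edge pair decomposes uniquely into a (domain pair, ligand pair)
#' and is counted once.  Metrics depend only on the set of aligned pairs,
#' not their order.
#'
#' @param trace an \linkS4class{AlignmentTrace}.
#' @param net1,net2 the aligned \linkS4class{IIN}s.
#' @param orth an \linkS4class{OrthologyMap}.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateAlignment <- function(trace, net1, net2, orth) {
  counts <- .metrics_counts(trace, net1, net2, orth)
  rpo <- counts[["rpo"]]; ovp <- counts[["ovp"]]; ea <- counts[["ea"]]
  mx <- metricMaxima(net1, net2, orth)
  methods::new("MetricsReport",
               rpo = as.integer(rpo), ovp = as.integer(ovp),
               ea = as.integer(ea),
               maxRpo = mx[["max_rpo"]], maxOvp = mx[["max_ovp"]],
               maxEa = mx[["max_ea"]])
}

## Raw RPO/OVP/EA counts without the (more expensive) maxima; shared by
## evaluateAlignment and the training objective.
.metrics_counts <- function(trace, net1, net2, orth) {
  p <- trace@pairs
  prot1 <- vertexProteins(net1)
  prot2 <- vertexProteins(net2)
  unknown <- c(setdiff(p$u, names(prot1)), setdiff(p$v, names(prot2)))
  if (length(unknown)) stop("unknown vertex id in trace: ", unknown[1])

  if (nrow(p)) {
    pu <- unname(prot1[p$u]); pv <- unname(prot2[p$v])
    is_orth <- isOrthologous(orth, pu, pv)
    ovp <- sum(is_orth)
    rpo <- length(unique(paste(pmin(pu, pv), pmax(pu, pv))[is_orth]))
  } else ovp <- rpo <- 0L

  ## EA: for each net1 edge with both endpoints aligned, check whether the
  ## partner pair is an edge of net2
  ea <- 0L
  e1 <- net1@edges; e2 <- net2@edges
  if (nrow(p) && nrow(e1) && nrow(e2)) {
    partner <- stats::setNames(p$v, p$u)
    e2key <- paste(e2$domain, e2$ligand, sep = "\t")
    pd <- partner[e1$domain]; pl <- partner[e1$ligand]
    ok <- !is.na(pd) & !is.na(pl)
    ea <- sum(paste(pd[ok], pl[ok], sep = "\t") %in% e2key)
  }
  c(rpo = as.integer(rpo), ovp = as.integer(ovp), ea = as.integer(ea))
}

#' Data-dependent maxima of the RPO/OVP/EA metrics
#'
#' \code{max_ea} is the smaller edge count.  \code{max_rpo} counts the
#' orthologous protein pairs that have at least one same-side vertex pair
#' available.  \code{max_ovp} is the size of a maximum one-to-one matching
#' in the bipartite graph whose edges join same-side cross-network vertex
#' pairs belonging to orthologous proteins.
#'
#' @param net1,net2 \linkS4class{IIN}s.
#' @param orth an \linkS4class{OrthologyMap}.
#' @return named integer vector: \code{max_rpo}, \code{max_ovp},
#'   \code{max_ea}.
#' @export
metricMaxima <- function(net1, net2, orth) {
  v1 <- net1@vertices; v2 <- net2@vertices
  max_ea <- min(nrow(net1@edges), nrow(net2@edges))

  op <- orth@pairs
  max_rpo <- 0L
  if (nrow(op) && nrow(v1) && nrow(v2)) {
    for (k in seq_len(nrow(op))) {
      ## the map is unordered: a protein pair is available if either
      ## orientation yields a same-side vertex pair
      hit <- FALSE
      for (pp in list(c(op$p1[k], op$p2[k]), c(op$p2[k], op$p1[k]))) {
        k1 <- v1$kind[v1$protein == pp[1]]
        k2 <- v2$kind[v2$protein == pp[2]]
        if (length(intersect(k1, k2))) { hit <- TRUE; break }
      }
      if (hit) max_rpo <- max_rpo + 1L
    }
    ## maximum matching over orthologous same-side vertex pairs
    orth_ok <- isOrthologous(orth,
                             rep(v1$protein, times = nrow(v2)),
                             rep(v2$protein, each = nrow(v1)))
    same_side <- rep(v1$kind, times = nrow(v2)) == rep(v2$kind, each = nrow(v1))
    sel <- which(orth_ok & same_side)
    if (length(sel)) {
      i <- (sel - 1L) %% nrow(v1) + 1L
      j <- (sel - 1L) %/% nrow(v1) + 1L
      g <- igraph::make_empty_graph(nrow(v1) + nrow(v2), directed = FALSE)
      igraph::V(g)$type <- rep(c(FALSE, TRUE), c(nrow(v1), nrow(v2)))
      g <- igraph::add_edges(g, rbind(i, nrow(v1) + j))
      max_ovp <- igraph::max_bipartite_match(g)$matching_size
    } else max_ovp <- 0L
  } else max_ovp <- 0L

  c(max_rpo = as.integer(max_rpo), max_ovp = as.integer(max_ovp),
    max_ea = as.integer(max_ea))
}

#' Write a metrics report as TSV
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path output file.
#' @export
writeMetricsReport <- function(report, path) {
  v <- metricsVector(report)
  pct <- function(x, m) if (m > 0) sprintf("%.1f", 100 * x / m) else "NA"
  lines <- c("metric\tvalue\tmaximum\tpercent",
             sprintf("rpo\t%d\t%d\t%s", v["rpo"], v["max_rpo"],
                     pct(v["rpo"], v["max_rpo"])),
             sprintf("ovp\t%d\t%d\t%s", v["ovp"], v["max_ovp"],
                     pct(v["ovp"], v["max_ovp"])),
             sprintf("ea\t%d\t%d\t%s", v["ea"], v["max_ea"],
                     pct(v["ea"], v["max_ea"])))
  writeLines(lines, path)
  invisible(NULL)
}
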