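## Programmatic fixtures shared across tests (and by scripts/acceptance.R).

## Random bipartite IIN with one protein per vertex.
rand_iin <- function(nd, nl, p = 0.4, prefix = "X") {
  dom <- sprintf("%sD%02d,1,20", prefix, seq_len(nd))
  lig <- sprintf("%sL%02d,1,15", prefix, seq_len(nl))
  v <- data.frame(id = c(dom, lig),
                  kind = rep(c("domain", "ligand"), c(nd, nl)),
                  stringsAsFactors = FALSE)
  grid <- expand.grid(domain = dom, ligand = lig, stringsAsFactors = FALSE)
  e <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  IIN(v, e)
}

## Random base similarity matrices over the side pair universes; scores on
## a 0.01 grid so working-score comparisons are reproducible.
rand_base <- function(net1, net2, grid = 100) {
  out <- list()
  for (side in c("domain", "ligand")) {
    ids1 <- sort(vertexTable(net1)$id[vertexTable(net1)$kind == side])
    ids2 <- sort(vertexTable(net2)$id[vertexTable(net2)$kind == side])
    if (!length(ids1) || !length(ids2)) next
    out[[side]] <- matrix(
      round(stats::runif(length(ids1) * length(ids2)), 2),
      length(ids1), length(ids2), dimnames = list(ids1, ids2))
  }
  out
}

## Random orthology over the proteins of two networks.
rand_orth <- function(net1, net2, frac = 0.3) {
  p1 <- unique(vertexTable(net1)$protein)
  p2 <- unique(vertexTable(net2)$protein)
  n <- round(frac * min(length(p1), length(p2)))
  if (n == 0) return(OrthologyMap())
  OrthologyMap(sample(p1, n), sample(p2, n))
}

## Small named IIN from compact edge strings like "D1-L2".
mk_iin <- function(domains, ligands, edges = character()) {
  v <- data.frame(
    id = c(sprintf("%s,1,20", domains), sprintf("%s,1,15", ligands)),
    kind = rep(c("domain", "ligand"), c(length(domains), length(ligands))),
    stringsAsFactors = FALSE)
  if (length(edges)) {
    parts <- strsplit(edges, "-", fixed = TRUE)
    e <- data.frame(domain = sprintf("%s,1,20", vapply(parts, `[`, "", 1)),
                    ligand = sprintf("%s,1,15", vapply(parts, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  } else e <- NULL
  IIN(v, e)
}
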