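## Core IIN data model: constructors, accessors, identifier conventions.

#' Compose an interface identifier
#'
#' Interface vertices are named \code{"PROTEIN,start,end"} with 1-based
#' inclusive amino-acid coordinates.  Protein names may not contain commas.
#'
#' @param protein protein name(s).
#' @param start,end 1-based inclusive coordinates.
#' @return character vector of ids.
#' @export
makeInterfaceId <- function(protein, start, end) {
  if (any(grepl(",", protein, fixed = TRUE)))
    stop("protein names must not contain commas")
  sprintf("%s,%d,%d", protein, as.integer(start), as.integer(end))
}

#' Parse interface identifiers
#'
#' @param id character vector of \code{"PROTEIN,start,end"} ids.
#' @return data.frame with columns \code{protein}, \code{start}, \code{end}.
#' @export
parseInterfaceId <- function(id) {
  parts <- strsplit(id, ",", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed interface id (expected PROTEIN,start,end): ", id[bad][1])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinates in interface id: ",
         id[which(is.na(start) | is.na(end))[1]])
  data.frame(protein = m[, 1], start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Construct a validated IIN
#'
#' @param vertices data.frame with columns \code{id}, \code{kind} and
#'   optionally \code{protein}, \code{start}, \code{end} (parsed from
#'   \code{id} when absent) and \code{sequence}.
#' @param edges data.frame with columns \code{domain}, \code{ligand}
#'   (vertex ids), or NULL for an edgeless network.
#' @return an \linkS4class{IIN}.
#' @export
IIN <- function(vertices, edges = NULL) {
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(domain = character(), ligand = character(),
                        stringsAsFactors = FALSE)
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(vertices) && !all(c("protein", "start", "end") %in% names(vertices))) {
    parsed <- parseInterfaceId(vertices$id)
    vertices$protein <- parsed$protein
    vertices$start <- parsed$start
    vertices$end <- parsed$end
  }
  if (!"sequence" %in% names(vertices))
    vertices$sequence <- rep(NA_character_, nrow(vertices))
  if (!nrow(vertices))
    vertices <- data.frame(id = character(), protein = character(),
                           kind = character(), start = integer(),
                           end = integer(), sequence = character(),
                           stringsAsFactors = FALSE)
  vertices <- vertices[, c("id", "protein", "kind", "start", "end", "sequence")]
  vertices$start <- as.integer(vertices$start)
  vertices$end <- as.integer(vertices$end)
  vertices <- vertices[order(vertices$id), , drop = FALSE]
  rownames(vertices) <- NULL
  edges <- edges[, c("domain", "ligand")]
  edges <- unique(edges)
  edges <- edges[order(edges$domain, edges$ligand), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("IIN", vertices = vertices, edges = edges)
}

#' @describeIn IIN vertex metadata table.
#' @param x an IIN.
#' @export
vertexTable <- function(x) x@vertices

#' @describeIn IIN ids of the domain-side vertices.
#' @export
domainVertices <- function(x) x@vertices$id[x@vertices$kind == "domain"]

#' @describeIn IIN ids of the ligand-side vertices.
#' @export
ligandVertices <- function(x) x@vertices$id[x@vertices$kind == "ligand"]

#' @describeIn IIN edge table (columns \code{domain}, \code{ligand}).
#' @export
iinEdges <- function(x) x@edges

#' @describeIn IIN named vector mapping vertex id to protein.
#' @export
vertexProteins <- function(x) stats::setNames(x@vertices$protein, x@vertices$id)

#' @describeIn IIN named vector mapping vertex id to side.
#' @export
vertexKinds <- function(x) stats::setNames(x@vertices$kind, x@vertices$id)

#' Adjacency list of an IIN
#'
#' @param x an IIN.
#' @return named list: for every vertex id, the character vector of its
#'   neighbours (ligands of a domain, domains of a ligand).
#' @export
adjacencyList <- function(x) {
  ids <- x@vertices$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character()
  e <- x@edges
  if (nrow(e)) {
    byd <- split(e$ligand, e$domain)
    byl <- split(e$domain, e$ligand)
    adj[names(byd)] <- lapply(byd, sort)
    adj[names(byl)] <- lapply(byl, sort)
  }
  adj
}

#' Convert an IIN to an igraph graph
#'
#' Vertices carry \code{kind}, \code{protein} and a logical \code{type}
#' attribute (TRUE for ligands) so igraph's bipartite tooling applies.
#'
#' @param x an IIN.
#' @return an igraph object.
#' @export
asIgraph <- function(x) {
  v <- x@vertices
  g <- igraph::make_empty_graph(n = nrow(v), directed = FALSE)
  igraph::V(g)$name <- v$id
  igraph::V(g)$kind <- v$kind
  igraph::V(g)$protein <- v$protein
  igraph::V(g)$type <- v$kind == "ligand"
  if (nrow(x@edges))
    g <- igraph::add_edges(g, rbind(x@edges$domain, x@edges$ligand))
  g
}

#' Construct an orthology map
#'
#' @param p1,p2 character vectors of protein names (one species per
#'   column); pairs are unordered and deduplicated.
#' @return an \linkS4class{OrthologyMap}.
#' @export
OrthologyMap <- function(p1 = character(), p2 = character()) {
  p <- data.frame(p1 = as.character(p1), p2 = as.character(p2),
                  stringsAsFactors = FALSE)
  p <- p[!duplicated(paste(pmin(p$p1, p$p2), pmax(p$p1, p$p2), sep = "\t")), ,
         drop = FALSE]
  p <- p[order(p$p1, p$p2), , drop = FALSE]
  rownames(p) <- NULL
  methods::new("OrthologyMap", pairs = p)
}

#' @describeIn OrthologyMap pair table.
#' @param x an OrthologyMap.
#' @export
orthologyPairs <- function(x) x@pairs

#' Membership test for unordered protein pairs
#'
#' @param orth an \linkS4class{OrthologyMap}.
#' @param p1,p2 protein name vectors (recycled).
#' @return logical vector.
#' @export
isOrthologous <- function(orth, p1, p2) {
  key <- paste(pmin(p1, p2), pmax(p1, p2), sep = "\t")
  have <- paste(pmin(orth@pairs$p1, orth@pairs$p2),
                pmax(orth@pairs$p1, orth@pairs$p2), sep = "\t")
  key %in% have
}

#' Construct a weight vector
#'
#' @param weights named numeric vector of feature weights in [0,1].
#' @param eaw Edge Alignment Weight, >= 0 (\code{Inf} allowed).
#' @return a \linkS4class{WeightVector}.
#' @export
WeightVector <- function(weights = numeric(), eaw = 0.5) {
  methods::new("WeightVector", weights = weights, eaw = as.numeric(eaw))
}

#' Construct a feature matrix
#'
#' @param name feature name.
#' @param side "domain" or "ligand".
#' @param scores numeric matrix in [0,1] with vertex-id dimnames (rows:
#'   network 1, columns: network 2).
#' @param provenance "computed" or "imported".
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(name, side, scores, provenance = "computed") {
  methods::new("FeatureMatrix", name = name, side = side,
               scores = scores, provenance = provenance)
}

#' @describeIn FeatureMatrix the score matrix.
#' @param x a FeatureMatrix.
#' @export
featureScores <- function(x) x@scores

#' @describeIn FeatureMatrix feature name.
#' @export
featureName <- function(x) x@name

#' @describeIn FeatureMatrix partition side.
#' @export
featureSide <- function(x) x@side

#' Construct a feature stack
#'
#' @param features list of \linkS4class{FeatureMatrix} objects.
#' @param weights a \linkS4class{WeightVector} covering their names.
#' @return a \linkS4class{FeatureStack}.
#' @export
FeatureStack <- function(features, weights) {
  methods::new("FeatureStack", features = features, weights = weights)
}

#' @describeIn AlignmentTrace the per-step pair table.
#' @param x an AlignmentTrace.
#' @export
tracePairs <- function(x) x@pairs

#' @describeIn MetricsReport metrics as a named numeric vector.
#' @param x a MetricsReport.
#' @export
metricsVector <- function(x) {
  c(rpo = x@rpo, ovp = x@ovp, ea = x@ea,
    max_rpo = x@maxRpo, max_ovp = x@maxOvp, max_ea = x@maxEa)
}
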