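#' @import methods
NULL

#' Bipartite interface-interaction network
#'
#' An IIN is an undirected bipartite graph whose vertices are individual
#' binding sites ("interfaces") on proteins.  One partition holds
#' peptide-recognition domains (e.g. SH3 domains), the other their short
#' peptide ligand sites; every edge joins a domain interface to a ligand
#' interface.  Vertex identifiers follow the convention
#' \code{"PROTEIN,start,end"} with 1-based inclusive amino-acid coordinates,
#' which implies protein names themselves may not contain commas.
#'
#' @slot vertices data.frame with columns \code{id}, \code{protein},
#'   \code{kind} ("domain" or "ligand"), \code{start}, \code{end},
#'   \code{sequence} (NA when unknown).
#' @slot edges data.frame with columns \code{domain}, \code{ligand} holding
#'   vertex ids.
#' @aliases IIN
#' @export
setClass("IIN", slots = c(vertices = "data.frame", edges = "data.frame"))

#' One-to-one alignment between two IINs with per-step provenance
#'
#' Rows are recorded in the order the aligner committed them.  For each
#' aligned pair the base (similarity-only) score at the moment of selection
#' and the accumulated Edge Alignment Weight bonus are kept, so alignments
#' can be audited step by step.
#'
#' @slot pairs data.frame with columns \code{step}, \code{u} (id in network
#'   1), \code{v} (id in network 2), \code{side}, \code{base_score},
#'   \code{bonus_count}, \code{eaw_bonus}.
#' @slot eaw the Edge Alignment Weight under which the trace was produced
#'   (may be \code{Inf}).
#' @export
setClass("AlignmentTrace", slots = c(pairs = "data.frame", eaw = "numeric"))

#' Known orthologous protein pairs between two species
#'
#' @slot pairs data.frame with columns \code{p1} (protein in species 1),
#'   \code{p2} (protein in species 2); pairs are treated as unordered and
#'   deduplicated.
#' @export
setClass("OrthologyMap", slots = c(pairs = "data.frame"))

#' Normalized pairwise vertex-similarity matrix for one network side
#'
#' Scores live in [0,1] over the full cross-network pair universe of one
#' partition side (domain--domain or ligand--ligand); pairs without data are
#' explicit zeros.
#'
#' @slot name feature name.
#' @slot side "domain" or "ligand".
#' @slot scores numeric matrix, rows = network-1 vertex ids, columns =
#'   network-2 vertex ids.
#' @slot provenance "computed" or "imported".
#' @export
setClass("FeatureMatrix",
         slots = c(name = "character", side = "character",
                   scores = "matrix", provenance = "character"))

#' Feature weights plus the Edge Alignment Weight
#'
#' @slot weights named numeric vector of per-feature weights in [0,1].
#' @slot eaw non-negative Edge Alignment Weight; \code{Inf} selects the
#'   limiting always-extend-edges behaviour.
#' @export
setClass("WeightVector", slots = c(weights = "numeric", eaw = "numeric"))

#' Named collection of feature matrices plus a weight vector
#'
#' @slot features list of \linkS4class{FeatureMatrix} objects (a feature
#'   name may appear once per side).
#' @slot weights a \linkS4class{WeightVector}.
#' @export
setClass("FeatureStack", slots = c(features = "list", weights = "WeightVector"))

#' Orthology-recovery metrics for one alignment
#'
#' Counts of represented protein orthologies (RPO), orthologous vertex
#' pairs (OVP) and edges aligned (EA), next to their data-dependent maxima.
#'
#' @slot rpo,ovp,ea achieved counts.
#' @slot maxRpo,maxOvp,maxEa maxima attainable on the given inputs.
#' @export
setClass("MetricsReport",
         slots = c(rpo = "integer", ovp = "integer", ea = "integer",
                   maxRpo = "integer", maxOvp = "integer", maxEa = "integer"))

#' Scenario for the duplication-and-divergence IIN simulator
#'
#' @slot nDomains,nLigands ancestor partition sizes.
#' @slot meanLigandDegree expected edges per ligand, in [1,2].
#' @slot rewireProb per-edge probability of resampling the ligand endpoint
#'   in each descendant.
#' @slot vertexLossProb per-vertex deletion probability in each descendant.
#' @slot featureInformativeness mean similarity of planted pairs under the
#'   informative feature (non-planted pairs centre on its complement).
#' @slot featureNoise standard deviation of informative-feature scores.
#' @slot nNoiseFeatures number of uninformative U[0,1] features per side.
#' @slot ligandsPerProtein how many ligand sites share one protein.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticScenario",
         slots = c(nDomains = "integer", nLigands = "integer",
                   meanLigandDegree = "numeric", rewireProb = "numeric",
                   vertexLossProb = "numeric",
                   featureInformativeness = "numeric",
                   featureNoise = "numeric", nNoiseFeatures = "integer",
                   ligandsPerProtein = "integer", seed = "integer"))

#' Outcome of a random-restart hill-climbing training run
#'
#' @slot seed,restarts run configuration.
#' @slot schedule decreasing step sizes used by the climber.
#' @slot best best \linkS4class{WeightVector} found.
#' @slot history data.frame with one row per restart: \code{restart},
#'   \code{rpo}, \code{ovp}, \code{ea} and one column per trained weight.
#' @export
setClass("TrainingRun",
         slots = c(seed = "integer", restarts = "integer",
                   schedule = "numeric", best = "WeightVector",
                   history = "data.frame"))

## ---- validity ------------------------------------------------------------

setValidity("IIN", function(object) {
  v <- object@vertices
  e <- object@edges
  need <- c("id", "protein", "kind", "start", "end", "sequence")
  if (!all(need %in% names(v)))
    return(paste("vertices must have columns:", paste(need, collapse = ", ")))
  if (!all(c("domain", "ligand") %in% names(e)))
    return("edges must have columns: domain, ligand")
  if (anyDuplicated(v$id)) return("duplicate vertex ids")
  if (!all(v$kind %in% c("domain", "ligand")))
    return("vertex kind must be 'domain' or 'ligand'")
  if (nrow(v)) {
    if (any(v$start < 1L)) return("start positions must be >= 1")
    if (any(v$end < v$start)) return("end must be >= start")
    parsed <- parseInterfaceId(v$id)
    if (!all(parsed$protein == v$protein & parsed$start == v$start &
             parsed$end == v$end))
      return("vertex ids must parse back to (protein, start, end)")
    has_seq <- !is.na(v$sequence)
    if (any(nchar(v$sequence[has_seq]) != v$end[has_seq] - v$start[has_seq] + 1L))
      return("sequence length must equal end - start + 1")
  }
  if (nrow(e)) {
    kind <- stats::setNames(v$kind, v$id)
    if (!all(e$domain %in% v$id) || !all(e$ligand %in% v$id))
      return("edge endpoint not among vertices")
    bad <- which(kind[e$domain] != "domain" | kind[e$ligand] != "ligand")
    if (length(bad))
      return(sprintf("edge %s -- %s violates bipartiteness (domain--ligand only)",
                     e$domain[bad[1]], e$ligand[bad[1]]))
    if (anyDuplicated(paste(e$domain, e$ligand, sep = "\t")))
      return("duplicate edges")
  }
  TRUE
})

setValidity("AlignmentTrace", function(object) {
  p <- object@pairs
  need <- c("step", "u", "v", "side", "base_score", "bonus_count", "eaw_bonus")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$u) || anyDuplicated(p$v))
    return("alignment must be one-to-one on each side")
  if (nrow(p) && !all(p$side %in% c("domain", "ligand")))
    return("side must be 'domain' or 'ligand'")
  if (length(object@eaw) != 1L || object@eaw < 0)
    return("eaw must be a single non-negative number")
  TRUE
})

setValidity("OrthologyMap", function(object) {
  p <- object@pairs
  if (!all(c("p1", "p2") %in% names(p)))
    return("pairs must have columns p1, p2")
  if (nrow(p) && anyDuplicated(paste(pmin(p$p1, p$p2), pmax(p$p1, p$p2))))
    return("duplicate orthology pairs")
  TRUE
})

setValidity("FeatureMatrix", function(object) {
  if (!object@side %in% c("domain", "ligand"))
    return("side must be 'domain' or 'ligand'")
  if (!object@provenance %in% c("computed", "imported"))
    return("provenance must be 'computed' or 'imported'")
  s <- object@scores
  if (length(s)) {
    if (is.null(rownames(s)) || is.null(colnames(s)))
      return("score matrix needs vertex-id dimnames")
    if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
      return("scores must be finite and in [0,1]")
  }
  TRUE
})

setValidity("WeightVector", function(object) {
  w <- object@weights
  if (length(w) && (is.null(names(w)) || any(!nzchar(names(w)))))
    return("weights must be named")
  if (length(w) && (any(!is.finite(w)) || any(w < 0) || any(w > 1)))
    return("feature weights must lie in [0,1]")
  if (length(object@eaw) != 1L || is.na(object@eaw) || object@eaw < 0)
    return("eaw must be a single non-negative number (Inf allowed)")
  TRUE
})

setValidity("MetricsReport", function(object) {
  if (object@rpo > object@ovp) return("rpo must be <= ovp")
  if (object@rpo > object@maxRpo) return("rpo exceeds its maximum")
  if (object@ovp > object@maxOvp) return("ovp exceeds its maximum")
  if (object@ea > object@maxEa) return("ea exceeds its maximum")
  if (any(c(object@rpo, object@ovp, object@ea) < 0L))
    return("counts must be non-negative")
  TRUE
})

setValidity("SyntheticScenario", function(object) {
  if (object@nDomains < 1L || object@nLigands < 1L)
    return("nDomains and nLigands must be >= 1")
  for (p in c("rewireProb", "vertexLossProb"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      return(paste(p, "must lie in [0,1]"))
  if (object@meanLigandDegree < 1 || object@meanLigandDegree > 2)
    return("meanLigandDegree must lie in [1,2] under the attachment model")
  if (object@featureInformativeness <= 0 || object@featureInformativeness > 1)
    return("featureInformativeness must lie in (0,1]")
  if (object@featureNoise < 0) return("featureNoise must be >= 0")
  if (object@nNoiseFeatures < 0L) return("nNoiseFeatures must be >= 0")
  if (object@ligandsPerProtein < 1L) return("ligandsPerProtein must be >= 1")
  TRUE
})

## ---- show methods --------------------------------------------------------

setMethod("show", "IIN", function(object) {
  v <- object@vertices
  cat(sprintf("IIN: %d domain + %d ligand vertices, %d edges\n",
              sum(v$kind == "domain"), sum(v$kind == "ligand"),
              nrow(object@edges)))
})

setMethod("show", "AlignmentTrace", function(object) {
  cat(sprintf("AlignmentTrace: %d aligned pairs (eaw = %s)\n",
              nrow(object@pairs), format(object@eaw)))
  if (nrow(object@pairs))
    print(utils::head(object@pairs, 5L), row.names = FALSE)
})

setMethod("show", "OrthologyMap", function(object) {
  cat(sprintf("OrthologyMap: %d protein pairs\n", nrow(object@pairs)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix '%s' (%s side, %s): %d x %d\n",
              object@name, object@side, object@provenance,
              nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "WeightVector", function(object) {
  cat(sprintf("WeightVector: %d feature weights, EAW = %s\n",
              length(object@weights), format(object@eaw)))
})

setMethod("show", "MetricsReport", function(object) {
  pct <- function(x, m) if (m > 0) sprintf(" (%.0f%%)", 100 * x / m) else ""
  cat(sprintf("MetricsReport: RPO %d/%d%s, OVP %d/%d%s, EA %d/%d%s\n",
              object@rpo, object@maxRpo, pct(object@rpo, object@maxRpo),
              object@ovp, object@maxOvp, pct(object@ovp, object@maxOvp),
              object@ea, object@maxEa, pct(object@ea, object@maxEa)))
})

setMethod("show", "TrainingRun", function(object) {
  cat(sprintf("TrainingRun: %d restarts (seed %d), best RPO %s\n",
              object@restarts, object@seed,
              if (nrow(object@history)) max(object@history$rpo) else "NA"))
})
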