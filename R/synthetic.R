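## Duplication-and-divergence simulator: paired bipartite IINs with
## planted vertex and protein orthology, plus feature matrices with
## controllable informativeness, so the whole toolkit is testable without
## external data.

#' Construct a simulation scenario
#'
#' @param nDomains,nLigands ancestor partition sizes.
#' @param meanLigandDegree expected edges per ligand in [1,2]: every
#'   ligand attaches to one domain preferentially (probability
#'   proportional to current degree + 1, reproducing the hub-and-spoke,
#'   multi-fan shape of real IINs) and to a second domain with
#'   probability \code{meanLigandDegree - 1}.
#' @param rewireProb per-edge probability, in each descendant, of
#'   resampling the edge's ligand endpoint (bipartiteness-preserving
#'   rewiring).
#' @param vertexLossProb per-vertex deletion probability in each
#'   descendant.
#' @param featureInformativeness mean informative-feature score of
#'   planted pairs (non-planted pairs centre on its complement).
#' @param featureNoise standard deviation of informative-feature scores
#'   before clamping to [0,1].
#' @param nNoiseFeatures number of pure-noise U[0,1] features per side.
#' @param ligandsPerProtein ligand sites grouped onto one protein.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
syntheticScenario <- function(nDomains = 20L, nLigands = 150L,
                              meanLigandDegree = 1.3, rewireProb = 0.1,
                              vertexLossProb = 0.05,
                              featureInformativeness = 0.9,
                              featureNoise = 0.05, nNoiseFeatures = 3L,
                              ligandsPerProtein = 2L, seed = 1L) {
  methods::new("SyntheticScenario",
               nDomains = as.integer(nDomains),
               nLigands = as.integer(nLigands),
               meanLigandDegree = meanLigandDegree,
               rewireProb = rewireProb, vertexLossProb = vertexLossProb,
               featureInformativeness = featureInformativeness,
               featureNoise = featureNoise,
               nNoiseFeatures = as.integer(nNoiseFeatures),
               ligandsPerProtein = as.integer(ligandsPerProtein),
               seed = as.integer(seed))
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate a pair of diverged IINs with planted orthology
#'
#' An ancestor bipartite network is drawn by preferential attachment of
#' ligands to domains.  Two descendants are derived independently: each
#' vertex is deleted with probability \code{vertexLossProb}, then each
#' surviving edge has its ligand endpoint resampled with probability
#' \code{rewireProb}.  The planted vertex map pairs the surviving
#' co-copies of each ancestor vertex; proteins (one per domain,
#' \code{ligandsPerProtein} sites per ligand protein) inherit orthology
#' from their ancestor protein when both copies retain at least one
#' vertex.  One informative similarity feature per side scores planted
#' pairs around \code{featureInformativeness} and other pairs around its
#' complement (normal noise, clamped to [0,1]); \code{nNoiseFeatures}
#' uninformative U[0,1] features per side are added.
#'
#' @param scn a \linkS4class{SyntheticScenario}.
#' @return list with elements \code{net1}, \code{net2}
#'   (\linkS4class{IIN}s), \code{orthology}
#'   (\linkS4class{OrthologyMap}), \code{planted} (data.frame
#'   \code{id1}, \code{id2} of surviving co-copies), \code{features}
#'   (a \linkS4class{FeatureStack} with equal weights and the default
#'   EAW), and \code{scenario}.
#' @export
generatePair <- function(scn) {
  methods::validObject(scn)
  set.seed(scn@seed)
  nd <- scn@nDomains; nl <- scn@nLigands

  ## ancestor: preferential attachment of ligands to domains
  deg <- rep(0L, nd)
  anc_edges <- list()
  for (l in seq_len(nl)) {
    d1 <- sample.int(nd, 1L, prob = deg + 1)
    ends <- d1
    if (nd > 1L && stats::runif(1) < scn@meanLigandDegree - 1) {
      rest <- setdiff(seq_len(nd), d1)
      d2 <- if (length(rest) == 1L) rest
            else sample(rest, 1L, prob = deg[rest] + 1)
      ends <- c(ends, d2)
    }
    deg[ends] <- deg[ends] + 1L
    anc_edges[[l]] <- cbind(domain = ends, ligand = l)
  }
  anc_edges <- do.call(rbind, anc_edges)

  ## ancestor vertex identities: proteins and coordinates
  dom_protein <- sprintf("DP%03d", seq_len(nd))
  lig_protein <- sprintf("LP%03d", (seq_len(nl) - 1L) %/% scn@ligandsPerProtein + 1L)
  lig_slot <- (seq_len(nl) - 1L) %% scn@ligandsPerProtein
  lig_start <- lig_slot * 40L + 1L

  descend <- function(species) {
    keep_d <- stats::runif(nd) >= scn@vertexLossProb
    keep_l <- stats::runif(nl) >= scn@vertexLossProb
    if (!any(keep_d) || !any(keep_l))
      stop("degenerate scenario: a partition side lost all vertices")
    e <- anc_edges[keep_d[anc_edges[, "domain"]] &
                     keep_l[anc_edges[, "ligand"]], , drop = FALSE]
    ## rewire ligand endpoints uniformly among surviving ligands; a rewire
    ## landing on an existing edge simply merges with it (edges are a set)
    surv_l <- which(keep_l)
    rw <- stats::runif(nrow(e)) < scn@rewireProb
    if (any(rw))
      e[rw, "ligand"] <- sample(surv_l, sum(rw), replace = TRUE)
    did <- makeInterfaceId(paste0(species, dom_protein), 1L, 60L)
    lid <- makeInterfaceId(paste0(species, lig_protein), lig_start,
                           lig_start + 14L)
    v <- rbind(
      data.frame(id = did[keep_d], kind = "domain", stringsAsFactors = FALSE),
      data.frame(id = lid[keep_l], kind = "ligand", stringsAsFactors = FALSE))
    ed <- unique(data.frame(domain = did[e[, "domain"]],
                            ligand = lid[e[, "ligand"]],
                            stringsAsFactors = FALSE))
    list(net = IIN(v, ed), keep_d = keep_d, keep_l = keep_l,
         dom_ids = did, lig_ids = lid)
  }
  s1 <- descend("A")
  s2 <- descend("B")

  planted <- rbind(
    data.frame(id1 = s1$dom_ids[s1$keep_d & s2$keep_d],
               id2 = s2$dom_ids[s1$keep_d & s2$keep_d],
               stringsAsFactors = FALSE),
    data.frame(id1 = s1$lig_ids[s1$keep_l & s2$keep_l],
               id2 = s2$lig_ids[s1$keep_l & s2$keep_l],
               stringsAsFactors = FALSE))

  ## protein orthology: ancestor proteins surviving (>=1 vertex) in both
  p1 <- vertexProteins(s1$net); p2 <- vertexProteins(s2$net)
  anc_of <- function(p, species) substring(p, nchar(species) + 1L)
  common <- intersect(anc_of(unique(p1), "A"), anc_of(unique(p2), "B"))
  orth <- OrthologyMap(paste0("A", common), paste0("B", common))

  ## similarity features
  planted_key <- paste(planted$id1, planted$id2, sep = "\t")
  make_feature <- function(side, name, informative) {
    ids1 <- s1$net@vertices$id[s1$net@vertices$kind == side]
    ids2 <- s2$net@vertices$id[s2$net@vertices$kind == side]
    n <- length(ids1) * length(ids2)
    m <- if (informative) {
      mu <- scn@featureInformativeness
      vals <- .clamp01(stats::rnorm(n, 1 - mu, scn@featureNoise))
      mm <- matrix(vals, length(ids1), length(ids2),
                   dimnames = list(ids1, ids2))
      key <- outer(ids1, ids2, paste, sep = "\t")
      hit <- key %in% planted_key
      mm[hit] <- .clamp01(stats::rnorm(sum(hit), mu, scn@featureNoise))
      mm
    } else matrix(stats::runif(n), length(ids1), length(ids2),
                  dimnames = list(ids1, ids2))
    FeatureMatrix(name, side, m, "computed")
  }
  feats <- list()
  for (side in c("domain", "ligand")) {
    feats[[length(feats) + 1L]] <- make_feature(side, "informative", TRUE)
    for (k in seq_len(scn@nNoiseFeatures))
      feats[[length(feats) + 1L]] <- make_feature(side, paste0("noise", k), FALSE)
  }
  fnames <- unique(vapply(feats, featureName, ""))
  wv <- WeightVector(stats::setNames(rep(1 / (length(fnames) + 1), length(fnames)),
                                     fnames),
                     eaw = 0.5)

  list(net1 = s1$net, net2 = s2$net, orthology = orth, planted = planted,
       features = FeatureStack(feats, wv), scenario = scn)
}

#' Packaged toy fixture showing the Edge Alignment Weight in action
#'
#' A pair of small one-component bipartite networks (five vertices each)
#' with hand-picked base scores.  With \code{eaw = 0}, alignment order
#' follows base scores alone and the third aligned pair is (E, 3); with
#' \code{eaw = 1}, the candidate (C, 3) is boosted twice - once by each of
#' the first two alignments, whose endpoints neighbour C and 3 - and
#' overtakes (E, 3) as the third pair.
#'
#' @return list with \code{net1}, \code{net2} (\linkS4class{IIN}s) and
#'   \code{base} (per-side score matrices ready for the aligners).
#' @export
fig10Fixture <- function() {
  v1 <- data.frame(
    id = c("C,1,20", "E,1,20", "A,1,15", "B,1,15", "F,1,15"),
    kind = c("domain", "domain", "ligand", "ligand", "ligand"),
    stringsAsFactors = FALSE)
  e1 <- data.frame(domain = c("C,1,20", "C,1,20", "C,1,20", "E,1,20"),
                   ligand = c("A,1,15", "B,1,15", "F,1,15", "F,1,15"),
                   stringsAsFactors = FALSE)
  v2 <- data.frame(
    id = c("3,1,20", "Y,1,20", "1,1,15", "2,1,15", "5,1,15"),
    kind = c("domain", "domain", "ligand", "ligand", "ligand"),
    stringsAsFactors = FALSE)
  e2 <- data.frame(domain = c("3,1,20", "3,1,20", "3,1,20", "Y,1,20"),
                   ligand = c("1,1,15", "2,1,15", "5,1,15", "5,1,15"),
                   stringsAsFactors = FALSE)
  dom <- matrix(c(2.3, 0.2,
                  4.0, 0.25),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("C,1,20", "E,1,20"),
                                c("3,1,20", "Y,1,20")))
  lig <- matrix(c(5.0, 0.10, 0.11,
                  0.12, 4.5, 0.13,
                  0.14, 0.15, 0.30),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("A,1,15", "B,1,15", "F,1,15"),
                                c("1,1,15", "2,1,15", "5,1,15")))
  list(net1 = IIN(v1, e1), net2 = IIN(v2, e2),
       base = list(domain = dom, ligand = lig))
}
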