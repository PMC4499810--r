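## File I/O: edge-list networks, vertex metadata, orthology maps,
## alignment traces, feature matrices, weight configs, interface FASTA.

.read_tsv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file (missing header): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(columns %in% header))
    stop(sprintf("%s: header must contain columns %s", path,
                 paste(columns, collapse = ", ")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                         header), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop(sprintf("%s: line %d has %d fields, expected %d", path, bad[1] + 1L,
                 lengths(parts)[bad[1]], length(header)))
  m <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  out
}

#' Read an IIN from tab-separated edge and vertex files
#'
#' The canonical format is an edge TSV with header \code{domain\tligand}
#' holding one interface id per column, plus an optional vertex-metadata
#' TSV (header \code{id\tkind\tprotein\tstart\tend\tsequence}) that also
#' declares isolated vertices and sequences.  Without metadata, vertex
#' kinds are inferred from the edge column a vertex appears in; a vertex
#' occurring in both columns is a bipartiteness violation and is rejected.
#'
#' @param path edge-list TSV.
#' @param vertexPath optional vertex-metadata TSV.
#' @param format currently only \code{"edge_tsv"}.
#' @return an \linkS4class{IIN}.
#' @export
readIIN <- function(path, vertexPath = NULL, format = c("edge_tsv")) {
  format <- match.arg(format)
  e <- .read_tsv(path, c("domain", "ligand"))
  if (!is.null(vertexPath)) {
    v <- .read_tsv(vertexPath, c("id", "kind"))
    if (!"sequence" %in% names(v)) v$sequence <- NA_character_
    v$sequence[!nzchar(v$sequence) | v$sequence == "NA"] <- NA_character_
    if (all(c("start", "end") %in% names(v))) {
      v$start <- as.integer(v$start)
      v$end <- as.integer(v$end)
    }
  } else {
    both <- intersect(e$domain, e$ligand)
    if (length(both)) {
      row <- which(e$domain == both[1] | e$ligand == both[1])[1]
      stop(sprintf(
        "bipartiteness violation: vertex '%s' appears on both sides (edge %s -- %s)",
        both[1], e$domain[row], e$ligand[row]))
    }
    ids <- c(unique(e$domain), unique(e$ligand))
    v <- data.frame(id = ids,
                    kind = rep(c("domain", "ligand"),
                               c(length(unique(e$domain)),
                                 length(unique(e$ligand)))),
                    stringsAsFactors = FALSE)
  }
  IIN(v, e)
}

#' Write an IIN to tab-separated files
#'
#' Output is deterministic (vertices and edges sorted lexicographically),
#' so identical networks produce byte-identical files.
#'
#' @param net an \linkS4class{IIN}.
#' @param path edge TSV to write.
#' @param vertexPath optional vertex-metadata TSV to write.
#' @export
writeIIN <- function(net, path, vertexPath = NULL) {
  e <- net@edges
  lines <- c("domain\tligand",
             if (nrow(e)) paste(e$domain, e$ligand, sep = "\t"))
  writeLines(lines, path)
  if (!is.null(vertexPath)) {
    v <- net@vertices
    seqs <- ifelse(is.na(v$sequence), "NA", v$sequence)
    lines <- c("id\tkind\tprotein\tstart\tend\tsequence",
               if (nrow(v)) paste(v$id, v$kind, v$protein, v$start, v$end,
                                  seqs, sep = "\t"))
    writeLines(lines, vertexPath)
  }
  invisible(NULL)
}

#' Export an IIN as GraphML (interoperability only)
#'
#' @param net an \linkS4class{IIN}.
#' @param path output file.
#' @export
writeIINGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(NULL)
}

#' Read an orthology map from a two-column TSV
#'
#' Accepts a headerless two-column file or one with header \code{p1\tp2};
#' duplicate pairs are collapsed.
#'
#' @param path input TSV.
#' @return an \linkS4class{OrthologyMap}.
#' @export
readOrthology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(strsplit(lines[1], "\t")[[1]], c("p1", "p2")))
    lines <- lines[-1]
  if (!length(lines)) return(OrthologyMap())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("%s: line %d is not a two-column protein pair", path, bad[1]))
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  OrthologyMap(m[, 1], m[, 2])
}

#' Write an orthology map
#' @param orth an \linkS4class{OrthologyMap}.
#' @param path output TSV.
#' @export
writeOrthology <- function(orth, path) {
  p <- orth@pairs
  writeLines(c("p1\tp2", if (nrow(p)) paste(p$p1, p$p2, sep = "\t")), path)
  invisible(NULL)
}

#' Write an alignment trace as TSV
#'
#' Columns: step, u, v, side, base_score, bonus_count, eaw_bonus, total.
#'
#' @param trace an \linkS4class{AlignmentTrace}.
#' @param path output TSV.
#' @export
writeTrace <- function(trace, path) {
  p <- trace@pairs
  total <- p$base_score + ifelse(is.finite(p$eaw_bonus), p$eaw_bonus, 0)
  lines <- c("step\tu\tv\tside\tbase_score\tbonus_count\teaw_bonus\ttotal",
             if (nrow(p)) paste(p$step, p$u, p$v, p$side,
                                format(p$base_score, digits = 12),
                                p$bonus_count,
                                format(p$eaw_bonus, digits = 12),
                                format(total, digits = 12), sep = "\t"))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read an alignment trace written by \code{writeTrace}
#' @param path trace TSV.
#' @param eaw the Edge Alignment Weight the trace was produced under.
#' @return an \linkS4class{AlignmentTrace}.
#' @export
readTrace <- function(path, eaw = NA_real_) {
  d <- .read_tsv(path, c("step", "u", "v", "side", "base_score",
                         "bonus_count", "eaw_bonus"))
  p <- data.frame(step = as.integer(d$step), u = d$u, v = d$v, side = d$side,
                  base_score = as.numeric(d$base_score),
                  bonus_count = as.integer(d$bonus_count),
                  eaw_bonus = as.numeric(d$eaw_bonus),
                  stringsAsFactors = FALSE)
  if (is.na(eaw))
    eaw <- if (nrow(p) && any(p$bonus_count > 0))
      p$eaw_bonus[p$bonus_count > 0][1] / p$bonus_count[p$bonus_count > 0][1]
    else 0
  methods::new("AlignmentTrace", pairs = p, eaw = eaw)
}

#' Read a pairwise score table (id1, id2, score)
#'
#' Used for imported protein-level BLAST or functional-similarity scores.
#'
#' @param path TSV with header \code{id1\tid2\tscore}.
#' @return data.frame with character ids and numeric scores.
#' @export
readScoreTable <- function(path) {
  d <- .read_tsv(path, c("id1", "id2", "score"))
  d$score <- as.numeric(d$score)
  if (anyNA(d$score)) stop(path, ": non-numeric score")
  d
}

#' Write / read a feature matrix as TSV (id1, id2, score rows)
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path output TSV.
#' @export
writeFeatureMatrix <- function(fm, path) {
  s <- fm@scores
  grid <- expand.grid(id1 = rownames(s), id2 = colnames(s),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$id1, grid$id2), ]
  lines <- c(sprintf("# feature=%s side=%s provenance=%s",
                     fm@name, fm@side, fm@provenance),
             "id1\tid2\tscore",
             paste(grid$id1, grid$id2,
                   format(s[cbind(grid$id1, grid$id2)], digits = 12),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(NULL)
}

#' @rdname writeFeatureMatrix
#' @return \code{readFeatureMatrix}: the \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  lines <- readLines(path)
  meta <- c(name = "imported", side = "domain", provenance = "imported")
  if (length(lines) && startsWith(lines[1], "#")) {
    kv <- regmatches(lines[1], gregexpr("[a-z]+=[^ ]+", lines[1]))[[1]]
    for (item in kv) {
      k <- sub("=.*", "", item)
      v <- sub(".*=", "", item)
      if (k == "feature") meta["name"] <- v
      if (k == "side") meta["side"] <- v
      if (k == "provenance") meta["provenance"] <- v
    }
    tmp <- tempfile(); on.exit(unlink(tmp))
    writeLines(lines[-1], tmp)
    d <- .read_tsv(tmp, c("id1", "id2", "score"))
  } else {
    d <- .read_tsv(path, c("id1", "id2", "score"))
  }
  r <- sort(unique(d$id1)); cc <- sort(unique(d$id2))
  s <- matrix(0, length(r), length(cc), dimnames = list(r, cc))
  s[cbind(d$id1, d$id2)] <- as.numeric(d$score)
  FeatureMatrix(unname(meta["name"]), unname(meta["side"]), s,
                unname(meta["provenance"]))
}

#' Read / write a weight configuration file
#'
#' Plain \code{key=value} lines; the reserved key \code{EAW} holds the
#' Edge Alignment Weight (\code{Inf} accepted).
#'
#' @param path config file.
#' @return \code{readWeights}: a \linkS4class{WeightVector}.
#' @export
readWeights <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(WeightVector(eaw = 0.5))
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop(path, ": malformed line: ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  if (anyNA(vals)) stop(path, ": non-numeric weight")
  eaw <- if ("EAW" %in% keys) vals[keys == "EAW"][1] else 0.5
  w <- vals[keys != "EAW"]
  names(w) <- keys[keys != "EAW"]
  WeightVector(weights = w, eaw = eaw)
}

#' @rdname readWeights
#' @param wv a \linkS4class{WeightVector} to write.
#' @export
writeWeights <- function(wv, path) {
  w <- wv@weights[order(names(wv@weights))]
  writeLines(c(paste0(names(w), "=", format(w, digits = 12)),
               paste0("EAW=", format(wv@eaw, digits = 12))), path)
  invisible(NULL)
}

#' Read interface sequences from FASTA keyed by vertex id
#'
#' @param path FASTA file whose record names are interface ids.
#' @return named character vector of amino-acid sequences.
#' @export
readInterfaceFasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Attach sequences to an IIN's vertices
#'
#' @param net an \linkS4class{IIN}.
#' @param sequences named character vector keyed by vertex id.
#' @return the updated IIN (unknown ids are ignored).
#' @export
setVertexSequences <- function(net, sequences) {
  v <- net@vertices
  hit <- match(v$id, names(sequences))
  v$sequence <- ifelse(is.na(hit), v$sequence, unname(sequences[hit]))
  IIN(v, net@edges)
}
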