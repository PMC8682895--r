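#' Read a kinase-kinase PPI edge list
#'
#' @param path delimited two-column edge list (header required; tab or
#'   comma), each row an undirected interaction between two kinases.
#' @return data.frame with columns `from`, `to`.
#' @export
readPPI <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  edges <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  if (ncol(edges) < 2L)
    stop("PPI edge list needs two columns", call. = FALSE)
  data.frame(from = as.character(edges[[1]]), to = as.character(edges[[2]]),
             stringsAsFactors = FALSE)
}

# case-fold + alias-map kinase names so family-level scores join PPI names
normalizeKinaseNames <- function(x, aliases = NULL) {
  x <- toupper(trimws(x))
  if (length(aliases)) {
    nm <- toupper(trimws(names(aliases)))
    hit <- match(x, nm)
    x[!is.na(hit)] <- toupper(trimws(aliases))[hit[!is.na(hit)]]
  }
  x
}

#' Read a kinase-name alias table
#'
#' Two-column delimited file (`alias`, `canonical`) bridging the namespace
#' of the kinase-family scores to the protein names used in a PPI extract.
#'
#' @param path alias file.
#' @return named character vector (names = aliases, values = canonical).
#' @export
readKinaseAliases <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Grow a kinase interaction network around the hits
#'
#' Builds the "ball model": the kinase hits plus their
#' protein-protein-interaction neighbours up to the given depth. Kinase
#' names are case-folded (and alias-mapped, if a table is given) before
#' joining scores to the PPI namespace. Isolated hits are retained; edges
#' touching at least one hit are classed `hit_incident`, all others
#' `other`. Node size in the rendered figure is conventionally the degree,
#' node colour the averaged Z.
#'
#' @param hits hit table from [selectHits()] (or a character vector of
#'   kinase names).
#' @param scores a [KinaseScores] (or its averaged table) supplying
#'   `meanZ` annotations; interactors without a score get NA.
#' @param ppi PPI edge list (data.frame `from`/`to`, or a file path).
#' @param depth neighbour expansion depth (default 1 = hits plus direct
#'   interactors; 0 = hits only).
#' @param aliases optional named vector (or file path) of name aliases.
#' @return a [KinaseNetwork].
#' @export
buildKinaseNetwork <- function(hits, scores = NULL, ppi = NULL, depth = 1L,
                               aliases = NULL) {
  if (is.character(aliases) && length(aliases) == 1L && file.exists(aliases))
    aliases <- readKinaseAliases(aliases)
  hitNames <- if (is.data.frame(hits)) hits$kinase else as.character(hits)
  hitNames <- unique(normalizeKinaseNames(hitNames, aliases))
  if (length(hitNames) == 0L)
    warning("empty hit list: network contains no seed nodes",
            call. = FALSE)

  if (is.character(ppi) && length(ppi) == 1L) ppi <- readPPI(ppi)
  if (is.null(ppi))
    ppi <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  ppi$from <- normalizeKinaseNames(ppi$from, aliases)
  ppi$to <- normalizeKinaseNames(ppi$to, aliases)
  ppi <- ppi[ppi$from != ppi$to, , drop = FALSE]          # no self-loops
  key <- ifelse(ppi$from < ppi$to, paste(ppi$from, ppi$to),
                paste(ppi$to, ppi$from))
  ppi <- ppi[!duplicated(key), , drop = FALSE]

  # breadth-first expansion from the hit seeds
  nodes <- hitNames
  frontier <- hitNames
  d <- 0L
  while (d < depth && length(frontier)) {
    nb <- c(ppi$to[ppi$from %in% frontier], ppi$from[ppi$to %in% frontier])
    frontier <- setdiff(unique(nb), nodes)
    nodes <- c(nodes, frontier)
    d <- d + 1L
  }
  edges <- ppi[ppi$from %in% nodes & ppi$to %in% nodes, , drop = FALSE]
  rownames(edges) <- NULL

  avg <- if (is(scores, "KinaseScores")) scores@averaged else scores
  meanZ <- rep(NA_real_, length(nodes))
  if (!is.null(avg)) {
    zn <- normalizeKinaseNames(avg$kinase, aliases)
    meanZ <- avg$meanZ[match(nodes, zn)]
  }
  nodeTab <- data.frame(kinase = nodes, meanZ = meanZ,
                        isHit = nodes %in% hitNames,
                        stringsAsFactors = FALSE)
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  nodeTab$degree <- as.integer(deg[nodeTab$kinase])
  hitInc <- nodeTab$isHit[match(edges$from, nodeTab$kinase)] |
            nodeTab$isHit[match(edges$to, nodeTab$kinase)]
  edges$class <- ifelse(hitInc, "hit_incident", "other")

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = nodeTab["kinase"])
  new("KinaseNetwork", graph = g, nodes = nodeTab, edges = edges)
}

#' Node metric table of a kinase network
#'
#' @param net a [KinaseNetwork].
#' @return data.frame `kinase`, `degree`, `isHit`, `meanZ`, ordered by
#'   decreasing degree (most-connected kinases first).
#' @export
nodeMetrics <- function(net) {
  nd <- net@nodes[, c("kinase", "degree", "isHit", "meanZ")]
  nd <- nd[order(-nd$degree, nd$kinase), ]
  rownames(nd) <- NULL
  nd
}

#' Export a kinase network
#'
#' Writes the node and edge tables as TSV plus a GraphML file for external
#' viewers.
#'
#' @param net a [KinaseNetwork].
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
writeNetwork <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("network_nodes.tsv", "network_edges.tsv",
                            "network.graphml"))
  writeTable(net@nodes, paths[1])
  writeTable(net@edges, paths[2])
  igraph::write_graph(net@graph, paths[3], format = "graphml")
  invisible(paths)
}
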