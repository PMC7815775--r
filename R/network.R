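## Protein-protein interaction network analysis of differential proteins.
##
## Per-group networks are induced subgraphs of a merged interactome
## (HPRD/IntAct/MINT/CORUM/PhosphoSitePlus-style edge lists) on the union
## of differentially regulated proteins across groups, annotated with the
## group's own fold changes. The giant connected component's size is scored
## against a permutation null (uniform node resampling), nodes carry
## degree/betweenness/closeness/clustering, and hubs are ranked by the
## multiplicative score log2FC x Degree.

#' Load and merge interactome edge lists
#'
#' Accepts headered 4-column TSV (protein_a, protein_b, source, evidence)
#' and minimal PSI-MITAB (tab-separated, interactor ids in columns 1-2 with
#' optional `db:` prefixes, source database in column 13 when present,
#' lines starting with '#' treated as header). Self-loops are dropped,
#' unordered duplicate pairs are merged with their source and evidence
#' labels unioned (';'-joined); malformed lines are logged and skipped.
#'
#' @param paths character vector of edge-list files.
#' @return data frame: protein_a, protein_b (lexicographically ordered
#'   pair), source, evidence.
#' @export
load_interactome <- function(paths) {
  parse_one <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(NULL)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    mitab <- startsWith(lines[1], "#") || length(header) >= 15L
    if ((!mitab && identical(tolower(header[1]), "protein_a")) ||
        startsWith(lines[1], "#"))
      lines <- lines[-1]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    rows <- lapply(parts, function(p) {
      if (length(p) < 2L || !nzchar(p[1]) || !nzchar(p[2])) return(NULL)
      strip <- function(x) sub("^[A-Za-z0-9_-]+:", "", x)
      if (mitab)
        c(strip(p[1]), strip(p[2]),
          if (length(p) >= 13L && nzchar(p[13])) strip(p[13]) else "unknown",
          "physical")
      else
        c(p[1], p[2],
          if (length(p) >= 3L && nzchar(p[3])) p[3] else "unknown",
          if (length(p) >= 4L && nzchar(p[4])) p[4] else "physical")
    })
    bad <- vapply(rows, is.null, TRUE)
    if (any(bad))
      message(sum(bad), " malformed line(s) skipped in ", basename(path))
    if (all(bad)) return(NULL)
    do.call(rbind, rows[!bad])
  }

  m <- do.call(rbind, lapply(paths, parse_one))
  stop_if(is.null(m) || nrow(m) == 0L, "no usable edges in input")
  a <- pmin(m[, 1], m[, 2])
  b <- pmax(m[, 1], m[, 2])
  loops <- a == b
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  stop_if(all(loops), "no usable edges after dropping self-loops")
  a <- a[!loops]; b <- b[!loops]
  src <- m[!loops, 3]; ev <- m[!loops, 4]
  key <- paste(a, b, sep = "\r")
  merge_lab <- function(x) paste(sort(unique(x)), collapse = ";")
  first <- !duplicated(key)
  out <- data.frame(protein_a = a[first], protein_b = b[first],
                    source = as.character(tapply(src, key, merge_lab)[key[first]]),
                    evidence = as.character(tapply(ev, key, merge_lab)[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

edges_to_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Build a dose group's annotated interaction network
#'
#' Induces the interactome subgraph on the union of proteins called
#' differential (up or down) in any group, then annotates each node with
#' this group's log2 fold change and modulation class. Using the union
#' list, rather than the group's own calls, is what lets a group's network
#' contain "un-regulated" nodes. Isolated nodes are dropped, so the network
#' can hold fewer proteins than the differential list.
#'
#' @param calls full differential call table ([call_differential()]
#'   `calls`, all groups).
#' @param group the group whose fold changes annotate the nodes.
#' @param interactome merged edge data frame ([load_interactome()] /
#'   [sim_interactome()] `edges`).
#' @param log2fc_cut modulation cutoff: up if log2FC > cut, down if
#'   log2FC < -cut (strict), else un-regulated. Default `log2(1.2)` printed
#'   as 0.263.
#' @return igraph graph with vertex attributes log2_fc, modulation,
#'   node_size and edge attributes source, evidence.
#' @export
build_group_network <- function(calls, group, interactome,
                                log2fc_cut = 0.263) {
  diff_union <- unique(calls$protein_id[calls$status %in% c("up", "down")])
  stop_if(length(diff_union) == 0L, "no differential proteins to map")
  keep <- interactome$protein_a %in% diff_union &
    interactome$protein_b %in% diff_union
  stop_if(!any(keep),
          "interactome contains no edge between differential proteins")
  g <- edges_to_graph(interactome[keep, ])

  gc <- calls[calls$group == group, ]
  lfc <- gc$log2_fc[match(igraph::V(g)$name, gc$protein_id)]
  lfc[is.na(lfc)] <- 0  # differential in another group, unquantified here
  igraph::V(g)$log2_fc <- lfc
  igraph::V(g)$modulation <- ifelse(lfc > log2fc_cut, "up-regulated",
                                    ifelse(lfc < -log2fc_cut,
                                           "down-regulated", "un-regulated"))
  igraph::V(g)$node_size <- node_size(lfc, igraph::degree(g))
  g
}

#' Extract the giant connected component
#'
#' Largest connected component by node count; ties are broken towards the
#' component containing the lexicographically smallest protein id.
#'
#' @param network igraph graph.
#' @return list with `subnetwork` (igraph) and `size` (node count).
#' @export
extract_gcc <- function(network) {
  stop_if(igraph::vcount(network) == 0L, "network is empty")
  comp <- igraph::components(network)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    mins <- vapply(best, function(ci)
      min(igraph::V(network)$name[comp$membership == ci]), "")
    best <- best[order(mins)][1]
  }
  sub <- igraph::induced_subgraph(network,
                                  which(comp$membership == best[1]))
  list(subnetwork = sub, size = igraph::vcount(sub))
}

## Null GCC sizes by uniform (or degree-weighted) node resampling: filter
## the interactome's edges to the sampled node set and take the largest
## component among the surviving edges (isolated sampled nodes are size-1
## components, which never win unless no edge survives).
gcc_null_sizes <- function(edge_idx, n_nodes_total, n_selected, B,
                           weights = NULL) {
  sizes <- integer(B)
  for (i in seq_len(B)) {
    sel <- sample.int(n_nodes_total, n_selected, prob = weights)
    inset <- logical(n_nodes_total)
    inset[sel] <- TRUE
    keep <- inset[edge_idx[, 1]] & inset[edge_idx[, 2]]
    if (!any(keep)) { sizes[i] <- 1L; next }
    sub <- igraph::graph_from_edgelist(
      cbind(as.character(edge_idx[keep, 1]),
            as.character(edge_idx[keep, 2])), directed = FALSE)
    sizes[i] <- max(igraph::components(sub)$csize)
  }
  sizes
}

#' Permutation significance of a giant-connected-component size
#'
#' Scores an observed GCC size against random expectation: each
#' permutation draws `n_selected` nodes without replacement from the
#' interactome's node set (uniformly by default, or weighted by degree with
#' `null = "degree"`), induces the subgraph and records its GCC size. The
#' empirical z-score is (observed - null mean) / null sd and the empirical
#' p-value uses the add-one convention
#' `(#{null >= observed} + 1) / (B + 1)`, which can never be zero.
#'
#' @param interactome merged edge data frame.
#' @param n_selected number of selected proteins (the differential list
#'   size mapped onto the interactome).
#' @param observed_gcc observed GCC node count.
#' @param n_permutations number of null draws (>= 1000).
#' @param seed RNG seed; results are reproducible bit-for-bit.
#' @param null `"uniform"` node resampling (default) or `"degree"`
#'   (degree-weighted sampling without replacement).
#' @return list: observed_gcc, null_mean, null_sd, z, empirical_p,
#'   n_permutations, seed. `z` is `NA` (with a warning) when the null sd
#'   is zero.
#' @export
gcc_significance <- function(interactome, n_selected, observed_gcc,
                             n_permutations = 10000L, seed = 1L,
                             null = c("uniform", "degree")) {
  null <- match.arg(null)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1000L)
  n_selected <- check_count(n_selected, "n_selected")
  observed_gcc <- check_count(observed_gcc, "observed_gcc", min = 0L)

  nodes <- sort(unique(c(interactome$protein_a, interactome$protein_b)))
  stop_if(n_selected > length(nodes),
          "'n_selected' exceeds the interactome's %d nodes", length(nodes))
  edge_idx <- cbind(match(interactome$protein_a, nodes),
                    match(interactome$protein_b, nodes))
  weights <- NULL
  if (null == "degree")
    weights <- tabulate(edge_idx, nbins = length(nodes))

  sizes <- with_seed(seed,
    gcc_null_sizes(edge_idx, length(nodes), n_selected, n_permutations,
                   weights))
  null_mean <- mean(sizes)
  null_sd <- stats::sd(sizes)
  z <- if (null_sd > 0) (observed_gcc - null_mean) / null_sd else {
    warning("degenerate null: sd = 0, z not defined")
    NA_real_
  }
  list(observed_gcc = observed_gcc, null_mean = null_mean,
       null_sd = null_sd, z = z,
       empirical_p = (sum(sizes >= observed_gcc) + 1) / (n_permutations + 1),
       n_permutations = n_permutations, seed = check_seed(seed))
}

#' Topological node centralities
#'
#' Degree (raw count), betweenness (unnormalised shortest-path), closeness
#' (within the node's component: (reachable - 1) / sum of distances) and
#' local clustering coefficient (triangle density; 0 for degree < 2).
#'
#' @param network igraph graph (simple, undirected).
#' @return data frame: protein_id, dc, bc, cc, clustering.
#' @export
centralities <- function(network) {
  d <- igraph::distances(network)
  cc <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    if (length(reach) <= 1L) return(0)
    (length(reach) - 1) / sum(reach)
  })
  cl <- igraph::transitivity(network, type = "local", isolates = "zero")
  ## igraph returns NaN for degree-1 nodes in some versions; define as 0
  cl[!is.finite(cl)] <- 0
  data.frame(protein_id = igraph::V(network)$name,
             dc = unname(igraph::degree(network)),
             bc = unname(igraph::betweenness(network, directed = FALSE)),
             cc = unname(cc), clustering = cl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Node size for network rendering
#'
#' `(DC + 1) * (|log2FC| + 1)`: emphasises differentially regulated
#' proteins with high connectivity. Minimum 1 for an isolated unchanged
#' protein.
#'
#' @param log2_fc log2 fold change(s).
#' @param dc degree(s), >= 0.
#' @return numeric vector.
#' @export
node_size <- function(log2_fc, dc) {
  stop_if(any(dc < 0), "'dc' must be >= 0")
  (dc + 1) * (abs(log2_fc) + 1)
}

#' Rank hub proteins by the multiplicative fold-change x degree score
#'
#' hub score = log2FC x Degree. Ranking uses the absolute score (so a
#' strongly down-regulated high-degree node can top the list) with the
#' signed score retained in the output; ties break towards higher degree,
#' then lexicographic protein id.
#'
#' @param network annotated igraph graph ([build_group_network()]).
#' @param k number of hubs to return (all, with a warning, if k exceeds
#'   the node count).
#' @return data frame: rank, protein_id, dc, bc, cc, clustering, log2_fc,
#'   modulation, hub_score, node_size.
#' @export
hub_rank <- function(network, k = 10L) {
  k <- check_count(k, "k")
  cent <- centralities(network)
  cent$log2_fc <- igraph::V(network)$log2_fc
  cent$modulation <- igraph::V(network)$modulation
  cent$hub_score <- cent$log2_fc * cent$dc
  cent$node_size <- node_size(cent$log2_fc, cent$dc)
  ord <- order(-abs(cent$hub_score), -cent$dc, cent$protein_id)
  if (k > nrow(cent)) {
    warning("k = ", k, " exceeds node count ", nrow(cent),
            "; returning all nodes")
    k <- nrow(cent)
  }
  out <- cent[ord[seq_len(k)], ]
  out <- cbind(rank = seq_len(k), out)
  rownames(out) <- NULL
  out
}

annotate_network <- function(network) {
  cent <- centralities(network)
  igraph::V(network)$dc <- cent$dc
  igraph::V(network)$bc <- cent$bc
  igraph::V(network)$cc <- cent$cc
  igraph::V(network)$clustering <- cent$clustering
  igraph::V(network)$hub_score <- igraph::V(network)$log2_fc * cent$dc
  network
}

NODE_EXPORT_ATTRS <- c("log2_fc", "modulation", "node_size", "hub_score",
                       "dc", "bc", "cc", "clustering")
EDGE_EXPORT_ATTRS <- c("source", "evidence")

#' Export an annotated network for external visualisation
#'
#' Writes GraphML or GEXF with all node attributes (log2_fc, modulation,
#' node_size, hub_score, dc, bc, cc, clustering) and edge attributes
#' (source, evidence), suitable for Gephi-style layout tools.
#' Re-importing ([import_network()]) reproduces the graph and its
#' attributes.
#'
#' @param network annotated igraph graph; missing attributes are an error
#'   naming the first absent one.
#' @param path output file.
#' @param format `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  have_v <- igraph::vertex_attr_names(network)
  miss <- setdiff(NODE_EXPORT_ATTRS, have_v)
  stop_if(length(miss) > 0, "missing node attribute: %s", miss[1])
  have_e <- igraph::edge_attr_names(network)
  miss_e <- setdiff(EDGE_EXPORT_ATTRS, have_e)
  stop_if(length(miss_e) > 0, "missing edge attribute: %s", miss_e[1])

  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    write_gexf(network, path)
  }
  invisible(path)
}

numeric_attrs <- c("log2_fc", "node_size", "hub_score", "bc", "cc",
                   "clustering", "dc")

write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  natts <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(NODE_EXPORT_ATTRS))
    xml2::xml_add_child(natts, "attribute", id = as.character(i - 1),
                        title = NODE_EXPORT_ATTRS[i],
                        type = if (NODE_EXPORT_ATTRS[i] %in% numeric_attrs)
                          "double" else "string")
  eatts <- xml2::xml_add_child(graph, "attributes", class = "edge")
  for (i in seq_along(EDGE_EXPORT_ATTRS))
    xml2::xml_add_child(eatts, "attribute",
                        id = as.character(length(NODE_EXPORT_ATTRS) + i - 1),
                        title = EDGE_EXPORT_ATTRS[i], type = "string")

  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(network)$name
  for (vi in seq_along(vnames)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[vi],
                              label = vnames[vi])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (ai in seq_along(NODE_EXPORT_ATTRS)) {
      val <- igraph::vertex_attr(network, NODE_EXPORT_ATTRS[ai], vi)
      xml2::xml_add_child(av, "attvalue", `for` = as.character(ai - 1),
                          value = format(val, digits = 15))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(network)
  for (ei in seq_len(nrow(el))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(ei - 1),
                              source = el[ei, 1], target = el[ei, 2])
    av <- xml2::xml_add_child(ed, "attvalues")
    for (ai in seq_along(EDGE_EXPORT_ATTRS)) {
      val <- igraph::edge_attr(network, EDGE_EXPORT_ATTRS[ai], ei)
      xml2::xml_add_child(av, "attvalue",
                          `for` = as.character(length(NODE_EXPORT_ATTRS) +
                                                 ai - 1),
                          value = as.character(val))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path file written by [export_network()].
#' @param format `"graphml"` or `"gexf"`.
#' @return igraph graph with the exported attributes restored.
#' @export
import_network <- function(path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1]])
  title_of <- stats::setNames(
    xml2::xml_attr(xml2::xml_find_all(doc, ".//g:attribute", ns), "title"),
    xml2::xml_attr(xml2::xml_find_all(doc, ".//g:attribute", ns), "id"))
  get_attvals <- function(node) {
    avs <- xml2::xml_find_all(node, "./g:attvalues/g:attvalue", ns)
    vals <- xml2::xml_attr(avs, "value")
    names(vals) <- title_of[xml2::xml_attr(avs, "for")]
    vals
  }
  node_els <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  vdf <- data.frame(name = xml2::xml_attr(node_els, "id"),
                    stringsAsFactors = FALSE)
  for (a in NODE_EXPORT_ATTRS) {
    raw <- vapply(node_els, function(nd) get_attvals(nd)[[a]], "")
    vdf[[a]] <- if (a %in% numeric_attrs) as.numeric(raw) else raw
  }
  edge_els <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  edf <- data.frame(from = xml2::xml_attr(edge_els, "source"),
                    to = xml2::xml_attr(edge_els, "target"),
                    stringsAsFactors = FALSE)
  for (a in EDGE_EXPORT_ATTRS)
    edf[[a]] <- vapply(edge_els, function(ed) get_attvals(ed)[[a]], "")
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}
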