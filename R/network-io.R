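#' Write a co-occurrence network to GraphML or GEXF
#'
#' Exports an igraph co-occurrence network with its node attributes
#' (module id, Zi, Pi, role, abundance where present) and edge attributes
#' (correlation `rho`, adjusted p, `sign`) for visualisation in Gephi or
#' Cytoscape.
#'
#' @param network An igraph object (see [build_co_network()]).
#' @param path Output file path.
#' @param format `"graphml"` (default, round-trippable via igraph) or
#'   `"gexf"` (write-only).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (igraph::vcount(network) == 0) {
    warn("Writing an empty network.")
  }
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    write_gexf(network, path)
  }
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return An igraph object.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(paste0("File does not exist: ", path))
  igraph::read_graph(path, format = "graphml")
}

# Minimal GEXF 1.2 writer: nodes with attvalues, undirected weighted edges.
write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")

  vattr <- igraph::vertex_attr_names(network)
  vattr <- setdiff(vattr, "name")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(vattr)) {
    xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                        title = vattr[i], type = "string")
  }

  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- if ("name" %in% igraph::vertex_attr_names(network)) {
    igraph::V(network)$name
  } else {
    as.character(seq_len(igraph::vcount(network)))
  }
  for (v in seq_len(igraph::vcount(network))) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[v], label = vnames[v])
    if (length(vattr) > 0) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattr)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = as.character(igraph::vertex_attr(network, vattr[i], v)))
      }
    }
  }

  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- if ("rho" %in% igraph::edge_attr_names(network)) {
    abs(igraph::E(network)$rho)
  } else {
    rep(1, nrow(el))
  }
  sgn <- if ("sign" %in% igraph::edge_attr_names(network)) {
    igraph::E(network)$sign
  } else {
    rep("positive", nrow(el))
  }
  for (e in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                        source = el[e, 1], target = el[e, 2],
                        weight = as.character(w[e]), label = sgn[e])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
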