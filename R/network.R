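# Reconstruction of the activated kinase-substrate network: called kinases
# as nodes, experimentally curated KSRs as directed phosphorylation edges,
# plus curated upstream kinases of the increased regulatory sites.

#' Build the activated kinase network
#'
#' Nodes are the called kinases (node class = evidence). A directed edge
#' A -> B annotated with the substrate site is added when both A and B are
#' called and a curated KSR (A phosphorylates B at site) exists. In
#' addition, for every called kinase's increased activity-regulatory site,
#' any curated upstream kinase phosphorylating exactly that site is wired
#' in: if it is not itself called it appears as an `upstream_only` node.
#' Autophosphorylation KSRs yield retained, flagged self-loops. Output is
#' deterministic (sorted) and invariant to input row order.
#'
#' @param calls Activity calls from [merge_activity()] (the `sites` column
#'   carries each kinase's increased regulatory-site labels).
#' @param curated Curated KSR table from [read_ksr_table()].
#' @return A `ksr_network`: list with `nodes` (`kinase_id`, `node_class`)
#'   and `edges` (`source`, `target`, `site`, `self_loop`).
#' @export
build_network <- function(calls, curated) {
  nodes <- data.frame(kinase_id = calls$kinase_id,
                      node_class = calls$evidence,
                      stringsAsFactors = FALSE)
  called <- calls$kinase_id
  # (i) curated edges between called kinases
  e1 <- curated[curated$kinase_id %in% called &
                  curated$substrate_protein_id %in% called, , drop = FALSE]
  edges <- data.frame(source = e1$kinase_id,
                      target = e1$substrate_protein_id,
                      site = site_label(e1$substrate_residue,
                                        e1$substrate_position),
                      stringsAsFactors = FALSE)
  # (ii) curated upstream kinases of each called kinase's increased
  # regulatory sites (site-exact match)
  for (i in seq_len(nrow(calls))) {
    sites <- calls$sites[i]
    if (is.na(sites) || !nzchar(sites)) next
    for (lab in strsplit(sites, ";")[[1]]) {
      res <- substr(lab, 1, 1)
      pos <- as.integer(substring(lab, 2))
      up <- curated[curated$substrate_protein_id == calls$kinase_id[i] &
                      curated$substrate_position == pos &
                      curated$substrate_residue == res, , drop = FALSE]
      if (nrow(up) == 0) next
      edges <- rbind(edges, data.frame(source = up$kinase_id,
                                       target = calls$kinase_id[i],
                                       site = lab, stringsAsFactors = FALSE))
      new_up <- setdiff(up$kinase_id, nodes$kinase_id)
      if (length(new_up) > 0)
        nodes <- rbind(nodes, data.frame(kinase_id = new_up,
                                         node_class = "upstream_only",
                                         stringsAsFactors = FALSE))
    }
  }
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$site)), ,
                 drop = FALSE]
  edges$self_loop <- edges$source == edges$target
  nodes <- nodes[order(nodes$kinase_id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$site), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ksr_network")
}

#' @export
print.ksr_network <- function(x, ...) {
  cat(sprintf("ksr_network: %d nodes, %d edges (%d self-loops)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$self_loop)))
  invisible(x)
}

#' Export a kinase network
#'
#' Serializes a [build_network()] result deterministically. `sif` writes
#' `source phosphorylates target` lines; `tsv` writes the edge list with a
#' node-class table alongside (`<path>.nodes.tsv`); `graphml` writes via
#' igraph with node-class and site attributes.
#'
#' @param net A `ksr_network`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "ksr_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\tphosphorylates\t%s", net$edges$source, net$edges$target)
    lonely <- setdiff(net$nodes$kinase_id,
                      c(net$edges$source, net$edges$target))
    writeLines(c(sort(unique(lines)), sort(lonely)), path)
  } else if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(net$edges) > 0) net$edges else
        data.frame(source = character(), target = character(),
                   site = character(), self_loop = logical()),
      directed = TRUE, vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML network export
#'
#' Round-trip companion to [export_network()]: reads a GraphML file back
#' into a `ksr_network`.
#'
#' @param path GraphML file path.
#' @return A `ksr_network`.
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(kinase_id = igraph::vertex_attr(g, "name"),
                      node_class = igraph::vertex_attr(g, "node_class"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(source = el$from, target = el$to,
                      site = if (nrow(el) > 0) el$site else character(),
                      stringsAsFactors = FALSE)
  edges$self_loop <- edges$source == edges$target
  nodes <- nodes[order(nodes$kinase_id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$site), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ksr_network")
}
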