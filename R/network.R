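#' Build the bipartite tissue / group enrichment network
#'
#' Tissue nodes carry each tissue's tissue-enriched gene count. Group nodes
#' represent distinct elevated-tissue sets of group-enriched genes, kept
#' only when the set has at most \code{network_max_tissues} members and at
#' least \code{network_min_genes} genes; larger or sparser sets are dropped
#' from the graph, not reassigned. Each group node links to every member
#' tissue, and its display size is the square root of its gene count.
#'
#' @param calls Calls data.frame from \code{\link{classify_all}}.
#' @param config An \code{\link{atlas_config}}.
#' @param tissues Tissue names for the tissue nodes; defaults to
#'   \code{attr(calls, "tissues")}, falling back to the tissues seen in
#'   elevated sets.
#' @return An object of class \code{enrichment_network}: list with
#'   \code{tissue_nodes} (tissue, gene_count), \code{group_nodes}
#'   (group_id, tissues, gene_count, display_size) and \code{edges}
#'   (group_id, tissue). Group ids are \code{"group:"} plus the sorted
#'   ';'-joined tissue names, so the network is independent of call order.
#' @export
build_network <- function(calls, config = atlas_config(),
                          tissues = attr(calls, "tissues")) {
  sets <- strsplit(calls$elevated_tissues, ";", fixed = TRUE)
  if (is.null(tissues))
    tissues <- sort(unique(unlist(sets)))
  enr <- calls$category == "tissue_enriched"
  tissue_nodes <- data.frame(
    tissue = tissues,
    gene_count = vapply(tissues, function(tt)
      sum(enr & vapply(sets, function(s) tt %in% s, logical(1))), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  grp <- calls$category == "group_enriched"
  key <- vapply(sets, function(s) paste(sort(s), collapse = ";"), character(1))
  counts <- c(table(key[grp]))
  if (length(counts)) {
    sizes <- lengths(strsplit(names(counts), ";", fixed = TRUE))
    keep <- sizes <= config$network_max_tissues & counts >= config$network_min_genes
    counts <- counts[keep]
    counts <- counts[order(names(counts))]
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  group_nodes <- if (length(counts)) {
    data.frame(group_id = paste0("group:", names(counts)),
               tissues = names(counts),
               gene_count = as.integer(counts),
               display_size = sqrt(as.integer(counts)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(group_id = character(0), tissues = character(0),
               gene_count = integer(0), display_size = numeric(0))
  }
  edges <- if (nrow(group_nodes)) {
    member <- strsplit(group_nodes$tissues, ";", fixed = TRUE)
    data.frame(group_id = rep(group_nodes$group_id, lengths(member)),
               tissue = unlist(member), row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(group_id = character(0), tissue = character(0))
  }
  missing <- setdiff(edges$tissue, tissue_nodes$tissue)
  if (length(missing))
    stop("group member tissue(s) absent from tissue node set: ",
         paste(missing, collapse = ", "))
  structure(list(tissue_nodes = tissue_nodes, group_nodes = group_nodes,
                 edges = edges), class = "enrichment_network")
}

#' @export
print.enrichment_network <- function(x, ...) {
  cat(sprintf("enrichment network: %d tissue nodes, %d group nodes, %d edges\n",
              nrow(x$tissue_nodes), nrow(x$group_nodes), nrow(x$edges)))
  invisible(x)
}

# internal: igraph view of the network
as_igraph_network <- function(net) {
  vert <- rbind(
    data.frame(name = net$tissue_nodes$tissue,
               kind = rep("tissue", nrow(net$tissue_nodes)),
               gene_count = net$tissue_nodes$gene_count,
               display_size = sqrt(pmax(net$tissue_nodes$gene_count, 0)),
               stringsAsFactors = FALSE),
    data.frame(name = net$group_nodes$group_id,
               kind = rep("group", nrow(net$group_nodes)),
               gene_count = net$group_nodes$gene_count,
               display_size = net$group_nodes$display_size,
               stringsAsFactors = FALSE)
  )
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = vert)
}

#' Export an enrichment network
#'
#' GraphML output carries node attributes \code{kind}, \code{gene_count}
#' and \code{display_size}; the edge TSV has columns \code{group_id} and
#' \code{tissue}.
#'
#' @param net An \code{enrichment_network}.
#' @param path Output path.
#' @param format "graphml" or "edge_tsv".
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  if (!inherits(net, "enrichment_network")) stop("net must be an enrichment_network")
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network export format"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph_network(net), path, format = "graphml")
  } else {
    write_tsv(net$edges, path)
  }
  invisible(path)
}
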