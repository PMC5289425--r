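# Differential response pathways: gene-by-gene comparison of two drugs
# within a curated pathway graph.

#' Pairwise toxic-change differences between two drugs
#'
#' @param toxic_changes gene-level `toxic_change_table`.
#' @param drug_a,drug_b drug labels; the difference is A minus B.
#' @param genes genes to compare (default: all genes present for both
#'   drugs); genes missing for either drug are excluded with a message.
#' @param timepoints timepoints to compare (default: all shared).
#' @return data.frame with `gene`, `time_h`, `tc_a`, `tc_b`, `delta`.
#' @export
pairwise_difference <- function(toxic_changes, drug_a, drug_b,
                                genes = NULL, timepoints = NULL) {
  ta <- toxic_changes[toxic_changes$drug == drug_a, , drop = FALSE]
  tb <- toxic_changes[toxic_changes$drug == drug_b, , drop = FALSE]
  genes <- genes %||% intersect(ta$entity, tb$entity)
  timepoints <- timepoints %||% intersect(ta$time_h, tb$time_h)
  miss <- setdiff(genes, intersect(ta$entity, tb$entity))
  if (length(miss)) {
    message(sprintf("excluded %d gene(s) missing for either drug",
                    length(miss)))
    genes <- setdiff(genes, miss)
  }
  ta <- ta[ta$entity %in% genes & ta$time_h %in% timepoints, , drop = FALSE]
  key <- paste(ta$entity, ta$time_h)
  key_b <- paste(tb$entity, tb$time_h)
  m <- match(key, key_b)
  out <- data.frame(gene = ta$entity, time_h = ta$time_h,
                    tc_a = ta$toxic_change, tc_b = tb$toxic_change[m],
                    stringsAsFactors = FALSE)
  out$delta <- out$tc_a - out$tc_b
  out <- out[order(out$time_h, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify similarly and differentially responding genes
#'
#' A gene responds differentially toward drug A when the toxic-change
#' difference exceeds `diff_threshold` (toward B when below its negative);
#' it responds similarly high when both drugs' toxic changes exceed
#' `high_threshold`. The flags are independent: a gene can be both
#' differential and similar-high.
#'
#' @param deltas output of [pairwise_difference()].
#' @param diff_threshold absolute toxic-change difference cutoff, default
#'   0.15.
#' @param high_threshold both-drugs toxic-change cutoff, default 0.15.
#' @return `deltas` with logical columns `differential_a`,
#'   `differential_b`, `similar_high` appended (class
#'   `differential_classification`).
#' @export
classify_genes <- function(deltas, diff_threshold = 0.15,
                           high_threshold = 0.15) {
  out <- deltas
  out$differential_a <- out$delta > diff_threshold
  out$differential_b <- out$delta < -diff_threshold
  out$similar_high <- out$tc_a > high_threshold & out$tc_b > high_threshold
  structure(out,
            thresholds = c(diff = diff_threshold, high = high_threshold),
            class = c("differential_classification", "data.frame"))
}

#' Read a pathway graph from an edge-list TSV
#'
#' Expected columns: `source`, `target`, `interaction` (free-text label).
#' Self-loops are rejected.
#'
#' @param path TSV file path.
#' @param name pathway name (default: the file name).
#' @return a directed [igraph::graph] with edge attribute `interaction`.
#' @export
read_pathway_graph <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("source", "target") %in% names(df)),
              "edge list needs 'source' and 'target' columns")
  pathway_graph(df, name = name)
}

#' Build a pathway graph from an edge data.frame
#'
#' @param edges data.frame with `source`, `target` and optional
#'   `interaction` columns.
#' @param name pathway name.
#' @return a directed igraph graph.
#' @export
pathway_graph <- function(edges, name = "pathway") {
  assert_that(all(edges$source != edges$target),
              "pathway graph must not contain self-loops")
  if (is.null(edges$interaction)) edges$interaction <- "interacts"
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "interaction")], directed = TRUE)
  g$name <- name
  g
}

#' Build the differential response pathway at a timepoint
#'
#' The induced subgraph on all flagged genes (union of differential-A,
#' differential-B and similar-high) at the given timepoint, with node
#' attributes `delta`, `differential_a`, `differential_b`, `similar_high`.
#' Only genes present in the graph appear; edges between flagged genes are
#' preserved with their interaction labels (no one-hop bridging). Nodes
#' are ordered alphabetically for deterministic output.
#'
#' @param classification a [classify_genes()] result.
#' @param graph a pathway [igraph::graph].
#' @param timepoint timepoint in h to build for.
#' @return an igraph graph (possibly empty, with a warning).
#' @export
build_differential_response_pathway <- function(classification, graph,
                                                timepoint) {
  cl <- classification[classification$time_h == timepoint, , drop = FALSE]
  flagged <- cl$gene[cl$differential_a | cl$differential_b |
                       cl$similar_high]
  nodes <- sort(intersect(flagged, igraph::V(graph)$name))
  if (!length(nodes)) {
    warning("no flagged genes present in the pathway graph",
            call. = FALSE)
    return(igraph::make_empty_graph(directed = TRUE))
  }
  sg <- igraph::induced_subgraph(graph, nodes)
  sg <- igraph::permute(sg, match(igraph::V(sg)$name, nodes))
  m <- match(igraph::V(sg)$name, cl$gene)
  igraph::V(sg)$delta <- cl$delta[m]
  igraph::V(sg)$differential_a <- cl$differential_a[m]
  igraph::V(sg)$differential_b <- cl$differential_b[m]
  igraph::V(sg)$similar_high <- cl$similar_high[m]
  sg$name <- paste0(graph$name %||% "pathway", "@", timepoint, "h")
  sg
}

#' Export a differential response pathway
#'
#' Writes GraphML (node flags as attributes) or an edge-list TSV.
#'
#' @param graph an igraph graph.
#' @param path output path; format chosen by extension (`.graphml` or
#'   `.tsv`).
#' @return `path`, invisibly.
#' @export
write_pathway_graph <- function(graph, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(graph, what = "edges")
    names(df)[1:2] <- c("source", "target")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
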