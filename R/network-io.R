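# Network serialization. The TSV is the canonical lossless format; GraphML
# and SIF target graph viewers.

edge_columns <- c("parent_layer", "parent_feature", "child_layer",
                  "child_feature", "lag", "coefficient", "normalized_weight",
                  "bootstrap_support")

empty_edges <- function() {
  data.frame(parent_layer = character(0), parent_feature = character(0),
             child_layer = character(0), child_feature = character(0),
             lag = character(0), coefficient = numeric(0),
             normalized_weight = numeric(0), bootstrap_support = numeric(0),
             stringsAsFactors = FALSE)
}

canonical_edge_order <- function(edges) {
  edges[order(edges$child_layer, edges$child_feature, edges$parent_layer,
              edges$parent_feature, edges$lag), , drop = FALSE]
}

model_edges <- function(model) {
  if (is.data.frame(model)) model else model$edges
}

model_nodes <- function(model) {
  if (is.data.frame(model)) {
    e <- model
    unique(c(node_id(e$parent_layer, e$parent_feature),
             node_id(e$child_layer, e$child_feature)))
  } else {
    model$nodes
  }
}

#' Export a learned network
#'
#' Writes every edge with its lag (intra/inter), signed coefficient,
#' normalized weight and bootstrap support. Self-loops are serialized like any
#' other inter-edge. The TSV format round-trips exactly through
#' [read_network_tsv()].
#'
#' @param model a `DBNModel`, `BootstrapNetwork`, or plain edge data frame.
#' @param path output file.
#' @param format one of `"tsv"`, `"graphml"`, `"sif"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(model, path, format = c("tsv", "graphml", "sif")) {
  format <- match.arg(format)
  edges <- canonical_edge_order(model_edges(model))
  nodes <- sort(model_nodes(model))
  if (format == "tsv") {
    out <- edges
    for (col in c("coefficient", "normalized_weight", "bootstrap_support")) {
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
      }, "")
    }
    utils::write.table(out[, edge_columns], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(edges)) {
      sprintf("%s\t%s\t%s", node_id(edges$parent_layer, edges$parent_feature),
              edges$lag, node_id(edges$child_layer, edges$child_feature))
    } else character(0)
    # isolated nodes are listed bare, as Cytoscape's SIF allows
    iso <- setdiff(nodes, unique(c(
      node_id(edges$parent_layer, edges$parent_feature),
      node_id(edges$child_layer, edges$child_feature))))
    writeLines(c(lines, iso), path)
  } else {
    xml_esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    con <- file(path, "w"); on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
    w('  <key id="kind" for="node" attr.name="kind" attr.type="string"/>')
    w('  <key id="lag" for="edge" attr.name="lag" attr.type="string"/>')
    w('  <key id="coefficient" for="edge" attr.name="coefficient" attr.type="double"/>')
    w('  <key id="normalized_weight" for="edge" attr.name="normalized_weight" attr.type="double"/>')
    w('  <key id="bootstrap_support" for="edge" attr.name="bootstrap_support" attr.type="double"/>')
    w('  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>')
    w('  <graph edgedefault="directed">')
    for (n in nodes) {
      kind <- sub(":.*$", "", n)
      w('    <node id="%s"><data key="kind">%s</data></node>',
        xml_esc(n), xml_esc(kind))
    }
    if (nrow(edges)) {
      for (i in seq_len(nrow(edges))) {
        e <- edges[i, ]
        w(paste0('    <edge source="%s" target="%s">',
                 '<data key="lag">%s</data>',
                 '<data key="coefficient">%.17g</data>',
                 '<data key="normalized_weight">%.17g</data>',
                 '<data key="bootstrap_support">%.17g</data>',
                 '<data key="sign">%s</data></edge>'),
          xml_esc(node_id(e$parent_layer, e$parent_feature)),
          xml_esc(node_id(e$child_layer, e$child_feature)),
          e$lag, e$coefficient,
          if (is.na(e$normalized_weight)) 0 else e$normalized_weight,
          if (is.na(e$bootstrap_support)) 0 else e$bootstrap_support,
          if (!is.na(e$coefficient) && e$coefficient < 0) "negative" else "positive")
      }
    }
    w('  </graph>')
    w('</graphml>')
  }
  invisible(path)
}

#' Re-import a network TSV written by [export_network()]
#'
#' @param path network TSV file.
#' @return edge data frame with the standard eight columns.
#' @export
read_network_tsv <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "", colClasses = c(
                           parent_layer = "character", parent_feature = "character",
                           child_layer = "character", child_feature = "character",
                           lag = "character", coefficient = "numeric",
                           normalized_weight = "numeric",
                           bootstrap_support = "numeric"))
  if (!all(edge_columns %in% names(x))) {
    stop("'", path, "' is not a network TSV (missing columns)")
  }
  x[, edge_columns]
}
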