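# Constraint matrices restrict which (parent kind, child kind, lag) edges
# the structure search may add. Cells flagged self_only permit only
# self-loops (same feature, previous slice). host_gene and env nodes never
# receive edges.

constraint_cell <- function(parent_kind, child_kind, lag, self_only = FALSE) {
  data.frame(parent_kind = parent_kind, child_kind = child_kind, lag = lag,
             self_only = self_only, stringsAsFactors = FALSE)
}

new_constraints <- function(cells, name) {
  if (any(cells$child_kind %in% c("env", "host_gene"))) {
    stop("constraint matrix gives env/host_gene nodes incoming edges")
  }
  structure(list(allowed = cells, name = name), class = "ConstraintMatrix")
}

#' Skeleton constraint matrix
#'
#' The biologically motivated flow: within a time slice, environment and host
#' genes -> taxa -> microbial genes -> metabolites; between slices,
#' metabolites -> taxa, plus self-loops for every dynamic node. Environmental
#' and host-gene nodes receive no edges.
#'
#' @return a `ConstraintMatrix` named `"skeleton"`.
#' @export
skeleton_constraints <- function() {
  cells <- rbind(
    constraint_cell("env", "taxon", "intra"),
    constraint_cell("host_gene", "taxon", "intra"),
    constraint_cell("taxon", "gene", "intra"),
    constraint_cell("gene", "metabolite", "intra"),
    constraint_cell("metabolite", "taxon", "inter"),
    constraint_cell("taxon", "taxon", "inter", self_only = TRUE),
    constraint_cell("gene", "gene", "inter", self_only = TRUE),
    constraint_cell("metabolite", "metabolite", "inter", self_only = TRUE))
  new_constraints(cells, "skeleton")
}

#' Augmented constraint matrix
#'
#' Skeleton plus direct taxon -> metabolite edges, covering cases where gene
#' profiling noise hides the indirect taxon -> gene -> metabolite path. The
#' lag of the added cells is configurable (the two-slice placement of these
#' direct edges is a modelling choice); both are enabled by default.
#'
#' @param intra allow taxon -> metabolite within a slice?
#' @param inter allow taxon -> metabolite across slices?
#' @return a `ConstraintMatrix` named `"augmented"`.
#' @export
augmented_constraints <- function(intra = TRUE, inter = TRUE) {
  cells <- skeleton_constraints()$allowed
  if (intra) cells <- rbind(cells, constraint_cell("taxon", "metabolite", "intra"))
  if (inter) cells <- rbind(cells, constraint_cell("taxon", "metabolite", "inter"))
  new_constraints(cells, "augmented")
}

get_constraints <- function(spec, cfg = default_config()$dbn) {
  if (inherits(spec, "ConstraintMatrix")) return(spec)
  switch(spec,
         skeleton = skeleton_constraints(),
         augmented = augmented_constraints(cfg$augmented_intra,
                                           cfg$augmented_inter),
         stop("unknown constraint preset '", spec, "'"))
}

#' Is an edge permitted by a constraint matrix?
#'
#' @param constraints a `ConstraintMatrix`.
#' @param parent_kind,child_kind node kinds.
#' @param lag `"intra"` or `"inter"`.
#' @param is_self is the edge a self-loop (same feature, consecutive slices)?
#' @return logical scalar.
#' @export
edge_allowed <- function(constraints, parent_kind, child_kind, lag,
                         is_self = FALSE) {
  a <- constraints$allowed
  hit <- a$parent_kind == parent_kind & a$child_kind == child_kind & a$lag == lag
  any(hit & (!a$self_only | is_self))
}

#' Write a constraint matrix to JSON
#' @param constraints a `ConstraintMatrix`.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_constraints <- function(constraints, path) {
  jsonlite::write_json(list(name = constraints$name,
                            cells = constraints$allowed),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a constraint matrix from JSON
#' @param path JSON file written by [write_constraints()] (or hand-authored
#'   with the same shape).
#' @return a `ConstraintMatrix` named `"custom"` unless the file names it.
#' @export
read_constraints <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(x$cells, stringsAsFactors = FALSE)
  if (is.null(cells$self_only)) cells$self_only <- FALSE
  new_constraints(cells[, c("parent_kind", "child_kind", "lag", "self_only")],
                  if (is.null(x$name)) "custom" else x$name)
}
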