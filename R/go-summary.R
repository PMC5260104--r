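# Hierarchy-level views over the ontology: each virtual transcript inherits
# the GO terms of its best-hit subject, annotations are rolled up to all
# ancestors, and per-term cumulative totals are reported at a chosen level.

#' Assign a hierarchy level to every ontology term
#'
#' Level is the minimum number of edges (over is_a and part_of) from the
#' term to its namespace root; roots are level 0. \code{mode = "max"} uses
#' the longest path instead, for users who prefer deepest placement.
#'
#' @param dag a \code{go_dag}.
#' @param mode \code{"min"} (default) or \code{"max"}.
#' @return object of class \code{go_level_index}: named integer vector of
#'   levels, names are term ids.
#' @export
assign_levels <- function(dag, mode = c("min", "max")) {
  mode <- match.arg(mode)
  g <- dag$graph
  ids <- dag$terms$id
  ns_of <- stats::setNames(dag$terms$namespace, ids)
  lev <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (root in dag$roots) {
    same_ns <- ids[ns_of == ns_of[root]]
    if (mode == "min") {
      d <- igraph::distances(g, v = same_ns, to = root, mode = "out")[, 1]
    } else {
      # longest path to root in a DAG: process terms in topological order
      # (children before parents along child->parent edges)
      topo <- names(igraph::topo_sort(g, mode = "in"))   # root first
      d <- stats::setNames(rep(-Inf, length(same_ns)), same_ns)
      d[root] <- 0
      for (v in topo) {
        if (!(v %in% same_ns) || is.infinite(d[v])) next
        kids <- names(igraph::neighbors(g, v, mode = "in"))
        kids <- kids[kids %in% same_ns]
        d[kids] <- pmax(d[kids], d[v] + 1)
      }
    }
    reached <- names(d)[is.finite(d)]
    lev[reached] <- pmin(lev[reached], as.integer(d[reached]), na.rm = TRUE)
  }
  if (anyNA(lev))
    stop("term(s) unreachable from any namespace root: ",
         paste(utils::head(names(lev)[is.na(lev)], 5), collapse = ", "))
  class(lev) <- "go_level_index"
  lev
}

#' Transfer subject GO terms to virtual transcripts
#'
#' A virtual transcript inherits the annotation of its best-hit subject;
#' orphan singletons and subjects without associations get the empty set.
#'
#' @param vref a \code{virtual_reference}.
#' @param assoc a \code{go_association}.
#' @return named list vt_id -> character vector of term ids.
#' @export
annotate_vtranscripts <- function(vref, assoc) {
  tr <- vref$transcripts
  out <- lapply(seq_len(nrow(tr)), function(i) {
    s <- tr$subject_id[i]
    if (is.na(s) || is.null(assoc[[s]])) character(0) else assoc[[s]]
  })
  stats::setNames(out, tr$vt_id)
}

#' Close annotation sets under the ancestor relation
#'
#' Adds every ancestor (via is_a and part_of, up to the namespace root) of
#' each annotated term, so that summaries at shallow levels accumulate the
#' expression of all descendant annotations. Idempotent.
#'
#' @param dag a \code{go_dag}.
#' @param vt_terms named list vt_id -> term ids, e.g. from
#'   \code{\link{annotate_vtranscripts}}.
#' @return named list of the same shape, each set ancestor-closed and sorted.
#' @export
propagate <- function(dag, vt_terms) {
  needed <- unique(unlist(vt_terms, use.names = FALSE))
  needed <- needed[needed %in% dag$terms$id]
  anc <- lapply(needed, function(t)
    names(igraph::subcomponent(dag$graph, t, mode = "out")))
  names(anc) <- needed
  lapply(vt_terms, function(terms) {
    terms <- terms[terms %in% needed]
    out <- unlist(anc[terms], use.names = FALSE)
    if (is.null(out)) character(0) else sort(unique(out))
  })
}

#' Cumulative per-term summary at one hierarchy level
#'
#' For every term of the namespace sitting at the requested level, reports
#' how many virtual transcripts carry the term after ancestor closure and
#' the summed RC / eRPKM / eTPM of those transcripts per dataset. A
#' transcript annotated to several sibling terms contributes its full value
#' to each, so sums across rows can exceed the dataset total by design.
#'
#' @param quant a \code{quant_table}.
#' @param vt_terms_closed ancestor-closed annotation from
#'   \code{\link{propagate}} (or direct annotation, for a direct-only view).
#' @param levels a \code{go_level_index}.
#' @param level requested level (>= 0).
#' @param dag the \code{go_dag} (for names and namespaces).
#' @param namespace restrict to one namespace; \code{NULL} keeps all.
#' @return data.frame with term_id, name, namespace, level, then per-dataset
#'   n_vtranscripts.<label>, rc_sum.<label>, erpkm_sum.<label>,
#'   etpm_sum.<label>; rows sorted by term_id. Empty (with a warning) when
#'   no term sits at that level.
#' @export
summarize_at_level <- function(quant, vt_terms_closed, levels, level, dag,
                               namespace = NULL) {
  if (level < 0) stop("level must be >= 0")
  ids <- names(levels)[unclass(levels) == level]
  if (!is.null(namespace)) {
    ns_of <- stats::setNames(dag$terms$namespace, dag$terms$id)
    ids <- ids[ns_of[ids] == namespace]
  }
  ids <- sort(ids)
  labels <- attr(quant, "dataset_labels")
  if (length(ids) == 0L) {
    warning("no ontology terms at level ", level)
  }
  name_of <- stats::setNames(dag$terms$name, dag$terms$id)
  ns_of <- stats::setNames(dag$terms$namespace, dag$terms$id)
  out <- data.frame(term_id = ids,
                    name = unname(name_of[ids]),
                    namespace = unname(ns_of[ids]),
                    level = rep(as.integer(level), length(ids)),
                    stringsAsFactors = FALSE)
  vt_ids <- quant$vtranscript_id
  vt_terms_closed <- vt_terms_closed[vt_ids]
  # membership matrix term x vt would be wasteful for a real GO; invert the
  # annotation instead: term -> vts carrying it
  term2vt <- list()
  for (i in seq_along(vt_ids)) {
    for (t in vt_terms_closed[[i]]) {
      term2vt[[t]] <- c(term2vt[[t]], i)
    }
  }
  for (lab in labels) {
    rc <- quant[[paste0("rc.", lab)]]
    er <- quant[[paste0("erpkm.", lab)]]
    et <- quant[[paste0("etpm.", lab)]]
    sum_for <- function(vals, t) sum(vals[term2vt[[t]]])
    out[[paste0("n_vtranscripts.", lab)]] <-
      vapply(ids, function(t) length(term2vt[[t]]), 0L)
    out[[paste0("rc_sum.", lab)]] <- vapply(ids, sum_for, 0, vals = rc)
    out[[paste0("erpkm_sum.", lab)]] <- vapply(ids, sum_for, 0, vals = er)
    out[[paste0("etpm_sum.", lab)]] <- vapply(ids, sum_for, 0, vals = et)
  }
  rownames(out) <- NULL
  out
}

#' Write a GO level summary as tab-delimited text
#' @param rows data.frame from \code{\link{summarize_at_level}}.
#' @param path output path.
#' @export
write_go_summary <- function(rows, path) {
  df <- rows
  for (col in grep("^(erpkm_sum|etpm_sum)\\.", names(df), value = TRUE))
    df[[col]] <- signif(df[[col]], 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
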