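#' @importFrom stats rpois runif setNames
#' @importFrom utils read.table write.table head
NULL

# ---- contig sets -----------------------------------------------------------

#' Construct a contig set
#'
#' A contig set is the in-memory form of an assembled transcriptome: one row
#' per contig with its id and length, optionally carrying the sequences
#' themselves as a \code{Biostrings::DNAStringSet}.
#'
#' @param id character vector of unique contig ids.
#' @param length integer vector of contig lengths in bp (> 0).
#' @param sequences optional \code{DNAStringSet} named by \code{id}; when
#'   present each width must equal \code{length}.
#' @return an object of class \code{contig_set}: a data.frame with columns
#'   \code{id} and \code{length}, sequences (if any) kept in the
#'   \code{"sequences"} attribute.
#' @export
contig_set <- function(id, length, sequences = NULL) {
  id <- as.character(id)
  length <- as.integer(length)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  }
  if (any(is.na(length)) || any(length <= 0L))
    stop("contig lengths must be positive integers")
  if (!is.null(sequences)) {
    if (!all(id %in% names(sequences)))
      stop("sequences must be named by contig id")
    w <- Biostrings::width(sequences[id])
    if (!all(w == length))
      stop("sequence width disagrees with declared length for: ",
           paste(id[w != length], collapse = ", "))
  }
  out <- data.frame(id = id, length = length, stringsAsFactors = FALSE)
  attr(out, "sequences") <- sequences
  class(out) <- c("contig_set", "data.frame")
  out
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contigs, total %s bp\n",
              nrow(x), format(sum(as.numeric(x$length)), big.mark = ",")))
  invisible(x)
}

#' Named vector of contig lengths
#' @param contigs a \code{contig_set}.
#' @return named integer vector, names are contig ids.
#' @export
contig_lengths <- function(contigs) {
  stats::setNames(contigs$length, contigs$id)
}

#' Read assembled contigs from a FASTA file
#'
#' The contig id is the header token before the first whitespace, the same
#' normalization applied to hit tables and alignment files so the three
#' sources join cleanly.
#'
#' @param path FASTA file of assembled contigs.
#' @return a \code{contig_set} carrying sequences.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate contig id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  names(seqs) <- ids
  contig_set(ids, Biostrings::width(seqs), sequences = seqs)
}

#' Write a contig set to FASTA
#' @param contigs a \code{contig_set} carrying sequences.
#' @param path output path.
#' @export
write_contigs <- function(contigs, path) {
  seqs <- attr(contigs, "sequences")
  if (is.null(seqs)) stop("contig_set carries no sequences")
  Biostrings::writeXStringSet(seqs[contigs$id], path)
  invisible(path)
}

# ---- homology hits ---------------------------------------------------------

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Read a tabular homology hit file (BLAST outfmt 6)
#'
#' Parses the 12-column tab-separated format produced by \code{blastn -outfmt 6}
#' and by LAST in blast-tab mode. Comment lines starting with \code{#} are
#' skipped. Malformed rows fail hard with their line number so upstream search
#' problems surface immediately instead of silently losing contigs.
#'
#' @param path tab-separated hit file.
#' @param dialect only \code{"blast6"} is supported.
#' @return data.frame of class \code{homology_hits} with one row per hit.
#' @export
read_hits <- function(path, dialect = "blast6") {
  dialect <- match.arg(dialect, "blast6")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    hits <- data.frame(matrix(nrow = 0, ncol = 12,
                              dimnames = list(NULL, BLAST6_COLS)))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L)) {
      bad <- lineno[which(nf != 12L)[1]]
      stop(sprintf("line %d of %s: expected 12 tab-separated columns, got %d",
                   bad, path, nf[which(nf != 12L)[1]]))
    }
    m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
    hits <- data.frame(m, stringsAsFactors = FALSE)
    names(hits) <- BLAST6_COLS
    num_cols <- setdiff(BLAST6_COLS, c("query_id", "subject_id"))
    for (col in num_cols) {
      v <- suppressWarnings(as.numeric(hits[[col]]))
      if (anyNA(v)) {
        bad <- lineno[which(is.na(v))[1]]
        stop(sprintf("line %d of %s: unparsable numeric field '%s'",
                     bad, path, col))
      }
      hits[[col]] <- v
    }
    int_cols <- c("alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end")
    for (col in int_cols) hits[[col]] <- as.integer(hits[[col]])
    if (any(hits$e_value < 0)) stop("negative e-value in ", path)
  }
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

#' Write hits in BLAST outfmt-6 layout (fixture support / round-tripping)
#' @param hits a \code{homology_hits} data.frame.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  df <- as.data.frame(hits)[, BLAST6_COLS]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- mapping profiles ------------------------------------------------------

#' Construct a per-dataset mapping profile
#'
#' Holds the number of reads mapped to each contig for one sequencing
#' dataset; this is the n_j of the read-count quantification.
#'
#' @param dataset_label short label for the dataset (condition, tissue, run).
#' @param counts named non-negative numeric vector, names are contig ids.
#' @return object of class \code{mapping_profile} with elements
#'   \code{dataset_label}, \code{counts}, \code{total_mapped}.
#' @export
mapping_profile <- function(dataset_label, counts) {
  if (is.null(names(counts))) {
    if (length(counts)) stop("counts must be named by contig id")
    counts <- stats::setNames(numeric(0), character(0))
  }
  counts <- counts[order(names(counts))]
  if (any(counts < 0)) stop("negative read count in profile '", dataset_label, "'")
  structure(list(dataset_label = as.character(dataset_label),
                 counts = counts,
                 total_mapped = sum(as.numeric(counts))),
            class = "mapping_profile")
}

#' @export
print.mapping_profile <- function(x, ...) {
  cat(sprintf("<mapping_profile> '%s': %d contigs, %s mapped reads\n",
              x$dataset_label, length(x$counts),
              format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Read a per-dataset mapping into a profile
#'
#' Accepts a SAM/BAM alignment of reads against the contigs or a two-column
#' \code{contig_id<TAB>count} TSV. For alignments, a record is counted toward
#' its reference contig iff it is mapped and neither secondary nor
#' supplementary; paired-end mates each count 1 read. Multi-mapped reads are
#' counted once, wherever the aligner marked the primary record.
#'
#' @param path SAM, BAM or TSV file.
#' @param dataset_label label stored in the profile.
#' @param format \code{"auto"} (by extension), \code{"sam"}, \code{"bam"}
#'   or \code{"tsv"}.
#' @return a \code{mapping_profile}.
#' @export
read_mapping <- function(path, dataset_label, format = c("auto", "sam", "bam", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") {
    info <- file.info(path)
    if (info$size == 0) return(mapping_profile(dataset_label, numeric(0)))
    df <- read.table(path, sep = "\t", header = FALSE,
                     colClasses = c("character", "numeric"),
                     col.names = c("contig_id", "count"))
    if (any(df$count < 0))
      stop("negative count in ", path, " for contig ",
           df$contig_id[which(df$count < 0)[1]])
    counts <- tapply(df$count, df$contig_id, sum)
    return(mapping_profile(dataset_label, stats::setNames(as.numeric(counts), names(counts))))
  }
  bam <- path
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "rname")
  rn <- Rsamtools::scanBam(bam, param = param)[[1]]$rname
  rn <- as.character(rn)
  counts <- table(rn)
  mapping_profile(dataset_label,
                  stats::setNames(as.numeric(counts), names(counts)))
}

# ---- GO ontology -----------------------------------------------------------

#' Read a Gene Ontology graph from an OBO file
#'
#' Parses \code{[Term]} stanzas of OBO 1.2/1.4. \code{is_a} and
#' \code{relationship: part_of} become child-to-parent edges; obsolete terms
#' are dropped; other relationship types (regulates, ...) are ignored. Roots
#' are the terms without parents, one expected per namespace.
#'
#' @param path OBO file.
#' @return object of class \code{go_dag}: list with \code{terms} (data.frame
#'   id/name/namespace), \code{edges} (data.frame child/parent/rel),
#'   \code{graph} (igraph, edges child -> parent) and \code{roots}.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  bounds <- c(grep("^\\[", lines), length(lines) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  children <- character(0); parents <- character(0); rels <- character(0)
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    ns <- sub("^namespace: *", "", grep("^namespace:", block, value = TRUE)[1])
    if (is.na(ns)) ns <- "default"
    ids <- c(ids, id); nms <- c(nms, if (is.na(nm)) id else nm); nss <- c(nss, ns)
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
    children <- c(children, rep(id, length(isa) + length(po)))
    parents <- c(parents, isa, po)
    rels <- c(rels, rep("is_a", length(isa)), rep("part_of", length(po)))
  }
  terms <- data.frame(id = ids, name = nms, namespace = nss,
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = children, parent = parents, rel = rels,
                      stringsAsFactors = FALSE)
  # edges to terms unknown here (e.g. obsolete parents) are dropped
  edges <- edges[edges$parent %in% terms$id & edges$child %in% terms$id, ,
                 drop = FALSE]
  go_dag(terms, edges)
}

#' Construct a GO DAG from term and edge tables
#' @param terms data.frame with columns id, name, namespace.
#' @param edges data.frame with columns child, parent and optionally rel.
#' @return a \code{go_dag}; errors if the graph is cyclic, naming a member
#'   of one cycle.
#' @export
go_dag <- function(terms, edges) {
  if (anyDuplicated(terms$id)) stop("duplicate GO term ids")
  if (is.null(edges$rel)) edges$rel <- "is_a"
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]][1]
    stop("ontology graph contains a cycle involving term ", bad)
  }
  roots <- terms$id[igraph::degree(g, v = terms$id, mode = "out") == 0]
  # every non-root term must reach a root of its own namespace
  ns_of <- stats::setNames(terms$namespace, terms$id)
  for (t in setdiff(terms$id, roots)) {
    reach <- names(igraph::subcomponent(g, t, mode = "out"))
    if (!any(reach %in% roots & ns_of[reach] == ns_of[t]))
      stop("term ", t, " cannot reach a root of namespace ", ns_of[t])
  }
  structure(list(terms = terms, edges = edges, graph = g, roots = roots),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges, roots: %s\n",
              nrow(x$terms), nrow(x$edges), paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Write a GO DAG as OBO (fixture support)
#' @param dag a \code{go_dag}.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    writeLines(c("[Term]",
                 paste0("id: ", t$id),
                 paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    e <- dag$edges[dag$edges$child == t$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$rel[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# ---- GO associations -------------------------------------------------------

#' Read a subject-to-GO association table
#'
#' Two tab-separated columns, \code{subject_id<TAB>GO:XXXXXXX}, one pair per
#' row. Duplicate pairs collapse; terms absent from the DAG (when one is
#' supplied) are dropped with a warning, since they cannot be placed in the
#' hierarchy.
#'
#' @param path TSV file.
#' @param dag optional \code{go_dag} used to validate term ids.
#' @return object of class \code{go_association}: named list mapping
#'   subject id to a character vector of term ids.
#' @export
read_associations <- function(path, dag = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(structure(list(), class = "go_association"))
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character",
                   col.names = c("subject_id", "term_id"))
  if (!is.null(dag)) {
    unknown <- setdiff(unique(df$term_id), dag$terms$id)
    if (length(unknown)) {
      warning("dropping ", length(unknown),
              " association term(s) absent from the ontology: ",
              paste(head(unknown, 5), collapse = ", "))
      df <- df[df$term_id %in% dag$terms$id, , drop = FALSE]
    }
  }
  assoc <- lapply(split(df$term_id, df$subject_id), function(v) sort(unique(v)))
  structure(assoc, class = "go_association")
}

#' Write an association table (fixture support)
#' @param assoc a \code{go_association}.
#' @param path output path.
#' @export
write_associations <- function(assoc, path) {
  subj <- rep(names(assoc), lengths(assoc))
  term <- unlist(assoc, use.names = FALSE)
  df <- data.frame(subject_id = subj, term_id = term)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- quantification table I/O ---------------------------------------------

#' Write a quantification table as tab-delimited text
#'
#' One header row, one row per virtual transcript sorted lexicographically by
#' id, then per-dataset RC / eRPKM / eTPM columns. Floats are printed at 6
#' significant digits; values in memory stay double precision.
#'
#' @param table a \code{quant_table} from \code{\link{compare_datasets}}.
#' @param path output path.
#' @export
write_quant_table <- function(table, path) {
  if (!inherits(table, "quant_table")) stop("not a quant_table")
  if (nrow(table) == 0L) stop("empty quantification table, nothing written")
  df <- as.data.frame(table)
  df <- df[order(df$vtranscript_id), , drop = FALSE]
  for (col in grep("^(erpkm|etpm)\\.", names(df), value = TRUE))
    df[[col]] <- signif(df[[col]], 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read back a written quantification table
#' @param path TSV produced by \code{\link{write_quant_table}}.
#' @return a \code{quant_table}.
#' @export
read_quant_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  labels <- unique(sub("^rc\\.", "", grep("^rc\\.", names(df), value = TRUE)))
  attr(df, "dataset_labels") <- labels
  class(df) <- c("quant_table", "data.frame")
  df
}
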