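# Clustering of annotated contigs into homolog-keyed virtual transcripts.
# A virtual transcript is the set of contigs sharing a best homology hit;
# it stands in for the (unknown) real transcript during quantification.

#' Keep contigs long enough to annotate
#'
#' Only contigs strictly longer than \code{min_length} enter homology-based
#' clustering; shorter contigs risk spurious annotation since at 200 bp a
#' contig can encode at most 66 amino acids even with no UTR. Excluded ids
#' are retrievable from the \code{"excluded_ids"} attribute.
#'
#' @param contigs a \code{contig_set}.
#' @param min_length length cutoff in bp; default 200.
#' @return a filtered \code{contig_set}.
#' @export
filter_annotatable <- function(contigs, min_length = 200L) {
  if (min_length < 0) stop("min_length must be >= 0")
  keep <- contigs$length > min_length
  out <- contigs[keep, , drop = FALSE]
  seqs <- attr(contigs, "sequences")
  attr(out, "sequences") <- if (is.null(seqs)) NULL else seqs[out$id]
  attr(out, "excluded_ids") <- contigs$id[!keep]
  class(out) <- c("contig_set", "data.frame")
  if (nrow(out) == 0L)
    warning("no contigs longer than ", min_length, " bp remain")
  out
}

#' Longest protein encodable below an annotation cutoff
#'
#' A contig of \code{cutoff_bp} bases can encode at most
#' \code{floor(cutoff_bp / 3)} amino acids, assuming the entire contig is
#' coding (no untranslated region). At the default 200 bp cutoff this is 66
#' amino acids, which bounds what annotation can miss among short contigs.
#'
#' @param cutoff_bp annotation length cutoff in bp.
#' @return maximum encodable protein length in amino acids.
#' @export
max_encodable_protein <- function(cutoff_bp = 200L) {
  as.integer(floor(cutoff_bp / 3))
}

#' Select each contig's best homology hit
#'
#' Per contig the hit with maximal bit score wins; ties break by minimal
#' e-value, then by lexicographically smallest subject id, so the result is
#' independent of row order. Hits for contigs outside \code{eligible} are
#' ignored.
#'
#' @param hits a \code{homology_hits} data.frame.
#' @param eligible the \code{contig_set} of annotatable contigs.
#' @param max_evalue optional e-value ceiling; hits above it are discarded
#'   before selection. Default \code{Inf} (no ceiling).
#' @return object of class \code{best_hit_map}: data.frame with columns
#'   contig_id, subject_id, e_value, bit_score; at most one row per contig.
#' @export
select_best_hit <- function(hits, eligible, max_evalue = Inf) {
  h <- as.data.frame(hits)
  h <- h[h$query_id %in% eligible$id & h$e_value <= max_evalue, , drop = FALSE]
  if (nrow(h)) {
    ord <- order(h$query_id, -h$bit_score, h$e_value, h$subject_id)
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
  }
  out <- data.frame(contig_id = h$query_id, subject_id = h$subject_id,
                    e_value = h$e_value, bit_score = h$bit_score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("best_hit_map", "data.frame")
  out
}

#' Cluster contigs into virtual transcripts by shared best hit
#'
#' Each distinct best-hit subject becomes one virtual transcript whose
#' members are all contigs selecting it; the subject accession is the
#' transcript id. Eligible contigs without a qualifying hit are orphans and
#' excluded from the reference by default; with \code{include_orphans} each
#' becomes a singleton transcript named \code{orphan:<contig_id>}, which
#' enters every quantification denominator.
#'
#' @param best a \code{best_hit_map}.
#' @param eligible annotatable \code{contig_set} (superset of \code{best}'s
#'   contigs).
#' @param all_contigs the full \code{contig_set}, used to account for
#'   below-cutoff contigs.
#' @param include_orphans logical, default \code{FALSE}.
#' @return object of class \code{virtual_reference}: list with
#'   \code{transcripts} (data.frame vt_id/subject_id/n_contigs/total_length),
#'   \code{members} (named list vt_id -> contig ids), \code{orphans} and
#'   \code{short} contig id vectors.
#' @export
build_virtual_transcripts <- function(best, eligible, all_contigs = eligible,
                                      include_orphans = FALSE) {
  stopifnot(all(best$contig_id %in% eligible$id),
            all(eligible$id %in% all_contigs$id))
  members <- lapply(split(best$contig_id, best$subject_id), sort)
  subjects <- names(members)
  orphans <- sort(setdiff(eligible$id, best$contig_id))
  if (include_orphans && length(orphans)) {
    omem <- stats::setNames(as.list(orphans), paste0("orphan:", orphans))
    members <- c(members, omem)
    subjects <- c(subjects, rep(NA_character_, length(omem)))
    orphans <- character(0)
  }
  if (length(members) == 0L)
    stop("no virtual transcripts: empty best-hit map and include_orphans is FALSE")
  ord <- order(names(members))
  members <- members[ord]
  subjects <- subjects[ord]
  len <- contig_lengths(eligible)
  transcripts <- data.frame(
    vt_id = names(members),
    subject_id = subjects,
    n_contigs = lengths(members),
    total_length = vapply(members, function(m) sum(as.numeric(len[m])), 0),
    stringsAsFactors = FALSE)
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts,
                 members = members,
                 orphans = orphans,
                 short = sort(setdiff(all_contigs$id, eligible$id)),
                 contig_lengths = len),
            class = "virtual_reference")
}

#' @export
print.virtual_reference <- function(x, ...) {
  cat(sprintf(
    "<virtual_reference> m=%d virtual transcripts (%d member contigs), %d orphans, %d below cutoff\n",
    nrow(x$transcripts), sum(x$transcripts$n_contigs),
    length(x$orphans), length(x$short)))
  invisible(x)
}

#' Write the contig-to-transcript reference map
#'
#' One row per contig in the full assembly: its length, its status
#' (\code{member}, \code{orphan} or \code{short}) and, for members, the
#' virtual transcript and subject it belongs to.
#'
#' @param vref a \code{virtual_reference}.
#' @param all_contigs the full \code{contig_set} given to the builder.
#' @param path output TSV path.
#' @export
write_reference_map <- function(vref, all_contigs, path) {
  tr <- vref$transcripts
  vt_of <- stats::setNames(rep(tr$vt_id, tr$n_contigs),
                           unlist(vref$members, use.names = FALSE))
  subj_of <- stats::setNames(tr$subject_id, tr$vt_id)
  status <- ifelse(all_contigs$id %in% names(vt_of), "member",
            ifelse(all_contigs$id %in% vref$orphans, "orphan", "short"))
  df <- data.frame(
    contig_id = all_contigs$id,
    length = all_contigs$length,
    status = status,
    vt_id = ifelse(status == "member", vt_of[all_contigs$id], NA),
    subject_id = ifelse(status == "member",
                        subj_of[vt_of[all_contigs$id]], NA),
    stringsAsFactors = FALSE)
  df <- df[order(df$contig_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

#' Rebuild a virtual reference from a written reference map
#' @param path TSV from \code{\link{write_reference_map}}.
#' @return a \code{virtual_reference}.
#' @export
read_reference_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "", colClasses = c("character", "integer",
                                                   "character", "character",
                                                   "character"))
  mem <- df[df$status == "member", , drop = FALSE]
  if (nrow(mem) == 0L) stop("reference map ", path, " has no member contigs")
  members <- lapply(split(mem$contig_id, mem$vt_id), sort)
  subj <- vapply(split(mem$subject_id, mem$vt_id), function(v) v[1], "")
  ord <- order(names(members))
  members <- members[ord]
  len <- stats::setNames(df$length, df$contig_id)
  transcripts <- data.frame(
    vt_id = names(members),
    subject_id = unname(subj[names(members)]),
    n_contigs = lengths(members),
    total_length = vapply(members, function(m) sum(as.numeric(len[m])), 0),
    stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts,
                 members = members,
                 orphans = sort(df$contig_id[df$status == "orphan"]),
                 short = sort(df$contig_id[df$status == "short"]),
                 contig_lengths = len),
            class = "virtual_reference")
}
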