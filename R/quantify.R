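# Expression measures over a shared virtual reference.
#
# For a dataset d and virtual transcript x with member contigs i = 1..k_x,
# each with length l_{x,i} and mapped reads n_{x,i}:
#
#   RC_j     = n_j                                          (per contig)
#   eRPKM_x  = 1e9 * sum_i n_{x,i} /
#              ( sum_i l_{x,i} * sum_t sum_i n_{t,i} )
#   eTPM_x   = 1e6 * r_x / sum_t r_t,  r_x = sum_i n_{x,i} / sum_i l_{x,i}
#
# The read total in eRPKM's denominator runs over virtual-transcript members
# only (orphan and below-cutoff contigs excluded), exactly as the formula is
# written; a denominator = "all-mapped" mode relaxes this.

#' Per-contig read counts
#'
#' RC is the raw count of reads mapped to each contig; contigs absent from
#' the profile get 0.
#'
#' @param profile a \code{mapping_profile}.
#' @param contigs a \code{contig_set} defining the contig universe.
#' @return data.frame with columns contig_id, rc.
#' @export
compute_rc <- function(profile, contigs) {
  n <- profile$counts[contigs$id]
  n[is.na(n)] <- 0
  data.frame(contig_id = contigs$id, rc = unname(n),
             stringsAsFactors = FALSE)
}

#' Per-contig RPKM
#'
#' \code{rpkm_j = 1e9 * n_j / (l_j * N)} with N the total mapped reads in
#' the profile (all contigs, not just virtual-transcript members — the
#' classic per-contig normalization used for assembly-wide expression
#' overviews).
#'
#' @inheritParams compute_rc
#' @return data.frame with columns contig_id, rc, rpkm.
#' @export
compute_contig_rpkm <- function(profile, contigs) {
  if (profile$total_mapped <= 0)
    stop("no mapped reads in dataset '", profile$dataset_label, "'")
  q <- compute_rc(profile, contigs)
  q$rpkm <- 1e9 * q$rc / (as.numeric(contigs$length) * profile$total_mapped)
  q
}

vt_read_sums <- function(vref, profile) {
  cnt <- profile$counts
  vapply(vref$members, function(m) {
    n <- cnt[m]
    sum(n[!is.na(n)])
  }, 0)
}

#' Estimated RPKM per virtual transcript
#'
#' @param vref a \code{virtual_reference}.
#' @param profile a \code{mapping_profile}.
#' @param denominator \code{"vt-only"} (default; read total over member
#'   contigs of virtual transcripts, as the formula is written) or
#'   \code{"all-mapped"} (total mapped reads in the profile).
#' @return named numeric vector, names are vt ids.
#' @export
compute_erpkm <- function(vref, profile, denominator = c("vt-only", "all-mapped")) {
  denominator <- match.arg(denominator)
  nx <- vt_read_sums(vref, profile)
  N <- if (denominator == "vt-only") sum(nx) else profile$total_mapped
  if (N <= 0)
    stop("no reads mapped to virtual reference (dataset ",
         profile$dataset_label, ")")
  1e9 * nx / (vref$transcripts$total_length * N)
}

#' Estimated TPM per virtual transcript
#'
#' Length-normalized read rates per transcript rescaled so the dataset's
#' values sum to one million; zero-read transcripts get 0 but remain rows.
#'
#' @inheritParams compute_erpkm
#' @return named numeric vector, names are vt ids.
#' @export
compute_etpm <- function(vref, profile) {
  nx <- vt_read_sums(vref, profile)
  if (sum(nx) <= 0)
    stop("no reads mapped to virtual reference (dataset ",
         profile$dataset_label, ")")
  rate <- nx / vref$transcripts$total_length
  1e6 * rate / sum(rate)
}

#' Quantify one dataset against the virtual reference
#'
#' Computes the per-contig view (RC and RPKM) and the per-virtual-transcript
#' view (summed RC, eRPKM, eTPM) consistently from a single mapping profile.
#'
#' @inheritParams compute_erpkm
#' @param contigs a \code{contig_set}; defaults to the lengths recorded in
#'   the reference.
#' @return list with elements \code{contig} (data.frame contig_id, rc, rpkm)
#'   and \code{vt} (data.frame vt_id, rc_sum, erpkm, etpm).
#' @export
quantify_dataset <- function(vref, profile, contigs = NULL,
                             denominator = c("vt-only", "all-mapped")) {
  denominator <- match.arg(denominator)
  if (is.null(contigs)) {
    len <- vref$contig_lengths
    contigs <- contig_set(names(len), unname(len))
  }
  vt <- data.frame(vt_id = vref$transcripts$vt_id,
                   rc_sum = unname(vt_read_sums(vref, profile)),
                   stringsAsFactors = FALSE)
  vt$erpkm <- unname(compute_erpkm(vref, profile, denominator))
  vt$etpm <- unname(compute_etpm(vref, profile))
  list(contig = compute_contig_rpkm(profile, contigs), vt = vt)
}

#' Compare two or more datasets on the shared reference
#'
#' Because every dataset is quantified against the same virtual reference,
#' the rows align and normalized columns are directly comparable; raw RC
#' columns still reflect sequencing depth.
#'
#' @param vref a \code{virtual_reference}.
#' @param profiles list of \code{mapping_profile}s with distinct labels
#'   (two or more).
#' @param contigs optional \code{contig_set} (lengths default to the
#'   reference's record).
#' @param denominator see \code{\link{compute_erpkm}}.
#' @return a \code{quant_table}: data.frame with vtranscript_id, subject_id,
#'   n_contigs, total_length, then rc.<label>, erpkm.<label>, etpm.<label>
#'   per dataset.
#' @export
compare_datasets <- function(vref, profiles, contigs = NULL,
                             denominator = c("vt-only", "all-mapped")) {
  denominator <- match.arg(denominator)
  if (length(profiles) < 2L)
    stop("need at least two mapping profiles to compare")
  labels <- vapply(profiles, function(p) p$dataset_label, "")
  if (anyDuplicated(labels))
    stop("duplicate dataset labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out <- data.frame(vtranscript_id = vref$transcripts$vt_id,
                    subject_id = vref$transcripts$subject_id,
                    n_contigs = vref$transcripts$n_contigs,
                    total_length = vref$transcripts$total_length,
                    stringsAsFactors = FALSE)
  for (p in profiles) {
    q <- quantify_dataset(vref, p, contigs, denominator)$vt
    out[[paste0("rc.", p$dataset_label)]] <- q$rc_sum
    out[[paste0("erpkm.", p$dataset_label)]] <- q$erpkm
    out[[paste0("etpm.", p$dataset_label)]] <- q$etpm
  }
  out <- out[order(out$vtranscript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset_labels") <- unname(labels)
  class(out) <- c("quant_table", "data.frame")
  out
}
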