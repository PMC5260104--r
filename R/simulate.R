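# Self-contained synthetic worlds for testing the whole pipeline offline:
# ground-truth "transcripts" (known homolog subjects with known per-condition
# abundance), contigs fragmented from them, a blast-tab hit file recovering
# the truth, per-condition count files, and a small DAG-shaped ontology.
#
# Abundance is modelled as an integer per-base read rate per transcript and
# condition. In exact mode, counts are that rate times contig length times an
# integer depth factor, so expected eRPKM/eTPM have closed forms that the
# pipeline must reproduce to floating-point accuracy; Poisson mode adds
# counting noise around the same means.

#' Simulate a ground-truth world
#'
#' Draws \code{n_transcripts} homolog subjects with lengths uniform in
#' \code{length_range} and an integer per-base abundance rate (1-20) per
#' condition; fragments each transcript into about
#' \code{mean_contigs_per_transcript} non-overlapping contigs; marks a
#' fraction of contigs as below the 200 bp annotation cutoff and a disjoint
#' fraction as orphans (no homology hit); builds a random single-rooted
#' is_a ontology of \code{n_go_terms} terms and assigns 0-3 terms per
#' subject. Fully determined by \code{seed}.
#'
#' @param n_transcripts number of ground-truth transcripts.
#' @param mean_contigs_per_transcript mean fragmentation (>= 1).
#' @param length_range length 2 integer vector, transcript length bounds bp.
#' @param orphan_fraction fraction of contigs stripped of hits, in [0,1].
#' @param short_fraction fraction of contigs truncated to <= 200 bp, in [0,1].
#' @param n_go_terms ontology size (>= 1; term 1 is the root).
#' @param n_conditions number of conditions with independent rates.
#' @param seed RNG seed.
#' @return object of class \code{fixture_truth}; see
#'   \code{\link{truth_expected}} for its analytic expectations.
#' @export
simulate_world <- function(n_transcripts = 20, mean_contigs_per_transcript = 2,
                           length_range = c(300L, 3000L),
                           orphan_fraction = 0.1, short_fraction = 0.1,
                           n_go_terms = 20, n_conditions = 2, seed = 1) {
  if (n_transcripts < 1 || n_go_terms < 1 || n_conditions < 1)
    stop("counts must be positive")
  if (mean_contigs_per_transcript < 1)
    stop("mean_contigs_per_transcript must be >= 1")
  if (orphan_fraction < 0 || orphan_fraction > 1 ||
      short_fraction < 0 || short_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (length(length_range) != 2 || length_range[1] > length_range[2])
    stop("length_range must be (min, max) with min <= max")
  if (length_range[1] < 250)
    stop("length_range minimum below 250 bp cannot guarantee annotatable fragments")
  set.seed(seed)
  conds <- paste0("cond", seq_len(n_conditions))
  subj <- sprintf("P%04d", seq_len(n_transcripts))
  tlen <- sample(length_range[1]:length_range[2], n_transcripts, replace = TRUE)
  rates <- matrix(sample(1:20, n_transcripts * n_conditions, replace = TRUE),
                  nrow = n_transcripts, dimnames = list(subj, conds))

  # fragmentation: >= 1 contig per transcript, each >= 250 bp where possible
  plan <- list()
  for (i in seq_len(n_transcripts)) {
    L <- tlen[i]
    nf <- 1L + stats::rpois(1, mean_contigs_per_transcript - 1)
    nf <- max(1L, min(nf, L %/% 250L))
    # random composition with a 250 bp floor so no fragment is accidentally
    # below the annotation cutoff; only the explicit short marking is
    extra <- L - 250L * nf
    w <- stats::runif(nf)
    extra_i <- floor(extra * w / sum(w))
    extra_i[nf] <- extra - sum(extra_i[-nf])
    flen <- 250L + as.integer(extra_i)
    starts <- cumsum(c(1L, flen[-nf]))
    plan[[i]] <- data.frame(
      contig_id = sprintf("%s_c%02d", subj[i], seq_len(nf)),
      subject_id = subj[i],
      length = flen,
      offset = as.integer(starts),
      stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, plan)

  nc <- nrow(plan)
  n_short <- floor(short_fraction * nc)
  n_orphan <- floor(orphan_fraction * nc)
  shuffled <- sample(nc)
  short_idx <- shuffled[seq_len(n_short)]
  orphan_idx <- shuffled[n_short + seq_len(n_orphan)]
  plan$is_short <- seq_len(nc) %in% short_idx
  plan$has_hit <- !(seq_len(nc) %in% orphan_idx)
  if (n_short)
    plan$length[short_idx] <- sample(50:200, n_short, replace = TRUE)

  # single-namespace random DAG; every non-root term parented by earlier terms
  go_ids <- sprintf("GO:%07d", seq_len(n_go_terms))
  terms <- data.frame(id = go_ids,
                      name = paste0("synthetic term ", seq_len(n_go_terms)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- NULL
  if (n_go_terms > 1) {
    for (j in 2:n_go_terms) {
      np <- sample(1:min(2, j - 1), 1)
      par <- sample(seq_len(j - 1), np)
      edges <- rbind(edges, data.frame(child = go_ids[j], parent = go_ids[par],
                                       rel = "is_a", stringsAsFactors = FALSE))
    }
  } else {
    edges <- data.frame(child = character(0), parent = character(0),
                        rel = character(0), stringsAsFactors = FALSE)
  }
  n_terms_per_subj <- sample(0:3, n_transcripts, replace = TRUE)
  assoc <- lapply(n_terms_per_subj, function(k)
    if (k == 0) character(0) else sort(sample(go_ids, k)))
  names(assoc) <- subj
  assoc <- assoc[lengths(assoc) > 0]

  structure(list(
    transcripts = data.frame(subject_id = subj, length = tlen,
                             stringsAsFactors = FALSE),
    rates = rates,
    plan = plan,
    go = list(terms = terms, edges = edges),
    assoc = assoc,
    conditions = conds,
    params = list(n_transcripts = n_transcripts,
                  mean_contigs_per_transcript = mean_contigs_per_transcript,
                  length_range = as.integer(length_range),
                  orphan_fraction = orphan_fraction,
                  short_fraction = short_fraction,
                  n_go_terms = n_go_terms,
                  n_conditions = n_conditions),
    seed = seed), class = "fixture_truth")
}

#' Analytic expectations implied by a truth object
#'
#' The pipeline's virtual transcripts are the truth's subjects that keep at
#' least one contig longer than \code{min_length} bp with a hit. With counts
#' exactly proportional to rate x length, per condition:
#' \code{eTPM_x = 1e6 * rate_x / sum(rate_t)} and
#' \code{eRPKM_x = 1e9 * rate_x / sum(rate_t * L_t)} over the surviving
#' transcripts t with member total length L_t.
#'
#' @param truth a \code{fixture_truth}.
#' @param min_length annotation cutoff used downstream (default 200).
#' @return list with \code{members} (named list subject -> member contig
#'   ids), \code{vt_length}, and matrices \code{etpm}, \code{erpkm}
#'   (subject x condition).
#' @export
truth_expected <- function(truth, min_length = 200L) {
  p <- truth$plan
  member <- p$length > min_length & p$has_hit
  mem <- split(p$contig_id[member], p$subject_id[member])
  mem <- lapply(mem, sort)
  vts <- sort(names(mem))
  mem <- mem[vts]
  L <- vapply(vts, function(s)
    sum(as.numeric(p$length[member & p$subject_id == s])), 0)
  r <- truth$rates[vts, , drop = FALSE]
  etpm <- sweep(r, 2, colSums(r), "/") * 1e6
  erpkm <- sweep(r, 2, colSums(r * L), "/") * 1e9
  list(members = mem, vt_length = L, etpm = etpm, erpkm = erpkm)
}

#' Simulate per-condition mapped read counts
#'
#' Per condition, the expected count of contig i from transcript x is
#' proportional to \code{rate_x * length_i} over all contigs (short and
#' orphan contigs also attract reads). Exact mode multiplies rates by the
#' integer factor bringing the total closest to \code{depth} (minimum 1), so
#' counts stay exactly proportional to rate x length and the analytic
#' expectations hold to machine precision; Poisson mode draws
#' \code{Poisson(mu)} around means scaled to \code{depth}.
#'
#' @param truth a \code{fixture_truth}.
#' @param depth target number of mapped reads per condition (> 0). Scalar or
#'   one value per condition.
#' @param noise \code{"exact"} or \code{"poisson"}.
#' @param seed RNG seed (Poisson mode).
#' @return named list of \code{mapping_profile}, one per condition.
#' @export
simulate_counts <- function(truth, depth = 1e5, noise = c("exact", "poisson"),
                            seed = 1) {
  noise <- match.arg(noise)
  if (any(depth <= 0)) stop("depth must be > 0")
  conds <- truth$conditions
  depth <- rep(depth, length.out = length(conds))
  p <- truth$plan
  base <- as.numeric(p$length)   # per-contig length
  profiles <- list()
  for (ci in seq_along(conds)) {
    rate <- truth$rates[p$subject_id, conds[ci]]
    mu <- rate * base
    if (noise == "exact") {
      f <- max(1, round(depth[ci] / sum(mu)))
      counts <- mu * f
    } else {
      set.seed(seed + ci * 1000L)
      counts <- stats::rpois(length(mu), mu * depth[ci] / sum(mu))
    }
    profiles[[conds[ci]]] <- mapping_profile(
      conds[ci], stats::setNames(counts, p$contig_id))
  }
  profiles
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a minimal SAM file realizing a count vector
#'
#' One primary, mapped, position-agnostic record per counted read (fixed
#' CIGAR, no stored sequence), plus a few unmapped and secondary records to
#' exercise flag filtering. Only suitable for small depths.
#'
#' @param profile a \code{mapping_profile}.
#' @param contigs a \code{contig_set} providing reference names/lengths.
#' @param path output SAM path.
#' @param decoys add one unmapped and one secondary record (default TRUE).
#' @export
write_sam_counts <- function(profile, contigs, path, decoys = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, contigs$length), con)
  k <- 0L
  for (cid in names(profile$counts)) {
    n <- profile$counts[[cid]]
    if (n <= 0) next
    qn <- sprintf("r%06d", k + seq_len(n))
    k <- k + n
    writeLines(sprintf("%s\t0\t%s\t1\t60\t50M\t*\t0\t0\t*\t*", qn, cid), con)
  }
  if (decoys && nrow(contigs) > 0) {
    writeLines(sprintf("decoy_unmapped\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), con)
    writeLines(sprintf("decoy_secondary\t256\t%s\t1\t0\t50M\t*\t0\t0\t*\t*",
                       contigs$id[1]), con)
  }
  invisible(path)
}

#' Materialize a truth object as a fixture bundle on disk
#'
#' Writes \code{contigs.fasta}, \code{hits.tsv} (blast-tab, with lower-scored
#' decoy hits so best-hit selection is exercised), one
#' \code{counts_<label>.tsv} per condition, \code{ontology.obo},
#' \code{associations.tsv} and \code{truth.json} (parameters, plan and
#' analytic expectations).
#'
#' @param truth a \code{fixture_truth}.
#' @param out_dir output directory (created if needed).
#' @param depth per-condition target depth, see \code{\link{simulate_counts}}.
#' @param noise \code{"exact"} or \code{"poisson"}.
#' @param seed RNG seed for sequences/decoys and Poisson counts.
#' @return invisibly, a named list of the written paths.
#' @export
emit_fixture_bundle <- function(truth, out_dir, depth = 1e5,
                                noise = c("exact", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- truth$plan
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(p$length, random_dna, ""))
  names(seqs) <- p$contig_id
  contigs <- contig_set(p$contig_id, p$length, sequences = seqs)
  paths <- list(contigs = file.path(out_dir, "contigs.fasta"))
  write_contigs(contigs, paths$contigs)

  hp <- p[p$has_hit, , drop = FALSE]
  mk_hit <- function(q, s, bits, ev, alen) data.frame(
    query_id = q, subject_id = s, percent_identity = 90,
    alignment_length = alen, mismatches = pmax(0L, alen %/% 10L),
    gap_opens = 0L, q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
    e_value = ev, bit_score = bits, stringsAsFactors = FALSE)
  hits <- mk_hit(hp$contig_id, hp$subject_id,
                 bits = 200 + round(runif(nrow(hp)) * 100),
                 ev = 1e-50, alen = pmin(hp$length, 300L))
  # decoy second-best hits to a different subject, strictly lower bit score
  n_decoy <- min(nrow(hp), max(1L, nrow(hp) %/% 3L))
  di <- sample(nrow(hp), n_decoy)
  other <- vapply(hp$subject_id[di], function(s) {
    pool <- setdiff(truth$transcripts$subject_id, s)
    if (length(pool)) sample(pool, 1) else s
  }, "")
  decoys <- mk_hit(hp$contig_id[di], other,
                   bits = hits$bit_score[di] - 50,
                   ev = 1e-20, alen = pmin(hp$length[di], 200L))
  allhits <- rbind(hits, decoys)
  allhits <- allhits[sample(nrow(allhits)), , drop = FALSE]
  class(allhits) <- c("homology_hits", "data.frame")
  paths$hits <- file.path(out_dir, "hits.tsv")
  write_hits(allhits, paths$hits)

  profiles <- simulate_counts(truth, depth = depth, noise = noise, seed = seed)
  for (lab in names(profiles)) {
    f <- file.path(out_dir, paste0("counts_", lab, ".tsv"))
    cnt <- profiles[[lab]]$counts
    write.table(data.frame(id = names(cnt), n = unname(cnt)), f, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[[paste0("counts_", lab)]] <- f
  }

  dag <- go_dag(truth$go$terms, truth$go$edges)
  paths$obo <- file.path(out_dir, "ontology.obo")
  write_obo(dag, paths$obo)
  paths$assoc <- file.path(out_dir, "associations.tsv")
  write_associations(structure(truth$assoc, class = "go_association"),
                     paths$assoc)

  exp <- truth_expected(truth)
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    params = truth$params, seed = truth$seed,
    conditions = truth$conditions,
    transcripts = truth$transcripts,
    rates = as.data.frame(truth$rates),
    plan = truth$plan,
    expected = list(vt_ids = names(exp$members),
                    vt_length = exp$vt_length,
                    etpm = as.data.frame(exp$etpm),
                    erpkm = as.data.frame(exp$erpkm))),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
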