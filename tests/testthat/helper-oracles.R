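# Independent oracles, deliberately written as literal loops/nested sums so
# they share no code path with the package implementation.

# eRPKM as the formula reads: 1e9 * sum_i n_xi / (sum_i l_xi * sum_t sum_i n_ti)
# members: named list vt -> contig ids; len/cnt: named vectors per contig.
oracle_erpkm <- function(members, len, cnt) {
  grand <- 0
  for (t in names(members)) for (i in members[[t]]) grand <- grand + cnt[[i]]
  out <- numeric(0)
  for (x in names(members)) {
    nsum <- 0; lsum <- 0
    for (i in members[[x]]) {
      nsum <- nsum + cnt[[i]]
      lsum <- lsum + len[[i]]
    }
    out[[x]] <- 1e9 * nsum / (lsum * grand)
  }
  out
}

oracle_etpm <- function(members, len, cnt) {
  rates <- numeric(0)
  for (x in names(members)) {
    nsum <- 0; lsum <- 0
    for (i in members[[x]]) {
      nsum <- nsum + cnt[[i]]
      lsum <- lsum + len[[i]]
    }
    rates[[x]] <- nsum / lsum
  }
  out <- numeric(0)
  for (x in names(members)) out[[x]] <- 1e6 * rates[[x]] / sum(rates)
  out
}

# per-contig argmax over hit rows: max bit score, then min e-value, then
# lexicographically smallest subject
oracle_best_hit <- function(hits) {
  best <- list()
  for (r in seq_len(nrow(hits))) {
    q <- hits$query_id[r]
    cand <- list(subject = hits$subject_id[r],
                 e = hits$e_value[r], bits = hits$bit_score[r])
    cur <- best[[q]]
    if (is.null(cur) ||
        cand$bits > cur$bits ||
        (cand$bits == cur$bits && cand$e < cur$e) ||
        (cand$bits == cur$bits && cand$e == cur$e &&
         cand$subject < cur$subject)) {
      best[[q]] <- cand
    }
  }
  best
}

# plain queue BFS from each root over child->parent edge table; no igraph
oracle_bfs_levels <- function(terms, edges, roots) {
  children_of <- split(edges$child, edges$parent)
  lev <- stats::setNames(rep(NA_integer_, nrow(terms)), terms$id)
  for (root in roots) {
    queue <- root
    lev[root] <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (ch in children_of[[v]]) {
        if (is.na(lev[ch]) || lev[ch] > lev[v] + 1L) {
          lev[ch] <- lev[v] + 1L
          queue <- c(queue, ch)
        }
      }
    }
  }
  lev
}

# naive line-by-line SAM counting with the same flag filter (mapped,
# not secondary 0x100, not supplementary 0x800)
oracle_sam_count <- function(path) {
  counts <- list()
  for (line in readLines(path)) {
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    if (bitwAnd(flag, 256L) != 0L) next
    if (bitwAnd(flag, 2048L) != 0L) next
    rn <- f[3]
    counts[[rn]] <- (counts[[rn]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# transitive ancestor closure by repeated parent lookup on the edge table
oracle_closure <- function(edges, term_set) {
  parents_of <- split(edges$parent, edges$child)
  out <- character(0)
  queue <- term_set
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, parents_of[[t]] %||% character(0))
  }
  sort(unique(out))
}

# ---- fixture builders ------------------------------------------------------

# the worked two-transcript example used throughout:
# VT A = {c1: 1000 bp / 100 reads, c2: 500 bp / 50 reads}
# VT B = {c3: 2000 bp / 300 reads}
toy_world <- function() {
  contigs <- contig_set(c("c1", "c2", "c3"), c(1000L, 500L, 2000L))
  best <- data.frame(contig_id = c("c1", "c2", "c3"),
                     subject_id = c("A", "A", "B"),
                     e_value = 1e-50, bit_score = 200,
                     stringsAsFactors = FALSE)
  class(best) <- c("best_hit_map", "data.frame")
  vref <- build_virtual_transcripts(best, contigs, contigs)
  profile <- mapping_profile("d1", c(c1 = 100, c2 = 50, c3 = 300))
  list(contigs = contigs, vref = vref, profile = profile,
       members = list(A = c("c1", "c2"), B = "c3"),
       len = c(c1 = 1000, c2 = 500, c3 = 2000),
       cnt = c(c1 = 100, c2 = 50, c3 = 300))
}

# random small quantification fixture: m VTs with random member counts,
# lengths and reads; guarantees >= 1 mapped read overall
random_quant_fixture <- function(m, seed) {
  set.seed(seed)
  members <- list()
  len <- numeric(0); cnt <- numeric(0)
  cid <- 0
  for (x in seq_len(m)) {
    k <- sample(1:4, 1)
    ids <- sprintf("c%03d", cid + seq_len(k)); cid <- cid + k
    members[[sprintf("S%03d", x)]] <- ids
    len[ids] <- sample(201:5000, k, replace = TRUE)
    cnt[ids] <- sample(0:500, k, replace = TRUE)
  }
  if (sum(cnt) == 0) cnt[1] <- 1
  contigs <- contig_set(names(len), unname(len))
  best <- data.frame(
    contig_id = unlist(members, use.names = FALSE),
    subject_id = rep(names(members), lengths(members)),
    e_value = 1e-10, bit_score = 100, stringsAsFactors = FALSE)
  class(best) <- c("best_hit_map", "data.frame")
  vref <- build_virtual_transcripts(best, contigs, contigs)
  profile <- mapping_profile("rand", cnt)
  list(vref = vref, contigs = contigs, profile = profile,
       members = members, len = len, cnt = cnt)
}

# tiny 5-term diamond ontology: T0 root; T1,T2 -> T0; T3 -> T1,T2; T4 -> T3
diamond_dag <- function() {
  terms <- data.frame(
    id = paste0("GO:000000", 0:4),
    name = paste("term", 0:4),
    namespace = "biological_process", stringsAsFactors = FALSE)
  edges <- data.frame(
    child = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000003",
              "GO:0000004"),
    parent = c("GO:0000000", "GO:0000000", "GO:0000001", "GO:0000002",
               "GO:0000003"),
    rel = "is_a", stringsAsFactors = FALSE)
  go_dag(terms, edges)
}
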