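# Frozen expected values for the worked two-transcript example, evaluated by
# hand from the formulas:
#   eRPKM_A = 1e9*150/(1500*450), eRPKM_B = 1e9*300/(2000*450)
#   rate_A = 150/1500 = 0.1, rate_B = 300/2000 = 0.15
#   eTPM_A = 1e6*0.1/0.25 = 400000, eTPM_B = 600000
TOY_ERPKM <- c(A = 1e9 * 150 / (1500 * 450), B = 1e9 * 300 / (2000 * 450))
TOY_ETPM <- c(A = 400000, B = 600000)

test_that("compute_rc is identity on counts with zero fill", {
  cs <- contig_set(c("c1", "c2", "c3"), c(100L, 100L, 100L))
  p <- mapping_profile("d", c(c1 = 100, c2 = 50))
  expect_equal(compute_rc(p, cs)$rc, c(100, 50, 0))
  p0 <- mapping_profile("d", numeric(0))
  expect_equal(compute_rc(p0, cs)$rc, c(0, 0, 0))
})

test_that("per-contig RPKM matches hand value and is scale invariant", {
  cs <- contig_set(c("c1", "c2"), c(1000L, 500L))
  p <- mapping_profile("d", c(c1 = 100, c2 = 1e6 - 100))
  q <- compute_contig_rpkm(p, cs)
  expect_equal(q$rpkm[1], 100.0)  # 1e9*100/(1000*1e6)
  p2 <- mapping_profile("d", p$counts * 2)
  expect_equal(compute_contig_rpkm(p2, cs)$rpkm, q$rpkm)
  p0 <- mapping_profile("d", c(c1 = 0, c2 = 0))
  expect_error(compute_contig_rpkm(p0, cs), "no mapped reads")
})

test_that("worked example: eRPKM and eTPM match frozen values and oracle", {
  w <- toy_world()
  er <- compute_erpkm(w$vref, w$profile)
  et <- compute_etpm(w$vref, w$profile)
  expect_equal(er[["A"]], TOY_ERPKM[["A"]], tolerance = 1e-9)
  expect_equal(er[["B"]], TOY_ERPKM[["B"]], tolerance = 1e-9)
  expect_equal(et[["A"]], TOY_ETPM[["A"]], tolerance = 1e-9)
  expect_equal(et[["B"]], TOY_ETPM[["B"]], tolerance = 1e-9)
  o_er <- oracle_erpkm(w$members, w$len, w$cnt)
  o_et <- oracle_etpm(w$members, w$len, w$cnt)
  expect_equal(unname(er[names(o_er)]), unname(unlist(o_er)),
               tolerance = 1e-12)
  expect_equal(unname(et[names(o_et)]), unname(unlist(o_et)),
               tolerance = 1e-12)
})

test_that("degenerate cases: single VT, zero-read VT, orphan-only reads", {
  cs <- contig_set(c("c1", "c2"), c(1000L, 500L))
  best <- data.frame(contig_id = "c1", subject_id = "A",
                     e_value = 1e-9, bit_score = 50, stringsAsFactors = FALSE)
  vref <- build_virtual_transcripts(best, cs, cs)
  p <- mapping_profile("d", c(c1 = 123))
  expect_equal(compute_etpm(vref, p)[["A"]], 1e6)           # self-normalizes
  expect_equal(compute_erpkm(vref, p)[["A"]], 1e9 / 1000)   # reads cancel

  # reads only on the orphan contig -> zero denominator, hard error
  p_orph <- mapping_profile("d", c(c2 = 50))
  expect_error(compute_etpm(vref, p_orph), "no reads mapped")
  expect_error(compute_erpkm(vref, p_orph), "no reads mapped")

  # a zero-read VT stays in the table at 0
  best2 <- rbind(best, data.frame(contig_id = "c2", subject_id = "B",
                                  e_value = 1e-9, bit_score = 50))
  vref2 <- build_virtual_transcripts(best2, cs, cs)
  et <- compute_etpm(vref2, p)
  expect_equal(et[["B"]], 0)
  expect_equal(sum(et), 1e6)
})

test_that("implementation equals nested-sum oracle on random small fixtures", {
  for (seed in 1:20) {
    fx <- random_quant_fixture(m = sample(1:5, 1), seed = seed)
    er <- compute_erpkm(fx$vref, fx$profile)
    et <- compute_etpm(fx$vref, fx$profile)
    o_er <- unlist(oracle_erpkm(fx$members, fx$len, fx$cnt))
    o_et <- unlist(oracle_etpm(fx$members, fx$len, fx$cnt))
    expect_equal(unname(er[names(o_er)]), unname(o_er), tolerance = 1e-12)
    expect_equal(unname(et[names(o_et)]), unname(o_et), tolerance = 1e-12)
  }
})

test_that("quantify_dataset combines views consistently; RC conserved", {
  w <- toy_world()
  # add an orphan and a short contig carrying reads
  cs <- contig_set(c("c1", "c2", "c3", "c4", "c5"),
                   c(1000L, 500L, 2000L, 400L, 150L))
  el <- filter_annotatable(cs)
  best <- data.frame(contig_id = c("c1", "c2", "c3"),
                     subject_id = c("A", "A", "B"),
                     e_value = 1e-50, bit_score = 200,
                     stringsAsFactors = FALSE)
  vref <- build_virtual_transcripts(best, el, cs)
  p <- mapping_profile("d1", c(c1 = 100, c2 = 50, c3 = 300, c4 = 7, c5 = 3))
  out <- quantify_dataset(vref, p, cs)
  expect_equal(out$vt$rc_sum, c(150, 300))
  # orphan/short reads visible per contig but absent from VT records
  expect_equal(out$contig$rc[out$contig$contig_id == "c4"], 7)
  expect_equal(sum(out$vt$rc_sum) +
                 sum(out$contig$rc[out$contig$contig_id %in% c("c4", "c5")]),
               p$total_mapped)
  # eRPKM denominator excludes orphan/short reads (450, not 460)
  expect_equal(out$vt$erpkm[out$vt$vt_id == "A"], TOY_ERPKM[["A"]],
               tolerance = 1e-12)
  # all-mapped mode uses the full profile total
  out2 <- quantify_dataset(vref, p, cs, denominator = "all-mapped")
  expect_equal(out2$vt$erpkm[out2$vt$vt_id == "A"],
               1e9 * 150 / (1500 * 460), tolerance = 1e-12)
})

test_that("split invariance: splitting a member contig changes nothing", {
  for (seed in 1:5) {
    fx <- random_quant_fixture(m = 4, seed = seed)
    # split the first member contig of the first VT into two pieces
    vt1 <- names(fx$members)[1]
    cid <- fx$members[[vt1]][1]
    l <- fx$len[[cid]]; n <- fx$cnt[[cid]]
    l1 <- max(1, floor(l / 3)); l2 <- l - l1
    n1 <- floor(n / 2); n2 <- n - n1
    len2 <- c(fx$len[setdiff(names(fx$len), cid)],
              stats::setNames(c(l1, l2), c("sp1", "sp2")))
    cnt2 <- c(fx$cnt[setdiff(names(fx$cnt), cid)],
              stats::setNames(c(n1, n2), c("sp1", "sp2")))
    members2 <- fx$members
    members2[[vt1]] <- c(setdiff(members2[[vt1]], cid), "sp1", "sp2")
    cs2 <- contig_set(names(len2), unname(len2))
    best2 <- data.frame(
      contig_id = unlist(members2, use.names = FALSE),
      subject_id = rep(names(members2), lengths(members2)),
      e_value = 1e-10, bit_score = 100, stringsAsFactors = FALSE)
    vref2 <- build_virtual_transcripts(best2, cs2, cs2)
    p2 <- mapping_profile("rand", cnt2)
    er1 <- compute_erpkm(fx$vref, fx$profile)
    er2 <- compute_erpkm(vref2, p2)
    et1 <- compute_etpm(fx$vref, fx$profile)
    et2 <- compute_etpm(vref2, p2)
    expect_equal(er1[sort(names(er1))], er2[sort(names(er2))],
                 tolerance = 1e-12)
    expect_equal(et1[sort(names(et1))], et2[sort(names(et2))],
                 tolerance = 1e-12)
  }
})

test_that("scale invariance: c*counts fixes eRPKM/eTPM, scales RC", {
  fx <- random_quant_fixture(m = 6, seed = 31)
  p7 <- mapping_profile(fx$profile$dataset_label, fx$profile$counts * 7)
  expect_equal(compute_erpkm(fx$vref, p7), compute_erpkm(fx$vref, fx$profile),
               tolerance = 1e-12)
  expect_equal(compute_etpm(fx$vref, p7), compute_etpm(fx$vref, fx$profile),
               tolerance = 1e-12)
  q1 <- quantify_dataset(fx$vref, fx$profile)$vt
  q7 <- quantify_dataset(fx$vref, p7)$vt
  expect_equal(q7$rc_sum, 7 * q1$rc_sum)
})

test_that("compare_datasets: depth-scaled profiles give equal normalized columns", {
  w <- toy_world()
  p10 <- mapping_profile("d2", w$profile$counts * 10)
  q <- compare_datasets(w$vref, list(w$profile, p10), w$contigs)
  expect_equal(q$erpkm.d1, q$erpkm.d2, tolerance = 1e-12)
  expect_equal(q$etpm.d1, q$etpm.d2, tolerance = 1e-12)
  expect_equal(q$rc.d2, 10 * q$rc.d1)

  # dataset with zero reads on VT B
  pB0 <- mapping_profile("d3", c(c1 = 10, c2 = 10))
  q2 <- compare_datasets(w$vref, list(w$profile, pB0), w$contigs)
  expect_equal(q2$etpm.d3[q2$vtranscript_id == "A"], 1e6)
  expect_equal(q2$etpm.d3[q2$vtranscript_id == "B"], 0)

  # three profiles accepted; duplicate labels rejected
  q3 <- compare_datasets(w$vref, list(w$profile, p10, pB0), w$contigs)
  expect_length(attr(q3, "dataset_labels"), 3)
  expect_error(compare_datasets(w$vref, list(w$profile, w$profile)),
               "duplicate")
})
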