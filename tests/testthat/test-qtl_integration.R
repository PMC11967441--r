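chr_small <- c(c1 = 100000, c2 = 80000)

test_that("interval validation: swaps, duplicates, unknown chromosomes", {
  qtl <- data.frame(qtl_id = c("q1", "q2", "q3"),
                    study_id = c("s1", "s2", "s1"),
                    chrom = "c1", start = c(500, 100, 100),
                    end = c(100, 400, 400), stringsAsFactors = FALSE)
  expect_warning(v <- build_intervals(qtl, chr_small), "swapped")
  expect_equal(v$start[v$qtl_id == "q1"], 100)
  expect_equal(v$end[v$qtl_id == "q1"], 500)
  dup <- qtl[c(2, 2, 3), ]
  expect_warning(v2 <- build_intervals(dup, chr_small), "duplicate")
  expect_equal(nrow(v2), 2)
  bad <- qtl; bad$chrom <- c("c1", "cX", "c1")
  expect_error(build_intervals(bad, chr_small), "cX")
  miss <- data.frame(qtl_id = c("q1", "q2"), study_id = c("s1", "s2"),
                     chrom = "c1", start = c(100, NA), end = c(400, 500),
                     stringsAsFactors = FALSE)
  expect_warning(v3 <- build_intervals(miss, chr_small), "missing")
  expect_equal(attr(v3, "n_skipped"), 1)
})

test_that("worked hotspot example: overlap merges, singleton dropped", {
  qtl <- data.frame(qtl_id = c("q1", "q2", "q3"),
                    study_id = c("S1", "S2", "S1"),
                    chrom = "c1",
                    start = c(1, 50, 200), end = c(100, 150, 300),
                    stringsAsFactors = FALSE)
  hs <- merge_hotspots(qtl)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start, 1)
  expect_equal(hs$end, 150)
  expect_equal(hs$support, 2)
  expect_setequal(strsplit(hs$members, ",")[[1]], c("q1", "q2"))
  # single study only: no hotspots when distinct studies required
  one <- qtl; one$study_id <- "S1"
  expect_equal(nrow(merge_hotspots(one)), 0)
  expect_equal(nrow(merge_hotspots(one, require_distinct_studies = FALSE)), 1)
})

test_that("abutting intervals do not merge; 1 bp of overlap does", {
  qtl <- data.frame(qtl_id = c("a", "b", "c", "d"),
                    study_id = c("s1", "s2", "s1", "s2"),
                    chrom = "c1",
                    start = c(100, 201, 500, 600), end = c(200, 300, 600, 700),
                    stringsAsFactors = FALSE)
  hs <- merge_hotspots(qtl)
  # a/b abut (end + 1 = start): not merged; c/d share bp 600: merged
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start, 500)
  expect_equal(hs$end, 700)
})

test_that("hotspot merging is idempotent and order-invariant", {
  set.seed(10)
  inst <- random_instance(10)
  hs <- merge_hotspots(inst$qtl)
  # order invariance
  perm <- inst$qtl[sample(nrow(inst$qtl)), ]
  hs_p <- merge_hotspots(perm)
  expect_equal(hs[, c("chrom", "start", "end", "support")],
               hs_p[, c("chrom", "start", "end", "support")])
  # idempotence: treating hotspots as intervals and re-merging changes nothing
  if (nrow(hs) > 0) {
    again <- data.frame(qtl_id = hs$hotspot_id, study_id = "x",
                        chrom = hs$chrom, start = hs$start, end = hs$end,
                        stringsAsFactors = FALSE)
    re <- merge_hotspots(again, min_support = 1,
                         require_distinct_studies = FALSE)
    expect_equal(re[, c("chrom", "start", "end")],
                 hs[, c("chrom", "start", "end")])
  }
})

test_that("QTN windows: arithmetic, clamping, width bound", {
  qtn <- data.frame(qtn_id = c("n1", "n2", "n3"), chrom = "c1",
                    pos = c(50000, 40000 / 100, 99990),
                    stringsAsFactors = FALSE)
  w <- qtn_flanks(qtn, flank = 10000, chrom_lengths = chr_small)
  expect_equal(w$start, c(40000, 1, 89990))
  expect_equal(w$end, c(60000, 10400, 100000))
  expect_true(all(w$end - w$start + 1 <= 2 * 10000 + 1))
  # the 100 kb default gives a 200 kb window
  w2 <- qtn_flanks(data.frame(qtn_id = "n", chrom = "c", pos = 150000),
                   chrom_lengths = c(c = 1e6))
  expect_equal(c(w2$start, w2$end), c(50000, 250000))
  expect_error(qtn_flanks(data.frame(qtn_id = "n", chrom = "c", pos = 2e6),
                          chrom_lengths = c(c = 1e6)), "outside")
})

test_that("gene-region overlap: membership rules and name mismatch error", {
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = c("c1", "c2"),
                    start = c(149900, 100), end = c(151000, 200),
                    stringsAsFactors = FALSE)
  regions <- data.frame(region_id = "r1", chrom = "c1",
                        start = 50000, end = 250000, stringsAsFactors = FALSE)
  ov <- overlap_genes(ann, regions)
  expect_equal(ov$gene_id, "g1")
  bad <- data.frame(region_id = "r1", chrom = "chrom_1",
                    start = 1, end = 10, stringsAsFactors = FALSE)
  expect_error(overlap_genes(ann, bad), "chrom_1")
})

test_that("interval operations agree with the per-bp oracle on random instances", {
  n_instances <- 150
  for (s in seq_len(n_instances)) {
    inst <- random_instance(s, max_len = 1e5)
    hs <- merge_hotspots(inst$qtl)
    oracle <- bp_hotspots(inst$qtl, inst$chrom_lengths)
    expect_equal(nrow(hs), nrow(oracle))
    if (nrow(hs) > 0) {
      ord <- order(hs$chrom, hs$start)
      expect_equal(hs$chrom[ord], oracle$chrom)
      expect_equal(hs$start[ord], oracle$start)
      expect_equal(hs$end[ord], oracle$end)
      expect_equal(hs$support[ord], oracle$support)
      expect_equal(vapply(strsplit(hs$members[ord], ","),
                          function(x) paste(sort(x), collapse = ","),
                          character(1)),
                   oracle$members)
    }
    # gene-window overlap equivalence on a subsample of instances
    if (s <= 60) {
      w <- qtn_flanks(inst$qtn, flank = 5000, chrom_lengths = inst$chrom_lengths)
      w_id <- w; names(w_id)[names(w_id) == "qtn_id"] <- "region_id"
      ov <- overlap_genes(inst$annotation, w_id)
      ov_o <- bp_overlap(inst$annotation, w_id)
      key <- function(d) sort(paste(d$gene_id, d$region_id))
      expect_equal(key(ov), key(ov_o))
      # candidate predicate equivalence
      degs <- inst$annotation$gene_id
      cand <- suppressWarnings(
        call_candidates(degs, hs, w, inst$annotation))
      oracle_cand <- bp_candidates(degs, hs, w, inst$annotation)
      expect_equal(sort(cand$gene_id), oracle_cand$tier1)
      expect_equal(sort(cand$gene_id[cand$common_region]), oracle_cand$common)
    }
  }
})

test_that("common-region predicate distinguishes same-hotspot from any-hotspot", {
  # hotspot c1:1-500000 with a QTN at 400000; windows are +/- 100 kb
  hs <- data.frame(hotspot_id = "H1", chrom = "c1", start = 1, end = 500000,
                   support = 2L, n_studies = 2L, members = "q1,q2",
                   stringsAsFactors = FALSE)
  w <- qtn_flanks(data.frame(qtn_id = "n1", chrom = "c1", pos = 400000),
                  chrom_lengths = c(c1 = 1e6))
  ann <- data.frame(gene_id = c("near", "far"), chrom = "c1",
                    start = c(310000, 120000), end = c(312000, 121000),
                    stringsAsFactors = FALSE)
  cand <- call_candidates(c("near", "far"), hs, w, ann)
  expect_setequal(cand$gene_id, c("near", "far"))  # both tier 1 via hotspot
  expect_true(cand$common_region[cand$gene_id == "near"])
  expect_false(cand$common_region[cand$gene_id == "far"])
  # no QTNs: never common-region
  w0 <- qtn_flanks(data.frame(qtn_id = character(), chrom = character(),
                              pos = numeric()), chrom_lengths = c(c1 = 1e6))
  cand0 <- call_candidates(c("near", "far"), hs, w0, ann)
  expect_false(any(cand0$common_region))
  # common-region candidates are a subset of tier 1, which is within the DEGs
  expect_true(all(cand$gene_id[cand$common_region] %in% cand$gene_id))
  expect_true(all(cand$gene_id %in% c("near", "far")))
})

test_that("round trip: planted hotspots and tier counts recovered from truth", {
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 300, libsize_range = c(3e5, 5e5), seed = 3000 + s)
    maps <- simulate_genetic_maps(cfg)
    sim <- simulate_experiment(cfg)
    v <- build_intervals(maps$qtl, cfg$chrom_lengths)
    hs <- merge_hotspots(v)
    planted <- maps$truth$hotspots
    expect_equal(nrow(hs), length(planted))
    for (h in planted) {
      hit <- hs[hs$chrom == h$chrom & hs$start == h$start & hs$end == h$end, ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$support, h$support)
      expect_setequal(strsplit(hit$members, ",")[[1]], h$members)
    }
    # tier counts equal truth-derived counts from the brute-force predicate
    w <- qtn_flanks(maps$qtn, cfg$qtn_flank, cfg$chrom_lengths)
    degs <- sample(sim$annotation$gene_id, 150)
    cand <- suppressWarnings(call_candidates(degs, hs, w, sim$annotation))
    oracle <- bp_candidates(degs, hs, w, sim$annotation)
    cnt <- attr(cand, "counts")
    expect_equal(unname(cnt["n_tier1"]), length(oracle$tier1))
    expect_equal(unname(cnt["n_common_region"]), length(oracle$common))
  }
})

test_that("TF annotation tallies families and leaves non-TFs unannotated", {
  cand <- data.frame(gene_id = c("g1", "g2", "g3"),
                     in_hotspot = c("H1", "", "H2"),
                     in_qtn_window = c("", "n1", "n2"),
                     common_region = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  tf <- data.frame(gene_id = c("g1", "g3"), family = c("SBP", "AP2/EREBP"),
                   stringsAsFactors = FALSE)
  ann <- annotate_tfs(cand, tf)
  expect_equal(ann$candidates$tf_family, c("SBP", NA, "AP2/EREBP"))
  expect_equal(unname(ann$tally[c("AP2/EREBP", "SBP")]), c(1L, 1L),
               ignore_attr = TRUE)
  # empty TF table: nothing annotated
  none <- annotate_tfs(cand, tf[0, ])
  expect_true(all(is.na(none$candidates$tf_family)))
  # per-stage directional tally partitions the annotated TFs
  dirs <- data.frame(gene_id = c("g1", "g1", "g3"),
                     stage = c("V6", "V7", "V6"),
                     direction = c("up", "up", "down"),
                     stringsAsFactors = FALSE)
  tal <- annotate_tfs(cand, tf, dirs)$tally
  expect_equal(sum(tal), 3)
})

test_that("overlapping windows are kept separate per QTN", {
  qtn <- data.frame(qtn_id = c("n1", "n2"), chrom = "c1",
                    pos = c(50000, 52000), stringsAsFactors = FALSE)
  w <- qtn_flanks(qtn, flank = 10000, chrom_lengths = chr_small)
  expect_equal(nrow(w), 2)    # not merged despite 18 kb of shared span
})
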