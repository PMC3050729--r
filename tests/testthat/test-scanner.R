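# The moving-average scanner, probe scoring and site calling.

test_that("a 14-bp sequence under a constant table has one window with that score", {
  arr <- build_dense_array(uniform_table(0.2))
  prof <- score_profile(random_dna(14, seed = 1), arr, scan_config(window = 7))
  expect_length(prof$score, 1)
  expect_equal(prof$score, 0.2)
  expect_identical(prof$window_start, 0L)
})

test_that("profiles equal the naive per-window recomputation", {
  tab <- random_symmetric_table(31)
  arr <- build_dense_array(tab)
  # the spec'd two-window case
  s <- random_dna(15, seed = 2)
  prof <- score_profile(s, arr, scan_config(window = 7))
  expect_length(prof$score, 2)
  expect_equal(prof$score, oracle_profile(s, tab, 7), tolerance = 1e-12)
  # random lengths and window sizes
  set.seed(3)
  for (i in 1:25) {
    W <- sample(1:8, 1)
    s <- random_dna(sample((W + 7):60, 1))
    prof <- score_profile(s, arr, scan_config(window = W))
    expect_equal(prof$score, oracle_profile(s, tab, W), tolerance = 1e-12)
  }
})

test_that("too-short sequences fail with the minimum length named", {
  arr <- build_dense_array(uniform_table())
  expect_error(score_profile(random_dna(13, seed = 4), arr,
                             scan_config(window = 7)),
               "minimum length 14")
  expect_error(score_probe("ACGTACG", arr), "shorter than 8")
})

test_that("windows overlapping ambiguity codes are masked", {
  tab <- random_symmetric_table(32)
  arr <- build_dense_array(tab)
  s <- paste0(random_dna(20, seed = 5), "N", random_dna(20))
  prof <- score_profile(s, arr, scan_config(window = 7))
  expect_identical(is.na(prof$score), !prof$valid)
  expect_equal(prof$score[prof$valid],
               oracle_profile(s, tab, 7)[prof$valid], tolerance = 1e-12)
  # the N sits at offset 21: windows starting 8..21 (1-based) overlap it
  expect_true(all(!prof$valid[8:21]))
  expect_true(all(prof$valid[c(1:7, 22:length(prof$valid))]))
})

test_that("skip_masked excludes soft-masked windows", {
  arr <- build_dense_array(uniform_table(0.3))
  s <- strrep("ACGT", 10)
  mask <- rep(FALSE, 40); mask[20] <- TRUE
  cfg <- scan_config(window = 7, skip_masked = TRUE)
  prof <- score_profile(s, arr, cfg, softmask = mask)
  touching <- prof$window_start + 1 <= 20 & prof$window_start + 14 >= 20
  expect_identical(prof$valid, !touching)
  # same scan without the flag keeps every window
  prof2 <- score_profile(s, arr, scan_config(window = 7), softmask = mask)
  expect_true(all(prof2$valid))
})

test_that("probe scores match brute force and obey the mean<=max invariant", {
  tab <- random_symmetric_table(33)
  arr <- build_dense_array(tab)
  ut <- build_dense_array(uniform_table(0.3))
  ps <- score_probe(random_dna(20, seed = 6), ut)
  expect_equal(ps$max_escore, 0.3)
  expect_equal(ps$pbm_mapping_score, 0.3)
  set.seed(7)
  for (i in 1:25) {
    s <- random_dna(30)
    ps <- score_probe(s, arr, scan_config(window = 7))
    or <- oracle_probe(s, tab, 7)
    expect_equal(ps$max_escore, or$max_escore, tolerance = 1e-12)
    expect_equal(ps$pbm_mapping_score, or$pbm_mapping_score, tolerance = 1e-12)
    expect_lte(ps$pbm_mapping_score, ps$max_escore + 1e-12)
  }
  # probe shorter than a full window: mapping score undefined and flagged
  ps <- score_probe(random_dna(10, seed = 8), arr, scan_config(window = 7))
  expect_false(ps$has_window)
  expect_true(is.na(ps$pbm_mapping_score))
})

test_that("profiles are reverse-complement invariant", {
  tab <- random_symmetric_table(34)
  arr <- build_dense_array(tab)
  set.seed(9)
  for (i in 1:20) {
    W <- sample(1:8, 1)
    s <- random_dna(sample((W + 7):50, 1))
    fwd <- score_profile(s, arr, scan_config(window = W))$score
    rev <- score_profile(reverse_complement(s), arr,
                         scan_config(window = W))$score
    expect_equal(rev, rev(fwd), tolerance = 1e-12)
  }
})

test_that("raising one octamer score never lowers any window or probe score", {
  tab <- random_symmetric_table(35)
  set.seed(10)
  for (i in 1:5) {
    s <- random_dna(40)
    base <- score_profile(s, build_dense_array(tab), scan_config(window = 7))
    oct <- substr(s, 12, 19)                 # an octamer present in s
    tab2 <- tab
    bump <- 0.5 - tab2$scores[[oct]]
    tab2$scores[[oct]] <- 0.5
    tab2$scores[[reverse_complement(oct)]] <- 0.5
    after <- score_profile(s, build_dense_array(tab2), scan_config(window = 7))
    expect_true(all(after$score - base$score >= -1e-12, na.rm = TRUE))
    expect_gte(bump, 0 - 1)                  # sanity: bump defined
  }
})

test_that("site calling merges runs, spans all window bases and sorts output", {
  res <- make_table()
  arr <- build_dense_array(res$table)
  g <- make_genome(res$table, seed = 17)
  cfg <- scan_config(window = 7, threshold = 0.37)
  sites <- call_sites(g$records, arr, cfg)
  # every planted site recovered, every call overlaps a plant
  man <- g$manifest[g$manifest$supra, ]
  hits <- vapply(seq_len(nrow(man)), function(i)
    any(sites$start < man$end[i] & sites$end > man$start[i]), logical(1))
  expect_true(all(hits))
  covered <- vapply(seq_len(nrow(sites)), function(i)
    any(man$start < sites$end[i] & man$end > sites$start[i]), logical(1))
  expect_true(all(covered))
  expect_true(all(sites$end - sites$start >= 7 + 7))
  expect_true(all(sites$peak_score > 0.37))
  expect_false(is.unsorted(sites$start))

  # all scores below threshold: no calls
  high <- scan_config(window = 7, threshold = 0.49)
  expect_identical(nrow(call_sites(g$records, arr, high)), 0L)

  # degenerate threshold -0.5 on clean sequence: one site spanning all windows
  s <- random_dna(60, seed = 11)
  all_sites <- call_sites(c(chrA = s), arr,
                          scan_config(window = 7, threshold = -0.5))
  expect_identical(nrow(all_sites), 1L)
  expect_identical(all_sites$start, 0L)
  expect_identical(all_sites$end, 60L)
})

test_that("chunked scanning reproduces the whole-sequence scan exactly", {
  res <- make_table()
  arr <- build_dense_array(res$table)
  g <- make_genome(res$table, seed = 18)
  cfg <- scan_config(window = 7, threshold = 0.37)
  whole <- call_sites(g$records, arr, cfg)
  for (cs in c(137, 1000, 4096)) {
    chunked <- call_sites(g$records, arr, cfg, chunk_size = cs)
    expect_identical(as.data.frame(chunked), as.data.frame(whole))
  }
})

test_that("region scanning lifts coordinates back to the genome", {
  res <- make_table()
  arr <- build_dense_array(res$table)
  g <- make_genome(res$table, seed = 19)
  cfg <- scan_config(window = 7, threshold = 0.37)
  plant <- g$manifest[g$manifest$supra, ][2, ]

  regions <- data.frame(chrom = "chr_syn",
                        start = c(plant$start - 50, plant$end + 200),
                        end = c(plant$end + 50, plant$end + 300),
                        name = c("hit", "miss"))
  sites <- scan_regions(g$records, regions, arr, cfg)
  expect_true(all(sites$region == "hit"))
  expect_true(any(sites$start < plant$end & sites$end > plant$start))
  # coordinates are genomic: the called site overlaps the plant's interval
  expect_true(all(sites$start >= plant$start - 50))

  oob <- data.frame(chrom = "chr_syn", start = -5, end = 100, name = "bad")
  expect_error(scan_regions(g$records, oob, arr, cfg), "out of bounds")

  # a minus-strand region scores identically (calls are strandless)
  regions$strand <- c("-", "+")
  sites_minus <- scan_regions(g$records, regions, arr, cfg)
  expect_identical(as.data.frame(sites_minus), as.data.frame(sites))
})

test_that("promoter regions are strand-aware around the TSS", {
  tss <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    pos = c(5000L, 8000L), strand = c("+", "-"))
  reg <- promoter_regions(tss, upstream = 2500, downstream = 1000)
  expect_identical(reg$start, c(2500L, 7000L))
  expect_identical(reg$end, c(6000L, 10500L))
})
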