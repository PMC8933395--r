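make_pair <- function(len = 76, t_counts, c_counts, lib = 1000) {
  list(treated = trac_library(list(t1 = t_counts), lib),
       control = trac_library(list(t1 = c_counts), lib))
}

test_that("position_frequency is the pseudocounted start frequency", {
  v <- numeric(76); v[11] <- 200
  lib <- trac_library(list(t1 = v), 1000)
  expect_equal(position_frequency(lib, "t1", 10, pseudocount = 0), 0.2)
  expect_equal(position_frequency(lib, "t1", 0, pseudocount = 0), 0)
  zero <- trac_library(list(t1 = numeric(76)), 0)
  expect_error(position_frequency(zero, "t1", 0, pseudocount = 0),
               class = "m7gseq_degenerate_input")
})

test_that("cleavage_score matches the closed form and is antisymmetric", {
  t_counts <- numeric(76); t_counts[11] <- 200
  c_counts <- numeric(76); c_counts[11] <- 50
  p <- make_pair(t_counts = t_counts, c_counts = c_counts)
  expect_equal(cleavage_score(p$treated, p$control, "t1", 10,
                              pseudocount = 0), 2)  # log2(0.2 / 0.05)
  # identical profiles score 0 everywhere
  q <- make_pair(t_counts = c_counts, c_counts = c_counts)
  for (pos in c(0, 10, 75))
    expect_equal(cleavage_score(q$treated, q$control, "t1", pos), 0)
  # treated 50/1000 vs control 0/1000, pc 0.5, len 76:
  # both denominators are 1000 + 0.5 * 76, so the score is log2(50.5 / 0.5)
  t2 <- numeric(76); t2[11] <- 50
  r <- make_pair(t_counts = t2, c_counts = numeric(76))
  expect_equal(cleavage_score(r$treated, r$control, "t1", 10, 0.5),
               log2((50 + 0.5) / 0.5))
  # antisymmetry at every position
  set.seed(11)
  a <- rpois(76, 3); b <- rpois(76, 3)
  s <- make_pair(t_counts = a, c_counts = b, lib = 500)
  for (pos in 0:75)
    expect_equal(cleavage_score(s$treated, s$control, "t1", pos),
                 -cleavage_score(s$control, s$treated, "t1", pos))
})

test_that("site calling applies the motif, score and coverage gates", {
  genes <- tiny_reference()[1, ]
  vl <- c(genes$vl_start, genes$vl_end)
  # force a motif at loop position 50..54 with G at 52 (0-based)
  substr(genes$sequence, 51, 55) <- "ACGAC"
  # and make sure no second motif confuses the test
  substr(genes$sequence, 56, 64) <- strrep("C", 9)
  len <- nchar(genes$sequence)
  t_counts <- numeric(len); c_counts <- numeric(len)
  t_counts[54] <- 400     # read start 53 = site 52 + 1
  t_counts[60] <- 400     # high signal in the loop with no motif (site 58)
  lib <- function(x) trac_library(setNames(list(x), genes$id), 2000)
  calls <- call_m7g_sites(lib(t_counts), lib(c_counts), genes)
  called <- calls[calls$called, ]
  expect_equal(called$position, 52)
  expect_equal(called$read_start, 53)
  expect_equal(m7g_modified_trnas(calls), genes$id)
  # the non-motif high-score position is reported but gated out
  spurious <- calls[calls$position == 58, ]
  expect_equal(nrow(spurious), 1)
  expect_false(spurious$motif_ok)
  expect_false(spurious$called)
  expect_gt(spurious$score, 1)
  # score below threshold at a motif position is not called
  calls_hi <- call_m7g_sites(lib(t_counts), lib(c_counts), genes,
                             min_score = 100)
  expect_false(any(calls_hi$called))
  # coverage gate
  t_low <- numeric(len); t_low[54] <- 5
  calls_low <- call_m7g_sites(lib(t_low), lib(c_counts), genes,
                              min_coverage = 10)
  expect_false(any(calls_low$called))
  # profile without gene errors; gene without profile is reported uncovered
  expect_error(call_m7g_sites(trac_library(list(stranger = t_counts), 2000),
                              lib(c_counts), genes),
               class = "m7gseq_input")
  two <- tiny_reference()
  calls2 <- call_m7g_sites(lib(t_counts), lib(c_counts), two)
  expect_equal(attr(calls2, "uncovered"), two$id[2])
})

test_that("calls are invariant to joint integer scaling with scaled pseudocount", {
  cfg <- simulation_config(seed = 3, n_isotypes = 10L)
  ref <- simulate_trna_reference(cfg)
  libs <- simulate_trac_libraries(ref, cfg)
  calls1 <- call_m7g_sites(libs$treated, libs$control, ref$genes,
                           pseudocount = 0.5)
  k <- 3L
  scale_lib <- function(lib)
    trac_library(lapply(lib$counts, function(v) v * k), lib$library_size * k)
  calls2 <- call_m7g_sites(scale_lib(libs$treated), scale_lib(libs$control),
                           ref$genes, pseudocount = 0.5 * k,
                           min_coverage = 10 * k)
  expect_equal(calls1$position, calls2$position)
  expect_equal(calls1$score, calls2$score)
  expect_equal(calls1$called, calls2$called)
})

test_that("simulated sites are recovered with high recall and precision", {
  hits <- 0; truths <- 0; called_total <- 0; true_pos <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed)
    ref <- simulate_trna_reference(cfg)
    libs <- simulate_trac_libraries(ref, cfg)
    calls <- call_m7g_sites(libs$treated, libs$control, ref$genes)
    truth_key <- paste(ref$truth$trna_id, ref$truth$position)
    call_key <- paste(calls$trna_id[calls$called], calls$position[calls$called])
    hits <- hits + sum(truth_key %in% call_key)
    truths <- truths + length(truth_key)
    true_pos <- true_pos + sum(call_key %in% truth_key)
    called_total <- called_total + length(call_key)
  }
  expect_gte(hits / truths, 0.95)
  expect_gte(true_pos / called_total, 0.95)
})

test_that("m7g_level_change pairs sites and detects reduced cleavage", {
  cfg_a <- simulation_config(seed = 5)
  ref <- simulate_trna_reference(cfg_a)
  libs_a <- simulate_trac_libraries(ref, cfg_a)
  calls_a <- call_m7g_sites(libs_a$treated, libs_a$control, ref$genes)
  # identical libraries: all deltas 0
  same <- m7g_level_change(calls_a, calls_a)
  expect_true(all(same$per_site$delta == 0))
  # knockdown halves the cleavage rate
  cfg_b <- simulation_config(seed = 6, trac = list(cleavage_rate = 0.075))
  libs_b <- simulate_trac_libraries(ref, cfg_b)
  calls_b <- call_m7g_sites(libs_b$treated, libs_b$control, ref$genes)
  chg <- m7g_level_change(calls_a, calls_b)
  expect_lt(chg$median_delta, 0)
  expect_true(all(c("per_site", "per_trna", "test") %in% names(chg)))
  # disjoint site sets error
  empty_calls <- calls_b[0, ]
  attr(empty_calls, "params") <- attr(calls_a, "params")
  class(empty_calls) <- class(calls_a)
  expect_error(m7g_level_change(calls_a, empty_calls),
               class = "m7gseq_degenerate_input")
  # differing parameters error
  calls_c <- call_m7g_sites(libs_b$treated, libs_b$control, ref$genes,
                            min_score = 2)
  expect_error(m7g_level_change(calls_a, calls_c), class = "m7gseq_input")
})
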