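test_that("fpkm closed form and scale invariance", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_error(fpkm(10, 0, 1e6), class = "m7gseq_input")
  set.seed(41)
  cnt <- rpois(20, 50); tot <- 1e6
  expect_equal(fpkm(3 * cnt, 777, 3 * tot), fpkm(cnt, 777, tot))
})

test_that("translation efficiency ratio and reciprocal identity", {
  expect_equal(translation_efficiency(5, 10), 0.5)
  expect_equal(translation_efficiency(7, 7), 1)
  expect_true(is.na(translation_efficiency(5, 0)))
  expect_error(translation_efficiency(5, -1), class = "m7gseq_input")
  set.seed(42)
  a <- rlnorm(50); b <- rlnorm(50)
  expect_equal(translation_efficiency(a, b) * translation_efficiency(b, a),
               rep(1, 50))
})

test_that("TE classification thresholds, filtering, and monotonicity", {
  expect_equal(classify_te(1, 0.4), "down")     # log2(0.4) = -1.32
  expect_equal(classify_te(1, 1), "non")
  expect_equal(classify_te(1, 2.1), "up")
  expect_equal(classify_te(1, 1, input_fpkm_control = 0.2,
                           input_fpkm_kd = 5), "filtered")
  expect_equal(classify_te(NA, 1), "filtered")
  # monotone: raising te_kd never moves the class toward down
  rank <- c(down = 1, non = 2, up = 3)
  cls <- classify_te(rep(1, 200), seq(0.1, 4, length.out = 200))
  expect_true(all(diff(rank[cls]) >= 0))
  expect_error(classify_te(1, 1, lfc_threshold = 0), class = "m7gseq_input")
})

test_that("footprints map to codons through the A-site offset rule", {
  gene <- gene_models("g1", strrep("GCT", 40))[1, ]
  fp <- data.frame(five_prime_pos = c(0, 0, 3, 100), length = c(29, 20, 30, 29))
  occ <- assign_codon_occupancy(fp, gene)
  expect_equal(length(occ$counts), 40)
  expect_equal(occ$counts[6], 1)   # 5' 0 + 15 -> nt 15 -> codon index 5
  expect_equal(occ$counts[7], 1)   # 5' 3 + 15 -> codon index 6
  # length 20 has no offset; A-site 115 is within the 120-nt CDS
  expect_equal(occ$discarded, 1)
  beyond <- data.frame(five_prime_pos = 110, length = 29)
  expect_equal(assign_codon_occupancy(beyond, gene)$discarded, 1)
  expect_error(assign_codon_occupancy(
    data.frame(five_prime_pos = -1, length = 29), gene),
    class = "m7gseq_input")
  # aggregated count column is honoured
  agg <- assign_codon_occupancy(
    data.frame(five_prime_pos = 0, length = 29, count = 7), gene)
  expect_equal(agg$counts[6], 7)
})

test_that("pause scores are mean-normalized with an occupancy floor", {
  expect_equal(pause_scores(c(2, 2, 8)), c(0.5, 0.5, 2))
  expect_equal(pause_scores(rep(4, 10)), rep(1, 10))
  expect_null(pause_scores(numeric(30)))
  expect_equal(mean(pause_scores(rpois(60, 5) + 1)), 1)
})

test_that("te_table runs the shared polysome/ribo code path", {
  genes <- gene_models(c("g1", "g2"), c(strrep("GCT", 100), strrep("AAG", 100)),
                       transcript_length = c(500, 400))
  mk <- function(c1, c2, type, cond)
    library_counts(c(g1 = c1, g2 = c2), type, cond, total = 1e6)
  te <- te_table(genes, mk(500, 500, "input_rna", "control"),
                 mk(500, 500, "input_rna", "kd"),
                 mk(500, 500, "polysome", "control"),
                 mk(125, 500, "polysome", "kd"))
  expect_equal(te$te_class, c("down", "non"))
  expect_equal(te$log2_ratio[1], -2)
  # ribo libraries use CDS length for the translated FPKM
  ter <- te_table(genes, mk(500, 500, "input_rna", "control"),
                  mk(500, 500, "input_rna", "kd"),
                  mk(500, 500, "ribo_footprint", "control"),
                  mk(500, 500, "ribo_footprint", "kd"))
  expect_equal(ter$te_control[1], fpkm(500, 300, 1e6) / fpkm(500, 500, 1e6))
  expect_error(te_table(genes, mk(1, 1, "polysome", "c"),
                        mk(1, 1, "input_rna", "k"),
                        mk(1, 1, "polysome", "c"), mk(1, 1, "polysome", "k")),
               class = "m7gseq_input")
})

test_that("knockdown pausing at m7G codons is detected and quantified", {
  codons <- c("GTT", "GTC", "GTA", "AAG", "AAA", "CAA", "CAG")
  cfg <- simulation_config(seed = 17, mrna = list(n_genes = 120L))
  tx <- simulate_transcriptome(cfg, codons)
  fp <- simulate_footprints(tx$genes, cfg, codons)
  occ_c <- occupancy_from_footprints(fp$control, tx$genes)
  occ_k <- occupancy_from_footprints(fp$kd, tx$genes)
  res <- m7g_pause_shift(occ_c, occ_k, tx$genes, codons)
  expect_lt(res$test$p, 0.05)
  expect_true(all(res$per_codon$delta[res$per_codon$m7g] > 0))
  expect_equal(res$ratio_ratio, 2, tolerance = 0.1)
  expect_gt(res$median_delta_m7g, res$median_delta_non)
  # stop codons are excluded from the per-codon table
  expect_false(any(res$per_codon$codon %in% c("TAA", "TAG", "TGA")))
  expect_error(m7g_pause_shift(occ_c, occ_k, tx$genes, character(0)),
               class = "m7gseq_input")
})

test_that("a null pausing simulation shows no m7G shift", {
  codons <- c("GTT", "GTC", "GTA", "AAG")
  cfg <- simulation_config(seed = 18, mrna = list(n_genes = 100L),
                           ribo = list(pause_multiplier = 1))
  tx <- simulate_transcriptome(cfg, codons)
  fp <- simulate_footprints(tx$genes, cfg, codons)
  res <- m7g_pause_shift(occupancy_from_footprints(fp$control, tx$genes),
                         occupancy_from_footprints(fp$kd, tx$genes),
                         tx$genes, codons)
  expect_lt(abs(res$median_delta_m7g), 0.05)
  expect_lt(abs(res$median_delta_non), 0.05)
  expect_equal(res$ratio_ratio, 1, tolerance = 0.1)
})
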