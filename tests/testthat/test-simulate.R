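test_that("simulation config validates rates and replicates", {
  expect_error(simulation_config(fraction_m7g = 0), class = "m7gseq_config")
  expect_error(simulation_config(trac = list(cleavage_rate = 1.5)),
               class = "m7gseq_config")
  expect_error(simulation_config(expr = list(replicates = 0L)),
               class = "m7gseq_config")
  cfg <- simulation_config(seed = 9, trac = list(cleavage_rate = 0.2))
  expect_equal(cfg$trac$cleavage_rate, 0.2)
  expect_equal(cfg$trac$background_rate, 5e-3)  # untouched default
})

test_that("the simulated reference implants motifs exactly as listed", {
  cfg <- simulation_config(seed = 101)
  ref <- simulate_trna_reference(cfg)
  expect_equal(nrow(ref$genes), 50)
  expect_equal(sum(ref$genes$m7g), 20)
  expect_equal(nrow(ref$truth), 20)
  expect_equal(length(ref$m7g_isotypes), 20)
  for (i in seq_len(nrow(ref$genes))) {
    g <- ref$genes[i, ]
    hits <- scan_motif(g$sequence, c(g$vl_start, g$vl_end))
    if (g$m7g) {
      expect_true(ref$truth$position[ref$truth$trna_id == g$id] %in% hits)
    } else {
      expect_equal(hits, integer(0))
    }
  }
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 77, mrna = list(n_genes = 50L))
  r1 <- simulate_trna_reference(cfg)
  r2 <- simulate_trna_reference(cfg)
  expect_identical(r1, r2)
  expect_identical(simulate_trac_libraries(r1, cfg),
                   simulate_trac_libraries(r2, cfg))
  expect_identical(simulate_trna_counts(r1, cfg)$counts,
                   simulate_trna_counts(r2, cfg)$counts)
  codons <- m7g_codon_set(r1$genes[r1$genes$m7g, ])
  t1 <- simulate_transcriptome(cfg, codons)
  t2 <- simulate_transcriptome(cfg, codons)
  expect_identical(t1, t2)
  cnt <- setNames(codon_count_records(t1$genes, codons)$m7g_codon_count,
                  t1$genes$id)
  expect_identical(simulate_mrna_libraries(t1$genes, cfg, cnt),
                   simulate_mrna_libraries(t2$genes, cfg, cnt))
  expect_identical(simulate_footprints(t1$genes, cfg, codons),
                   simulate_footprints(t2$genes, cfg, codons))
  # written files share digests
  f1 <- tempfile(); f2 <- tempfile()
  write_trna_reference(r1$genes, f1); write_trna_reference(r2$genes, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("TRAC libraries have the configured totals and exchangeable null", {
  cfg <- simulation_config(seed = 5, trac = list(cleavage_rate = 0))
  ref <- simulate_trna_reference(cfg)
  libs <- simulate_trac_libraries(ref, cfg)
  expect_equal(sum(unlist(libs$treated$counts)), 2e5)
  expect_equal(sum(unlist(libs$control$counts)), 2e5)
  # with no cleavage signal nothing should be called
  calls <- call_m7g_sites(libs$treated, libs$control, ref$genes)
  expect_equal(sum(calls$called), 0)
})

test_that("tRNA count depletion is recovered within 10%", {
  cfg <- simulation_config(seed = 55,
                           expr = list(replicates = 6L, mean_count = 2000))
  ref <- simulate_trna_reference(cfg)
  cm <- simulate_trna_counts(ref, cfg)
  cpm <- cpm_normalize(cm)$counts
  ctrl <- rowMeans(cpm[, cm$condition == "control"])
  kd <- rowMeans(cpm[, cm$condition == "kd"])
  est <- median((kd / ctrl)[ref$genes$m7g]) /
    median((kd / ctrl)[!ref$genes$m7g])
  expect_equal(est, 0.6, tolerance = 0.1)
  # no depletion: conditions exchangeable in distribution
  cfg0 <- simulation_config(seed = 56, expr = list(depletion_factor = 1))
  cm0 <- simulate_trna_counts(simulate_trna_reference(cfg0), cfg0)
  expect_gt(mann_whitney_u(colSums(cm0$counts)[cm0$condition == "control"],
                           colSums(cm0$counts)[cm0$condition == "kd"])$p, 0.05)
})

test_that("transcriptome propensity gradient is realized in codon content", {
  codons <- c("GTT", "GTC", "GTA", "AAG")
  cfg <- simulation_config(seed = 88, mrna = list(n_genes = 300L))
  tx <- simulate_transcriptome(cfg, codons)
  recs <- codon_count_records(tx$genes, codons)
  # no internal stops in frame
  internal <- vapply(tx$genes$cds[1:50], function(s) {
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    any(cods %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(internal))
  # empirical fraction tracks the true propensity
  frac <- recs$m7g_codon_count / recs$cds_codons
  expect_gt(cor(frac, tx$propensity[recs$gene]), 0.9)
  # binomial-scale agreement of the mean
  expect_equal(mean(frac), mean(tx$propensity), tolerance = 0.05)
})

test_that("footprint records invert exactly through occupancy assignment", {
  codons <- c("GTT", "AAG")
  cfg <- simulation_config(seed = 91, mrna = list(n_genes = 20L))
  tx <- simulate_transcriptome(cfg, codons)
  fp <- simulate_footprints(tx$genes, cfg, codons)
  occ <- occupancy_from_footprints(fp$control, tx$genes)
  # per-gene sums equal emitted read counts; nothing discarded
  for (g in tx$genes$id[1:5]) {
    expect_equal(sum(occ[[g]]), sum(fp$control$count[fp$control$gene == g]))
  }
  one <- fp$control[fp$control$gene == tx$genes$id[1], ]
  res <- assign_codon_occupancy(one, tx$genes[1, ])
  expect_equal(res$discarded, 0)
  # first five codons carry no occupancy by construction
  expect_equal(res$counts[1:5], numeric(5))
})
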