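test_that("summary percentages are computed from their stated denominators", {
  s <- run_summary_from_counts(n_total = 1231, n_tm = 629, n_signal = 171,
                               n_tm_no_signal = 458, n_tm_cyto_quant = 385,
                               n_tm_extra_quant = 362)
  expect_equal(s$pct_tm, 51)
  expect_equal(s$pct_tm_no_signal, 73)
  expect_equal(s$pct_tm_cyto_quant, round(100 * 385 / 629))
  # self-consistency: recomputing percentages from the counts matches
  expect_equal(s$pct_tm, round(100 * s$n_tm / s$n_total))
  expect_equal(s$pct_tm_no_signal, round(100 * s$n_tm_no_signal / s$n_tm))
})

test_that("summarize_run counts topology classes over a mapped run", {
  fx <- synth_fixture(n = 30, dir = withr::local_tempdir(), seed = 17,
                      sub_threshold_frac = 0, missing_frac = 0)
  res <- pepmap(fx$protxml, fx$annotations)
  s <- glance(res)
  templates <- vapply(fx$specs, `[[`, character(1), "template")
  expect_equal(s$n_total, 30L)
  expect_equal(s$n_tm, sum(templates != "soluble"))
  expect_equal(s$n_signal, sum(templates == "type1"))
  expect_equal(s$n_tm_no_signal, sum(templates %in% c("type2", "multi")))
  expect_lte(s$n_tm_cyto_quant, s$n_tm)
  expect_lte(s$n_tm_extra_quant, s$n_tm)
  # invariant chain of inequalities
  expect_lte(s$n_tm, s$n_total)
  expect_lte(s$n_tm_no_signal, s$n_tm)
})

test_that("an empty run summarizes to zero without error", {
  fx <- synth_fixture(n = 3, dir = withr::local_tempdir(), seed = 2)
  res <- pepmap(fx$protxml, fx$annotations,
                config = run_config(threshold = 1.0))
  res$proteins <- res$proteins[0, ]
  s <- summarize_run(res)
  expect_equal(s$n_total, 0L)
  expect_true(is.na(s$pct_tm))
})

test_that("fold-change distributions bin over the display range", {
  fx <- synth_fixture(n = 40, dir = withr::local_tempdir(), seed = 23,
                      effect_sd = 0.5, sub_threshold_frac = 0)
  res <- pepmap(fx$protxml, fx$annotations)
  fc <- fc_distribution(res, "all")
  expect_equal(sum(fc$histogram$count), length(fc$values))
  expect_equal(nrow(fc$histogram), 24L)  # 6 log2 units / 0.25
  # protein effects are drawn from N(0, ~0.5): sample mean near 0
  se <- sd(fc$values) / sqrt(length(fc$values))
  expect_lt(abs(mean(fc$values)), 3 * se + 1e-9)

  tm <- fc_distribution(res, "tm")
  expect_lte(length(tm$values), length(fc$values))
  cyt <- fc_distribution(res, "cytoplasmic_domains")
  expect_equal(length(cyt$values), sum(!is.na(res$proteins$cyto_mean)))
  expect_error(fc_distribution(res, "bogus"))
})

test_that("an empty category yields an empty list and zero histogram", {
  fx <- synth_fixture(n = 5, dir = withr::local_tempdir(), seed = 31,
                      template_mix = c(soluble = 1, type2 = 0, type1 = 0, multi = 0),
                      sub_threshold_frac = 0)
  res <- pepmap(fx$protxml, fx$annotations)
  fc <- fc_distribution(res, "cytoplasmic_domains")
  expect_equal(length(fc$values), 0L)
  expect_equal(sum(fc$histogram$count), 0L)
})

test_that("the substrate screen applies topology and fold-change criteria", {
  dir <- withr::local_tempdir()
  fx <- demo_substrate_fixture(file.path(dir, "hit"))
  res <- pepmap(fx$protxml, fx$annotations)
  cand <- screen_sppl_candidates(res, fc_cutoff = 1.0)
  expect_equal(cand$accession, "P90001")
  expect_equal(cand$tail_length, 29L)
  # opposing domain means are reported together
  expect_equal(cand$cyto_mean, 1.2, tolerance = 1e-6)
  expect_equal(cand$extra_mean, -0.6, tolerance = 1e-6)

  # sub-threshold tail accumulation is not flagged
  fx2 <- demo_substrate_fixture(file.path(dir, "low"), cyto_log2 = 0.8)
  res2 <- pepmap(fx2$protxml, fx2$annotations)
  expect_equal(nrow(screen_sppl_candidates(res2, fc_cutoff = 1.0)), 0L)

  # a multi-pass protein never qualifies, however strong its tail signal
  sp <- make_protein_spec("multi", length = 300, n_tm = 2,
                          effects = c(cytoplasmic = 2), sigma = 0,
                          accession = "P90002", seed = 8)
  obs <- digest_and_quantify(sp, seed = 9)
  fx3 <- write_fixture(list(sp), list(obs), file.path(dir, "multi"))
  res3 <- pepmap(fx3$protxml, fx3$annotations)
  expect_gt(res3$proteins$cyto_mean[1], 1)
  expect_equal(nrow(screen_sppl_candidates(res3)), 0L)

  # optional short-tail filter
  expect_equal(nrow(screen_sppl_candidates(res, max_tail_length = 20)), 0L)
  expect_equal(nrow(screen_sppl_candidates(res, max_tail_length = 40)), 1L)
})

test_that("the candidate set shrinks monotonically as the cutoff rises", {
  fx <- synth_fixture(n = 25, dir = withr::local_tempdir(), seed = 55,
                      effect_sd = 1.2, sub_threshold_frac = 0)
  res <- pepmap(fx$protxml, fx$annotations)
  cuts <- c(-1, 0, 0.5, 1, 2, Inf)
  sizes <- vapply(cuts, function(fc) {
    nrow(screen_sppl_candidates(res, fc_cutoff = fc))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0L)  # +Inf cutoff -> empty
  # candidates are a subset of valid TM proteins
  cand <- screen_sppl_candidates(res, fc_cutoff = 0)
  expect_true(all(cand$accession %in%
                    res$proteins$accession[res$proteins$has_tm %in% TRUE]))
})
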