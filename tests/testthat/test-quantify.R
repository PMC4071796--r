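test_that("the probability filter conserves counts and keeps the boundary", {
  ps <- tibble::tibble(accession = sprintf("P%03d", 1:5),
                       probability = c(0.89, 0.90, 0.95, 0.10, 1.0))
  split <- filter_proteins(ps, 0.90)
  expect_equal(nrow(split$valid) + nrow(split$discarded), 5L)
  expect_equal(split$valid$accession, c("P002", "P003", "P005"))
  expect_equal(split$discarded$accession, c("P001", "P004"))  # order preserved
  expect_match(split$discarded$reason[1], "below cutoff")
  # threshold 0 keeps everything
  expect_equal(nrow(filter_proteins(ps, 0)$valid), 5L)
})

test_that("raising the threshold never grows the valid set", {
  withr::local_seed(99)
  ps <- tibble::tibble(accession = sprintf("P%04d", 1:200),
                       probability = runif(200))
  sizes <- vapply(seq(0, 1, by = 0.05),
                  function(t) nrow(filter_proteins(ps, t)$valid), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ratio selection validates ASAPRatio against XPRESS", {
  peps <- peptide_tbl(c("AK", "BK", "CK"), asap = c(2.0, 2.0, NA),
                      xpress = c(2.2, 0.4, 1.0))
  on_ <- select_ratio(peps, run_config(validate = TRUE))
  expect_equal(on_$ratio, c(2.0, 2.0, NA))
  expect_equal(on_$validation, c("pass", "fail", "untestable"))
  off <- select_ratio(peps, run_config())
  expect_equal(unique(off$validation), "untested")
})

test_that("log2 transform handles identity, inversion and sentinels", {
  expect_equal(to_log2(1.0), 0.0)
  expect_equal(to_log2(0.25), -2.0)
  expect_equal(to_log2(2.0, invert = TRUE), -1.0)
  expect_equal(to_log2(0), -Inf)
  expect_equal(to_log2(10000), Inf)   # XPRESS infinite-ratio convention
  expect_error(to_log2(-0.5), "negative")
  # double inversion is the identity
  x <- c(0.1, 1, 2.5, 8)
  expect_equal(-to_log2(x, invert = TRUE), to_log2(x))
})

test_that("clamping is idempotent, bounded and maps infinities to bounds", {
  expect_equal(clamp_log2(5.2), 3.0)
  expect_equal(clamp_log2(-7), -3.0)
  expect_equal(clamp_log2(1.4), 1.4)
  expect_equal(clamp_log2(c(-Inf, Inf)), c(-3, 3))
  withr::local_seed(1)
  x <- rnorm(500, sd = 4)
  cl <- clamp_log2(x)
  expect_true(all(cl >= -3 & cl <= 3))
  expect_equal(clamp_log2(cl), cl)
})

test_that("change classification respects the inclusive no-change zone", {
  expect_equal(classify_change(0.1), "no_change")
  expect_equal(classify_change(0.30), "up")
  expect_equal(classify_change(-0.25), "no_change")  # inclusive boundary
  expect_equal(classify_change(0.25), "no_change")
  expect_equal(classify_change(-0.26), "down")
})

test_that("deduplication keeps the best-supported occurrence", {
  peps <- peptide_tbl(c("AAAK", "AAAK", "CCCK"),
                      probability = c(0.80, 0.95, 0.70),
                      asap = c(1, 2, 3))
  d <- dedupe_peptides(peps)
  expect_equal(nrow(d), 2L)
  expect_equal(d$asap_ratio[d$sequence == "AAAK"], 2)  # the 0.95 record

  e <- dedupe_peptides(peps, elaborate = TRUE)
  expect_equal(nrow(e), 3L)
  expect_equal(sum(e$primary), 2L)
  expect_equal(e$sequence, c("AAAK", "AAAK", "CCCK"))  # grouped by sequence

  # probability ties broken by number of quantified spectra
  tied <- peptide_tbl(c("GGGK", "GGGK"), probability = 0.9,
                      asap = c(5, 7), asap_n = c(1L, 4L))
  expect_equal(dedupe_peptides(tied)$asap_ratio, 7)

  distinct <- peptide_tbl(c("AK", "CK", "DK"))
  expect_equal(dedupe_peptides(distinct)$sequence, c("AK", "CK", "DK"))
})

test_that("region averages are arithmetic means of contributing peptides", {
  mapped <- tibble::tibble(
    sequence = c("A", "B", "C", "D"),
    region_class = c("cytoplasmic", "cytoplasmic", "extra_cytoplasmic",
                     "cytoplasmic"),
    log2_ratio = c(1.0, 2.0, 0.7, NA),
    validation = "untested", primary = TRUE
  )
  cy <- region_average(mapped, "cytoplasmic")
  expect_equal(cy$mean_log2, 1.5)
  expect_equal(cy$n_peptides, 2L)
  ex <- region_average(mapped, "extra_cytoplasmic")
  expect_equal(ex$mean_log2, 0.7)
  expect_equal(ex$n_peptides, 1L)
  # no contributing peptide -> absent
  none <- mapped[mapped$region_class == "transmembrane", ]
  expect_equal(nrow(region_average(none, "cytoplasmic")), 0L)
  # validation failures are excluded
  mapped$validation <- c("fail", "untested", "untested", "untested")
  expect_equal(region_average(mapped, "cytoplasmic")$mean_log2, 2.0)
})

test_that("region means always lie within their contributors' range", {
  withr::local_seed(33)
  for (i in 1:30) {
    n <- sample(1:10, 1)
    mapped <- tibble::tibble(
      sequence = as.character(seq_len(n)),
      region_class = sample(c("cytoplasmic", "extra_cytoplasmic", "spanning"),
                            n, replace = TRUE),
      log2_ratio = clamp_log2(rnorm(n, 0, 2)),
      validation = "untested", primary = TRUE
    )
    for (reg in c("cytoplasmic", "extra_cytoplasmic")) {
      rq <- region_average(mapped, reg)
      if (nrow(rq) == 0) next
      vals <- mapped$log2_ratio[mapped$region_class == reg]
      expect_gte(rq$mean_log2, min(vals))
      expect_lte(rq$mean_log2, max(vals))
      expect_true(rq$mean_log2 >= -3 && rq$mean_log2 <= 3)
    }
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(run_config(threshold = 1.01), "threshold")
  expect_error(run_config(rmin = 1, rmax = -1), "rmin")
  expect_error(run_config(zn = 0.5, zp = 0.25), "rmin < zn")
  expect_error(run_config(validation_tolerance = 0), "positive")
})
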