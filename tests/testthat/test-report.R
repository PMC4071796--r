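test_that("ratio colours follow the red-green scale contract", {
  cfg <- run_config()
  expect_equal(color_for_ratio(0, cfg), "#808080")
  expect_equal(color_for_ratio(0.25, cfg), "#808080")   # zone is inclusive
  expect_equal(color_for_ratio(3, cfg), "#00FF00")
  expect_equal(color_for_ratio(-3, cfg), "#FF0000")
  expect_error(color_for_ratio(3.5, cfg), "outside")
  # configurable direction swaps the channels
  red_up <- run_config(color_up = "red")
  expect_equal(color_for_ratio(3, red_up), "#FF0000")
  expect_equal(color_for_ratio(-3, red_up), "#00FF00")
})

channel <- function(hex, which) strtoi(substr(hex, 2 * which, 2 * which + 1), 16L)

test_that("colour intensity is monotone in each half-range and symmetric", {
  cfg <- run_config()
  ups <- seq(0.26, 3, length.out = 40)
  greens <- channel(color_for_ratio(ups, cfg), 2)
  expect_true(all(diff(greens) >= 0))
  expect_gte(min(greens), 64)
  downs <- seq(-0.26, -3, length.out = 40)
  reds <- channel(color_for_ratio(downs, cfg), 1)
  expect_true(all(diff(reds) >= 0))
  # mirror symmetry: negating the value and the zone swaps red and green
  for (v in c(-2.4, -1, 0.5, 1.7, 2.9)) {
    a <- color_for_ratio(v, cfg)
    b <- color_for_ratio(-v, cfg)
    expect_equal(channel(a, 2), channel(b, 1))
    expect_equal(channel(a, 1), channel(b, 2))
  }
})

test_that("the rendered bundle holds the documented inventory", {
  fx <- synth_fixture(n = 10, dir = withr::local_tempdir(), seed = 77)
  res <- pepmap(fx$protxml, fx$annotations)
  out <- file.path(withr::local_tempdir(), "report")
  render_html(res, out)
  zipfile <- bundle(out)
  inv <- zip_inventory(zipfile)
  for (want in c("index.html", "run_stats.out", "average_molecular_weight.txt",
                 "suppoted_browsers_and_os.txt", "images/", "small_images/",
                 "index_files/")) {
    expect_true(want %in% inv, label = paste(want, "present"))
  }
  # one page and two graphics per valid protein
  n <- nrow(res$proteins)
  expect_equal(sum(grepl("^images/.+\\.svg$", inv)), n)
  expect_equal(sum(grepl("^small_images/.+\\.svg$", inv)), n)
  expect_equal(sum(grepl("^index_files/.+\\.html$", inv)), n)
  # run_stats.out has exactly one line per discarded protein
  expect_equal(length(readLines(file.path(out, "run_stats.out"))),
               nrow(res$discarded))
  # corrected-spelling switch renames the browser note
  res2 <- res; res2$config <- run_config(corrected_browser_note = TRUE)
  out2 <- file.path(withr::local_tempdir(), "report2")
  render_html(res2, out2)
  inv2 <- zip_inventory(bundle(out2, config = res2$config))
  expect_true("supported_browsers_and_os.txt" %in% inv2)
  expect_false("suppoted_browsers_and_os.txt" %in% inv2)
})

test_that("average molecular weight is the mean over valid proteins", {
  dir <- withr::local_tempdir()
  specs <- list(
    make_protein_spec("soluble", length = 120, accession = "P10001", seed = 1),
    make_protein_spec("soluble", length = 150, accession = "P10002", seed = 2)
  )
  specs[[1]]$molecular_weight <- 10000
  specs[[2]]$molecular_weight <- 30000
  obs <- lapply(specs, digest_and_quantify, seed = 4)
  fx <- write_fixture(specs, obs, dir)
  res <- pepmap(fx$protxml, fx$annotations)
  out <- file.path(dir, "rep")
  render_html(res, out)
  mw <- readLines(file.path(out, "average_molecular_weight.txt"))
  expect_equal(as.numeric(strsplit(mw[1], "\t")[[1]][2]), 20000)
  expect_equal(as.integer(strsplit(mw[2], "\t")[[1]][2]), 2L)
})

test_that("emitted HTML is well-formed and pages are reachable from the index", {
  fx <- synth_fixture(n = 6, dir = withr::local_tempdir(), seed = 13)
  res <- pepmap(fx$protxml, fx$annotations)
  out <- file.path(withr::local_tempdir(), "report")
  render_html(res, out)
  idx <- xml2::read_html(file.path(out, "index.html"))
  hrefs <- xml2::xml_attr(xml2::xml_find_all(idx, ".//a"), "href")
  local_pages <- grep("^index_files/.+\\.html$", hrefs, value = TRUE)
  expect_equal(length(local_pages), nrow(res$proteins))
  for (pg in local_pages) {
    expect_true(file.exists(file.path(out, pg)))
    expect_no_error(xml2::read_html(file.path(out, pg)))
  }
  # table rows carry the data attributes the filter toggles use
  rows <- xml2::xml_find_all(idx, ".//tbody/tr")
  tm_flags <- xml2::xml_attr(rows, "data-tm")
  expect_equal(sum(tm_flags == "1"), res$summary$n_tm)
})

test_that("archive content extracts byte-identically via the internal reader", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.txt"); writeLines(c("alpha", strrep("b", 4000)), f1)
  f2 <- file.path(dir, "sub", "c.bin")
  dir.create(dirname(f2))
  writeBin(as.raw(sample(0:255, 2000, replace = TRUE)), f2)
  zipfile <- file.path(dir, "t.zip")
  zip_create(zipfile, c("a.txt", "sub/", "sub/c.bin"), root = dir)
  ex <- file.path(dir, "out")
  utils::unzip(zipfile, exdir = ex)
  expect_identical(readBin(file.path(ex, "a.txt"), "raw", 1e5),
                   readBin(f1, "raw", 1e5))
  expect_identical(readBin(file.path(ex, "sub", "c.bin"), "raw", 1e5),
                   readBin(f2, "raw", 1e5))
  expect_equal(zip_inventory(zipfile), c("a.txt", "sub/", "sub/c.bin"))
})
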