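test_that("tabular annotation records load with their features", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\tname\tlength\tmw\tsequence\tfeatures",
    paste0("P00001\tTestTM\t100\t11000\t", strrep("A", 100),
           "\tTOPO_DOM 1..10 Cytoplasmic; TRANSMEM 11..31; TOPO_DOM 32..100 Extracellular"),
    paste0("P00002\tSoluble\t50\t5500\t", strrep("C", 50), "\t")
  ), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 2L)
  f <- ann$features[[1]]
  expect_equal(nrow(f), 3L)
  expect_equal(f$category, c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"))
  expect_equal(f$start, c(1L, 11L, 32L))
  expect_equal(f$end, c(10L, 31L, 100L))
  expect_equal(nrow(ann$features[[2]]), 0L)  # soluble protein
})

test_that("out-of-bounds features are dropped with a warning, entry kept", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\tname\tlength\tmw\tsequence\tfeatures",
    paste0("P00003\tBad\t20\t2000\t", strrep("A", 20),
           "\tTRANSMEM 5..10; TOPO_DOM 11..99 Extracellular")
  ), path)
  expect_warning(ann <- read_annotations(path), "dropped")
  f <- ann$features[[1]]
  expect_equal(nrow(f), 1L)
  expect_true(all(f$start >= 1 & f$end <= 20))
})

test_that("missing files and entry-free files raise errors", {
  expect_error(read_annotations(file.path(tempdir(), "nope.tsv")), "not found")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("accession\tname\tlength\tmw\tsequence\tfeatures", path)
  expect_error(read_annotations(path), "no annotation entries")
})

test_that("load -> save -> load is the identity on the tabular format", {
  fx <- synth_fixture(n = 8, dir = withr::local_tempdir(), seed = 5)
  a1 <- read_annotations(fx$annotations)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(a1, path)
  a2 <- read_annotations(path)
  expect_equal(a1, a2)
  # every loaded feature satisfies the coordinate invariant
  for (i in seq_len(nrow(a1))) {
    f <- a1$features[[i]]
    expect_true(all(f$start >= 1 & f$start <= f$end & f$end <= a1$length[i]))
  }
})

test_that("UniProt flat text parses name, sequence, mass and topology", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "ID   TEST_MOUSE              Reviewed;          60 AA.",
    "AC   P99999; Q00001;",
    "DE   RecName: Full=Test membrane protein;",
    "FT   TOPO_DOM        1..10",
    "FT                   /note=\"Cytoplasmic\"",
    "FT   TRANSMEM        11..31",
    "FT                   /note=\"Helical\"",
    "FT   TOPO_DOM        32..60",
    "FT                   /note=\"Lumenal\"",
    "SQ   SEQUENCE   60 AA;  6600 MW;  0000000000000000 CRC64;",
    paste("    ", strrep("MAAAAAAAAA", 6)),
    "//"
  ), path)
  ann <- read_annotations(path)
  expect_equal(ann$accession, "P99999")
  expect_equal(ann$recommended_name, "Test membrane protein")
  expect_equal(ann$length, 60L)
  expect_equal(ann$molecular_weight, 6600)
  f <- ann$features[[1]]
  expect_equal(f$subtype, c("Cytoplasmic", NA, "Lumenal"))
  expect_equal(classify_feature(f$category, f$subtype),
               c("cytoplasmic", "transmembrane", "extra_cytoplasmic"))
})

test_that("feature classification follows the topology vocabulary", {
  expect_equal(classify_feature("TOPO_DOM", "Cytoplasmic"), "cytoplasmic")
  expect_equal(classify_feature("TRANSMEM", NA), "transmembrane")
  expect_equal(classify_feature("SIGNAL", NA), "signal")
  expect_equal(classify_feature("TOPO_DOM", "Lumenal"), "extra_cytoplasmic")
  expect_equal(classify_feature("TOPO_DOM", "Extracellular"), "extra_cytoplasmic")
  expect_equal(classify_feature("TOPO_DOM", "Periplasmic"), "extra_cytoplasmic")
  expect_equal(classify_feature("TOPO_DOM", "Mitochondrial matrix"), "unclassified")
  # the synonym list is configurable
  expect_equal(
    classify_feature("TOPO_DOM", "Mitochondrial matrix",
                     extra_synonyms = "Mitochondrial matrix"),
    "extra_cytoplasmic")
  # total and deterministic over a grid of inputs
  cats <- c("SIGNAL", "TRANSMEM", "TOPO_DOM")
  subs <- c("Cytoplasmic", "Extracellular", "Lumenal", "Weird", NA)
  grid <- expand.grid(category = cats, subtype = subs,
                      stringsAsFactors = FALSE)
  r1 <- classify_feature(grid$category, grid$subtype)
  r2 <- classify_feature(grid$category, grid$subtype)
  expect_identical(r1, r2)
  expect_true(all(r1 %in% c("cytoplasmic", "extra_cytoplasmic",
                            "transmembrane", "signal", "unclassified")))
})

test_that("the fetcher refuses unfetchable namespaces offline", {
  expect_error(fetch_annotation("IPI00112233"), "IPI")
  expect_error(fetch_annotation("not an accession"), "not a UniProt-shaped")
})
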