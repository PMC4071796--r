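# Shared in-code fixtures.  Everything is generated at test time; nothing
# binary is stored in the repository.

# Feature table of a simple single-pass protein: cytoplasmic 1..10,
# TM 11..31, extracellular 32..100.
simple_features <- function() {
  tibble::tibble(
    category = c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"),
    subtype = c("Cytoplasmic", NA, "Extracellular"),
    start = c(1L, 11L, 32L),
    end = c(10L, 31L, 100L)
  )
}

# Minimal peptide tibble in the shape read_protxml() produces.
peptide_tbl <- function(sequence, probability = 0.95, asap = NA_real_,
                        xpress = NA_real_, charge = 2L, asap_n = 1L) {
  n <- length(sequence)
  tibble::tibble(
    sequence = sequence,
    charge = rep_len(charge, n),
    probability = rep_len(probability, n),
    asap_ratio = rep_len(asap, n),
    asap_sd = rep_len(NA_real_, n),
    asap_n = rep_len(asap_n, n),
    xpress_ratio = rep_len(xpress, n),
    is_nondegenerate = rep_len(TRUE, n)
  )
}

protein_record <- function(peptides, probability = 0.99,
                           accession = "P00001") {
  tibble::tibble(
    group_index = 1L,
    protein_name = sprintf("sp|%s|TEST_MOUSE", accession),
    accession = accession, namespace = "uniprot",
    probability = probability, percent_coverage = NA_real_,
    total_peptides = nrow(peptides),
    asap_ratio = NA_real_, asap_sd = NA_real_, asap_n = NA_integer_,
    xpress_ratio = NA_real_, xpress_sd = NA_real_, xpress_n = NA_integer_,
    peptides = list(peptides)
  )
}

annotation_row <- function(sequence, features = simple_features(),
                           accession = "P00001", name = "TestTM") {
  tibble::tibble(
    accession = accession, recommended_name = name,
    length = nchar(sequence), molecular_weight = 11000,
    sequence = sequence, features = list(features)
  )
}

# brute-force oracle for locate_peptide: try every start position
locate_oracle <- function(pep, prot) {
  np <- nchar(pep); n <- nchar(prot)
  if (np > n) return(integer(0))
  starts <- seq_len(n - np + 1L)
  starts[substring(prot, starts, starts + np - 1L) == pep]
}

random_seq <- function(n, alphabet = c("A", "C", "D", "K", "R")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
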