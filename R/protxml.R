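#' Read a protXML document into a protein tibble
#'
#' Parses ProteinProphet output (the protXML format of the Trans Proteomic
#' Pipeline) into one row per protein, with the identified peptides nested
#' in a list-column.  ASAPRatio and XPRESS quantitations are captured from
#' their `analysis_result` wrappers at both the protein and the peptide
#' level; when a protein carries both the original and a recomputed
#' ("adjusted") ASAPRatio, the adjusted value is preferred.  The format's
#' negative-ratio sentinel ("not computed") is mapped to `NA`.
#'
#' Peptide sequences are stripped of modification annotations so that they
#' can be matched against database sequences; a protein lacking a
#' probability attribute is kept with probability 0 and a warning.
#'
#' @param path Path to a protXML file.
#' @return A tibble with columns `group_index`, `protein_name`,
#'   `accession`, `namespace`, `probability`, `percent_coverage`,
#'   `total_peptides`, `asap_ratio`, `asap_sd`, `asap_n`, `xpress_ratio`,
#'   `xpress_sd`, `xpress_n` and list-column `peptides` (tibbles with
#'   `sequence`, `charge`, `probability`, `asap_ratio`, `asap_sd`,
#'   `asap_n`, `xpress_ratio`, `is_nondegenerate`).  Attributes
#'   `source_file` and `n_groups` carry run metadata.
#' @examples
#' fx <- synth_fixture(n = 3, dir = tempfile(), seed = 1)
#' proteins <- read_protxml(fx$protxml)
#' proteins$accession
#' @export
read_protxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  groups <- xml2::xml_find_all(doc, ".//protein_group")
  if (length(groups) == 0) {
    stop("no protein_group elements found in ", path, call. = FALSE)
  }
  rows <- purrr::map(groups, function(grp) {
    gidx <- as.integer(xml2::xml_attr(grp, "group_number"))
    prots <- xml2::xml_find_all(grp, "./protein")
    purrr::map(prots, parse_protein_node, group_index = gidx)
  })
  proteins <- dplyr::bind_rows(purrr::flatten(rows))
  acc <- extract_accession(proteins$protein_name)
  proteins <- tibble::add_column(proteins, accession = acc$accession,
                                 namespace = acc$namespace,
                                 .after = "protein_name")
  attr(proteins, "source_file") <- path
  attr(proteins, "n_groups") <- length(groups)
  proteins
}

parse_protein_node <- function(prot, group_index) {
  name <- xml2::xml_attr(prot, "protein_name")
  prob <- xml2::xml_attr(prot, "probability")
  if (is.na(prob)) {
    warning("protein '", name, "' has no probability attribute; treated as 0",
            call. = FALSE)
    prob <- "0"
  }
  asap <- quant_from_node(prot, "asapratio", "ASAPRatio")
  adj <- xml2::xml_find_first(
    prot, "./analysis_result[@analysis='asapratio_pvalue']/ASAPRatio_pvalue"
  )
  if (!inherits(adj, "xml_missing")) {
    adj_mean <- as.numeric(xml2::xml_attr(adj, "adj_ratio_mean"))
    if (!is.na(adj_mean)) {
      asap$ratio <- if (adj_mean < 0) NA_real_ else adj_mean
      sd <- as.numeric(xml2::xml_attr(adj, "adj_ratio_standard_dev"))
      if (!is.na(sd)) asap$sd <- sd
    }
  }
  xpress <- quant_from_node(prot, "xpress", "XPressRatio")
  peptides <- parse_peptide_nodes(xml2::xml_find_all(prot, "./peptide"))
  tibble(
    group_index = group_index,
    protein_name = name,
    probability = as.numeric(prob),
    percent_coverage = as.numeric(xml2::xml_attr(prot, "percent_coverage")),
    total_peptides = as.integer(xml2::xml_attr(prot, "total_number_peptides")),
    asap_ratio = asap$ratio, asap_sd = asap$sd, asap_n = asap$n,
    xpress_ratio = xpress$ratio, xpress_sd = xpress$sd, xpress_n = xpress$n,
    peptides = list(peptides)
  )
}

quant_from_node <- function(node, analysis, child) {
  el <- xml2::xml_find_first(
    node, sprintf("./analysis_result[@analysis='%s']/%s", analysis, child)
  )
  if (inherits(el, "xml_missing")) {
    return(list(ratio = NA_real_, sd = NA_real_, n = NA_integer_))
  }
  ratio <- as.numeric(xml2::xml_attr(el, "ratio_mean"))
  list(
    ratio = if (!is.na(ratio) && ratio < 0) NA_real_ else ratio,
    sd = as.numeric(xml2::xml_attr(el, "ratio_standard_dev")),
    n = as.integer(xml2::xml_attr(el, "ratio_number_peptides"))
  )
}

parse_peptide_nodes <- function(peps) {
  if (length(peps) == 0) {
    return(tibble(sequence = character(), charge = integer(),
                  probability = double(), asap_ratio = double(),
                  asap_sd = double(), asap_n = integer(),
                  xpress_ratio = double(), is_nondegenerate = logical()))
  }
  prob <- as.numeric(xml2::xml_attr(peps, "nsp_adjusted_probability"))
  init <- as.numeric(xml2::xml_attr(peps, "initial_probability"))
  prob[is.na(prob)] <- init[is.na(prob)]

  asap_el <- xml2::xml_find_first(
    peps, "./analysis_result[@analysis='asapratio']/ASAPRatio")
  xp_el <- xml2::xml_find_first(
    peps, "./analysis_result[@analysis='xpress']/XPressRatio")
  asap <- as.numeric(xml2::xml_attr(asap_el, "ratio_mean"))
  # attribute fallback for dialects writing quant inline on the peptide
  inline <- as.numeric(xml2::xml_attr(peps, "asap_ratio_mean"))
  asap[is.na(asap)] <- inline[is.na(asap)]
  xp <- as.numeric(xml2::xml_attr(xp_el, "ratio_mean"))
  xp_inline <- as.numeric(xml2::xml_attr(peps, "xpress_ratio_mean"))
  xp[is.na(xp)] <- xp_inline[is.na(xp)]

  tibble(
    sequence = strip_modifications(xml2::xml_attr(peps, "peptide_sequence")),
    charge = as.integer(xml2::xml_attr(peps, "charge")),
    probability = prob,
    asap_ratio = ifelse(!is.na(asap) & asap < 0, NA_real_, asap),
    asap_sd = as.numeric(xml2::xml_attr(asap_el, "ratio_standard_dev")),
    asap_n = as.integer(xml2::xml_attr(asap_el, "ratio_number_peptides")),
    xpress_ratio = ifelse(!is.na(xp) & xp < 0, NA_real_, xp),
    is_nondegenerate = xml2::xml_attr(peps, "is_nondegenerate_evidence") == "Y"
  )
}

# "ABC[147]DEK" / "n[43]ABCK" -> "ABCDEK"/"ABCK": bracketed mass annotations
# and lowercase terminus markers are not residues
strip_modifications <- function(x) {
  gsub("[^A-Z]", "", gsub("\\[[^]]*\\]", "", x))
}

#' Normalize a raw protXML protein name into an accession
#'
#' Recognizes pipe-delimited FASTA-style names (`sp|P12345|TEST_MOUSE`),
#' International Protein Index identifiers (version suffix stripped) and
#' bare UniProt-shaped accessions; anything else passes through with
#' namespace `"unknown"`, which downstream annotation lookup treats as
#' unannotatable (decoy entries typically land here).
#'
#' @param protein_name Character vector of raw protein names.
#' @return A tibble with columns `accession` and `namespace`
#'   (`"uniprot"`, `"ipi"` or `"unknown"`).
#' @examples
#' extract_accession(c("sp|P12345|TEST_MOUSE", "IPI:IPI00112233.1", "decoy_xyz"))
#' @export
extract_accession <- function(protein_name) {
  stopifnot(all(nzchar(protein_name)))
  n <- length(protein_name)
  accession <- protein_name
  namespace <- rep("unknown", n)

  piped <- grepl("|", protein_name, fixed = TRUE)
  if (any(piped)) {
    toks <- strsplit(protein_name[piped], "|", fixed = TRUE)
    accession[piped] <- vapply(toks, function(t) {
      if (length(t) >= 2) t[2] else t[1]
    }, character(1))
    namespace[piped] <- "uniprot"
  }

  ipi <- !piped & grepl("^IPI[:0]", protein_name)
  if (any(ipi)) {
    m <- stringr::str_match(protein_name[ipi], "(IPI\\d+)")
    hit <- !is.na(m[, 2])
    accession[ipi][hit] <- m[hit, 2]
    namespace[ipi][hit] <- "ipi"
  }

  uniprot_pat <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
  bare <- !piped & !ipi & grepl(uniprot_pat, protein_name)
  namespace[bare] <- "uniprot"

  tibble(accession = accession, namespace = namespace)
}

#' Write the mapped-peptide table as TSV
#'
#' One row per displayed peptide with its protein context, position,
#' region class and transformed ratio.  Missing values are written as
#' `"NA"`; column order is fixed, so identical runs produce byte-identical
#' files.
#'
#' @param tidied Peptide-level tibble from [tidy.pepmap_result()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(tidied, path) {
  stopifnot(nrow(tidied) > 0)
  cols <- c("accession", "protein_name", "protein_probability",
            "sequence", "charge", "probability", "start", "end",
            "region_class", "ratio", "log2_ratio", "change_class",
            "validation")
  readr::write_tsv(tidied[, cols], path, na = "NA")
  invisible(path)
}
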