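#' Locate every occurrence of a peptide in a protein sequence
#'
#' Exact substring search returning all (possibly overlapping) matches in
#' ascending start order, 1-based inclusive coordinates.
#' Isoleucine/leucine are distinct: the upstream database search already
#' committed to a residue-level sequence.
#'
#' @param peptide_seq Uppercase peptide sequence.
#' @param protein_seq Uppercase protein sequence.
#' @return A tibble with columns `start` and `end`; zero rows when absent.
#' @examples
#' locate_peptide("MKTAYR", "AAMKTAYRCC")
#' locate_peptide("AA", "AAAA")  # overlapping matches
#' @export
locate_peptide <- function(peptide_seq, protein_seq) {
  stopifnot(nzchar(peptide_seq), nzchar(protein_seq))
  if (nchar(peptide_seq) > nchar(protein_seq)) {
    return(tibble(start = integer(), end = integer()))
  }
  # lookahead finds overlapping occurrences
  pat <- paste0("(?=", gsub("([^A-Za-z0-9])", "\\\\\\1", peptide_seq), ")")
  hits <- gregexpr(pat, protein_seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(tibble(start = integer(), end = integer()))
  starts <- as.integer(hits)
  tibble(start = starts, end = starts + nchar(peptide_seq) - 1L)
}

#' Assign a sequence span to a topological region class
#'
#' Each residue of the span takes the category of the covering feature,
#' overlaps resolved by priority signal > transmembrane > cytoplasmic >
#' extra-cytoplasmic (unclassified features never cover).  A span wholly
#' inside one category gets that category; a span touching two or more
#' categories — or crossing from annotated into unannotated sequence — is
#' `"spanning"`; a span covering no classified feature is `"unannotated"`.
#' The result is invariant under feature-list reordering.
#'
#' @param start,end 1-based inclusive span within the protein.
#' @param features Feature tibble (`category`, `subtype`, `start`, `end`).
#' @param extra_synonyms Passed to [classify_feature()].
#' @return A single region class string.
#' @examples
#' feats <- tibble::tibble(category = c("TOPO_DOM", "TRANSMEM"),
#'                         subtype = c("Cytoplasmic", NA),
#'                         start = c(1L, 11L), end = c(10L, 31L))
#' assign_region(2, 8, feats)
#' assign_region(8, 15, feats)
#' @export
assign_region <- function(start, end, features,
                          extra_synonyms = c("Extracellular", "Lumenal",
                                             "Periplasmic", "Vesicular")) {
  stopifnot(start >= 1, end >= start)
  if (is.null(features) || nrow(features) == 0) return("unannotated")
  priority <- c(extra_cytoplasmic = 1L, cytoplasmic = 2L,
                transmembrane = 3L, signal = 4L)
  reg <- classify_feature(features$category, features$subtype, extra_synonyms)
  pr <- priority[reg]  # NA for unclassified
  res <- seq.int(start, end)
  best <- integer(length(res))
  for (i in seq_len(nrow(features))) {
    if (is.na(pr[i])) next
    idx <- res >= features$start[i] & res <= features$end[i]
    best[idx] <- pmax(best[idx], pr[i])
  }
  cats <- unique(best)
  if (identical(cats, 0L)) return("unannotated")
  if (length(cats) > 1L) return("spanning")
  names(priority)[match(cats, priority)]
}

#' Map one protein's peptides onto its annotated sequence
#'
#' Runs the full per-protein pipeline: duplicate resolution
#' ([dedupe_peptides()]), ratio selection with optional XPRESS validation
#' ([select_ratio()]), log2 transformation and clamping, change
#' classification, sequence placement ([locate_peptide()]) and region
#' assignment ([assign_region()]), then per-region averaging
#' ([region_average()]).
#'
#' A peptide occurring at several positions takes the region of its first
#' occurrence unless the occurrences disagree in category, in which case it
#' is `"ambiguous"`.  Peptides not found in the sequence are `"unmapped"`;
#' with no annotation available every peptide is `"unannotated"`.
#' Spanning, ambiguous, signal, unannotated and unmapped peptides are all
#' excluded from region averages.
#'
#' @param record One protein row from [read_protxml()] (one-row tibble or
#'   list with a `peptides` element).
#' @param annotation One annotation row from [read_annotations()], or
#'   `NULL` when the protein has no annotation.
#' @param config A [run_config()].
#' @return A list with `peptides` (mapped-peptide tibble: sequence, charge,
#'   probability, start, end, n_matches, region_class, ratio, log2_ratio,
#'   change_class, validation, primary) and `regions` (tibble from
#'   [region_average()] for the cytoplasmic and extra-cytoplasmic domains).
#' @export
map_protein <- function(record, annotation = NULL, config = run_config()) {
  peptides <- if (is.data.frame(record)) record$peptides[[1]] else record$peptides
  if (is.data.frame(annotation) && nrow(annotation) == 0) annotation <- NULL

  mapped <- dedupe_peptides(peptides, elaborate = config$elaborate)
  mapped <- select_ratio(mapped, config)
  mapped$log2_ratio <- clamp_log2(to_log2(mapped$ratio, config$invert),
                                  config$rmin, config$rmax)
  cls <- classify_change(mapped$log2_ratio, config$zn, config$zp)
  mapped$change_class <- ifelse(is.na(cls), "unquantified", cls)

  n <- nrow(mapped)
  mapped$start <- rep(NA_integer_, n)
  mapped$end <- rep(NA_integer_, n)
  mapped$n_matches <- rep(0L, n)
  mapped$region_class <- rep("unannotated", n)

  if (!is.null(annotation)) {
    seqs <- if (is.data.frame(annotation)) annotation$sequence[[1]] else annotation$sequence
    feats <- if (is.data.frame(annotation)) annotation$features[[1]] else annotation$features
    syn <- config$extra_synonyms
    for (i in seq_len(n)) {
      pos <- locate_peptide(mapped$sequence[i], seqs)
      mapped$n_matches[i] <- nrow(pos)
      if (nrow(pos) == 0) {
        mapped$region_class[i] <- "unmapped"
        next
      }
      mapped$start[i] <- pos$start[1]
      mapped$end[i] <- pos$end[1]
      regions <- vapply(seq_len(nrow(pos)), function(j) {
        assign_region(pos$start[j], pos$end[j], feats, syn)
      }, character(1))
      mapped$region_class[i] <-
        if (length(unique(regions)) > 1L) "ambiguous" else regions[1]
    }
  }

  regions <- dplyr::bind_rows(
    region_average(mapped, "cytoplasmic"),
    region_average(mapped, "extra_cytoplasmic")
  )
  list(peptides = mapped, regions = regions)
}
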