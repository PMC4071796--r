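#' Load protein annotations from a local file
#'
#' Reads sequence and membrane-topology annotation for a set of accessions
#' from either the package's tabular annotation format or UniProt flat
#' text (detected automatically).  Coordinates are 1-based inclusive on
#' the precursor sequence — the stored sequence always includes any signal
#' peptide, so peptides from unprocessed protein remain mappable.
#'
#' The tabular format is tab-separated with a header row and columns
#' `accession`, `name`, `length`, `mw`, `sequence`, `features`; the
#' feature list is semicolon-separated, e.g.
#' `"TOPO_DOM 1..10 Cytoplasmic; TRANSMEM 11..31; TOPO_DOM 32..100 Extracellular"`.
#' An empty feature field denotes a soluble protein.
#'
#' Features violating `1 <= start <= end <= length` are dropped with a
#' warning; the entry itself is kept with the parsable subset.
#'
#' @param path Path to an annotation file.
#' @return A tibble with columns `accession`, `recommended_name`, `length`,
#'   `molecular_weight`, `sequence` and a list-column `features` of tibbles
#'   (`category`, `subtype`, `start`, `end`).
#' @seealso [write_annotations()], [classify_feature()], [fetch_annotation()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  ann <- if (grepl("^ID\\s", first)) {
    parse_uniprot_flat(readLines(path, warn = FALSE))
  } else {
    parse_annotation_table(path)
  }
  if (nrow(ann) == 0) {
    stop("no annotation entries parsed from ", path, call. = FALSE)
  }
  ann$features <- purrr::pmap(
    list(ann$features, ann$length, ann$accession),
    validate_features
  )
  ann
}

parse_annotation_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    name = readr::col_character(),
    length = readr::col_integer(),
    mw = readr::col_double(),
    sequence = readr::col_character(),
    features = readr::col_character()
  ))
  tibble(
    accession = tab$accession,
    recommended_name = tab$name,
    length = tab$length,
    molecular_weight = tab$mw,
    sequence = tab$sequence,
    features = purrr::map(tab$features, parse_feature_string)
  )
}

empty_features <- function() {
  tibble(category = character(), subtype = character(),
         start = integer(), end = integer())
}

# "TOPO_DOM 1..10 Cytoplasmic; TRANSMEM 11..31" -> feature tibble
parse_feature_string <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(empty_features())
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  m <- stringr::str_match(
    parts, "^(SIGNAL|TRANSMEM|TOPO_DOM)\\s+(\\d+)\\.\\.(\\d+)\\s*(.*)$"
  )
  bad <- is.na(m[, 1])
  if (any(bad)) {
    warning("unparsable feature(s) skipped: ",
            paste(parts[bad], collapse = "; "), call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  tibble(
    category = m[, 2],
    subtype = ifelse(nzchar(trimws(m[, 5])), trimws(m[, 5]), NA_character_),
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4])
  )
}

feature_string <- function(features) {
  if (nrow(features) == 0) return("")
  paste(
    ifelse(is.na(features$subtype),
           sprintf("%s %d..%d", features$category, features$start, features$end),
           sprintf("%s %d..%d %s", features$category, features$start,
                   features$end, features$subtype)),
    collapse = "; "
  )
}

validate_features <- function(features, length, accession) {
  ok <- features$start >= 1L & features$start <= features$end &
    features$end <= length
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sprintf("%s: dropped %d feature(s) outside [1, %d]",
                    accession, sum(!ok), length), call. = FALSE)
  }
  feats <- features[ok, , drop = FALSE]
  # overlapping features are legal (region assignment resolves by priority)
  # but worth flagging once per entry
  if (nrow(feats) > 1) {
    o <- order(feats$start, feats$end)
    if (any(feats$start[o][-1] <= feats$end[o][-nrow(feats)])) {
      message(accession, ": overlapping topological features retained")
    }
  }
  feats
}

#' Write annotations in the tabular annotation format
#'
#' Inverse of the tabular branch of [read_annotations()]; a load-save-load
#' cycle is the identity.
#'
#' @param annotations Annotation tibble from [read_annotations()] or
#'   [fetch_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  tab <- tibble(
    accession = annotations$accession,
    name = annotations$recommended_name,
    length = annotations$length,
    mw = annotations$molecular_weight,
    sequence = annotations$sequence,
    features = purrr::map_chr(annotations$features, feature_string)
  )
  readr::write_tsv(tab, path, na = "NA")
  invisible(path)
}

# --- UniProt flat text (DE/SQ/FT lines) --------------------------------------

parse_uniprot_flat <- function(lines) {
  entry_end <- grep("^//", lines)
  entry_start <- c(1L, head(entry_end, -1) + 1L)
  entries <- purrr::map2(entry_start, entry_end,
                         function(s, e) parse_uniprot_entry(lines[s:(e - 1)]))
  dplyr::bind_rows(purrr::compact(entries))
}

parse_uniprot_entry <- function(lines) {
  ac <- grep("^AC\\s", lines, value = TRUE)
  if (length(ac) == 0) return(NULL)
  accession <- trimws(strsplit(sub("^AC\\s+", "", ac[1]), ";")[[1]][1])

  de <- grep("^DE\\s+RecName: Full=", lines, value = TRUE)
  name <- if (length(de)) {
    sub(";.*$", "", sub("^DE\\s+RecName: Full=", "", de[1]))
  } else {
    accession
  }
  name <- sub("\\s*\\{[^}]*\\}", "", name)  # strip evidence tags

  sq <- grep("^SQ\\s", lines, value = TRUE)
  mw <- NA_real_
  if (length(sq)) {
    m <- stringr::str_match(sq[1], "(\\d+)\\s+MW")
    if (!is.na(m[1, 2])) mw <- as.numeric(m[1, 2])
  }
  sq_at <- grep("^SQ\\s", lines)
  sequence <- ""
  if (length(sq_at)) {
    seq_lines <- lines[seq(sq_at[1] + 1L, length(lines))]
    sequence <- gsub("[^A-Z]", "", paste(seq_lines, collapse = ""))
  }
  if (!nzchar(sequence)) return(NULL)

  tibble(
    accession = accession,
    recommended_name = name,
    length = nchar(sequence),
    molecular_weight = mw,
    sequence = sequence,
    features = list(parse_uniprot_features(lines))
  )
}

# Modern FT layout: "FT   TRANSMEM        30..52" followed by
# 'FT                   /note="Helical"' continuation lines.
parse_uniprot_features <- function(lines) {
  ft <- grep("^FT\\s", lines, value = TRUE)
  if (length(ft) == 0) return(empty_features())
  key <- stringr::str_match(ft, "^FT   (\\S+)\\s+(\\d+)\\.\\.(\\d+)")
  note <- stringr::str_match(ft, "^FT\\s+/note=\"([^\"]*)\"")
  feats <- list()
  current <- NULL
  for (i in seq_along(ft)) {
    if (!is.na(key[i, 1])) {
      if (!is.null(current)) feats[[length(feats) + 1]] <- current
      current <- list(category = key[i, 2], subtype = NA_character_,
                      start = as.integer(key[i, 3]), end = as.integer(key[i, 4]))
    } else if (!is.na(note[i, 1]) && !is.null(current)) {
      if (is.na(current$subtype)) current$subtype <- note[i, 2]
    }
  }
  if (!is.null(current)) feats[[length(feats) + 1]] <- current
  out <- dplyr::bind_rows(feats)
  out <- out[out$category %in% c("SIGNAL", "TRANSMEM", "TOPO_DOM"), , drop = FALSE]
  if (nrow(out) == 0) return(empty_features())
  # TRANSMEM "Helical" notes are not topology subtypes
  out$subtype[out$category != "TOPO_DOM"] <- NA_character_
  out
}

#' Classify topological features into region categories
#'
#' Maps stored feature annotation onto the four region categories used for
#' peptide assignment: cytoplasmic domains, extra-cytoplasmic domains
#' (extracellular, lumenal and configurable synonyms such as periplasmic),
#' transmembrane segments and signal peptides.  Topological domains whose
#' description matches none of these are `"unclassified"` and never define
#' a region.
#'
#' @param category Character vector: `SIGNAL`, `TRANSMEM` or `TOPO_DOM`.
#' @param subtype Topological-domain description (`Cytoplasmic`,
#'   `Extracellular`, ...); ignored for the other categories.
#' @param extra_synonyms Descriptions treated as extra-cytoplasmic
#'   (case-insensitive).
#' @return Character vector in `{"cytoplasmic", "extra_cytoplasmic",
#'   "transmembrane", "signal", "unclassified"}`.
#' @examples
#' classify_feature("TOPO_DOM", "Lumenal")
#' classify_feature("TRANSMEM", NA)
#' @export
classify_feature <- function(category, subtype = NA_character_,
                             extra_synonyms = c("Extracellular", "Lumenal",
                                                "Periplasmic", "Vesicular")) {
  subtype_lc <- tolower(ifelse(is.na(subtype), "", subtype))
  extra_lc <- tolower(extra_synonyms)
  out <- rep("unclassified", length(category))
  out[category == "TRANSMEM"] <- "transmembrane"
  out[category == "SIGNAL"] <- "signal"
  topo <- category == "TOPO_DOM"
  out[topo & subtype_lc == "cytoplasmic"] <- "cytoplasmic"
  out[topo & subtype_lc %in% extra_lc] <- "extra_cytoplasmic"
  out
}

#' Fetch one annotation entry from UniProt
#'
#' Downloads the flat-text record for a UniProt accession and parses it
#' with the same code path as [read_annotations()], so fetched entries can
#' be cached with [write_annotations()] and reloaded identically.  Requires
#' network access; analysis pipelines treat a failed lookup as an
#' unannotated protein and continue.
#'
#' IPI identifiers cannot be fetched (the International Protein Index was
#' retired); supply a local annotation file or a mapping to UniProt
#' accessions instead.
#'
#' @param accession A UniProt accession.
#' @param base_url Endpoint serving flat-text records.
#' @return A one-row annotation tibble.
#' @export
fetch_annotation <- function(accession,
                             base_url = "https://rest.uniprot.org/uniprotkb") {
  if (grepl("^IPI", accession)) {
    stop("cannot fetch IPI identifier '", accession,
         "': the IPI database is retired; provide a local annotation file",
         call. = FALSE)
  }
  if (!grepl("^[A-Z][A-Z0-9]{5,9}$", accession)) {
    stop("'", accession, "' is not a UniProt-shaped accession", call. = FALSE)
  }
  con <- url(sprintf("%s/%s.txt", base_url, accession))
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  lines <- tryCatch(readLines(con, warn = FALSE), error = function(e) {
    stop("annotation lookup failed for ", accession, ": ",
         conditionMessage(e), call. = FALSE)
  })
  ann <- parse_uniprot_flat(lines)
  if (nrow(ann) == 0) {
    stop("no parsable UniProt entry returned for ", accession, call. = FALSE)
  }
  ann$features <- purrr::pmap(list(ann$features, ann$length, ann$accession),
                              validate_features)
  ann
}
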