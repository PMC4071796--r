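#' Run the full peptide-mapping pipeline
#'
#' Parses (or accepts) a protein table, applies the ProteinProphet
#' probability filter, looks up topology annotation per accession, maps
#' and quantifies every valid protein ([map_protein()]) and summarizes the
#' run.  This is the programmatic equivalent of the command-line tool.
#'
#' @param protxml Path to a protXML file, or a protein tibble from
#'   [read_protxml()].
#' @param annotations Path to an annotation file, an annotation tibble
#'   from [read_annotations()], or `NULL` (all proteins unannotated).
#' @param config A [run_config()].
#' @param fetch Attempt [fetch_annotation()] for uniprot-namespace
#'   accessions missing from `annotations` (requires network access);
#'   failures degrade to unannotated.
#' @return An object of class `pepmap_result`: a list with
#'   * `proteins` — one row per valid protein with nested `mapped`
#'     peptides and unnested region means (`cyto_mean`, `cyto_n`,
#'     `extra_mean`, `extra_n`), protein-level `protein_log2`, and
#'     annotation flags (`annotated`, `has_tm`, `n_tm`, `has_signal`,
#'     `tail_length`);
#'   * `discarded` — sub-threshold proteins with reasons;
#'   * `annotations`, `config`, `summary` (from [summarize_run()]).
#' @examples
#' fx <- synth_fixture(n = 5, dir = tempfile(), seed = 7)
#' res <- pepmap(fx$protxml, fx$annotations)
#' glance(res)
#' @export
pepmap <- function(protxml, annotations = NULL, config = run_config(),
                   fetch = FALSE) {
  proteins <- if (is.character(protxml)) read_protxml(protxml) else protxml
  ann <- if (is.character(annotations)) read_annotations(annotations) else annotations

  split <- filter_proteins(proteins, config$threshold)
  valid <- split$valid

  if (fetch && !is.null(ann)) {
    missing <- setdiff(valid$accession[valid$namespace == "uniprot"],
                       ann$accession)
    for (acc in missing) {
      fetched <- tryCatch(fetch_annotation(acc), error = function(e) {
        message("annotation lookup failed, continuing unannotated: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(fetched)) ann <- dplyr::bind_rows(ann, fetched)
    }
  }

  per_protein <- purrr::map(seq_len(nrow(valid)), function(i) {
    a <- annotation_for(ann, valid$accession[i])
    map_protein(valid[i, ], a, config)
  })

  valid$mapped <- purrr::map(per_protein, "peptides")
  valid$regions <- purrr::map(per_protein, "regions")
  valid$protein_log2 <- clamp_log2(to_log2(valid$asap_ratio, config$invert),
                                   config$rmin, config$rmax)
  valid$cyto_mean <- region_col(valid$regions, "cytoplasmic", "mean_log2")
  valid$cyto_n <- region_col(valid$regions, "cytoplasmic", "n_peptides")
  valid$extra_mean <- region_col(valid$regions, "extra_cytoplasmic", "mean_log2")
  valid$extra_n <- region_col(valid$regions, "extra_cytoplasmic", "n_peptides")

  feat <- purrr::map(valid$accession, function(acc) {
    a <- annotation_for(ann, acc)
    if (is.null(a)) return(list(annotated = FALSE, n_tm = NA_integer_,
                                has_signal = NA, tail_length = NA_integer_))
    f <- a$features[[1]]
    tm <- f[f$category == "TRANSMEM", , drop = FALSE]
    tail_len <- NA_integer_
    if (nrow(tm) == 1) {
      reg <- classify_feature(f$category, f$subtype, config$extra_synonyms)
      cyto_before <- which(reg == "cytoplasmic" & f$start < tm$start[1])
      if (length(cyto_before)) {
        j <- cyto_before[which.max(f$end[cyto_before])]
        tail_len <- f$end[j] - f$start[j] + 1L
      }
    }
    list(annotated = TRUE, n_tm = nrow(tm),
         has_signal = any(f$category == "SIGNAL"), tail_length = tail_len)
  })
  valid$annotated <- purrr::map_lgl(feat, "annotated")
  valid$n_tm <- purrr::map_int(feat, "n_tm")
  valid$has_tm <- !is.na(valid$n_tm) & valid$n_tm > 0
  valid$has_signal <- purrr::map_lgl(feat, "has_signal")
  valid$tail_length <- purrr::map_int(feat, "tail_length")

  res <- structure(
    list(proteins = valid, discarded = split$discarded, annotations = ann,
         config = config, source = attr(proteins, "source_file")),
    class = "pepmap_result"
  )
  res$summary <- summarize_run(res)
  res
}

annotation_for <- function(ann, accession) {
  if (is.null(ann)) return(NULL)
  i <- match(accession, ann$accession)
  if (is.na(i)) NULL else ann[i, , drop = FALSE]
}

region_col <- function(regions, region, col) {
  purrr::map_dbl(regions, function(r) {
    v <- r[[col]][r$region == region]
    if (length(v)) v else NA_real_
  })
}

#' @export
print.pepmap_result <- function(x, ...) {
  s <- x$summary
  cat("<pepmap_result>\n")
  cat(sprintf("  %d valid proteins (%d discarded below threshold %.2f)\n",
              nrow(x$proteins), nrow(x$discarded), x$config$threshold))
  cat(sprintf("  %d with transmembrane domain (%d%%), %d of those without signal peptide (%d%%)\n",
              s$n_tm, s$pct_tm, s$n_tm_no_signal, s$pct_tm_no_signal))
  cat(sprintf("  quantified cytoplasmic / extra-cytoplasmic domains: %d / %d proteins\n",
              s$n_tm_cyto_quant, s$n_tm_extra_quant))
  invisible(x)
}

#' Peptide-level tidy view of a mapped run
#'
#' One row per displayed peptide with protein context — the table behind
#' the TSV export ([write_peptide_table()]).
#'
#' @param x A `pepmap_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pepmap_result <- function(x, ...) {
  p <- x$proteins
  cols <- c("accession", "protein_name", "protein_probability", "sequence",
            "charge", "probability", "start", "end", "n_matches",
            "region_class", "ratio", "log2_ratio", "change_class",
            "validation", "primary")
  if (nrow(p) == 0) {
    return(tibble(accession = character(), protein_name = character(),
                  protein_probability = double(), sequence = character(),
                  charge = integer(), probability = double(),
                  start = integer(), end = integer(), n_matches = integer(),
                  region_class = character(), ratio = double(),
                  log2_ratio = double(), change_class = character(),
                  validation = character(), primary = logical()))
  }
  out <- purrr::map(seq_len(nrow(p)), function(i) {
    m <- p$mapped[[i]]
    m$accession <- p$accession[i]
    m$protein_name <- p$protein_name[i]
    m$protein_probability <- p$probability[i]
    m
  })
  out <- dplyr::bind_rows(out)
  out[, cols]
}

#' One-row summary of a mapped run
#'
#' @param x A `pepmap_result`.
#' @param ... Unused.
#' @return A one-row tibble of run-level counts and percentages.
#' @export
glance.pepmap_result <- function(x, ...) {
  x$summary
}

#' Histogram of fold-change values
#'
#' @param object A `pepmap_result` or `pepmap_fc` object.
#' @param category Passed to [fc_distribution()] for a `pepmap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pepmap_result <- function(object, category = "all", ...) {
  autoplot(fc_distribution(object, category))
}

#' @rdname autoplot.pepmap_result
#' @export
autoplot.pepmap_fc <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 0.24, fill = "grey35") +
    ggplot2::labs(x = "log2 light:heavy ratio", y = "count",
                  title = paste0("Fold-change distribution (",
                                 object$category, ")")) +
    ggplot2::theme_minimal()
}

#' Peptide map of one protein as a ggplot
#'
#' Draws the linear sequence with its topological features and the mapped
#' peptides coloured by their clamped log2 ratio on the red-green scale.
#'
#' @param result A `pepmap_result`.
#' @param accession Protein to draw.
#' @return A ggplot.
#' @export
plot_protein_map <- function(result, accession) {
  i <- match(accession, result$proteins$accession)
  if (is.na(i)) stop("accession not in result: ", accession, call. = FALSE)
  p <- result$proteins[i, ]
  ann <- annotation_for(result$annotations, accession)
  len <- if (!is.null(ann)) ann$length[[1]] else max(p$mapped[[1]]$end, 100, na.rm = TRUE)
  feats <- if (!is.null(ann)) ann$features[[1]] else empty_features()
  feats$region <- classify_feature(feats$category, feats$subtype,
                                   result$config$extra_synonyms)
  m <- p$mapped[[1]]
  m <- m[!is.na(m$start), , drop = FALSE]
  m$color <- color_for_ratio(ifelse(is.na(m$log2_ratio), 0, m$log2_ratio),
                             result$config)
  m$color[is.na(m$log2_ratio)] <- "#C0C0C0"
  g <- ggplot2::ggplot() +
    ggplot2::annotate("rect", xmin = 1, xmax = len, ymin = 0, ymax = 0.3,
                      fill = "grey85", colour = "grey40")
  if (nrow(feats)) {
    g <- g + ggplot2::geom_rect(
      data = feats,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, fill = .data$region),
      ymin = 0, ymax = 0.3, colour = NA, alpha = 0.9
    )
  }
  if (nrow(m)) {
    g <- g + ggplot2::geom_rect(
      data = m,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = 0.4, ymax = 0.7, fill = m$color, colour = "grey20"
    )
  }
  g + ggplot2::scale_fill_manual(values = c(
        cytoplasmic = "#4477AA", extra_cytoplasmic = "#DDCC77",
        transmembrane = "#555555", signal = "#EE7733",
        unclassified = "grey70")) +
    ggplot2::labs(title = sprintf("%s — %s", accession, p$protein_name),
                  x = "residue", y = NULL, fill = "region") +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-0.1, 0.9)) +
    ggplot2::theme_minimal()
}
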