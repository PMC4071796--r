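#' Run-level summary counts and percentages
#'
#' Counts, over the valid proteins of a run: quantified proteins, proteins
#' with an annotated transmembrane domain, proteins with a signal peptide,
#' transmembrane proteins lacking a signal peptide, and transmembrane
#' proteins with at least one quantified cytoplasmic or extra-cytoplasmic
#' peptide — together with the percentages of each count relative to its
#' natural denominator (transmembrane counts relative to the
#' transmembrane-protein total, the rest relative to all quantified
#' proteins).
#'
#' @param result A `pepmap_result` from [pepmap()].
#' @return A one-row tibble (see [run_summary_from_counts()]).
#' @export
summarize_run <- function(result) {
  p <- result$proteins
  if (nrow(p) == 0) return(run_summary_from_counts(0, 0, 0, 0, 0, 0))
  quantified <- !is.na(p$protein_log2) |
    purrr::map_lgl(p$mapped, function(m) any(!is.na(m$log2_ratio)))
  tm <- quantified & p$has_tm %in% TRUE
  run_summary_from_counts(
    n_total = sum(quantified),
    n_tm = sum(tm),
    n_signal = sum(quantified & p$has_signal %in% TRUE),
    n_tm_no_signal = sum(tm & !(p$has_signal %in% TRUE)),
    n_tm_cyto_quant = sum(tm & !is.na(p$cyto_mean)),
    n_tm_extra_quant = sum(tm & !is.na(p$extra_mean))
  )
}

#' Build a run summary from raw counts
#'
#' Computes the derived percentages from externally supplied counts, e.g.
#' to re-derive the percentages a published run reports from its printed
#' count table.  Percentages are rounded to whole numbers; a zero
#' denominator yields `NA`.
#'
#' @param n_total Quantified proteins.
#' @param n_tm Proteins with an annotated transmembrane (TM) domain.
#' @param n_signal Proteins with a signal peptide.
#' @param n_tm_no_signal TM proteins without a signal peptide.
#' @param n_tm_cyto_quant TM proteins with quantified cytoplasmic peptides.
#' @param n_tm_extra_quant TM proteins with quantified extra-cytoplasmic
#'   peptides.
#' @return A one-row tibble with the six counts and percentages `pct_tm`
#'   (of total), `pct_signal` (of total), `pct_tm_no_signal`,
#'   `pct_tm_cyto_quant`, `pct_tm_extra_quant` (each of `n_tm`).
#' @examples
#' run_summary_from_counts(1231, 629, 171, 458, 385, 362)[, c("pct_tm", "pct_tm_no_signal")]
#' @export
run_summary_from_counts <- function(n_total, n_tm, n_signal = 0,
                                    n_tm_no_signal = 0, n_tm_cyto_quant = 0,
                                    n_tm_extra_quant = 0) {
  stopifnot(n_tm <= n_total, n_tm_no_signal <= n_tm,
            n_tm_cyto_quant <= n_tm, n_tm_extra_quant <= n_tm)
  pct <- function(x, d) if (d > 0) round(100 * x / d) else NA_real_
  tibble(
    n_total = as.integer(n_total), n_tm = as.integer(n_tm),
    n_signal = as.integer(n_signal),
    n_tm_no_signal = as.integer(n_tm_no_signal),
    n_tm_cyto_quant = as.integer(n_tm_cyto_quant),
    n_tm_extra_quant = as.integer(n_tm_extra_quant),
    pct_tm = pct(n_tm, n_total),
    pct_signal = pct(n_signal, n_total),
    pct_tm_no_signal = pct(n_tm_no_signal, n_tm),
    pct_tm_cyto_quant = pct(n_tm_cyto_quant, n_tm),
    pct_tm_extra_quant = pct(n_tm_extra_quant, n_tm)
  )
}

#' Fold-change distribution of a run
#'
#' Collects log2 light:heavy values for one of four views — protein-level
#' ratios of all valid proteins, the same restricted to
#' transmembrane proteins, or the per-protein cytoplasmic /
#' extra-cytoplasmic domain means — and bins them with fixed width 0.25
#' over the configured \[rmin, rmax\] display range.
#'
#' @param result A `pepmap_result`.
#' @param category One of `"all"`, `"tm"`, `"cytoplasmic_domains"`,
#'   `"extra_cytoplasmic_domains"`.
#' @return A list of class `pepmap_fc` with `values` (numeric vector),
#'   `histogram` (tibble `bin_start`, `bin_end`, `count`; counts sum to
#'   `length(values)`) and `category`.
#' @export
fc_distribution <- function(result,
                            category = c("all", "tm", "cytoplasmic_domains",
                                         "extra_cytoplasmic_domains")) {
  category <- match.arg(category)
  p <- result$proteins
  values <- switch(
    category,
    all = p$protein_log2,
    tm = p$protein_log2[p$has_tm %in% TRUE],
    cytoplasmic_domains = p$cyto_mean,
    extra_cytoplasmic_domains = p$extra_mean
  )
  values <- values[!is.na(values)]
  cfg <- result$config
  breaks <- seq(cfg$rmin, cfg$rmax, by = 0.25)
  if (length(values)) {
    h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    counts <- h$counts
  } else {
    counts <- integer(length(breaks) - 1L)
  }
  structure(
    list(values = values,
         histogram = tibble(bin_start = head(breaks, -1),
                            bin_end = breaks[-1],
                            count = as.integer(counts)),
         category = category),
    class = "pepmap_fc"
  )
}

#' Screen for candidate substrates of SPPL-type intramembrane proteases
#'
#' Known SPPL2a/b substrates are single-pass type 2 transmembrane proteins
#' whose short cytoplasmic tail accumulates (its N-terminal fragment is no
#' longer cleared by intramembrane proteolysis) after the ectodomain has
#' been shed.  A valid protein is flagged when it
#' 1. has exactly one annotated transmembrane segment,
#' 2. is in type 2 orientation — a cytoplasmic topological domain starts
#'    before the transmembrane segment and an extra-cytoplasmic domain
#'    follows it, and
#' 3. has a quantified cytoplasmic domain mean above `fc_cutoff`
#'    (default 1.0 in log2, i.e. more than 2-fold accumulation).
#'
#' A short cytoplasmic tail is characteristic of the known substrates but
#' is not enforced by default; set `max_tail_length` to add that filter.
#'
#' @param result A `pepmap_result`.
#' @param fc_cutoff Minimum cytoplasmic-domain mean log2 ratio.
#' @param max_tail_length Optional maximum cytoplasmic-tail length in
#'   residues (`Inf` disables).
#' @return Tibble of candidates: `accession`, `protein_name`,
#'   `tail_length`, `cyto_mean`, `cyto_n`, `extra_mean`, `extra_n`,
#'   `reason`.
#' @export
screen_sppl_candidates <- function(result, fc_cutoff = 1.0,
                                   max_tail_length = Inf) {
  p <- result$proteins
  ann <- result$annotations
  hit <- purrr::map_lgl(seq_len(nrow(p)), function(i) {
    if (!(p$annotated[i] %in% TRUE) || is.na(p$n_tm[i]) || p$n_tm[i] != 1L) {
      return(FALSE)
    }
    a <- annotation_for(ann, p$accession[i])
    f <- a$features[[1]]
    reg <- classify_feature(f$category, f$subtype, result$config$extra_synonyms)
    tm_start <- f$start[f$category == "TRANSMEM"][1]
    tm_end <- f$end[f$category == "TRANSMEM"][1]
    type2 <- any(reg == "cytoplasmic" & f$start < tm_start) &&
      any(reg == "extra_cytoplasmic" & f$start > tm_end)
    if (!type2) return(FALSE)
    if (!is.na(p$tail_length[i]) && p$tail_length[i] > max_tail_length) {
      return(FALSE)
    }
    !is.na(p$cyto_mean[i]) && p$cyto_mean[i] > fc_cutoff
  })
  cand <- p[hit, , drop = FALSE]
  tibble(
    accession = cand$accession,
    protein_name = cand$protein_name,
    tail_length = cand$tail_length,
    cyto_mean = cand$cyto_mean,
    cyto_n = cand$cyto_n,
    extra_mean = cand$extra_mean,
    extra_n = cand$extra_n,
    reason = sprintf(
      "single TM, type 2 orientation, cytoplasmic mean log2 %.2f > %.2f",
      cand$cyto_mean, fc_cutoff)
  )
}
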