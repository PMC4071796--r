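#' Run configuration
#'
#' Bundles the user-adjustable options that govern filtering, ratio
#' transformation and display.  Defaults reproduce the tool's standard
#' behaviour: proteins below ProteinProphet probability 0.90 are rejected,
#' log2 light:heavy ratios are clamped to \[-3, 3\] (which also defines the
#' endpoints of the red-green colour scale), and ratios within
#' \[-0.25, 0.25\] are treated as unchanged.
#'
#' @param invert Flip light:heavy to heavy:light, i.e. negate every log2
#'   ratio.  Default off.
#' @param validate Cross-check each peptide's ASAPRatio against its XPRESS
#'   ratio; peptides whose two quantitations disagree by more than
#'   `validation_tolerance` in log2 are kept in the display but excluded
#'   from per-region averages.  Default off.
#' @param elaborate Keep every occurrence of a repeatedly identified
#'   peptide instead of only the one with the highest PeptideProphet
#'   probability.  Default off.
#' @param threshold ProteinProphet probability cutoff; proteins with a
#'   score strictly below it are discarded.  Default 0.90.
#' @param rmin,rmax Minimum/maximum allowed log2 peptide ratio; values
#'   outside saturate at the bound.  Defaults -3.0 and 3.0.
#' @param zn,zp Negative/positive bounds of the no-change zone (inclusive).
#'   Defaults -0.25 and 0.25.
#' @param validation_tolerance Maximum tolerated |log2(ASAP) - log2(XPRESS)|
#'   when `validate` is on.  Default 1.0.
#' @param extra_synonyms Topological-domain descriptions (beyond
#'   Extracellular/Lumenal) treated as extra-cytoplasmic, matched
#'   case-insensitively.
#' @param color_up Direction of the red-green scale: `"green"` (default)
#'   colours increases green and decreases red; `"red"` swaps the channels.
#' @param corrected_browser_note Use the corrected spelling
#'   `supported_browsers_and_os.txt` for the browser-compatibility note in
#'   the output bundle instead of the historical file name.
#'
#' @return A list of class `pepmap_config`.
#' @examples
#' run_config(invert = TRUE, threshold = 0.95)
#' @export
run_config <- function(invert = FALSE, validate = FALSE, elaborate = FALSE,
                       threshold = 0.90, rmin = -3.0, rmax = 3.0,
                       zn = -0.25, zp = 0.25, validation_tolerance = 1.0,
                       extra_synonyms = c("Extracellular", "Lumenal",
                                          "Periplasmic", "Vesicular"),
                       color_up = c("green", "red"),
                       corrected_browser_note = FALSE) {
  color_up <- match.arg(color_up)
  if (!(threshold >= 0 && threshold <= 1)) {
    stop("`threshold` must lie in [0, 1], got ", threshold, call. = FALSE)
  }
  if (!(rmin < zn && zn <= 0 && 0 <= zp && zp < rmax)) {
    stop("configuration bounds must satisfy rmin < zn <= 0 <= zp < rmax",
         call. = FALSE)
  }
  if (!(validation_tolerance > 0)) {
    stop("`validation_tolerance` must be positive", call. = FALSE)
  }
  structure(
    list(invert = isTRUE(invert), validate = isTRUE(validate),
         elaborate = isTRUE(elaborate), threshold = threshold,
         rmin = rmin, rmax = rmax, zn = zn, zp = zp,
         validation_tolerance = validation_tolerance,
         extra_synonyms = extra_synonyms, color_up = color_up,
         corrected_browser_note = isTRUE(corrected_browser_note)),
    class = "pepmap_config"
  )
}

#' @export
print.pepmap_config <- function(x, ...) {
  cat("<pepmap_config>\n")
  cat(sprintf("  threshold: %.2f  rmin/rmax: %.2f/%.2f  zn/zp: %.2f/%.2f\n",
              x$threshold, x$rmin, x$rmax, x$zn, x$zp))
  cat(sprintf("  invert: %s  validate: %s (tol %.2f)  elaborate: %s\n",
              x$invert, x$validate, x$validation_tolerance, x$elaborate))
  invisible(x)
}

#' Split proteins into valid and discarded sets by ProteinProphet probability
#'
#' A protein is valid when its probability is greater than or equal to the
#' cutoff; proteins strictly below it are discarded.  Document order is
#' preserved within each set.
#'
#' @param proteins Protein tibble as returned by [read_protxml()].
#' @param threshold Probability cutoff in \[0, 1\].
#' @return A list with elements `valid` (tibble) and `discarded` (tibble
#'   with an added `reason` column).
#' @examples
#' ps <- tibble::tibble(accession = c("A", "B"), probability = c(0.95, 0.5))
#' filter_proteins(ps, 0.9)$discarded$accession
#' @export
filter_proteins <- function(proteins, threshold = 0.90) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- proteins$probability >= threshold
  keep[is.na(keep)] <- FALSE
  discarded <- proteins[!keep, , drop = FALSE]
  discarded$reason <- sprintf(
    "ProteinProphet probability %.4g below cutoff %.4g",
    discarded$probability, threshold
  )
  list(valid = proteins[keep, , drop = FALSE], discarded = discarded)
}

#' Select the reported ratio for each peptide, optionally cross-validating
#'
#' The ASAPRatio mean is the reported quantitation.  With `validate` on and
#' both quantitations present, the peptide passes when
#' |log2(ASAP) - log2(XPRESS)| is within the configured tolerance; with
#' XPRESS (or ASAPRatio) absent the check is untestable.  Failing peptides
#' stay visible per peptide but are excluded from region averages.
#'
#' @param peptides Peptide tibble with columns `asap_ratio` and
#'   `xpress_ratio` (NA for absent).
#' @param config A [run_config()].
#' @return The input tibble with columns `ratio` (selected linear L:H
#'   ratio) and `validation` (one of `"untested"`, `"pass"`, `"fail"`,
#'   `"untestable"`).
#' @export
select_ratio <- function(peptides, config = run_config()) {
  asap <- peptides$asap_ratio
  xpress <- if ("xpress_ratio" %in% names(peptides)) {
    peptides$xpress_ratio
  } else {
    rep(NA_real_, nrow(peptides))
  }
  validation <- rep("untested", length(asap))
  if (config$validate) {
    validation <- rep("untestable", length(asap))
    both <- !is.na(asap) & !is.na(xpress) & asap > 0 & xpress > 0
    delta <- abs(log2(asap[both]) - log2(xpress[both]))
    validation[both] <- ifelse(delta <= config$validation_tolerance,
                               "pass", "fail")
  }
  peptides$ratio <- asap
  peptides$validation <- validation
  peptides
}

#' Log2-transform a linear light:heavy ratio
#'
#' A ratio of 0 maps to `-Inf` and the XPRESS "infinite ratio" convention
#' (values of 9999 or more) to `+Inf`; both saturate at the configured
#' bounds once clamped.  With `invert` on the result is negated,
#' converting light:heavy into heavy:light fold changes.
#'
#' @param ratio Numeric vector of linear L:H ratios (NA for absent).
#' @param invert Negate the result.
#' @return Numeric vector of log2 ratios.
#' @examples
#' to_log2(c(1, 2, 0.25))
#' to_log2(2, invert = TRUE)
#' @export
to_log2 <- function(ratio, invert = FALSE) {
  if (any(ratio < 0, na.rm = TRUE)) {
    stop("negative linear ratio: absent quantitations must be NA", call. = FALSE)
  }
  out <- ifelse(ratio >= 9999, Inf, ifelse(ratio == 0, -Inf, log2(ratio)))
  if (isTRUE(invert)) -out else out
}

#' Clamp log2 ratios to the configured display range
#'
#' Values below `rmin` or above `rmax` (including infinities) saturate at
#' the bound; this both scales the colour map and caps the influence of
#' extreme single-peptide quantitations on region averages.
#'
#' @param x Numeric vector of log2 ratios.
#' @param rmin,rmax Lower/upper bound, `rmin < rmax`.
#' @return Numeric vector within \[`rmin`, `rmax`\].
#' @examples
#' clamp_log2(c(-7, 1.4, 5.2))
#' @export
clamp_log2 <- function(x, rmin = -3.0, rmax = 3.0) {
  stopifnot(rmin < rmax)
  pmin(pmax(x, rmin), rmax)
}

#' Classify a clamped log2 ratio as up, down or no change
#'
#' The no-change zone \[`zn`, `zp`\] is inclusive at both ends.
#'
#' @param x Numeric vector of clamped log2 ratios.
#' @param zn,zp No-change bounds, `zn <= zp`.
#' @return Character vector in `{"up", "down", "no_change"}` (NA in, NA out).
#' @examples
#' classify_change(c(-0.3, 0.1, 0.3))
#' @export
classify_change <- function(x, zn = -0.25, zp = 0.25) {
  stopifnot(zn <= zp)
  ifelse(is.na(x), NA_character_,
         ifelse(x > zp, "up", ifelse(x < zn, "down", "no_change")))
}

#' Resolve repeatedly identified peptides
#'
#' By default one record is kept per stripped sequence (charge-agnostic):
#' the occurrence with the highest PeptideProphet probability, ties broken
#' by the larger number of quantified spectra, then by first occurrence.
#' With `elaborate` every occurrence is kept, occurrences of the same
#' sequence made adjacent, and the column `primary` marks the occurrence
#' the default rule would have chosen (region averages always use the
#' primary set).
#'
#' @param peptides Peptide tibble with columns `sequence`, `probability`
#'   and optionally `asap_n`.
#' @param elaborate Keep all occurrences.
#' @return Tibble with a logical `primary` column.
#' @export
dedupe_peptides <- function(peptides, elaborate = FALSE) {
  if (nrow(peptides) == 0) {
    peptides$primary <- logical(0)
    return(peptides)
  }
  n_spec <- if ("asap_n" %in% names(peptides)) peptides$asap_n else rep(NA_real_, nrow(peptides))
  n_spec[is.na(n_spec)] <- -1
  ord <- order(match(peptides$sequence, unique(peptides$sequence)),
               -peptides$probability, -n_spec,
               seq_len(nrow(peptides)))
  out <- peptides[ord, , drop = FALSE]
  out$primary <- !duplicated(out$sequence)
  if (isTRUE(elaborate)) out else out[out$primary, , drop = FALSE]
}

#' Average the clamped log2 ratios of one topological region
#'
#' The per-domain fold change is the arithmetic mean, in log2 space, over
#' deduplicated, quantified, validation-passing peptides assigned wholly to
#' that region.  Averaging in log space treats up- and down-regulation
#' symmetrically.
#'
#' @param mapped Mapped-peptide tibble (see [map_protein()]).
#' @param region `"cytoplasmic"` or `"extra_cytoplasmic"`.
#' @return A one-row tibble (`region`, `n_peptides`, `mean_log2`), or a
#'   zero-row tibble when no peptide contributes.
#' @export
region_average <- function(mapped, region = c("cytoplasmic", "extra_cytoplasmic")) {
  region <- match.arg(region)
  primary <- if ("primary" %in% names(mapped)) mapped$primary else rep(TRUE, nrow(mapped))
  use <- primary &
    mapped$region_class == region &
    !is.na(mapped$log2_ratio) &
    mapped$validation != "fail"
  empty <- tibble(region = character(), n_peptides = integer(),
                  mean_log2 = double())
  if (!any(use)) return(empty)
  tibble(region = region, n_peptides = sum(use),
         mean_log2 = mean(mapped$log2_ratio[use]))
}
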