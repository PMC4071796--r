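# Synthetic protXML + annotation fixtures with known ground truth.
# The generator emulates a stable-isotope (light:heavy) membrane-proteomics
# run: proteins with defined topology, in-silico tryptic digestion, and
# per-region true log2 effects observed with Gaussian noise.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# average residue masses (Da); peptide/protein MW = sum + one water
AA_MASS <- c(A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
             E = 129.12, Q = 128.13, G = 57.05, H = 137.14, I = 113.16,
             L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
             S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13)

protein_mw <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  m <- AA_MASS[aa]
  sum(m, na.rm = TRUE) + 18.02
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, force(code))
}

#' Describe one synthetic protein with known topology and true effects
#'
#' Generates a random amino-acid sequence (uniform over the 20 canonical
#' residues) and a feature table following a topology template:
#' * `"type2"` — cytoplasmic N-terminal tail, one transmembrane segment,
#'   large extra-cytoplasmic ectodomain (the topology of known SPPL2a/b
#'   substrates such as the invariant chain CD74, whose tail spans 29
#'   residues);
#' * `"type1"` — signal peptide, ectodomain, one transmembrane segment,
#'   C-terminal cytoplasmic tail;
#' * `"multi"` — `n_tm` membrane passes with alternating cytoplasmic and
#'   extracellular loops, starting cytoplasmic;
#' * `"soluble"` — no features.
#'
#' @param template Topology template name.
#' @param length Total residue count of the precursor.
#' @param tail_length Length of the cytoplasmic tail (type1/type2).
#' @param tm_length Length of each transmembrane segment.
#' @param signal_length Signal-peptide length (type1).
#' @param n_tm Number of membrane passes (multi).
#' @param effects Named numeric vector of true log2 L:H effects per region
#'   category (`cytoplasmic`, `extra_cytoplasmic`, `transmembrane`,
#'   `signal`, `unannotated`); unnamed categories default to 0.
#' @param sigma Peptide-level observation noise (log2 standard deviation).
#' @param probability ProteinProphet probability to write for the protein.
#' @param accession,name Identifier and display name; generated when NULL.
#' @param seed Optional seed for reproducibility of the sequence.
#' @return A list of class `pepmap_protein_spec` with the sequence,
#'   feature tibble, effects, sigma and probability.
#' @examples
#' sp <- make_protein_spec("type2", length = 296, tail_length = 29,
#'                         tm_length = 23, seed = 1)
#' sp$features
#' @export
make_protein_spec <- function(template = c("type2", "type1", "multi", "soluble"),
                              length = 296L, tail_length = 29L,
                              tm_length = 23L, signal_length = 20L,
                              n_tm = 4L,
                              effects = c(cytoplasmic = 0, extra_cytoplasmic = 0),
                              sigma = 0.2, probability = 0.99,
                              accession = NULL, name = NULL, seed = NULL) {
  template <- match.arg(template)
  full <- c(cytoplasmic = 0, extra_cytoplasmic = 0, transmembrane = 0,
            signal = 0, unannotated = 0)
  full[names(effects)] <- effects

  feats <- switch(
    template,
    soluble = empty_features(),
    type2 = {
      if (tail_length + tm_length >= length) {
        stop("type2 template: tail + TM exceed protein length", call. = FALSE)
      }
      tibble(category = c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"),
             subtype = c("Cytoplasmic", NA, "Extracellular"),
             start = c(1L, tail_length + 1L, tail_length + tm_length + 1L),
             end = c(tail_length, tail_length + tm_length, as.integer(length)))
    },
    type1 = {
      if (signal_length + tm_length + tail_length >= length) {
        stop("type1 template: features exceed protein length", call. = FALSE)
      }
      tm_start <- length - tail_length - tm_length + 1L
      tibble(category = c("SIGNAL", "TOPO_DOM", "TRANSMEM", "TOPO_DOM"),
             subtype = c(NA, "Extracellular", NA, "Cytoplasmic"),
             start = c(1L, signal_length + 1L, tm_start, tm_start + tm_length),
             end = c(signal_length, tm_start - 1L,
                     tm_start + tm_length - 1L, as.integer(length)))
    },
    multi = {
      loop <- (as.integer(length) - n_tm * tm_length) %/% (n_tm + 1L)
      if (loop < 5L) {
        stop("multi template: features exceed protein length", call. = FALSE)
      }
      pos <- 1L
      rows <- list()
      for (k in seq_len(n_tm)) {
        side <- if (k %% 2L == 1L) "Cytoplasmic" else "Extracellular"
        rows[[2 * k - 1]] <- list(category = "TOPO_DOM", subtype = side,
                                  start = pos, end = pos + loop - 1L)
        pos <- pos + loop
        rows[[2 * k]] <- list(category = "TRANSMEM", subtype = NA_character_,
                              start = pos, end = pos + tm_length - 1L)
        pos <- pos + tm_length
      }
      side <- if ((n_tm + 1L) %% 2L == 1L) "Cytoplasmic" else "Extracellular"
      rows[[2 * n_tm + 1]] <- list(category = "TOPO_DOM", subtype = side,
                                   start = pos, end = as.integer(length))
      dplyr::bind_rows(rows)
    }
  )
  if (nrow(feats) > 0 && any(feats$end > length)) {
    stop("template features exceed protein length", call. = FALSE)
  }

  sequence <- with_optional_seed(seed,
    paste(sample(AA20, length, replace = TRUE), collapse = ""))
  if (is.null(accession)) {
    accession <- sprintf("P%05d", with_optional_seed(
      if (is.null(seed)) NULL else seed + 1L, sample.int(99999L, 1)))
  }
  structure(
    list(accession = accession,
         name = name %||% paste0("Synthetic ", template, " protein ", accession),
         template = template, sequence = sequence,
         length = as.integer(length), molecular_weight = protein_mw(sequence),
         features = feats, effects = full, sigma = sigma,
         probability = probability),
    class = "pepmap_protein_spec"
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is proline,
#' with up to `missed` missed cleavages.
#'
#' @param sequence Protein sequence.
#' @param missed Maximum missed cleavages (0-2).
#' @return Tibble with `sequence`, `start`, `end`, `n_missed`.
#' @examples
#' tryptic_digest("MAKRTTKGW")
#' @export
tryptic_digest <- function(sequence, missed = 0L) {
  stopifnot(missed >= 0L, missed <= 2L)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- head(bounds, -1) + 1L
  ends <- bounds[-1]
  frags <- list()
  for (m in 0:missed) {
    if (length(starts) <= m) next
    i <- seq_len(length(starts) - m)
    frags[[m + 1]] <- tibble(start = starts[i], end = ends[i + m],
                             n_missed = m)
  }
  out <- dplyr::bind_rows(frags)
  out$sequence <- substring(sequence, out$start, out$end)
  out[, c("sequence", "start", "end", "n_missed")]
}

# true region of a span under the spec's features (same semantics as
# assign_region, reused directly so truth matches the mapping contract)
spec_region <- function(spec, start, end) {
  assign_region(start, end, spec$features)
}

#' Digest a synthetic protein and simulate peptide quantitation
#'
#' Tryptic peptides of length 6-30 are retained; each gets a true log2
#' ratio equal to its region's effect, an observed log2 ratio with
#' `N(0, sigma)` noise, the corresponding linear L:H ratio for the file,
#' a PeptideProphet-style probability drawn from `Beta(prob_beta)`, and a
#' charge of 2 or 3.  Peptides crossing region boundaries take the mean of
#' the effects of the regions they touch (the mapping stage excludes them
#' from averages anyway); a configurable fraction is marked unquantified
#' (the absent-ratio sentinel in the file).
#'
#' @param spec A [make_protein_spec()] object.
#' @param missed Maximum missed cleavages.
#' @param min_len,max_len Retained peptide length window.
#' @param missing_frac Fraction of peptides written without quantitation.
#' @param prob_beta Shape parameters of the probability distribution.
#' @param xpress_jitter Log2 sd of the simulated XPRESS ratio around the
#'   ASAPRatio; `NA` omits XPRESS values entirely.
#' @param seed Optional seed.
#' @return Tibble of peptide observations (one row per retained peptide)
#'   with ground-truth columns `region` and `true_log2`.
#' @export
digest_and_quantify <- function(spec, missed = 0L, min_len = 6L, max_len = 30L,
                                missing_frac = 0, prob_beta = c(9, 1),
                                xpress_jitter = 0.1, seed = NULL) {
  stopifnot(inherits(spec, "pepmap_protein_spec"))
  peps <- tryptic_digest(spec$sequence, missed)
  len <- nchar(peps$sequence)
  peps <- peps[len >= min_len & len <= max_len, , drop = FALSE]
  n <- nrow(peps)
  with_optional_seed(seed, {
    region <- vapply(seq_len(n), function(i) {
      spec_region(spec, peps$start[i], peps$end[i])
    }, character(1))
    eff <- spec$effects
    true_log2 <- vapply(region, function(r) {
      switch(r,
             spanning = mean(eff[c("cytoplasmic", "extra_cytoplasmic",
                                   "transmembrane", "signal")]),
             unannotated = eff[["unannotated"]],
             eff[[r]])
    }, numeric(1))
    obs_log2 <- true_log2 + rnorm(n, 0, spec$sigma)
    missing <- runif(n) < missing_frac
    tibble(
      accession = spec$accession,
      sequence = peps$sequence,
      start = peps$start, end = peps$end, n_missed = peps$n_missed,
      region = region,
      true_log2 = true_log2,
      obs_log2 = ifelse(missing, NA_real_, obs_log2),
      ratio = ifelse(missing, NA_real_, 2^obs_log2),
      xpress_ratio = if (is.na(xpress_jitter)) NA_real_ else {
        ifelse(missing, NA_real_, 2^(obs_log2 + rnorm(n, 0, xpress_jitter)))
      },
      probability = round(rbeta(n, prob_beta[1], prob_beta[2]), 4),
      charge = sample(2:3, n, replace = TRUE),
      missing = missing
    )
  })
}

#' Write a matched protXML + annotation + ground-truth fixture
#'
#' Serializes a set of synthetic proteins and their simulated peptide
#' observations into (a) a schema-valid protXML file parseable by
#' [read_protxml()], (b) an annotation table loadable by
#' [read_annotations()], and (c) a ground-truth TSV recording each
#' protein's true per-region effects and each peptide's true ratio, for
#' parameter-recovery tests.  The protein-level ASAPRatio is the linear
#' equivalent of the mean observed log2 ratio over quantified peptides.
#'
#' @param specs List of [make_protein_spec()] objects.
#' @param observations List of observation tibbles from
#'   [digest_and_quantify()], parallel to `specs`.
#' @param dir Output directory (created if needed).
#' @return A list of paths: `protxml`, `annotations`, `truth`.
#' @export
write_fixture <- function(specs, observations, dir) {
  stopifnot(length(specs) > 0, length(specs) == length(observations))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(protxml = file.path(dir, "synthetic.prot.xml"),
                annotations = file.path(dir, "annotations.tsv"),
                truth = file.path(dir, "ground_truth.tsv"))

  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<protein_summary xmlns="http://regis-web.systemsbiology.net/protXML">',
    '<protein_summary_header reference_database="synthetic"/>'
  )
  blocks <- purrr::map2_chr(specs, observations, function(sp, obs) {
    quant <- obs$ratio[!obs$missing]
    prot_quant <- if (length(quant)) {
      ratio <- 2^mean(log2(quant))
      sprintf(
        paste0('<analysis_result analysis="asapratio">',
               '<ASAPRatio ratio_mean="%.6f" ratio_standard_dev="%.6f" ',
               'ratio_number_peptides="%d"/></analysis_result>'),
        ratio, stats::sd(log2(quant)) %|NA|% 0, length(quant))
    } else {
      ""
    }
    pep_lines <- vapply(seq_len(nrow(obs)), function(i) {
      quant_xml <- if (obs$missing[i]) {
        paste0('<analysis_result analysis="asapratio">',
               '<ASAPRatio ratio_mean="-1.000000" ratio_standard_dev="-1" ',
               'ratio_number_peptides="0"/></analysis_result>')
      } else {
        xp <- if (is.na(obs$xpress_ratio[i])) "" else {
          sprintf(paste0('<analysis_result analysis="xpress">',
                         '<XPressRatio ratio_mean="%.6f"/></analysis_result>'),
                  obs$xpress_ratio[i])
        }
        paste0(sprintf(
          paste0('<analysis_result analysis="asapratio">',
                 '<ASAPRatio ratio_mean="%.6f" ratio_standard_dev="%.6f" ',
                 'ratio_number_peptides="1"/></analysis_result>'),
          obs$ratio[i], obs$ratio[i] * 0.05), xp)
      }
      sprintf(
        paste0('<peptide peptide_sequence="%s" charge="%d" ',
               'nsp_adjusted_probability="%.4f" is_nondegenerate_evidence="Y">',
               '%s</peptide>'),
        obs$sequence[i], obs$charge[i], obs$probability[i], quant_xml)
    }, character(1))
    sprintf(
      paste0('<protein protein_name="sp|%s|%s" probability="%.4f" ',
             'total_number_peptides="%d" percent_coverage="%.1f">%s%s</protein>'),
      sp$accession, paste0("SYN", sp$accession, "_MOUSE"), sp$probability,
      nrow(obs),
      100 * sum(nchar(obs$sequence)) / sp$length,
      prot_quant, paste(pep_lines, collapse = ""))
  })
  groups <- sprintf('<protein_group group_number="%d" probability="%.4f">%s</protein_group>',
                    seq_along(blocks),
                    vapply(specs, `[[`, numeric(1), "probability"),
                    blocks)
  writeLines(c(xml, groups, "</protein_summary>"), paths$protxml)

  ann <- tibble(
    accession = vapply(specs, `[[`, character(1), "accession"),
    recommended_name = vapply(specs, `[[`, character(1), "name"),
    length = vapply(specs, `[[`, integer(1), "length"),
    molecular_weight = round(vapply(specs, `[[`, numeric(1), "molecular_weight"), 2),
    sequence = vapply(specs, `[[`, character(1), "sequence"),
    features = purrr::map(specs, `[[`, "features")
  )
  write_annotations(ann, paths$annotations)

  truth <- dplyr::bind_rows(purrr::map2(specs, observations, function(sp, obs) {
    obs$template <- sp$template
    obs$protein_probability <- sp$probability
    obs$effect_cytoplasmic <- sp$effects[["cytoplasmic"]]
    obs$effect_extra_cytoplasmic <- sp$effects[["extra_cytoplasmic"]]
    obs
  }))
  readr::write_tsv(truth, paths$truth, na = "NA")
  paths
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Generate a complete synthetic run in one call
#'
#' Convenience wrapper producing `n` proteins with a realistic template
#' mix (45% soluble, 20% type 2, 20% type 1, 15% multi-pass by default),
#' per-region effects drawn from `N(0, effect_sd)` — giving the near-normal
#' fold-change distribution typical of a perturbation that leaves most of
#' the membrane proteome unchanged — and a fraction of sub-threshold
#' ProteinProphet probabilities, then writing the fixture files.
#'
#' @param n Number of proteins.
#' @param dir Output directory.
#' @param seed Seed governing every random draw.
#' @param template_mix Named probabilities for the four templates.
#' @param effect_sd Spread of true per-region log2 effects across proteins.
#' @param sigma Peptide-level noise (log2 sd).
#' @param sub_threshold_frac Fraction of proteins given a probability
#'   below 0.90 (drawn uniformly from \[0.2, 0.89\]); the rest draw from
#'   \[0.90, 1\].
#' @param missing_frac Fraction of peptides without quantitation.
#' @return List with fixture `paths` plus the `specs` and `observations`.
#' @export
synth_fixture <- function(n = 50, dir = tempfile("pepmap_fixture"), seed = 1,
                          template_mix = c(soluble = 0.45, type2 = 0.2,
                                           type1 = 0.2, multi = 0.15),
                          effect_sd = 0.5, sigma = 0.2,
                          sub_threshold_frac = 0.1, missing_frac = 0.05) {
  withr::with_seed(seed, {
    templates <- sample(names(template_mix), n, replace = TRUE,
                        prob = template_mix)
    sub <- runif(n) < sub_threshold_frac
    probs <- ifelse(sub, runif(n, 0.2, 0.89), runif(n, 0.90, 1.0))
    accs <- sprintf("P%05d", sample.int(99999L, n))
    specs <- purrr::map(seq_len(n), function(i) {
      len <- sample(200:500, 1)
      make_protein_spec(
        templates[i], length = len,
        tail_length = sample(20:60, 1), tm_length = 21L,
        n_tm = sample(2:7, 1),
        effects = c(cytoplasmic = rnorm(1, 0, effect_sd),
                    extra_cytoplasmic = rnorm(1, 0, effect_sd),
                    unannotated = rnorm(1, 0, effect_sd)),
        sigma = sigma, probability = round(probs[i], 4), accession = accs[i]
      )
    })
    observations <- purrr::map(specs, digest_and_quantify,
                               missing_frac = missing_frac)
    paths <- write_fixture(specs, observations, dir)
    c(paths, list(specs = specs, observations = observations))
  })
}

#' Designed single-substrate fixture with opposing domain regulation
#'
#' Builds a deterministic type 2 single-pass protein in the mould of the
#' invariant chain (CD74): a 29-residue cytoplasmic tail covered by a
#' single tryptic peptide, one transmembrane segment, and an ectodomain
#' yielding several peptides.  The tail peptide carries `cyto_log2` and
#' the ectodomain peptides `ecto_log2` (no observation noise), so the
#' mapped protein shows opposing cytoplasmic and extra-cytoplasmic domain
#' means — the signature of an intramembrane-protease substrate whose
#' tail fragment accumulates while the shed ectodomain is depleted.  The
#' peptide crossing the membrane boundary is retained to exercise the
#' spanning-peptide exclusion.
#'
#' @param dir Output directory for the fixture files.
#' @param cyto_log2 True log2 L:H ratio of the cytoplasmic tail peptide.
#' @param ecto_log2 True log2 L:H ratio of each ectodomain peptide.
#' @param probability ProteinProphet probability of the protein.
#' @return As [write_fixture()], plus `spec` and `observations`.
#' @export
demo_substrate_fixture <- function(dir = tempfile("substrate"),
                                   cyto_log2 = 1.2, ecto_log2 = -0.6,
                                   probability = 0.99) {
  tail_pep <- paste0(strrep("M", 5), strrep("A", 23), "K")   # residues 1..29
  tm_seg <- strrep("L", 23)                                  # 30..52
  span_tail <- "DDDDDK"                                      # TM+this: 30..58
  ecto_peps <- c("EEEEEEEEEK", "FFFFFFFFFK", "GGGGGGGGGK", "HHHHHHHHHK")
  sequence <- paste0(tail_pep, tm_seg, span_tail,
                     paste(ecto_peps, collapse = ""), "VVVVV")
  len <- nchar(sequence)
  feats <- tibble(category = c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"),
                  subtype = c("Cytoplasmic", NA, "Extracellular"),
                  start = c(1L, 30L, 53L), end = c(29L, 52L, len))
  spec <- structure(
    list(accession = "P90001", name = "Synthetic short-tail substrate",
         template = "type2", sequence = sequence, length = len,
         molecular_weight = protein_mw(sequence), features = feats,
         effects = c(cytoplasmic = cyto_log2, extra_cytoplasmic = ecto_log2,
                     transmembrane = 0, signal = 0, unannotated = 0),
         sigma = 0, probability = probability),
    class = "pepmap_protein_spec"
  )
  peps <- c(tail_pep, paste0(tm_seg, span_tail), ecto_peps)
  starts <- c(1L, 30L, 59L, 69L, 79L, 89L)
  region <- c("cytoplasmic", "spanning", rep("extra_cytoplasmic", 4))
  log2s <- c(cyto_log2, 0, rep(ecto_log2, 4))
  obs <- tibble(
    accession = spec$accession, sequence = peps,
    start = starts, end = starts + nchar(peps) - 1L, n_missed = 0L,
    region = region, true_log2 = log2s, obs_log2 = log2s,
    ratio = 2^log2s, xpress_ratio = 2^log2s,
    probability = 0.99, charge = 2L, missing = FALSE
  )
  paths <- write_fixture(list(spec), list(obs), dir)
  c(paths, list(spec = spec, observations = obs))
}

#' Cohort of type 2 proteins for effect-recovery studies
#'
#' Generates `n` single-pass type 2 proteins sharing the same true
#' per-domain effects, sized (long cytoplasmic tail, long ectodomain) and
#' rejection-sampled so that every protein yields at least `min_peptides`
#' quantified tryptic peptides wholly inside each of the cytoplasmic and
#' extra-cytoplasmic domains — the design needed to judge how well the
#' per-domain average recovers a known effect at a given peptide noise.
#'
#' @param n Number of proteins.
#' @param cyto_effect,ecto_effect True log2 L:H effects of the
#'   cytoplasmic and extra-cytoplasmic domains.
#' @param sigma Peptide-level log2 observation noise.
#' @param min_peptides Minimum quantified peptides per domain.
#' @param seed Seed governing all draws.
#' @return List with `specs` and `observations`, ready for
#'   [write_fixture()].
#' @export
recovery_cohort <- function(n = 40, cyto_effect = 1.5, ecto_effect = -0.5,
                            sigma = 0.2, min_peptides = 5, seed = 1) {
  specs <- vector("list", n)
  observations <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 0:49) {
      s <- seed + i + 100003L * try
      sp <- make_protein_spec(
        "type2", length = 600, tail_length = 150, tm_length = 23,
        effects = c(cytoplasmic = cyto_effect, extra_cytoplasmic = ecto_effect),
        sigma = sigma, accession = sprintf("P6%04d", i), seed = s
      )
      obs <- digest_and_quantify(sp, seed = s + 50021L)
      ok <- sum(obs$region == "cytoplasmic" & !obs$missing) >= min_peptides &&
        sum(obs$region == "extra_cytoplasmic" & !obs$missing) >= min_peptides
      if (ok) break
    }
    if (!ok) stop("could not realise the cohort design for protein ", i,
                  call. = FALSE)
    specs[[i]] <- sp
    observations[[i]] <- obs
  }
  list(specs = specs, observations = observations)
}
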