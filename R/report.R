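#' Map a clamped log2 ratio to the red-green display colour
#'
#' Values inside the no-change zone \[zn, zp\] are neutral grey
#' (`#808080`).  Outside it the relevant channel rises linearly from 64 at
#' the zone boundary (a floor that keeps faint changes visibly coloured)
#' to 255 at the clamp bound, so `rmax` maps to `#00FF00` and `rmin` to
#' `#FF0000` under the default direction.  With `color_up = "red"` in the
#' configuration the channels are swapped.
#'
#' @param x Numeric vector of clamped log2 ratios in \[rmin, rmax\].
#' @param config A [run_config()].
#' @return Character vector of `#RRGGBB` strings.
#' @examples
#' color_for_ratio(c(-3, 0, 3), run_config())
#' @export
color_for_ratio <- function(x, config = run_config()) {
  rmin <- config$rmin; rmax <- config$rmax
  zn <- config$zn; zp <- config$zp
  if (any(x < rmin | x > rmax, na.rm = TRUE)) {
    stop("color_for_ratio: value outside [rmin, rmax]; clamp first",
         call. = FALSE)
  }
  up <- x > zp
  down <- x < zn
  chan <- integer(length(x))
  chan[up] <- round(64 + (x[up] - zp) / (rmax - zp) * 191)
  chan[down] <- round(64 + (zn - x[down]) / (zn - rmin) * 191)
  out <- rep("#808080", length(x))
  green_up <- identical(config$color_up, "green")
  out[up] <- if (green_up) sprintf("#00%02X00", chan[up]) else sprintf("#%02X0000", chan[up])
  out[down] <- if (green_up) sprintf("#%02X0000", chan[down]) else sprintf("#00%02X00", chan[down])
  out[is.na(x)] <- NA_character_
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

safe_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

browser_note_name <- function(config) {
  if (isTRUE(config$corrected_browser_note)) {
    "supported_browsers_and_os.txt"
  } else {
    "suppoted_browsers_and_os.txt"
  }
}

#' Render the static HTML report
#'
#' Writes the complete report tree into `out_dir`: a sortable, filterable
#' `index.html` with one row per valid protein (accession linked to its
#' UniProt page, name, probability, protein-level and per-domain log2
#' ratios, transmembrane and signal-peptide flags usable as filters);
#' per-protein pages under `index_files/` with an SVG peptide map
#' (`images/`, thumbnail in `small_images/`) and the peptide table,
#' coloured by [color_for_ratio()]; the discarded-protein log
#' `run_stats.out` (one line per discarded protein);
#' `average_molecular_weight.txt` (mean molecular weight of valid
#' annotated proteins plus count); a browser-compatibility note; and
#' shared CSS/JS assets.  Everything is static HTML5 + CSS3 with no
#' server dependency.
#'
#' @param result A `pepmap_result`.
#' @param out_dir Output directory (created; must not exist or be empty).
#' @return `out_dir`, invisibly, with attribute `members` holding the
#'   canonical bundle inventory.
#' @seealso [bundle()]
#' @export
render_html <- function(result, out_dir) {
  for (d in c("", "images", "small_images", "index_files")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  p <- result$proteins
  cfg <- result$config
  files <- safe_filename(p$accession)
  if (anyDuplicated(files)) files <- make.unique(files, sep = "_")

  for (i in seq_len(nrow(p))) {
    svg <- protein_svg(result, i)
    writeLines(svg$full, file.path(out_dir, "images", paste0(files[i], ".svg")))
    writeLines(svg$thumb, file.path(out_dir, "small_images", paste0(files[i], ".svg")))
    writeLines(protein_page(result, i, files[i]),
               file.path(out_dir, "index_files", paste0(files[i], ".html")))
  }
  writeLines(report_css(), file.path(out_dir, "index_files", "style.css"))
  writeLines(report_js(), file.path(out_dir, "index_files", "filter.js"))
  writeLines(index_page(result, files), file.path(out_dir, "index.html"))

  d <- result$discarded
  writeLines(sprintf("%s\t%.4f\t%s", d$protein_name, d$probability, d$reason),
             file.path(out_dir, "run_stats.out"))

  mw <- numeric(0)
  if (!is.null(result$annotations)) {
    mw <- result$annotations$molecular_weight[
      match(p$accession, result$annotations$accession)]
    mw <- mw[!is.na(mw)]
  }
  writeLines(c(
    sprintf("average_molecular_weight_Da\t%.2f",
            if (length(mw)) mean(mw) else NA_real_),
    sprintf("n_proteins\t%d", length(mw))
  ), file.path(out_dir, "average_molecular_weight.txt"))

  writeLines(c(
    "The report is static HTML5 + CSS3 and requires no server.",
    "Any CSS3-capable browser displays it as intended; recent versions of",
    "Firefox, Chrome and Opera are recommended.  Platform independent."
  ), file.path(out_dir, browser_note_name(cfg)))

  members <- c(
    "index.html", "run_stats.out", "average_molecular_weight.txt",
    browser_note_name(cfg),
    "images/", paste0("images/", sort(files), ".svg"),
    "small_images/", paste0("small_images/", sort(files), ".svg"),
    "index_files/", "index_files/style.css", "index_files/filter.js",
    paste0("index_files/", sort(files), ".html")
  )
  invisible(structure(out_dir, members = members))
}

#' Compress a rendered report into the shareable ZIP bundle
#'
#' Archives the output of [render_html()] with a deterministic member
#' order and fixed timestamps, so identical runs give identical archives.
#'
#' @param out_dir Directory previously populated by [render_html()].
#' @param zipfile Output archive path; defaults to `<out_dir>.zip`.
#' @param config The [run_config()] used for rendering (determines the
#'   browser-note file name).
#' @return The archive path, invisibly.
#' @export
bundle <- function(out_dir, zipfile = paste0(out_dir, ".zip"),
                   config = run_config()) {
  top <- c("index.html", "run_stats.out", "average_molecular_weight.txt",
           browser_note_name(config))
  missing <- top[!file.exists(file.path(out_dir, top))]
  if (length(missing)) {
    stop("rendering incomplete; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  listed <- function(d) {
    fs <- sort(list.files(file.path(out_dir, d)))
    c(paste0(d, "/"), if (length(fs)) paste0(d, "/", fs))
  }
  members <- c(top, listed("images"), listed("small_images"),
               listed("index_files"))
  zip_create(zipfile, members, root = out_dir)
  invisible(zipfile)
}

# ---- HTML/SVG building blocks ----------------------------------------------

index_page <- function(result, files) {
  p <- result$proteins
  s <- result$summary
  rows <- vapply(seq_len(nrow(p)), function(i) {
    link <- if (p$namespace[i] == "uniprot") {
      sprintf('<a href="https://www.uniprot.org/uniprotkb/%s">%s</a>',
              p$accession[i], html_escape(p$accession[i]))
    } else {
      html_escape(p$accession[i])
    }
    name <- if (p$annotated[i]) {
      ann <- annotation_for(result$annotations, p$accession[i])
      html_escape(ann$recommended_name[[1]])
    } else {
      '<span class="badge">unannotated</span>'
    }
    sprintf(paste0(
      '<tr data-tm="%d" data-signal="%d">',
      '<td>%s</td><td><a href="index_files/%s.html">%s</a></td>',
      '<td>%.3f</td><td>%s</td><td>%s</td><td>%s</td>',
      '<td>%s</td><td>%s</td></tr>'),
      as.integer(p$has_tm[i] %in% TRUE), as.integer(p$has_signal[i] %in% TRUE),
      link, files[i], name,
      p$probability[i], fmt_num(p$protein_log2[i]),
      fmt_num(p$cyto_mean[i]), fmt_num(p$extra_mean[i]),
      if (p$has_tm[i] %in% TRUE) "yes" else "no",
      if (p$has_signal[i] %in% TRUE) "yes" else "no"
    )
  }, character(1))
  c('<!DOCTYPE html>',
    '<html lang="en"><head><meta charset="utf-8"/>',
    '<title>Peptide mapping report</title>',
    '<link rel="stylesheet" href="index_files/style.css"/>',
    '<script src="index_files/filter.js" defer></script></head><body>',
    '<h1>Peptide mapping report</h1>',
    sprintf('<p class="summary">%d valid proteins (%d discarded); %d with transmembrane domain (%s%%), of which %d (%s%%) lack a signal peptide.</p>',
            nrow(p), nrow(result$discarded), s$n_tm, s$pct_tm,
            s$n_tm_no_signal, s$pct_tm_no_signal),
    '<p><label><input type="checkbox" id="flt-tm"/> only transmembrane</label>',
    '<label><input type="checkbox" id="flt-signal"/> only signal peptide</label></p>',
    '<table id="proteins"><thead><tr>',
    '<th>accession</th><th>name</th><th>probability</th><th>protein log2</th>',
    '<th>cytoplasmic mean</th><th>extra-cytoplasmic mean</th>',
    '<th>TM</th><th>signal</th></tr></thead><tbody>',
    rows,
    '</tbody></table></body></html>')
}

protein_page <- function(result, i, file) {
  p <- result$proteins[i, ]
  m <- p$mapped[[1]]
  ann <- annotation_for(result$annotations, p$accession)
  head_html <- c(
    '<!DOCTYPE html>',
    '<html lang="en"><head><meta charset="utf-8"/>',
    sprintf('<title>%s</title>', html_escape(p$accession)),
    '<link rel="stylesheet" href="style.css"/></head><body>',
    sprintf('<h1>%s</h1>', html_escape(p$protein_name)),
    sprintf('<p><a href="../index.html">back to index</a></p>')
  )
  info <- if (!is.null(ann)) {
    sprintf('<p>%s — %d residues, %.0f Da, ProteinProphet probability %.3f</p>',
            html_escape(ann$recommended_name[[1]]), ann$length[[1]],
            ann$molecular_weight[[1]], p$probability)
  } else {
    sprintf('<p><span class="badge">unannotated</span> ProteinProphet probability %.3f; peptides listed without positions.</p>',
            p$probability)
  }
  img <- sprintf('<p><img src="../images/%s.svg" alt="peptide map"/></p>', file)
  rows <- vapply(seq_len(nrow(m)), function(j) {
    col <- if (is.na(m$log2_ratio[j])) "#C0C0C0" else
      color_for_ratio(m$log2_ratio[j], result$config)
    sprintf(paste0('<tr><td class="pep" style="background:%s">%s</td>',
                   '<td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>'),
            col, html_escape(m$sequence[j]),
            ifelse(is.na(m$start[j]), "NA",
                   sprintf("%d-%d", m$start[j], m$end[j])),
            m$region_class[j], fmt_num(m$ratio[j]),
            fmt_num(m$log2_ratio[j]), m$change_class[j])
  }, character(1))
  regions <- p$regions[[1]]
  reg_html <- if (nrow(regions)) {
    sprintf('<p class="regions">%s</p>',
            paste(sprintf("%s: mean log2 %s over %d peptide(s)",
                          regions$region, fmt_num(regions$mean_log2),
                          regions$n_peptides), collapse = "; "))
  } else {
    '<p class="regions">no quantified cytoplasmic or extra-cytoplasmic peptides</p>'
  }
  c(head_html, info, img, reg_html,
    '<table><thead><tr><th>peptide</th><th>position</th><th>region</th>',
    '<th>L:H ratio</th><th>log2</th><th>change</th></tr></thead><tbody>',
    rows, '</tbody></table></body></html>')
}

FEATURE_FILL <- c(cytoplasmic = "#4477AA", extra_cytoplasmic = "#DDCC77",
                  transmembrane = "#555555", signal = "#EE7733",
                  unclassified = "#AAAAAA")

protein_svg <- function(result, i) {
  p <- result$proteins[i, ]
  ann <- annotation_for(result$annotations, p$accession)
  m <- p$mapped[[1]]
  len <- if (!is.null(ann)) ann$length[[1]] else
    max(c(m$end, 100L), na.rm = TRUE)
  sx <- function(pos) 20 + (pos - 1) / max(len - 1, 1) * 760

  body <- c(sprintf(
    '<rect x="20" y="70" width="760" height="16" fill="#DDDDDD" stroke="#666666"/>'
  ))
  if (!is.null(ann)) {
    f <- ann$features[[1]]
    if (nrow(f)) {
      reg <- classify_feature(f$category, f$subtype, result$config$extra_synonyms)
      body <- c(body, sprintf(
        '<rect x="%.1f" y="70" width="%.1f" height="16" fill="%s"><title>%s %d-%d</title></rect>',
        sx(f$start), pmax(sx(f$end) - sx(f$start), 1), FEATURE_FILL[reg],
        reg, f$start, f$end))
    }
  }
  mm <- m[!is.na(m$start), , drop = FALSE]
  if (nrow(mm)) {
    col <- ifelse(is.na(mm$log2_ratio), "#C0C0C0",
                  color_for_ratio(ifelse(is.na(mm$log2_ratio), 0, mm$log2_ratio),
                                  result$config))
    body <- c(body, sprintf(
      '<rect x="%.1f" y="44" width="%.1f" height="14" fill="%s" stroke="#333333"><title>%s (%.2f)</title></rect>',
      sx(mm$start), pmax(sx(mm$end) - sx(mm$start), 1), col,
      mm$sequence, ifelse(is.na(mm$log2_ratio), NA_real_, mm$log2_ratio)))
  }
  body <- c(body,
            '<text x="20" y="100" font-size="10">1</text>',
            sprintf('<text x="780" y="100" font-size="10" text-anchor="end">%d</text>', len))
  svg_at <- function(width, height) {
    c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 800 110">',
              width, height),
      body, '</svg>')
  }
  list(full = svg_at(800L, 110L), thumb = svg_at(200L, 28L))
}

report_css <- function() {
  c("body { font-family: sans-serif; margin: 1.5em; }",
    "table { border-collapse: collapse; }",
    "td, th { border: 1px solid #999; padding: 2px 8px; font-size: 0.9em; }",
    "th { background: #eee; }",
    ".badge { background: #B85; color: #fff; padding: 1px 5px; border-radius: 3px; }",
    ".pep { font-family: monospace; }",
    "tr.hidden { display: none; }")
}

report_js <- function() {
  c("function applyFilters() {",
    "  var tm = document.getElementById('flt-tm').checked;",
    "  var sg = document.getElementById('flt-signal').checked;",
    "  document.querySelectorAll('#proteins tbody tr').forEach(function (r) {",
    "    var show = (!tm || r.dataset.tm === '1') && (!sg || r.dataset.signal === '1');",
    "    r.classList.toggle('hidden', !show);",
    "  });",
    "}",
    "document.getElementById('flt-tm').addEventListener('change', applyFilters);",
    "document.getElementById('flt-signal').addEventListener('change', applyFilters);")
}
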