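# Survey stage: correlate crystallization-buffer ionic strength with the
# observed M20 loop conformation across a table of PDB entries.

#' Parse a survey table of PDB entries
#'
#' Reads a tab-delimited table (header required) of crystal structures and
#' their crystallization salts. Required columns: `pdb_id`, `salt`,
#' `conc_M`; optional: `label` (consumed conformer classification),
#' `resolution`, `pH`, `Rc`. Rows whose concentration does not parse are
#' dropped with a row-numbered warning.
#'
#' @param path Path to a TSV file.
#' @return A tibble of structure records, one per row, with columns
#'   `pdb_id`, `salt`, `conc_M` and the optional columns present,
#'   plus empty `I_M`, `Rc`, `class` placeholders where absent.
#' @export
parse_survey_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("pdb_id", "salt", "conc_M")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    abort(paste0("Survey table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  conc <- suppressWarnings(as.numeric(tab$conc_M))
  bad <- which(is.na(conc) | conc < 0)
  if (length(bad)) {
    warn(paste0("Dropping row(s) with unparseable concentration: ",
                paste(bad, collapse = ", ")))
    tab <- tab[-bad, , drop = FALSE]
    conc <- conc[-bad]
  }
  out <- tibble(
    pdb_id = tolower(tab$pdb_id),
    salt = tab$salt,
    conc_M = conc
  )
  if (any(nchar(out$pdb_id) != 4)) {
    warn("Some pdb_id values are not 4-character codes.")
  }
  for (opt in c("label", "resolution", "pH", "Rc")) {
    if (opt %in% names(tab)) {
      out[[opt]] <- if (opt == "label") tab[[opt]] else
        suppressWarnings(as.numeric(tab[[opt]]))
    }
  }
  if (!"I_M" %in% names(out)) out$I_M <- NA_real_
  if (!"Rc" %in% names(out)) out$Rc <- NA_real_
  if (!"class" %in% names(out)) out$class <- NA_character_
  out
}

#' Annotate survey records with ionic strength
#'
#' Fills the `I_M` column from each record's salt and concentration via
#' [salt_species()] and [ionic_strength()] (the same code path as the
#' solution module, so a 2:1 salt at concentration c gives exactly 3c).
#' Records with an unsupported salt are flagged (`I_M` left NA) with a
#' warning.
#'
#' @param records Survey records (see [parse_survey_table()]).
#' @return `records` with `I_M` filled (mol/L).
#' @examples
#' rec <- tibble::tibble(pdb_id = "1rx2", salt = "CaCl2", conc_M = 0.10)
#' annotate_ionic_strength(rec)$I_M # 0.30
#' @export
annotate_ionic_strength <- function(records) {
  stopifnot(all(c("salt", "conc_M") %in% names(records)))
  im <- purrr::map2_dbl(records$salt, records$conc_M, function(s, c) {
    out <- try(ionic_strength(salt_species(s, c)), silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  })
  unsupported <- which(is.na(im) & !is.na(records$conc_M))
  if (length(unsupported)) {
    warn(paste0("Unsupported salt formula in record(s): ",
                paste(records$pdb_id[unsupported], collapse = ", "),
                "; I_M left missing."))
  }
  records$I_M <- im
  records
}

#' Attach computed R_c values to survey records
#'
#' Looks for `<pdb_id>.pdb` under `dir` for each record, computes the loop
#' descriptor with [compute_rc()] and fills `Rc` and `class`. Records
#' without a structure file keep missing values (with a warning); existing
#' `Rc` values from the table are preserved for those.
#'
#' @param records Survey records.
#' @param dir Directory of PDB files named `<pdb_id>.pdb`.
#' @param anchors An [anchor_set()].
#' @param boundaries See [class_boundaries()].
#' @return `records` with `Rc` and `class` filled where possible.
#' @export
attach_rc <- function(records, dir, anchors = anchor_set(),
                      boundaries = class_boundaries()) {
  if (!"Rc" %in% names(records)) records$Rc <- NA_real_
  if (!"class" %in% names(records)) records$class <- NA_character_
  missing_files <- character(0)
  for (i in seq_len(nrow(records))) {
    f <- file.path(dir, paste0(records$pdb_id[i], ".pdb"))
    if (!file.exists(f)) {
      missing_files <- c(missing_files, records$pdb_id[i])
      next
    }
    desc <- suppressWarnings(
      compute_rc(read_structure(f), anchors, boundaries)
    )
    records$Rc[i] <- desc$Rc
    records$class[i] <- desc$class
  }
  if (length(missing_files)) {
    warn(paste0("No structure file for: ",
                paste(missing_files, collapse = ", ")))
  }
  # classify rows that carry a tabulated Rc but no structure
  needs <- is.na(records$class) & is.finite(records$Rc)
  records$class[needs] <- classify_conformer(records$Rc[needs], boundaries)
  records
}

#' Summarize the survey against the physiological threshold
#'
#' Splits classified records at the physiological ionic-strength threshold
#' (default 0.24 M, the E. coli intracellular upper limit; 0.25 M
#' available via the argument) and tallies conformer classes above and
#' below, plus a per-class R_c histogram.
#'
#' @param records Survey records with `I_M` and `class` filled.
#' @param threshold Physiological ionic-strength threshold (mol/L).
#' @param bin_width R_c histogram bin width (Angstrom, default 0.2).
#' @return A list of class `survey_summary`: `counts` (tibble `class`,
#'   `side`, `n`), `histogram` (tibble `class`, `Rc`, `n`), `threshold`,
#'   `n_classified`, `n_excluded`.
#' @export
summarize_survey <- function(records, threshold = 0.24, bin_width = 0.2) {
  usable <- is.finite(records$I_M) & !is.na(records$class)
  if (!any(usable)) abort("No records with both I_M and class.")
  rec <- records[usable, , drop = FALSE]
  counts <- rec |>
    mutate(side = ifelse(.data$I_M >= threshold, "above", "below")) |>
    dplyr::count(.data$class, .data$side, name = "n") |>
    arrange(.data$class, .data$side)
  hist <- rec[is.finite(rec$Rc), , drop = FALSE]
  histogram <- if (nrow(hist)) {
    hist |>
      mutate(Rc = floor(.data$Rc / bin_width) * bin_width + bin_width / 2) |>
      dplyr::count(.data$class, .data$Rc, name = "n") |>
      arrange(.data$class, .data$Rc)
  } else {
    tibble(class = character(), Rc = double(), n = integer())
  }
  structure(
    list(counts = counts, histogram = histogram, threshold = threshold,
         n_classified = nrow(rec), n_excluded = sum(!usable)),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Survey of", x$n_classified, "classified structures (",
      x$n_excluded, "excluded ) at threshold", x$threshold, "M\n")
  print(x$counts)
  invisible(x)
}

#' @export
#' @method tidy survey_summary
#' @rdname survey-tidiers
tidy.survey_summary <- function(x, ...) x$counts

#' Tidiers for survey summaries
#'
#' `tidy()` returns the class-by-threshold counts; `glance()` a one-row
#' overview.
#'
#' @param x A `survey_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method glance survey_summary
#' @rdname survey-tidiers
glance.survey_summary <- function(x, ...) {
  tibble(threshold = x$threshold, n_classified = x$n_classified,
         n_excluded = x$n_excluded,
         n_above = sum(x$counts$n[x$counts$side == "above"]),
         n_below = sum(x$counts$n[x$counts$side == "below"]))
}

#' Plot the survey R_c histogram by conformer class
#'
#' @param object A `survey_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot survey_summary
autoplot.survey_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$Rc, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = expression(R[c] ~ "(Å)"), y = "structures",
                  fill = "conformer")
}
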