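#' Residue classification for peptaibol statistics
#'
#' Peptaibol shift-tensor statistics separate the helix-promoting
#' alpha-aminoisobutyric acid (Aib) sites from the proteinogenic amino
#' acids; prolines (no amide H) and the C-terminal amino alcohol
#' phenylalaninol (Phl) are excluded from both groups, and the N-terminal
#' acetyl cap is its own class.
#'
#' @param name 3-letter residue code (case-insensitive), e.g. `"AIB"`,
#'   `"GLY"`, `"PHL"`, `"ACE"`.
#' @return one of `"Aib"`, `"Pro"`, `"proteinogenic"`, `"Phl"`, `"cap"`.
#' @export
classify_residue <- function(name) {
  code <- toupper(name)
  if (code == "AIB") return("Aib")
  if (code == "PRO") return("Pro")
  if (code == "PHL") return("Phl")
  if (code == "ACE") return("cap")
  if (code %in% aa3_codes()) return("proteinogenic")
  stop("unknown residue code '", name, "'; known codes: ",
       paste(c(aa3_codes(), "AIB", "PHL", "ACE"), collapse = ", "))
}

#' Group summary statistics
#'
#' Means and sample (n-1) standard deviations per group, with extremes.
#' Empty groups are omitted with a warning. Reported "x ± y" values in
#' tensor summaries are mean ± sample sd from this function.
#'
#' @param values numeric vector.
#' @param grouping factor/character vector parallel to `values`.
#' @param sd_single `"na"` or `"zero"`: sd convention for single-value
#'   groups.
#' @param na.rm drop `NA` values before summarizing.
#' @return data.frame with `group`, `n`, `mean`, `sd`, `min`, `max`,
#'   `range`.
#' @export
group_stats <- function(values, grouping, sd_single = c("na", "zero"),
                        na.rm = TRUE) {
  sd_single <- match.arg(sd_single)
  if (length(values) != length(grouping))
    stop("values and grouping lengths differ")
  levels_seen <- unique(as.character(grouping))
  if (na.rm) {
    keep <- !is.na(values)
    values <- values[keep]; grouping <- grouping[keep]
  }
  out <- NULL
  for (g in levels_seen) {
    v <- values[grouping == g]
    if (length(v) == 0) {
      warning("empty group '", g, "' omitted")
      next
    }
    s <- if (length(v) == 1) {
      if (sd_single == "zero") 0 else NA_real_
    } else stats::sd(v)
    out <- rbind(out, data.frame(
      group = g, n = length(v), mean = mean(v), sd = s,
      min = min(v), max = max(v), range = max(v) - min(v)))
  }
  if (is.null(out)) stop("all groups empty")
  out
}

#' Extremes of a set of values
#'
#' @param values non-empty numeric vector.
#' @param na.rm drop `NA` values first.
#' @return named vector `c(min, max, range)`.
#' @export
value_range <- function(values, na.rm = TRUE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values supplied")
  c(min = min(values), max = max(values), range = max(values) - min(values))
}

# round-half-up at `digits` decimals; matches how printed tables round
round_half_up <- function(x, digits = 1) {
  sgn <- sign(x)
  sgn * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Emit the analysis report bundle
#'
#' Writes tab-delimited tables mirroring the standard presentation of a
#' helical-peptide tensor study — a backbone table (Ramachandran angles
#' and hydrogen-bond inventory), an amide 15N table (shift principal
#' values and alpha/beta/gamma orientation angles) and a carbonyl 13C
#' table (with the axial anisotropy) — plus a run log. Shift values and
#' angles are rounded to 1 decimal (half-up); undefined cells are rendered
#' as an em dash. The run log records group statistics and any
#' discrepancy notes accumulated upstream.
#'
#' @param model a [structure_model] (required).
#' @param shifts optional named list with elements `"15N"` and/or `"13C"`,
#'   each a data.frame in [read_shift_table()] layout.
#' @param hbonds optional [detect_hbonds()] result (computed from the
#'   model when `NULL`).
#' @param frame optional parametrized helix frame ([parametrize_helix()]);
#'   its per-residue azimuths and tilt are appended to the log.
#' @param dir output directory (created if needed); `NULL` returns the
#'   tables without writing.
#' @param notes character vector of discrepancy notes to append to the log.
#' @return invisibly, a list with `backbone`, `table_15N`, `table_13C`
#'   data.frames (NULL where unavailable) and `log` (character).
#' @export
emit_report <- function(model, shifts = NULL, hbonds = NULL, frame = NULL,
                        dir = NULL, notes = character(0)) {
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  if (nrow(model$atoms) == 0) stop("empty model: nothing to report")
  log <- character(0)

  rama <- ramachandran(model)
  if (is.null(hbonds)) hbonds <- detect_hbonds(model)
  arrows <- vapply(rama$resno, function(i) {
    to <- hbonds$donor[hbonds$acceptor == i]      # i's C=O accepts from...
    from <- hbonds$acceptor[hbonds$donor == i]    # i's N-H donates to...
    lab <- function(r) {
      rr <- rama$resid[match(r, rama$resno)]
      paste0(substr(rr, 1, 1), tolower(substr(rr, 2, 3)), r)
    }
    paste(c(if (length(to)) paste0("→", vapply(to, lab, character(1))),
            if (length(from)) paste0(vapply(from, lab, character(1)),
                                     "←")),
          collapse = ", ")
  }, character(1))
  fmt <- function(x, digits = 1) ifelse(is.na(x), "—",
                                        sprintf(paste0("%.", digits, "f"),
                                                round_half_up(x, digits)))
  backbone <- data.frame(
    residue = paste0(substr(rama$resid, 1, 1),
                     tolower(substr(rama$resid, 2, 3)), rama$resno),
    phi = fmt(rama$phi, 0), psi = fmt(rama$psi, 0),
    phi_plus_psi = fmt(rama$phi_psi_sum, 0),
    h_bonding = arrows, stringsAsFactors = FALSE)
  log <- c(log, sprintf("backbone: %d residues, %d hydrogen bonds (%d of span 4)",
                        nrow(rama), nrow(hbonds), sum(hbonds$span == 4)))

  shift_table <- function(tab, nucleus) {
    cols <- c("residue", "eps_iso", "eps11", "eps22", "eps33",
              "alpha", "beta", "gamma")
    if (nucleus == "13C" && "eps_aniso" %in% names(tab))
      cols <- c(cols, "eps_aniso")
    out <- tab[intersect(cols, names(tab))]
    for (nm in setdiff(names(out), "residue")) out[[nm]] <- fmt(out[[nm]])
    out
  }
  table_15N <- NULL; table_13C <- NULL
  if (!is.null(shifts$`15N`)) {
    tab <- shifts$`15N`
    table_15N <- shift_table(tab, "15N")
    cls <- classify_labels(tab$residue)
    for (col in c("eps_iso", "eps11", "eps22", "eps33", "beta")) {
      gs <- group_stats(tab[[col]][cls %in% c("Aib", "proteinogenic")],
                        cls[cls %in% c("Aib", "proteinogenic")])
      for (i in seq_len(nrow(gs)))
        log <- c(log, sprintf("15N %s %s: mean %.1f sd %.1f (n=%d)", col,
                              gs$group[i], round_half_up(gs$mean[i]),
                              round_half_up(gs$sd[i]), gs$n[i]))
    }
  }
  if (!is.null(shifts$`13C`)) {
    tab <- shifts$`13C`
    if (!"eps_aniso" %in% names(tab))
      tab$eps_aniso <- mapply(function(a, b, c) axial_anisotropy(c(a, b, c)),
                              tab$eps11, tab$eps22, tab$eps33)
    table_13C <- shift_table(tab, "13C")
    vr <- value_range(tab$eps_aniso)
    log <- c(log, sprintf("13C eps_aniso span: %.1f ppm", vr["range"]))
  }
  if (!is.null(frame)) {
    log <- c(log, sprintf("helix: radius %.2f A, rise %.2f A, tilt %.1f deg",
                          frame$radius, frame$rise,
                          if (is.null(frame$tilt)) NA else frame$tilt))
    if (!is.null(frame$residue_azimuth)) {
      inc <- diff(frame$residue_azimuth[!is.na(frame$residue_azimuth)]) %% 360
      log <- c(log, sprintf("helix: mean azimuth increment %.1f deg",
                            mean(inc)))
    }
  }
  log <- c(log, notes)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wr <- function(tab, file) if (!is.null(tab))
      utils::write.table(tab, file.path(dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    wr(backbone, "backbone.tsv")
    wr(table_15N, "shifts_15N.tsv")
    wr(table_13C, "shifts_13C.tsv")
    writeLines(log, file.path(dir, "run_log.txt"), useBytes = TRUE)
  }
  invisible(list(backbone = backbone, table_15N = table_15N,
                 table_13C = table_13C, log = log))
}

# "Aib8" / "Gln19" style labels -> 3-letter code
residue_code_from_label <- function(label) {
  toupper(substr(gsub("[0-9]", "", label), 1, 3))
}

#' Residue classes for labelled table rows
#'
#' Maps row labels like `"Aib8"` or `"Gln19"` to residue classes; used to
#' form the Aib versus proteinogenic groupings of shift-table statistics.
#'
#' @param labels character vector of residue labels.
#' @return character vector of classes (see [classify_residue()]).
#' @export
classify_labels <- function(labels) {
  vapply(labels, function(s) classify_residue(residue_code_from_label(s)),
         character(1), USE.NAMES = FALSE)
}
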