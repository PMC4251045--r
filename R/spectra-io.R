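# Peak-list I/O: MGF reading/writing, NIST-style MSP annotated libraries,
# and the result table.

#' Construct a spectrum object
#'
#' @param mz Numeric vector of fragment m/z values (Th); re-sorted ascending
#'   together with the intensities.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param pepmass Precursor m/z (Th), > 0.
#' @param charge Precursor charge, or `NA` when unknown.
#' @param title Scan identifier.
#' @return List of class `xl_spectrum` with fields `title`, `pepmass`,
#'   `charge`, `mz`, `intensity`.
#' @export
spectrum <- function(mz, intensity = rep(1, length(mz)), pepmass,
                     charge = NA_integer_, title = "") {
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' lengths differ")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!is.na(pepmass) && pepmass <= 0) stop("precursor m/z must be > 0")
  o <- order(mz)
  structure(list(title = title, pepmass = pepmass,
                 charge = as.integer(charge),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "xl_spectrum")
}

#' @export
print.xl_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  precursor %.4f Th (z=%s)  %d peaks\n",
              if (nzchar(x$title)) x$title else "(untitled)", x$pepmass,
              if (is.na(x$charge)) "?" else x$charge, length(x$mz)))
  invisible(x)
}

#' Read a Mascot generic format (MGF) peak list
#'
#' One spectrum per `BEGIN IONS`/`END IONS` block. `PEPMASS` is interpreted
#' as precursor m/z (its optional second field, the intensity, is ignored),
#' `CHARGE` as e.g. `4+`, `TITLE` as the scan identifier. Blocks without
#' `CHARGE` yield `charge = NA`; downstream search assumes candidate
#' charges per [search_config()]. Peaks are re-sorted ascending by m/z.
#'
#' @param path Path to the MGF file.
#' @return List of `xl_spectrum` objects in file order (empty list, with a
#'   warning, when the file holds no block).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  pepmass <- NA_real_; charge <- NA_integer_; title <- ""
  mzs <- numeric(0); ints <- numeric(0); block_start <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block)
        stop(sprintf("line %d: BEGIN IONS inside an open block (started line %d)",
                     ln, block_start))
      in_block <- TRUE; block_start <- ln
      pepmass <- NA_real_; charge <- NA_integer_; title <- ""
      mzs <- numeric(0); ints <- numeric(0)
    } else if (line == "END IONS") {
      if (!in_block) stop(sprintf("line %d: END IONS without BEGIN IONS", ln))
      if (is.na(pepmass))
        stop(sprintf("line %d: block starting line %d has no PEPMASS",
                     ln, block_start))
      spectra[[length(spectra) + 1L]] <-
        spectrum(mzs, ints, pepmass, charge, title)
      in_block <- FALSE
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      key <- toupper(substr(line, 1L, eq - 1L))
      val <- substring(line, eq + 1L)
      if (key == "PEPMASS") {
        pepmass <- as.numeric(strsplit(trimws(val), "\\s+")[[1L]][1L])
      } else if (key == "CHARGE") {
        z <- sub("^([0-9]+).*$", "\\1", trimws(val))
        charge <- as.integer(z)
      } else if (key == "TITLE") {
        title <- trimws(val)
      }  # other headers (RTINSECONDS, SCANS, ...) are ignored
    } else if (in_block) {
      fields <- strsplit(line, "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(fields[1:2]))
      if (anyNA(vals))
        stop(sprintf("line %d: malformed peak line '%s'", ln, line))
      mzs <- c(mzs, vals[1L])
      ints <- c(ints, if (length(fields) >= 2L) vals[2L] else 1)
    } else {
      stop(sprintf("line %d: content outside BEGIN IONS/END IONS: '%s'",
                   ln, line))
    }
  }
  if (in_block)
    stop(sprintf("unterminated block starting at line %d", block_start))
  if (!length(spectra)) warning("no spectra found in ", path)
  spectra
}

#' Write spectra as MGF
#'
#' @param spectra List of `xl_spectrum` objects.
#' @param path Output path.
#' @param header Optional comment lines written at the top (prefixed `#`).
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path, header = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    if (!is.na(sp$charge)) writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

# parse one MSP annotation field into (series, index, charge) or NULL;
# neutral-loss / isotope / internal-ion tokens stay opaque
.parse_annotation <- function(field) {
  field <- gsub('"', "", field)
  for (tok in strsplit(field, ",", fixed = TRUE)[[1L]]) {
    tok <- sub("/.*$", "", tok)
    m <- regmatches(tok, regexec("^([by])([0-9]+)(\\^([0-9]+))?$", tok))[[1L]]
    if (length(m)) {
      return(list(series = m[2L], index = as.integer(m[3L]),
                  charge = if (nzchar(m[5L])) as.integer(m[5L]) else 1L))
    }
  }
  NULL
}

#' Read a NIST-style MSP annotated spectral library
#'
#' Entries start at `Name:` (conventionally `PEPTIDE/charge`) and carry
#' header fields until `Num peaks:`, followed by that many peak lines of
#' `m/z intensity annotation`. Plain b/y annotations (e.g. `b2/0.1`,
#' `y5^2/0.2`) are parsed into (series, index, charge); anything else
#' (neutral losses, isotopes, internal ions) is retained as opaque and
#' ignored by the ratio statistics.
#'
#' @param path Path to the MSP file.
#' @return List of `xl_annotated` objects: an `xl_spectrum` plus `peptide`
#'   and an annotation data.frame (`peak`, `series`, `index`, `charge`).
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!startsWith(line, "Name:")) { i <- i + 1L; next }
    name <- trimws(sub("^Name:", "", line))
    peptide <- sub("/.*$", "", name)
    charge <- suppressWarnings(as.integer(sub("^[^/]*/", "", name)))
    mw <- NA_real_; npeaks <- NA_integer_
    i <- i + 1L
    while (i <= length(lines)) {
      hl <- trimws(lines[i])
      if (startsWith(hl, "Num peaks:") || startsWith(hl, "NumPeaks:")) {
        npeaks <- as.integer(trimws(sub("^[^:]*:", "", hl)))
        i <- i + 1L
        break
      }
      if (startsWith(hl, "MW:"))
        mw <- as.numeric(trimws(sub("^MW:", "", hl)))
      if (startsWith(hl, "Name:"))
        stop(sprintf("entry '%s' has no 'Num peaks:' header", name))
      i <- i + 1L
    }
    if (is.na(npeaks))
      stop(sprintf("entry '%s' has no 'Num peaks:' header", name))
    mzs <- numeric(npeaks); ints <- numeric(npeaks)
    ann <- list()
    for (k in seq_len(npeaks)) {
      fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      mzs[k] <- as.numeric(fields[1L])
      ints[k] <- as.numeric(fields[2L])
      if (length(fields) >= 3L) {
        parsed <- .parse_annotation(paste(fields[-(1:2)], collapse = " "))
        if (!is.null(parsed))
          ann[[length(ann) + 1L]] <- data.frame(
            peak = k, series = parsed$series, index = parsed$index,
            charge = parsed$charge, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
    ann <- if (length(ann)) do.call(rbind, ann) else
      data.frame(peak = integer(0), series = character(0),
                 index = integer(0), charge = integer(0))
    sp <- spectrum(mzs, ints,
                   pepmass = if (!is.na(mw) && !is.na(charge))
                     neutral_mass_to_mz(mw, charge) else NA_real_,
                   charge = charge, title = name)
    # annotations follow the peak re-sort
    ann$peak <- match(mzs, sp$mz)[ann$peak]
    entries[[length(entries) + 1L]] <-
      structure(c(sp, list(peptide = peptide, annotations = ann)),
                class = c("xl_annotated", "xl_spectrum"))
  }
  entries
}

#' Write the cross-link search result table
#'
#' Tab-separated with one header line and the eight reporting columns:
#' m/z, the two chain sequences, calculated (database) mass, observed
#' precursor mass, charge, score, and the cross-linked residues as protein
#' coordinates `a-b`. Masses are printed at six decimals.
#'
#' @param results data.frame of class `xl_results` (see [run_search()]), or
#'   any data.frame with columns `mz`, `seq_a`, `seq_b`, `calc_mass`,
#'   `prec_mass`, `charge`, `score`, `residues`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  header <- c("m/z", "Sequence 1", "Sequence 2", "Calculated mass",
              "Precursor mass", "Charge", "XLPM score", "Cross-linked residue")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(results))
    writeLines(sprintf("%.6f\t%s\t%s\t%.6f\t%.6f\t%d\t%.6f\t%s",
                       results$mz, results$seq_a, results$seq_b,
                       results$calc_mass, results$prec_mass,
                       as.integer(results$charge), results$score,
                       results$residues), con)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return data.frame with the internal column names (`mz`, `seq_a`,
#'   `seq_b`, `calc_mass`, `prec_mass`, `charge`, `score`, `residues`).
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(df, c("mz", "seq_a", "seq_b", "calc_mass", "prec_mass",
                        "charge", "score", "residues"))
}
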