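# Empirical validation of the b -> complementary-y filter: per-spectrum
# complementary ratios and per-charge median (Ryb) estimation from an
# annotated library.

#' Complementary y/b ratio of one annotated spectrum
#'
#' Counts annotated b ions whose charge is below the precursor charge
#' (per ion: each (index, charge) annotation counts separately) and, for
#' each, whether the complementary y ion - same chain, index `n - i`,
#' charge `precursor - b charge` - is annotated in the same spectrum. The
#' ratio is the fraction of such b ions with an annotated complement.
#'
#' @param aspec An `xl_annotated` spectrum from [read_msp()] or
#'   [simulate_annotated_library()].
#' @return List of class `xl_ratio`: `charge`, `n_b`, `n_y_comp`, `ratio`
#'   and `excluded` (`TRUE`, with `ratio = NA`, when no qualifying b ion is
#'   annotated).
#' @export
complementary_ratio <- function(aspec) {
  n <- nchar(aspec$peptide)
  zp <- aspec$charge
  ann <- aspec$annotations
  b <- ann[ann$series == "b" & ann$charge < zp &
             ann$index >= 1L & ann$index <= n - 1L, , drop = FALSE]
  rec <- list(charge = zp, n_b = nrow(b), n_y_comp = 0L, ratio = NA_real_,
              excluded = nrow(b) == 0L)
  if (!rec$excluded) {
    ys <- ann[ann$series == "y", , drop = FALSE]
    comp <- mapply(function(i, zb)
      any(ys$index == n - i & ys$charge == zp - zb), b$index, b$charge)
    rec$n_y_comp <- sum(comp)
    rec$ratio <- rec$n_y_comp / rec$n_b
  }
  structure(rec, class = "xl_ratio")
}

.charge_bin <- function(z) ifelse(z >= 5L, "5", as.character(z))

#' Estimate the per-charge median complementary y/b ratio table
#'
#' Computes [complementary_ratio()] for every annotated spectrum and takes
#' the median per precursor-charge bin. Charges five and higher pool into
#' one bin. The result is directly usable as the `ryb` argument of
#' [search_config()].
#'
#' @param library List of `xl_annotated` spectra.
#' @return Named numeric vector (class `xl_ryb`) mapping charge bin
#'   (`"2"`, `"3"`, `"4"`, `"5"` = five and higher) to the median ratio;
#'   bins without any valid spectrum are absent (with a warning). The
#'   per-bin ratio vectors are attached as attribute `histograms`.
#' @export
ryb_table <- function(library) {
  recs <- lapply(library, complementary_ratio)
  keep <- !vapply(recs, `[[`, TRUE, "excluded")
  if (!any(keep)) {
    warning("no spectrum with annotated sub-precursor-charge b ions")
    return(structure(stats::setNames(numeric(0), character(0)),
                     histograms = list(), class = "xl_ryb"))
  }
  ratio <- vapply(recs[keep], `[[`, 0, "ratio")
  bin <- .charge_bin(vapply(recs[keep], `[[`, 0L, "charge"))
  hists <- split(ratio, bin)
  expected <- c("2", "3", "4", "5")
  missing <- setdiff(expected, names(hists))
  if (length(missing))
    warning("no spectra in charge bin(s): ", paste(missing, collapse = ", "))
  med <- vapply(hists, stats::median, 0)
  med <- med[order(as.integer(names(med)))]
  structure(med, histograms = hists[names(med)], class = "xl_ryb")
}

#' @export
print.xl_ryb <- function(x, ...) {
  cat("<complementary y/b ratio table> (median per precursor-charge bin)\n")
  h <- attr(x, "histograms")
  for (nm in names(x))
    cat(sprintf("  z %s%s: median %.3f  (n = %d)\n", nm,
                if (nm == "5") "+" else "", x[[nm]], length(h[[nm]])))
  invisible(unclass(x))
}

#' Write a ratio table (and optional per-bin histograms) to TSV
#'
#' @param ryb An `xl_ryb` from [ryb_table()] (or any named numeric vector).
#' @param path Output TSV path (columns `charge`, `median_ratio`).
#' @param hist_dir Optional directory for per-bin ratio histograms (one TSV
#'   of raw ratios per charge bin, for plotting).
#' @return Invisibly, `path`.
#' @export
write_ryb <- function(ryb, path, hist_dir = NULL) {
  utils::write.table(
    data.frame(charge = names(ryb), median_ratio = as.numeric(ryb)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hist_dir)) {
    dir.create(hist_dir, showWarnings = FALSE, recursive = TRUE)
    h <- attr(ryb, "histograms")
    for (nm in names(h))
      utils::write.table(data.frame(ratio = h[[nm]]),
                         file.path(hist_dir, paste0("ratios_z", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a ratio table written by [write_ryb()]
#'
#' @param path TSV path.
#' @return Named numeric vector usable as the `ryb` search parameter.
#' @export
read_ryb <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$median_ratio, df$charge)
}
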