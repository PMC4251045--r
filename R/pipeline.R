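# Orchestration: database build -> precursor match -> b/y scoring ->
# report, with a run manifest of per-stage counts.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run a complete cross-link search
#'
#' Wires the pipeline end to end: read proteins and spectra, digest and
#' filter, build the candidate pair database, match precursors within the
#' ppm tolerance, localize and score every candidate with the
#' b -> complementary-y filter, and report one row per (spectrum, candidate
#' pair, charge) sorted by score. The run is deterministic for fixed inputs
#' and configuration. Decoy searches use the same entry point on a reversed
#' database (`decoy = TRUE`); targets and decoys are searched separately.
#'
#' @param fasta FASTA path or protein data.frame ([read_fasta()]).
#' @param mgf MGF path or list of `xl_spectrum` objects.
#' @param linker An [crosslinker()] or built-in name (`"DSS"`, `"SDA"`).
#' @param config An [search_config()].
#' @param enzyme An [cleavage_rule()] (default trypsin).
#' @param mods List of [modification()] objects.
#' @param labeling `TRUE` for a 14N/15N mixed-labeling experiment.
#' @param decoy `TRUE` to reverse every protein before searching.
#' @param out Optional path: write the result TSV there ([write_results()]
#'   column layout). Nothing is written when any stage fails.
#' @return List of class `xl_search`: `results` (data.frame, one row per
#'   scored candidate with sequences, localized sites as protein
#'   coordinates, fragment counts, score and per-spectrum `rank`) and
#'   `manifest` (configuration echo plus per-stage counts).
#' @export
run_search <- function(fasta, mgf, linker, config = search_config(),
                       enzyme = cleavage_rule("trypsin"), mods = list(),
                       labeling = FALSE, decoy = FALSE, out = NULL) {
  if (is.character(linker)) linker <- crosslinker(linker)
  md5 <- function(p) if (is.character(p) && file.exists(p))
    unname(tools::md5sum(p)) else NULL
  input_files <- c(fasta = md5(fasta), mgf = md5(mgf))
  proteins <- .stage("read_fasta",
    if (is.character(fasta)) read_fasta(fasta) else fasta)
  if (decoy) proteins <- .stage("build_decoy", build_decoy(proteins))
  spectra <- .stage("read_mgf",
    if (is.character(mgf)) read_mgf(mgf) else mgf)
  peptides <- .stage("digest", do.call(rbind,
    lapply(seq_len(nrow(proteins)), function(i)
      digest(proteins[i, ], enzyme, config$max_missed))))
  filtered <- .stage("filter_candidates",
    filter_candidates(peptides, linker, enzyme))
  db <- .stage("build_pair_database",
    build_pair_database(filtered, linker, mods = mods, labeling = labeling))
  matches <- if (length(spectra) && nrow(db))
    .stage("match_precursors", match_precursors(spectra, db, config))
  else data.frame(spectrum = integer(0), scan = character(0),
                  pair = integer(0), charge = integer(0),
                  prec_mass = numeric(0), ppm_error = numeric(0))
  rows <- .stage("localize_and_score", {
    res <- vector("list", nrow(matches))
    for (k in seq_len(nrow(matches))) {
      sp <- spectra[[matches$spectrum[k]]]
      pair <- db[matches$pair[k], , drop = FALSE]
      m <- localize_sites(sp, pair, matches$charge[k], config, linker)
      coord <- function(site, start) start + max(site, 1L) - 1L
      res[[k]] <- data.frame(
        mz = sp$pepmass, seq_a = pair$seq_a, seq_b = pair$seq_b,
        calc_mass = pair$mass, prec_mass = matches$prec_mass[k],
        charge = matches$charge[k], score = m$score,
        residues = sprintf("%d-%d", coord(m$site_a, pair$start_a),
                           coord(m$site_b, pair$start_b)),
        scan = sp$title, spectrum = matches$spectrum[k],
        site_a = m$site_a, site_b = m$site_b,
        Nmb = m$counts$Nmb, Ntb = m$counts$Ntb,
        Nmy = m$counts$Nmy, Nty = m$counts$Nty,
        label_a = pair$label_a, label_b = pair$label_b,
        ambiguous = m$ambiguous, decoy = pair$decoy,
        ppm_error = matches$ppm_error[k], stringsAsFactors = FALSE)
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  if (is.null(rows))
    rows <- data.frame(mz = numeric(0), seq_a = character(0),
                       seq_b = character(0), calc_mass = numeric(0),
                       prec_mass = numeric(0), charge = integer(0),
                       score = numeric(0), residues = character(0),
                       scan = character(0), spectrum = integer(0),
                       site_a = integer(0), site_b = integer(0),
                       Nmb = integer(0), Ntb = integer(0), Nmy = integer(0),
                       Nty = integer(0), label_a = character(0),
                       label_b = character(0), ambiguous = logical(0),
                       decoy = logical(0), ppm_error = numeric(0))
  # deterministic report order: score descending, then scan, then chains
  rows <- rows[order(-rows$score, rows$scan, rows$seq_a, rows$seq_b), ,
               drop = FALSE]
  rownames(rows) <- NULL
  # rank within each spectrum (1 = best-scoring candidate)
  rows$rank <- stats::ave(-rows$score, rows$spectrum,
                          FUN = function(x) rank(x, ties.method = "first"))
  manifest <- list(
    tool = sprintf("xlms %s", as.character(utils::packageVersion("xlms"))),
    inputs = input_files,
    linker = linker$name,
    precursor_ppm = config$precursor_ppm,
    fragment_tol = config$fragment_tol,
    ryb = config$ryb,
    score_grouping = config$score_grouping,
    labeling = labeling, decoy = decoy,
    counts = c(proteins = nrow(proteins),
               peptides = nrow(peptides),
               peptides_filtered = nrow(filtered),
               pairs = nrow(db),
               spectra = length(spectra),
               precursor_matches = nrow(matches),
               reported = nrow(rows)))
  if (!is.null(out)) write_results(rows, out)
  structure(list(results = rows, manifest = manifest),
            class = "xl_search")
}

#' @export
print.xl_search <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf("<cross-link search> linker %s, %g ppm / %g Da\n",
              x$manifest$linker, x$manifest$precursor_ppm,
              x$manifest$fragment_tol))
  cat(sprintf("  %d proteins -> %d peptides (%d after filters) -> %d pairs\n",
              cts["proteins"], cts["peptides"], cts["peptides_filtered"],
              cts["pairs"]))
  cat(sprintf("  %d spectra, %d precursor matches, %d reported rows\n",
              cts["spectra"], cts["precursor_matches"], cts["reported"]))
  if (nrow(x$results)) {
    cat("  top hits:\n")
    top <- utils::head(x$results[x$results$rank == 1, , drop = FALSE], 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s x %s  %s  score %.4f (z=%d)\n", top$seq_a[i],
                  top$seq_b[i], top$residues[i], top$score[i], top$charge[i]))
  }
  invisible(x)
}
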