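# Ground-truth simulator: CID spectra of cross-linked tryptic peptide pairs
# (and annotated linear-peptide libraries for the ratio statistics), so the
# whole search stack is testable without external data.

#' Simulation parameters
#'
#' Fragmentation model: each chain of a cross-linked pair fragments like an
#' independent lower-charge peptide, the precursor's protons partitioning
#' between the b fragment and its complementary y fragment. Each theoretical
#' b ion is detected with probability `p_detect` at a uniformly drawn charge
#' below the precursor's; given a detected b ion, its complementary y ion at
#' the remaining charge appears with the per-charge probability `q_comp`
#' (decreasing with precursor charge, as complementary pairs become rarer at
#' high charge). Peak m/z values receive uniform jitter and `n_noise`
#' uniform background peaks are appended; intensities are exponential with
#' unit mean (scores are count-based, so intensities only exercise I/O).
#'
#' @param p_detect Detection probability per theoretical b ion (default
#'   0.8, a moderately noisy spectrum).
#' @param q_comp Named probability per precursor-charge bin (`"2"`..`"5"`,
#'   five and higher pooled) of observing the complementary y ion of a
#'   detected b ion.
#' @param n_noise Number of uniform background noise peaks (default 20).
#' @param noise_range m/z range of noise peaks, Th (default 200-2000).
#' @param jitter Half-width of the uniform fragment m/z error, Da (default
#'   0.2; well inside the 0.5 Da ion-trap fragment tolerance).
#' @return List of class `xl_simparams`.
#' @export
sim_params <- function(p_detect = 0.8,
                       q_comp = c(`2` = 0.70, `3` = 0.55, `4` = 0.40,
                                  `5` = 0.30),
                       n_noise = 20L, noise_range = c(200, 2000),
                       jitter = 0.2) {
  stopifnot(p_detect >= 0, p_detect <= 1, all(q_comp >= 0), all(q_comp <= 1),
            n_noise >= 0, jitter >= 0, length(noise_range) == 2L)
  structure(list(p_detect = p_detect, q_comp = q_comp,
                 n_noise = as.integer(n_noise), noise_range = noise_range,
                 jitter = jitter),
            class = "xl_simparams")
}

.q_lookup <- function(q_comp, charge) {
  zs <- as.integer(names(q_comp))
  hit <- which(zs == charge)
  if (!length(hit)) hit <- which.min(abs(zs - charge))
  unname(q_comp[hit])
}

#' Simulate one CID spectrum of a cross-linked peptide pair
#'
#' @param pair One row of an `xl_pairdb` (data.frame slice).
#' @param site_a,site_b True cross-linked positions (1-based; 0 = protein
#'   N-terminus token).
#' @param charge Precursor charge (>= 2).
#' @param linker The [crosslinker()] the pair was built with.
#' @param params An [sim_params()].
#' @param seed Optional integer seed (set once per spectrum; omit when the
#'   caller manages the RNG stream).
#' @param title Scan identifier.
#' @return List with `spectrum` (an `xl_spectrum`) and `truth` (one-row
#'   data.frame: scan, chains, sites, charge, labels, neutral mass).
#' @export
simulate_spectrum <- function(pair, site_a, site_b, charge, linker,
                              params = sim_params(), seed = NULL,
                              title = "sim") {
  if (charge < 2L) stop("precursor charge must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  H <- .elements$hydrogen_atom
  valid <- .site_combos(pair)
  if (!any(valid[, 1L] == site_a & valid[, 2L] == site_b))
    stop(sprintf("(%d, %d) is not a valid site combination for this pair",
                 site_a, site_b))
  q <- .q_lookup(params$q_comp, charge)
  mzs <- numeric(0)
  emit_chain <- function(seq_i, mods_i, label_i, site_i, partner_mass) {
    lad <- fragment_ladders(seq_i, mods = .parse_mods(mods_i),
                            xl_site = site_i,
                            xl_delta = linker$delta + partner_mass,
                            label = label_i)
    n1 <- length(lad$b)
    out <- numeric(0)
    for (i in seq_len(n1)) {
      zb <- sample.int(charge - 1L, 1L)
      if (stats::runif(1) <= params$p_detect) {
        out <- c(out, (lad$b[i] + zb * H) / zb)
        zy <- charge - zb
        if (stats::runif(1) <= q)
          out <- c(out, (lad$y[n1 + 1L - i] + zy * H) / zy)
      }
    }
    out
  }
  mzs <- c(emit_chain(pair$seq_a, pair$mods_a, pair$label_a, site_a,
                      pair$mass_b),
           emit_chain(pair$seq_b, pair$mods_b, pair$label_b, site_b,
                      pair$mass_a))
  if (params$jitter > 0 && length(mzs))
    mzs <- mzs + stats::runif(length(mzs), -params$jitter, params$jitter)
  if (params$n_noise > 0L)
    mzs <- c(mzs, stats::runif(params$n_noise, params$noise_range[1L],
                               params$noise_range[2L]))
  sp <- spectrum(mzs, stats::rexp(length(mzs)),
                 pepmass = neutral_mass_to_mz(pair$mass, charge),
                 charge = charge, title = title)
  truth <- data.frame(
    scan = title, seq_a = pair$seq_a, seq_b = pair$seq_b,
    site_a = site_a, site_b = site_b, charge = charge,
    label_a = pair$label_a, label_b = pair$label_b, mass = pair$mass,
    stringsAsFactors = FALSE)
  list(spectrum = sp, truth = truth)
}

#' Generate a simulated cross-linked dataset (MGF plus truth table)
#'
#' Digests the proteins, builds the candidate pair database, samples pairs,
#' site combinations and precursor charges, and simulates one spectrum per
#' draw. Cross-linked tryptic pairs are simulated at charges 4-6 by
#' default, where such species typically ionize.
#'
#' @param fasta Path to a FASTA file, or a protein data.frame as from
#'   [read_fasta()].
#' @param linker An [crosslinker()] (or built-in name).
#' @param n_spectra Number of spectra to simulate (>= 1).
#' @param params An [sim_params()].
#' @param seed Integer seed; recorded in the MGF and truth headers.
#' @param charges Candidate precursor charges to sample from (default 4:6).
#' @param enzyme An [cleavage_rule()] (default trypsin).
#' @param mods List of [modification()] objects.
#' @param labeling `TRUE` to enumerate 14N/15N chain label combinations.
#' @param max_missed Missed-cleavage cap for the digest (default 2).
#' @param mgf,truth Optional output paths for the MGF peak list and the
#'   tab-separated truth table.
#' @return Invisibly, a list: `spectra`, `truth` (data.frame), `db` (the
#'   `xl_pairdb` used), `peptides`, `seed`.
#' @export
generate_dataset <- function(fasta, linker, n_spectra, params = sim_params(),
                             seed = 1L, charges = 4:6,
                             enzyme = cleavage_rule("trypsin"),
                             mods = list(), labeling = FALSE,
                             max_missed = 2L, mgf = NULL, truth = NULL) {
  if (n_spectra < 1L) stop("'n_spectra' must be >= 1")
  if (is.character(linker)) linker <- crosslinker(linker)
  proteins <- if (is.character(fasta)) read_fasta(fasta) else fasta
  peps <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins[i, ], enzyme, max_missed)))
  peps <- filter_candidates(peps, linker, enzyme)
  db <- build_pair_database(peps, linker, mods = mods, labeling = labeling)
  if (!nrow(db)) stop("no valid cross-linked pairs from these proteins")
  set.seed(seed)
  rows <- sample.int(nrow(db), n_spectra, replace = TRUE)
  spectra <- vector("list", n_spectra)
  truths <- vector("list", n_spectra)
  for (k in seq_len(n_spectra)) {
    pair <- db[rows[k], , drop = FALSE]
    combos <- .site_combos(pair)
    pick <- combos[sample.int(nrow(combos), 1L), ]
    z <- if (length(charges) == 1L) charges else sample(charges, 1L)
    sim <- simulate_spectrum(pair, pick[[1L]], pick[[2L]], z, linker, params,
                             title = sprintf("sim_%04d", k))
    spectra[[k]] <- sim$spectrum
    truths[[k]] <- sim$truth
  }
  truth_df <- do.call(rbind, truths)
  if (!is.null(mgf))
    write_mgf(spectra, mgf, header = sprintf("simulated dataset, seed %d",
                                             seed))
  if (!is.null(truth)) {
    con <- file(truth, "w")
    writeLines(sprintf("# simulated dataset, seed %d", seed), con)
    close(con)
    suppressWarnings(utils::write.table(truth_df, truth, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
  }
  invisible(list(spectra = spectra, truth = truth_df, db = db,
                 peptides = peps, seed = seed))
}

#' Simulate an annotated library of linear peptide spectra
#'
#' Emulates a NIST-style annotated library for validating the
#' complementary-ratio statistics: random tryptic-like peptides, each b ion
#' annotated with probability `p_b` at a uniform charge below the
#' precursor's, and its complementary y ion (remaining charge) with the
#' per-charge probability `q_comp`.
#'
#' @param n Number of spectra.
#' @param charges Precursor charges to sample from (default 2:6).
#' @param p_b Annotation probability per b ion (default 0.8).
#' @param q_comp Named per-charge-bin complementary-y probability (see
#'   [sim_params()]).
#' @param length_range Peptide length range (default 8-18).
#' @param seed Integer seed.
#' @return List of `xl_annotated` spectra.
#' @export
simulate_annotated_library <- function(n, charges = 2:6, p_b = 0.8,
                                       q_comp = sim_params()$q_comp,
                                       length_range = c(8L, 18L),
                                       seed = 1L) {
  set.seed(seed)
  aas <- names(.residue_mass)
  H <- .elements$hydrogen_atom
  out <- vector("list", n)
  for (k in seq_len(n)) {
    len <- sample(length_range[1L]:length_range[2L], 1L)
    pep <- paste(c(sample(aas, len - 1L, replace = TRUE),
                   sample(c("K", "R"), 1L)), collapse = "")
    zp <- if (length(charges) == 1L) charges else sample(charges, 1L)
    q <- .q_lookup(q_comp, zp)
    lad <- fragment_ladders(pep)
    n1 <- length(lad$b)
    mzs <- numeric(0); ann <- list()
    add <- function(mz, series, index, z) {
      mzs <<- c(mzs, mz)
      ann[[length(ann) + 1L]] <<- data.frame(
        peak = length(mzs), series = series, index = index, charge = z,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n1)) {
      zb <- if (zp > 2L) sample.int(zp - 1L, 1L) else 1L
      if (stats::runif(1) <= p_b) {
        add((lad$b[i] + zb * H) / zb, "b", i, zb)
        if (stats::runif(1) <= q)
          add((lad$y[n1 + 1L - i] + (zp - zb) * H) / (zp - zb),
              "y", n1 + 1L - i, zp - zb)
      }
    }
    ann <- if (length(ann)) do.call(rbind, ann) else
      data.frame(peak = integer(0), series = character(0),
                 index = integer(0), charge = integer(0))
    sp <- spectrum(mzs, stats::rexp(length(mzs)),
                   pepmass = neutral_mass_to_mz(peptide_mass(pep), zp),
                   charge = zp, title = sprintf("%s/%d", pep, zp))
    ann$peak <- match(mzs, sp$mz)[ann$peak]
    out[[k]] <- structure(c(sp, list(peptide = pep, annotations = ann)),
                          class = c("xl_annotated", "xl_spectrum"))
  }
  out
}
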