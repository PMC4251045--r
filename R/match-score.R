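# Search core: precursor matching against the pair database, the
# b -> complementary-y fragment filter, site localization, and the score.

#' Default per-charge median complementary y/b ratio table
#'
#' A placeholder ratio table for scoring: charges 2, 3, 4 and the pooled
#' 5-and-higher bin. These are round fallback values, not empirical medians;
#' regenerate a table from any annotated spectral library with
#' [ryb_table()] and pass it to [search_config()]. The ratio table in use is
#' a required, logged run parameter because scores are not comparable across
#' tables.
#'
#' @return Named numeric vector mapping precursor charge (as name; `"5"` is
#'   the 5-and-higher bin) to the median complementary y/b ratio.
#' @export
default_ryb <- function() c(`2` = 0.50, `3` = 0.40, `4` = 0.30, `5` = 0.25)

#' Look up the complementary y/b ratio for a precursor charge
#'
#' Falls back to the nearest defined charge bin when the exact charge is
#' absent (charges above the last bin pool into it).
#'
#' @param ryb Named numeric ratio table (see [default_ryb()]).
#' @param charge Precursor charge.
#' @return Ratio in (0, 1].
#' @export
ryb_lookup <- function(ryb, charge) {
  if (!length(ryb) || any(ryb <= 0))
    stop("ratio table must be non-empty with positive entries")
  zs <- as.integer(names(ryb))
  hit <- which(zs == charge)
  if (!length(hit)) hit <- which.min(abs(zs - charge))
  unname(ryb[hit])
}

#' Search configuration
#'
#' @param precursor_ppm Precursor mass tolerance in ppm (default 10).
#' @param fragment_tol Fragment tolerance in Da (default 0.5, ion-trap CID;
#'   use 0.02 for FT-acquired fragment spectra).
#' @param ryb Per-charge complementary y/b ratio table ([default_ryb()] or a
#'   table estimated by [ryb_table()]).
#' @param min_xl_charge Minimum precursor charge considered for cross-linked
#'   candidates (default 2; cross-linked tryptic pairs typically ionize at
#'   4+).
#' @param candidate_charges Charges assumed for spectra whose MGF block
#'   carries no CHARGE line (default 3:8).
#' @param score_grouping `"y"`: the 1/Ryb weight applies to the y term only
#'   (default); `"global"`: it divides the whole sum.
#' @param max_missed Maximum missed cleavages during digestion (default 2).
#' @return List of class `xl_config`.
#' @export
search_config <- function(precursor_ppm = 10, fragment_tol = 0.5,
                          ryb = default_ryb(), min_xl_charge = 2L,
                          candidate_charges = 3:8,
                          score_grouping = c("y", "global"),
                          max_missed = 2L) {
  if (precursor_ppm <= 0 || fragment_tol <= 0)
    stop("tolerances must be > 0")
  if (min_xl_charge < 1L) stop("'min_xl_charge' must be >= 1")
  structure(list(precursor_ppm = precursor_ppm, fragment_tol = fragment_tol,
                 ryb = ryb, min_xl_charge = as.integer(min_xl_charge),
                 candidate_charges = as.integer(candidate_charges),
                 score_grouping = match.arg(score_grouping),
                 max_missed = as.integer(max_missed)),
            class = "xl_config")
}

# logical: does any peak lie within 'tol' Da of each target m/z?
.peak_match <- function(peaks, targets, tol) {
  if (!length(peaks) || !length(targets))
    return(logical(length(targets)))
  idx <- findInterval(targets, peaks)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peaks))
  abs(peaks[lo] - targets) <= tol | abs(peaks[hi] - targets) <= tol
}

#' Match spectrum precursors against the candidate pair database
#'
#' A (spectrum, pair) combination qualifies when the spectrum's neutral
#' precursor mass agrees with the pair's database mass within the ppm
#' tolerance. All qualifying pairs are returned; no best-only pruning
#' happens before fragment scoring. Spectra without a charge are evaluated
#' at each of `config$candidate_charges`.
#'
#' @param spectra List of `xl_spectrum` objects (see [read_mgf()]).
#' @param db An `xl_pairdb` from [build_pair_database()].
#' @param config An [search_config()].
#' @return data.frame with columns `spectrum` (index into `spectra`),
#'   `scan`, `pair` (row index into `db`), `charge`, `prec_mass` (observed
#'   neutral mass) and `ppm_error`.
#' @export
match_precursors <- function(spectra, db, config = search_config()) {
  if (!nrow(db)) stop("empty pair database")
  masses <- db$mass  # sorted ascending by construction
  out <- list()
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    charges <- if (is.na(sp$charge)) config$candidate_charges else sp$charge
    charges <- charges[charges >= config$min_xl_charge]
    for (z in charges) {
      neutral <- mz_to_neutral_mass(sp$pepmass, z)
      tol <- config$precursor_ppm * 1e-6
      lo <- findInterval(neutral * (1 - tol) - 1e-9, masses) + 1L
      hi <- findInterval(neutral * (1 + tol) + 1e-9, masses)
      if (hi < lo) next
      cand <- lo:hi
      ppm <- (neutral - masses[cand]) / masses[cand] * 1e6
      ok <- abs(ppm) <= config$precursor_ppm
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        spectrum = si, scan = sp$title, pair = cand[ok], charge = z,
        prec_mass = neutral, ppm_error = ppm[ok], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(spectrum = integer(0), scan = character(0),
                      pair = integer(0), charge = integer(0),
                      prec_mass = numeric(0), ppm_error = numeric(0)))
  do.call(rbind, out)
}

#' Count matched b ions and complementary y ions for one site assignment
#'
#' The cross-link is treated as a site modification on each chain whose
#' delta is the partner chain's mass plus the bridge. For every theoretical
#' b ion of each chain and every b charge below the precursor charge, the
#' spectrum is searched for the b ion; when found, the complementary y ion
#' (same chain, remaining residues) is sought at the remaining charge
#' (precursor charge minus the matched b charge). A (chain, index) ion
#' counts once toward `Nmb` (and once toward `Nmy`) regardless of how many
#' charge states matched. `Ntb = Nty` = total cleavage sites over both
#' chains.
#'
#' @param spectrum An `xl_spectrum`.
#' @param seq_a,seq_b Chain sequences.
#' @param site_a,site_b Cross-linked positions (1-based; `0` = protein
#'   N-terminus token).
#' @param mass_a,mass_b Neutral chain masses including modifications and
#'   label shifts.
#' @param bridge Cross-linker bridge delta (Da).
#' @param charge Precursor charge (>= 2 so that a b charge below it exists).
#' @param config An [search_config()] (fragment tolerance).
#' @param mods_a,mods_b Positioned modification vectors per chain (see
#'   [peptide_mass()]).
#' @param label_a,label_b Chain labels (`"N14"`/`"N15"`).
#' @return List with `Nmb`, `Ntb`, `Nmy`, `Nty`.
#' @export
by_filter_match <- function(spectrum, seq_a, seq_b, site_a, site_b,
                            mass_a, mass_b, bridge, charge,
                            config = search_config(),
                            mods_a = NULL, mods_b = NULL,
                            label_a = "N14", label_b = "N14") {
  H <- .elements$hydrogen_atom
  peaks <- spectrum$mz
  tol <- config$fragment_tol
  count_chain <- function(seq_i, mods_i, label_i, site_i, partner_mass) {
    lad <- fragment_ladders(seq_i, mods = mods_i, xl_site = site_i,
                            xl_delta = bridge + partner_mass, label = label_i)
    n1 <- length(lad$b)
    if (n1 == 0L || charge < 2L)
      return(c(nmb = 0L, nmy = 0L, ntb = n1))
    zb <- seq_len(charge - 1L)
    # b-ion m/z matrix: rows = cleavage index, cols = b charge
    bmat <- outer(lad$b, zb, function(bm, z) (bm + z * H) / z)
    hit_b <- matrix(.peak_match(peaks, as.vector(bmat), tol), nrow = n1)
    nmb <- 0L; nmy <- 0L
    for (i in seq_len(n1)) {
      zs <- zb[hit_b[i, ]]
      if (!length(zs)) next
      nmb <- nmb + 1L
      ycomp <- lad$y[n1 + 1L - i]  # y_(n-i), complement of b_i
      zy <- charge - zs
      ymz <- (ycomp + zy * H) / zy
      if (any(.peak_match(peaks, ymz, tol))) nmy <- nmy + 1L
    }
    c(nmb = nmb, nmy = nmy, ntb = n1)
  }
  a <- count_chain(seq_a, mods_a, label_a, site_a, mass_b)
  b <- count_chain(seq_b, mods_b, label_b, site_b, mass_a)
  list(Nmb = unname(a["nmb"] + b["nmb"]), Ntb = unname(a["ntb"] + b["ntb"]),
       Nmy = unname(a["nmy"] + b["nmy"]), Nty = unname(a["ntb"] + b["ntb"]))
}

#' Count-based cross-link match score
#'
#' `score = Nmb/Ntb + (Nmy/Nty) / Ryb(charge)` under the default grouping:
#' the reciprocal of the per-charge median complementary y/b ratio up-weights
#' observed complementary y ions, which become rarer as the precursor charge
#' grows. With `grouping = "global"` the whole sum is divided by the ratio
#' instead.
#'
#' @param counts List with `Nmb`, `Ntb`, `Nmy`, `Nty` (from
#'   [by_filter_match()]).
#' @param ryb Ratio table (see [default_ryb()]).
#' @param charge Precursor charge.
#' @param grouping `"y"` (default) or `"global"`.
#' @return Non-negative score; at most `1 + 1/Ryb` (grouping `"y"`).
#' @export
#' @examples
#' xlpm_score(list(Nmb = 4, Ntb = 8, Nmy = 2, Nty = 8), c(`4` = 0.25), 4)
xlpm_score <- function(counts, ryb, charge, grouping = c("y", "global")) {
  grouping <- match.arg(grouping)
  if (counts$Ntb <= 0L || counts$Nty <= 0L)
    stop("total ion counts must be positive")
  r <- ryb_lookup(ryb, charge)
  fb <- counts$Nmb / counts$Ntb
  fy <- counts$Nmy / counts$Nty
  if (grouping == "y") fb + fy / r else (fb + fy) / r
}

# enumerate valid (site_a, site_b) combinations for a pair row, honoring
# both linker-end orientations
.site_combos <- function(pair) {
  s1a <- .parse_sites(pair$sites1_a); s2a <- .parse_sites(pair$sites2_a)
  s1b <- .parse_sites(pair$sites1_b); s2b <- .parse_sites(pair$sites2_b)
  combos <- matrix(integer(0), ncol = 2L)
  if (length(s1a) && length(s2b))
    combos <- rbind(combos, as.matrix(expand.grid(a = s1a, b = s2b)))
  if (length(s2a) && length(s1b))
    combos <- rbind(combos, as.matrix(expand.grid(a = s2a, b = s1b)))
  combos <- unique(combos)
  combos <- combos[order(combos[, 1L], combos[, 2L]), , drop = FALSE]
  dimnames(combos) <- NULL
  combos
}

#' Localize the cross-linked residues of a candidate pair
#'
#' Evaluates [by_filter_match()] and [xlpm_score()] over every valid
#' (site A, site B) combination of the pair and returns the highest-scoring
#' assignment. Ties are broken to the lexicographically lowest (site A,
#' site B) and flagged as ambiguous with the co-optimal site list.
#'
#' @param spectrum An `xl_spectrum`.
#' @param pair One row of an `xl_pairdb` (data.frame slice).
#' @param charge Precursor charge to evaluate at.
#' @param config An [search_config()].
#' @param linker The [crosslinker()] the database was built with (bridge
#'   delta).
#' @return List of class `xl_match`: `site_a`, `site_b` (0 = protein
#'   N-terminus), `counts`, `score`, `ambiguous`, `co_optimal` (matrix of
#'   tied site pairs), and the chain descriptors.
#' @export
localize_sites <- function(spectrum, pair, charge, config = search_config(),
                           linker) {
  combos <- .site_combos(pair)
  if (!nrow(combos)) stop("candidate pair has no valid site combination")
  mods_a <- .parse_mods(pair$mods_a); mods_b <- .parse_mods(pair$mods_b)
  best <- NULL; best_score <- -Inf; scores <- numeric(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    counts <- by_filter_match(spectrum, pair$seq_a, pair$seq_b,
                              combos[k, 1L], combos[k, 2L],
                              pair$mass_a, pair$mass_b, linker$delta, charge,
                              config, mods_a, mods_b,
                              pair$label_a, pair$label_b)
    scores[k] <- xlpm_score(counts, config$ryb, charge,
                            config$score_grouping)
    if (scores[k] > best_score) {  # first max wins: combos are sorted
      best_score <- scores[k]
      best <- counts
      best_k <- k
    }
  }
  ties <- which(scores == best_score)
  structure(list(
    scan = spectrum$title, seq_a = pair$seq_a, seq_b = pair$seq_b,
    site_a = combos[best_k, 1L], site_b = combos[best_k, 2L],
    counts = best, score = best_score, charge = charge,
    ambiguous = length(ties) > 1L,
    co_optimal = combos[ties, , drop = FALSE],
    label_a = pair$label_a, label_b = pair$label_b,
    decoy = pair$decoy), class = "xl_match")
}

#' @export
print.xl_match <- function(x, ...) {
  cat(sprintf("<match> %s x %s  sites %s-%s  score %.4f (z=%d, Nmb %d/%d, Nmy %d/%d)%s\n",
              x$seq_a, x$seq_b, x$site_a, x$site_b, x$score, x$charge,
              x$counts$Nmb, x$counts$Ntb, x$counts$Nmy, x$counts$Nty,
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}
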