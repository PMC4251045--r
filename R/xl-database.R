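# In-silico digestion, cross-linkable site marking, candidate filters, and
# the pairwise cross-linked candidate database (target and reversed decoy).

#' Define (or look up) a proteolytic cleavage rule
#'
#' @param name Built-in name (`"trypsin"`) or a name for a custom rule.
#' @param residues Residues at which the enzyme cleaves (custom rules).
#' @param side `"C"` to cleave C-terminal of the residue (trypsin-like) or
#'   `"N"` for N-terminal.
#' @param exceptions Residues that suppress cleavage when adjacent on the
#'   cut side (for trypsin: no cleavage before proline).
#' @return An object of class `xl_enzyme`.
#' @export
#' @examples
#' cleavage_rule("trypsin")
#' cleavage_rule("gluc", residues = "E", side = "C")
cleavage_rule <- function(name, residues = NULL, side = c("C", "N"),
                          exceptions = character(0)) {
  if (is.null(residues)) {
    if (identical(name, "trypsin"))
      return(structure(list(name = "trypsin", residues = c("K", "R"),
                            side = "C", exceptions = "P"),
                       class = "xl_enzyme"))
    stop(sprintf("unknown built-in enzyme '%s'", name))
  }
  side <- match.arg(side)
  if (!length(residues)) stop("cleavage residue set must be non-empty")
  structure(list(name = name, residues = residues, side = side,
                 exceptions = as.character(exceptions)),
            class = "xl_enzyme")
}

#' @export
print.xl_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s: cleaves %s-terminal of %s%s\n", x$name, x$side,
              paste(x$residues, collapse = "/"),
              if (length(x$exceptions))
                paste0(" (not next to ", paste(x$exceptions, collapse = "/"), ")")
              else ""))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file of amino-acid sequences.
#' @return data.frame with columns `id` (full description line), `sequence`
#'   and `decoy` (`FALSE`).
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    ids <- names(ss); seqs <- as.character(ss)
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("no FASTA records in ", path)
    grp <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(x, collapse = ""), "")
  }
  if (anyDuplicated(ids)) stop("duplicate FASTA identifiers")
  data.frame(id = unname(ids), sequence = toupper(unname(seqs)),
             decoy = FALSE, stringsAsFactors = FALSE)
}

# positions (0..n) after which the enzyme cuts, excluding the termini
.cut_points <- function(letters, rule) {
  n <- length(letters)
  cuts <- integer(0)
  if (rule$side == "C") {
    for (i in seq_len(n - 1L))
      if (letters[i] %in% rule$residues &&
          !(letters[i + 1L] %in% rule$exceptions))
        cuts <- c(cuts, i)
  } else {
    for (i in 2L:n)
      if (letters[i] %in% rule$residues &&
          !(letters[i - 1L] %in% rule$exceptions))
        cuts <- c(cuts, i - 1L)
  }
  cuts
}

#' In-silico digestion of a protein
#'
#' Enumerates every digestion product with up to `max_missed` missed
#' cleavages: each peptide is a run of `missed + 1` adjacent fully-cleaved
#' fragments.
#'
#' @param protein A one-row data.frame (or list) with `id`, `sequence` and
#'   optionally `decoy`, as produced by [read_fasta()].
#' @param rule An [cleavage_rule()] object.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return data.frame with columns `sequence`, `protein`, `start`, `end`
#'   (1-based inclusive protein coordinates), `missed` and `decoy`.
#' @export
#' @examples
#' p <- data.frame(id = "toy", sequence = "MAKDDGSKR")
#' digest(p, cleavage_rule("trypsin"), max_missed = 1)
digest <- function(protein, rule, max_missed = 2L) {
  if (max_missed < 0L) stop("'max_missed' must be >= 0")
  seqs <- protein$sequence
  if (is.null(seqs) || !nzchar(seqs[1L])) stop("empty protein sequence")
  letters <- .check_sequence(seqs[1L])
  n <- length(letters)
  bounds <- c(0L, .cut_points(letters, rule), n)
  k <- length(bounds) - 1L  # number of fully-cleaved fragments
  out <- list()
  for (i in seq_len(k)) {
    for (m in 0:min(max_missed, k - i)) {
      from <- bounds[i] + 1L
      to <- bounds[i + m + 1L]
      out[[length(out) + 1L]] <- list(
        sequence = paste(letters[from:to], collapse = ""),
        start = from, end = to, missed = m)
    }
  }
  data.frame(
    sequence = vapply(out, `[[`, "", "sequence"),
    protein = protein$id[1L],
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    missed = vapply(out, `[[`, 0L, "missed"),
    decoy = isTRUE(protein$decoy[1L]),
    stringsAsFactors = FALSE)
}

#' Cross-linkable positions of a peptide for one reactive end
#'
#' @param sequence Peptide sequence.
#' @param end One end of an [crosslinker()] (list with `residues`, `nterm`,
#'   `any`).
#' @param start Protein coordinate of the peptide's first residue; the
#'   protein N-terminal alpha-amine is a site for amine-reactive ends only
#'   when `start == 1`.
#' @return Integer vector of 1-based peptide positions; the protein
#'   N-terminus is encoded as the distinct token `0L`.
#' @export
#' @examples
#' find_linkable_sites("MDFSK", crosslinker("DSS")$end1, start = 1)  # 0, 5
find_linkable_sites <- function(sequence, end, start = 1L) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (isTRUE(end$any)) return(seq_along(letters))
  sites <- which(letters %in% end$residues)
  if (isTRUE(end$nterm) && start == 1L) sites <- c(0L, sites)
  as.integer(sites)
}

.encode_sites <- function(x) paste(x, collapse = ",")
.parse_sites <- function(x) {
  if (!nzchar(x)) integer(0) else as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
}

#' Apply the candidate filters to a digested peptide list
#'
#' Annotates each peptide with its linkable positions for both linker ends
#' and removes peptides that cannot occur as a chain of a cross-linked pair:
#' (a) length below 3; (b) no linkable site for either end; (c) peptides
#' whose only linkable site is a C-terminal cleavage-site residue. Rule (c)
#' forces a missed cleavage: a cross-link on the C-terminal Lys of a tryptic
#' peptide would have blocked cleavage there, so the true cross-linked
#' peptide must extend past it.
#'
#' @param peptides data.frame from [digest()].
#' @param linker An [crosslinker()] object.
#' @param rule The [cleavage_rule()] used for digestion (for rule (c)).
#' @param min_length Minimum retained peptide length (default 3).
#' @return The filtered data.frame with additional columns `sites1` and
#'   `sites2` (comma-separated linkable positions per linker end; `0` is the
#'   protein N-terminus token).
#' @export
filter_candidates <- function(peptides, linker, rule, min_length = 3L) {
  if (!nrow(peptides)) {
    peptides$sites1 <- character(0); peptides$sites2 <- character(0)
    return(peptides)
  }
  s1 <- character(nrow(peptides)); s2 <- character(nrow(peptides))
  keep <- logical(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    seq_i <- peptides$sequence[i]
    n <- nchar(seq_i)
    sites1 <- find_linkable_sites(seq_i, linker$end1, peptides$start[i])
    sites2 <- find_linkable_sites(seq_i, linker$end2, peptides$start[i])
    s1[i] <- .encode_sites(sites1); s2[i] <- .encode_sites(sites2)
    all_sites <- sort(unique(c(sites1, sites2)))
    ok <- n >= min_length && length(all_sites) > 0L
    if (ok && length(all_sites) == 1L && all_sites == n &&
        substr(seq_i, n, n) %in% rule$residues)
      ok <- FALSE  # forced missed cleavage
    keep[i] <- ok
  }
  peptides$sites1 <- s1
  peptides$sites2 <- s2
  peptides[keep, , drop = FALSE]
}

.encode_mods <- function(mods) {
  if (is.null(mods) || !length(mods)) return("")
  paste(sprintf("%s:%.5f", names(mods), unname(mods)), collapse = ";")
}
.parse_mods <- function(x) {
  if (!nzchar(x)) return(NULL)
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2L]), 0),
                  vapply(kv, `[[`, "", 1L))
}

# expand one peptide into modification variants: fixed mods always applied,
# variable mods in all position subsets up to 'max_var'
.mod_variants <- function(sequence, mods, max_var = 2L) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  fixed <- numeric(0)
  var_pos <- integer(0); var_delta <- numeric(0)
  for (m in mods) {
    targets <- setdiff(m$targets, "N-term")
    pos <- which(letters %in% targets)
    if ("N-term" %in% m$targets) pos <- sort(unique(c(1L, pos)))
    if (!length(pos)) next
    if (m$variable) {
      var_pos <- c(var_pos, pos)
      var_delta <- c(var_delta, rep(m$delta, length(pos)))
    } else {
      fixed <- c(fixed, stats::setNames(rep(m$delta, length(pos)), pos))
    }
  }
  variants <- list(fixed)
  if (length(var_pos)) {
    for (k in seq_len(min(max_var, length(var_pos)))) {
      for (sel in utils::combn(seq_along(var_pos), k, simplify = FALSE)) {
        if (anyDuplicated(var_pos[sel])) next
        variants[[length(variants) + 1L]] <-
          c(fixed, stats::setNames(var_delta[sel], var_pos[sel]))
      }
    }
  }
  variants
}

#' Reversed-sequence decoy protein
#'
#' Produces the decoy counterpart of a protein record: the residue string
#' reversed and the decoy flag set. Decoys are digested, filtered and paired
#' by the same pipeline as targets but searched separately.
#'
#' @param protein data.frame with `id`, `sequence`, `decoy` (one or more
#'   rows).
#' @return data.frame of the same shape with reversed sequences,
#'   `decoy = TRUE` and ids prefixed `rev_` (the prefix is stripped when a
#'   decoy is reversed back).
#' @export
#' @examples
#' build_decoy(data.frame(id = "p", sequence = "MAKR", decoy = FALSE))
build_decoy <- function(protein) {
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                            collapse = "")
  data.frame(
    id = ifelse(startsWith(protein$id, "rev_"),
                sub("^rev_", "", protein$id), paste0("rev_", protein$id)),
    sequence = vapply(protein$sequence, rev1, "", USE.NAMES = FALSE),
    decoy = !protein$decoy,
    stringsAsFactors = FALSE)
}

#' Build the cross-linked candidate pair database
#'
#' Enumerates every unordered pair of filtered peptides (including a peptide
#' with itself: homodimeric complexes yield same-same links), expanded over
#' variable-modification states and, for labeling experiments, over
#' 14N/15N chain label combinations. A pair is a candidate when its two
#' chains can satisfy the two linker ends in at least one orientation. The
#' neutral pair mass is mass(A) + mass(B) + bridge delta, with each chain
#' mass carrying its own modifications and label shift.
#'
#' @param peptides Filtered peptide data.frame from [filter_candidates()].
#' @param linker An [crosslinker()] object.
#' @param mods List of [modification()] objects (fixed mods applied
#'   everywhere; variable mods expanded combinatorially).
#' @param labeling `FALSE` (single label, all 14N) or `TRUE` (mixed
#'   experiment: chains enumerate 14N x 15N combinations).
#' @param max_var_mods Cap on simultaneous variable modifications per
#'   peptide (default 2).
#' @return data.frame of class `xl_pairdb`, one row per candidate: chain
#'   sequences, protein coordinates, encoded modifications, linkable sites
#'   per end, labels, chain masses and the neutral pair `mass`. The linker
#'   is attached as attribute `linker`.
#' @export
build_pair_database <- function(peptides, linker, mods = list(),
                                labeling = FALSE, max_var_mods = 2L) {
  cols <- c("seq_a", "seq_b", "protein_a", "protein_b", "start_a", "start_b",
            "mods_a", "mods_b", "sites1_a", "sites2_a", "sites1_b",
            "sites2_b", "label_a", "label_b", "mass_a", "mass_b", "mass",
            "decoy")
  empty <- function() {
    db <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    for (nm in c("start_a", "start_b")) db[[nm]] <- integer(0)
    for (nm in c("mass_a", "mass_b", "mass")) db[[nm]] <- numeric(0)
    db$decoy <- logical(0)
    structure(db, linker = linker, class = c("xl_pairdb", "data.frame"))
  }
  if (!nrow(peptides)) {
    warning("empty peptide list: returning an empty pair database")
    return(empty())
  }
  labels <- if (labeling) c("N14", "N15") else "N14"
  # expand peptides x mod variants x labels into chain records
  chains <- list()
  for (i in seq_len(nrow(peptides))) {
    variants <- .mod_variants(peptides$sequence[i], mods, max_var_mods)
    nN <- nitrogen_count(peptides$sequence[i])
    for (v in variants) {
      base_mass <- peptide_mass(peptides$sequence[i],
                                mods = if (length(v)) v else NULL)
      for (lab in labels) {
        m <- base_mass + if (lab == "N15") .elements$n15_minus_n14 * nN else 0
        chains[[length(chains) + 1L]] <- list(
          pep = i, mods = .encode_mods(v), label = lab, mass = m)
      }
    }
  }
  has1 <- nchar(peptides$sites1) > 0L
  has2 <- nchar(peptides$sites2) > 0L
  rows <- list()
  for (i in seq_along(chains)) {
    for (j in i:length(chains)) {
      ci <- chains[[i]]; cj <- chains[[j]]
      pi <- ci$pep; pj <- cj$pep
      if (!((has1[pi] && has2[pj]) || (has2[pi] && has1[pj]))) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_a = peptides$sequence[pi], seq_b = peptides$sequence[pj],
        protein_a = peptides$protein[pi], protein_b = peptides$protein[pj],
        start_a = peptides$start[pi], start_b = peptides$start[pj],
        mods_a = ci$mods, mods_b = cj$mods,
        sites1_a = peptides$sites1[pi], sites2_a = peptides$sites2[pi],
        sites1_b = peptides$sites1[pj], sites2_b = peptides$sites2[pj],
        label_a = ci$label, label_b = cj$label,
        mass_a = ci$mass, mass_b = cj$mass,
        mass = ci$mass + cj$mass + linker$delta,
        decoy = peptides$decoy[pi] || peptides$decoy[pj],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no linker-compatible pairs: returning an empty pair database")
    return(empty())
  }
  db <- do.call(rbind, rows)
  # canonical unordered-pair key: identical records from permuted input
  # orders collapse to the same row set
  key_a <- paste(db$seq_a, db$start_a, db$protein_a, db$mods_a, db$label_a)
  key_b <- paste(db$seq_b, db$start_b, db$protein_b, db$mods_b, db$label_b)
  swap <- key_a > key_b
  if (any(swap)) {
    a_cols <- c("seq_a", "protein_a", "start_a", "mods_a", "sites1_a",
                "sites2_a", "label_a", "mass_a")
    b_cols <- sub("_a$", "_b", a_cols)
    tmp <- db[swap, a_cols]
    db[swap, a_cols] <- db[swap, b_cols]
    db[swap, b_cols] <- tmp
  }
  key <- paste(pmin(key_a, key_b), pmax(key_a, key_b), sep = " | ")
  db <- db[!duplicated(key), , drop = FALSE]
  db <- db[order(db$mass, db$seq_a, db$seq_b), , drop = FALSE]
  rownames(db) <- NULL
  structure(db, linker = linker, class = c("xl_pairdb", "data.frame"))
}

#' @export
print.xl_pairdb <- function(x, ...) {
  lk <- attr(x, "linker")
  cat(sprintf("<cross-linked pair database> %d candidates, linker %s\n",
              nrow(x), if (is.null(lk)) "?" else lk$name))
  if (nrow(x))
    cat(sprintf("  neutral mass range %.4f - %.4f Da\n",
                min(x$mass), max(x$mass)))
  invisible(x)
}

#' Export a pair database as TSV
#'
#' @param db An `xl_pairdb` from [build_pair_database()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pair_database <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
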