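# Monoisotopic mass arithmetic: residues, modifications, cross-linker deltas,
# 15N shifts, m/z <-> neutral mass conversion, and b/y fragment ladders.

# Monoisotopic residue masses (Da) and elemental nitrogen counts for the 20
# standard amino acids. L and I are isobaric.
.residue_mass <- c(
  G =  57.0214637, A =  71.0371138, S =  87.0320284, P =  97.0527638,
  V =  99.0684139, T = 101.0476785, C = 103.0091848, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269430, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404849, H = 137.0589119,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)

.residue_nitrogen <- c(
  G = 1L, A = 1L, S = 1L, P = 1L, V = 1L, T = 1L, C = 1L, L = 1L, I = 1L,
  N = 2L, D = 1L, Q = 2L, K = 2L, E = 1L, M = 1L, H = 3L, F = 1L, R = 4L,
  Y = 1L, W = 2L
)

.elements <- list(
  hydrogen_atom = 1.00782503207,
  proton        = 1.00727646677,
  oxygen        = 15.9949146196,
  water         = 18.0105646837,
  n15_minus_n14 = 0.9970349
)

#' Element and molecule masses used throughout the package
#'
#' Monoisotopic masses in Da. The charge-carrier convention is the hydrogen
#' atom (1.007825 Da per charge), which is the convention under which the
#' package interconverts m/z and neutral mass; see
#' [mz_to_neutral_mass()].
#'
#' @return Named list with elements `hydrogen_atom`, `proton`, `oxygen`,
#'   `water` and `n15_minus_n14` (the mass difference between one 15N and one
#'   14N atom), all in Da.
#' @export
#' @examples
#' element_masses()$water
element_masses <- function() .elements

#' Monoisotopic residue mass table
#'
#' @return A data.frame with one row per standard amino acid: `residue`
#'   (one-letter code), `mass` (monoisotopic residue mass, Da) and `nitrogen`
#'   (number of nitrogen atoms, backbone plus side chain).
#' @export
residue_table <- function() {
  data.frame(residue = names(.residue_mass),
             mass = unname(.residue_mass),
             nitrogen = unname(.residue_nitrogen[names(.residue_mass)]),
             stringsAsFactors = FALSE)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string")
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!letters %in% names(.residue_mass))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 letters[bad[1L]], bad[1L], sequence))
  letters
}

#' Total nitrogen atoms in a peptide
#'
#' Backbone plus side-chain nitrogens summed over the residues. Used to
#' compute the mass shift of uniformly 15N metabolically labeled chains.
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @return Integer nitrogen count.
#' @export
#' @examples
#' nitrogen_count("GG")  # 2: one backbone nitrogen per glycine
nitrogen_count <- function(sequence) {
  letters <- .check_sequence(sequence)
  sum(.residue_nitrogen[letters])
}

.mods_to_vector <- function(mods, n) {
  # normalize 'mods' to a numeric vector of per-position deltas (length n);
  # input is a named numeric vector, names = 1-based residue positions
  deltas <- numeric(n)
  if (is.null(mods) || length(mods) == 0L) return(deltas)
  if (!is.numeric(mods) || is.null(names(mods)))
    stop("'mods' must be a named numeric vector (names = residue positions)")
  pos <- as.integer(names(mods))
  if (anyNA(pos) || any(pos < 1L) || any(pos > n))
    stop("modification positions must be integers in 1..peptide length")
  for (k in seq_along(pos)) deltas[pos[k]] <- deltas[pos[k]] + mods[[k]]
  deltas
}

#' Monoisotopic neutral mass of a (modified, optionally 15N-labeled) peptide
#'
#' Mass = sum of residue masses + water + modification deltas + the 15N shift
#' when `label = "N15"`. The 15N shift is `n15_minus_n14` times the number of
#' nitrogen atoms in the residues; modification deltas are taken at face
#' value (chemical modifications introduced after metabolic labeling carry
#' natural-abundance nitrogen).
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param mods Named numeric vector of mass deltas (Da); names are 1-based
#'   residue positions. `NULL` for none.
#' @param label `"N14"` (natural) or `"N15"` (uniform 15N labeling).
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("MDFSK")                     # 626.2734
#' peptide_mass("GG", label = "N15") - peptide_mass("GG")  # 2 x 0.9970349
peptide_mass <- function(sequence, mods = NULL, label = c("N14", "N15")) {
  label <- match.arg(label)
  letters <- .check_sequence(sequence)
  m <- sum(.residue_mass[letters]) + .elements$water +
    sum(.mods_to_vector(mods, length(letters)))
  if (label == "N15")
    m <- m + .elements$n15_minus_n14 * sum(.residue_nitrogen[letters])
  m
}

#' Convert m/z to neutral mass
#'
#' Uses the hydrogen-atom charge carrier: mass = charge * m/z -
#' charge * 1.007825.
#'
#' @param mz Observed m/z (Th), > 0.
#' @param charge Positive integer charge state.
#' @return Neutral mass (Da).
#' @export
#' @examples
#' mz_to_neutral_mass(720.9754028, 5)  # 3599.8379
mz_to_neutral_mass <- function(mz, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("'charge' must be a positive integer")
  if (any(mz <= 0)) stop("'mz' must be > 0")
  charge * mz - charge * .elements$hydrogen_atom
}

#' Convert neutral mass to m/z
#'
#' Inverse of [mz_to_neutral_mass()].
#'
#' @param mass Neutral mass (Da), > 0.
#' @param charge Positive integer charge state.
#' @return m/z (Th).
#' @export
neutral_mass_to_mz <- function(mass, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("'charge' must be a positive integer")
  if (any(mass <= 0)) stop("'mass' must be > 0")
  (mass + charge * .elements$hydrogen_atom) / charge
}

#' Theoretical b- and y-ion ladders of a peptide
#'
#' Neutral fragment masses for the b and y series of a peptide, optionally
#' carrying positioned modifications and a cross-link treated as a site
#' modification of mass `xl_delta` (bridge plus partner chain). Ladders run
#' over cleavage sites 1..n-1: `b[i]` is the prefix of length i, `y[j]` the
#' suffix of length j, so `b[i] + y[n-i]` equals the full neutral peptide
#' mass for every i.
#'
#' @param sequence Peptide sequence.
#' @param mods Named numeric vector of positioned mass deltas (see
#'   [peptide_mass()]).
#' @param xl_site 1-based residue index carrying the cross-link, or `NULL`.
#'   The protein N-terminus site token `0` is accepted and treated as
#'   residue 1 for fragment bookkeeping.
#' @param xl_delta Mass added at `xl_site` (Da).
#' @param label `"N14"` or `"N15"`.
#' @return List with numeric vectors `b` and `y`, each of length
#'   `nchar(sequence) - 1`.
#' @export
#' @examples
#' fragment_ladders("GG")$b  # 57.02146
fragment_ladders <- function(sequence, mods = NULL, xl_site = NULL,
                             xl_delta = 0, label = c("N14", "N15")) {
  label <- match.arg(label)
  letters <- .check_sequence(sequence)
  n <- length(letters)
  res <- .residue_mass[letters]
  if (label == "N15")
    res <- res + .elements$n15_minus_n14 * .residue_nitrogen[letters]
  deltas <- .mods_to_vector(mods, n)
  if (!is.null(xl_site)) {
    if (length(xl_site) != 1L || xl_site < 0L || xl_site > n)
      stop(sprintf("xl_site %s out of range for peptide of length %d",
                   as.character(xl_site), n))
    site <- max(as.integer(xl_site), 1L)  # N-terminus token 0 -> residue 1
    deltas[site] <- deltas[site] + xl_delta
  }
  cum <- cumsum(res + deltas)
  total <- cum[n]
  if (n == 1L) return(list(b = numeric(0), y = numeric(0)))
  b <- cum[seq_len(n - 1L)]
  # y_j covers the suffix of length j = total - prefix(n - j) + water
  y <- total - cum[n - seq_len(n - 1L)] + .elements$water
  list(b = unname(b), y = unname(y))
}

#' Define a post-translational or chemical modification
#'
#' @param name Modification name.
#' @param targets Character vector of target residues (one-letter codes),
#'   optionally including `"N-term"`.
#' @param delta Mass delta (Da), finite.
#' @param variable Logical; `FALSE` for a fixed (always applied)
#'   modification.
#' @return An object of class `xl_modification`.
#' @export
#' @examples
#' modification("carbamidomethyl", "C", 57.02146, variable = FALSE)
modification <- function(name, targets, delta, variable = FALSE) {
  if (!length(targets)) stop("'targets' must be non-empty")
  if (!is.finite(delta)) stop("'delta' must be finite")
  structure(list(name = name, targets = targets, delta = delta,
                 variable = isTRUE(variable)),
            class = "xl_modification")
}

#' @export
print.xl_modification <- function(x, ...) {
  cat(sprintf("<modification> %s %+0.5f Da on %s (%s)\n", x$name, x$delta,
              paste(x$targets, collapse = ","),
              if (x$variable) "variable" else "fixed"))
  invisible(x)
}

.builtin_linkers <- list(
  # DSS: homobifunctional NHS ester, links primary amines (Lys side chain,
  # protein N-terminal alpha-amine). Bridge C8H10O2 once both esters react.
  DSS = list(name = "DSS",
             end1 = list(residues = "K", nterm = TRUE, any = FALSE),
             end2 = list(residues = "K", nterm = TRUE, any = FALSE),
             delta = 138.06808),
  # SDA: NHS ester at end 1 (amines); diazirine at end 2 which, after UV
  # photolysis loses N2 and the carbene inserts into any residue. Net bridge
  # C5H6O.
  SDA = list(name = "SDA",
             end1 = list(residues = "K", nterm = TRUE, any = FALSE),
             end2 = list(residues = character(0), nterm = FALSE, any = TRUE),
             delta = 82.04186)
)

.linker_end <- function(end) {
  if (is.null(end)) stop("cross-linker end specificity missing")
  out <- list(residues = as.character(end$residues %||% character(0)),
              nterm = isTRUE(end$nterm), any = isTRUE(end$any))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define (or look up) a cross-linking reagent
#'
#' A cross-linker has two reactive ends, each specified by a set of target
#' residues, an optional protein N-terminus reactivity flag, and an optional
#' wildcard (`any = TRUE`, reacts with every residue), plus the bridge mass
#' delta: the net mass added to the two linked peptides after both reactive
#' groups have reacted. `"DSS"` (amine-to-amine, bridge 138.06808 Da) and
#' `"SDA"` (amine-to-any after diazirine photolysis, bridge 82.04186 Da) are
#' built in.
#'
#' @param name Built-in name (`"DSS"`, `"SDA"`) or a name for a custom
#'   linker.
#' @param end1,end2 For a custom linker, lists with elements `residues`
#'   (character vector), `nterm` (logical) and `any` (logical). The wildcard
#'   is allowed on end 2 (or both), not on end 1 alone.
#' @param delta Bridge mass delta in Da (custom linkers).
#' @return An object of class `xl_linker`.
#' @export
#' @examples
#' crosslinker("DSS")
#' crosslinker("BS3-like", end1 = list(residues = "K", nterm = TRUE),
#'             end2 = list(residues = c("K", "S", "T", "Y"), nterm = TRUE),
#'             delta = 138.06808)
crosslinker <- function(name, end1 = NULL, end2 = NULL, delta = NULL) {
  if (is.null(end1) && is.null(end2) && is.null(delta)) {
    if (!name %in% names(.builtin_linkers))
      stop(sprintf("unknown built-in cross-linker '%s'; built-ins: %s", name,
                   paste(names(.builtin_linkers), collapse = ", ")))
    lk <- .builtin_linkers[[name]]
  } else {
    if (is.null(delta) || !is.finite(delta))
      stop("'delta' must be a finite bridge mass in Da")
    lk <- list(name = name, end1 = .linker_end(end1),
               end2 = .linker_end(end2), delta = delta)
  }
  lk$end1 <- .linker_end(lk$end1); lk$end2 <- .linker_end(lk$end2)
  if (lk$end1$any && !lk$end2$any)
    stop("wildcard specificity is allowed on end 2 (or both ends), not end 1")
  if (!lk$end1$any && !length(lk$end1$residues) && !lk$end1$nterm)
    stop("end 1 specificity is empty")
  structure(lk, class = "xl_linker")
}

.end_label <- function(end) {
  if (end$any) return("any")
  parts <- end$residues
  if (end$nterm) parts <- c(parts, "protein N-term")
  paste(parts, collapse = "/")
}

#' @export
print.xl_linker <- function(x, ...) {
  cat(sprintf("<cross-linker> %s: [%s] -- %.5f Da -- [%s]\n", x$name,
              .end_label(x$end1), x$delta, .end_label(x$end2)))
  invisible(x)
}

#' Read cross-linker / enzyme / modification definitions from a config file
#'
#' Plain-text `key = value` format, one definition block per `[section]`.
#' Sections: `[linker]` (keys `name`, `end1_residues`, `end1_nterm`,
#' `end2_residues`, `end2_nterm`, `end2_any`, `delta`), `[enzyme]` (keys
#' `name`, `residues`, `side`, `exceptions`) and `[modification]` (keys
#' `name`, `targets`, `delta`, `variable`). Residue sets are comma-separated
#' one-letter codes; logicals are `true`/`false`.
#'
#' @param path Path to the config file.
#' @return List with elements `linkers`, `enzymes`, `modifications`.
#' @export
read_xl_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(linkers = list(), enzymes = list(), modifications = list())
  section <- NULL; kv <- list()
  flush <- function(section, kv, out) {
    if (is.null(section) || !length(kv)) return(out)
    split_set <- function(x) if (is.null(x)) character(0)
      else trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
    as_flag <- function(x) isTRUE(tolower(x %||% "false") == "true")
    if (section == "linker") {
      lk <- crosslinker(kv$name,
        end1 = list(residues = split_set(kv$end1_residues),
                    nterm = as_flag(kv$end1_nterm), any = as_flag(kv$end1_any)),
        end2 = list(residues = split_set(kv$end2_residues),
                    nterm = as_flag(kv$end2_nterm), any = as_flag(kv$end2_any)),
        delta = as.numeric(kv$delta))
      out$linkers[[lk$name]] <- lk
    } else if (section == "enzyme") {
      en <- cleavage_rule(kv$name, residues = split_set(kv$residues),
                          side = kv$side %||% "C",
                          exceptions = split_set(kv$exceptions))
      out$enzymes[[en$name]] <- en
    } else if (section == "modification") {
      md <- modification(kv$name, split_set(kv$targets),
                         as.numeric(kv$delta), as_flag(kv$variable))
      out$modifications[[md$name]] <- md
    } else stop(sprintf("unknown config section '%s'", section))
    out
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      out <- flush(section, kv, out)
      section <- sub("^\\[(.+)\\]$", "\\1", ln); kv <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      kv[[trimws(substr(ln, 1L, eq - 1L))]] <- trimws(substring(ln, eq + 1L))
    } else stop(sprintf("malformed config line: '%s'", ln))
  }
  flush(section, kv, out)
}
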