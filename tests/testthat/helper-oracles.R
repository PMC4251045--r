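# Independent brute-force oracles and shared fixtures. These deliberately
# re-derive results by the most direct route available (enumeration,
# pairwise comparison, prefix/suffix sums) so they share no code path with
# the implementation they check.

# independent residue masses (rounded to 5 dp on purpose: tolerances in the
# tests that use this table allow for it) and nitrogen counts
oracle_residues <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
oracle_nitrogens <- c(
  G = 1, A = 1, S = 1, P = 1, V = 1, T = 1, C = 1, L = 1, I = 1, N = 2,
  D = 1, Q = 2, K = 2, E = 1, M = 1, H = 3, F = 1, R = 4, Y = 1, W = 2)

oracle_peptide_mass <- function(seq) {
  sum(oracle_residues[strsplit(seq, "")[[1]]]) + 18.010565
}

# brute-force digestion: every substring whose two boundaries are cleavage
# boundaries and which spans at most max_missed internal cleavage points
oracle_digest <- function(seq, max_missed = 2) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  cuts <- integer(0)
  for (i in seq_len(max(n - 1, 0)))
    if (aa[i] %in% c("K", "R") && aa[i + 1] != "P") cuts <- c(cuts, i)
  bounds <- c(0, cuts, n)
  out <- character(0)
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    if (!(i %in% bounds) || !(j %in% bounds)) next
    internal <- sum(cuts > i & cuts < j)
    if (internal <= max_missed)
      out <- c(out, paste0(i + 1, ":", j))
  }
  sort(out)
}

# exhaustive fragment matcher: triple loop over chains, indices, charges,
# peaks, with the cross-link as an added mass at the site
oracle_by_counts <- function(peaks, seq_a, seq_b, site_a, site_b,
                             mass_a, mass_b, bridge, zp, tol) {
  H <- 1.00782503207
  chain <- function(seq, site, partner) {
    aa <- strsplit(seq, "")[[1]]
    n <- length(aa)
    res <- oracle_residues[aa]
    res[max(site, 1)] <- res[max(site, 1)] + bridge + partner
    nmb <- 0; nmy <- 0
    for (i in seq_len(n - 1)) {
      bi <- sum(res[1:i])
      yi <- sum(res[(i + 1):n]) + 18.010565
      hit_b <- FALSE; hit_y <- FALSE
      for (zb in seq_len(zp - 1)) {
        if (any(abs(peaks - (bi + zb * H) / zb) <= tol)) {
          hit_b <- TRUE
          zy <- zp - zb
          if (any(abs(peaks - (yi + zy * H) / zy) <= tol)) hit_y <- TRUE
        }
      }
      nmb <- nmb + hit_b
      nmy <- nmy + (hit_b && hit_y)
    }
    c(nmb, nmy, n - 1)
  }
  a <- chain(seq_a, site_a, mass_b)
  b <- chain(seq_b, site_b, mass_a)
  list(Nmb = a[1] + b[1], Ntb = a[3] + b[3], Nmy = a[2] + b[2],
       Nty = a[3] + b[3])
}

# Mann-Whitney AUC: exhaustive pair comparison with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

random_protein <- function(len, aas = names(oracle_residues)) {
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

# two K-rich synthetic proteins used by the end-to-end fixtures
toy_proteins <- function() {
  data.frame(
    id = c("synA", "synB"),
    sequence = c("MDFSKGALVYVEADAANYVFERDDGSKGTTLSLVQKYLKYSIASQPRR",
                 "MSIVGRIGSEFTEHTSANNNRYLKYSIASQPRKLEDAEGQENAASSELEK"),
    decoy = FALSE, stringsAsFactors = FALSE)
}
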