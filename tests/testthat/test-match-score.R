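dss <- crosslinker("DSS")
H <- element_masses()$hydrogen_atom

# assemble a spectrum holding chosen theoretical ions of a two-chain pair
make_pair_spectrum <- function(seq_a, seq_b, site_a, site_b, zp,
                               emit = c("b", "y"), zb = 1L,
                               extra = numeric(0)) {
  mass_a <- peptide_mass(seq_a); mass_b <- peptide_mass(seq_b)
  mzs <- extra
  for (chain in 1:2) {
    sq <- if (chain == 1) seq_a else seq_b
    site <- if (chain == 1) site_a else site_b
    partner <- if (chain == 1) mass_b else mass_a
    lad <- fragment_ladders(sq, xl_site = site,
                            xl_delta = dss$delta + partner)
    n1 <- length(lad$b)
    for (i in seq_len(n1)) {
      if ("b" %in% emit) mzs <- c(mzs, (lad$b[i] + zb * H) / zb)
      if ("y" %in% emit)
        mzs <- c(mzs, (lad$y[n1 + 1 - i] + (zp - zb) * H) / (zp - zb))
    }
  }
  spectrum(mzs, pepmass = neutral_mass_to_mz(mass_a + mass_b + dss$delta, zp),
           charge = zp, title = "fixture")
}

test_that("the score combines matched fractions with the y/b ratio weight", {
  expect_equal(xlpm_score(list(Nmb = 8, Ntb = 8, Nmy = 8, Nty = 8),
                          c(`4` = 0.5), 4), 3.0)
  expect_equal(xlpm_score(list(Nmb = 0, Ntb = 8, Nmy = 0, Nty = 8),
                          c(`4` = 0.5), 4), 0.0)
  expect_equal(xlpm_score(list(Nmb = 4, Ntb = 8, Nmy = 2, Nty = 8),
                          c(`4` = 0.25), 4), 1.5)
  expect_equal(xlpm_score(list(Nmb = 4, Ntb = 8, Nmy = 2, Nty = 8),
                          c(`4` = 0.25), 4, grouping = "global"), 3.0)
  expect_error(xlpm_score(list(Nmb = 0, Ntb = 0, Nmy = 0, Nty = 0),
                          c(`4` = 0.5), 4), "positive")
})

test_that("ratio lookup falls back to the nearest defined charge", {
  tab <- default_ryb()
  expect_equal(ryb_lookup(tab, 3), 0.40)
  expect_equal(ryb_lookup(tab, 7), 0.25)   # pools into the 5+ bin
  expect_equal(ryb_lookup(c(`3` = 0.4), 2), 0.4)
  expect_error(ryb_lookup(numeric(0), 3), "non-empty")
})

test_that("precursor matching applies the ppm window exactly", {
  f <- filter_candidates(
    digest(data.frame(id = "p", sequence = "MAKDDGSKR", decoy = FALSE),
           cleavage_rule("trypsin"), 1), dss, cleavage_rule("trypsin"))
  db <- build_pair_database(f, dss)
  cfg <- search_config(precursor_ppm = 10)
  m0 <- db$mass[3]
  hit <- spectrum(500, pepmass = neutral_mass_to_mz(m0, 4), charge = 4)
  edge <- spectrum(500, pepmass = neutral_mass_to_mz(m0 * (1 + 10.1e-6), 4),
                   charge = 4)
  pm <- match_precursors(list(hit, edge), db, cfg)
  expect_true(all(pm$spectrum == 1L))
  expect_true(3L %in% pm$pair)
  expect_true(all(abs(pm$ppm_error) <= 10))
})

test_that("planted precursors pick out exactly their pairs in a sparse database", {
  set.seed(31)
  # many random proteins to get a database of 100+ well-separated masses
  peps <- do.call(rbind, lapply(1:8, function(i)
    digest(data.frame(id = paste0("p", i), sequence = random_protein(60),
                      decoy = FALSE), cleavage_rule("trypsin"), 1)))
  f <- filter_candidates(peps, dss, cleavage_rule("trypsin"))
  db <- build_pair_database(f, dss)
  expect_gt(nrow(db), 100)
  # pick five pairs whose masses are > 50 ppm from every other pair
  gaps <- vapply(seq_len(nrow(db)), function(i)
    min(abs(db$mass[-i] - db$mass[i]) / db$mass[i] * 1e6), 0)
  planted <- which(gaps > 50)[1:5]
  spectra <- lapply(planted, function(i)
    spectrum(500, pepmass = neutral_mass_to_mz(db$mass[i], 4), charge = 4))
  pm <- match_precursors(spectra, db, search_config(precursor_ppm = 5))
  expect_equal(nrow(pm), 5L)
  expect_equal(pm$pair, planted)
})

test_that("saturated spectra max out both counts; empty spectra give zero", {
  sp <- make_pair_spectrum("MAKDDGSK", "DDGSKR", 3, 5, zp = 4)
  counts <- by_filter_match(sp, "MAKDDGSK", "DDGSKR", 3, 5,
                            peptide_mass("MAKDDGSK"), peptide_mass("DDGSKR"),
                            dss$delta, 4)
  expect_equal(counts$Ntb, 7 + 5)
  expect_equal(counts$Nmb, counts$Ntb)
  expect_equal(counts$Nmy, counts$Nty)
  empty <- spectrum(numeric(0), pepmass = sp$pepmass, charge = 4)
  c0 <- by_filter_match(empty, "MAKDDGSK", "DDGSKR", 3, 5,
                        peptide_mass("MAKDDGSK"), peptide_mass("DDGSKR"),
                        dss$delta, 4)
  expect_equal(c0$Nmb + c0$Nmy, 0)
})

test_that("complementary y ions are sought, never assumed", {
  sp_b <- make_pair_spectrum("MAKDDGSK", "DDGSKR", 3, 5, zp = 4,
                             emit = "b")
  counts <- by_filter_match(sp_b, "MAKDDGSK", "DDGSKR", 3, 5,
                            peptide_mass("MAKDDGSK"), peptide_mass("DDGSKR"),
                            dss$delta, 4)
  expect_gt(counts$Nmb, 0)
  expect_equal(counts$Nmy, 0)
})

test_that("fragment counting equals an exhaustive brute-force matcher", {
  set.seed(32)
  for (k in 1:15) {
    seq_a <- paste0(random_protein(sample(4:9, 1)), "K")
    seq_b <- paste0(random_protein(sample(4:9, 1)), "K")
    zp <- sample(3:6, 1)
    site_a <- sample(nchar(seq_a), 1)
    site_b <- sample(nchar(seq_b), 1)
    # some true ions at assorted charges plus uniform noise
    sp <- make_pair_spectrum(seq_a, seq_b, site_a, site_b, zp,
                             zb = sample(seq_len(zp - 1), 1),
                             extra = runif(30, 150, 2500))
    keep <- sort(sample(length(sp$mz), ceiling(length(sp$mz) * 0.6)))
    sp2 <- spectrum(sp$mz[keep], pepmass = sp$pepmass, charge = zp)
    got <- by_filter_match(sp2, seq_a, seq_b, site_a, site_b,
                           peptide_mass(seq_a), peptide_mass(seq_b),
                           dss$delta, zp)
    want <- oracle_by_counts(sp2$mz, seq_a, seq_b, site_a, site_b,
                             peptide_mass(seq_a), peptide_mass(seq_b),
                             dss$delta, zp, 0.5)
    expect_equal(got$Nmb, want$Nmb)
    expect_equal(got$Nmy, want$Nmy)
    expect_equal(got$Ntb, want$Ntb)
  }
})

test_that("adding a matched theoretical peak never decreases the score", {
  set.seed(33)
  cfg <- search_config()
  for (k in 1:10) {
    seq_a <- paste0(random_protein(6), "K")
    seq_b <- paste0(random_protein(6), "K")
    zp <- 4L
    sp <- make_pair_spectrum(seq_a, seq_b, 2, 3, zp, emit = "b",
                             extra = runif(10, 150, 2000))
    drop <- sample(length(sp$mz), 5)
    base <- spectrum(sp$mz[-drop], pepmass = sp$pepmass, charge = zp)
    score_of <- function(s) xlpm_score(
      by_filter_match(s, seq_a, seq_b, 2, 3, peptide_mass(seq_a),
                      peptide_mass(seq_b), dss$delta, zp, cfg),
      cfg$ryb, zp)
    s0 <- score_of(base)
    lad <- fragment_ladders(seq_a, xl_site = 2,
                            xl_delta = dss$delta + peptide_mass(seq_b))
    for (i in seq_along(lad$b)) {
      plus <- spectrum(c(base$mz, (lad$b[i] + H)), pepmass = sp$pepmass,
                       charge = zp)
      expect_gte(score_of(plus), s0)
    }
  }
})

test_that("site localization recovers planted sites and flags ambiguity", {
  sda <- crosslinker("SDA")
  trypsin <- cleavage_rule("trypsin")
  f <- filter_candidates(digest(toy_proteins()[1, ], trypsin, 1), sda,
                         trypsin)
  db <- build_pair_database(f, sda)
  # FT-style fragment tolerance: at 0.5 Da, chance coincidences with other
  # ions legitimately blur adjacent-site discrimination
  cfg <- search_config(fragment_tol = 0.02)
  set.seed(34)
  clean <- sim_params(p_detect = 1, q_comp = c(`4` = 1), n_noise = 0,
                      jitter = 0)
  hits <- 0; total <- 0
  # exclude genuinely ambiguous cases: protein-start chains (the N-terminus
  # token and residue 1 carry identical fragment evidence) and self- or
  # prefix-sharing pairs (identical-sequence ions cross-match between the
  # chains, so shared positions cannot be told apart)
  internal <- which(db$start_a > 1 & db$start_b > 1 &
                      !mapply(function(a, b) startsWith(a, b) ||
                                startsWith(b, a), db$seq_a, db$seq_b))
  for (r in sample(internal, 12)) {
    pair <- db[r, , drop = FALSE]
    combos <- xlms:::.site_combos(pair)
    pick <- combos[sample(nrow(combos), 1), ]
    sim <- simulate_spectrum(pair, pick[[1]], pick[[2]], 4L, sda, clean)
    m <- localize_sites(sim$spectrum, pair, 4L, cfg, sda)
    # sites separated by >= 1 residue on a >= 2 site chain must resolve
    total <- total + 1
    if (m$site_a == pick[[1]] && m$site_b == pick[[2]] && !m$ambiguous)
      hits <- hits + 1
  }
  expect_equal(hits, total)
  # no discriminating fragments: every combination ties, ambiguity flagged
  pair <- db[1, , drop = FALSE]
  blank <- spectrum(numeric(0),
                    pepmass = neutral_mass_to_mz(pair$mass, 4), charge = 4)
  m0 <- localize_sites(blank, pair, 4L, cfg, sda)
  expect_true(m0$ambiguous)
  expect_equal(nrow(m0$co_optimal), nrow(xlms:::.site_combos(pair)))
  expect_equal(c(m0$site_a, m0$site_b),
               unname(xlms:::.site_combos(pair)[1, ]))  # lexicographic tie-break
})

test_that("single-site chains evaluate exactly one combination", {
  trypsin <- cleavage_rule("trypsin")
  f <- filter_candidates(
    digest(data.frame(id = "p", sequence = "AGLRDDKPSETLVRGGKPAATR",
                      decoy = FALSE), trypsin, 0), dss, trypsin)
  db <- build_pair_database(f, dss)
  one <- which(nchar(db$sites1_a) == 1 & nchar(db$sites1_b) == 1)[1]
  expect_false(is.na(one))
  combos <- xlms:::.site_combos(db[one, , drop = FALSE])
  expect_equal(nrow(combos), 1L)
})
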