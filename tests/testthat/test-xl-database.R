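trypsin <- cleavage_rule("trypsin")
dss <- crosslinker("DSS")
sda <- crosslinker("SDA")

prot <- function(seq, id = "p", decoy = FALSE)
  data.frame(id = id, sequence = seq, decoy = decoy, stringsAsFactors = FALSE)

test_that("tryptic digestion enumerates missed-cleavage products", {
  d <- digest(prot("MAKDDGSKR"), trypsin, max_missed = 1)
  expect_setequal(d$sequence, c("MAK", "DDGSK", "R", "MAKDDGSK", "DDGSKR"))
  expect_equal(d$missed[d$sequence == "MAKDDGSK"], 1L)
  expect_equal(d$start[d$sequence == "DDGSK"], 4L)
  expect_equal(d$end[d$sequence == "DDGSK"], 8L)
  # no cleavage residue at all: the whole chain comes back
  d2 <- digest(prot("MAGDDGS"), trypsin, max_missed = 0)
  expect_equal(d2$sequence, "MAGDDGS")
  expect_equal(d2$missed, 0L)
  # proline suppression
  d3 <- digest(prot("AKPG"), trypsin, max_missed = 0)
  expect_equal(d3$sequence, "AKPG")
  expect_error(digest(prot(""), trypsin), "empty")
})

test_that("digestion equals brute-force cleavage-point enumeration", {
  set.seed(21)
  for (k in 1:300) {
    s <- random_protein(sample(5:60, 1))
    mm <- sample(0:2, 1)
    d <- digest(prot(s), trypsin, mm)
    got <- sort(paste0(d$start, ":", d$end))
    expect_equal(got, oracle_digest(s, mm))
    expect_equal(substr(rep(s, nrow(d)), d$start, d$end), d$sequence)
  }
})

test_that("linkable sites honor residue, N-terminus and wildcard ends", {
  expect_equal(find_linkable_sites("DDGSKGTTLSLVQK", dss$end1, start = 64),
               c(5L, 14L))
  expect_equal(find_linkable_sites("MDFSK", dss$end1, start = 1), c(0L, 5L))
  expect_equal(find_linkable_sites("MDFSK", dss$end1, start = 10), 5L)
  expect_equal(find_linkable_sites("AGDE", sda$end2), 1:4)
})

test_that("candidate filters drop short, siteless and C-terminal-only peptides", {
  d <- digest(prot("MAKDDGSKR"), trypsin, max_missed = 1)
  f <- filter_candidates(d, dss, trypsin)
  expect_setequal(f$sequence, c("MAK", "MAKDDGSK", "DDGSKR"))
  # DDGSK: only site is the C-terminal cleavage Lys -> forced missed cleavage
  expect_false("DDGSK" %in% f$sequence)
  # no amine site anywhere: internal peptide without Lys (the protein
  # N-terminal fragment AK is dropped separately for being too short)
  f2 <- filter_candidates(digest(prot("AKGGADDGSETLVR"), trypsin, 0), dss,
                          trypsin)
  expect_equal(nrow(f2), 0L)
  # fully non-specific end: every length >= 3 peptide is retained
  d3 <- digest(prot("MAKDDGSKR"), trypsin, max_missed = 1)
  f3 <- filter_candidates(d3, crosslinker("any-any",
    end1 = list(any = TRUE), end2 = list(any = TRUE), delta = 10), trypsin)
  expect_setequal(f3$sequence,
                  setdiff(d3$sequence, "R"))  # only length < 3 dropped
})

test_that("candidate filtering is idempotent", {
  set.seed(22)
  for (k in 1:50) {
    d <- digest(prot(random_protein(sample(10:60, 1))), trypsin, 2)
    f1 <- filter_candidates(d, dss, trypsin)
    f2 <- filter_candidates(f1, dss, trypsin)
    expect_equal(f1, f2)
  }
})

test_that("pair database enumerates unordered pairs including self-pairs", {
  d <- digest(prot("MAKDDGSKR"), trypsin, max_missed = 1)
  f <- filter_candidates(d, dss, trypsin)   # 3 peptides
  db <- build_pair_database(f, dss)
  expect_equal(nrow(db), 3 * 4 / 2)
  expect_true(any(db$seq_a == db$seq_b))    # homodimeric self-pairs present
  # masses: chain sums plus the bridge
  i <- which(db$seq_a == "MAK" & db$seq_b == "MAK")
  expect_equal(db$mass[i], 2 * peptide_mass("MAK") + dss$delta,
               tolerance = 1e-9)
  expect_true(all(diff(db$mass) >= 0))
})

test_that("pair database is invariant under peptide list order", {
  set.seed(23)
  d <- digest(prot(random_protein(40)), trypsin, 2)
  f <- filter_candidates(d, dss, trypsin)
  if (nrow(f) >= 2) {
    db1 <- build_pair_database(f, dss)
    db2 <- build_pair_database(f[sample(nrow(f)), ], dss)
    key <- function(db) sort(paste(db$seq_a, db$mods_a, db$seq_b, db$mods_b,
                                   round(db$mass, 6)))
    expect_equal(key(db1), key(db2))
  }
  expect_warning(
    build_pair_database(filter_candidates(d[0, ], dss, trypsin), dss),
    "empty")
})

test_that("labeling mode expands each pair into chain label combinations", {
  f <- filter_candidates(digest(prot("MAKDDGSKR"), trypsin, 0), dss, trypsin)
  expect_equal(f$sequence, "MAK")
  db <- build_pair_database(f, dss, labeling = TRUE)
  # self-pair of one peptide: 14/14, 14/15, 15/15
  expect_equal(nrow(db), 3L)
  combos <- paste(db$label_a, db$label_b)
  expect_setequal(combos, c("N14 N14", "N14 N15", "N15 N15"))
  sh <- element_masses()$n15_minus_n14 * nitrogen_count("MAK")
  m14 <- db$mass[combos == "N14 N14"]
  expect_equal(db$mass[combos == "N14 N15"], m14 + sh, tolerance = 1e-9)
  expect_equal(db$mass[combos == "N15 N15"], m14 + 2 * sh, tolerance = 1e-9)
})

test_that("variable modifications expand combinatorially under the cap", {
  f <- filter_candidates(digest(prot("MAMKDDGMSKR"), trypsin, 1), dss,
                         trypsin)
  ox <- modification("oxMet", "M", 15.99491, variable = TRUE)
  pep <- f[f$sequence == "MAMKDDGMSK", , drop = FALSE]
  db1 <- build_pair_database(pep, dss, mods = list(ox), max_var_mods = 2)
  # 3 Met positions -> 1 + 3 + 3 = 7 variants; self-pairs: 7*8/2 = 28
  expect_equal(nrow(db1), 28L)
  db0 <- build_pair_database(pep, dss, mods = list(ox), max_var_mods = 0)
  expect_equal(nrow(db0), 1L)
  fx <- modification("carbamidomethyl", "C", 57.02146, variable = FALSE)
  dbf <- build_pair_database(pep, dss, mods = list(fx))
  expect_equal(nrow(dbf), 1L)  # no Cys: fixed mod changes nothing
})

test_that("decoy construction reverses sequences and is an involution", {
  p <- prot("MAKR")
  d <- build_decoy(p)
  expect_equal(d$sequence, "RKAM")
  expect_true(d$decoy)
  expect_equal(build_decoy(d)$sequence, p$sequence)
  expect_equal(build_decoy(d)$id, p$id)
  pal <- build_decoy(prot("MAKAM"))
  expect_equal(pal$sequence, "MAKAM")
  expect_true(pal$decoy)
})

test_that("decoy peptides mirror target length distribution", {
  set.seed(24)
  # avoid the terminal off-by-one: termini not cleavable, no proline
  aas <- setdiff(names(oracle_residues), "P")
  for (k in 1:20) {
    core <- random_protein(48, aas)
    p <- prot(paste0("A", core, "G"))
    dt <- digest(p, trypsin, 1)
    dd <- digest(build_decoy(p), trypsin, 1)
    # reversal shifts each cleavage boundary by one residue (cut after K/R
    # becomes cut before it), so lengths agree elementwise within 1
    expect_equal(nrow(dd), nrow(dt))
    expect_equal(sum(nchar(dd$sequence)), sum(nchar(dt$sequence)))
    expect_lte(max(abs(sort(nchar(dd$sequence)) - sort(nchar(dt$sequence)))),
               1L)
  }
})

test_that("FASTA round trip preserves identifiers and sequences", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">protA test protein", "MDFSKGALVY", "VEADAANYVFER",
               ">protB", "MSIVGR"), fa)
  ps <- read_fasta(fa)
  expect_equal(nrow(ps), 2L)
  expect_equal(ps$sequence[1], "MDFSKGALVYVEADAANYVFER")
  expect_equal(ps$id[2], "protB")
  db <- build_pair_database(
    filter_candidates(digest(ps[1, ], trypsin, 1), dss, trypsin), dss)
  tsv <- tempfile(fileext = ".tsv")
  write_pair_database(db, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(db))
  expect_equal(back$mass, db$mass, tolerance = 1e-9)
})
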