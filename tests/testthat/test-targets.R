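# Candidate enumeration, off-target search, QC, feature expansion,
# ranking and the editability sweep.

test_that("scan_targets finds exactly one planted landing-pad site", {
  set.seed(41)
  backbone <- paste(rep("A", 500), collapse = "")
  seqs <- plant(backbone, 200, "CGTACGCTGCAGGTCGACAGTGG")
  g <- lp_genome(c(chr = seqs))
  hits <- scan_targets(g, parse_motif("N{20}>NGG"))
  # the planted site itself, plus one window using the AGG inside it
  # (CGTACGCTGC-AGG): every NGG in the scan region lies in the plant
  expect_equal(nrow(hits), 2L)
  planted <- hits[hits$start == 200L, ]
  expect_equal(planted$spacer, "CGTACGCTGCAGGTCGACAG")
  expect_equal(planted$pam, "TGG")
  # an all-A region has no NGG at all
  g0 <- lp_genome(c(chr = backbone))
  expect_equal(nrow(scan_targets(g0, parse_motif("N{20}>NGG"))), 0L)
})

test_that("scan_targets region overlap is >= 1 bp of the spacer+PAM window", {
  set.seed(42)
  seqs <- plant(random_dna(400), 100, "CGTACGCTGCAGGTCGACAGTGG")
  g <- lp_genome(c(chr = seqs))
  m <- parse_motif("N{20}>NGG")
  # window [100,123); a region touching its last base must find it
  r1 <- scan_targets(g, m, list(contig = "chr", start = 122, end = 140))
  expect_true(any(r1$start == 100))
  # a region ending exactly at its start must not
  r2 <- scan_targets(g, m, list(contig = "chr", start = 90, end = 100))
  expect_false(any(r2$start == 100))
})

test_that("scan_targets equals the naive oracle on random sequence", {
  set.seed(43)
  m <- parse_motif("N{8}>NGG")
  for (rep in 1:3) {
    seqs <- random_dna(2000)
    g <- lp_genome(c(chr = seqs))
    impl <- scan_targets(g, m)
    oracle <- oracle_scan(seqs, rep("N", 8), c("N", "G", "G"))
    expect_equal(paste(impl$start, impl$end, impl$strand),
                 paste(oracle$start, oracle$end, oracle$strand))
    expect_equal(sort(impl$spacer), sort(oracle$spacer))
  }
})

test_that("find_offtargets recovers a planted near-match with its
           mismatch positions", {
  set.seed(44)
  m <- parse_motif("N{20}>NGG")
  spacer <- "CGTACGCTGCAGGTCGACAG"
  # plant the on-target and one copy with 2 known substitutions
  mutated <- spacer
  substr(mutated, 5, 5) <- "T"   # position 5 (C->T)
  substr(mutated, 12, 12) <- "A" # position 12 (G->A)
  backbone <- random_dna(3000, gc = 0)  # AT-only: no NGG noise
  seqs <- plant(plant(backbone, 500, paste0(spacer, "TGG")),
                2000, paste0(mutated, "AGG"))
  g <- lp_genome(c(chr = seqs))
  hits <- find_offtargets(g, spacer, m, max_errors = 5,
                          exclude = data.frame(contig = "chr", start = 500,
                                               strand = "+"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_mismatches, 2L)
  expect_equal(hits$mismatch_positions[[1]], c(5L, 12L))
  expect_equal(hits$per_hit_score, hsu_zhang_single(c(5, 12)))
  # with the on-target not excluded it appears as a 0-mismatch hit
  hits2 <- find_offtargets(g, spacer, m, max_errors = 5)
  expect_true(any(hits2$n_mismatches == 0))
})

test_that("find_offtargets equals exhaustive window enumeration on random
           genomes", {
  set.seed(45)
  m <- parse_motif("N{10}>NGG")
  for (rep in 1:3) {
    seqs <- random_dna(3000)
    g <- lp_genome(c(chr = seqs))
    spacer <- substr(seqs, 1001, 1010)
    impl <- find_offtargets(g, spacer, m, max_errors = 3)
    oracle <- oracle_offtargets(seqs, spacer, c("N", "G", "G"),
                                max_errors = 3)
    expect_equal(paste(impl$start, impl$strand, impl$n_mismatches),
                 paste(oracle$start, oracle$strand, oracle$n_mismatches))
  }
})

test_that("QC evaluation fails guides for the documented reasons", {
  m <- parse_motif("N{20}>NGG")
  th <- qc_thresholds()
  mk <- function(spacer) {
    data.frame(contig = "chr", start = 0L, end = 23L, strand = "+",
               spacer = spacer, pam = "TGG", cut_position = 17L,
               stringsAsFactors = FALSE)
  }
  no_hits <- find_offtargets(lp_genome(c(chr = strrep("A", 50))),
                             strrep("A", 20), m)
  t1 <- qc_evaluate(mk("GCGTTTTTTAGCATCAGCAG"), no_hits, th)
  expect_false(t1$passes_qc)
  expect_match(t1$fail_reasons, "polyT")
  t2 <- qc_evaluate(mk("GCGCGCGCGCGCGCGCGCGC"), no_hits, th)
  expect_false(t2$passes_qc)
  expect_match(t2$fail_reasons, "GC")
  t3 <- qc_evaluate(mk("GACGATCGATCGATCGATCG"), no_hits, th)
  expect_true(t3$passes_qc)
  expect_equal(t3$errors, Inf)
  expect_equal(t3$offtarget, 100)
  # a single 1-mismatch site violates the uniqueness floor
  one_close <- data.frame(contig = "chr", start = 10L, strand = "+",
                          protospacer = "x", pam = "AGG",
                          n_mismatches = 1L, stringsAsFactors = FALSE)
  one_close$mismatch_positions <- list(3L)
  one_close$per_hit_score <- hsu_zhang_single(3L)
  t4 <- qc_evaluate(mk("GACGATCGATCGATCGATCG"), one_close, th)
  expect_false(t4$passes_qc)
  expect_match(t4$fail_reasons, "uniqueness")
})

test_that("expand_feature keeps bounds when a passing target sits inside", {
  set.seed(46)
  synth <- design_fixture(seed = 146, len = 8000)
  g <- synth$genome
  m <- cas9_motif()
  # use a feature that already spans a passing target
  cands <- scan_targets(g, m, list(contig = "chr1", start = 3000,
                                   end = 5000))
  cands <- evaluate_targets(g, cands, m)
  pass <- cands[cands$passes_qc, ][1, ]
  f <- data.frame(contig = "chr1", start = pass$start - 10,
                  end = pass$end + 10, strand = "+", name = "f",
                  stringsAsFactors = FALSE)
  ex <- expand_feature(g, f, m)
  expect_equal(ex$expanded_start, f$start)
  expect_equal(ex$expanded_end, f$end)
})

test_that("expand_feature grows alternately until a passing target fits and
           errors when none exists within the cap", {
  set.seed(47)
  # AT-only genome: no NGG anywhere -> not editable
  g0 <- lp_genome(c(chr = random_dna(6000, gc = 0)))
  f0 <- data.frame(contig = "chr", start = 3000L, end = 3009L,
                   strand = "+", name = "f0", stringsAsFactors = FALSE)
  err <- tryCatch(expand_feature(g0, f0, cas9_motif()),
                  condition = function(c) c)
  expect_s3_class(err, "lp_not_editable")

  # one passing target planted 172 bp upstream of a 9 bp feature
  backbone <- random_dna(6000, gc = 0)
  site <- "CGTACGCTGCAGGTCGACAGTGG"
  fpos <- 3000L
  seqs <- plant(plant(backbone, fpos, "TTAAAGTTT"),
                fpos - 172L - nchar(site), site)
  g1 <- lp_genome(c(chr = seqs))
  f1 <- data.frame(contig = "chr", start = fpos, end = fpos + 9L,
                   strand = "+", name = "f1", stringsAsFactors = FALSE)
  ex <- expand_feature(g1, f1, cas9_motif())
  expect_lte(ex$expanded_start, fpos - 172L - nchar(site))
  expect_gte(ex$expanded_end, f1$end)
  expect_lte(ex$expanded_end - ex$expanded_start, 4096L)
  tgt <- attr(ex, "target")
  expect_true(tgt$passes_qc)
  expect_equal(tgt$spacer, "CGTACGCTGCAGGTCGACAG")
})

test_that("arm polymorphism check uses the mismatch fraction", {
  set.seed(48)
  arm <- random_dna(50)
  expect_true(check_arm_polymorphism(arm, arm))
  # 2 of 50 = 0.04 <= 0.05 -> acceptable
  arm2 <- arm
  substr(arm2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(arm, 10, 10))[1]
  substr(arm2, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                  substr(arm, 30, 30))[1]
  expect_true(check_arm_polymorphism(arm, arm2, 0.05))
  # 10% divergence fails the default
  arm10 <- arm
  for (p in seq(1, 50, by = 10)) {
    substr(arm10, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(arm, p, p))[1]
  }
  expect_false(check_arm_polymorphism(arm, arm10))
  expect_error(check_arm_polymorphism(arm, substr(arm, 1, 49)), "length")
})

test_that("rank_targets puts passing first and breaks ties
           deterministically", {
  base <- data.frame(
    contig = "chr", start = c(10L, 50L, 30L), end = c(33L, 73L, 53L),
    strand = "+", spacer = "x", pam = "TGG",
    cut_position = c(27L, 67L, 47L), polyt = c(1, 1, 1),
    gc = 50, errors = Inf, ontarget = c(90, 95, 95),
    offtarget = c(100, 100, 100), passes_qc = c(FALSE, TRUE, TRUE),
    fail_reasons = c("GC", "", ""), stringsAsFactors = FALSE)
  r <- rank_targets(base)
  expect_true(all(which(r$passes_qc) < which(!r$passes_qc)))
  # equal scores: lower start first
  expect_equal(r$start[1:2], c(30L, 50L))
  # permuted input gives identical output
  r2 <- rank_targets(base[c(3, 1, 2), ])
  expect_identical(r$start, r2$start)
})

test_that("editability sweep: indirect >= direct everywhere and direct is
           non-decreasing in feature size", {
  synth <- generate_synthetic_genome(synthetic_spec(30000, gc = 0.4,
                                                    seed = 49))
  tab <- editability_sweep(synth$genome, 40, motif = cas9_motif(),
                           seed = 50)
  expect_equal(nrow(tab), 11L)
  expect_true(all(tab$indirect_prop >= tab$direct_prop))
  expect_true(all(diff(tab$direct_prop) >= 0))
  expect_true(all(tab$direct_prop >= 0 & tab$indirect_prop <= 1))
})

test_that("editability sweep degenerate cases", {
  # motif that can never match (requires an impossible PAM run)
  g <- lp_genome(c(chr = random_dna(2000, gc = 0)))
  tab <- editability_sweep(g, 10, feature_sizes = c(1, 16, 64),
                           motif = parse_motif("N{20}>NGG"), seed = 51)
  expect_true(all(tab$direct_prop == 0))
  expect_true(all(tab$indirect_prop == 0))
  expect_error(editability_sweep(g, 1e7, motif = parse_motif("N{20}>NGG")),
               "exceeds")
})
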