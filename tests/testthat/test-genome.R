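# Genome/feature I/O and the simulated-HDR genome-state model.

test_that("FASTA round trip preserves content and uppercases sequence", {
  set.seed(21)
  seqs <- c(chrA = random_dna(60), chrB = random_dna(143),
            chrC = random_dna(35))
  g <- lp_genome(seqs)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, path)
  g2 <- read_fasta(path)
  expect_identical(g2$contigs, g$contigs)

  # lowercase input is normalized to uppercase
  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">lc", tolower(seqs[["chrA"]])), path2)
  expect_identical(read_fasta(path2)$contigs[["lc"]], seqs[["chrA"]])

  # headers truncate at first whitespace
  path3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">name description here", "ACGTACGTAC"), path3)
  expect_identical(names(read_fasta(path3)$contigs), "name")
})

test_that("FASTA reader rejects duplicate names", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("genome constructor validates names and characters", {
  expect_error(lp_genome(c("ACGT")), "named")
  expect_error(lp_genome(c(a = "ACGT", a = "GG")), "duplicate")
  expect_error(lp_genome(c(a = "ACXT")), "invalid character")
  expect_error(lp_genome(c(a = "ACGT"), ploidy_groups = list(g = "zzz")),
               "unknown contig")
})

test_that("GFF3 1-based closed coordinates convert to 0-based half-open", {
  set.seed(22)
  g <- lp_genome(c(chr1 = random_dna(500)))
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "test", "region", "11", "20", ".", "+", ".",
                     "ID=f1", sep = "\t")), path)
  feats <- read_features(path, g)
  expect_equal(feats$start, 10L)
  expect_equal(feats$end, 20L)
  expect_equal(feats$end - feats$start, 10L)
  expect_equal(feats$name, "f1")
})

test_that("coordinate literals are taken as 0-based half-open", {
  g <- lp_genome(c(chr1 = strrep("ACGT", 50)))
  f <- read_features("chr1:100-109:+", g)
  expect_equal(f$end - f$start, 9L)
  expect_equal(f$strand, "+")
  f2 <- read_features("chr1:0-10", g)
  expect_equal(f2$start, 0L)
})

test_that("features on unknown contigs or out of bounds are rejected", {
  g <- lp_genome(c(chr1 = strrep("ACGT", 25)))
  expect_error(read_features("chrX:0-10", g), "unknown contig")
  expect_error(read_features("chr1:90-200", g), "past end")
  expect_error(read_features("chr1:50-50", g), "start >= end")
})

test_that("step-1 HDR replaces the expanded feature with the insert", {
  set.seed(23)
  us_flank <- random_dna(200)
  feature <- random_dna(60)
  ds_flank <- random_dna(200)
  genome <- lp_genome(c(chr = paste0(us_flank, feature, ds_flank)))
  insert <- "CGTACGCTGCAGGTCGACAGTGG"
  us_arm <- substr(us_flank, 151, 200)
  ds_arm <- substr(ds_flank, 1, 50)
  donor <- donor_dna(us_arm, insert, ds_arm, step = "one",
                     source_coords = list(contig = "chr"))
  delta <- apply_hdr(genome_state("plus", genome), donor)
  expect_equal(delta$label, "delta")
  expect_identical(delta$genome$contigs[["chr"]],
                   paste0(us_flank, insert, ds_flank))
  # locus reads US-arm + insert + DS-arm
  expect_true(grepl(paste0(us_arm, insert, ds_arm),
                    delta$genome$contigs[["chr"]], fixed = TRUE))
})

test_that("wild-type add-back restores the + genome byte-identically", {
  set.seed(24)
  us_flank <- random_dna(300)
  feature <- random_dna(80)
  ds_flank <- random_dna(300)
  genome <- lp_genome(c(chr = paste0(us_flank, feature, ds_flank)))
  us_arm <- substr(us_flank, 251, 300)
  ds_arm <- substr(ds_flank, 1, 50)
  step1 <- donor_dna(us_arm, "CGTACGCTGCAGGTCGACAGTGG", ds_arm,
                     step = "one", source_coords = list(contig = "chr"))
  step2 <- donor_dna(us_arm, feature, ds_arm, step = "two",
                     source_coords = list(contig = "chr"),
                     payload_kind = "addback_feature")
  plus <- genome_state("plus", genome)
  delta <- apply_hdr(plus, step1)
  ab <- apply_hdr(delta, step2)
  expect_equal(ab$label, "addback")
  expect_identical(ab$genome$contigs, genome$contigs)
})

test_that("HDR errors name the offending arm", {
  set.seed(25)
  backbone <- random_dna(400)
  rep_arm <- substr(backbone, 1, 50)
  genome <- lp_genome(c(chr = paste0(backbone, rep_arm)))  # arm twice
  donor <- donor_dna(rep_arm, "TTTT", substr(backbone, 101, 150),
                     step = "one", source_coords = list(contig = "chr"))
  expect_error(apply_hdr(genome_state("plus", genome), donor),
               "upstream homology arm found 2 times")
  donor2 <- donor_dna(strrep("ACGT", 13), "TTTT",
                      substr(backbone, 101, 150), step = "one",
                      source_coords = list(contig = "chr"))
  expect_error(apply_hdr(genome_state("plus", genome), donor2,
                         max_mismatch_fraction = 0),
               "upstream homology arm not found")
  # arms out of order: US arm downstream of DS arm
  genome3 <- lp_genome(c(chr = backbone))
  donor3 <- donor_dna(substr(backbone, 201, 250), "TTTT",
                      substr(backbone, 51, 100), step = "one",
                      source_coords = list(contig = "chr"))
  expect_error(apply_hdr(genome_state("plus", genome3), donor3),
               "out of order")
})

test_that("edit-log replay reproduces the stored state sequence exactly", {
  set.seed(26)
  us_flank <- random_dna(250)
  feature <- random_dna(40)
  ds_flank <- random_dna(250)
  genome <- lp_genome(c(chr = paste0(us_flank, feature, ds_flank)))
  us_arm <- substr(us_flank, 201, 250)
  ds_arm <- substr(ds_flank, 1, 50)
  step1 <- donor_dna(us_arm, "GATTACAGATTACAGATTACATGG", ds_arm,
                     step = "one", source_coords = list(contig = "chr"))
  step2 <- donor_dna(us_arm, feature, ds_arm, step = "two",
                     source_coords = list(contig = "chr"),
                     payload_kind = "addback_feature")
  ab <- apply_hdr(apply_hdr(genome_state("plus", genome), step1), step2)
  replayed <- replay_edits(genome, ab$edit_log)
  expect_identical(replayed$contigs, ab$genome$contigs)
})

test_that("delta length accounting: removed interval out, insert in", {
  set.seed(27)
  us_flank <- random_dna(200); feature <- random_dna(77)
  ds_flank <- random_dna(200)
  genome <- lp_genome(c(chr = paste0(us_flank, feature, ds_flank)))
  insert <- "CGTACGCTGCAGGTCGACAGTGG"
  donor <- donor_dna(substr(us_flank, 151, 200), insert,
                     substr(ds_flank, 1, 50), step = "one",
                     source_coords = list(contig = "chr"))
  delta <- apply_hdr(genome_state("plus", genome), donor)
  expect_equal(nchar(delta$genome$contigs[["chr"]]),
               nchar(genome$contigs[["chr"]]) - nchar(feature) +
                 nchar(insert))
})

test_that("all haplotypes of a ploidy group are edited identically", {
  set.seed(28)
  synth <- generate_synthetic_genome(synthetic_spec(
    4000, n_haplotypes = 2, snv_rate = 0.02, seed = 91,
    planted_features = list(list(pos = 2000, seq = "TTAAAGTTT",
                                 name = "f")),
    protect_margin = 300))
  g <- synth$genome
  hapA <- g$contigs[["chr1_hapA"]]
  us_arm <- substr(hapA, 1901, 1950)
  ds_arm <- substr(hapA, 2060, 2109)
  donor <- donor_dna(us_arm, "CGTACGCTGCAGGTCGACAGTGG", ds_arm,
                     step = "one",
                     source_coords = list(contig = "chr1_hapA"))
  delta <- apply_hdr(genome_state("plus", g), donor)
  # the edited interval reads identically on both haplotypes
  edited <- lapply(c("chr1_hapA", "chr1_hapB"), function(cn) {
    s <- delta$genome$contigs[[cn]]
    regmatches(s, regexpr(paste0(us_arm, ".*?", ds_arm), s))
  })
  expect_identical(edited[[1]], edited[[2]])
  # but heterozygous sites far from the locus are untouched
  expect_false(identical(delta$genome$contigs[["chr1_hapA"]],
                         delta$genome$contigs[["chr1_hapB"]]))
})
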