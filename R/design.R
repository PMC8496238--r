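# End-to-end design pipeline: scan -> QC -> expand -> donors -> genome
# states -> primers -> cPCR prediction; plus flat key=value configuration.

#' Design configuration
#'
#' All defaults match the tool's standard settings: SpCas9 motif
#' `N{17}|N{3}>NGG`, the [qc_thresholds()] defaults, 50 nt homology arms,
#' a 4096 bp expanded-feature cap, and a 6-mismatch uniqueness floor for
#' the generated landing-pad insert.
#'
#' @param motif Motif string (default `"N{17}|N{3}>NGG"`).
#' @param thresholds A [qc_thresholds()].
#' @param arm_length Homology-arm length in nt (default 50).
#' @param max_expansion Expanded-feature cap in bp (default 4096).
#' @param expansion_step Feature expansion step in bp (default 50).
#' @param min_insert_distance Minimum Hamming distance of the generated
#'   insert's spacer to every motif-compatible genomic window (default 6).
#' @param primer_lengths Allowed primer lengths (default 18:28).
#' @param constraints A [primer_constraints()].
#' @param scan_width Width of the flanking regions scanned for sF/sR
#'   primers (default 300 bp).
#' @param amp_scan_width Width of the donor-end regions scanned for
#'   AmpF/AmpR (default 50 bp).
#' @param max_amplicon In-silico PCR product cap (default 5000).
#' @param annealing Simulated-annealing parameters, see
#'   [optimize_primer_set()].
#' @param candidates_per_role Candidate pool size per primer role
#'   (default 20).
#' @param seed Master seed; per-stage child seeds are derived with
#'   [child_seed()].
#' @param scorer On-target scorer name.
#' @return List of class `design_config`.
#' @export
design_config <- function(motif = "N{17}|N{3}>NGG",
                          thresholds = qc_thresholds(),
                          arm_length = 50L, max_expansion = 4096L,
                          expansion_step = 50L, min_insert_distance = 6L,
                          primer_lengths = 18:28,
                          constraints = primer_constraints(),
                          scan_width = 300L, amp_scan_width = 50L,
                          max_amplicon = 5000L,
                          annealing = list(t0 = 10, cooling = 0.995,
                                           iterations = 20000L),
                          candidates_per_role = 20L, seed = 1L,
                          scorer = "rule_surrogate") {
  structure(list(motif = motif, thresholds = thresholds,
                 arm_length = as.integer(arm_length),
                 max_expansion = as.integer(max_expansion),
                 expansion_step = as.integer(expansion_step),
                 min_insert_distance = as.integer(min_insert_distance),
                 primer_lengths = as.integer(primer_lengths),
                 constraints = constraints,
                 scan_width = as.integer(scan_width),
                 amp_scan_width = as.integer(amp_scan_width),
                 max_amplicon = as.integer(max_amplicon),
                 annealing = annealing,
                 candidates_per_role = as.integer(candidates_per_role),
                 seed = as.integer(seed), scorer = scorer),
            class = "design_config")
}

#' Write a design configuration as a flat key=value file
#'
#' @param config A [design_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(config, path) {
  th <- config$thresholds; pc <- config$constraints; an <- config$annealing
  kv <- c(
    motif = config$motif,
    polyt_max = th$polyt_max, gc_min = th$gc_min, gc_max = th$gc_max,
    errors_max = th$errors_max, ontarget_min = th$ontarget_min,
    offtarget_min = th$offtarget_min, min_uniqueness = th$min_uniqueness,
    arm_length = config$arm_length, max_expansion = config$max_expansion,
    expansion_step = config$expansion_step,
    min_insert_distance = config$min_insert_distance,
    primer_lengths = paste(config$primer_lengths, collapse = ","),
    primer_gc_min = pc$gc_min, primer_gc_max = pc$gc_max,
    max_homopolymer = pc$max_homopolymer,
    gc_clamp = tolower(pc$gc_clamp),
    max_tail_selfcomp = pc$max_tail_selfcomp,
    scan_width = config$scan_width,
    amp_scan_width = config$amp_scan_width,
    max_amplicon = config$max_amplicon,
    anneal_t0 = an$t0, anneal_cooling = an$cooling,
    anneal_iterations = an$iterations,
    candidates_per_role = config$candidates_per_role,
    seed = config$seed, scorer = config$scorer)
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' Read a design configuration from a flat key=value file
#'
#' Keys missing from the file keep their defaults; the round trip
#' `write(read(write(config)))` is idempotent.
#'
#' @param path Config path.
#' @return A [design_config()].
#' @export
read_design_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  g <- function(key, default, as = as.numeric) {
    if (key %in% keys) as(vals[keys == key][1]) else default
  }
  design_config(
    motif = g("motif", "N{17}|N{3}>NGG", as.character),
    thresholds = qc_thresholds(
      polyt_max = g("polyt_max", 4.5),
      gc_min = g("gc_min", 25), gc_max = g("gc_max", 75),
      errors_max = g("errors_max", 5L, as.integer),
      ontarget_min = g("ontarget_min", 45),
      offtarget_min = g("offtarget_min", 90),
      min_uniqueness = g("min_uniqueness", 1L, as.integer)),
    arm_length = g("arm_length", 50L, as.integer),
    max_expansion = g("max_expansion", 4096L, as.integer),
    expansion_step = g("expansion_step", 50L, as.integer),
    min_insert_distance = g("min_insert_distance", 6L, as.integer),
    primer_lengths = g("primer_lengths", 18:28, function(x) {
      as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
    }),
    constraints = primer_constraints(
      gc_min = g("primer_gc_min", 30), gc_max = g("primer_gc_max", 70),
      max_homopolymer = g("max_homopolymer", 4L, as.integer),
      gc_clamp = g("gc_clamp", TRUE, function(x) tolower(x) == "true"),
      max_tail_selfcomp = g("max_tail_selfcomp", 4L, as.integer)),
    scan_width = g("scan_width", 300L, as.integer),
    amp_scan_width = g("amp_scan_width", 50L, as.integer),
    max_amplicon = g("max_amplicon", 5000L, as.integer),
    annealing = list(t0 = g("anneal_t0", 10),
                     cooling = g("anneal_cooling", 0.995),
                     iterations = g("anneal_iterations", 20000L, as.integer)),
    candidates_per_role = g("candidates_per_role", 20L, as.integer),
    seed = g("seed", 1L, as.integer),
    scorer = g("scorer", "rule_surrogate", as.character))
}

#' Run the full two-step design for one feature
#'
#' Pipeline: expand the feature to a QC-passing cut target, generate (or
#' accept) the landing-pad insert, build the step-1 and step-2 donors,
#' simulate both HDR steps to obtain the delta and add-back genome
#' states, enumerate and optimize the validation primer set, and predict
#' the colony-PCR outcome for every state.
#'
#' @param genome An `lp_genome` (the + genome).
#' @param feature One-row feature data frame (see [read_features()]).
#' @param config A [design_config()].
#' @param insert Optional user-supplied insert sequence; `NULL` generates
#'   a unique landing-pad target.
#' @param replacement Optional step-2 feature replacement; `NULL` means
#'   wild-type add-back.
#' @return List of class `locus_design` with the expanded feature, ranked
#'   targets, insert (and its re-scored QC against the delta genome),
#'   donors, the three `genome_state`s, the optimized `primer_set`, the
#'   `cpcr_table`, and accumulated warnings.
#' @export
design_locus <- function(genome, feature, config = design_config(),
                         insert = NULL, replacement = NULL) {
  motif <- parse_motif(config$motif)
  notes <- character(0)
  index <- offtarget_index(genome, motif)

  expanded <- expand_feature(genome, feature, motif, config$thresholds,
                             max_expansion = config$max_expansion,
                             step = config$expansion_step,
                             arm_length = config$arm_length,
                             index = index, scorer = config$scorer)
  cut_target <- attr(expanded, "target")

  region <- list(contig = expanded$contig, start = expanded$expanded_start,
                 end = expanded$expanded_end)
  targets <- scan_targets(genome, motif, region)
  targets <- evaluate_targets(genome, targets, motif, config$thresholds,
                              index = index, scorer = config$scorer)
  targets <- rank_targets(targets, expanded)

  if (is.null(insert)) {
    insert <- generate_unique_target(
      genome, motif, config$thresholds,
      min_genome_distance = config$min_insert_distance,
      seed = child_seed(config$seed, "insert"), index = index)
    payload_kind <- "generated_target"
  } else {
    insert <- normalize_dna(as.character(insert), "insert")
    payload_kind <- "user_insert"
    if (nrow(motif_matches(motif, insert)) == 0L) {
      stop("user insert contains no match of the working motif",
           call. = FALSE)
    }
  }

  step1 <- build_step1_donor(genome, expanded, insert, config$arm_length,
                             payload_kind = payload_kind)
  step2 <- build_step2_donor(genome, expanded, replacement,
                             config$arm_length)

  plus <- genome_state("plus", genome)
  delta <- apply_hdr(plus, step1)
  addback <- apply_hdr(delta, step2)

  # Re-score the insert's own spacer against the delta genome and report
  # (without failing) when the step-2 cut target misses QC thresholds.
  insert_qc <- NULL
  ins_match <- motif_matches(motif, as.character(insert))
  if (nrow(ins_match)) {
    d_index <- offtarget_index(delta$genome, motif)
    ins_sites <- scan_targets(delta$genome, motif)
    ins_sites <- ins_sites[ins_sites$spacer == ins_match$spacer[1], ,
                           drop = FALSE]
    hits <- find_offtargets(delta$genome, ins_match$spacer[1], motif,
                            max_errors = config$thresholds$errors_max,
                            exclude = if (nrow(ins_sites)) {
                              target_protospacer_coords(ins_sites[1, ], motif)
                            } else NULL,
                            index = d_index)
    insert_qc <- qc_evaluate(ins_match[1, , drop = FALSE], hits,
                             config$thresholds, scorer = config$scorer)
    if (!insert_qc$passes_qc) {
      notes <- c(notes, paste0("landing-pad spacer misses QC against the ",
                               "delta genome: ", insert_qc$fail_reasons))
    }
  }

  pr <- design_primer_roles(genome, expanded, insert, delta, config)
  notes <- c(notes, pr$notes)
  pset <- withCallingHandlers(
    optimize_primer_set(pr$candidates, config$annealing,
                        seed = child_seed(config$seed, "primers")),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  states <- list(plus = plus, delta = delta, addback = addback)
  cpcr <- cpcr_decision_table(pset, states, config$max_amplicon)

  structure(list(feature = expanded, targets = targets,
                 cut_target = cut_target, insert = insert,
                 insert_qc = insert_qc, donors = list(step1 = step1,
                                                      step2 = step2),
                 states = states, primer_candidates = pr$candidates,
                 primer_set = pset, cpcr = cpcr, config = config,
                 notes = notes),
            class = "locus_design")
}

# Candidate primers for every cPCR role. Regions:
#   sF / sR      flanks of the replaced interval (+ genome; all states)
#   oF/oR/iF/iR_delta   inside the landing-pad insert (delta genome)
#   oF/oR/iF/iR_ab      inside the original feature (+ genome; AB state)
#   AmpF / AmpR  outer ends of the step-2 donor region (+ genome)
design_primer_roles <- function(genome, expanded, insert, delta, config) {
  seqc <- contig_seq(genome, expanded$contig)
  es <- expanded$expanded_start; ee <- expanded$expanded_end
  fs <- expanded$start; fe <- expanded$end
  arm <- config$arm_length; sw <- config$scan_width
  aw <- config$amp_scan_width
  lens <- config$primer_lengths
  cons <- config$constraints
  enum <- function(sequence, lo, hi, contig) {
    enumerate_primers(sequence, c(max(0L, lo), hi), lens, cons,
                      contig = contig)
  }
  top <- function(df, strand, n = config$candidates_per_role) {
    df <- df[df$strand == strand, , drop = FALSE]
    utils::head(df[order(-df$weight), , drop = FALSE], n)
  }
  flank_us <- enum(seqc, es - sw, es, expanded$contig)
  flank_ds <- enum(seqc, ee, ee + sw, expanded$contig)
  # The delta contig corresponding to the feature's contig: insert sits
  # where the expanded feature was, i.e. at [es, es + nchar(insert)).
  dname <- expanded$contig
  dseq <- contig_seq(delta$genome, dname)
  ins_len <- nchar(as.character(insert))
  ins_reg <- enum(dseq, es, es + ins_len, dname)
  feat_reg <- enum(seqc, fs, fe, expanded$contig)
  amp_us <- enum(seqc, es - arm, es - arm + aw, expanded$contig)
  amp_ds <- enum(seqc, ee + arm - aw, ee + arm, expanded$contig)
  cands <- list(
    sF = top(flank_us, "+"), sR = top(flank_ds, "-"),
    oF_delta = top(ins_reg, "+"), oR_delta = top(ins_reg, "-"),
    iF_delta = top(ins_reg, "+"), iR_delta = top(ins_reg, "-"),
    oF_ab = top(feat_reg, "+"), oR_ab = top(feat_reg, "-"),
    iF_ab = top(feat_reg, "+"), iR_ab = top(feat_reg, "-"),
    AmpF = top(amp_us, "+"), AmpR = top(amp_ds, "-"))
  notes <- character(0)
  short <- names(cands)[vapply(cands, nrow, integer(1)) == 0L]
  optional_short <- setdiff(short, c("sF", "sR"))
  if (length(optional_short)) {
    notes <- paste0("no usable candidates for optional primer role(s): ",
                    paste(optional_short, collapse = ", "),
                    " (region too short)")
  }
  list(candidates = cands, notes = notes)
}

#' @export
print.locus_design <- function(x, ...) {
  f <- x$feature
  cat("<locus_design> '", f$name, "' ", f$contig, ":", f$start, "-", f$end,
      "\n  expanded to ", f$expanded_start, "-", f$expanded_end, " (",
      f$expanded_end - f$expanded_start, " bp)\n", sep = "")
  cat("  cut target: ", x$cut_target$spacer, " ", x$cut_target$pam,
      " (", x$cut_target$strand, ") off-target score ",
      round(x$cut_target$offtarget, 1), "\n", sep = "")
  cat("  landing pad: ", as.character(x$insert), "\n", sep = "")
  cat("  donors: step1 ", nchar(donor_sequence(x$donors$step1)),
      " nt, step2 ", nchar(donor_sequence(x$donors$step2)), " nt\n",
      sep = "")
  cat("  primer set weight: ", signif(x$primer_set$set_weight, 4), "\n",
      sep = "")
  cat("  cPCR: sF/sR mode ", x$cpcr$verdict$sf_sr_mode, "\n", sep = "")
  for (w in x$notes) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}

#' Write the full design bundle to a directory
#'
#' Emits the four key artifacts (targets, step-1 donor, step-2 donor,
#' primers with the cPCR decision table) plus the predicted delta and
#' add-back genomes (FASTA with state suffixes), the edit log, and a
#' JSON-lines run manifest.
#'
#' @param design A `locus_design`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_design_bundle <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_targets(design$targets, p("targets.bed"), p("targets.tsv"))
  write_donors(design$donors, p("donors.fasta"), p("donors.tsv"),
               locus = design$feature$name %||% "locus")
  write_fasta(design$states$delta$genome, p("genome_delta.fasta"))
  write_fasta(design$states$addback$genome, p("genome_addback.fasta"))
  write_edit_log(design$states$addback, p("edit_log.tsv"))
  write_primer_set(design$primer_set, design$cpcr, p("primers.tsv"),
                   p("cpcr_table.tsv"))
  write_design_config(design$config, p("config.txt"))
  manifest <- c(
    paste0('{"stage":"feature","name":"', design$feature$name,
           '","expanded_start":', design$feature$expanded_start,
           ',"expanded_end":', design$feature$expanded_end, '}'),
    paste0('{"stage":"insert","sequence":"', as.character(design$insert),
           '"}'),
    paste0('{"stage":"primer_set","weight":',
           signif(design$primer_set$set_weight, 6), '}'),
    paste0('{"stage":"cpcr","sf_sr_mode":"',
           design$cpcr$verdict$sf_sr_mode, '"}'))
  writeLines(manifest, p("run_manifest.jsonl"))
  invisible(dir)
}
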