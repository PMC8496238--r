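# Validation-primer design: sliding-window candidate enumeration,
# nearest-neighbor melting temperatures, Gaussian weighting, simulated
# annealing over role assignments, and in-silico PCR genotype prediction.
#
# cPCR roles: sF/sR flank the replaced interval and anneal in all three
# genome states; oF/oR pair a flanking primer with a state-specific
# internal one; iF/iR lie wholly inside the landing-pad insert (delta) or
# the restored feature (add-back); AmpF/AmpR amplify the step-2 donor
# region from + genomic DNA.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); keys are 5'->3' top-strand dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor duplex melting temperature
#'
#' Tm of a primer/template duplex from SantaLucia (1998) unified
#' nearest-neighbor enthalpies and entropies with terminal initiation
#' terms, the 0.368 * N * ln[Na+] entropic salt correction, and a
#' symmetry correction for self-complementary sequences. Deterministic;
#' this is a duplex model, not a folding partition function.
#'
#' @param sequence Primer sequence(s), length >= 8 nt.
#' @param conditions List with `Na` (monovalent salt, molar; default 0.05)
#'   and `conc` (primer concentration, molar; default 5e-7).
#' @return Tm in degrees Celsius (numeric vector).
#' @export
melting_temperature <- function(sequence,
                                conditions = list(Na = 0.05, conc = 5e-7)) {
  Na <- conditions$Na %||% 0.05
  conc <- conditions$conc %||% 5e-7
  vapply(toupper(sequence), function(s) {
    n <- nchar(s)
    if (n < 8L) stop("sequence shorter than 8 nt", call. = FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    steps <- paste0(chars[-n], chars[-1])
    dH <- sum(NN_DH[steps])
    dS <- sum(NN_DS[steps])
    for (term in chars[c(1L, n)]) {
      if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
      else { dH <- dH + 2.3; dS <- dS + 4.1 }
    }
    selfcomp <- identical(s, revcomp(s))
    ct <- if (selfcomp) conc else conc / 4
    if (selfcomp) dS <- dS - 1.4
    dS_salt <- dS + 0.368 * (n - 1) * log(Na)
    dH * 1000 / (dS_salt + 1.9872 * log(ct)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hard constraints for primer enumeration
#'
#' @param gc_min,gc_max GC percent bounds (defaults 30, 70).
#' @param max_homopolymer Longest allowed homopolymer run (default 4).
#' @param gc_clamp Require the 3'-terminal base to be G or C (default
#'   `TRUE`).
#' @param max_tail_selfcomp Reject a primer whose 3'-terminal run of this
#'   length (default 4) can anneal elsewhere within the primer itself.
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(gc_min = 30, gc_max = 70,
                               max_homopolymer = 4L, gc_clamp = TRUE,
                               max_tail_selfcomp = 4L) {
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 gc_clamp = gc_clamp,
                 max_tail_selfcomp = as.integer(max_tail_selfcomp)),
            class = "primer_constraints")
}

primer_passes_constraints <- function(seq, constraints) {
  gc <- gc_percent(seq)
  if (gc < constraints$gc_min || gc > constraints$gc_max) return(FALSE)
  hp <- paste0("A{", constraints$max_homopolymer + 1L, ",}|",
               "C{", constraints$max_homopolymer + 1L, ",}|",
               "G{", constraints$max_homopolymer + 1L, ",}|",
               "T{", constraints$max_homopolymer + 1L, ",}")
  if (grepl(hp, seq)) return(FALSE)
  if (grepl("N", seq, fixed = TRUE)) return(FALSE)
  last <- substr(seq, nchar(seq), nchar(seq))
  if (constraints$gc_clamp && !last %in% c("G", "C")) return(FALSE)
  k <- constraints$max_tail_selfcomp
  if (k > 0L) {
    tail <- substr(seq, nchar(seq) - k + 1L, nchar(seq))
    if (grepl(revcomp(tail), seq, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

#' Gaussian primer weight
#'
#' Product of bounded penalty terms `exp(-(x - opt)^2 / (2 sigma^2))` for
#' melting temperature (optimum 60 C, sigma 2.5), GC (50 percent, sigma
#' 10) and length (20 nt, sigma 2); in `(0, 1]`, with 1 at all optima.
#'
#' @param tm,gc,length Primer properties (vectors recycled together).
#' @param optima List overriding `tm`, `gc`, `len`, `sigma_tm`,
#'   `sigma_gc`, `sigma_len`.
#' @return Numeric weight(s) in `(0, 1]`.
#' @export
primer_weight <- function(tm, gc, length,
                          optima = list(tm = 60, gc = 50, len = 20,
                                        sigma_tm = 2.5, sigma_gc = 10,
                                        sigma_len = 2)) {
  exp(-(tm - optima$tm)^2 / (2 * optima$sigma_tm^2)) *
    exp(-(gc - optima$gc)^2 / (2 * optima$sigma_gc^2)) *
    exp(-(length - optima$len)^2 / (2 * optima$sigma_len^2))
}

#' Enumerate candidate primers in a region by sliding window
#'
#' Every window of each allowed length on both strands of the region that
#' passes the hard constraints becomes a candidate, scored with
#' [primer_weight()]. Minus-strand candidates are reported as the reverse
#' complement (the primer sequence actually ordered).
#'
#' @param sequence Contig sequence (plus strand).
#' @param region `c(start, end)` 0-based half-open within the sequence;
#'   `NULL` means the whole sequence. Windows must lie wholly inside.
#' @param lengths Allowed primer lengths (default 18:28).
#' @param constraints A [primer_constraints()].
#' @param conditions Tm conditions, see [melting_temperature()].
#' @param contig Contig name recorded in the output.
#' @param optima Weight optima, see [primer_weight()].
#' @return `data.frame` with columns `sequence`, `contig`, `start`,
#'   `length`, `strand`, `tm`, `gc`, `weight`. `start` is the 0-based
#'   plus-strand coordinate of the window.
#' @export
enumerate_primers <- function(sequence, region = NULL, lengths = 18:28,
                              constraints = primer_constraints(),
                              conditions = list(Na = 0.05, conc = 5e-7),
                              contig = "contig", optima = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (is.null(region)) region <- c(0L, n)
  rs <- max(0L, as.integer(region[1])); re <- min(n, as.integer(region[2]))
  rows <- list()
  for (len in lengths) {
    if (re - rs < len) next
    starts <- rs:(re - len)
    windows <- substring(sequence, starts + 1L, starts + len)
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") windows else revcomp(windows)
      keep <- vapply(seqs, primer_passes_constraints, logical(1),
                     constraints = constraints, USE.NAMES = FALSE)
      if (!any(keep)) next
      kseqs <- seqs[keep]
      tm <- melting_temperature(kseqs, conditions)
      gc <- gc_percent(kseqs)
      w <- if (is.null(optima)) primer_weight(tm, gc, len)
           else primer_weight(tm, gc, len, optima)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = kseqs, contig = contig, start = starts[keep],
        length = len, strand = strand, tm = tm, gc = gc, weight = w,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), length = integer(0),
                      strand = character(0), tm = numeric(0),
                      gc = numeric(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start, out$length, out$strand), , drop = FALSE]
}

# TRUE when the forward primer contains a k-mer that can anneal to the
# reverse primer (cross-dimer risk).
has_cross_dimer <- function(fwd, rev, k = 8L) {
  lf <- nchar(fwd)
  if (lf < k || nchar(rev) < k) return(FALSE)
  rc_rev <- revcomp(rev)
  for (i in 1:(lf - k + 1L)) {
    if (grepl(substr(fwd, i, i + k - 1L), rc_rev, fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Primer-pair compatibility weight
#'
#' `forward.weight * reverse.weight * exp(-dTm^2 / (2 sigma^2))` (sigma
#' 2 C) times a dimer factor: 1 when the primers share no
#' cross-complementary run of at least `dimer_len` nt, else 0.1. Never
#' exceeds either primer's own weight.
#'
#' @param forward,reverse One-row data frames from [enumerate_primers()]
#'   (need `sequence`, `tm`, `weight`).
#' @param sigma_dtm Tm-difference sigma in C (default 2).
#' @param dimer_len Cross-complementary run length triggering the penalty
#'   (default 8).
#' @param dimer_factor Penalty factor (default 0.1).
#' @return Numeric scalar in `[0, 1]`.
#' @export
pair_weight <- function(forward, reverse, sigma_dtm = 2, dimer_len = 8L,
                        dimer_factor = 0.1) {
  dtm <- forward$tm - reverse$tm
  w <- forward$weight * reverse$weight * exp(-dtm^2 / (2 * sigma_dtm^2))
  if (has_cross_dimer(forward$sequence, reverse$sequence, dimer_len)) {
    w <- w * dimer_factor
  }
  w
}

# Role pairs whose amplicons are scored when both roles are present.
PRIMER_SET_PAIRS <- list(
  c("sF", "sR"),
  c("sF", "oR_delta"), c("oF_delta", "sR"),
  c("sF", "oR_ab"), c("oF_ab", "sR"),
  c("iF_delta", "iR_delta"), c("iF_ab", "iR_ab"),
  c("AmpF", "AmpR"))

# Can this forward/reverse pick form an amplicon? Requires plus-strand
# forward upstream of the minus-strand reverse site when the candidate
# rows carry coordinates; permissive when they do not.
pair_amplifiable <- function(forward, reverse) {
  need <- c("contig", "start", "strand", "length")
  if (!all(need %in% names(forward)) || !all(need %in% names(reverse))) {
    return(TRUE)
  }
  if (forward$contig != reverse$contig) return(TRUE)
  forward$strand == "+" && reverse$strand == "-" &&
    forward$start + forward$length <= reverse$start
}

#' Joint weight of a primer-role assignment
#'
#' Product of [pair_weight()] over every scored role pair whose two roles
#' are present. The weight is 0 when the same primer sequence is reused
#' in different roles, and a scored pair contributes 0 when its two
#' primers cannot form an amplicon (the forward primer must sit on the
#' plus strand upstream of the reverse primer's minus-strand site,
#' checked whenever the candidate rows carry coordinates).
#'
#' @param primers_by_role Named list of one-row primer data frames.
#' @return Numeric scalar in `[0, 1]`.
#' @export
primer_set_weight <- function(primers_by_role) {
  seqs <- vapply(primers_by_role, function(p) p$sequence, character(1))
  if (anyDuplicated(seqs)) return(0)
  w <- 1
  for (pair in PRIMER_SET_PAIRS) {
    if (all(pair %in% names(primers_by_role))) {
      f <- primers_by_role[[pair[1]]]
      r <- primers_by_role[[pair[2]]]
      if (!pair_amplifiable(f, r)) return(0)
      w <- w * pair_weight(f, r)
    }
  }
  w
}

#' Select the validation primer set by simulated annealing
#'
#' Searches over one-candidate-per-role assignments for the set with the
#' highest joint compatibility weight ([primer_set_weight()]). The
#' mandatory roles are `sF` and `sR`; optional roles with no candidates
#' are dropped with a warning. Geometric-cooling Metropolis annealing,
#' deterministic given the seed; the best assignment ever seen is
#' returned.
#'
#' @param candidates_by_role Named list of candidate data frames from
#'   [enumerate_primers()].
#' @param annealing List with `t0` (initial temperature, default 10),
#'   `cooling` (geometric rate, default 0.995) and `iterations` (default
#'   20000).
#' @param seed Integer seed.
#' @return List of class `primer_set` with elements `roles` (named list
#'   of one-row primer data frames), `set_weight`, and `dropped_roles`.
#' @export
optimize_primer_set <- function(candidates_by_role,
                                annealing = list(t0 = 10, cooling = 0.995,
                                                 iterations = 20000L),
                                seed = 1L) {
  counts <- vapply(candidates_by_role, nrow, integer(1))
  for (role in c("sF", "sR")) {
    if (!role %in% names(candidates_by_role) || counts[[role]] == 0L) {
      stop(structure(class = c("lp_missing_primer_role", "error",
                               "condition"),
                     list(message = paste0("mandatory primer role '", role,
                                           "' has no candidates"),
                          call = NULL)))
    }
  }
  dropped <- names(counts)[counts == 0L]
  if (length(dropped)) {
    warning("dropping primer role(s) with no candidates: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  cands <- candidates_by_role[counts > 0L]
  # Drop optional roles whose scored pair cannot form an amplicon for any
  # candidate combination (e.g. iF/iR inside an insert too short to hold
  # two non-overlapping primers).
  repeat {
    unusable <- character(0)
    for (pair in PRIMER_SET_PAIRS) {
      if (!all(pair %in% names(cands))) next
      a <- cands[[pair[1]]]; b <- cands[[pair[2]]]
      need <- c("contig", "start", "strand", "length")
      if (!all(need %in% names(a)) || !all(need %in% names(b))) next
      diffc <- outer(a$contig, b$contig, "!=")
      geom <- outer(a$start + a$length, b$start, "<=") &
        outer(a$strand == "+", b$strand == "-", "&")
      if (!any(diffc | geom)) {
        unusable <- c(unusable, setdiff(pair, c("sF", "sR")))
      }
    }
    unusable <- unique(unusable)
    if (!length(unusable)) break
    warning("dropping primer role(s) with no amplifiable pairing: ",
            paste(unusable, collapse = ", "), call. = FALSE)
    dropped <- c(dropped, unusable)
    cands <- cands[setdiff(names(cands), unusable)]
  }
  roles <- names(cands)
  nr <- length(roles)
  pick <- function(state) {
    out <- lapply(seq_len(nr), function(j) cands[[j]][state[j], , drop = FALSE])
    names(out) <- roles
    out
  }
  t0 <- annealing$t0 %||% 10
  cooling <- annealing$cooling %||% 0.995
  iters <- as.integer(annealing$iterations %||% 20000L)
  # Precompute pair-weight matrices for every scored role pair so the
  # annealing loop is pure table lookup; the objective is identical to
  # primer_set_weight() on the picked rows.
  scored <- Filter(function(p) all(p %in% roles), PRIMER_SET_PAIRS)
  wmats <- lapply(scored, function(pair) {
    a <- cands[[pair[1]]]; b <- cands[[pair[2]]]
    outer(seq_len(nrow(a)), seq_len(nrow(b)),
          Vectorize(function(i, j) {
            ar <- a[i, , drop = FALSE]; br <- b[j, , drop = FALSE]
            if (!pair_amplifiable(ar, br)) 0
            else pair_weight(ar, br)
          }))
  })
  seqs_by_role <- lapply(cands, function(df) df$sequence)
  objective <- function(state) {
    ss <- vapply(seq_len(nr), function(j) seqs_by_role[[j]][state[j]],
                 character(1))
    if (anyDuplicated(ss)) return(0)
    w <- 1
    for (k in seq_along(scored)) {
      i <- state[match(scored[[k]][1], roles)]
      j <- state[match(scored[[k]][2], roles)]
      w <- w * wmats[[k]][i, j]
    }
    w
  }
  result <- with_seed(seed, {
    state <- vapply(cands, function(df) sample.int(nrow(df), 1L), integer(1))
    cur_w <- objective(state)
    best <- state; best_w <- cur_w
    temp <- t0
    for (it in seq_len(iters)) {
      j <- sample.int(nr, 1L)
      prop <- state
      prop[j] <- sample.int(nrow(cands[[j]]), 1L)
      w <- objective(prop)
      if (w >= cur_w || stats::runif(1) < exp((w - cur_w) / temp)) {
        state <- prop; cur_w <- w
        if (cur_w > best_w) { best <- state; best_w <- cur_w }
      }
      temp <- temp * cooling
    }
    list(best = best, best_w = best_w)
  })
  structure(list(roles = pick(result$best), set_weight = result$best_w,
                 dropped_roles = dropped),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat("<primer_set> weight ", signif(x$set_weight, 4), "\n", sep = "")
  for (role in names(x$roles)) {
    p <- x$roles[[role]]
    cat(sprintf("  %-9s %s  Tm %.1f C  GC %.0f%%  w %.3f\n", role,
                p$sequence, p$tm, p$gc, p$weight))
  }
  if (length(x$dropped_roles)) {
    cat("  dropped roles:", paste(x$dropped_roles, collapse = ", "), "\n")
  }
  invisible(x)
}

#' In-silico PCR
#'
#' Predicts amplicons: every site where the forward primer matches the
#' plus strand exactly (full length) paired with every downstream site
#' where the reverse primer matches the minus strand, within
#' `max_amplicon`. Product length is the outer-coordinate difference, so
#' it includes both primers.
#'
#' @param x An `lp_genome`, a `genome_state`, or a named character vector
#'   of contig sequences.
#' @param forward,reverse Primer sequences (5'->3').
#' @param max_amplicon Maximum product length (default 5000).
#' @return `data.frame` with columns `contig`, `start`, `end`, `length`.
#' @export
insilico_pcr <- function(x, forward, reverse, max_amplicon = 5000L) {
  contigs <- if (inherits(x, "genome_state")) x$genome$contigs
             else if (inherits(x, "lp_genome")) x$contigs
             else x
  forward <- toupper(forward); reverse <- toupper(reverse)
  lf <- nchar(forward); lr <- nchar(reverse)
  rc_rev <- revcomp(reverse)
  rows <- list()
  for (cname in names(contigs)) {
    seqc <- contigs[[cname]]
    fm <- gregexpr(paste0("(?=", escape_regex(forward), ")"), seqc,
                   perl = TRUE)[[1]]
    rm_ <- gregexpr(paste0("(?=", escape_regex(rc_rev), ")"), seqc,
                    perl = TRUE)[[1]]
    if (fm[1] == -1L || rm_[1] == -1L) next
    fstarts <- as.integer(fm) - 1L
    rstarts <- as.integer(rm_) - 1L
    for (fs in fstarts) {
      for (rs in rstarts) {
        if (rs < fs + lf) next  # reverse site must lie downstream
        len <- rs + lr - fs
        if (len > max_amplicon) next
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cname, start = fs, end = rs + lr, length = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$length), , drop = FALSE]
}

#' Colony-PCR decision table across genome states
#'
#' Runs in-silico PCR for every scored primer pair of the set against the
#' +, delta and add-back genome states, and derives the genotyping
#' verdict: the sF/sR pair discriminates either by amplifying only the
#' delta state (replaced interval too long to amplify in + and AB) or by
#' amplifying all three states with three distinct product lengths.
#'
#' @param primer_set A `primer_set`.
#' @param states Named list of `genome_state` objects (`plus`, `delta`,
#'   `addback`).
#' @param max_amplicon Maximum product length (default 5000).
#' @return List of class `cpcr_table` with elements `table` (one row per
#'   pair and state: `pair`, `state`, `present`, `n_products`, `lengths`)
#'   and `verdict` (list with `sf_sr_mode` one of `"delta_only"`,
#'   `"three_lengths"`, `"ambiguous"`, and logical `discriminates`).
#' @export
cpcr_decision_table <- function(primer_set, states, max_amplicon = 5000L) {
  stopifnot(all(c("plus", "delta", "addback") %in% names(states)))
  roles <- primer_set$roles
  rows <- list()
  for (pair in PRIMER_SET_PAIRS) {
    if (!all(pair %in% names(roles))) next
    pair_name <- paste(pair, collapse = "/")
    for (st in c("plus", "delta", "addback")) {
      prods <- insilico_pcr(states[[st]], roles[[pair[1]]]$sequence,
                            roles[[pair[2]]]$sequence, max_amplicon)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair_name, state = st, present = nrow(prods) > 0L,
        n_products = nrow(prods),
        lengths = paste(prods$length, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sf <- tab[tab$pair == "sF/sR", , drop = FALSE]
  verdict <- list(sf_sr_mode = "ambiguous", discriminates = FALSE)
  if (nrow(sf) == 3L) {
    pres <- stats::setNames(sf$present, sf$state)
    if (pres[["delta"]] && !pres[["plus"]] && !pres[["addback"]]) {
      verdict <- list(sf_sr_mode = "delta_only", discriminates = TRUE)
    } else if (all(pres)) {
      lens <- vapply(sf$lengths, function(s) {
        strsplit(s, ",", fixed = TRUE)[[1]][1]
      }, character(1))
      if (!anyDuplicated(lens)) {
        verdict <- list(sf_sr_mode = "three_lengths", discriminates = TRUE)
      }
    }
  }
  structure(list(table = tab, verdict = verdict), class = "cpcr_table")
}

#' @export
print.cpcr_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("sF/sR mode:", x$verdict$sf_sr_mode,
      if (x$verdict$discriminates) "(discriminates the three genotypes)"
      else "(does not discriminate)", "\n")
  invisible(x)
}

#' Write a primer set and decision table as TSV
#'
#' @param primer_set A `primer_set`.
#' @param cpcr Optional `cpcr_table`.
#' @param primers_path,cpcr_path Output paths (either may be `NULL`).
#' @return Invisibly, `NULL`.
#' @export
write_primer_set <- function(primer_set, cpcr = NULL, primers_path = NULL,
                             cpcr_path = NULL) {
  if (!is.null(primers_path)) {
    df <- do.call(rbind, lapply(names(primer_set$roles), function(role) {
      p <- primer_set$roles[[role]]
      data.frame(role = role, sequence = p$sequence, contig = p$contig,
                 start = p$start, strand = p$strand, tm = round(p$tm, 2),
                 gc = round(p$gc, 1), weight = signif(p$weight, 4),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(df, primers_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(cpcr) && !is.null(cpcr_path)) {
    utils::write.table(cpcr$table, cpcr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
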