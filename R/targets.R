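# Candidate-target enumeration, genome-wide off-target search, QC
# filtering, feature expansion and ranking.

#' Scan a region for candidate RGN targets
#'
#' Enumerates all motif matches on both strands whose spacer+PAM window
#' overlaps the region by at least 1 bp, sorted by (contig, start, strand).
#'
#' @param genome An `lp_genome`.
#' @param motif A `target_motif`.
#' @param region Optional restriction: a list or one-row data frame with
#'   `contig`, `start`, `end` (0-based half-open). `NULL` scans every
#'   contig fully.
#' @return `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `spacer`, `pam`, `cut_position`.
#' @export
scan_targets <- function(genome, motif, region = NULL) {
  contigs <- names(genome$contigs)
  if (!is.null(region)) {
    if (!region$contig %in% contigs) {
      stop("region on unknown contig '", region$contig, "'", call. = FALSE)
    }
    contigs <- region$contig
  }
  out <- list()
  max_len <- sum(motif$spacer_segments$max) + sum(motif$pam_segments$max)
  for (cname in contigs) {
    seqc <- contig_seq(genome, cname)
    if (!is.null(region)) {
      # Scan a padded slice so windows merely overlapping the region by
      # 1 bp are found, then filter on true overlap.
      lo <- max(0L, as.integer(region$start) - max_len + 1L)
      hi <- min(nchar(seqc), as.integer(region$end) + max_len - 1L)
      hits <- motif_matches(motif, substr(seqc, lo + 1L, hi), cname)
      if (nrow(hits)) {
        hits$start <- hits$start + lo
        hits$end <- hits$end + lo
        hits$cut_position <- hits$cut_position + lo
        hits <- hits[hits$end > region$start & hits$start < region$end, ,
                     drop = FALSE]
      }
    } else {
      hits <- motif_matches(motif, seqc, cname)
    }
    out[[cname]] <- hits
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

#' Build a genome-wide protospacer window index
#'
#' Enumerates every PAM-compatible window on both strands of the genome
#' once (protospacer of the given length adjacent to a PAM matching the
#' motif's PAM pattern) and encodes the sense protospacers as an integer
#' matrix. The index makes repeated off-target queries against the same
#' genome fast.
#'
#' @param genome An `lp_genome`.
#' @param motif A `target_motif`.
#' @param spacer_len Protospacer length to index (defaults to the motif's
#'   minimum spacer length).
#' @return An object of class `offtarget_index`.
#' @export
offtarget_index <- function(genome, motif, spacer_len = NULL) {
  spacer_len <- as.integer(spacer_len %||% motif$spacer_len_range[1])
  pam_exps <- unique(lapply(motif_expansions(motif), `[[`, "pam"))
  rows <- list()
  for (cname in names(genome$contigs)) {
    seqc <- contig_seq(genome, cname)
    n <- nchar(seqc)
    rc <- revcomp(seqc)
    for (pam_codes in pam_exps) {
      lp <- length(pam_codes)
      pam_pat <- paste0("(?=", paste(vapply(pam_codes, iupac_regex_class,
                                            character(1)), collapse = ""), ")")
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") seqc else rc
        m <- gregexpr(pam_pat, subject, perl = TRUE)[[1]]
        if (m[1] == -1L) next
        pstart <- as.integer(m)  # 1-based PAM start on scanned strand
        # Sense protospacer sits 5' of a 3' PAM, 3' of a 5' PAM.
        if (motif$pam_side == "three_prime") {
          sp_start <- pstart - spacer_len
          keep <- sp_start >= 1L
          sp_start <- sp_start[keep]; pk <- pstart[keep]
        } else {
          sp_start <- pstart + lp
          keep <- sp_start + spacer_len - 1L <= n
          sp_start <- sp_start[keep]; pk <- pstart[keep]
        }
        if (!length(sp_start)) next
        prot <- substring(subject, sp_start, sp_start + spacer_len - 1L)
        pam <- substring(subject, pk, pk + lp - 1L)
        # Genomic 0-based start of the sense protospacer window.
        gstart <- if (strand == "+") sp_start - 1L else n - (sp_start - 1L) - spacer_len
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cname, start = gstart, strand = strand,
          protospacer = prot, pam = pam, stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig = character(0), start = integer(0),
               strand = character(0), protospacer = character(0),
               pam = character(0), stringsAsFactors = FALSE)
  }
  df <- unique(df)
  rownames(df) <- NULL
  mat <- if (nrow(df)) {
    matrix(utf8ToInt(paste(df$protospacer, collapse = "")),
           ncol = spacer_len, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = spacer_len)
  }
  structure(list(windows = df, mat = mat, spacer_len = spacer_len,
                 pam_side = motif$pam_side), class = "offtarget_index")
}

#' Find genomic off-target sites of a spacer
#'
#' Enumerates every PAM-compatible genomic window (both strands) whose
#' protospacer is within Hamming distance `max_errors` of the spacer,
#' excluding the on-target coordinates, and scores each hit with the
#' Hsu-Zhang single-hit formula. Substitution-only (Hamming) matching.
#'
#' @param genome An `lp_genome`.
#' @param spacer Spacer sequence (concrete ACGT).
#' @param motif A `target_motif` supplying the PAM pattern.
#' @param max_errors Maximum mismatches (default 5).
#' @param exclude Optional data frame of on-target sites to exclude, with
#'   columns `contig`, `start`, `strand` (protospacer window coordinates).
#' @param index Optional prebuilt [offtarget_index()].
#' @return `data.frame` with columns `contig`, `start`, `strand`,
#'   `protospacer`, `pam`, `n_mismatches`, `mismatch_positions` (list
#'   column, 1 = PAM-distal), `per_hit_score`.
#' @export
find_offtargets <- function(genome, spacer, motif, max_errors = 5L,
                            exclude = NULL, index = NULL) {
  stopifnot(max_errors >= 0)
  spacer <- normalize_dna(spacer, "spacer")
  if (is.null(index)) index <- offtarget_index(genome, motif, nchar(spacer))
  if (index$spacer_len != nchar(spacer)) {
    stop("index spacer length ", index$spacer_len,
         " does not match spacer length ", nchar(spacer), call. = FALSE)
  }
  df <- index$windows
  if (!nrow(df)) return(empty_offtargets())
  spv <- utf8ToInt(spacer)
  mm <- rowSums(index$mat != matrix(spv, nrow(index$mat),
                                    length(spv), byrow = TRUE))
  keep <- mm <= max_errors
  if (!is.null(exclude) && nrow(exclude)) {
    # The on-target site is excluded on every haplotype contig of its
    # ploidy group: sister-haplotype copies of the cut site are the same
    # locus, not off-targets (haplotypes are assumed colinear; indels in
    # the region are caught by the arm-polymorphism check instead).
    key <- paste(df$contig, df$start, df$strand)
    xkey <- unlist(lapply(seq_len(nrow(exclude)), function(k) {
      grp <- ploidy_group_of(genome, exclude$contig[k])
      paste(grp, exclude$start[k], exclude$strand[k])
    }))
    keep <- keep & !(key %in% xkey)
  }
  hits <- df[keep, , drop = FALSE]
  if (!nrow(hits)) return(empty_offtargets())
  hits$n_mismatches <- as.integer(mm[keep])
  sc <- strsplit(spacer, "", fixed = TRUE)[[1]]
  L <- length(sc)
  pos_list <- lapply(hits$protospacer, function(p) {
    idx <- which(strsplit(p, "", fixed = TRUE)[[1]] != sc)
    # Convert 5'->3' spacer index to 1 = PAM-distal.
    if (index$pam_side == "three_prime") idx else rev(L + 1L - idx)
  })
  hits$mismatch_positions <- pos_list
  hits$per_hit_score <- vapply(pos_list, hsu_zhang_single, numeric(1),
                               spacer_len = L)
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_offtargets <- function() {
  df <- data.frame(contig = character(0), start = integer(0),
                   strand = character(0), protospacer = character(0),
                   pam = character(0), n_mismatches = integer(0),
                   stringsAsFactors = FALSE)
  df$mismatch_positions <- list()
  df$per_hit_score <- numeric(0)
  df
}

#' Evaluate quality control for one candidate target
#'
#' Populates the metric columns (`polyt`, `gc`, `errors`, `ontarget`,
#' `offtarget`) and sets `passes_qc` plus a comma-separated `fail_reasons`
#' string. The `errors` metric is the minimum mismatch count over the
#' supplied off-target hits (`Inf` when there are none); a guide fails the
#' uniqueness filter if any non-identical site lies within
#' `min_uniqueness` mismatches.
#'
#' @param target One-row data frame from [scan_targets()].
#' @param hits Off-target hits for this target's spacer, from
#'   [find_offtargets()] (on-target site excluded).
#' @param thresholds A [qc_thresholds()] object.
#' @param scorer On-target scorer name (default `"rule_surrogate"`).
#' @return The target row with metric columns added.
#' @export
qc_evaluate <- function(target, hits, thresholds = qc_thresholds(),
                        scorer = "rule_surrogate") {
  stopifnot(nrow(target) == 1L)
  target$polyt <- polyt_score(target$spacer)
  target$gc <- gc_percent(target$spacer)
  target$errors <- if (nrow(hits)) min(hits$n_mismatches) else Inf
  target$ontarget <- ontarget_score(target$spacer, scorer = scorer)
  target$offtarget <- hsu_zhang_aggregate(hits)
  reasons <- character(0)
  if (target$polyt > thresholds$polyt_max) reasons <- c(reasons, "polyT")
  if (target$gc < thresholds$gc_min || target$gc > thresholds$gc_max) {
    reasons <- c(reasons, "GC")
  }
  if (target$errors <= thresholds$min_uniqueness) {
    reasons <- c(reasons, "uniqueness")
  }
  if (target$ontarget < thresholds$ontarget_min) {
    reasons <- c(reasons, "ontarget")
  }
  if (target$offtarget < thresholds$offtarget_min) {
    reasons <- c(reasons, "offtarget")
  }
  target$passes_qc <- length(reasons) == 0L
  target$fail_reasons <- paste(reasons, collapse = ",")
  target
}

# Protospacer-window coordinates of a candidate target (used to exclude the
# on-target site from its own off-target search).
target_protospacer_coords <- function(target, motif) {
  n_pm <- nchar(target$pam)
  if (motif$pam_side == "three_prime") {
    start <- if (target$strand == "+") target$start else target$start + n_pm
  } else {
    start <- if (target$strand == "+") target$start + n_pm else target$start
  }
  data.frame(contig = target$contig, start = start, strand = target$strand,
             stringsAsFactors = FALSE)
}

#' QC-evaluate a table of candidate targets
#'
#' Runs [find_offtargets()] (excluding each target's own site) and
#' [qc_evaluate()] for every row.
#'
#' @param genome An `lp_genome`.
#' @param targets Data frame from [scan_targets()].
#' @param motif A `target_motif`.
#' @param thresholds A [qc_thresholds()].
#' @param index Optional prebuilt [offtarget_index()].
#' @param scorer On-target scorer name.
#' @return The targets data frame with metric columns.
#' @export
evaluate_targets <- function(genome, targets, motif,
                             thresholds = qc_thresholds(), index = NULL,
                             scorer = "rule_surrogate") {
  if (!nrow(targets)) return(targets)
  if (is.null(index)) {
    index <- offtarget_index(genome, motif, nchar(targets$spacer[1]))
  }
  rows <- lapply(seq_len(nrow(targets)), function(k) {
    t1 <- targets[k, , drop = FALSE]
    hits <- find_offtargets(genome, t1$spacer, motif,
                            max_errors = thresholds$errors_max,
                            exclude = target_protospacer_coords(t1, motif),
                            index = index)
    qc_evaluate(t1, hits, thresholds, scorer = scorer)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare haplotype homology arms for polymorphism
#'
#' Ungapped, length-strict comparison: returns `TRUE` when the mismatch
#' fraction between equal-length arm sequences is at most
#' `max_mismatch_fraction`. A length difference (an indel in the arm
#' region) is an error and should be treated as failing.
#'
#' @param haplotype_a_arm,haplotype_b_arm Arm sequences of equal length.
#' @param max_mismatch_fraction Maximum tolerated mismatch fraction
#'   (default 0.05).
#' @return Logical scalar.
#' @export
check_arm_polymorphism <- function(haplotype_a_arm, haplotype_b_arm,
                                   max_mismatch_fraction = 0.05) {
  a <- toupper(haplotype_a_arm); b <- toupper(haplotype_b_arm)
  if (nchar(a) != nchar(b)) {
    stop("homology arms differ in length (indel in arm region)",
         call. = FALSE)
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av != bv) <= max_mismatch_fraction
}

# The alternating left/right expansion series for a feature:
# data.frame(L, R) starting at the original bounds, growing by `step` per
# move (left first), clamped to the contig and capped at `max_expansion`
# total width.
expansion_series <- function(fstart, fend, contig_len, step = 50L,
                             max_expansion = 4096L) {
  L <- fstart; R <- fend
  Ls <- L; Rs <- R
  side <- "left"
  repeat {
    width <- R - L
    if (width >= max_expansion) break
    room_left <- L
    room_right <- contig_len - R
    if (room_left == 0L && room_right == 0L) break
    take <- function(room) min(step, room, max_expansion - (R - L))
    if (side == "left" && room_left > 0L) {
      L <- L - take(room_left)
    } else if (side == "left") {
      R <- R + take(room_right)
    } else if (room_right > 0L) {
      R <- R + take(room_right)
    } else {
      L <- L - take(room_left)
    }
    side <- if (side == "left") "right" else "left"
    Ls <- c(Ls, L); Rs <- c(Rs, R)
  }
  data.frame(L = Ls, R = Rs)
}

#' Expand a feature until it contains a passing target
#'
#' Grows the feature bounds by alternating one step left, one step right
#' (step size `step`, default 50 bp) until at least one QC-passing
#' candidate target lies wholly inside the expanded bounds, never exceeding
#' `max_expansion` total width. When haplotypes are present the prospective
#' homology arms are checked for polymorphism and a candidate whose arms
#' fail is skipped.
#'
#' @param genome An `lp_genome`.
#' @param feature One-row feature data frame (see [read_features()]).
#' @param motif A `target_motif`.
#' @param thresholds A [qc_thresholds()].
#' @param max_expansion Maximum expanded width in bp (default 4096).
#' @param step Expansion step in bp (default 50).
#' @param arm_length Homology-arm length used for the polymorphism check
#'   (default 50).
#' @param max_arm_mismatch Arm polymorphism tolerance (default 0.05).
#' @param index Optional prebuilt [offtarget_index()].
#' @param scorer On-target scorer name.
#' @return The feature row with `expanded_start` / `expanded_end` columns
#'   and the chosen QC-passing target attached as attribute `"target"`.
#'   Raises a condition of class `lp_not_editable` when no passing target
#'   exists within `max_expansion`.
#' @export
expand_feature <- function(genome, feature, motif,
                           thresholds = qc_thresholds(),
                           max_expansion = 4096L, step = 50L,
                           arm_length = 50L, max_arm_mismatch = 0.05,
                           index = NULL, scorer = "rule_surrogate") {
  stopifnot(nrow(feature) == 1L)
  seqc <- contig_seq(genome, feature$contig)
  clen <- nchar(seqc)
  if (feature$start < 0 || feature$end > clen) {
    stop("feature outside contig bounds", call. = FALSE)
  }
  if (feature$end - feature$start > max_expansion) {
    stop_not_editable(feature, "feature wider than max_expansion")
  }
  series <- expansion_series(feature$start, feature$end, clen, step,
                             max_expansion)
  region <- list(contig = feature$contig,
                 start = series$L[nrow(series)],
                 end = series$R[nrow(series)])
  cands <- scan_targets(genome, motif, region)
  cands <- cands[cands$start >= region$start & cands$end <= region$end, ,
                 drop = FALSE]
  if (nrow(cands)) {
    # Smallest expansion index at which each candidate is fully contained.
    contain_at <- vapply(seq_len(nrow(cands)), function(k) {
      i <- which(series$L <= cands$start[k] & series$R >= cands$end[k])
      if (length(i)) min(i) else NA_integer_
    }, integer(1))
    ord <- order(contain_at, cands$start, cands$strand)
    if (is.null(index)) {
      index <- offtarget_index(genome, motif, nchar(cands$spacer[1]))
    }
    group <- ploidy_group_of(genome, feature$contig)
    for (k in ord) {
      if (is.na(contain_at[k])) next
      t1 <- cands[k, , drop = FALSE]
      hits <- find_offtargets(genome, t1$spacer, motif,
                              max_errors = thresholds$errors_max,
                              exclude = target_protospacer_coords(t1, motif),
                              index = index)
      t1 <- qc_evaluate(t1, hits, thresholds, scorer = scorer)
      if (!t1$passes_qc) next
      i <- contain_at[k]
      es <- series$L[i]; ee <- series$R[i]
      if (length(group) > 1L &&
          !arms_compatible(genome, group, es, ee, arm_length,
                           max_arm_mismatch)) next
      feature$expanded_start <- es
      feature$expanded_end <- ee
      attr(feature, "target") <- t1
      return(feature)
    }
  }
  stop_not_editable(feature, paste0("no QC-passing target within ",
                                    max_expansion, " bp"))
}

stop_not_editable <- function(feature, why) {
  stop(structure(class = c("lp_not_editable", "error", "condition"),
                 list(message = paste0("feature not editable: '",
                                       feature$name %||% "feature", "' (",
                                       why, ")"),
                      call = NULL)))
}

arms_compatible <- function(genome, group, es, ee, arm_length,
                            max_arm_mismatch) {
  ref <- group[1]
  refseq <- contig_seq(genome, ref)
  if (es - arm_length < 0 || ee + arm_length > nchar(refseq)) return(FALSE)
  us_ref <- substr(refseq, es - arm_length + 1L, es)
  ds_ref <- substr(refseq, ee + 1L, ee + arm_length)
  for (other in group[-1]) {
    oseq <- contig_seq(genome, other)
    if (nchar(oseq) < ee + arm_length) return(FALSE)
    us_o <- substr(oseq, es - arm_length + 1L, es)
    ds_o <- substr(oseq, ee + 1L, ee + arm_length)
    ok <- tryCatch(
      check_arm_polymorphism(us_ref, us_o, max_arm_mismatch) &&
        check_arm_polymorphism(ds_ref, ds_o, max_arm_mismatch),
      error = function(e) FALSE)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Rank QC-evaluated candidate targets
#'
#' Passing candidates first, then by descending aggregate off-target score,
#' descending on-target score, ascending polyT run, and proximity of the
#' cut position to the feature midpoint; deterministic ties broken by
#' (contig, start, strand).
#'
#' @param candidates QC-evaluated target data frame.
#' @param feature Optional one-row feature used for the midpoint-proximity
#'   key.
#' @return Reordered data frame.
#' @export
rank_targets <- function(candidates, feature = NULL) {
  if (!nrow(candidates)) return(candidates)
  mid <- if (!is.null(feature)) (feature$start + feature$end) / 2 else NA
  prox <- if (is.na(mid)) rep(0, nrow(candidates)) else {
    abs(candidates$cut_position - mid)
  }
  ord <- order(!candidates$passes_qc, -candidates$offtarget,
               -candidates$ontarget, candidates$polyt, prox,
               candidates$contig, candidates$start, candidates$strand)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Editability sweep over random loci and feature sizes
#'
#' Samples `n_loci` positions, grows a nested feature of each size around
#' every position, and reports the proportion editable Directly (at least
#' 1 bp overlap between the feature and a QC-passing target window) and
#' Indirectly (a QC-passing target and the feature jointly fit inside a
#' `max_expansion`-wide window). QC results are cached per candidate
#' target, so the sweep cost is dominated by the distinct candidates
#' actually examined.
#'
#' @param genome An `lp_genome`.
#' @param n_loci Number of random loci.
#' @param feature_sizes Feature sizes in bp (default 1 and the powers of
#'   two up to 1024, 11 sizes).
#' @param motif A `target_motif`.
#' @param thresholds A [qc_thresholds()].
#' @param seed Integer seed for locus sampling.
#' @param max_expansion Expanded-feature cap (default 4096).
#' @param scorer On-target scorer name.
#' @return `data.frame` with columns `size`, `direct_prop`,
#'   `indirect_prop`.
#' @export
editability_sweep <- function(genome, n_loci, feature_sizes = c(1, 2^(1:10)),
                              motif, thresholds = qc_thresholds(), seed = 1L,
                              max_expansion = 4096L,
                              scorer = "rule_surrogate") {
  lens <- nchar(genome$contigs)
  if (n_loci > sum(lens)) {
    stop("n_loci exceeds the number of genome positions", call. = FALSE)
  }
  feature_sizes <- sort(as.integer(feature_sizes))
  loci <- with_seed(seed, {
    cn <- sample(names(lens), n_loci, replace = TRUE,
                 prob = lens / sum(lens))
    pos <- vapply(cn, function(x) sample.int(lens[[x]], 1L) - 1L, integer(1))
    data.frame(contig = cn, pos = pos, stringsAsFactors = FALSE)
  })
  all_cands <- scan_targets(genome, motif)
  index <- offtarget_index(genome, motif)
  qc_cache <- rep(NA, nrow(all_cands))  # logical; NA = not yet evaluated
  passes <- function(k) {
    if (is.na(qc_cache[k])) {
      t1 <- all_cands[k, , drop = FALSE]
      hits <- find_offtargets(genome, t1$spacer, motif,
                              max_errors = thresholds$errors_max,
                              exclude = target_protospacer_coords(t1, motif),
                              index = index)
      t1 <- qc_evaluate(t1, hits, thresholds, scorer = scorer)
      qc_cache[k] <<- t1$passes_qc
    }
    qc_cache[k]
  }
  direct <- matrix(FALSE, n_loci, length(feature_sizes))
  indirect <- matrix(FALSE, n_loci, length(feature_sizes))
  for (li in seq_len(n_loci)) {
    cname <- loci$contig[li]; cpos <- loci$pos[li]
    clen <- lens[[cname]]
    on_contig <- which(all_cands$contig == cname)
    for (si in seq_along(feature_sizes)) {
      s <- feature_sizes[si]
      if (s > clen) next
      fs <- max(0L, min(cpos - s %/% 2L, clen - s))
      fe <- fs + s
      if (si > 1L && direct[li, si - 1L]) {
        direct[li, si] <- TRUE  # nested features: containment
      } else {
        ov <- on_contig[all_cands$end[on_contig] > fs &
                          all_cands$start[on_contig] < fe]
        for (k in ov) if (passes(k)) { direct[li, si] <- TRUE; break }
      }
      if (direct[li, si]) { indirect[li, si] <- TRUE; next }
      near <- on_contig[
        pmax(all_cands$end[on_contig], fe) -
          pmin(all_cands$start[on_contig], fs) <= max_expansion]
      for (k in near) if (passes(k)) { indirect[li, si] <- TRUE; break }
    }
  }
  data.frame(size = feature_sizes,
             direct_prop = colMeans(direct),
             indirect_prop = colMeans(indirect))
}

#' Write candidate targets as BED and TSV
#'
#' @param targets QC-evaluated target data frame.
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, `NULL`.
#' @export
write_targets <- function(targets, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(targets$contig, targets$start, targets$end,
                      paste0(targets$spacer, "|", targets$pam),
                      round(targets$offtarget %||% 0),
                      targets$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(targets, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
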