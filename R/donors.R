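# Landing-pad insert generation and step-1 / step-2 donor DNA assembly.

#' Construct a donor DNA object
#'
#' A donor is an upstream homology arm, a payload, and a downstream
#' homology arm. Step-1 donors carry the engineered landing-pad target (or
#' a user insert) as payload; step-2 donors carry the restored (possibly
#' edited) feature region.
#'
#' @param us_arm,payload,ds_arm Nucleotide text; arms must be nonempty.
#' @param step `"one"` or `"two"`.
#' @param source_coords List with `contig`, `us_interval`, `ds_interval`
#'   (0-based half-open genomic intervals of the arms).
#' @param payload_kind One of `"generated_target"`, `"user_insert"`,
#'   `"addback_feature"`.
#' @return An object of class `donor_dna`.
#' @export
donor_dna <- function(us_arm, payload, ds_arm, step = c("one", "two"),
                      source_coords = NULL,
                      payload_kind = c("generated_target", "user_insert",
                                       "addback_feature")) {
  step <- match.arg(step)
  payload_kind <- match.arg(payload_kind)
  if (!nzchar(us_arm) || !nzchar(ds_arm)) {
    stop("homology arms must be nonempty", call. = FALSE)
  }
  structure(list(us_arm = normalize_dna(us_arm, "upstream arm"),
                 payload = normalize_dna(payload, "payload",
                                         allow_iupac = TRUE),
                 ds_arm = normalize_dna(ds_arm, "downstream arm"),
                 step = step, source_coords = source_coords,
                 payload_kind = payload_kind),
            class = "donor_dna")
}

#' Full donor sequence (arm + payload + arm)
#'
#' @param donor A `donor_dna`.
#' @return Character scalar.
#' @export
donor_sequence <- function(donor) {
  paste0(donor$us_arm, donor$payload, donor$ds_arm)
}

#' @export
print.donor_dna <- function(x, ...) {
  cat("<donor_dna> step ", x$step, " (", x$payload_kind, "): ",
      nchar(x$us_arm), " nt US arm + ", nchar(x$payload), " nt payload + ",
      nchar(x$ds_arm), " nt DS arm\n", sep = "")
  invisible(x)
}

#' Generate a genome-unique landing-pad target
#'
#' Samples a spacer+PAM sequence from the motif (uniform base choice per
#' ambiguous position), keeps it only if it passes the polyT and GC
#' filters and its spacer has at least `min_genome_distance` mismatches to
#' every motif-compatible window of the genome on both strands, and
#' returns the first acceptable sample. Deterministic given the seed.
#'
#' @param genome An `lp_genome` (the + genome).
#' @param motif A `target_motif`.
#' @param thresholds A [qc_thresholds()] (polyT/GC bounds are applied).
#' @param min_genome_distance Minimum Hamming distance to every
#'   motif-compatible genomic window (default 6).
#' @param seed Integer seed.
#' @param max_attempts Bounded retry count (default 100).
#' @param index Optional prebuilt [offtarget_index()].
#' @return Spacer+PAM text with attributes `spacer` and `pam`.
#' @export
generate_unique_target <- function(genome, motif,
                                   thresholds = qc_thresholds(),
                                   min_genome_distance = 6L, seed = 1L,
                                   max_attempts = 100L, index = NULL) {
  stopifnot(min_genome_distance >= 1L)
  exp <- motif_expansions(motif)[[1]]
  if (is.null(index)) {
    index <- offtarget_index(genome, motif, length(exp$spacer))
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      spacer <- paste(vapply(exp$spacer, function(code) {
        set <- IUPAC_SETS[[code]]
        set[sample.int(length(set), 1L)]
      }, character(1)), collapse = "")
      pam <- paste(vapply(exp$pam, function(code) {
        set <- IUPAC_SETS[[code]]
        set[sample.int(length(set), 1L)]
      }, character(1)), collapse = "")
      if (polyt_score(spacer) > thresholds$polyt_max) next
      gc <- gc_percent(spacer)
      if (gc < thresholds$gc_min || gc > thresholds$gc_max) next
      if (nrow(index$windows)) {
        spv <- utf8ToInt(spacer)
        mm <- rowSums(index$mat != matrix(spv, nrow(index$mat),
                                          length(spv), byrow = TRUE))
        if (min(mm) < min_genome_distance) next
      }
      seq <- if (motif$pam_side == "three_prime") paste0(spacer, pam)
             else paste0(pam, spacer)
      attr(seq, "spacer") <- spacer
      attr(seq, "pam") <- pam
      return(seq)
    }
    stop(structure(class = c("lp_no_unique_insert", "error", "condition"),
                   list(message = paste0("no unique insert found after ",
                                         max_attempts, " attempts"),
                        call = NULL)))
  })
}

# Check that an arm occurs exactly once in its source contig and at most
# once in every other contig of the same ploidy group.
check_arm_unique <- function(genome, contig, arm, which_arm) {
  group <- ploidy_group_of(genome, contig)
  for (cname in names(genome$contigs)) {
    n <- count_occurrences(contig_seq(genome, cname), arm)
    expected_max <- if (cname %in% group) 1L else 0L
    if (cname == contig && n != 1L) {
      stop(which_arm, " arm occurs ", n, " times in contig '", cname, "'",
           call. = FALSE)
    }
    if (n > expected_max) {
      stop(which_arm, " arm is non-unique: ", n, " occurrence(s) in ",
           "contig '", cname, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build the step-1 (knock-out) donor
#'
#' Homology arms of `arm_length` nt are taken immediately outside the
#' expanded feature bounds; the payload is the landing-pad insert.
#' Integrating this donor replaces the expanded feature with the insert.
#'
#' @param genome An `lp_genome` (the + genome).
#' @param expanded_feature Feature row with `expanded_start` /
#'   `expanded_end` (see [expand_feature()]).
#' @param insert Landing-pad sequence (spacer+PAM) or any user insert.
#' @param arm_length Homology-arm length (default 50, hard floor 20).
#' @param payload_kind `"generated_target"` (default) or `"user_insert"`.
#' @return A `donor_dna` of step `"one"`.
#' @export
build_step1_donor <- function(genome, expanded_feature, insert,
                              arm_length = 50L,
                              payload_kind = "generated_target") {
  arm_length <- as.integer(arm_length)
  if (arm_length < 20L) {
    stop("arm_length must be at least 20 nt", call. = FALSE)
  }
  es <- expanded_feature$expanded_start
  ee <- expanded_feature$expanded_end
  seqc <- contig_seq(genome, expanded_feature$contig)
  if (es - arm_length < 0L || ee + arm_length > nchar(seqc)) {
    stop("homology arm extends past the contig end", call. = FALSE)
  }
  us <- substr(seqc, es - arm_length + 1L, es)
  ds <- substr(seqc, ee + 1L, ee + arm_length)
  check_arm_unique(genome, expanded_feature$contig, us, "upstream")
  check_arm_unique(genome, expanded_feature$contig, ds, "downstream")
  donor_dna(us, as.character(insert), ds, step = "one",
            source_coords = list(contig = expanded_feature$contig,
                                 us_interval = c(es - arm_length, es),
                                 ds_interval = c(ee, ee + arm_length)),
            payload_kind = payload_kind)
}

#' Build the step-2 (add-back) donor
#'
#' The payload restores the expanded region: upstream intervening sequence,
#' then the feature (wild type, or `replacement` when given), then the
#' downstream intervening sequence. With a wild-type add-back the donor's
#' full sequence is a substring of the + genome and can be amplified from
#' +gDNA.
#'
#' @param genome An `lp_genome` (the + genome).
#' @param expanded_feature Feature row with original `start` / `end` and
#'   `expanded_start` / `expanded_end`.
#' @param replacement Optional replacement for the original feature
#'   interval (IUPAC letters); `NULL` means wild-type add-back.
#' @param arm_length Homology-arm length (default 50).
#' @return A `donor_dna` of step `"two"`.
#' @export
build_step2_donor <- function(genome, expanded_feature, replacement = NULL,
                              arm_length = 50L) {
  arm_length <- as.integer(arm_length)
  if (arm_length < 20L) {
    stop("arm_length must be at least 20 nt", call. = FALSE)
  }
  es <- expanded_feature$expanded_start
  ee <- expanded_feature$expanded_end
  fs <- expanded_feature$start
  fe <- expanded_feature$end
  seqc <- contig_seq(genome, expanded_feature$contig)
  if (es - arm_length < 0L || ee + arm_length > nchar(seqc)) {
    stop("homology arm extends past the contig end", call. = FALSE)
  }
  us <- substr(seqc, es - arm_length + 1L, es)
  ds <- substr(seqc, ee + 1L, ee + arm_length)
  check_arm_unique(genome, expanded_feature$contig, us, "upstream")
  check_arm_unique(genome, expanded_feature$contig, ds, "downstream")
  mid <- if (is.null(replacement)) {
    substr(seqc, fs + 1L, fe)
  } else {
    normalize_dna(replacement, "replacement", allow_iupac = TRUE)
  }
  payload <- paste0(substr(seqc, es + 1L, fs), mid,
                    substr(seqc, fe + 1L, ee))
  donor_dna(us, payload, ds, step = "two",
            source_coords = list(contig = expanded_feature$contig,
                                 us_interval = c(es - arm_length, es),
                                 ds_interval = c(ee, ee + arm_length)),
            payload_kind = "addback_feature")
}

#' Combinatorial add-back donors over multiple sites
#'
#' One step-2 donor per subset of the site edits (2^k donors), labeled by
#' bitmask (site 1 is the leftmost bit); intervening sequence is untouched.
#'
#' @param genome An `lp_genome`.
#' @param expanded_feature Feature row with expanded bounds.
#' @param site_edits List of `list(interval = c(start, end), replacement =
#'   "...")` with disjoint intervals inside the expanded feature.
#' @param arm_length Homology-arm length (default 50).
#' @return Named list of `donor_dna` objects, names are bitmasks such as
#'   `"00"`, `"01"`, `"10"`, `"11"`.
#' @export
combinatorial_donors <- function(genome, expanded_feature, site_edits,
                                 arm_length = 50L) {
  k <- length(site_edits)
  es <- expanded_feature$expanded_start
  ee <- expanded_feature$expanded_end
  ivs <- do.call(rbind, lapply(site_edits, function(e) e$interval))
  if (k) {
    if (any(ivs[, 1] < es | ivs[, 2] > ee)) {
      stop("site edit outside expanded feature", call. = FALSE)
    }
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    site_edits <- site_edits[ord]
    if (k > 1L && any(ivs[-1, 1] < ivs[-k, 2])) {
      stop("site edit intervals overlap", call. = FALSE)
    }
  }
  seqc <- contig_seq(genome, expanded_feature$contig)
  base_wt <- build_step2_donor(genome, expanded_feature, NULL, arm_length)
  out <- list()
  for (mask in 0:(2^k - 1)) {
    bits <- if (k) as.integer(intToBits(mask))[k:1] else integer(0)
    payload <- substr(seqc, es + 1L, ee)
    # Apply selected edits right-to-left so coordinates stay valid even
    # when replacements change length.
    for (j in rev(seq_len(k))) {
      if (bits[j] == 1L) {
        s_rel <- ivs[j, 1] - es; e_rel <- ivs[j, 2] - es
        payload <- paste0(substr(payload, 1L, s_rel),
                          site_edits[[j]]$replacement,
                          substr(payload, e_rel + 1L, nchar(payload)))
      }
    }
    label <- if (k) paste(bits, collapse = "") else "0"
    d <- donor_dna(base_wt$us_arm, payload, base_wt$ds_arm, step = "two",
                   source_coords = base_wt$source_coords,
                   payload_kind = "addback_feature")
    attr(d, "bitmask") <- label
    out[[label]] <- d
  }
  out
}

#' Write donors to FASTA with a TSV manifest
#'
#' FASTA headers carry the step, locus, optional bitmask and arm lengths.
#'
#' @param donors Named list of `donor_dna` objects.
#' @param fasta_path,tsv_path Output paths (either may be `NULL`).
#' @param locus Locus label used in headers.
#' @return Invisibly, `NULL`.
#' @export
write_donors <- function(donors, fasta_path = NULL, tsv_path = NULL,
                         locus = "locus") {
  nms <- names(donors) %||% paste0("donor", seq_along(donors))
  headers <- vapply(seq_along(donors), function(i) {
    d <- donors[[i]]
    paste0(locus, "_step", d$step, "_", nms[i],
           " arms=", nchar(d$us_arm), ",", nchar(d$ds_arm),
           " payload=", nchar(d$payload), " kind=", d$payload_kind)
  }, character(1))
  if (!is.null(fasta_path)) {
    seqs <- vapply(donors, donor_sequence, character(1))
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- headers
    Biostrings::writeXStringSet(set, fasta_path)
  }
  if (!is.null(tsv_path)) {
    df <- do.call(rbind, lapply(seq_along(donors), function(i) {
      d <- donors[[i]]
      data.frame(name = nms[i], step = d$step, kind = d$payload_kind,
                 us_arm = nchar(d$us_arm), payload = nchar(d$payload),
                 ds_arm = nchar(d$ds_arm), total = nchar(donor_sequence(d)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
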