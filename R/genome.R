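# Genome and feature I/O, coordinate bookkeeping, and simulated
# homology-directed repair across the +, deletion and add-back states.
#
# All internal coordinates are 0-based half-open; GFF3's 1-based closed
# convention is converted at the boundary.

#' Construct a genome object
#'
#' @param contigs Named character vector of contig sequences (ACGTN;
#'   normalized to uppercase).
#' @param ploidy_groups Optional named list grouping haplotype contig names
#'   that represent the same locus, e.g.
#'   `list(chr1 = c("chr1_hapA", "chr1_hapB"))`.
#' @return An object of class `lp_genome`.
#' @export
lp_genome <- function(contigs, ploidy_groups = NULL) {
  if (is.null(names(contigs)) || anyNA(names(contigs)) ||
      any(!nzchar(names(contigs)))) {
    stop("all contigs must be named", call. = FALSE)
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig names: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(contigs))) stop("empty contig sequence", call. = FALSE)
  contigs <- vapply(contigs, normalize_dna, character(1), what = "contig")
  if (!is.null(ploidy_groups)) {
    unknown <- setdiff(unlist(ploidy_groups), names(contigs))
    if (length(unknown)) {
      stop("ploidy group names unknown contig(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(contigs = contigs, ploidy_groups = ploidy_groups),
            class = "lp_genome")
}

#' @export
print.lp_genome <- function(x, ...) {
  cat("<lp_genome> ", length(x$contigs), " contig(s), ",
      sum(nchar(x$contigs)), " bp total\n", sep = "")
  for (nm in names(x$contigs)) {
    cat("  ", nm, ": ", nchar(x$contigs[[nm]]), " bp\n", sep = "")
  }
  invisible(x)
}

contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome$contigs)) {
    stop("unknown contig '", contig, "'", call. = FALSE)
  }
  unname(genome$contigs[[contig]])
}

# Names of contigs in the same ploidy group as `contig` (including itself).
ploidy_group_of <- function(genome, contig) {
  if (!is.null(genome$ploidy_groups)) {
    for (grp in genome$ploidy_groups) {
      if (contig %in% grp) return(grp)
    }
  }
  contig
}

#' Read a genome from FASTA
#'
#' Headers are truncated at the first whitespace; sequence case is
#' normalized to uppercase.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param ploidy_groups Optional ploidy grouping, see [lp_genome()].
#' @return An `lp_genome`.
#' @export
read_fasta <- function(path, ploidy_groups = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(set))
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty FASTA record in ", path, call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA record names in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nms
  lp_genome(seqs, ploidy_groups = ploidy_groups)
}

#' Write a genome to FASTA
#'
#' @param genome An `lp_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read features from GFF3 or coordinate literals
#'
#' GFF3 coordinates (1-based closed) are converted to 0-based half-open.
#' Literals of the form `"contig:start-end"` or `"contig:start-end:strand"`
#' are taken as already 0-based half-open.
#'
#' @param x Path to a GFF3 file, or a character vector of literals.
#' @param genome Optional `lp_genome` used to validate contig names and
#'   bounds.
#' @return `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `name`.
#' @export
read_features <- function(x, genome = NULL) {
  if (length(x) == 1L && file.exists(x) &&
      grepl("\\.gff3?$", x, ignore.case = TRUE)) {
    gr <- rtracklayer::import(x)
    df <- as.data.frame(gr)
    nm <- if (!is.null(df$ID)) as.character(df$ID)
          else if (!is.null(df$Name)) as.character(df$Name)
          else as.character(df$type)
    feats <- data.frame(
      contig = as.character(df$seqnames),
      start = as.integer(df$start) - 1L,
      end = as.integer(df$end),
      strand = ifelse(as.character(df$strand) == "-", "-", "+"),
      name = nm, stringsAsFactors = FALSE)
  } else {
    m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)(?::([+-]))?$", x))
    bad <- vapply(m, length, integer(1)) == 0L
    if (any(bad)) {
      stop("cannot parse feature literal '", x[bad][1], "'", call. = FALSE)
    }
    feats <- data.frame(
      contig = vapply(m, `[`, character(1), 2L),
      start = as.integer(vapply(m, `[`, character(1), 3L)),
      end = as.integer(vapply(m, `[`, character(1), 4L)),
      strand = ifelse(vapply(m, `[`, character(1), 5L) == "-", "-", "+"),
      name = paste0("feature", seq_along(x)), stringsAsFactors = FALSE)
  }
  if (any(feats$start >= feats$end)) {
    stop("feature with start >= end", call. = FALSE)
  }
  if (!is.null(genome)) {
    for (k in seq_len(nrow(feats))) {
      if (!feats$contig[k] %in% names(genome$contigs)) {
        stop("feature '", feats$name[k], "' on unknown contig '",
             feats$contig[k], "'", call. = FALSE)
      }
      if (feats$end[k] > nchar(contig_seq(genome, feats$contig[k]))) {
        stop("feature '", feats$name[k], "' extends past end of contig '",
             feats$contig[k], "'", call. = FALSE)
      }
    }
  }
  feats
}

#' Construct a genome-state object
#'
#' A genome state is one of the three sequence states of the edited locus:
#' wild-type (`"plus"`), intermediate knock-out (`"delta"`), or add-back
#' (`"addback"`), together with the edit log that produced it from the +
#' genome.
#'
#' @param label One of `"plus"`, `"delta"`, `"addback"`.
#' @param genome An `lp_genome`.
#' @param edit_log List of edits, each
#'   `list(contig, removed_start, removed_end, inserted)`.
#' @return An object of class `genome_state`.
#' @export
genome_state <- function(label = c("plus", "delta", "addback"), genome,
                         edit_log = list()) {
  label <- match.arg(label)
  structure(list(label = label, genome = genome, edit_log = edit_log),
            class = "genome_state")
}

#' @export
print.genome_state <- function(x, ...) {
  cat("<genome_state> '", x$label, "', ", length(x$edit_log),
      " edit(s) recorded\n", sep = "")
  invisible(x)
}

# Locate a homology arm in a contig. Exact search first; if absent and
# `max_mismatch_fraction` > 0, a Hamming-tolerant scan models annealing of a
# donor arm to a mildly polymorphic haplotype. Exactly one site is required.
locate_arm <- function(sequence, arm, which_arm,
                       max_mismatch_fraction = 0.05) {
  n <- nchar(sequence); la <- nchar(arm)
  exact <- gregexpr(paste0("(?=", escape_regex(arm), ")"), sequence,
                    perl = TRUE)[[1]]
  starts <- if (exact[1] == -1L) integer(0) else as.integer(exact) - 1L
  if (length(starts) == 0L && max_mismatch_fraction > 0) {
    max_mm <- floor(max_mismatch_fraction * la)
    if (max_mm > 0L) {
      cand <- 0:(n - la)
      mm <- integer(length(cand))
      arm_chars <- strsplit(arm, "", fixed = TRUE)[[1]]
      for (k in seq_len(la)) {
        mm <- mm + (substring(sequence, cand + k, cand + k) != arm_chars[k])
      }
      starts <- cand[mm <= max_mm]
    }
  }
  if (length(starts) == 0L) {
    stop("integration error: ", which_arm, " homology arm not found",
         call. = FALSE)
  }
  if (length(starts) > 1L) {
    stop("integration error: ", which_arm, " homology arm found ",
         length(starts), " times", call. = FALSE)
  }
  starts
}

#' Apply homology-directed repair with a donor DNA
#'
#' Models HDR as exact, seamless arm-anchored replacement: the interval
#' between the donor's upstream-arm end and downstream-arm start is replaced
#' by the donor payload. All haplotype contigs in the same ploidy group are
#' edited (homozygous-edit model), so heterozygosity inside the replaced
#' interval is lost.
#'
#' @param state A `genome_state`.
#' @param donor A `donor_dna` (see [build_step1_donor()]).
#' @param label Label for the resulting state; defaults to the natural
#'   progression plus -> delta -> addback.
#' @param max_mismatch_fraction Arm-annealing mismatch tolerance used when
#'   an arm has no exact match in a polymorphic haplotype (default 0.05).
#' @return A new `genome_state` with an appended edit log.
#' @export
apply_hdr <- function(state, donor, label = NULL,
                      max_mismatch_fraction = 0.05) {
  stopifnot(inherits(state, "genome_state"), inherits(donor, "donor_dna"))
  genome <- state$genome
  contig <- donor$source_coords$contig
  group <- ploidy_group_of(genome, contig)
  edits <- state$edit_log
  contigs <- genome$contigs
  for (cname in group) {
    seqc <- contigs[[cname]]
    us_start <- locate_arm(seqc, donor$us_arm, "upstream",
                           max_mismatch_fraction)
    ds_start <- locate_arm(seqc, donor$ds_arm, "downstream",
                           max_mismatch_fraction)
    us_end <- us_start + nchar(donor$us_arm)
    if (us_end > ds_start) {
      stop("integration error: homology arms out of order (upstream arm ",
           "ends at ", us_end, ", downstream arm starts at ", ds_start, ")",
           call. = FALSE)
    }
    new_seq <- paste0(substr(seqc, 1L, us_end), donor$payload,
                      substr(seqc, ds_start + 1L, nchar(seqc)))
    contigs[[cname]] <- new_seq
    edits[[length(edits) + 1L]] <- list(
      contig = cname, removed_start = us_end, removed_end = ds_start,
      inserted = donor$payload)
  }
  if (is.null(label)) {
    label <- switch(state$label, plus = "delta", delta = "addback", "addback")
  }
  genome$contigs <- contigs
  genome_state(label, genome, edits)
}

#' Replay an edit log on a genome
#'
#' Re-applies the coordinate edits recorded in a `genome_state`'s edit log
#' to the original + genome; used to verify that a state's stored sequence
#' is exactly reproduced by its log.
#'
#' @param genome The + `lp_genome`.
#' @param edit_log Edit log from a `genome_state`.
#' @return An `lp_genome`.
#' @export
replay_edits <- function(genome, edit_log) {
  contigs <- genome$contigs
  # Edits are recorded in application order with coordinates valid at the
  # time of application, so sequential replay is exact.
  for (e in edit_log) {
    seqc <- contigs[[e$contig]]
    contigs[[e$contig]] <- paste0(substr(seqc, 1L, e$removed_start),
                                  e$inserted,
                                  substr(seqc, e$removed_end + 1L,
                                         nchar(seqc)))
  }
  genome$contigs <- contigs
  genome
}

#' Write an edit log as TSV
#'
#' @param state A `genome_state`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edit_log <- function(state, path) {
  df <- do.call(rbind, lapply(state$edit_log, function(e) {
    data.frame(contig = e$contig, removed_start = e$removed_start,
               removed_end = e$removed_end,
               inserted_length = nchar(e$inserted),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(contig = character(0), removed_start = integer(0),
                     removed_end = integer(0), inserted_length = integer(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
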