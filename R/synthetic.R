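# Seeded synthetic-genome generator: random background at a requested GC,
# planted features, planted decoy off-target sites, and optional diploid
# haplotypes with heterozygous SNVs. Every test input in the package is
# built with this module; it emulates a compact fungal-genome locus, not
# any real assembly.

#' Specify a synthetic genome
#'
#' @param length Genome length in bp.
#' @param gc Background GC fraction (default 0.5).
#' @param n_haplotypes 1 (haploid) or 2 (diploid) haplotype contigs per
#'   locus.
#' @param snv_rate Per-base heterozygous SNV rate applied to haplotype B
#'   outside protected intervals (default 0).
#' @param planted_features List of `list(pos, seq, name)`: sequences
#'   inserted verbatim (overwriting the background) at 0-based positions.
#' @param planted_offtargets List of `list(pos, spacer, n_mismatches,
#'   pam)`: the spacer is mutated at `n_mismatches` random positions and
#'   planted together with its PAM, giving a decoy off-target site.
#' @param protect_margin SNV-free margin around every planted element in
#'   bp (default 0); keeps designed homology arms and payloads clear of
#'   haplotype differences when desired.
#' @param seed Integer seed.
#' @param contig_name Base contig name (default `"chr1"`).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(length, gc = 0.5, n_haplotypes = 1L,
                           snv_rate = 0, planted_features = list(),
                           planted_offtargets = list(), protect_margin = 0L,
                           seed = 1L, contig_name = "chr1") {
  stopifnot(length > 0, gc >= 0, gc <= 1, n_haplotypes %in% c(1L, 2L),
            snv_rate >= 0, snv_rate < 1)
  structure(list(length = as.integer(length), gc = gc,
                 n_haplotypes = as.integer(n_haplotypes),
                 snv_rate = snv_rate, planted_features = planted_features,
                 planted_offtargets = planted_offtargets,
                 protect_margin = as.integer(protect_margin),
                 seed = as.integer(seed), contig_name = contig_name),
            class = "synthetic_spec")
}

#' Generate a synthetic genome from a specification
#'
#' Deterministic given the spec's seed: the same spec yields a
#' byte-identical genome. Planted elements must be non-overlapping and
#' inside the genome.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_genome` with elements `genome` (an
#'   `lp_genome`; diploid specs produce `<contig>_hapA` / `<contig>_hapB`
#'   contigs in one ploidy group), `features` (data frame of planted
#'   feature coordinates on hapA), `manifest` (truth table of every
#'   planted element), and `spec`.
#' @export
generate_synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$length
  plant_iv <- function(pos, seq) c(pos, pos + nchar(seq))
  ivs <- list()
  for (f in spec$planted_features) {
    ivs[[length(ivs) + 1L]] <- plant_iv(f$pos, f$seq)
  }
  for (o in spec$planted_offtargets) {
    ivs[[length(ivs) + 1L]] <- plant_iv(o$pos, paste0(o$spacer, o$pam))
  }
  if (length(ivs)) {
    m <- do.call(rbind, ivs)
    if (any(m[, 1] < 0L) || any(m[, 2] > L)) {
      stop("planted element outside genome bounds", call. = FALSE)
    }
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2])) {
      stop("planted elements overlap", call. = FALSE)
    }
  }
  with_seed(spec$seed, {
    probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
               T = (1 - spec$gc) / 2)
    base <- sample(names(probs), L, replace = TRUE, prob = probs)
    manifest <- list()
    for (f in spec$planted_features) {
      s <- strsplit(toupper(f$seq), "", fixed = TRUE)[[1]]
      base[(f$pos + 1L):(f$pos + length(s))] <- s
      manifest[[length(manifest) + 1L]] <- data.frame(
        what = "feature", name = f$name %||% "feature",
        start = f$pos, end = f$pos + length(s), seq = toupper(f$seq),
        stringsAsFactors = FALSE)
    }
    for (o in spec$planted_offtargets) {
      spacer <- strsplit(toupper(o$spacer), "", fixed = TRUE)[[1]]
      nm <- o$n_mismatches %||% 0L
      if (nm > 0L) {
        at <- sample.int(length(spacer), nm)
        for (p in at) {
          spacer[p] <- sample(setdiff(c("A", "C", "G", "T"), spacer[p]), 1L)
        }
      }
      planted <- c(spacer, strsplit(toupper(o$pam), "", fixed = TRUE)[[1]])
      base[(o$pos + 1L):(o$pos + length(planted))] <- planted
      manifest[[length(manifest) + 1L]] <- data.frame(
        what = "offtarget_decoy", name = paste0("decoy_", o$pos),
        start = o$pos, end = o$pos + length(planted),
        seq = paste(planted, collapse = ""), stringsAsFactors = FALSE)
    }
    hapA <- paste(base, collapse = "")
    if (spec$n_haplotypes == 1L) {
      genome <- lp_genome(stats::setNames(hapA, spec$contig_name))
    } else {
      protected <- logical(L)
      margin <- spec$protect_margin
      if (length(ivs)) {
        for (r in seq_len(nrow(m))) {
          lo <- max(1L, m[r, 1] + 1L - margin)
          hi <- min(L, m[r, 2] + margin)
          protected[lo:hi] <- TRUE
        }
      }
      hit <- which(stats::runif(L) < spec$snv_rate & !protected)
      baseB <- base
      for (p in hit) {
        baseB[p] <- sample(setdiff(c("A", "C", "G", "T"), baseB[p]), 1L)
      }
      hapB <- paste(baseB, collapse = "")
      nms <- paste0(spec$contig_name, c("_hapA", "_hapB"))
      genome <- lp_genome(stats::setNames(c(hapA, hapB), nms),
                          ploidy_groups = stats::setNames(list(nms),
                                                          spec$contig_name))
      manifest[[length(manifest) + 1L]] <- data.frame(
        what = "het_snv_count", name = "hapB", start = NA_integer_,
        end = NA_integer_, seq = as.character(length(hit)),
        stringsAsFactors = FALSE)
    }
    manifest_df <- if (length(manifest)) do.call(rbind, manifest) else {
      data.frame(what = character(0), name = character(0),
                 start = integer(0), end = integer(0), seq = character(0),
                 stringsAsFactors = FALSE)
    }
    contig1 <- names(genome$contigs)[1]
    feat_rows <- manifest_df[manifest_df$what == "feature", , drop = FALSE]
    features <- if (nrow(feat_rows)) {
      data.frame(contig = contig1, start = feat_rows$start,
                 end = feat_rows$end, strand = "+", name = feat_rows$name,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(contig = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 name = character(0), stringsAsFactors = FALSE)
    }
    structure(list(genome = genome, features = features,
                   manifest = manifest_df, spec = spec),
              class = "synthetic_genome")
  })
}

#' Write synthetic-genome fixtures to disk
#'
#' Emits FASTA, a GFF3 of planted features, and the truth manifest TSV.
#'
#' @param synth A `synthetic_genome`.
#' @param fasta_path,gff_path,manifest_path Output paths (any may be
#'   `NULL`).
#' @return Invisibly, `NULL`.
#' @export
write_synthetic_genome <- function(synth, fasta_path = NULL,
                                   gff_path = NULL, manifest_path = NULL) {
  if (!is.null(fasta_path)) write_fasta(synth$genome, fasta_path)
  if (!is.null(gff_path) && nrow(synth$features)) {
    gr <- GenomicRanges::GRanges(
      seqnames = synth$features$contig,
      ranges = IRanges::IRanges(start = synth$features$start + 1L,
                                end = synth$features$end),
      strand = synth$features$strand)
    gr$ID <- synth$features$name
    gr$type <- "region"
    rtracklayer::export(gr, gff_path, format = "gff3")
  }
  if (!is.null(manifest_path)) {
    utils::write.table(synth$manifest, manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
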