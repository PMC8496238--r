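# Guide-quality metrics: polyT, GC, Hsu-Zhang off-target scoring, optional
# CFD table scorer, and a pluggable on-target scorer seam.

#' Quality-control thresholds for candidate targets
#'
#' Defaults are the tool's standard guide filters: longest T run at most
#' 4.5 (so runs of five or more fail), GC between 25 and 75 percent,
#' off-target search error budget 5, on-target score at least 45 and
#' Hsu-Zhang aggregate off-target score at least 90.
#'
#' @param polyt_max Maximum longest-T-run score (default 4.5).
#' @param gc_min,gc_max GC percent bounds (defaults 25, 75).
#' @param errors_max Off-target enumeration error budget (default 5).
#' @param ontarget_min Minimum on-target score (default 45).
#' @param offtarget_min Minimum aggregate off-target score (default 90).
#' @param min_uniqueness A guide fails if any non-identical genomic site
#'   lies within this many mismatches (default 1).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(polyt_max = 4.5, gc_min = 25, gc_max = 75,
                          errors_max = 5L, ontarget_min = 45,
                          offtarget_min = 90, min_uniqueness = 1L) {
  stopifnot(gc_min < gc_max, is.finite(polyt_max), is.finite(ontarget_min),
            is.finite(offtarget_min), errors_max >= 0)
  structure(list(polyt_max = polyt_max, gc_min = gc_min, gc_max = gc_max,
                 errors_max = as.integer(errors_max),
                 ontarget_min = ontarget_min, offtarget_min = offtarget_min,
                 min_uniqueness = as.integer(min_uniqueness)),
            class = "qc_thresholds")
}

#' Longest T-homopolymer run of a spacer
#'
#' Strand-specific: the spacer is scored as written. Under the default
#' threshold of 4.5, spacers with runs of five or more consecutive T fail.
#'
#' @param spacer Spacer sequence (character vector).
#' @return Numeric vector of run lengths.
#' @examples
#' polyt_score("GTTTTTACGATCGATCGATC")  # 5
#' @export
polyt_score <- function(spacer) {
  vapply(toupper(spacer), function(s) {
    m <- gregexpr("T+", s)[[1]]
    if (m[1] == -1L) 0 else max(attr(m, "match.length"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC percentage of a sequence
#'
#' @param spacer Character vector of sequences.
#' @return Numeric vector, `100 * (#G + #C) / length`.
#' @examples
#' gc_percent("CGTACGCTGCAGGTCGACAG")  # 65
#' @export
gc_percent <- function(spacer) {
  vapply(toupper(spacer), function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    100 * sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hsu-Zhang experimental position weights
#'
#' The published 20-entry mismatch position-weight vector of Hsu et
#' al. (2013), indexed with position 1 at the PAM-distal end of a 20 nt
#' spacer.
#'
#' @format Numeric vector of length 20.
#' @export
HSU_ZHANG_WEIGHTS <- c(
  0.000, 0.000, 0.014, 0.000, 0.000, 0.395, 0.317, 0.000, 0.389, 0.079,
  0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804, 0.685, 0.583)

# Map mismatch positions (1 = PAM-distal) on a spacer of length L onto
# indices of the 20-entry weight vector. Shorter spacers use the
# PAM-proximal tail; positions beyond 20 from the PAM get weight 0.
hsu_weight_at <- function(positions, spacer_len) {
  idx <- positions + 20L - spacer_len
  w <- numeric(length(idx))
  ok <- idx >= 1L & idx <= 20L
  w[ok] <- HSU_ZHANG_WEIGHTS[idx[ok]]
  w
}

#' Hsu-Zhang single-hit off-target score
#'
#' Scores one genomic near-match of a spacer in `[0, 100]` using the
#' position-weighted scheme of Hsu et al. (2013):
#' `100 * prod(1 - W[p]) * 1 / (((19 - d)/19) * 4 + 1) * 1 / n^2`,
#' where `d` is the mean pairwise distance between mismatch positions and
#' `n` the number of mismatches. A perfect match scores 100; a single
#' mismatch scores `100 * (1 - W[p])`.
#'
#' @param mismatch_positions Integer vector of mismatched spacer positions,
#'   1 = PAM-distal end. Order does not matter.
#' @param spacer_len Spacer length (default 20).
#' @return Numeric scalar in `[0, 100]`.
#' @export
hsu_zhang_single <- function(mismatch_positions, spacer_len = 20L) {
  p <- as.integer(mismatch_positions)
  if (anyDuplicated(p)) stop("duplicate mismatch positions", call. = FALSE)
  if (length(p) && (min(p) < 1L || max(p) > spacer_len)) {
    stop("mismatch positions out of range 1..", spacer_len, call. = FALSE)
  }
  n <- length(p)
  if (n == 0L) return(100)
  term1 <- prod(1 - hsu_weight_at(p, spacer_len))
  if (n == 1L) return(100 * term1)
  d <- mean(stats::dist(p))
  100 * term1 * (1 / (((19 - d) / 19) * 4 + 1)) * (1 / n^2)
}

#' Hsu-Zhang aggregate guide-specificity score
#'
#' Aggregates single-hit scores of all genomic near-matches (excluding the
#' on-target site itself) into a `(0, 100]` guide score:
#' `100 * 100 / (100 + sum(per-hit scores))`. An empty hit list scores
#' exactly 100; every additional hit strictly decreases the score.
#'
#' @param hits Either a numeric vector of per-hit scores or a data frame
#'   with a `per_hit_score` column (as returned by [find_offtargets()]).
#' @return Numeric scalar.
#' @examples
#' hsu_zhang_aggregate(numeric(0))  # 100
#' hsu_zhang_aggregate(100)         # 50
#' @export
hsu_zhang_aggregate <- function(hits) {
  scores <- if (is.data.frame(hits)) hits$per_hit_score else hits
  100 * 100 / (100 + sum(scores))
}

#' Read a CFD penalty table from TSV
#'
#' The table has columns `mismatch_type`, `position`, `penalty`. Mismatch
#' rows use keys of the form `rX:dY` (spacer base X paired with off-target
#' protospacer base Y) with a 1-based spacer position (1 = PAM-distal); PAM
#' rows use keys of the form `PAM:XX` (the two PAM bases after the N) with
#' an empty position field.
#'
#' @param path TSV path.
#' @return `data.frame` of class `cfd_table`.
#' @export
read_cfd_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mismatch_type", "position", "penalty")
  if (!all(need %in% names(df))) {
    stop("CFD table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("cfd_table", "data.frame")
  df
}

#' CFD (cutting frequency determination) off-target score
#'
#' Product of per-position mismatch penalties looked up in a user-supplied
#' table, times the PAM penalty. A perfect match with a canonical PAM
#' scores 1.0. The published penalty table is not bundled; supply one via
#' [read_cfd_table()].
#'
#' @param spacer Guide spacer (5'->3', PAM-distal first).
#' @param offtarget_protospacer Genomic protospacer of equal length.
#' @param pam Off-target PAM sequence (last two bases are looked up).
#' @param table A `cfd_table`, or `NULL`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
cfd_score <- function(spacer, offtarget_protospacer, pam, table) {
  if (is.null(table)) {
    stop("CFD scoring is disabled: no penalty table supplied ",
         "(load one with read_cfd_table())", call. = FALSE)
  }
  spacer <- toupper(spacer); prot <- toupper(offtarget_protospacer)
  if (nchar(spacer) != nchar(prot)) {
    stop("spacer and protospacer lengths differ", call. = FALSE)
  }
  sc <- strsplit(spacer, "", fixed = TRUE)[[1]]
  pc <- strsplit(prot, "", fixed = TRUE)[[1]]
  score <- 1
  for (k in which(sc != pc)) {
    key <- paste0("r", sc[k], ":d", pc[k])
    row <- table$mismatch_type == key & !is.na(table$position) &
      table$position == k
    if (!any(row)) {
      stop("CFD table has no entry for key '", key, "' at position ", k,
           call. = FALSE)
    }
    score <- score * table$penalty[which(row)[1]]
  }
  pam2 <- substr(toupper(pam), nchar(pam) - 1L, nchar(pam))
  pam_key <- paste0("PAM:", pam2)
  prow <- table$mismatch_type == pam_key
  if (!any(prow)) {
    stop("CFD table has no entry for key '", pam_key, "'", call. = FALSE)
  }
  score * table$penalty[which(prow)[1]]
}

# --- pluggable on-target scorer seam --------------------------------------

.scorer_registry <- new.env(parent = emptyenv())

#' Register an on-target scorer plugin
#'
#' @param name Scorer name.
#' @param fun Function `(spacer, context) -> score in [0, 100]`.
#' @return `fun`, invisibly.
#' @export
register_ontarget_scorer <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .scorer_registry)
  invisible(fun)
}

#' Retrieve a registered on-target scorer
#'
#' @param name Scorer name.
#' @return The scorer function.
#' @export
get_ontarget_scorer <- function(name) {
  if (!exists(name, envir = .scorer_registry, inherits = FALSE)) {
    stop("unknown on-target scorer '", name, "'", call. = FALSE)
  }
  get(name, envir = .scorer_registry, inherits = FALSE)
}

# Deterministic rule-based surrogate: 100 minus penalties for GC deviation
# from 50% and T-homopolymer runs, clamped to [0, 100]. This is NOT a
# trained on-target model; it is a stand-in behind the scorer seam, and
# outputs produced with it are labeled "rule_surrogate".
rule_surrogate_scorer <- function(spacer, context = NULL) {
  gc_dev <- abs(gc_percent(spacer) - 50)
  t_run <- polyt_score(spacer)
  pmin(100, pmax(0, 100 - gc_dev - 10 * pmax(0, t_run - 1)))
}

#' On-target efficacy score (pluggable)
#'
#' Dispatches to a registered scorer plugin. The default
#' `"rule_surrogate"` scorer is a deterministic rule-based stand-in (GC
#' deviation and polyT penalties scaled to `[0, 100]`), not a trained
#' model; trained models can be plugged in via
#' [register_ontarget_scorer()].
#'
#' @param spacer Spacer sequence(s).
#' @param context Optional flanking-context string passed to the plugin.
#' @param scorer Registered scorer name (default `"rule_surrogate"`).
#' @return Numeric score(s) in `[0, 100]`.
#' @export
ontarget_score <- function(spacer, context = NULL,
                           scorer = "rule_surrogate") {
  fun <- get_ontarget_scorer(scorer)
  fun(spacer, context)
}
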