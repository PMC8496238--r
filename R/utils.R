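# Sequence and RNG utilities shared across the package.

#' IUPAC nucleotide code sets
#'
#' Named list mapping each of the 15 IUPAC nucleotide codes to the set of
#' concrete bases it denotes.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Works on plain character vectors and understands all IUPAC ambiguity
#' codes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGT")
#' revcomp("TTTV")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Regex character class for a motif code matched against genome text.
# Genome 'N' (assembly gap) is only allowed to match motif code 'N'.
iupac_regex_class <- function(code) {
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("unknown IUPAC code '", code, "'", call. = FALSE)
  if (code == "N") return("[ACGTN]")
  if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
}

# Does genome base `base` satisfy motif code `code`?
iupac_matches <- function(code, base) {
  if (base == "N") return(code == "N")
  base %in% IUPAC_SETS[[code]]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible per-stage child seed
#'
#' One global seed fans out to per-stage seeds by stable string hashing, so
#' individual pipeline stages are reproducible in isolation.
#'
#' @param seed Integer master seed.
#' @param stage Stage name (character scalar).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# Count (possibly overlapping) occurrences of a literal pattern.
count_occurrences <- function(subject, pattern) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(0L)
  m <- gregexpr(paste0("(?=", escape_regex(pattern), ")"), subject, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) 0L else length(m)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Validate an uppercase ACGTN sequence; returns normalized string.
normalize_dna <- function(x, what = "sequence", allow_iupac = FALSE) {
  x <- toupper(x)
  allowed <- if (allow_iupac) "ACGTRYSWKMBDHVN" else "ACGTN"
  bad <- regmatches(x, regexpr(paste0("[^", allowed, "]"), x))
  if (length(bad) && nchar(bad)) {
    stop(what, " contains invalid character '", bad, "'", call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
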