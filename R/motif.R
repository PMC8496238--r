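# RGN target-motif grammar: parsing, canonical serialization and matching.
#
# A motif string describes the spacer and PAM of an RNA-guided nuclease in
# IUPAC letters with optional quantifiers, e.g. 'N{17}|N{3}>NGG' for SpCas9:
# 20 nt spacer, 3' NGG PAM, blunt cut 3 nt from the PAM-proximal spacer end.
# '>' places the PAM 3' (right) of the spacer, '<' places it 5' (left);
# '|' marks a cut position inside the spacer.

#' Parse an RGN target-motif string
#'
#' The grammar accepts IUPAC nucleotide letters, `{n}` / `{n,m}` quantifiers,
#' `|` cut marks inside the spacer, and exactly one PAM separator: `>` for a
#' 3' PAM (e.g. SpCas9 `N{17}|N{3}>NGG`) or `<` for a 5' PAM (e.g. Cas12a
#' `TTTV<N{20}`).
#'
#' @param motif_string Motif in the grammar above.
#' @return An object of class `target_motif` with elements `raw`,
#'   `spacer_segments` and `pam_segments` (data frames with columns `code`,
#'   `min`, `max`), `pam_side` (`"three_prime"` or `"five_prime"`),
#'   `cut_offsets` (integer vector, nt from each cut mark to the
#'   PAM-proximal spacer end; may be empty), `cut_offset_sense` (the
#'   PAM-proximal cut offset actually used downstream, or `NA`), and
#'   `spacer_len_range`.
#' @examples
#' m <- parse_motif("N{17}|N{3}>NGG")
#' m$spacer_len_range   # c(20, 20)
#' m$cut_offset_sense   # 3
#' @export
parse_motif <- function(motif_string) {
  if (!is.character(motif_string) || length(motif_string) != 1L ||
      is.na(motif_string) || !nzchar(motif_string)) {
    stop("motif must be a nonempty string", call. = FALSE)
  }
  s <- toupper(motif_string)
  seps <- gregexpr("[<>]", s)[[1]]
  if (length(seps) != 1L || seps[1] == -1L) {
    stop("motif must contain exactly one PAM separator '>' or '<': '",
         motif_string, "'", call. = FALSE)
  }
  sep_char <- substr(s, seps[1], seps[1])
  left <- substr(s, 1L, seps[1] - 1L)
  right <- substr(s, seps[1] + 1L, nchar(s))
  if (sep_char == ">") {
    pam_side <- "three_prime"
    spacer_str <- left; pam_str <- right
    spacer_base <- 0L; pam_base <- seps[1]
  } else {
    pam_side <- "five_prime"
    pam_str <- left; spacer_str <- right
    pam_base <- 0L; spacer_base <- seps[1]
  }
  if (!nzchar(spacer_str)) stop("motif has an empty spacer part", call. = FALSE)
  if (!nzchar(pam_str)) stop("motif has an empty PAM part", call. = FALSE)

  sp <- parse_segments(spacer_str, allow_cut = TRUE, index_base = spacer_base)
  pm <- parse_segments(pam_str, allow_cut = FALSE, index_base = pam_base)

  # Cut marks sit at segment boundaries; convert each to nt from the
  # PAM-proximal spacer end using the minimum segment counts.
  min_total <- sum(sp$segments$min)
  cut_offsets <- if (length(sp$cut_positions)) {
    if (pam_side == "three_prime") {
      as.integer(min_total - sp$cut_positions)
    } else {
      as.integer(sp$cut_positions)
    }
  } else integer(0)

  motif <- structure(list(
    raw = motif_string,
    spacer_segments = sp$segments,
    pam_segments = pm$segments,
    pam_side = pam_side,
    cut_boundaries = sp$cut_positions,  # nt from spacer 5' end (min counts)
    cut_offsets = cut_offsets,
    cut_offset_sense = if (length(cut_offsets)) min(cut_offsets) else NA_integer_,
    spacer_len_range = c(sum(sp$segments$min), sum(sp$segments$max))
  ), class = "target_motif")
  motif
}

# Tokenize one side of a motif: letters with optional {n} / {n,m}
# quantifiers, plus '|' cut marks when allowed. `index_base` offsets error
# indices to positions in the full raw string.
parse_segments <- function(str, allow_cut = FALSE, index_base = 0L) {
  chars <- strsplit(str, "", fixed = TRUE)[[1]]
  i <- 1L
  codes <- character(0); mins <- integer(0); maxs <- integer(0)
  cut_positions <- integer(0)
  cum_min <- 0L
  while (i <= length(chars)) {
    ch <- chars[i]
    at <- index_base + i
    if (ch == "|") {
      if (!allow_cut) {
        stop("cut mark '|' is only allowed in the spacer (at index ", at, ")",
             call. = FALSE)
      }
      cut_positions <- c(cut_positions, cum_min)
      i <- i + 1L
      next
    }
    if (!ch %in% names(IUPAC_SETS)) {
      stop("unknown symbol '", ch, "' at index ", at, " of motif", call. = FALSE)
    }
    code <- ch
    lo <- 1L; hi <- 1L
    if (i < length(chars) && chars[i + 1L] == "{") {
      close <- i + 1L
      while (close <= length(chars) && chars[close] != "}") close <- close + 1L
      if (close > length(chars)) {
        stop("malformed quantifier: unclosed '{' at index ", index_base + i + 1L,
             call. = FALSE)
      }
      body <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
      if (grepl("^[0-9]+$", body)) {
        lo <- hi <- as.integer(body)
      } else if (grepl("^[0-9]+,[0-9]+$", body)) {
        parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
        lo <- parts[1]; hi <- parts[2]
      } else {
        stop("malformed quantifier '{", body, "}' at index ",
             index_base + i + 1L, call. = FALSE)
      }
      if (hi < lo || hi == 0L) {
        stop("malformed quantifier '{", body, "}': empty or inverted range",
             call. = FALSE)
      }
      i <- close + 1L
    } else {
      i <- i + 1L
    }
    codes <- c(codes, code); mins <- c(mins, lo); maxs <- c(maxs, hi)
    cum_min <- cum_min + lo
  }
  if (!length(codes)) stop("empty motif part", call. = FALSE)
  list(segments = data.frame(code = codes, min = mins, max = maxs,
                             stringsAsFactors = FALSE),
       cut_positions = cut_positions)
}

#' Serialize a motif to its canonical string
#'
#' Canonicalization collapses runs of identical fixed-count codes into
#' quantifier form (`NNN` becomes `N{3}`) while preserving cut marks and the
#' PAM separator. The canonical string re-parses to an equal motif.
#'
#' @param motif A `target_motif`.
#' @return Character scalar.
#' @examples
#' serialize_motif(parse_motif("NNNNNNNNNNNNNNNNN|NNN>NGG"))
#' @export
serialize_motif <- function(motif) {
  stopifnot(inherits(motif, "target_motif"))
  spacer <- format_segments(motif$spacer_segments, motif$cut_boundaries)
  pam <- format_segments(motif$pam_segments, integer(0))
  if (motif$pam_side == "three_prime") paste0(spacer, ">", pam)
  else paste0(pam, "<", spacer)
}

format_segments <- function(segments, cut_positions) {
  # Split conceptually at cut boundaries, merge adjacent fixed-count
  # identical codes between them, then format.
  out <- character(0)
  cum <- 0L
  pending_code <- NULL; pending_n <- 0L
  flush <- function() {
    if (is.null(pending_code)) return(invisible())
    out <<- c(out, if (pending_n == 1L) pending_code
              else paste0(pending_code, "{", pending_n, "}"))
    pending_code <<- NULL; pending_n <<- 0L
  }
  for (k in seq_len(nrow(segments))) {
    code <- segments$code[k]; lo <- segments$min[k]; hi <- segments$max[k]
    if (cum %in% cut_positions && cum > 0L) { flush(); out <- c(out, "|") }
    if (lo == hi) {
      if (!is.null(pending_code) && pending_code == code) {
        pending_n <- pending_n + lo
      } else {
        flush(); pending_code <- code; pending_n <- lo
      }
    } else {
      flush()
      out <- c(out, paste0(code, "{", lo, ",", hi, "}"))
    }
    cum <- cum + lo
  }
  flush()
  if (length(cut_positions) && sum(segments$min) %in% cut_positions) {
    out <- c(out, "|")
  }
  paste(out, collapse = "")
}

# All fixed-length expansions of a motif: one entry per choice of quantifier
# counts, each with per-position spacer and PAM code vectors. Matching a
# ranged motif equals the union of matches of its expansions.
motif_expansions <- function(motif, max_expansions = 512L) {
  expand_side <- function(segments) {
    choices <- lapply(seq_len(nrow(segments)), function(k) {
      segments$min[k]:segments$max[k]
    })
    grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(grid)), function(r) {
      counts <- as.integer(grid[r, ])
      rep(segments$code, counts)
    })
  }
  sp <- expand_side(motif$spacer_segments)
  pm <- expand_side(motif$pam_segments)
  if (length(sp) * length(pm) > max_expansions) {
    stop("motif has too many quantifier expansions (",
         length(sp) * length(pm), " > ", max_expansions, ")", call. = FALSE)
  }
  out <- list()
  for (a in sp) for (b in pm) {
    out[[length(out) + 1L]] <- list(spacer = a, pam = b,
                                    len = length(a) + length(b))
  }
  out[order(vapply(out, `[[`, integer(1), "len"))]
}

# Per-position check of a window against one expansion. Returns
# list(spacer=, pam=) or NULL. `window` is the sense-strand text.
match_expansion <- function(exp, window) {
  n_sp <- length(exp$spacer); n_pm <- length(exp$pam)
  if (nchar(window) != n_sp + n_pm) return(NULL)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  codes <- c(exp$spacer, exp$pam)  # layout fixed up by caller for 5' PAM
  for (k in seq_along(codes)) {
    if (!iupac_matches(codes[k], chars[k])) return(NULL)
  }
  list(spacer = substr(window, 1L, n_sp),
       pam = substr(window, n_sp + 1L, n_sp + n_pm))
}

#' Match a motif at a fixed offset
#'
#' Tests whether the window starting at `offset` (0-based, plus-strand
#' coordinates) matches the motif on the given strand. Minus-strand matching
#' is performed against the reverse complement of the window, and the
#' decomposition is reported 5'->3' on the spacer's sense.
#'
#' @param motif A `target_motif`.
#' @param sequence Plus-strand nucleotide text (ACGTN).
#' @param offset 0-based start of the window on the plus strand.
#' @param strand `"+"` or `"-"`.
#' @return `NULL` if no expansion of the motif matches; otherwise a list
#'   with elements `spacer`, `pam` and `length` (window width used).
#' @export
match_at <- function(motif, sequence, offset, strand = "+") {
  stopifnot(inherits(motif, "target_motif"), offset >= 0)
  sequence <- toupper(sequence)
  for (exp in motif_expansions(motif)) {
    if (offset + exp$len > nchar(sequence)) next
    window <- substr(sequence, offset + 1L, offset + exp$len)
    if (strand == "-") window <- revcomp(window)
    hit <- if (motif$pam_side == "three_prime") {
      match_expansion(exp, window)
    } else {
      # 5' PAM: sense layout is PAM then spacer.
      h <- match_expansion(list(spacer = exp$pam, pam = exp$spacer), window)
      if (!is.null(h)) list(spacer = h$pam, pam = h$spacer)
    }
    if (!is.null(hit)) {
      hit$length <- exp$len
      return(hit)
    }
  }
  NULL
}

# All motif matches in one contig, both strands. Returns a data.frame with
# 0-based half-open plus-strand coordinates, sense spacer/pam text, and the
# genomic cut coordinate (boundary immediately 5' of which the cut falls).
motif_matches <- function(motif, sequence, contig = "contig") {
  sequence <- toupper(sequence)
  rc <- revcomp(sequence)
  n <- nchar(sequence)
  rows <- list()
  for (exp in motif_expansions(motif)) {
    classes <- if (motif$pam_side == "three_prime") {
      c(vapply(exp$spacer, iupac_regex_class, character(1)),
        vapply(exp$pam, iupac_regex_class, character(1)))
    } else {
      c(vapply(exp$pam, iupac_regex_class, character(1)),
        vapply(exp$spacer, iupac_regex_class, character(1)))
    }
    pattern <- paste0("(?=", paste(classes, collapse = ""), ")")
    n_sp <- length(exp$spacer); n_pm <- length(exp$pam)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") sequence else rc
      m <- gregexpr(pattern, subject, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      p <- as.integer(m)               # 1-based starts on scanned strand
      start0 <- if (strand == "+") p - 1L else n - (p - 1L) - exp$len
      if (motif$pam_side == "three_prime") {
        spacer <- substring(subject, p, p + n_sp - 1L)
        pam <- substring(subject, p + n_sp, p + exp$len - 1L)
      } else {
        pam <- substring(subject, p, p + n_pm - 1L)
        spacer <- substring(subject, p + n_pm, p + exp$len - 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = start0, end = start0 + exp$len,
        strand = strand, spacer = spacer, pam = pam,
        cut_position = cut_coordinate(motif, start0, start0 + exp$len,
                                      strand, n_sp, n_pm),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      spacer = character(0), pam = character(0),
                      cut_position = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# Genomic coordinate of the (blunt) cut boundary for a match. Offset is nt
# from the PAM-proximal spacer end; absent cut marks default to the
# spacer/PAM junction (offset 0).
cut_coordinate <- function(motif, start, end, strand, n_sp, n_pm) {
  off <- motif$cut_offset_sense
  if (is.na(off)) off <- 0L
  if (motif$pam_side == "three_prime") {
    ifelse(strand == "+", end - n_pm - off, start + n_pm + off)
  } else {
    ifelse(strand == "+", start + n_pm + off, end - n_pm - off)
  }
}

#' @export
print.target_motif <- function(x, ...) {
  cat("<target_motif> ", serialize_motif(x), "\n", sep = "")
  cat("  spacer length: ", x$spacer_len_range[1],
      if (x$spacer_len_range[2] != x$spacer_len_range[1])
        paste0("-", x$spacer_len_range[2]), " nt; PAM ",
      ifelse(x$pam_side == "three_prime", "3'", "5'"), "\n", sep = "")
  if (!is.na(x$cut_offset_sense)) {
    cat("  cut offset: ", x$cut_offset_sense,
        " nt from PAM-proximal spacer end\n", sep = "")
  }
  invisible(x)
}
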