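# Independent brute-force oracles. These deliberately re-derive results
# with naive loops and their own lookup tables so they share no code path
# with the package implementation they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- rev(strsplit(s, "")[[1]])
  paste(vapply(chars, function(ch) map[[ch]], character(1)), collapse = "")
}

# Does genome base match motif code? Genome N only matches code N.
oracle_code_ok <- function(code, base) {
  if (base == "N") return(code == "N")
  base %in% ORACLE_IUPAC[[code]]
}

# Naive scan for a fixed-length motif given explicit per-position code
# vectors (sense layout: spacer then PAM for 3' PAM, PAM then spacer for
# 5' PAM). Returns 0-based half-open plus-strand coordinates.
oracle_scan <- function(sequence, spacer_codes, pam_codes,
                        pam_side = "three_prime") {
  codes <- if (pam_side == "three_prime") c(spacer_codes, pam_codes)
           else c(pam_codes, spacer_codes)
  len <- length(codes)
  n <- nchar(sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    for (start0 in 0:(n - len)) {
      window <- substr(sequence, start0 + 1, start0 + len)
      if (strand == "-") window <- oracle_revcomp(window)
      wchars <- strsplit(window, "")[[1]]
      ok <- TRUE
      for (k in seq_len(len)) {
        if (!oracle_code_ok(codes[k], wchars[k])) { ok <- FALSE; break }
      }
      if (ok) {
        n_sp <- length(spacer_codes)
        if (pam_side == "three_prime") {
          spacer <- substr(window, 1, n_sp)
          pam <- substr(window, n_sp + 1, len)
        } else {
          pam <- substr(window, 1, length(pam_codes))
          spacer <- substr(window, length(pam_codes) + 1, len)
        }
        rows[[length(rows) + 1]] <- data.frame(
          start = start0, end = start0 + len, strand = strand,
          spacer = spacer, pam = pam, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), spacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Naive off-target enumeration: every window (both strands) whose PAM
# matches and whose protospacer is within `max_errors` mismatches of the
# spacer. Returns protospacer-window coordinates and mismatch counts.
oracle_offtargets <- function(sequence, spacer, pam_codes,
                              max_errors = 5, pam_side = "three_prime") {
  L <- nchar(spacer)
  lp <- length(pam_codes)
  n <- nchar(sequence)
  sp <- strsplit(spacer, "")[[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    for (start0 in 0:(n - L - lp)) {
      window <- substr(sequence, start0 + 1, start0 + L + lp)
      if (strand == "-") window <- oracle_revcomp(window)
      wchars <- strsplit(window, "")[[1]]
      if (pam_side == "three_prime") {
        prot <- wchars[1:L]; pam <- wchars[(L + 1):(L + lp)]
      } else {
        pam <- wchars[1:lp]; prot <- wchars[(lp + 1):(lp + L)]
      }
      ok <- TRUE
      for (k in seq_len(lp)) {
        if (!oracle_code_ok(pam_codes[k], pam[k])) { ok <- FALSE; break }
      }
      if (!ok) next
      mm <- sum(prot != sp)
      if (mm <= max_errors) {
        # 0-based start of the sense protospacer window on the + strand.
        ps <- if (pam_side == "three_prime") {
          if (strand == "+") start0 else start0 + lp
        } else {
          if (strand == "+") start0 + lp else start0
        }
        rows[[length(rows) + 1]] <- data.frame(
          start = ps, strand = strand, n_mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), strand = character(0),
                      n_mismatches = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exhaustive Hamming scan: minimum mismatch count between `spacer` and
# every NGG-adjacent window on both strands of `sequence`. Written against
# the raw sequence with vectorized substring arithmetic (no shared code
# with the package's window index); returns Inf when no window exists.
oracle_min_hamming_ngg <- function(sequence, spacer) {
  L <- nchar(spacer)
  n <- nchar(sequence)
  best <- Inf
  for (strand_seq in c(sequence, oracle_revcomp(sequence))) {
    starts <- 0:(n - L - 3)
    pam2 <- substring(strand_seq, starts + L + 2, starts + L + 3)
    starts <- starts[pam2 == "GG"]
    if (!length(starts)) next
    mm <- integer(length(starts))
    sp <- strsplit(spacer, "")[[1]]
    for (k in seq_len(L)) {
      mm <- mm + (substring(strand_seq, starts + k, starts + k) != sp[k])
    }
    best <- min(best, mm)
  }
  best
}

# Independently transcribed Hsu et al. (2013) single-hit formula.
oracle_hsu_single <- function(positions, L = 20) {
  W <- c(0, 0, 0.014, 0, 0, 0.395, 0.317, 0, 0.389, 0.079,
         0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804,
         0.685, 0.583)
  n <- length(positions)
  if (n == 0) return(100)
  prodterm <- 1
  for (p in positions) {
    idx <- p + 20 - L
    w <- if (idx >= 1 && idx <= 20) W[idx] else 0
    prodterm <- prodterm * (1 - w)
  }
  if (n == 1) return(100 * prodterm)
  total <- 0; count <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + abs(positions[i] - positions[j])
      count <- count + 1
    }
  }
  d <- total / count
  100 * prodterm * (1 / (((19 - d) / 19) * 4 + 1)) * (1 / n^2)
}

# Independent SantaLucia (1998) nearest-neighbor Tm. Parameters are keyed
# by canonical duplex (the lexicographically smaller of a step and its
# reverse complement), a different table organization from the package.
oracle_tm <- function(s, Na = 0.05, conc = 5e-7) {
  dup <- list(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9))
  canon <- function(step) {
    rc <- oracle_revcomp(step)
    if (step %in% names(dup)) step else rc
  }
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    key <- canon(paste0(chars[i], chars[i + 1]))
    dH <- dH + dup[[key]][1]
    dS <- dS + dup[[key]][2]
  }
  for (endbase in c(chars[1], chars[n])) {
    if (endbase %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  selfcomp <- identical(toupper(s), oracle_revcomp(toupper(s)))
  ct <- if (selfcomp) conc else conc / 4
  if (selfcomp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1) * log(Na)
  dH * 1000 / (dS + 1.9872 * log(ct)) - 273.15
}

# Naive primer enumeration with its own constraint checks.
oracle_primers <- function(sequence, region, lengths = 18:28,
                           gc_min = 30, gc_max = 70, max_homo = 4,
                           tail_k = 4) {
  ok_primer <- function(p) {
    chars <- strsplit(p, "")[[1]]
    if ("N" %in% chars) return(FALSE)
    gc <- 100 * sum(chars %in% c("G", "C")) / length(chars)
    if (gc < gc_min || gc > gc_max) return(FALSE)
    runs <- rle(chars)
    if (max(runs$lengths) > max_homo) return(FALSE)
    if (!chars[length(chars)] %in% c("G", "C")) return(FALSE)
    tail <- substr(p, nchar(p) - tail_k + 1, nchar(p))
    if (grepl(oracle_revcomp(tail), p, fixed = TRUE)) return(FALSE)
    TRUE
  }
  rows <- list()
  for (len in lengths) {
    if (region[2] - region[1] < len) next
    for (start0 in region[1]:(region[2] - len)) {
      window <- substr(sequence, start0 + 1, start0 + len)
      for (strand in c("+", "-")) {
        p <- if (strand == "+") window else oracle_revcomp(window)
        if (ok_primer(p)) {
          rows[[length(rows) + 1]] <- data.frame(
            sequence = p, start = start0, length = len, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), start = integer(0),
                      length = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$length, out$strand), , drop = FALSE]
}

# Naive in-silico PCR over all site pairs.
oracle_pcr <- function(sequence, forward, reverse, max_amplicon = 5000) {
  find_sites <- function(needle) {
    out <- integer(0)
    ln <- nchar(needle)
    if (ln > nchar(sequence)) return(out)
    for (start0 in 0:(nchar(sequence) - ln)) {
      if (substr(sequence, start0 + 1, start0 + ln) == needle) {
        out <- c(out, start0)
      }
    }
    out
  }
  fs <- find_sites(forward)
  rs <- find_sites(oracle_revcomp(reverse))
  rows <- list()
  for (f in fs) {
    for (r in rs) {
      if (r < f + nchar(forward)) next
      len <- r + nchar(reverse) - f
      if (len <= max_amplicon) {
        rows[[length(rows) + 1]] <- data.frame(start = f, length = len)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$length), , drop = FALSE]
}

# Exhaustive search over all role assignments; the objective is the
# package's primer_set_weight so only the search is independent.
oracle_best_set <- function(candidates_by_role) {
  counts <- vapply(candidates_by_role, nrow, integer(1))
  grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  best_w <- -1; best <- NULL
  for (r in seq_len(nrow(grid))) {
    picked <- lapply(seq_along(candidates_by_role), function(j) {
      candidates_by_role[[j]][grid[r, j], , drop = FALSE]
    })
    names(picked) <- names(candidates_by_role)
    w <- landingpad::primer_set_weight(picked)
    if (w > best_w) { best_w <- w; best <- picked }
  }
  list(weight = best_w, roles = best)
}
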