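## CRISPR array detection: exact k-mer seeds (k = dr_min) chained at
## repeat-spacer periodicity, consensus extension with a per-copy mismatch
## budget, and recruitment of additional (possibly mutated) repeat copies.
## Spacers are pooled by canonical direct-repeat type within a sample.

#' Detection parameters for CRISPR arrays
#'
#' Defaults follow common repeat-spacer detector settings: direct repeats of
#' 23--47 bp, spacers of 26--50 bp, at least 3 repeat copies, and at most 2
#' mismatches per repeat copy against the consensus.
#'
#' @param dr_min,dr_max Direct-repeat length bounds (bp).
#' @param spacer_min,spacer_max Spacer length bounds (bp).
#' @param min_repeats Minimum repeat copies per array.
#' @param max_mismatch Mismatch budget per repeat copy vs the consensus.
#' @return A `crispr_params` list.
#' @export
crispr_params <- function(dr_min = 23L, dr_max = 47L,
                          spacer_min = 26L, spacer_max = 50L,
                          min_repeats = 3L, max_mismatch = 2L) {
  structure(list(dr_min = as.integer(dr_min), dr_max = as.integer(dr_max),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 min_repeats = as.integer(min_repeats),
                 max_mismatch = as.integer(max_mismatch)),
            class = "crispr_params")
}

## Split sequence into a character vector, masking non-ACGT positions with a
## per-position sentinel that never equals anything (not even itself is
## needed: "?" never equals A/C/G/T or the consensus alphabet).
seq_chars <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch[!ch %in% DNA_BASES] <- "?"
  ch
}

## Majority base over a character vector; ties broken alphabetically; "?"
## excluded. Returns NA when no informative base.
majority_base <- function(col) {
  col <- col[col %in% DNA_BASES]
  if (length(col) == 0) return(NA_character_)
  tb <- table(col)
  names(tb)[which.max(tb)]
}

## Extend a set of repeat-copy start offsets (1-based, all copies the same
## current [s, e] span relative to their anchor) in one direction.
## Returns the extended span after trimming trailing columns where not all
## copies agree. `starts` are 1-based anchor positions of the current left
## boundary of each copy.
extend_side <- function(ch, starts, span_len, params, right, limit_lo, limit_hi) {
  n_copies <- length(starts)
  required <- required_agreement(n_copies)
  mism <- integer(n_copies)          # per-copy mismatches in extension columns
  gained <- 0L                       # accepted extension columns
  last_full <- 0L                    # last extension depth where all agree
  depth <- 0L
  repeat {
    depth <- depth + 1L
    if (span_len + gained + 1L > params$dr_max) break
    pos <- if (right) starts + span_len - 1L + depth else starts - depth
    if (any(pos < limit_lo) || any(pos > limit_hi)) break
    col <- ch[pos]
    mb <- majority_base(col)
    if (is.na(mb)) break
    agree <- col == mb
    if (sum(agree) < required) break
    new_mism <- mism + !agree
    if (any(new_mism > params$max_mismatch)) break
    mism <- new_mism
    gained <- gained + 1L
    if (all(agree)) last_full <- gained
  }
  last_full
}

## Count mismatches between a candidate window and a consensus char vector.
window_mismatches <- function(ch, start, cons) {
  w <- ch[start:(start + length(cons) - 1L)]
  sum(w != cons)
}

#' Detect CRISPR repeat-spacer arrays in a nucleotide sequence
#'
#' Exact k-mer seeds (k = `dr_min`) occurring at repeat-spacer periodicity are
#' chained, the repeat is extended left and right by per-column majority
#' consensus under a per-copy mismatch budget (boundaries trimmed back to the
#' last unanimous column), and additional repeat copies (e.g. copies carrying
#' a substitution inside the seed) are recruited by scanning the flanking and
#' interior windows for consensus occurrences within the budget.
#'
#' @param seq A nucleotide string, or a length-1 named character vector.
#'   Non-ACGT characters are masked and never match.
#' @param params A [crispr_params()].
#' @param source_id Identifier recorded on the returned arrays (defaults to
#'   the name of `seq`, else `"seq"`).
#' @return A list of `crispr_array` objects, in coordinate order. Each has
#'   `source_id`, `repeat_start` / `repeat_end` (parallel integer vectors,
#'   0-based half-open), `dr_consensus` (per-column majority), `spacers`
#'   (ordered strings between repeats), and `strand` (always `"+"`; detection
#'   is orientation-agnostic and repeats are reported on the input strand).
#' @export
detect_arrays <- function(seq, params = crispr_params(), source_id = NULL) {
  if (is.null(source_id)) {
    source_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  }
  seq <- unname(seq[1])
  n <- nchar(seq)
  if (n < 3L * params$dr_min + 2L * params$spacer_min) return(list())
  ch <- seq_chars(seq)
  k <- params$dr_min

  kmers <- substring(paste(ch, collapse = ""), seq_len(n - k + 1L), k:n)
  valid <- !grepl("?", kmers, fixed = TRUE)
  pos_by_kmer <- split(which(valid), kmers[valid])
  pos_by_kmer <- pos_by_kmer[vapply(pos_by_kmer, length, 0L) >= 2L]
  if (length(pos_by_kmer) == 0) return(list())

  lo_gap <- params$dr_min + params$spacer_min
  hi_gap <- params$dr_max + params$spacer_max

  candidates <- list()
  for (positions in pos_by_kmer) {
    positions <- sort(positions)
    gaps <- diff(positions)
    ## chain link valid at one period or (one skipped copy) two periods
    link <- (gaps >= lo_gap & gaps <= hi_gap) |
      (gaps >= 2L * lo_gap & gaps <= 2L * hi_gap)
    brk <- c(0L, which(!link), length(positions))
    for (b in seq_len(length(brk) - 1L)) {
      idx <- (brk[b] + 1L):brk[b + 1L]
      if (length(idx) < 2L) next
      cand <- build_array(ch, positions[idx], k, params, source_id)
      if (!is.null(cand)) candidates[[length(candidates) + 1L]] <- cand
    }
  }
  if (length(candidates) == 0) return(list())
  dedupe_arrays(candidates)
}

## From seed anchor positions (1-based starts of an exact shared k-mer),
## extend to full repeat boundaries, recruit missed copies, validate.
build_array <- function(ch, anchors, k, params, source_id) {
  n <- length(ch)

  ## Right/left extension limits: never extend into a neighbouring copy's
  ## seed or squeeze a spacer below spacer_min.
  right_gain <- extend_side(ch, anchors, k, params, right = TRUE,
                            limit_lo = 1L, limit_hi = n)
  ## cap: keep spacers >= spacer_min
  if (length(anchors) > 1L) {
    max_right <- min(diff(sort(anchors))) - k - params$spacer_min
    ## a two-period (skipped-copy) gap should not cap extension; use the
    ## smallest single-period gap if available
    gaps <- diff(sort(anchors))
    single <- gaps[gaps <= params$dr_max + params$spacer_max]
    if (length(single)) max_right <- min(single) - k - params$spacer_min
    right_gain <- min(right_gain, max(0L, max_right))
  }
  left_gain <- extend_side(ch, anchors, k + right_gain, params, right = FALSE,
                           limit_lo = 1L, limit_hi = n)
  if (length(anchors) > 1L) {
    gaps <- diff(sort(anchors))
    single <- gaps[gaps <= params$dr_max + params$spacer_max]
    if (length(single)) {
      max_left <- min(single) - (k + right_gain) - params$spacer_min
      left_gain <- min(left_gain, max(0L, max_left))
    }
  }

  starts <- sort(anchors) - left_gain
  L <- k + left_gain + right_gain
  if (L < params$dr_min || L > params$dr_max) return(NULL)
  if (any(starts < 1L) || any(starts + L - 1L > n)) return(NULL)

  consensus <- vapply(seq_len(L), function(j) {
    mb <- majority_base(ch[starts + j - 1L])
    if (is.na(mb)) "?" else mb
  }, "")

  ## recruit copies: interior gaps of ~two periods, then flanks
  starts <- recruit_copies(ch, starts, consensus, params)

  ## re-trim boundaries over the full copy set: a seed spanning a chance
  ## spacer-end coincidence can over-extend; recruited copies expose the
  ## junk columns as low-agreement and they are trimmed here
  ref <- refine_boundaries(ch, starts, length(consensus), params)
  starts <- ref$starts
  L <- ref$L
  if (L < params$dr_min || L > params$dr_max) return(NULL)
  consensus <- vapply(seq_len(L), function(j) {
    mb <- majority_base(ch[starts + j - 1L])
    if (is.na(mb)) "?" else mb
  }, "")

  ## validate
  if (length(starts) < params$min_repeats) return(NULL)
  mm <- vapply(starts, function(s) window_mismatches(ch, s, consensus), 0L)
  if (any(mm > params$max_mismatch)) return(NULL)
  sp_len <- diff(starts) - L
  if (any(sp_len < params$spacer_min) || any(sp_len > params$spacer_max)) {
    return(NULL)
  }

  seqstr <- paste(ch, collapse = "")
  spacers <- substring(seqstr, starts[-length(starts)] + L, starts[-1] - 1L)
  structure(list(
    source_id = source_id,
    repeat_start = starts - 1L,                 # 0-based
    repeat_end = starts - 1L + L,               # half-open
    dr_consensus = paste(consensus, collapse = ""),
    spacers = spacers,
    strand = "+",
    total_mismatches = sum(mm)
  ), class = "crispr_array")
}

## Agreement needed for a column to count as repeat-like: with few copies a
## single disagreeing copy is indistinguishable from chance, so unanimity is
## required below 4 copies; with more copies one mutated copy is tolerated.
required_agreement <- function(n_copies) {
  if (n_copies >= 4L) n_copies - 1L else n_copies
}

## Trim boundary columns whose agreement across all copies falls below the
## required level (chance seed extensions into spacers are trimmed; one
## mutated copy among >= 4 is tolerated).
refine_boundaries <- function(ch, starts, L, params) {
  n_copies <- length(starts)
  required <- required_agreement(n_copies)
  col_agree <- function(pos) {
    col <- ch[pos]
    mb <- majority_base(col)
    if (is.na(mb)) 0L else sum(col == mb)
  }
  repeat {
    if (L <= params$dr_min) break
    if (col_agree(starts) < required) {
      starts <- starts + 1L
      L <- L - 1L
    } else break
  }
  repeat {
    if (L <= params$dr_min) break
    if (col_agree(starts + L - 1L) < required) {
      L <- L - 1L
    } else break
  }
  list(starts = starts, L = L)
}

## Scan for additional repeat copies matching the consensus within the
## mismatch budget: inside two-period gaps, then beyond both flanks.
recruit_copies <- function(ch, starts, consensus, params) {
  L <- length(consensus)
  n <- length(ch)
  lo <- L + params$spacer_min
  hi <- L + params$spacer_max

  scan_window <- function(from, to) {
    from <- max(1L, from); to <- min(n - L + 1L, to)
    if (from > to) return(NA_integer_)
    cand <- from:to
    mm <- vapply(cand, function(s) window_mismatches(ch, s, consensus), 0L)
    ok <- which(mm <= params$max_mismatch)
    if (length(ok) == 0) return(NA_integer_)
    ## best = fewest mismatches, tie to leftmost
    cand[ok[which.min(mm[ok])]]
  }

  ## interior gaps with room for a skipped copy
  repeat {
    gaps <- diff(starts)
    big <- which(gaps > hi)
    if (length(big) == 0) break
    added <- FALSE
    for (j in big) {
      s <- scan_window(starts[j] + lo, starts[j + 1L] - lo)
      if (!is.na(s)) {
        starts <- sort(c(starts, s))
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  ## left flank
  repeat {
    s <- scan_window(starts[1] - hi, starts[1] - lo)
    if (is.na(s)) break
    starts <- c(s, starts)
  }
  ## right flank
  repeat {
    s <- scan_window(starts[length(starts)] + lo, starts[length(starts)] + hi)
    if (is.na(s)) break
    starts <- c(starts, s)
  }
  starts
}

## Collapse candidates seeded from different k-mer offsets: identical arrays
## first, then overlapping ones (keep most copies, then fewest total
## mismatches to consensus, then longest repeat, then leftmost).
dedupe_arrays <- function(arrays) {
  keys <- vapply(arrays, function(a) {
    paste(a$repeat_start, collapse = ",")
  }, "")
  arrays <- arrays[!duplicated(keys)]
  spans <- t(vapply(arrays, function(a) {
    c(min(a$repeat_start), max(a$repeat_end))
  }, c(0, 0)))
  n_copies <- vapply(arrays, function(a) length(a$repeat_start), 0L)
  total_mm <- vapply(arrays, function(a) a$total_mismatches, 0L)
  rep_len <- vapply(arrays, function(a) a$repeat_end[1] - a$repeat_start[1], 0L)
  ord <- order(-n_copies, total_mm, -rep_len, spans[, 1])
  kept <- list()
  kept_spans <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    overlaps <- FALSE
    if (length(kept)) {
      overlaps <- any(spans[i, 1] < kept_spans[, 2] &
                        spans[i, 2] > kept_spans[, 1])
    }
    if (!overlaps) {
      kept[[length(kept) + 1L]] <- arrays[[i]]
      kept_spans <- rbind(kept_spans, spans[i, ])
    }
  }
  kept[order(vapply(kept, function(a) a$repeat_start[1], 0L))]
}

#' Canonical form of a direct repeat
#'
#' The lexicographic minimum of the repeat and its reverse complement, so that
#' repeats found on either strand merge to one type. Idempotent.
#'
#' @param dr A non-empty A/C/G/T string (vectorised).
#' @return Canonical string(s).
#' @export
#' @examples
#' canonical_dr("GGGTTT")  # "AAACCC"
canonical_dr <- function(dr) {
  if (any(nchar(dr) == 0)) stop("canonical_dr: empty repeat")
  rc <- revcomp(dr)
  ifelse(dr <= rc, dr, rc)
}

#' Pool spacers by direct-repeat type within a sample
#'
#' Arrays whose canonical direct repeats are identical are merged into one DR
#' type; the spacer multiset is the union over member arrays, preserving
#' duplicates. A DR type does not necessarily represent a single CRISPR
#' locus.
#'
#' @param arrays List of `crispr_array` objects from one sample.
#' @param sample_id Sample identifier recorded on each DR type.
#' @return A list of `dr_type` objects, each with `sample_id`,
#'   `canonical_dr`, `spacers` (character vector, duplicates preserved) and
#'   `source_arrays` (indices into `arrays`). Ordered by canonical repeat.
#' @export
pool_spacers_by_dr_type <- function(arrays, sample_id) {
  if (length(arrays) == 0) return(list())
  cdr <- vapply(arrays, function(a) canonical_dr(a$dr_consensus), "")
  out <- lapply(sort(unique(cdr)), function(d) {
    idx <- which(cdr == d)
    structure(list(
      sample_id = sample_id,
      canonical_dr = d,
      spacers = unlist(lapply(arrays[idx], `[[`, "spacers"), use.names = FALSE),
      source_arrays = idx
    ), class = "dr_type")
  })
  out
}
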