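## Virus-host linkage: MAG <- direct repeat (exact, either strand) and
## direct-repeat spacers -> viral protospacers (ungapped, bounded Hamming
## distance), assembled into a bipartite MAG-vOTU network with the shared-DR
## ambiguity flag.

#' Build MAG records from a contig-to-bin table
#'
#' Bins failing the quality rule (completeness >= 70%, redundancy <= 10%) are
#' dropped.
#'
#' @param mag_table data.frame with columns `contig_id`, `bin_id`,
#'   `taxonomy`, `completeness`, `redundancy`.
#' @return The filtered table, one row per retained contig.
#' @export
mag_records <- function(mag_table) {
  need <- c("contig_id", "bin_id", "taxonomy", "completeness", "redundancy")
  if (!all(need %in% names(mag_table))) {
    stop("mag_records: missing columns: ",
         paste(setdiff(need, names(mag_table)), collapse = ", "))
  }
  keep <- mag_table$completeness >= 70 & mag_table$redundancy <= 10
  out <- mag_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match direct-repeat types to MAGs by exact full-length occurrence
#'
#' A DR type links to a MAG iff the full-length repeat (either strand) occurs
#' as an exact substring of one of the MAG's member contigs. At direct-repeat
#' lengths (23--47 bp) this is equivalent to a 100%-identity search at a
#' stringent E-value.
#'
#' @param dr_types List of `dr_type` objects (see
#'   [pool_spacers_by_dr_type()]).
#' @param mags Filtered MAG table from [mag_records()] (same sample).
#' @param contigs Named character vector with the MAG member contig
#'   sequences.
#' @return data.frame `canonical_dr` / `mag_id`, one row per link.
#' @export
match_dr_to_mags <- function(dr_types, mags, contigs) {
  rows <- list()
  bins <- unique(mags$bin_id)
  for (dt in dr_types) {
    dr <- dt$canonical_dr
    rc <- revcomp(dr)
    for (b in bins) {
      member_ids <- mags$contig_id[mags$bin_id == b]
      member_ids <- intersect(member_ids, names(contigs))
      hit <- any(vapply(contigs[member_ids], function(g) {
        grepl(dr, g, fixed = TRUE) || grepl(rc, g, fixed = TRUE)
      }, logical(1)))
      if (hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          canonical_dr = dr, mag_id = b, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(canonical_dr = character(0), mag_id = character(0))
}

#' Match spacers to protospacers at bounded Hamming distance
#'
#' Exhaustive ungapped search of every spacer against every contig, both
#' strands, reporting all occurrences with at most `max_mismatch`
#' substitutions. Implemented with a pigeonhole seed split (`max_mismatch +
#' 1` exact chunks located with fixed-string search, then full-length
#' verification), which finds every qualifying hit. Spacers shorter than
#' 26 bp are rejected with a warning (chance hits dominate below that
#' length).
#'
#' @param spacers Named character vector of spacers.
#' @param contigs Named character vector of (viral) contigs.
#' @param max_mismatch Maximum substitutions (default 1; use 3 for the
#'   archaeal relaxation).
#' @return data.frame with `spacer_id`, `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `n_mismatches`.
#' @export
match_spacers_to_protospacers <- function(spacers, contigs, max_mismatch = 1L) {
  empty <- data.frame(spacer_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatches = integer(0))
  if (length(spacers) == 0 || length(contigs) == 0) return(empty)
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("sp%04d", seq_along(spacers))
  }
  short <- nchar(spacers) < 26L
  if (any(short)) {
    warning("rejecting ", sum(short), " spacer(s) shorter than 26 bp")
    spacers <- spacers[!short]
    if (length(spacers) == 0) return(empty)
  }
  max_mismatch <- as.integer(max_mismatch)

  ## concatenate contigs with a separator that never matches
  clens <- nchar(contigs)
  sep <- "X"
  big <- paste(contigs, collapse = sep)
  offsets <- cumsum(c(0L, head(clens + 1L, -1L)))  # 0-based contig starts
  names(offsets) <- names(contigs)

  locate_contig <- function(pos0, len) {
    ## pos0: 0-based start in `big`; return contig index or NA if it spans
    ci <- findInterval(pos0, offsets)
    st <- pos0 - offsets[ci]
    if (st < 0 || st + len > clens[ci]) return(NA_integer_)
    ci
  }

  rows <- list()
  for (sid in names(spacers)) {
    sp <- spacers[[sid]]
    L <- nchar(sp)
    nseed <- max_mismatch + 1L
    bounds <- floor(seq(0L, L, length.out = nseed + 1L))
    for (strand in c("+", "-")) {
      query <- if (strand == "+") sp else revcomp(sp)
      seen <- integer(0)
      for (s in seq_len(nseed)) {
        chunk <- substr(query, bounds[s] + 1L, bounds[s + 1L])
        hitpos <- gregexpr(chunk, big, fixed = TRUE)[[1]]
        if (hitpos[1] == -1L) next
        for (hp in hitpos) {
          qstart0 <- hp - 1L - bounds[s]   # implied 0-based start in big
          if (qstart0 < 0L) next
          if (qstart0 %in% seen) next
          ci <- locate_contig(qstart0, L)
          if (is.na(ci)) next
          st <- qstart0 - offsets[ci]
          frag <- substr(contigs[[ci]], st + 1L, st + L)
          mm <- hamming(frag, query)
          if (mm <= max_mismatch) {
            seen <- c(seen, qstart0)
            rows[[length(rows) + 1L]] <- data.frame(
              spacer_id = sid, contig_id = names(contigs)[ci],
              start = as.integer(st), end = as.integer(st + L),
              strand = strand, n_mismatches = as.integer(mm),
              stringsAsFactors = FALSE)
          } else {
            seen <- c(seen, qstart0)  # verified and rejected; skip re-checks
          }
        }
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(out$spacer_id, out$contig_id, out$start, out$strand), ]
    rownames(out) <- NULL
    out
  } else empty
}

#' Assemble the bipartite virus-host infection network
#'
#' For each (DR type, MAG) link and each protospacer hit by that DR type's
#' spacers, an edge (MAG, vOTU of the hit contig) is emitted for the sample,
#' deduplicated per distinct (sample, MAG, vOTU, DR) with supporting hits
#' counted. An edge is flagged ambiguous when its DR type links to more than
#' one MAG in that sample: the spacers cannot then be attributed to a single
#' host.
#'
#' @param dr_mag_links data.frame from [match_dr_to_mags()].
#' @param dr_types List of `dr_type` objects for the sample; spacer ids are
#'   formed as `<sample>_<canonical_dr index>_<ordinal>` and must match the
#'   ids used for `protospacer_hits`. Pass the same naming used by
#'   [dr_type_spacer_ids()].
#' @param protospacer_hits data.frame from
#'   [match_spacers_to_protospacers()].
#' @param votu_membership vOTU membership table from [cluster_votus()].
#' @param sample_id Sample identifier for the emitted edges.
#' @param mag_taxonomy Named character vector mag_id -> taxonomy label.
#' @return data.frame with columns `sample_id`, `mag_id`, `mag_taxonomy`,
#'   `votu_id`, `canonical_dr`, `n_spacer_hits`, `ambiguous`.
#' @export
build_infection_network <- function(dr_mag_links, dr_types, protospacer_hits,
                                    votu_membership, sample_id,
                                    mag_taxonomy = NULL) {
  empty <- data.frame(sample_id = character(0), mag_id = character(0),
                      mag_taxonomy = character(0), votu_id = character(0),
                      canonical_dr = character(0), n_spacer_hits = integer(0),
                      ambiguous = logical(0))
  if (nrow(dr_mag_links) == 0 || nrow(protospacer_hits) == 0) return(empty)

  contig_votu <- setNames(votu_membership$votu_id, votu_membership$contig_id)
  spacer_dr <- dr_type_spacer_ids(dr_types, sample_id)

  rows <- list()
  for (dt_i in seq_along(dr_types)) {
    dr <- dr_types[[dt_i]]$canonical_dr
    mags <- dr_mag_links$mag_id[dr_mag_links$canonical_dr == dr]
    if (length(mags) == 0) next
    sp_ids <- names(spacer_dr)[spacer_dr == dr]
    hits <- protospacer_hits[protospacer_hits$spacer_id %in% sp_ids, ,
                             drop = FALSE]
    if (nrow(hits) == 0) next
    hit_votus <- contig_votu[hits$contig_id]
    if (anyNA(hit_votus)) {
      missing <- unique(hits$contig_id[is.na(hit_votus)])
      message("build_infection_network: ", length(missing),
              " hit contig(s) absent from the vOTU table; edges skipped")
      hits <- hits[!is.na(hit_votus), , drop = FALSE]
      hit_votus <- hit_votus[!is.na(hit_votus)]
    }
    if (nrow(hits) == 0) next
    ambiguous <- length(mags) > 1L
    tab <- table(hit_votus)
    for (m in mags) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, mag_id = m,
        mag_taxonomy = if (!is.null(mag_taxonomy))
          unname(mag_taxonomy[m]) else NA_character_,
        votu_id = names(tab), canonical_dr = dr,
        n_spacer_hits = as.integer(tab), ambiguous = ambiguous,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  ## deduplicate per (sample, mag, votu, dr), aggregating hit counts
  key <- paste(out$sample_id, out$mag_id, out$votu_id, out$canonical_dr,
               sep = "\r")
  agg <- aggregate(list(n_spacer_hits = out$n_spacer_hits),
                   by = list(key = key), FUN = sum)
  first <- out[!duplicated(key), , drop = FALSE]
  first$n_spacer_hits <- agg$n_spacer_hits[match(
    paste(first$sample_id, first$mag_id, first$votu_id, first$canonical_dr,
          sep = "\r"), agg$key)]
  first <- first[order(first$mag_id, first$votu_id, first$canonical_dr), ]
  rownames(first) <- NULL
  first
}

#' Canonical spacer ids for a sample's DR types
#'
#' Spacer ids are `<sample>_dr<index>_<ordinal>`, the naming used when
#' writing spacer FASTA and when matching spacers to protospacers.
#'
#' @param dr_types List of `dr_type` objects.
#' @param sample_id Sample identifier.
#' @return Named character vector: names are spacer ids, values the
#'   canonical DR of the owning type.
#' @export
dr_type_spacer_ids <- function(dr_types, sample_id) {
  out <- character(0)
  for (i in seq_along(dr_types)) {
    dt <- dr_types[[i]]
    if (length(dt$spacers) == 0) next
    ids <- sprintf("%s_dr%02d_%03d", sample_id, i, seq_along(dt$spacers))
    out[ids] <- dt$canonical_dr
  }
  out
}

#' Extract a sample's spacers with canonical ids
#'
#' @inheritParams dr_type_spacer_ids
#' @return Named character vector of spacer sequences.
#' @export
dr_type_spacers <- function(dr_types, sample_id) {
  ids <- dr_type_spacer_ids(dr_types, sample_id)
  seqs <- unlist(lapply(dr_types, `[[`, "spacers"), use.names = FALSE)
  setNames(seqs, names(ids))
}

#' Summarise an infection network
#'
#' Distinct-pair counting collapses samples and DR types. A vOTU is counted
#' as shared across taxa when it is linked to at least two MAGs with
#' different taxonomy labels, each through at least one unambiguous edge.
#'
#' @param net Edge data.frame from [build_infection_network()] (possibly
#'   rbind-ed over samples/regions).
#' @return A list with `n_votus`, `n_mags`, `n_distinct_pairs`,
#'   `cross_taxon_shared_votus`.
#' @export
summarize_network <- function(net) {
  if (nrow(net) == 0) {
    return(list(n_votus = 0L, n_mags = 0L, n_distinct_pairs = 0L,
                cross_taxon_shared_votus = 0L))
  }
  pairs <- unique(net[, c("mag_id", "votu_id")])
  shared <- 0L
  for (v in unique(net$votu_id)) {
    sub <- net[net$votu_id == v & !net$ambiguous, , drop = FALSE]
    if (nrow(sub) == 0) next
    taxa <- unique(sub$mag_taxonomy[!is.na(sub$mag_taxonomy)])
    mags <- unique(sub$mag_id)
    if (length(mags) >= 2 && length(taxa) >= 2) shared <- shared + 1L
  }
  list(n_votus = length(unique(net$votu_id)),
       n_mags = length(unique(net$mag_id)),
       n_distinct_pairs = nrow(pairs),
       cross_taxon_shared_votus = shared)
}
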