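## Per-sample profiling: near-exact read pseudo-mapping, the relative
## abundance and diversity proxies, rarefaction curves, and best-hit viral
## taxonomy with rare-group collapsing.

#' Pseudo-map reads to reference sequences
#'
#' A read counts toward a reference when it matches somewhere on either
#' strand with at most `max_mismatch` substitutions over its full length
#' (ungapped). Among references a read hits, only those at the minimum
#' mismatch count are counted, split equally as fractional counts when
#' several references tie. Search is exhaustive via a pigeonhole trusted-band
#' dictionary (`max_mismatch + 1` bands), so every qualifying reference is
#' found.
#'
#' @param reads Named character vector of reads (>= 31 bp).
#' @param references Named character vector of reference sequences.
#' @param max_mismatch Maximum substitutions over the full read (default 2).
#' @return Named numeric vector of (possibly fractional) counts per
#'   reference, with attribute `n_mapped` (number of reads with >= 1 hit).
#' @export
pseudo_map_reads <- function(reads, references, max_mismatch = 2L) {
  if (length(references) == 0) stop("pseudo_map_reads: no references")
  counts <- setNames(numeric(length(references)), names(references))
  if (length(reads) == 0) {
    attr(counts, "n_mapped") <- 0L
    return(counts)
  }
  if (any(nchar(reads) < 31L)) {
    stop("pseudo_map_reads: reads shorter than 31 bp")
  }
  if (is.null(names(reads))) names(reads) <- sprintf("r%06d", seq_along(reads))
  max_mismatch <- as.integer(max_mismatch)

  ## best (minimum) mismatch count per read x reference, NA = no hit
  best <- matrix(NA_integer_, nrow = length(reads), ncol = length(references),
                 dimnames = list(names(reads), names(references)))

  for (w in unique(nchar(reads))) {
    idx <- which(nchar(reads) == w)
    rset <- Biostrings::DNAStringSet(reads[idx])
    nb <- max_mismatch + 1L
    bounds <- floor(seq(0L, w, length.out = nb + 1L))
    for (b in seq_len(nb)) {
      pd <- Biostrings::PDict(rset, tb.start = bounds[b] + 1L,
                              tb.end = bounds[b + 1L])
      for (ri in seq_along(references)) {
        for (strand in c("+", "-")) {
          subj <- if (strand == "+") references[[ri]] else
            revcomp(references[[ri]])
          m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj),
                                      max.mismatch = max_mismatch)
          nhit <- S4Vectors::elementNROWS(m)
          for (pi in which(nhit > 0)) {
            starts <- BiocGenerics::start(m[[pi]])
            mm <- min(Biostrings::neditStartingAt(
              rset[[pi]], Biostrings::DNAString(subj), starting.at = starts))
            prev <- best[idx[pi], ri]
            if (is.na(prev) || mm < prev) best[idx[pi], ri] <- mm
          }
        }
      }
    }
  }

  n_mapped <- 0L
  for (i in seq_len(nrow(best))) {
    row <- best[i, ]
    if (all(is.na(row))) next
    n_mapped <- n_mapped + 1L
    winners <- which(row == min(row, na.rm = TRUE))
    counts[winners] <- counts[winners] + 1 / length(winners)
  }
  attr(counts, "n_mapped") <- n_mapped
  counts
}

#' Construct a per-sample profile
#'
#' Carries the raw counts the relative-abundance and diversity proxies are
#' computed from. Merged and paired read totals are carried separately
#' because different metrics are normalised by different denominators.
#'
#' @param sample_id Sample identifier.
#' @param n_merged_reads,n_paired_reads Read totals.
#' @param reads_to_viral Reads mapping to viral contigs.
#' @param n_spacers,n_dr_types,n_viral_contigs,n_votus,n_spacer_clusters,n_host_classes
#'   Feature counts.
#' @param votu_read_counts Named numeric vector, reads per vOTU.
#' @param host_read_counts Named numeric vector, 16S-classified reads per
#'   host taxon.
#' @return A `sample_profile` list.
#' @export
sample_profile <- function(sample_id, n_merged_reads, n_paired_reads,
                           reads_to_viral = 0, n_spacers = 0L,
                           n_dr_types = 0L, n_viral_contigs = 0L,
                           n_votus = 0L, n_spacer_clusters = 0L,
                           n_host_classes = 0L,
                           votu_read_counts = numeric(0),
                           host_read_counts = numeric(0)) {
  if (reads_to_viral > n_merged_reads) {
    stop("sample_profile: reads_to_viral exceeds n_merged_reads in ", sample_id)
  }
  structure(list(sample_id = sample_id,
                 n_merged_reads = n_merged_reads,
                 n_paired_reads = n_paired_reads,
                 reads_to_viral = reads_to_viral,
                 n_spacers = n_spacers, n_dr_types = n_dr_types,
                 n_viral_contigs = n_viral_contigs, n_votus = n_votus,
                 n_spacer_clusters = n_spacer_clusters,
                 n_host_classes = n_host_classes,
                 votu_read_counts = votu_read_counts,
                 host_read_counts = host_read_counts),
            class = "sample_profile")
}

#' Relative abundance metrics for a sample
#'
#' Viral relative abundance is viral-mapped reads per merged read; spacer and
#' CRISPR (DR-type) abundance are per paired read. Per-vOTU abundance is
#' mapped reads divided by (vOTU total member length x merged reads).
#'
#' @param profile A [sample_profile()].
#' @param votu_lengths Named numeric vector of vOTU total member lengths
#'   (bp); required when per-vOTU counts are present.
#' @return A list with `viral_abundance`, `spacer_abundance`,
#'   `crispr_abundance` and `votu_abundance` (named vector).
#' @export
relative_abundances <- function(profile, votu_lengths = NULL) {
  if (profile$n_merged_reads <= 0 || profile$n_paired_reads <= 0) {
    stop("relative_abundances: zero reads in sample ", profile$sample_id)
  }
  votu_ab <- numeric(0)
  if (length(profile$votu_read_counts)) {
    if (is.null(votu_lengths)) {
      stop("relative_abundances: votu_lengths required for per-vOTU abundance")
    }
    vl <- votu_lengths[names(profile$votu_read_counts)]
    votu_ab <- profile$votu_read_counts / (vl * profile$n_merged_reads)
  }
  list(viral_abundance = profile$reads_to_viral / profile$n_merged_reads,
       spacer_abundance = profile$n_spacers / profile$n_paired_reads,
       crispr_abundance = profile$n_dr_types / profile$n_paired_reads,
       votu_abundance = votu_ab)
}

#' Diversity proxies for a sample
#'
#' Viral diversity is vOTUs per viral contig (undefined, and reported as NA
#' with a message, when a sample has no viral contigs); spacer diversity is
#' spacer clusters per paired read; host diversity is host classes per merged
#' read.
#'
#' @param profile A [sample_profile()].
#' @return List with `viral_diversity`, `spacer_diversity`,
#'   `host_diversity`.
#' @export
diversity_proxies <- function(profile) {
  if (profile$n_merged_reads <= 0 || profile$n_paired_reads <= 0) {
    stop("diversity_proxies: zero reads in sample ", profile$sample_id)
  }
  viral <- if (profile$n_viral_contigs > 0) {
    profile$n_votus / profile$n_viral_contigs
  } else {
    message("diversity_proxies: no viral contigs in ", profile$sample_id,
            "; viral diversity reported as missing")
    NA_real_
  }
  list(viral_diversity = viral,
       spacer_diversity = profile$n_spacer_clusters / profile$n_paired_reads,
       host_diversity = profile$n_host_classes / profile$n_merged_reads)
}

#' Rarefaction curve of expected feature richness
#'
#' Analytic mode evaluates the hypergeometric expectation
#' E\[S(d)\] = sum_i (1 - choose(N - N_i, d) / choose(N, d)) via log-scale
#' binomial coefficients; Monte-Carlo mode averages subsampled richness over
#' `reps` draws without replacement.
#'
#' @param feature_counts Named (or unnamed) non-negative integer vector of
#'   per-feature counts.
#' @param depths Integer vector of subsampling depths (all <= sum of counts).
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param reps Monte-Carlo replicates.
#' @return data.frame `depth` / `richness` (plus `se` in Monte-Carlo mode).
#' @export
rarefaction_curve <- function(feature_counts, depths,
                              mode = c("analytic", "montecarlo"),
                              reps = 500L) {
  mode <- match.arg(mode)
  feature_counts <- feature_counts[feature_counts > 0]
  N <- sum(feature_counts)
  if (any(depths < 1) || any(depths > N)) {
    stop("rarefaction_curve: depths must be within 1..", N)
  }
  if (mode == "analytic") {
    rich <- vapply(depths, function(d) {
      sum(1 - exp(lchoose(N - feature_counts, d) - lchoose(N, d)))
    }, 0)
    data.frame(depth = depths, richness = rich)
  } else {
    pool <- rep(seq_along(feature_counts), feature_counts)
    res <- vapply(depths, function(d) {
      r <- vapply(seq_len(reps), function(i) {
        length(unique(sample(pool, d)))
      }, 0L)
      c(mean(r), stats::sd(r) / sqrt(reps))
    }, c(0, 0))
    data.frame(depth = depths, richness = res[1, ], se = res[2, ])
  }
}

#' Assign viral taxonomy to vOTU representatives by best reference hit
#'
#' Each representative is aligned to the reference genomes; the best hit at
#' E-value <= `evalue_max` is selected by E-value, ties broken by percent
#' identity, then by reference identifier. Representatives with no
#' qualifying hit are `"unclassified"`.
#'
#' @param representatives Named character vector, vOTU id -> representative
#'   sequence.
#' @param references Named character vector of reference genomes.
#' @param ref_family Named character vector, reference id -> family label.
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return data.frame `votu_id`, `family`, `evalue`, `identity`.
#' @export
assign_votu_taxonomy <- function(representatives, references, ref_family,
                                 evalue_max = 1e-5) {
  total_ref <- sum(nchar(references))
  rows <- lapply(names(representatives), function(v) {
    rep_seq <- representatives[[v]]
    best <- NULL
    for (r in names(references)) {
      al <- align_pair(rep_seq, references[[r]], prefilter_k = 16L)
      if (al$score <= 0) next
      ev <- ka_evalue(al$score, nchar(rep_seq) * total_ref)
      if (ev > evalue_max) next
      cand <- list(ref = r, evalue = ev, identity = al$identity)
      if (is.null(best) ||
          cand$evalue < best$evalue ||
          (cand$evalue == best$evalue && cand$identity > best$identity) ||
          (cand$evalue == best$evalue && cand$identity == best$identity &&
             cand$ref < best$ref)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      data.frame(votu_id = v, family = "unclassified", evalue = NA_real_,
                 identity = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(votu_id = v, family = unname(ref_family[best$ref]),
                 evalue = best$evalue, identity = best$identity,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Per-sample viral family composition with rare-group collapsing
#'
#' Family abundance is the fraction of the sample's reads mapping to member
#' contigs of vOTUs assigned to the family. Families below `rare_frac` of
#' the sample's viral-mapped reads are collapsed into `"rare viral groups"`;
#' collapsing conserves the total viral-mapped fraction.
#'
#' @param votu_taxa data.frame from [assign_votu_taxonomy()].
#' @param votu_read_counts Named numeric vector, reads mapped per vOTU.
#' @param n_sample_reads Total reads in the sample (denominator).
#' @param rare_frac Collapsing threshold as a fraction of viral-mapped reads
#'   (default 0.05).
#' @return data.frame `family` / `abundance` (fraction of sample reads).
#' @export
family_composition <- function(votu_taxa, votu_read_counts, n_sample_reads,
                               rare_frac = 0.05) {
  fam <- setNames(votu_taxa$family, votu_taxa$votu_id)
  f <- fam[names(votu_read_counts)]
  f[is.na(f)] <- "unclassified"
  per_fam <- tapply(votu_read_counts, f, sum)
  viral_total <- sum(votu_read_counts)
  rare <- viral_total > 0 & (per_fam / viral_total) < rare_frac
  if (any(rare)) {
    collapsed <- c(per_fam[!rare], "rare viral groups" = sum(per_fam[rare]))
  } else {
    collapsed <- per_fam
  }
  data.frame(family = names(collapsed),
             abundance = as.numeric(collapsed) / n_sample_reads,
             stringsAsFactors = FALSE)
}
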