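## End-to-end pipeline over a (simulated or externally loaded) study:
## CRISPR detection per sample, global vOTU clustering, per-sample DR->MAG
## and spacer->protospacer matching with networks assembled per region, plus
## recovery metrics against planted ground truth.

#' Run the CRISPR-informed infection pipeline on a simulated community
#'
#' Steps: (1) cluster all viral contigs (study-wide) into vOTUs; (2) per
#' sample, detect CRISPR arrays on MAG contigs (memoised by sequence, since
#' the same genome recurs across samples), pool spacers by DR type, link DR
#' types to MAGs by exact occurrence, and match the sample's spacers against
#' the viral contigs of the sample's region; (3) assemble per-sample edges.
#' Networks are computed within regions: spacers are only searched against
#' their own region's viral contigs, so no edge ever crosses regions.
#'
#' @param sim A `vent_simulation` from [simulate_community()].
#' @param max_mismatch Spacer-protospacer mismatch bound (default 1).
#' @param crispr Detection parameters ([crispr_params()]).
#' @return A `pipeline_result` list with `network` (edge data.frame over all
#'   samples), `votu_membership`, `arrays` (per sample), `dr_types` (per
#'   sample), `spacers` (per sample, named vectors), and `hits` (per
#'   sample).
#' @export
run_infection_pipeline <- function(sim, max_mismatch = 1L,
                                   crispr = crispr_params()) {
  ## study-wide viral contigs and vOTUs
  viral_contigs <- unlist(lapply(sim$samples, function(s) {
    s$contigs[s$contig_role == "viral"]
  }))
  ## names arrive as "<sample>.<contig>" from unlist; restore contig ids
  names(viral_contigs) <- unlist(lapply(sim$samples, function(s) {
    names(s$contigs)[s$contig_role == "viral"]
  }))
  votu_membership <- cluster_votus(viral_contigs)

  region_of_sample <- setNames(sim$metadata$region, sim$metadata$sample_id)
  region_contigs <- lapply(unique(sim$metadata$region), function(r) {
    sids <- sim$metadata$sample_id[sim$metadata$region == r]
    out <- unlist(lapply(sim$samples[sids], function(s) {
      s$contigs[s$contig_role == "viral"]
    }))
    names(out) <- unlist(lapply(sim$samples[sids], function(s) {
      names(s$contigs)[s$contig_role == "viral"]
    }))
    out
  })
  names(region_contigs) <- unique(sim$metadata$region)

  array_cache <- new.env(parent = emptyenv())
  edges <- list()
  arrays_by_sample <- list()
  dr_types_by_sample <- list()
  spacers_by_sample <- list()
  hits_by_sample <- list()

  for (sid in names(sim$samples)) {
    s <- sim$samples[[sid]]
    mag_contig_ids <- names(s$contigs)[s$contig_role == "mag"]
    mags <- mag_records(s$mag_table)

    arrays <- list()
    for (cid in mag_contig_ids) {
      g <- s$contigs[[cid]]
      key <- substr(g, 1, 64)  # memoise by sequence prefix + length
      key <- paste0(key, "_", nchar(g))
      cached <- array_cache[[key]]
      if (is.null(cached) || cached$seq != g) {
        found <- detect_arrays(g, params = crispr, source_id = cid)
        array_cache[[key]] <- list(seq = g, arrays = found)
        cached <- array_cache[[key]]
      }
      for (a in cached$arrays) {
        a$source_id <- cid
        arrays[[length(arrays) + 1L]] <- a
      }
    }
    dr_types <- pool_spacers_by_dr_type(arrays, sid)
    spacers <- dr_type_spacers(dr_types, sid)

    links <- match_dr_to_mags(dr_types, mags, s$contigs[mag_contig_ids])

    rcontigs <- region_contigs[[region_of_sample[[sid]]]]
    hits <- if (length(spacers) && length(rcontigs)) {
      match_spacers_to_protospacers(spacers, rcontigs,
                                    max_mismatch = max_mismatch)
    } else {
      match_spacers_to_protospacers(character(0), character(0))
    }

    taxonomy <- setNames(mags$taxonomy, mags$bin_id)
    edges[[sid]] <- build_infection_network(links, dr_types, hits,
                                            votu_membership, sid,
                                            mag_taxonomy = taxonomy)
    arrays_by_sample[[sid]] <- arrays
    dr_types_by_sample[[sid]] <- dr_types
    spacers_by_sample[[sid]] <- spacers
    hits_by_sample[[sid]] <- hits
  }

  network <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
  structure(list(network = network, votu_membership = votu_membership,
                 arrays = arrays_by_sample, dr_types = dr_types_by_sample,
                 spacers = spacers_by_sample, hits = hits_by_sample),
            class = "pipeline_result")
}

#' Evaluate recovered network edges against the planted ground truth
#'
#' Maps MAG ids to planted hosts (bins are hosts in the simulator) and vOTUs
#' to planted lineages (via the simulator's contig-to-genome map and the
#' run's vOTU membership), then compares distinct (host, lineage) pairs.
#'
#' @param result A `pipeline_result` from [run_infection_pipeline()].
#' @param sim The `vent_simulation` the pipeline ran on.
#' @return List with `precision`, `recall`, `n_recovered`, `n_planted`,
#'   `false_pairs` and `missed_pairs` (data.frames).
#' @export
evaluate_network_recovery <- function(result, sim) {
  net <- result$network
  planted <- unique(sim$ground_truth$edges[, c("host_id", "lineage_id")])

  if (is.null(net) || nrow(net) == 0) {
    recovered <- planted[0, ]
  } else {
    vl <- votu_lineage_map(result$votu_membership, sim)
    recovered <- unique(data.frame(host_id = net$mag_id,
                                   lineage_id = unname(vl[net$votu_id]),
                                   stringsAsFactors = FALSE))
  }
  key <- function(df) paste(df$host_id, df$lineage_id)
  tp <- sum(key(recovered) %in% key(planted))
  precision <- if (nrow(recovered)) tp / nrow(recovered) else NA_real_
  recall <- if (nrow(planted)) tp / nrow(planted) else NA_real_
  list(precision = precision, recall = recall,
       n_recovered = nrow(recovered), n_planted = nrow(planted),
       false_pairs = recovered[!key(recovered) %in% key(planted), ,
                               drop = FALSE],
       missed_pairs = planted[!key(planted) %in% key(recovered), ,
                              drop = FALSE])
}

#' Map vOTUs to planted lineages (majority over member contigs)
#'
#' @param votu_membership Membership table from [cluster_votus()].
#' @param sim The `vent_simulation` that supplied the contigs.
#' @return Named character vector votu_id -> lineage id.
#' @export
votu_lineage_map <- function(votu_membership, sim) {
  contig_genome <- unlist(lapply(sim$samples, function(s) s$contig_genome))
  names(contig_genome) <- unlist(lapply(sim$samples, function(s) {
    names(s$contig_genome)
  }))
  lin <- sim$ground_truth$lineage_map[contig_genome[votu_membership$contig_id]]
  tab <- tapply(lin, votu_membership$votu_id,
                function(x) names(sort(-table(x)))[1])
  unlist(as.list(tab))
}

#' vOTU read-count composition table from simulator ground truth
#'
#' Aggregates the simulator's per-genome read counts to vOTUs using a
#' membership table, giving the samples x vOTUs count matrix that the
#' compositional clustering consumes (the counts-table input path of the
#' pipeline).
#'
#' @param sim A `vent_simulation`.
#' @param votu_membership Membership from [cluster_votus()] run on the
#'   simulation's viral contigs.
#' @return Numeric matrix samples x vOTUs of read counts.
#' @export
votu_count_table <- function(sim, votu_membership) {
  contig_genome <- unlist(lapply(sim$samples, function(s) s$contig_genome))
  names(contig_genome) <- unlist(lapply(sim$samples, function(s) {
    names(s$contig_genome)
  }))
  genome_votu_rows <- data.frame(
    sample_id = sub("_.*$", "", votu_membership$contig_id),
    genome_id = unname(contig_genome[votu_membership$contig_id]),
    votu_id = votu_membership$votu_id, stringsAsFactors = FALSE)
  rc <- sim$ground_truth$read_counts
  merged <- merge(rc, genome_votu_rows, by = c("sample_id", "genome_id"))
  votus <- sort(unique(votu_membership$votu_id))
  samples <- sim$metadata$sample_id
  out <- matrix(0, length(samples), length(votus),
                dimnames = list(samples, votus))
  if (nrow(merged)) {
    for (i in seq_len(nrow(merged))) {
      out[merged$sample_id[i], merged$votu_id[i]] <-
        out[merged$sample_id[i], merged$votu_id[i]] + merged$reads[i]
    }
  }
  out
}

#' Feature-by-site incidence from a per-sample count matrix
#'
#' Presence is >= 1 count in any sample of the site.
#'
#' @param counts Samples x features matrix.
#' @param metadata data.frame with `sample_id`, `site`, `field`, `region`.
#' @return An [incidence_matrix()] (features x sites).
#' @export
counts_to_incidence <- function(counts, metadata) {
  sites <- unique(metadata$site)
  mat <- sapply(sites, function(st) {
    sids <- metadata$sample_id[metadata$site == st]
    colSums(counts[sids, , drop = FALSE]) > 0
  })
  ## drop features absent everywhere (cannot sit in an incidence matrix)
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  hier <- unique(metadata[, c("site", "field", "region")])
  incidence_matrix(mat, hier)
}
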