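## Synthetic vent-community simulator. Generates a structured viral population,
## CRISPR-bearing host genomes whose spacers sample that population, and
## per-sample contigs/reads/tables, together with the planted ground truth the
## recovery tests assert against. Coordinates are 0-based half-open, forward
## strand throughout.

#' Configuration for the synthetic vent community
#'
#' Defaults describe a desk-scale study with the sampling design of a
#' multi-region vent survey: three regions (stand-ins for, e.g., Axial
#' Seamount and the Von Damm and Piccard vent fields), three vent sites per
#' region, and one sample per site per year over two years.
#'
#' @param n_regions Number of geographic regions.
#' @param sites_per_region Vent sites per region.
#' @param samples_per_site Samples (years) per site.
#' @param n_viral_lineages Number of unrelated viral lineages.
#' @param variants_per_lineage Genome variants per lineage.
#' @param viral_genome_len Viral genome length (bp).
#' @param within_lineage_divergence Per-site substitution rate of a variant
#'   relative to its lineage ancestor. Values below 0.05 keep planted
#'   lineages within the 95%-identity vOTU threshold.
#' @param n_hosts Number of host (microbial) genomes.
#' @param host_genome_len Host genome length (bp).
#' @param arrays_per_host CRISPR arrays per host genome.
#' @param spacers_per_array Spacers per array.
#' @param dr_len Direct-repeat length (bp), in 23--47.
#' @param spacer_len Spacer length (bp), in 26--50.
#' @param protospacer_mismatches Exact number of substitutions applied to each
#'   planted spacer relative to its protospacer (0--3).
#' @param site_endemism Probability that a viral lineage is endemic to its
#'   home region (present at all of that region's sites and nowhere else);
#'   otherwise it is cosmopolitan (present at every site of every region).
#' @param read_len Read length (bp); must be at least 31.
#' @param reads_per_sample Reads drawn per sample.
#' @param depth_dispersion sdlog of the lognormal per-genome depth weights.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_regions = 3L,
                              sites_per_region = 3L,
                              samples_per_site = 2L,
                              n_viral_lineages = 20L,
                              variants_per_lineage = 2L,
                              viral_genome_len = 4000L,
                              within_lineage_divergence = 0.02,
                              n_hosts = 8L,
                              host_genome_len = 12000L,
                              arrays_per_host = 1L,
                              spacers_per_array = 6L,
                              dr_len = 28L,
                              spacer_len = 34L,
                              protospacer_mismatches = 1L,
                              site_endemism = 0.8,
                              read_len = 100L,
                              reads_per_sample = 2000L,
                              depth_dispersion = 0.7,
                              seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    sites_per_region = as.integer(sites_per_region),
    samples_per_site = as.integer(samples_per_site),
    n_viral_lineages = as.integer(n_viral_lineages),
    variants_per_lineage = as.integer(variants_per_lineage),
    viral_genome_len = as.integer(viral_genome_len),
    within_lineage_divergence = as.numeric(within_lineage_divergence),
    n_hosts = as.integer(n_hosts),
    host_genome_len = as.integer(host_genome_len),
    arrays_per_host = as.integer(arrays_per_host),
    spacers_per_array = as.integer(spacers_per_array),
    dr_len = as.integer(dr_len),
    spacer_len = as.integer(spacer_len),
    protospacer_mismatches = as.integer(protospacer_mismatches),
    site_endemism = as.numeric(site_endemism),
    read_len = as.integer(read_len),
    reads_per_sample = as.integer(reads_per_sample),
    depth_dispersion = as.numeric(depth_dispersion),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c("n_regions", "sites_per_region", "samples_per_site",
              "n_viral_lineages", "variants_per_lineage", "viral_genome_len",
              "n_hosts", "host_genome_len", "arrays_per_host",
              "spacers_per_array", "reads_per_sample")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("invalid configuration: '", f, "' must be a count >= 1")
    }
  }
  if (cfg$within_lineage_divergence < 0 || cfg$within_lineage_divergence >= 1) {
    stop("invalid configuration: 'within_lineage_divergence' must be in [0, 1)")
  }
  if (cfg$dr_len < 23L || cfg$dr_len > 47L) {
    stop("invalid configuration: 'dr_len' must be within 23-47 bp")
  }
  if (cfg$spacer_len < 26L || cfg$spacer_len > 50L) {
    stop("invalid configuration: 'spacer_len' must be within 26-50 bp")
  }
  if (cfg$spacer_len > cfg$viral_genome_len) {
    stop("invalid configuration: 'spacer_len' exceeds 'viral_genome_len'")
  }
  if (cfg$protospacer_mismatches < 0L || cfg$protospacer_mismatches > 3L) {
    stop("invalid configuration: 'protospacer_mismatches' must be in 0-3")
  }
  if (cfg$site_endemism < 0 || cfg$site_endemism > 1) {
    stop("invalid configuration: 'site_endemism' must be a probability")
  }
  if (cfg$read_len < 31L) {
    stop("invalid configuration: 'read_len' must be >= 31 bp")
  }
  if (cfg$read_len > cfg$viral_genome_len || cfg$read_len > cfg$host_genome_len) {
    stop("invalid configuration: 'read_len' exceeds a genome length")
  }
  arr_len <- cfg$arrays_per_host *
    ((cfg$spacers_per_array + 1L) * cfg$dr_len +
       cfg$spacers_per_array * cfg$spacer_len)
  if (arr_len >= cfg$host_genome_len) {
    stop("invalid configuration: 'host_genome_len' too short for the arrays")
  }
  invisible(cfg)
}

## Site table: region / field / site identifiers. One vent field per region
## keeps the hierarchy a tree without adding a free parameter.
site_table <- function(cfg) {
  regions <- sprintf("region%02d", seq_len(cfg$n_regions))
  data.frame(
    region = rep(regions, each = cfg$sites_per_region),
    field = rep(regions, each = cfg$sites_per_region),
    site = paste0(rep(regions, each = cfg$sites_per_region), "_site",
                  rep(seq_len(cfg$sites_per_region), cfg$n_regions)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a structured viral population
#'
#' Lineage ancestors are independent uniform-random genomes; variants within a
#' lineage carry i.i.d. substitutions at rate `within_lineage_divergence`.
#' Each lineage is assigned a home region (round robin) and is either endemic
#' to that region or cosmopolitan, with probability `site_endemism`.
#'
#' Uses the current RNG stream; callers wanting reproducibility set the seed
#' (as [simulate_community()] does).
#'
#' @param cfg A [simulation_config()].
#' @return A `viral_population` list with elements `genomes` (named character
#'   vector of variant genomes), `ancestors`, `lineage_map` (variant ->
#'   lineage), `lineage_region`, and `site_occupancy` (lineage -> character
#'   vector of site ids).
#' @export
simulate_viral_population <- function(cfg) {
  validate_config(cfg)
  sites <- site_table(cfg)
  lineages <- sprintf("L%02d", seq_len(cfg$n_viral_lineages))
  regions <- unique(sites$region)
  home <- setNames(rep(regions, length.out = cfg$n_viral_lineages), lineages)

  ancestors <- setNames(
    vapply(lineages, function(l) random_dna(cfg$viral_genome_len), ""),
    lineages
  )

  genomes <- character(0)
  lineage_map <- character(0)
  for (l in lineages) {
    for (v in seq_len(cfg$variants_per_lineage)) {
      id <- sprintf("v_%s_%d", l, v)
      nmut <- stats::rbinom(1L, cfg$viral_genome_len,
                            cfg$within_lineage_divergence)
      genomes[[id]] <- mutate_bases(ancestors[[l]], nmut)
      lineage_map[[id]] <- l
    }
  }

  occupancy <- lapply(lineages, function(l) {
    if (runif(1) < cfg$site_endemism) {
      sites$site[sites$region == home[[l]]]
    } else {
      sites$site
    }
  })
  names(occupancy) <- lineages

  structure(list(genomes = genomes, ancestors = ancestors,
                 lineage_map = lineage_map, lineage_region = home,
                 site_occupancy = occupancy, sites = sites),
            class = "viral_population")
}

## Draw a direct repeat that is absent (both strands) from all given genomes
## and cannot overlap itself, so detection boundaries are exact.
draw_unique_dr <- function(len, genomes) {
  repeat {
    dr <- random_dna(len)
    dd <- paste0(dr, substr(dr, 1L, len - 1L))
    self_hits <- gregexpr(dr, dd, fixed = TRUE)[[1]]
    if (length(self_hits) != 1L) next  # self-overlapping period
    rc <- revcomp(dr)
    if (dr == rc) next
    found <- any(vapply(genomes, function(g) {
      grepl(dr, g, fixed = TRUE) || grepl(rc, g, fixed = TRUE)
    }, logical(1)))
    if (!found) return(dr)
  }
}

#' Simulate host genomes carrying CRISPR arrays targeting the viral population
#'
#' Each host receives a host-specific direct repeat (rejection-sampled to be
#' absent everywhere else) and `arrays_per_host` arrays of alternating exact
#' repeat copies and spacers. Spacers are copied from random positions of
#' genomes of lineages homed in the host's region, with exactly
#' `protospacer_mismatches` substitutions.
#'
#' @param cfg A [simulation_config()].
#' @param vpop Output of [simulate_viral_population()].
#' @return A `host_set` list with `genomes`, `host_region`, `taxonomy`,
#'   `mag_stats`, and `ground_truth` (`edges`, `arrays`, `protospacers`).
#' @export
simulate_hosts_with_crispr <- function(cfg, vpop) {
  validate_config(cfg)
  hosts <- sprintf("h%02d", seq_len(cfg$n_hosts))
  regions <- unique(vpop$sites$region)
  host_region <- setNames(rep(regions, length.out = cfg$n_hosts), hosts)

  taxa <- c("Bacteria;Aquificae", "Bacteria;Campylobacteria",
            "Archaea;Methanomicrobia", "Bacteria;Clostridia",
            "Bacteria;Ignavibacteria", "Bacteria;Desulfobacterales",
            "Archaea;Thermococci", "Bacteria;Sulfurovum")
  taxonomy <- setNames(rep(taxa, length.out = cfg$n_hosts), hosts)

  genomes <- character(0)
  edge_rows <- list()
  array_rows <- list()
  proto_rows <- list()

  for (h in hosts) {
    pool <- names(vpop$lineage_region)[vpop$lineage_region == host_region[[h]]]
    if (length(pool) == 0) pool <- names(vpop$lineage_region)
    dr <- draw_unique_dr(cfg$dr_len, c(vpop$genomes, genomes))

    arr_len <- (cfg$spacers_per_array + 1L) * cfg$dr_len +
      cfg$spacers_per_array * cfg$spacer_len
    total_arr <- cfg$arrays_per_host * arr_len
    backbone_len <- cfg$host_genome_len - total_arr

    repeat {
      backbone <- random_dna(backbone_len)
      if (!grepl(dr, backbone, fixed = TRUE) &&
          !grepl(revcomp(dr), backbone, fixed = TRUE)) break
    }

    ## insertion points for each array in the backbone, kept well apart
    seg <- floor(backbone_len / cfg$arrays_per_host)
    genome <- ""
    consumed <- 0L
    offset_in_genome <- 0L
    for (a in seq_len(cfg$arrays_per_host)) {
      lo <- (a - 1L) * seg
      hi <- a * seg - 1L
      ins <- lo + sample.int(hi - lo - 1L, 1L)  # 0-based pos in backbone

      spacers <- character(cfg$spacers_per_array)
      for (s in seq_len(cfg$spacers_per_array)) {
        lin <- sample(pool, 1L)
        variants <- names(vpop$lineage_map)[vpop$lineage_map == lin]
        var <- sample(variants, 1L)
        g <- vpop$genomes[[var]]
        ## substitutions are planted at positions conserved across all
        ## variants of the lineage, so the planted mismatch count is exact
        ## against every genome of the target lineage (and a fortiori
        ## against unrelated lineages)
        repeat {
          start0 <- sample.int(nchar(g) - cfg$spacer_len + 1L, 1L) - 1L
          window <- lapply(vpop$genomes[variants], function(vg) {
            substr(vg, start0 + 1L, start0 + cfg$spacer_len)
          })
          cols <- do.call(rbind, lapply(window, function(w) {
            strsplit(w, "", fixed = TRUE)[[1]]
          }))
          conserved <- which(apply(cols, 2, function(cc) {
            length(unique(cc)) == 1L
          }))
          if (length(conserved) >= cfg$protospacer_mismatches) break
        }
        proto <- substr(g, start0 + 1L, start0 + cfg$spacer_len)
        sp <- strsplit(proto, "", fixed = TRUE)[[1]]
        if (cfg$protospacer_mismatches > 0L) {
          mut_at <- conserved[sample.int(length(conserved),
                                         cfg$protospacer_mismatches)]
          for (p in mut_at) sp[p] <- sample(setdiff(DNA_BASES, sp[p]), 1L)
        }
        spacers[s] <- paste(sp, collapse = "")
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          host_id = h, lineage_id = lin, variant_id = var,
          stringsAsFactors = FALSE)
        proto_rows[[length(proto_rows) + 1L]] <- data.frame(
          host_id = h, array_index = a, spacer_ordinal = s,
          spacer = spacers[s], variant_id = var, start = start0,
          end = start0 + cfg$spacer_len,
          n_mismatches = cfg$protospacer_mismatches,
          stringsAsFactors = FALSE)
      }
      array_seq <- paste0(dr, paste0(spacers, dr, collapse = ""))
      pre <- substr(backbone, consumed + 1L, ins)
      genome <- paste0(genome, pre, array_seq)
      array_start <- offset_in_genome + nchar(pre)
      rep_starts <- array_start +
        (0:cfg$spacers_per_array) * (cfg$dr_len + cfg$spacer_len)
      array_rows[[length(array_rows) + 1L]] <- data.frame(
        host_id = h, array_index = a,
        array_start = array_start,
        array_end = array_start + arr_len,
        dr = dr,
        repeat_starts = I(list(rep_starts)),
        spacers = I(list(spacers)),
        stringsAsFactors = FALSE)
      offset_in_genome <- offset_in_genome + nchar(pre) + arr_len
      consumed <- ins
    }
    genome <- paste0(genome, substr(backbone, consumed + 1L, backbone_len))
    stopifnot(nchar(genome) == cfg$host_genome_len)

    ## junctions must not have created extra DR copies
    n_fwd <- length(gregexpr(dr, genome, fixed = TRUE)[[1]])
    stopifnot(n_fwd == cfg$arrays_per_host * (cfg$spacers_per_array + 1L))
    genomes[[h]] <- genome
  }

  edges <- unique(do.call(rbind, edge_rows)[, c("host_id", "lineage_id")])
  counts <- aggregate(list(n_spacers = rep(1L, length(edge_rows))),
                      by = list(host_id = vapply(edge_rows, `[[`, "", "host_id"),
                                lineage_id = vapply(edge_rows, `[[`, "", "lineage_id")),
                      FUN = sum)
  edges <- merge(edges, counts, by = c("host_id", "lineage_id"))
  edges$max_mismatches <- cfg$protospacer_mismatches
  edges <- edges[order(edges$host_id, edges$lineage_id), ]
  rownames(edges) <- NULL

  mag_stats <- data.frame(
    mag_id = hosts,
    taxonomy = unname(taxonomy),
    completeness = round(runif(cfg$n_hosts, 85, 99), 1),
    redundancy = round(runif(cfg$n_hosts, 0, 6), 1),
    stringsAsFactors = FALSE
  )

  structure(list(
    genomes = genomes,
    host_region = host_region,
    taxonomy = taxonomy,
    mag_stats = mag_stats,
    ground_truth = list(
      edges = edges,
      arrays = do.call(rbind, array_rows),
      protospacers = do.call(rbind, proto_rows)
    )
  ), class = "host_set")
}

#' Simulate per-sample contigs, reads and tables
#'
#' Hosts are present in every sample; viral variants are present where their
#' lineage's site occupancy says so. Present genomes are emitted as contigs;
#' reads are drawn from present genomes with lognormal per-genome depth
#' weights (sdlog = `depth_dispersion`) and uniform start positions. Each
#' sample's reads use an RNG substream seeded at a fixed offset from the
#' global seed so samples can be regenerated independently.
#'
#' @param cfg A [simulation_config()].
#' @param hosts Output of [simulate_hosts_with_crispr()].
#' @param vpop Output of [simulate_viral_population()].
#' @return A `vent_simulation` object; see [simulate_community()].
#' @export
simulate_samples <- function(cfg, hosts, vpop) {
  validate_config(cfg)
  sites <- vpop$sites
  years <- 2012L + seq_len(cfg$samples_per_site)
  metadata <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    data.frame(site = sites$site[i], field = sites$field[i],
               region = sites$region[i], year = years,
               type = "diffuse flow", stringsAsFactors = FALSE)
  }))
  metadata$sample_id <- sprintf("S%02d", seq_len(nrow(metadata)))
  metadata <- metadata[, c("sample_id", "region", "field", "site", "year", "type")]

  ## variants present per site
  variant_sites <- lapply(names(vpop$genomes), function(v) {
    vpop$site_occupancy[[vpop$lineage_map[[v]]]]
  })
  names(variant_sites) <- names(vpop$genomes)

  samples <- vector("list", nrow(metadata))
  names(samples) <- metadata$sample_id
  count_rows <- list()

  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    site <- metadata$site[i]
    present_variants <- names(variant_sites)[
      vapply(variant_sites, function(s) site %in% s, logical(1))]
    if (length(present_variants) == 0L) {
      warning("sample ", sid, " has no viral lineage at site ", site,
              "; emitted with hosts only")
    }

    host_contig_ids <- sprintf("%s_%s_c1", sid, names(hosts$genomes))
    viral_contig_ids <- if (length(present_variants)) {
      sprintf("%s_%s", sid, present_variants)
    } else character(0)

    contigs <- c(setNames(unname(hosts$genomes), host_contig_ids),
                 setNames(unname(vpop$genomes[present_variants]),
                          viral_contig_ids))
    contig_genome <- c(setNames(names(hosts$genomes), host_contig_ids),
                       setNames(present_variants, viral_contig_ids))
    contig_role <- c(setNames(rep("mag", length(host_contig_ids)),
                              host_contig_ids),
                     setNames(rep("viral", length(viral_contig_ids)),
                              viral_contig_ids))

    mag_table <- data.frame(
      contig_id = host_contig_ids,
      bin_id = names(hosts$genomes),
      taxonomy = unname(hosts$taxonomy[names(hosts$genomes)]),
      completeness = hosts$mag_stats$completeness[
        match(names(hosts$genomes), hosts$mag_stats$mag_id)],
      redundancy = hosts$mag_stats$redundancy[
        match(names(hosts$genomes), hosts$mag_stats$mag_id)],
      stringsAsFactors = FALSE
    )

    ## reads: dedicated substream at a fixed offset per sample
    set.seed((cfg$seed %% 1000000L) + 100000L + i)
    viral_score <- round(runif(length(viral_contig_ids), 0.001, 0.049), 4)
    viral_labels <- data.frame(contig_id = viral_contig_ids,
                               score = viral_score,
                               stringsAsFactors = FALSE)

    genome_ids <- c(names(hosts$genomes), present_variants)
    genome_seqs <- c(hosts$genomes, vpop$genomes[present_variants])
    w <- rlnorm(length(genome_ids), meanlog = 0, sdlog = cfg$depth_dispersion)
    eff_len <- vapply(genome_seqs, nchar, 0L) - cfg$read_len + 1L
    prob <- w * eff_len
    n_per_genome <- as.vector(rmultinom(1L, cfg$reads_per_sample,
                                        prob / sum(prob)))
    reads <- character(cfg$reads_per_sample)
    src <- character(cfg$reads_per_sample)
    k <- 0L
    for (gi in seq_along(genome_ids)) {
      ng <- n_per_genome[gi]
      if (ng == 0L) next
      starts <- sample.int(eff_len[gi], ng, replace = TRUE)
      reads[k + seq_len(ng)] <- substring(genome_seqs[[gi]], starts,
                                          starts + cfg$read_len - 1L)
      src[k + seq_len(ng)] <- genome_ids[gi]
      k <- k + ng
    }
    names(reads) <- sprintf("%s_r%05d", sid, seq_len(cfg$reads_per_sample))

    count_rows[[i]] <- data.frame(sample_id = sid, genome_id = genome_ids,
                                  reads = n_per_genome,
                                  depth_weight = w,
                                  stringsAsFactors = FALSE)

    samples[[sid]] <- list(contigs = contigs, contig_genome = contig_genome,
                           contig_role = contig_role, reads = reads,
                           read_source = src, mag_table = mag_table,
                           viral_labels = viral_labels)
  }

  structure(list(
    config = cfg, vpop = vpop, hosts = hosts,
    metadata = metadata, samples = samples,
    ground_truth = c(hosts$ground_truth,
                     list(lineage_map = vpop$lineage_map,
                          site_occupancy = vpop$site_occupancy,
                          read_counts = do.call(rbind, count_rows)))
  ), class = "vent_simulation")
}

#' Simulate a full synthetic vent community
#'
#' Orchestrates [simulate_viral_population()], [simulate_hosts_with_crispr()]
#' and [simulate_samples()] under the configuration's seed. The same
#' configuration always yields byte-identical results.
#'
#' @param cfg A [simulation_config()].
#' @return A `vent_simulation` object with `config`, `vpop`, `hosts`,
#'   `metadata`, per-sample data in `samples`, and `ground_truth`.
#' @export
#' @examples
#' sim <- simulate_community(simulation_config(
#'   n_viral_lineages = 4, n_hosts = 2, reads_per_sample = 50, seed = 7))
#' names(sim$samples)
simulate_community <- function(cfg) {
  validate_config(cfg)
  set.seed(cfg$seed)
  vpop <- simulate_viral_population(cfg)
  hosts <- simulate_hosts_with_crispr(cfg, vpop)
  simulate_samples(cfg, hosts, vpop)
}

#' Write a simulated community to disk
#'
#' Emits, per sample, contig and read FASTA plus MAG and viral-label TSVs,
#' together with study-wide metadata and ground-truth tables. All files are
#' plain text.
#'
#' @param sim A `vent_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  gt <- sim$ground_truth
  write_tsv(gt$edges, file.path(dir, "ground_truth_edges.tsv"))
  write_tsv(gt$read_counts, file.path(dir, "ground_truth_read_counts.tsv"))
  for (sid in names(sim$samples)) {
    s <- sim$samples[[sid]]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    write_fasta(s$contigs, file.path(sdir, "contigs.fasta"))
    write_fasta(s$reads, file.path(sdir, "reads.fasta"))
    write_tsv(s$mag_table, file.path(sdir, "mags.tsv"))
    write_tsv(s$viral_labels, file.path(sdir, "viral_labels.tsv"))
  }
  invisible(dir)
}
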