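# DR-to-MAG matching, spacer-protospacer search, network assembly and
# summaries.

make_mag_table <- function(bins, contig_ids, taxa = NULL,
                           completeness = 95, redundancy = 2) {
  data.frame(contig_id = contig_ids, bin_id = bins,
             taxonomy = if (is.null(taxa)) "Bacteria;X" else taxa,
             completeness = completeness, redundancy = redundancy,
             stringsAsFactors = FALSE)
}

test_that("MAG quality filter retains >=70% complete, <=10% redundant bins", {
  tab <- make_mag_table(c("m1", "m2", "m3"), c("c1", "c2", "c3"),
                        completeness = c(95, 60, 80),
                        redundancy = c(2, 2, 15))
  expect_identical(mag_records(tab)$bin_id, "m1")
})

test_that("DR-to-MAG links require exact full-length occurrence", {
  set.seed(41)
  dr <- canonical_dr(rand_seq(28))
  g1 <- paste0(rand_seq(300), dr, rand_seq(300))
  g2 <- paste0(rand_seq(300), substitute_at(dr, 14), rand_seq(300))
  g3 <- paste0(rand_seq(200), rc_str(dr), rand_seq(200))  # other strand
  contigs <- c(c1 = g1, c2 = g2, c3 = g3)
  mags <- make_mag_table(c("magA", "magB", "magC"), c("c1", "c2", "c3"))
  dt <- list(structure(list(sample_id = "S", canonical_dr = dr,
                            spacers = character(0), source_arrays = 1L),
                       class = "dr_type"))
  links <- match_dr_to_mags(dt, mags, contigs)
  expect_setequal(links$mag_id, c("magA", "magC"))   # 1 mismatch never links
})

test_that("spacer-protospacer matching is exact, stranded and bounded", {
  set.seed(42)
  contig <- rand_seq(2000)
  sp0 <- substr(contig, 501, 534)
  sp1 <- substitute_at(sp0, 10)
  sp2 <- substitute_at(sp0, c(10, 20))
  spm <- rc_str(substr(contig, 1001, 1034))
  spacers <- c(s0 = sp0, s1 = sp1, s2 = sp2, sm = spm)

  h1 <- match_spacers_to_protospacers(spacers, c(ctg = contig),
                                      max_mismatch = 1)
  expect_identical(h1$n_mismatches[h1$spacer_id == "s0"], 0L)
  expect_identical(h1$start[h1$spacer_id == "s0"], 500L)
  expect_identical(h1$end[h1$spacer_id == "s0"], 534L)
  expect_identical(h1$n_mismatches[h1$spacer_id == "s1"], 1L)
  expect_false("s2" %in% h1$spacer_id)
  expect_identical(h1$strand[h1$spacer_id == "sm"], "-")
  expect_identical(h1$start[h1$spacer_id == "sm"], 1000L)

  h3 <- match_spacers_to_protospacers(spacers, c(ctg = contig),
                                      max_mismatch = 3)
  expect_true("s2" %in% h3$spacer_id)
  # monotonicity: every mm<=1 hit remains at mm<=3
  key <- function(h) paste(h$spacer_id, h$contig_id, h$start, h$strand)
  expect_true(all(key(h1) %in% key(h3)))

  expect_warning(
    match_spacers_to_protospacers(c(short = rand_seq(20)), c(ctg = contig)),
    "26 bp")
})

test_that("matching agrees exactly with the naive all-positions scan", {
  set.seed(43)
  contigs <- setNames(vapply(1:3, function(i) rand_seq(5000), ""),
                      paste0("c", 1:3))
  spacers <- character(0)
  for (i in 1:10) {
    src <- sample(3, 1)
    st <- sample(4960, 1)
    sp <- substr(contigs[[src]], st, st + 33)
    sp <- substitute_at(sp, sample(34, sample(0:2, 1)))
    if (i %% 3 == 0) sp <- rc_str(sp)
    spacers[[sprintf("sp%02d", i)]] <- sp
  }
  for (i in 11:20) spacers[[sprintf("sp%02d", i)]] <- rand_seq(34)
  for (mm in 0:2) {
    got <- match_spacers_to_protospacers(spacers, contigs, max_mismatch = mm)
    want <- naive_hamming_scan(spacers, contigs, max_mm = mm)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("network assembly links, deduplicates, and flags shared DR types", {
  set.seed(44)
  # two viral contigs in two vOTUs
  v1 <- rand_seq(1000); v2 <- rand_seq(1000)
  votu <- data.frame(contig_id = c("vc1", "vc2"),
                     votu_id = c("vOTU0001", "vOTU0002"),
                     is_representative = TRUE,
                     contig_length = 1000L, stringsAsFactors = FALSE)
  dr1 <- canonical_dr(rand_seq(28)); dr2 <- canonical_dr(rand_seq(28))
  dt <- list(
    structure(list(sample_id = "S", canonical_dr = dr1,
                   spacers = substr(v1, 101, 134), source_arrays = 1L),
              class = "dr_type"),
    structure(list(sample_id = "S", canonical_dr = dr2,
                   spacers = substr(v2, 201, 234), source_arrays = 2L),
              class = "dr_type"))
  spacers <- dr_type_spacers(dt, "S")
  hits <- match_spacers_to_protospacers(spacers, c(vc1 = v1, vc2 = v2))
  links <- data.frame(canonical_dr = c(dr1, dr2, dr2),
                      mag_id = c("magA", "magA", "magB"),
                      stringsAsFactors = FALSE)
  net <- build_infection_network(links, dt, hits, votu, "S",
                                 mag_taxonomy = c(magA = "Bacteria;X",
                                                  magB = "Archaea;Y"))
  expect_identical(nrow(net), 3L)
  e1 <- net[net$canonical_dr == dr1, ]
  expect_identical(e1$mag_id, "magA")
  expect_false(e1$ambiguous)
  e2 <- net[net$canonical_dr == dr2, ]
  expect_setequal(e2$mag_id, c("magA", "magB"))
  expect_true(all(e2$ambiguous))

  # no hits -> empty network
  empty <- build_infection_network(links, dt, hits[0, ], votu, "S")
  expect_identical(nrow(empty), 0L)

  # hit contig absent from the vOTU table is skipped with a message
  expect_message(
    smaller <- build_infection_network(links, dt, hits, votu[1, ], "S"),
    "absent")
  expect_false("vOTU0002" %in% smaller$votu_id)
})

test_that("network summaries count distinct pairs and cross-taxon sharing", {
  expect_identical(
    summarize_network(data.frame(sample_id = character(0),
                                 mag_id = character(0),
                                 mag_taxonomy = character(0),
                                 votu_id = character(0),
                                 canonical_dr = character(0),
                                 n_spacer_hits = integer(0),
                                 ambiguous = logical(0)))$n_distinct_pairs,
    0L)
  net <- data.frame(
    sample_id = c("S1", "S2", "S1", "S1"),
    mag_id = c("magA", "magA", "magB", "magC"),
    mag_taxonomy = c("Bacteria;X", "Bacteria;X", "Archaea;Y", "Bacteria;Z"),
    votu_id = c("v1", "v1", "v1", "v2"),
    canonical_dr = "AAA", n_spacer_hits = 1L,
    ambiguous = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  s <- summarize_network(net)
  expect_identical(s$n_distinct_pairs, 3L)   # (A,v1) collapsed over samples
  expect_identical(s$n_votus, 2L)
  expect_identical(s$n_mags, 3L)
  expect_identical(s$cross_taxon_shared_votus, 1L)  # v1 via A+B unambiguous
})

test_that("pipeline spacer hits never cross regions", {
  sim <- default_sim()
  pipe <- default_pipeline()
  region_of <- setNames(sim$metadata$region, sim$metadata$sample_id)
  for (sid in names(pipe$hits)) {
    h <- pipe$hits[[sid]]
    if (nrow(h) == 0) next
    hit_samples <- sub("_.*$", "", h$contig_id)
    expect_true(all(region_of[hit_samples] == region_of[[sid]]))
  }
  # endemic lineages only ever link hosts within their home region
  vl <- votu_lineage_map(pipe$votu_membership, sim)
  occ <- sim$ground_truth$site_occupancy
  endemic <- names(occ)[vapply(occ, length, 0L) < nrow(sim$vpop$sites)]
  lin_region <- sim$vpop$lineage_region
  net <- pipe$network
  lin_of_edge <- unname(vl[net$votu_id])
  idx <- lin_of_edge %in% endemic
  expect_true(all(region_of[net$sample_id[idx]] ==
                    lin_region[lin_of_edge[idx]]))
})
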