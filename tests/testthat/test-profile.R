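# Pseudo-mapping, abundance/diversity metrics, rarefaction, viral taxonomy.

test_that("pseudo-mapper counts exact, near-exact, tied and unmapped reads", {
  set.seed(51)
  refs <- setNames(c(rand_seq(1500), rand_seq(1500)), c("rA", "rB"))
  r_exact <- substr(refs[["rA"]], 101, 200)
  r_mm2 <- substitute_at(r_exact, c(10, 60))
  r_mm3 <- substitute_at(r_exact, c(10, 50, 90))
  r_rc <- rc_str(substr(refs[["rB"]], 301, 400))
  reads <- c(e = r_exact, m2 = r_mm2, m3 = r_mm3, rc = r_rc,
             junk = rand_seq(100))
  cnt <- pseudo_map_reads(reads, refs, max_mismatch = 2)
  expect_equal(unname(cnt["rA"]), 2)   # exact + 2-mismatch
  expect_equal(unname(cnt["rB"]), 1)   # reverse-complement read
  expect_identical(attr(cnt, "n_mapped"), 3L)

  # tie: identical references split the count
  refs2 <- c(refs, rA2 = unname(refs["rA"]))
  cnt2 <- pseudo_map_reads(reads["e"], refs2)
  expect_equal(unname(cnt2["rA"]), 0.5)
  expect_equal(unname(cnt2["rA2"]), 0.5)

  expect_error(pseudo_map_reads(c(x = rand_seq(20)), refs), "31")
})

test_that("pseudo-mapped counts track planted depths", {
  set.seed(52)
  refs <- setNames(vapply(1:5, function(i) rand_seq(2000), ""),
                   paste0("g", 1:5))
  depth <- c(5, 20, 60, 120, 250)   # reads per genome
  reads <- character(0)
  for (i in 1:5) {
    st <- sample(1901, depth[i], replace = TRUE)
    reads <- c(reads, substring(refs[[i]], st, st + 99))
  }
  names(reads) <- paste0("r", seq_along(reads))
  cnt <- pseudo_map_reads(reads, refs)
  expect_gte(cor(as.numeric(cnt), depth, method = "spearman"), 0.9)
})

test_that("relative abundance arithmetic and denominators", {
  p <- sample_profile("S1", n_merged_reads = 100, n_paired_reads = 120,
                      reads_to_viral = 10, n_spacers = 0, n_dr_types = 3,
                      votu_read_counts = c(vOTU1 = 4))
  ab <- relative_abundances(p, votu_lengths = c(vOTU1 = 2000))
  expect_equal(ab$viral_abundance, 0.1)
  expect_equal(ab$spacer_abundance, 0)
  expect_equal(ab$crispr_abundance, 3 / 120)
  expect_equal(unname(ab$votu_abundance["vOTU1"]), 4 / (2000 * 100))

  # ratio normalisation: doubling reads and counts changes nothing
  p2 <- sample_profile("S1", n_merged_reads = 200, n_paired_reads = 240,
                       reads_to_viral = 20, n_spacers = 0, n_dr_types = 6,
                       votu_read_counts = c(vOTU1 = 8))
  ab2 <- relative_abundances(p2, votu_lengths = c(vOTU1 = 2000))
  expect_equal(ab2$viral_abundance, ab$viral_abundance)
  expect_equal(ab2$votu_abundance, ab$votu_abundance)

  expect_error(relative_abundances(
    sample_profile("S0", n_merged_reads = 0, n_paired_reads = 0)), "S0")
})

test_that("diversity proxies, including the no-viral-contig missing case", {
  p <- sample_profile("S1", n_merged_reads = 1000, n_paired_reads = 1200,
                      n_viral_contigs = 50, n_votus = 5,
                      n_spacer_clusters = 12, n_host_classes = 4)
  d <- diversity_proxies(p)
  expect_equal(d$viral_diversity, 0.1)
  expect_equal(d$spacer_diversity, 12 / 1200)
  expect_equal(d$host_diversity, 4 / 1000)

  pmax <- sample_profile("S2", 1000, 1000, n_viral_contigs = 7, n_votus = 7)
  expect_equal(diversity_proxies(pmax)$viral_diversity, 1)

  p0 <- sample_profile("OldManTree2012", 1000, 1000, n_viral_contigs = 0)
  expect_message(d0 <- diversity_proxies(p0), "missing")
  expect_true(is.na(d0$viral_diversity))
})

test_that("analytic rarefaction matches endpoints, vegan, and Monte Carlo", {
  counts <- c(a = 12, b = 5, c = 1, d = 30, e = 2)
  N <- sum(counts)
  rc <- rarefaction_curve(counts, c(1, 10, 25, N))
  expect_equal(rc$richness[rc$depth == N], 5)
  expect_equal(rarefaction_curve(c(x = 40), c(1, 40))$richness, c(1, 1))
  # non-decreasing and concave
  full <- rarefaction_curve(counts, 1:N)$richness
  expect_true(all(diff(full) >= -1e-12))
  expect_true(all(diff(diff(full)) <= 1e-9))
  # independent oracle: vegan's analytic rarefaction
  expect_equal(rc$richness,
               as.numeric(vegan::rarefy(counts, c(1, 10, 25, N))),
               tolerance = 1e-9)
  # Monte Carlo agrees within 3 standard errors
  set.seed(53)
  mc <- rarefaction_curve(counts, c(10, 25), mode = "montecarlo", reps = 500)
  an <- rarefaction_curve(counts, c(10, 25))
  expect_true(all(abs(mc$richness - an$richness) <=
                    pmax(3 * mc$se, 1 / 500)))
  expect_error(rarefaction_curve(counts, N + 1), "depths")
})

test_that("taxonomy assignment picks best E, then identity, then id; no hit
           is unclassified", {
  set.seed(54)
  rep_seq <- c(vOTU1 = rand_seq(600))
  exact50 <- substr(rep_seq[[1]], 51, 100)          # 50 bp exact: score 50
  with3 <- substitute_at(substr(rep_seq[[1]], 201, 259), c(10, 25, 40))
  refs <- c(refA = exact50, refB = with3, refC = rand_seq(600))
  fam <- c(refA = "Myoviridae", refB = "Siphoviridae", refC = "Podoviridae")
  tx <- assign_votu_taxonomy(rep_seq, refs, fam)
  # refA: score 50, identity 1; refB: 56 matches - 3 mism = score 50,
  # identity 56/59: tie on E resolved by identity
  expect_identical(tx$family, "Myoviridae")

  tx0 <- assign_votu_taxonomy(c(vOTUx = rand_seq(400)), refs, fam)
  expect_identical(tx0$family, "unclassified")

  # tie on E and identity resolved by reference identifier
  refs2 <- c(zeta = exact50, alpha = exact50)
  fam2 <- c(zeta = "Z", alpha = "A")
  expect_identical(assign_votu_taxonomy(rep_seq, refs2, fam2)$family, "A")
})

test_that("rare-group collapsing conserves the viral-mapped fraction", {
  taxa <- data.frame(votu_id = paste0("v", 1:4),
                     family = c("Myoviridae", "Myoviridae", "Siphoviridae",
                                "Podoviridae"),
                     evalue = 1e-20, identity = 0.99,
                     stringsAsFactors = FALSE)
  counts <- c(v1 = 500, v2 = 450, v3 = 30, v4 = 20)  # 3% and 2% are rare
  comp <- family_composition(taxa, counts, n_sample_reads = 10000,
                             rare_frac = 0.05)
  expect_true("rare viral groups" %in% comp$family)
  expect_equal(sum(comp$abundance), sum(counts) / 10000, tolerance = 1e-12)
  expect_equal(comp$abundance[comp$family == "rare viral groups"], 50 / 10000)
  # nothing rare: table unchanged
  comp2 <- family_composition(taxa, c(v1 = 500, v2 = 500, v3 = 500,
                                      v4 = 500), 10000)
  expect_false("rare viral groups" %in% comp2$family)
})
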