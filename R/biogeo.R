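## Biogeography: endemism/distribution statistics over a feature x site
## incidence matrix, compositional (clr) hierarchical clustering of samples
## with bootstrap support, and the top-vOTU vs top-spacer-cluster
## cross-check.

#' Build a feature-by-site incidence matrix
#'
#' @param mat Logical (or 0/1) matrix, features x sites, with dimnames.
#' @param hierarchy data.frame with columns `site`, `field`, `region`
#'   covering every column of `mat`.
#' @return An `incidence_matrix` list.
#' @export
incidence_matrix <- function(mat, hierarchy) {
  mat <- mat != 0
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("incidence_matrix: mat needs feature and site dimnames")
  }
  if (!all(colnames(mat) %in% hierarchy$site)) {
    stop("incidence_matrix: sites missing from hierarchy: ",
         paste(setdiff(colnames(mat), hierarchy$site), collapse = ", "))
  }
  if (any(rowSums(mat) == 0)) {
    stop("incidence_matrix: features present in no site")
  }
  structure(list(mat = mat,
                 hierarchy = hierarchy[match(colnames(mat), hierarchy$site), ,
                                       drop = FALSE]),
            class = "incidence_matrix")
}

#' Endemism and distribution statistics
#'
#' Per region (denominator: features present in at least one of the region's
#' sites): the percentage present in more than one of the region's vent
#' sites, and the percentage present in all of them. Globally (denominator:
#' all features): the percentage present in every region.
#'
#' @param inc An [incidence_matrix()].
#' @return data.frame with columns `scope` (region name or `"all regions"`),
#'   `n_features`, `pct_multi_site`, `pct_all_sites`, `pct_all_regions`.
#' @export
endemism_stats <- function(inc) {
  mat <- inc$mat
  hier <- inc$hierarchy
  regions <- unique(hier$region)
  rows <- lapply(regions, function(r) {
    sites <- hier$site[hier$region == r]
    sub <- mat[, sites, drop = FALSE]
    nsites_present <- rowSums(sub)
    present <- nsites_present > 0
    n <- sum(present)
    data.frame(scope = r, n_features = n,
               pct_multi_site = if (n) 100 * sum(nsites_present > 1) / n else 0,
               pct_all_sites = if (n)
                 100 * sum(nsites_present == length(sites)) / n else 0,
               pct_all_regions = NA_real_, stringsAsFactors = FALSE)
  })
  in_all_regions <- rep(TRUE, nrow(mat))
  for (r in regions) {
    sites <- hier$site[hier$region == r]
    in_all_regions <- in_all_regions &
      rowSums(mat[, sites, drop = FALSE]) > 0
  }
  rows[[length(rows) + 1L]] <- data.frame(
    scope = "all regions", n_features = nrow(mat),
    pct_multi_site = NA_real_, pct_all_sites = NA_real_,
    pct_all_regions = 100 * sum(in_all_regions) / nrow(mat),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiplicative zero replacement for compositional count tables
#'
#' `"CZM"` (count zero multiplicative) imputes each zero of sample i as
#' `frac / n_i` on the proportion scale (`n_i` = row total); `"BayesLaplace"`
#' imputes the Bayesian-multiplicative posterior mean under a Laplace prior,
#' `1 / (n_i + D)` (`D` = number of parts). Non-zero parts are adjusted
#' multiplicatively so each row remains a composition, and the result is
#' rescaled to the original row totals, so rows without zeros are returned
#' unchanged.
#'
#' @param tbl Numeric matrix, samples x parts, non-negative counts with
#'   dimnames.
#' @param method `"CZM"` or `"BayesLaplace"`.
#' @param frac CZM imputation fraction of one count (default 0.65).
#' @return Strictly positive matrix on the count scale.
#' @export
zero_replace <- function(tbl, method = c("CZM", "BayesLaplace"), frac = 0.65) {
  method <- match.arg(method)
  tbl <- as.matrix(tbl)
  ntot <- rowSums(tbl)
  if (any(ntot == 0)) {
    stop("zero_replace: all-zero sample(s): ",
         paste(rownames(tbl)[ntot == 0], collapse = ", "))
  }
  out <- tbl
  D <- ncol(tbl)
  for (i in seq_len(nrow(tbl))) {
    x <- tbl[i, ]
    z <- x == 0
    if (!any(z)) next
    n <- ntot[i]
    p <- x / n
    delta <- if (method == "CZM") frac / n else 1 / (n + D)
    p[z] <- delta
    p[!z] <- p[!z] * (1 - delta * sum(z))
    out[i, ] <- p * n
  }
  out
}

#' Centered log-ratio transform
#'
#' clr(x)_j = log(x_j / g(x)) per row, g the geometric mean; every output
#' row sums to zero and the transform is invariant to row scaling.
#'
#' @param tbl Strictly positive numeric matrix, samples x parts.
#' @return Real-valued matrix of the same shape.
#' @export
clr_transform <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (any(tbl <= 0)) stop("clr_transform: non-positive entries")
  lt <- log(tbl)
  sweep(lt, 1, rowMeans(lt), "-")
}

#' Ward.D2 clustering of samples with bootstrap support
#'
#' Euclidean distances on clr-transformed rows, Ward.D2 agglomeration
#' (Murtagh-Legendre squared-distance update, as implemented by
#' [stats::hclust()]), and ordinary (BP) bootstrap support: parts (columns)
#' are resampled with replacement `n_boot` times and each original
#' bipartition's support is the fraction of bootstrap dendrograms containing
#' it.
#'
#' @param clr_tbl Real matrix, samples x parts (>= 2 samples), e.g. from
#'   [clr_transform()].
#' @param n_boot Bootstrap replicates (default 200); 0 skips support.
#' @return A `sample_clustering` list with `hclust`, `phylo` (node labels =
#'   support %), `support` (per internal node), and `n_boot`.
#' @export
cluster_samples <- function(clr_tbl, n_boot = 200L) {
  clr_tbl <- as.matrix(clr_tbl)
  if (nrow(clr_tbl) < 2) stop("cluster_samples: need >= 2 samples")
  hc <- hclust(dist(clr_tbl), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  support <- NULL
  if (n_boot > 0) {
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(clr_tbl), replace = TRUE)
      boots[[b]] <- ape::as.phylo(hclust(dist(clr_tbl[, cols, drop = FALSE]),
                                         method = "ward.D2"))
    }
    counts <- ape::prop.clades(phy, boots, rooted = TRUE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / n_boot
    phy$node.label <- formatC(support, format = "f", digits = 1)
  }
  structure(list(hclust = hc, phylo = phy, support = support,
                 n_boot = n_boot),
            class = "sample_clustering")
}

#' Write a sample dendrogram as Newick with support labels
#'
#' @param clustering A [cluster_samples()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}

#' Bootstrap support for a given sample grouping
#'
#' Fraction of bootstrap dendrograms (parts resampled with replacement) in
#' which the given tip set forms a clade, evaluated independently of the
#' original tree. Used to ask, e.g., whether each region's samples cluster
#' together.
#'
#' @param clr_tbl Real matrix, samples x parts.
#' @param groups Named list: group name -> character vector of sample ids.
#' @param n_boot Bootstrap replicates.
#' @return Named numeric vector of support percentages per group.
#' @export
group_support <- function(clr_tbl, groups, n_boot = 200L) {
  clr_tbl <- as.matrix(clr_tbl)
  hits <- setNames(numeric(length(groups)), names(groups))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(clr_tbl), replace = TRUE)
    phy <- ape::as.phylo(hclust(dist(clr_tbl[, cols, drop = FALSE]),
                                method = "ward.D2"))
    for (g in names(groups)) {
      if (is_clade(phy, groups[[g]])) hits[g] <- hits[g] + 1
    }
  }
  100 * hits / n_boot
}

## TRUE when `tips` form a clade of the (rooted) tree.
is_clade <- function(phy, tips) {
  tips <- intersect(tips, phy$tip.label)
  if (length(tips) < 2) return(length(tips) == 1)
  if (length(tips) == length(phy$tip.label)) return(TRUE)
  node <- ape::getMRCA(phy, tips)
  desc <- ape::extract.clade(phy, node)$tip.label
  setequal(desc, tips)
}

#' Select top features by abundance or breadth
#'
#' @param values Named numeric vector: abundance, or number of sites with
#'   presence ("breadth", i.e. how widely distributed).
#' @param k Number of features to keep; when fewer are available all are
#'   returned and a message is emitted.
#' @return Character vector of feature ids, ties broken by identifier.
#' @export
top_features <- function(values, k) {
  if (length(values) < k) {
    message("top_features: only ", length(values),
            " features available (requested ", k, ")")
    k <- length(values)
  }
  ord <- order(-values, names(values))
  names(values)[ord][seq_len(k)]
}

#' Cross-check top vOTUs against top spacer clusters
#'
#' Reports which of the top spacer clusters have at least one member spacer
#' matching (bounded-mismatch protospacer search) at least one member contig
#' of a top vOTU.
#'
#' @param top_votus Character vector of vOTU ids.
#' @param top_clusters Character vector of spacer-cluster ids.
#' @param votu_membership vOTU membership table ([cluster_votus()]).
#' @param spacer_clusters Spacer cluster table (`node` / `cluster_id`).
#' @param contigs Named character vector of viral contig sequences.
#' @param spacers Named character vector of spacer sequences.
#' @param max_mismatch Mismatch bound for the matcher (default 1).
#' @return data.frame of matched `votu_id` / `spacer_cluster_id` pairs, with
#'   attributes `n_top_votus_matched` and `n_top_clusters_matched`.
#' @export
top_feature_crosscheck <- function(top_votus, top_clusters, votu_membership,
                                   spacer_clusters, contigs, spacers,
                                   max_mismatch = 1L) {
  member_contigs <- votu_membership$contig_id[
    votu_membership$votu_id %in% top_votus]
  member_spacers <- spacer_clusters$node[
    spacer_clusters$cluster_id %in% top_clusters]
  contigs <- contigs[intersect(member_contigs, names(contigs))]
  spacers <- spacers[intersect(member_spacers, names(spacers))]
  pairs <- data.frame(votu_id = character(0), spacer_cluster_id = character(0))
  if (length(contigs) && length(spacers)) {
    hits <- match_spacers_to_protospacers(spacers, contigs,
                                          max_mismatch = max_mismatch)
    if (nrow(hits)) {
      hv <- votu_membership$votu_id[match(hits$contig_id,
                                          votu_membership$contig_id)]
      hc <- spacer_clusters$cluster_id[match(hits$spacer_id,
                                             spacer_clusters$node)]
      pairs <- unique(data.frame(votu_id = hv, spacer_cluster_id = hc,
                                 stringsAsFactors = FALSE))
      pairs <- pairs[order(pairs$votu_id, pairs$spacer_cluster_id), ]
      rownames(pairs) <- NULL
    }
  }
  attr(pairs, "n_top_votus_matched") <- length(unique(pairs$votu_id))
  attr(pairs, "n_top_clusters_matched") <-
    length(unique(pairs$spacer_cluster_id))
  pairs
}
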