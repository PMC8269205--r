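## Viral contig clustering into vOTUs (greedy centroid, 95% identity / 80%
## coverage of the shorter sequence) and spacer clustering (all-vs-all local
## alignment graph under an E-value threshold, then Markov clustering).

## Ungapped Karlin-Altschul parameters for match +1 / mismatch -2 at uniform
## base composition. lambda solves 0.25*e^l + 0.75*e^(-2l) = 1, which has the
## closed form below; K is the standard tabulated ungapped value for +1/-2.
KA_LAMBDA <- log((0.75 + sqrt(1.3125)) / 0.5)
KA_K <- 0.621

#' Pairwise local alignment summary
#'
#' Local alignment (match +1, mismatch -2, gap open 5, gap extend 2) with
#' identity computed over aligned columns (internal gaps count as
#' differences; terminal gaps excluded by locality) and coverage relative to
#' the shorter sequence.
#'
#' @param a,b Nucleotide strings (optionally named length-1 vectors).
#' @param prefilter_k When > 0, pairs sharing no exact k-mer of this size are
#'   reported as unaligned (identity, coverage and score 0) without running
#'   the aligner. Set to 0 to force alignment.
#' @return A list with `identity`, `coverage` and `score`.
#' @export
#' @examples
#' align_pair("ACGTACGTACGT", "ACGTACGTACGT")$identity
align_pair <- function(a, b, prefilter_k = 0L) {
  a <- unname(a[1]); b <- unname(b[1])
  if (nchar(a) == 0 || nchar(b) == 0) stop("align_pair: empty sequence")
  if (prefilter_k > 0L && !shares_kmer(a, b, prefilter_k)) {
    return(list(identity = 0, coverage = 0, score = 0))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  ap <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  ncols <- nchar(ap)
  nm <- Biostrings::nmatch(al)
  shorter <- min(nchar(a), nchar(b))
  ## residues of the shorter sequence inside the aligned region
  span <- if (nchar(a) <= nchar(b)) {
    nchar(gsub("-", "", ap, fixed = TRUE))
  } else {
    nchar(gsub("-", "", as_, fixed = TRUE))
  }
  list(identity = if (ncols > 0) nm / ncols else 0,
       coverage = span / shorter,
       score = Biostrings::score(al))
}

#' Greedy centroid clustering of viral contigs into vOTUs
#'
#' Contigs are sorted by length (descending, ties by identifier); each contig
#' joins the first existing cluster whose representative it matches at
#' `id_thresh` identity and `cov_thresh` coverage of the shorter sequence,
#' else it seeds a new cluster. Deterministic and invariant to input order.
#'
#' @param contigs Named character vector of viral contig sequences.
#' @param id_thresh Identity threshold (default 0.95).
#' @param cov_thresh Coverage threshold on the shorter sequence (default 0.80).
#' @param prefilter_k Exact-k-mer prefilter passed to [align_pair()]
#'   (default 16; two sequences at >= 95% identity over >= 26 bp share a
#'   16-mer with overwhelming probability, while unrelated contigs share
#'   none).
#' @return A data.frame with columns `contig_id`, `votu_id`,
#'   `is_representative`, `contig_length`, plus attribute `votus`: a
#'   data.frame of `votu_id`, `representative`, `n_members`,
#'   `total_member_length`.
#' @export
cluster_votus <- function(contigs, id_thresh = 0.95, cov_thresh = 0.80,
                          prefilter_k = 16L) {
  if (length(contigs) == 0) {
    out <- data.frame(contig_id = character(0), votu_id = character(0),
                      is_representative = logical(0),
                      contig_length = integer(0))
    attr(out, "votus") <- data.frame(votu_id = character(0),
                                     representative = character(0),
                                     n_members = integer(0),
                                     total_member_length = integer(0))
    return(out)
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("cluster_votus: contigs must have unique names")
  }
  len <- nchar(contigs)
  ord <- order(-len, names(contigs))
  ids <- names(contigs)[ord]

  ## identical sequences share their assignment, computed once
  seq_key <- match(contigs[ids], unique(contigs[ids]))
  rep_ids <- character(0)       # representative contig per cluster
  assign <- integer(length(ids))
  key_cluster <- list()         # seq_key -> cluster, memoised

  for (i in seq_along(ids)) {
    kk <- as.character(seq_key[i])
    if (!is.null(key_cluster[[kk]])) {
      assign[i] <- key_cluster[[kk]]
      next
    }
    found <- 0L
    for (ci in seq_along(rep_ids)) {
      al <- align_pair(contigs[[ids[i]]], contigs[[rep_ids[ci]]],
                       prefilter_k = prefilter_k)
      if (al$identity >= id_thresh && al$coverage >= cov_thresh) {
        found <- ci
        break
      }
    }
    if (found == 0L) {
      rep_ids <- c(rep_ids, ids[i])
      found <- length(rep_ids)
    }
    assign[i] <- found
    key_cluster[[kk]] <- found
  }

  votu_ids <- sprintf("vOTU%04d", seq_along(rep_ids))
  membership <- data.frame(
    contig_id = ids,
    votu_id = votu_ids[assign],
    is_representative = ids == rep_ids[assign],
    contig_length = unname(len[ord]),
    stringsAsFactors = FALSE
  )
  membership <- membership[order(membership$votu_id, -membership$contig_length,
                                 membership$contig_id), ]
  rownames(membership) <- NULL
  votus <- aggregate(list(total_member_length = membership$contig_length,
                          n_members = rep(1L, nrow(membership))),
                     by = list(votu_id = membership$votu_id), FUN = sum)
  votus$representative <- rep_ids[match(votus$votu_id, votu_ids)]
  attr(membership, "votus") <-
    votus[, c("votu_id", "representative", "n_members", "total_member_length")]
  membership
}

#' Karlin-Altschul E-value for an ungapped-scored local alignment
#'
#' @param score Alignment score (match +1 / mismatch -2 scale).
#' @param search_space Product of effective query and database lengths.
#' @return The expected number of chance alignments at or above `score`.
#' @export
ka_evalue <- function(score, search_space) {
  KA_K * search_space * exp(-KA_LAMBDA * score)
}

#' All-versus-all spacer similarity graph
#'
#' Nodes are spacers; an undirected edge joins two spacers when their local
#' alignment has Karlin-Altschul E-value at most `evalue_max`, computed for a
#' search space of (number of spacers x mean spacer length)^2. Edge weight is
#' the alignment score. Self-edges are excluded; identical duplicate spacer
#' sequences are aligned once.
#'
#' @param spacers Named character vector of spacer sequences.
#' @param evalue_max E-value threshold (default 1e-8).
#' @return A list with `nodes` (spacer ids), `edges` (data.frame `from`,
#'   `to`, `score`, `evalue`), and `search_space`.
#' @export
spacer_similarity_graph <- function(spacers, evalue_max = 1e-8) {
  if (length(spacers) < 1) stop("spacer_similarity_graph: need >= 1 spacer")
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("sp%04d", seq_along(spacers))
  }
  n <- length(spacers)
  search_space <- (n * mean(nchar(spacers)))^2

  ids <- names(spacers)
  edges <- list()
  if (n > 1) {
    uniq <- unique(unname(spacers))
    key <- match(unname(spacers), uniq)
    ## align distinct sequence pairs once
    for (i in seq_along(uniq)) {
      for (j in i:length(uniq)) {
        if (i == j) {
          members <- which(key == i)
          if (length(members) < 2) next
          al <- list(score = nchar(uniq[i]))
        } else {
          al <- align_pair(uniq[i], uniq[j], prefilter_k = 8L)
        }
        ev <- ka_evalue(al$score, search_space)
        if (ev > evalue_max) next
        mi <- which(key == i); mj <- which(key == j)
        pairs <- if (i == j) {
          t(utils::combn(mi, 2))
        } else {
          as.matrix(expand.grid(mi, mj))
        }
        edges[[length(edges) + 1L]] <- data.frame(
          from = ids[pairs[, 1]], to = ids[pairs[, 2]],
          score = al$score, evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               score = numeric(0), evalue = numeric(0))
  list(nodes = ids, edges = edges, search_space = search_space)
}

## Dense adjacency matrix from a graph list (weights = score).
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, graph$nodes)
    ti <- match(graph$edges$to, graph$nodes)
    for (e in seq_along(fi)) {
      A[fi[e], ti[e]] <- max(A[fi[e], ti[e]], graph$edges$score[e])
      A[ti[e], fi[e]] <- A[fi[e], ti[e]]
    }
  }
  A
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Standard MCL iteration on the column-stochastic matrix of the weighted
#' adjacency with self-loops (loop weight = maximum incident edge weight, 1
#' for isolated nodes): alternate expansion (matrix squaring) and inflation
#' (elementwise power `inflation`, then column renormalisation) until the
#' maximum entrywise change is below 1e-9 or 200 iterations, then read
#' clusters from attractor rows. Overlapping attractor systems are merged;
#' every node is assigned to exactly one cluster (ties to the lowest cluster
#' index).
#'
#' @param graph A graph as returned by [spacer_similarity_graph()], or a
#'   symmetric non-negative adjacency matrix with dimnames.
#' @param inflation Inflation exponent (default 1.2).
#' @param max_iter,tol Convergence controls.
#' @return A data.frame with columns `node` and `cluster_id`
#'   (`SC0001`, ... numbered by lowest member node index).
#' @export
markov_cluster <- function(graph, inflation = 1.2, max_iter = 200L,
                           tol = 1e-9) {
  A <- if (is.matrix(graph)) graph else graph_adjacency(graph)
  n <- nrow(A)
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0) {
    return(data.frame(node = character(0), cluster_id = character(0)))
  }
  diag(A) <- 0
  loops <- apply(A, 2, max)
  loops[loops == 0] <- 1
  diag(A) <- loops

  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("markov_cluster: no convergence after ", max_iter,
            " iterations; interpreting current matrix")
  }
  interpret_mcl(M, nodes)
}

## Read clusters from a (near-)idempotent MCL matrix.
interpret_mcl <- function(M, nodes, eps = 1e-6) {
  n <- length(nodes)
  attractors <- which(diag(M) >= eps)
  clusters <- lapply(attractors, function(i) which(M[i, ] >= eps))
  ## merge overlapping attractor systems
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) any(m %in% cl), logical(1)))
    if (length(hit)) {
      merged[[hit[1]]] <- sort(unique(c(unlist(merged[hit]), cl)))
      extra <- setdiff(hit, hit[1])
      if (length(extra)) merged <- merged[-extra]
    } else {
      merged[[length(merged) + 1L]] <- sort(cl)
    }
  }
  assign <- rep(NA_integer_, n)
  ## order clusters by lowest member; ties (overlap) to lowest cluster index
  if (length(merged)) {
    merged <- merged[order(vapply(merged, min, 0L))]
    for (ci in seq_along(merged)) {
      for (v in merged[[ci]]) {
        if (is.na(assign[v])) assign[v] <- ci
      }
    }
  }
  ## unassigned nodes become singletons
  nxt <- length(merged)
  for (v in which(is.na(assign))) {
    nxt <- nxt + 1L
    assign[v] <- nxt
  }
  ## renumber by first appearance over node order
  lev <- unique(assign)
  assign <- match(assign, lev)
  data.frame(node = nodes,
             cluster_id = sprintf("SC%04d", assign),
             stringsAsFactors = FALSE)
}

#' Cluster spacers: similarity graph plus Markov clustering
#'
#' @param spacers Named character vector of spacers.
#' @param evalue_max E-value threshold for graph edges.
#' @param inflation MCL inflation.
#' @return A data.frame `node` / `cluster_id` covering every spacer.
#' @export
cluster_spacers <- function(spacers, evalue_max = 1e-8, inflation = 1.2) {
  g <- spacer_similarity_graph(spacers, evalue_max = evalue_max)
  markov_cluster(g, inflation = inflation)
}
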