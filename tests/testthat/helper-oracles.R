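# Independent oracles and shared fixtures. Oracles are written from the
# definitions, not by calling the code paths they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc_str <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

substitute_at <- function(seq, pos, base = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- if (is.null(base)) alt[1] else base
  }
  paste(ch, collapse = "")
}

# Naive all-positions Hamming scan: every ungapped occurrence of each spacer
# in each contig, both strands, at <= max_mm substitutions.
naive_hamming_scan <- function(spacers, contigs, max_mm) {
  rows <- list()
  for (sid in names(spacers)) {
    L <- nchar(spacers[[sid]])
    for (cid in names(contigs)) {
      cvec <- charToRaw(contigs[[cid]])
      n <- length(cvec)
      if (n < L) next
      for (strand in c("+", "-")) {
        q <- if (strand == "+") spacers[[sid]] else rc_str(spacers[[sid]])
        qraw <- charToRaw(q)
        mm <- integer(n - L + 1L)
        for (j in seq_len(L)) {
          mm <- mm + (cvec[j:(n - L + j)] != qraw[j])
        }
        for (st in which(mm <= max_mm)) {
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = sid, contig_id = cid, start = st - 1L,
            end = st - 1L + L, strand = strand,
            n_mismatches = mm[st], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$spacer_id, out$contig_id, out$start, out$strand), ]
  } else {
    data.frame(spacer_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               n_mismatches = integer(0))
  }
}

# Reference MCL: the same fixed-point definition, written independently
# (explicit loops for normalisation/inflation, union-find interpretation).
reference_mcl <- function(A, inflation = 1.2, max_iter = 200, tol = 1e-9) {
  n <- nrow(A)
  diag(A) <- 0
  for (j in seq_len(n)) {
    mx <- max(A[, j])
    A[j, j] <- if (mx > 0) mx else 1
  }
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    for (j in seq_len(n)) {
      col <- E[, j]^inflation
      E[, j] <- col / sum(col)
    }
    if (max(abs(E - M)) < tol) {
      M <- E
      break
    }
    M <- E
  }
  # attractor rows -> clusters, overlaps merged via union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  attractors <- which(diag(M) >= 1e-6)
  for (i in attractors) {
    members <- which(M[i, ] >= 1e-6)
    for (v in members[-1]) {
      ra <- find(members[1]); rb <- find(v)
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Brute-force greedy centroid clustering from the rule's definition, using
# an all-pairs alignment matrix computed up front.
greedy_votu_oracle <- function(contigs, id_thresh = 0.95, cov_thresh = 0.80) {
  ids <- names(contigs)[order(-nchar(contigs), names(contigs))]
  idm <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  cov <- idm
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) { idm[i, j] <- 1; cov[i, j] <- 1; next }
      al <- align_pair(contigs[[ids[i]]], contigs[[ids[j]]])
      idm[i, j] <- al$identity
      cov[i, j] <- al$coverage
    }
  }
  reps <- character(0)
  assign <- setNames(integer(length(ids)), ids)
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (idm[id, reps[ci]] >= id_thresh && cov[id, reps[ci]] >= cov_thresh) {
        assign[id] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[id] <- length(reps)
    }
  }
  assign
}

# Simple BFS connected components of a symmetric adjacency matrix.
graph_components <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(A[v, ] > 0 & is.na(comp)))
    }
  }
  comp
}

# Shared simulations, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

default_sim <- function() {
  cached("sim_mm1", simulate_community(simulation_config(seed = 101)))
}

default_pipeline <- function() {
  cached("pipe_mm1", run_infection_pipeline(default_sim(), max_mismatch = 1))
}

# Planted CRISPR array fixture with controlled flanks: the column adjacent
# to each repeat boundary is pairwise distinct across copies, so boundary
# detection has no chance extension.
planted_array_genome <- function(dr_len = 25, spacer_len = 32, n_spacers = 2,
                                 mutate_copy = 0, mutate_pos = 13) {
  dr <- rand_seq(dr_len)
  spacers <- vapply(seq_len(n_spacers), function(i) rand_seq(spacer_len), "")
  # force distinct boundary columns: spacer i starts/ends with base i
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_spacers)) {
    spacers[i] <- paste0(bases[i], substr(spacers[i], 2, spacer_len - 1),
                         bases[i])
  }
  left <- paste0(rand_seq(200), bases[n_spacers + 1])
  right <- paste0(bases[n_spacers + 1], rand_seq(200))
  copies <- rep(dr, n_spacers + 1)
  if (mutate_copy > 0) {
    copies[mutate_copy] <- substitute_at(copies[mutate_copy], mutate_pos)
  }
  body <- copies[1]
  for (i in seq_len(n_spacers)) body <- paste0(body, spacers[i], copies[i + 1])
  genome <- paste0(left, body, right)
  start0 <- nchar(left)
  list(genome = genome, dr = dr, spacers = spacers,
       repeat_starts = start0 + (0:n_spacers) * (dr_len + spacer_len))
}
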