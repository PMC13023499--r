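# Shared fixtures and independent reference (oracle) implementations.

# A small, fast synthetic session: 1 participant, 1 task, short trials.
tiny_session <- function(n_trials = 12, duration = 120, kappa = 0.9,
                         seed = 7, tasks = "EAT", n_participants = 1, ...) {
  durs <- stats::setNames(rep(duration, length(tasks)), tasks)
  generate_session(session_config(
    n_participants = n_participants, tasks = tasks, n_trials = n_trials,
    trial_duration_s = durs, coupling_kappa = kappa, seed = seed, ...))
}

# Brute-force mutual information: direct double sum over a joint probability
# matrix (independent of the package's vectorized path).
brute_mi <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  total
}

# Brute-force O(n^3) agglomerative clustering on a squared-Euclidean matrix.
# Returns merge heights and the sequence of partitions, for merge-for-merge
# comparison with the hclust-backed implementation.
brute_linkage <- function(X, linkage) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))^2
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        dd <- d[clusters[[a]], clusters[[b]], drop = FALSE]
        link <- switch(linkage,
                       single = min(dd), complete = max(dd), average = mean(dd))
        if (link < best[1L]) best <- c(link, a, b)
      }
    }
    heights <- c(heights, best[1L])
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- clusters[-c(best[2L], best[3L])]
    clusters[[length(clusters) + 1L]] <- merged
    labels <- integer(n)
    for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition (label by order of first appearance), so two
# labelings of the same grouping compare equal.
canon_partition <- function(labels) {
  match(labels, unique(labels))
}
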