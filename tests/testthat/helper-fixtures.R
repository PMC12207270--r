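# Shared fixtures. Backend responses are cached per session, so repeated
# parses of the same molecule across test files are cheap.

TABLE1_SMILES <- "CCCN(C)C(=O)c1ccc(C(=O)c2ccccc2)cc1"

pattern_table_path <- function() {
  system.file("extdata", "tomberg_patterns.tsv", package = "regiopd")
}

sub_phenylpyridine <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- parse_substrate("c1ccc(-c2ccccn2)cc1")
    val
  }
})

# random rigid rotation + translation of a coordinate matrix
rigid_motion <- function(coords, seed) {
  set.seed(seed)
  a <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(a))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t(q %*% t(coords)) + matrix(rnorm(3), nrow(coords), 3, byrow = TRUE)
}

# synthetic conformer ensembles for clustering tests: perturbed copies of a
# random base geometry, in well-separated groups
synthetic_ensemble <- function(n_conf, n_atoms, seed) {
  set.seed(seed)
  n_groups <- sample(1:3, 1)
  base <- lapply(seq_len(n_groups),
                 function(g) matrix(rnorm(n_atoms * 3, sd = 4), n_atoms, 3))
  lapply(seq_len(n_conf), function(i) {
    g <- sample(n_groups, 1)
    base[[g]] + matrix(rnorm(n_atoms * 3, sd = 0.05), n_atoms, 3)
  })
}

# independent O(n^2) reference for Butina medoid clustering
brute_force_cluster <- function(d, cutoff) {
  n <- nrow(d)
  d[is.na(d)] <- Inf
  assign <- rep(NA_integer_, n)
  cl <- 0L
  while (anyNA(assign)) {
    open <- which(is.na(assign))
    best <- open[1]
    best_count <- -1L
    for (i in open) {
      count <- 0L
      for (j in open) if (d[i, j] <= cutoff) count <- count + 1L
      if (count > best_count) {
        best <- i
        best_count <- count
      }
    }
    cl <- cl + 1L
    for (j in open) if (d[best, j] <= cutoff) assign[j] <- cl
  }
  reps <- integer(cl)
  for (k in seq_len(cl)) {
    members <- which(assign == k)
    tot <- sapply(members, function(i) sum(d[i, members]))
    reps[k] <- members[which.min(tot)]
  }
  list(cluster = assign, representatives = reps)
}
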