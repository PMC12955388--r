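# Shared fixtures, all built in code at test time.

make_meta <- function(n_families = 3, members = 2) {
  rows <- lapply(seq_len(n_families), function(f) {
    m <- if (length(members) > 1) members[f] else members
    role <- c("father", "mother", rep("child", max(0, m - 2)))[seq_len(m)]
    data.frame(sample_id = sprintf("F%d_S%d", f, seq_len(m)),
               family_id = sprintf("F%d", f), role = role,
               ethnicity = "Daur",
               sex = ifelse(role == "mother", "F", "M"),
               age = ifelse(role == "child", 8, 40),
               region = "regionA", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_cohort <- function(n_families = 3, members = 2) {
  family_cohort(make_meta(n_families, members))
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plant exactly n_sub substitutions at distinct random positions.
plant_substitutions <- function(seq, n_sub, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

make_genome <- function(id, sample_id, species = "sp1", seq = "ACGTACGTACGT",
                        completeness = 95, contamination = 1) {
  genome_asset(id, sample_id, species, seq, completeness, contamination)
}

# labelled distance matrix from a symmetric value matrix
dist_mat <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  m
}

# Independent one-factor PERMANOVA oracle from the sums-of-squared-distances
# identity: SS_total = (1/n) sum_{i<j} d^2, SS_within = sum_g (1/n_g)
# sum_{i<j in g} d^2 (McArdle & Anderson), F = (SS_b/df_b)/(SS_w/df_w).
brute_permanova <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
  }
  ss_b <- ss_total - ss_within
  df_b <- length(unique(groups)) - 1
  df_w <- n - length(unique(groups))
  list(r2 = ss_b / ss_total, f = (ss_b / df_b) / (ss_within / df_w))
}
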