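# Abundance normalisation, alpha diversity, Bray-Curtis dissimilarity and
# the within- vs between-family contrasts, plus the Spearman / Wilcoxon
# helpers those contrasts rely on.

#' RPKM normalisation of a read-count matrix
#'
#' RPKM = count / ((genome length / 1e3) * (total mapped reads / 1e6)):
#' reads per kilobase of genome per million mapped reads.
#'
#' @param read_counts samples x taxa non-negative count matrix (dimnames
#'   required).
#' @param genome_lengths_bp named vector of genome lengths (> 0) covering
#'   every column.
#' @param total_mapped_reads named vector of per-sample totals (> 0)
#'   covering every row, or a single number recycled to all samples.
#' @return samples x taxa RPKM matrix.
#' @export
rpkm <- function(read_counts, genome_lengths_bp, total_mapped_reads) {
  m <- as.matrix(read_counts)
  if (any(m < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (length(total_mapped_reads) == 1L && is.null(names(total_mapped_reads)))
    total_mapped_reads <- stats::setNames(rep(total_mapped_reads, nrow(m)),
                                          rownames(m))
  lens <- genome_lengths_bp[colnames(m)]
  if (anyNA(lens)) stop("genome length missing for column(s): ",
                        paste(colnames(m)[is.na(lens)], collapse = ", "),
                        call. = FALSE)
  if (any(lens <= 0)) stop("genome lengths must be positive", call. = FALSE)
  tot <- total_mapped_reads[rownames(m)]
  if (anyNA(tot) || any(tot <= 0)) {
    bad <- rownames(m)[is.na(tot) | tot <= 0]
    stop("zero or missing total mapped reads for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(sweep(m, 2, lens / 1000, `/`), 1, tot / 1e6, `/`)
}

#' Shannon diversity index (natural log)
#'
#' H = -sum p_i ln p_i over the normalised positive entries of an
#' abundance vector. Natural log, the common default of the ecology
#' toolkits; pass `base` to change it.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @param base logarithm base (default e).
#' @return Shannon index (scalar, >= 0).
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("all-zero abundance row: Shannon undefined", call. = FALSE)
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Per-sample Shannon diversity of an abundance matrix
#' @param abundance samples x taxa matrix with sample ids as rownames.
#' @inheritParams shannon
#' @return data.frame with columns `sample_id`, `shannon`.
#' @export
shannon_diversity <- function(abundance, base = exp(1)) {
  data.frame(sample_id = rownames(abundance),
             shannon = apply(abundance, 1, shannon, base = base),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in \[0, 1\]; 0 for
#' identical rows, 1 for disjoint supports.
#'
#' @param m samples x taxa non-negative matrix (>= 2 rows, rownames
#'   required).
#' @return symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  zero <- which(rs == 0)
  if (length(zero) >= 2L)
    stop("Bray-Curtis undefined for all-zero row pair: ",
         paste(rownames(m)[zero[1:2]], collapse = " / "), call. = FALSE)
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  den <- outer(rs, rs, `+`)
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  validate_distance_matrix(d, unit_interval = TRUE)
  d
}

# ---- rank statistics -------------------------------------------------------

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Spearman rank correlation with a defined tie convention
#'
#' Average ranks for ties; an all-tied vector on either side yields
#' `rho = 0, p = 1` by convention. P-values: exact permutation enumeration
#' when n <= 8, t approximation otherwise (two-sided).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = 0, p_value = 1, n = n))
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration over all group assignments (tie-aware) when both
#' groups have <= 10 observations; normal approximation with continuity
#' and tie correction otherwise. Identical pooled values give p = 1.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= 10L && ny <= 10L) {
    sums <- utils::combn(n, nx, FUN = function(ix) sum(r[ix]))
    return(mean(abs(sums - mu) >= abs(w - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

# ---- family contrasts ------------------------------------------------------

pair_index <- function(labels, fam) {
  n <- length(labels)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = ij[, 1], j = ij[, 2],
             within = fam[ij[, 1]] == fam[ij[, 2]])
}

resolve_families <- function(d, cohort) {
  fam <- sample_family(cohort)[rownames(d)]
  if (anyNA(fam))
    stop("distance matrix label(s) not in cohort: ",
         paste(rownames(d)[is.na(fam)], collapse = ", "), call. = FALSE)
  unname(fam)
}

#' Within- versus between-family distance contrast
#'
#' Splits all sample pairs of a distance matrix into same-family and
#' different-family pairs and compares the two sets of distances with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param d labelled distance matrix over cohort samples.
#' @param cohort a [family_cohort()].
#' @return list with `within`, `between` (distance vectors) and
#'   `wilcoxon_p`.
#' @export
within_between_test <- function(d, cohort) {
  validate_distance_matrix(d)
  fam <- resolve_families(d, cohort)
  pairs <- pair_index(rownames(d), fam)
  if (!any(pairs$within))
    stop("cohort contributes no within-family pair", call. = FALSE)
  within <- d[cbind(pairs$i, pairs$j)][pairs$within]
  between <- d[cbind(pairs$i, pairs$j)][!pairs$within]
  list(within = within, between = between,
       wilcoxon_p = if (length(between)) wilcoxon_rank_sum(within, between)
                    else NA_real_)
}

#' Child-to-parent distance versus child age
#'
#' For every child, the mean distance to the enrolled parents (roles
#' father/mother) of the same family; a child with a single enrolled
#' parent uses that single distance. The trend is the Spearman correlation
#' of that value against child age.
#'
#' @inheritParams within_between_test
#' @return list with `rho`, `p_value`, `n_pairs` and the per-child table
#'   `points`.
#' @export
child_parent_trend <- function(d, cohort) {
  validate_distance_matrix(d)
  meta <- cohort$samples
  meta <- meta[meta$sample_id %in% rownames(d), ]
  kids <- meta[meta$role == "child", ]
  rows <- lapply(seq_len(nrow(kids)), function(i) {
    parents <- meta$sample_id[meta$family_id == kids$family_id[i] &
                                meta$role %in% c("father", "mother")]
    if (!length(parents)) return(NULL)
    data.frame(sample_id = kids$sample_id[i], age = kids$age[i],
               mean_parent_distance = mean(d[kids$sample_id[i], parents]))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 3L)
    stop("need at least 3 child-parent co-family pairs", call. = FALSE)
  st <- spearman_test(rows$age, rows$mean_parent_distance)
  list(rho = st$rho, p_value = st$p_value, n_pairs = nrow(rows),
       points = rows)
}

#' Pair diversity versus pair dissimilarity within families
#'
#' For every within-family sample pair: x = mean Shannon index of the two
#' members, y = their distance; returns the Spearman correlation over all
#' pairs.
#'
#' @inheritParams within_between_test
#' @param diversity data.frame from [shannon_diversity()].
#' @return list with `rho`, `p_value`, `n_pairs`, `points`.
#' @export
diversity_similarity_trend <- function(d, diversity, cohort) {
  validate_distance_matrix(d)
  fam <- resolve_families(d, cohort)
  h <- stats::setNames(diversity$shannon, diversity$sample_id)[rownames(d)]
  if (anyNA(h))
    stop("Shannon value missing for matrix label(s)", call. = FALSE)
  pairs <- pair_index(rownames(d), fam)
  pairs <- pairs[pairs$within, ]
  if (nrow(pairs) < 3L)
    stop("need at least 3 within-family pairs", call. = FALSE)
  x <- (h[pairs$i] + h[pairs$j]) / 2
  y <- d[cbind(pairs$i, pairs$j)]
  st <- spearman_test(x, y)
  list(rho = st$rho, p_value = st$p_value, n_pairs = nrow(pairs),
       points = data.frame(mean_shannon = x, distance = y))
}
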