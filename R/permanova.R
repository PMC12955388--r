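# Distance-based multivariate ANOVA (PERMANOVA) with single-factor and
# marginal (each factor controlling all others) tests. Sums of squares
# follow the Gower-centered inner-product formulation; negative-eigenvalue
# contributions of non-Euclidean matrices are retained (no correction).

#' Gower double-centering of a distance matrix
#'
#' G = -1/2 J A J with A_ij = d_ij^2 and J = I - 11'/n. trace(G) equals
#' the total sum of squares (1/n) sum_{i<j} d_ij^2.
#'
#' @param d labelled symmetric distance matrix.
#' @return symmetric inner-product matrix with zero row sums.
#' @export
gower_center <- function(d) {
  validate_distance_matrix(d)
  a <- -0.5 * d^2
  n <- nrow(a)
  rm_ <- rowMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  dimnames(g) <- dimnames(d)
  g
}

# Treatment-coded design block for one factor (no intercept column).
# Continuous factors contribute one centered column.
factor_block <- function(x, name) {
  if (is.numeric(x)) {
    out <- matrix(x - mean(x), ncol = 1,
                  dimnames = list(NULL, name))
    return(out)
  }
  f <- factor(x)
  if (nlevels(f) < 2L)
    stop("factor '", name, "' has one level", call. = FALSE)
  mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(mm) <- paste0(name, levels(f)[-1])
  mm
}

# Orthonormal basis (hat matrix) of cbind(1, X); aliased columns dropped
# in input order via pivoted QR rank test on sequential addition.
hat_matrix <- function(X, n) {
  base <- matrix(1 / sqrt(n), nrow = n, ncol = 1)
  kept <- base
  rank <- 1L
  for (j in seq_len(ncol(X))) {
    cand <- cbind(kept, X[, j])
    qr_ <- qr(cand)
    if (qr_$rank > rank) {
      kept <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
      rank <- qr_$rank
    }
  }
  list(H = tcrossprod(kept), df = rank - 1L, rank = rank)
}

new_association_result <- function(factor, r2, p, n_perm, f = NA_real_,
                                   df = NA_integer_, aliased = FALSE) {
  data.frame(factor = factor, r_squared = r2, f_stat = f, df = df,
             p_value = p, n_permutations = n_perm, aliased = aliased,
             stringsAsFactors = FALSE)
}

#' Single-factor PERMANOVA
#'
#' Partitions the total sum of squares of a distance matrix into the part
#' explained by one factor (categorical or continuous) and a residual;
#' significance of the pseudo-F statistic by whole-sample label
#' permutation: p = (1 + #\{permuted F >= observed\}) / (1 + n_perm).
#'
#' @param d labelled distance matrix.
#' @param factor vector aligned with the matrix labels (categorical with
#'   >= 2 levels, or numeric).
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutation stream.
#' @param factor_name label used in the result.
#' @return one-row data.frame: factor, r_squared, f_stat, df, p_value,
#'   n_permutations, aliased.
#' @export
permanova_single <- function(d, factor, n_perm = 999, seed = NULL,
                             factor_name = "factor") {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  n <- nrow(d)
  if (length(factor) != n)
    stop("factor length must match the distance matrix", call. = FALSE)
  G <- gower_center(d)
  X <- factor_block(factor, factor_name)
  hm <- hat_matrix(X, n)
  ss_total <- sum(diag(G))
  ss_model <- sum(hm$H * G)
  df_model <- hm$df
  df_resid <- n - 1L - df_model
  ss_resid <- ss_total - ss_model
  f_obs <- (ss_model / df_model) / (ss_resid / df_resid)
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      ssm <- sum(hm$H * G[p, p])
      fb <- (ssm / df_model) / ((ss_total - ssm) / df_resid)
      if (fb >= f_obs - 1e-12) count <- count + 1L
    }
  })
  new_association_result(factor_name, ss_model / ss_total,
                         (1 + count) / (1 + n_perm), n_perm,
                         f = f_obs, df = df_model)
}

#' Marginal-effects PERMANOVA over several factors
#'
#' For each factor, the marginal sum of squares SS(full) - SS(model
#' without the factor), each factor thereby controlling for all others.
#' Significance by permutation of residuals under the reduced model
#' (Freedman-Lane): the reduced-model residual structure is permuted and
#' the marginal pseudo-F recomputed. Factors adding no rank beyond the
#' remaining ones are flagged `aliased` and reported with R-squared 0.
#'
#' @param d labelled distance matrix.
#' @param factors data.frame of factor columns aligned with the matrix
#'   labels (>= 2 factors).
#' @param n_perm permutations per factor.
#' @param seed RNG seed (one stream reused across factors,
#'   deterministically).
#' @return data.frame with one row per factor (see [permanova_single()]).
#' @export
permanova_marginal <- function(d, factors, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  n <- nrow(d)
  if (nrow(factors) != n)
    stop("factors must align 1:1 with the distance matrix", call. = FALSE)
  if (anyNA(factors)) stop("factors contain missing values", call. = FALSE)
  if (ncol(factors) == 1L)
    return(permanova_single(d, factors[[1]], n_perm = n_perm, seed = seed,
                            factor_name = names(factors)))
  G <- gower_center(d)
  ss_total <- sum(diag(G))
  blocks <- lapply(names(factors), function(nm)
    factor_block(factors[[nm]], nm))
  names(blocks) <- names(factors)
  X_all <- do.call(cbind, blocks)
  full <- hat_matrix(X_all, n)
  ss_full <- sum(full$H * G)
  df_resid <- n - 1L - full$df
  ss_resid <- ss_full_resid <- ss_total - ss_full
  I_n <- diag(n)
  results <- vector("list", length(blocks))
  with_seed(seed, {
    for (j in seq_along(blocks)) {
      nm <- names(blocks)[j]
      X_red <- do.call(cbind, blocks[-j])
      red <- hat_matrix(X_red, n)
      df_j <- full$df - red$df
      if (df_j == 0L) {
        warning("factor '", nm, "' is aliased with the remaining factors; ",
                "reported with R-squared 0", call. = FALSE)
        results[[j]] <- new_association_result(nm, 0, NA_real_, n_perm,
                                               aliased = TRUE)
        next
      }
      Hdiff <- full$H - red$H
      Hres <- I_n - full$H
      ss_margin <- sum(Hdiff * G)
      f_obs <- (ss_margin / df_j) / (ss_resid / df_resid)
      R <- I_n - red$H
      Gr <- R %*% G %*% R
      count <- 0L
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        Gp <- Gr[p, p]
        ssm <- sum(Hdiff * Gp)
        ssr <- sum(Hres * Gp)
        fb <- (ssm / df_j) / (ssr / df_resid)
        if (fb >= f_obs - 1e-12) count <- count + 1L
      }
      results[[j]] <- new_association_result(nm, ss_margin / ss_total,
                                             (1 + count) / (1 + n_perm),
                                             n_perm, f = f_obs, df = df_j)
    }
  })
  do.call(rbind, results)
}
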