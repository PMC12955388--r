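# Spearman co-occurrence networks among taxa, with the literal rho band
# (rho_min < |rho| < 1) and the maximum-degree core-node rule.

#' Spearman co-occurrence network over taxa profiles
#'
#' Keeps every unordered taxon pair with `|rho| > rho_min` (strict),
#' `|rho| < 1` (strict, excluding exactly monotone pairs — set
#' `include_perfect = TRUE` if the bound should only exclude self pairs)
#' and `p < p_max`. Zero-variance taxa are excluded with a warning.
#' Spearman p-values use exact permutation enumeration for n <= 8 samples
#' and the t approximation otherwise; no multiple-testing correction by
#' default (`bh = TRUE` applies Benjamini-Hochberg before filtering).
#'
#' @param profiles taxa x samples numeric matrix (>= 4 samples, taxa as
#'   rownames).
#' @param rho_min lower bound on |rho| (strict).
#' @param p_max upper bound on p (strict).
#' @param include_perfect keep |rho| = 1 edges.
#' @param bh apply Benjamini-Hochberg correction to the p-values.
#' @return data.frame of edges: taxon_a, taxon_b, rho, p_value, sign.
#' @export
correlation_network <- function(profiles, rho_min = 0.6, p_max = 0.05,
                                include_perfect = FALSE, bh = FALSE) {
  m <- as.matrix(profiles)
  if (ncol(m) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (is.null(rownames(m))) stop("taxa rownames required", call. = FALSE)
  v <- apply(m, 1, stats::sd)
  if (any(v == 0)) {
    warning("excluding zero-variance taxa: ",
            paste(rownames(m)[v == 0], collapse = ", "), call. = FALSE)
    m <- m[v > 0, , drop = FALSE]
  }
  taxa <- rownames(m)
  n <- length(taxa)
  rows <- list()
  for (i in seq_len(max(0, n - 1L))) for (j in (i + 1L):n) {
    st <- spearman_test(m[i, ], m[j, ])
    rows[[length(rows) + 1L]] <-
      data.frame(taxon_a = taxa[i], taxon_b = taxa[j], rho = st$rho,
                 p_value = st$p_value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      rho = numeric(), p_value = numeric(),
                      sign = character()))
  edges <- do.call(rbind, rows)
  if (bh) edges$p_value <- stats::p.adjust(edges$p_value, method = "BH")
  keep <- abs(edges$rho) > rho_min & edges$p_value < p_max
  if (!include_perfect) keep <- keep & abs(edges$rho) < 1 - 1e-12
  edges <- edges[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  rownames(edges) <- NULL
  edges
}

#' Core nodes of a correlation network
#'
#' Taxa attaining the maximum degree (number of incident edges); all ties
#' are returned. An empty edge list yields an empty result.
#'
#' @param edges data.frame from [correlation_network()].
#' @return character vector of taxon ids (sorted).
#' @export
core_nodes <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  deg <- table(c(edges$taxon_a, edges$taxon_b))
  sort(names(deg)[deg == max(deg)])
}
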