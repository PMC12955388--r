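# Fragment-based average nucleotide identity (fastANI-style, ungapped) and
# two-stage greedy dereplication (dRep-style primary/secondary thresholds).
# Ungapped scoring is exact for the substitution-only synthetic data model;
# with real genomes containing indels it underestimates ANI (documented).

concat_sequence <- function(x) {
  if (inherits(x, "genome_asset")) paste(x$sequence, collapse = "")
  else paste(toupper(x), collapse = "")
}

genome_id_of <- function(x, default) {
  if (inherits(x, "genome_asset")) x$genome_id
  else if (!is.null(names(x)) && length(x) == 1L) names(x)
  else default
}

#' Exact Hamming identity between equal-length sequences
#'
#' Percent identity over positions where neither sequence has N. This is
#' the exact oracle for ANI on indel-free sequence pairs.
#'
#' @param a,b nucleotide strings of equal length.
#' @return percent identity in \[0, 100\].
#' @export
hamming_identity <- function(a, b) {
  va <- utf8ToInt(concat_sequence(a)); vb <- utf8ToInt(concat_sequence(b))
  if (length(va) != length(vb))
    stop("sequences must have equal length", call. = FALSE)
  ok <- va != .N_INT & vb != .N_INT
  if (!any(ok)) stop("no comparable (non-N) positions", call. = FALSE)
  100 * mean(va[ok] == vb[ok])
}

ref_kmer_vector <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Core fragment-mapping ANI; ref_kmers may be precomputed with
# ref_kmer_vector() to amortise across pairs sharing a reference.
fragment_ani_core <- function(qseq, rseq, fragment_len, k, min_af,
                              probe_stride, ref_kmers = NULL) {
  nq <- nchar(qseq); nr <- nchar(rseq)
  if (nq < fragment_len || nr < fragment_len)
    stop("both sequences must be at least fragment_len long", call. = FALSE)
  if (is.null(ref_kmers)) ref_kmers <- ref_kmer_vector(rseq, k)
  n_frag <- nq %/% fragment_len
  frag_starts <- (seq_len(n_frag) - 1L) * fragment_len + 1L
  offsets <- seq(1L, fragment_len - k + 1L, by = probe_stride)
  # fragment-major ordering: probes of fragment f occupy rows
  # (f-1)*length(offsets) + 1 ... f*length(offsets)
  probe_pos <- rep(frag_starts - 1L, each = length(offsets)) + offsets
  probe_kmer <- substring(qseq, probe_pos, probe_pos + k - 1L)
  keep <- !grepl("N", probe_kmer, fixed = TRUE)
  uniq <- unique(probe_kmer[keep])
  m <- match(ref_kmers, uniq)
  hits <- which(!is.na(m))
  pos_by_probe <- split(hits, m[hits])
  max_start <- nr - fragment_len + 1L
  qv <- utf8ToInt(qseq); rv <- utf8ToInt(rseq)
  ids <- rep(NA_real_, n_frag)
  for (f in seq_len(n_frag)) {
    rows <- (f - 1L) * length(offsets) + seq_along(offsets)
    cands <- integer(0)
    for (jj in seq_along(offsets)) {
      row <- rows[jj]
      if (!keep[row]) next
      pk <- match(probe_kmer[row], uniq)
      rp <- pos_by_probe[[as.character(pk)]]
      if (is.null(rp)) next
      cands <- c(cands, rp - (offsets[jj] - 1L))
    }
    cands <- cands[cands >= 1L & cands <= max_start]
    if (!length(cands)) next
    tab <- table(cands)
    best <- as.integer(names(tab)[tab == max(tab)])
    place <- min(best)                      # leftmost tie-break
    qi <- qv[frag_starts[f]:(frag_starts[f] + fragment_len - 1L)]
    ri <- rv[place:(place + fragment_len - 1L)]
    ok <- qi != .N_INT & ri != .N_INT
    if (!any(ok)) next
    ids[f] <- mean(qi[ok] == ri[ok])
  }
  mapped <- which(!is.na(ids))
  af <- length(mapped) / n_frag
  if (af < min_af)
    list(ani = NA_real_, aligned_fraction = af, unrelated = TRUE)
  else
    list(ani = 100 * mean(ids[mapped]), aligned_fraction = af,
         unrelated = FALSE)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The query is cut into non-overlapping fragments; each fragment is
#' placed on the reference at the position receiving the most shared
#' k-mer votes (leftmost tie-break) and scored by ungapped percent
#' identity there. ANI is the mean identity over mapped fragments;
#' `aligned_fraction` the fraction of fragments that mapped. When fewer
#' than `min_af` of the fragments map the pair is reported as unrelated
#' (`ani = NA`), not as a number.
#'
#' @param query,reference [genome_asset()]s or nucleotide strings
#'   (multi-contig genomes are concatenated).
#' @param fragment_len fragment size in bp.
#' @param k k-mer size used for placement votes.
#' @param min_af minimum aligned fraction below which the pair is
#'   unrelated.
#' @param probe_stride spacing of placement probes within a fragment.
#' @return object of class `genome_pair_similarity`: list with
#'   `genome_a`, `genome_b`, `ani`, `aligned_fraction`, `unrelated`.
#' @export
fragment_ani <- function(query, reference, fragment_len = 1000, k = 16,
                         min_af = 0.3, probe_stride = 25) {
  res <- fragment_ani_core(concat_sequence(query),
                           concat_sequence(reference),
                           fragment_len, k, min_af, probe_stride)
  structure(c(list(genome_a = genome_id_of(query, "query"),
                   genome_b = genome_id_of(reference, "reference")),
              res),
            class = "genome_pair_similarity")
}

#' @export
print.genome_pair_similarity <- function(x, ...) {
  if (x$unrelated)
    cat(sprintf("%s vs %s: unrelated (aligned fraction %.2f)\n",
                x$genome_a, x$genome_b, x$aligned_fraction))
  else
    cat(sprintf("%s vs %s: ANI %.3f%% (aligned fraction %.2f)\n",
                x$genome_a, x$genome_b, x$ani, x$aligned_fraction))
  invisible(x)
}

#' Sketch (k-mer Jaccard) ANI estimate
#'
#' Mash-style coarse estimate from the Jaccard index j of the two genomes'
#' k-mer sets: ANI = 100 (1 + log(2j / (1 + j)) / k). Used for the
#' primary (coarse) dereplication stage only.
#'
#' @inheritParams fragment_ani
#' @return estimated ANI in percent, or NA when no k-mer is shared.
#' @export
sketch_ani <- function(query, reference, k = 16) {
  ua <- unique(ref_kmer_vector(concat_sequence(query), k))
  ub <- unique(ref_kmer_vector(concat_sequence(reference), k))
  ua <- ua[!grepl("N", ua, fixed = TRUE)]
  ub <- ub[!grepl("N", ub, fixed = TRUE)]
  inter <- length(intersect(ua, ub))
  if (inter == 0L) return(NA_real_)
  j <- inter / (length(ua) + length(ub) - inter)
  d <- -log(2 * j / (1 + j)) / k
  max(0, 100 * (1 - d))
}

# Symmetrized fragment ANI (mean of the two directions; NA directions
# dropped; both unrelated -> NA).
symmetric_ani <- function(seq_a, seq_b, fragment_len, k, min_af,
                          probe_stride, kmers_a = NULL, kmers_b = NULL) {
  ab <- fragment_ani_core(seq_a, seq_b, fragment_len, k, min_af,
                          probe_stride, ref_kmers = kmers_b)
  ba <- fragment_ani_core(seq_b, seq_a, fragment_len, k, min_af,
                          probe_stride, ref_kmers = kmers_a)
  vals <- c(ab$ani, ba$ani)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Pairwise ANI distance matrix for a set of genomes
#'
#' d = 1 - ANI/100 with ANI symmetrized as the mean of the two mapping
#' directions. Unrelated pairs (no direction reaches `min_af` aligned
#' fraction) are capped at d = 1 - `primary`, a documented convention
#' keeping the matrix bounded, not a measurement.
#'
#' @param genomes list of [genome_asset()] (>= 2).
#' @inheritParams fragment_ani
#' @param primary primary ANI threshold defining the unrelated-pair cap.
#' @return labelled symmetric distance matrix.
#' @export
ani_distance_matrix <- function(genomes, fragment_len = 1000, k = 16,
                                min_af = 0.3, probe_stride = 25,
                                primary = 0.90) {
  if (length(genomes) < 2L) stop("need at least 2 genomes", call. = FALSE)
  ids <- vapply(genomes, `[[`, "", "genome_id")
  seqs <- vapply(genomes, concat_sequence, "")
  kmers <- lapply(seqs, ref_kmer_vector, k = k)
  n <- length(genomes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  cap <- 1 - primary
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ani <- symmetric_ani(seqs[i], seqs[j], fragment_len, k, min_af,
                         probe_stride, kmers_a = kmers[[i]],
                         kmers_b = kmers[[j]])
    d[i, j] <- d[j, i] <- if (is.na(ani)) cap else max(0, 1 - ani / 100)
  }
  validate_distance_matrix(d)
  d
}

genome_score <- function(g) g$completeness - 5 * g$contamination

# Canonical processing order: best quality score first, ties by longer
# genome then lexicographic id — input-order invariant by construction.
canonical_order <- function(genomes) {
  score <- vapply(genomes, genome_score, 0)
  len <- vapply(genomes, genome_length, 0)
  ids <- vapply(genomes, `[[`, "", "genome_id")
  order(-score, -len, ids)
}

#' Two-stage greedy dereplication of genomes into clusters
#'
#' Primary stage: single-linkage components at sketch ANI >=
#' `primary * 100` (coarse k-mer Jaccard estimate). Secondary stage:
#' within each component, greedy complete-linkage subclusters at
#' symmetrized fragment ANI >= `secondary * 100`, seeded in canonical
#' quality order (score = completeness - 5 contamination, ties by longer
#' genome then id). The seed of each subcluster is its representative.
#' The result is independent of input order.
#'
#' @param genomes quality-filtered list of [genome_asset()].
#' @param primary,secondary ANI thresholds as fractions (dRep's -pa/-sa).
#' @inheritParams fragment_ani
#' @return list of clusters, each `list(cluster_id, members,
#'   representative)`; clusters partition the input.
#' @export
dereplicate <- function(genomes, primary = 0.90, secondary = 0.95,
                        fragment_len = 1000, k = 16, min_af = 0.3,
                        probe_stride = 25) {
  n <- length(genomes)
  if (n == 0L) return(list())
  ord <- canonical_order(genomes)
  genomes <- genomes[ord]
  ids <- vapply(genomes, `[[`, "", "genome_id")
  seqs <- vapply(genomes, concat_sequence, "")
  kmers <- lapply(seqs, ref_kmer_vector, k = k)
  # primary: union-find single linkage on sketch ANI
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sketch_ani(seqs[i], seqs[j], k = k)
    if (!is.na(s) && s >= primary * 100 - 1e-9) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  clusters <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)          # already in canonical order
    unassigned <- idx
    while (length(unassigned)) {
      seed <- unassigned[1]
      members <- seed
      for (g in unassigned[-1]) {
        ok <- all(vapply(members, function(m) {
          a <- symmetric_ani(seqs[g], seqs[m], fragment_len, k, min_af,
                             probe_stride, kmers_a = kmers[[g]],
                             kmers_b = kmers[[m]])
          !is.na(a) && a >= secondary * 100 - 1e-9
        }, logical(1)))
        if (ok) members <- c(members, g)
      }
      clusters[[length(clusters) + 1L]] <-
        list(members = ids[members], representative = ids[seed])
      unassigned <- setdiff(unassigned, members)
    }
  }
  reps <- vapply(clusters, `[[`, "", "representative")
  clusters <- clusters[order(reps)]
  lapply(seq_along(clusters), function(i)
    structure(list(cluster_id = sprintf("C%d", i),
                   members = clusters[[i]]$members,
                   representative = clusters[[i]]$representative),
              class = "genome_cluster"))
}
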