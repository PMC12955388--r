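# Core inference: which species populations are shared within families.
# Candidate populations (genomes from >= 2 members of enough families) are
# tested for family association of their genome-to-genome ANI distances;
# populations passing R-squared > 0.5 and p < 0.05 (strict, as
# conventional) are flagged shared, and sharing events / family prevalence
# are counted at an ANI threshold. Classical MDS projects the matrices.

#' Select candidate species populations for the sharing analysis
#'
#' A species qualifies when at least `min_members` distinct members of the
#' same family contributed a genome, in at least `min_family_frac` of all
#' cohort families (both comparisons inclusive; the denominator is all
#' families, including those of size 1).
#'
#' @param genomes list of [genome_asset()].
#' @param cohort a [family_cohort()].
#' @param min_members minimum same-family members with a genome.
#' @param min_family_frac minimum fraction of all families.
#' @return list of candidate populations, each `list(species_label,
#'   genomes, families_with_pairs)`.
#' @export
select_candidates <- function(genomes, cohort, min_members = 2,
                              min_family_frac = 0.30) {
  fam <- sample_family(cohort)
  n_families <- length(cohort$families)
  species <- vapply(genomes, `[[`, "", "species_label")
  out <- list()
  for (sp in sort(unique(species))) {
    gs <- genomes[species == sp]
    samp <- unique(vapply(gs, `[[`, "", "sample_id"))
    if (anyNA(fam[samp]))
      stop("genome sample(s) not in cohort: ",
           paste(samp[is.na(fam[samp])], collapse = ", "), call. = FALSE)
    counts <- table(fam[samp])
    fams <- names(counts)[counts >= min_members]
    if (length(fams) / n_families >= min_family_frac)
      out[[sp]] <- list(species_label = sp, genomes = gs,
                        families_with_pairs = sort(fams))
  }
  unname(out)
}

# One genome per sample: keep the highest-quality genome (same score and
# tie-breaks as the dereplication representative rule).
one_genome_per_sample <- function(genomes) {
  samp <- vapply(genomes, `[[`, "", "sample_id")
  keep <- integer(0)
  for (s in unique(samp)) {
    idx <- which(samp == s)
    keep <- c(keep, idx[canonical_order(genomes[idx])[1]])
  }
  genomes[sort(keep)]
}

#' Family association of a population's genome genetic variation
#'
#' Builds the population's pairwise ANI distance matrix and runs a
#' single-factor PERMANOVA with factor = family of each genome's sample.
#' The population is flagged shared when `R-squared > r2_threshold` and
#' `p < p_threshold` (both strict). Family is the only factor at genome
#' level, so the single-factor test is the appropriate one.
#'
#' @param population a candidate from [select_candidates()].
#' @param cohort a [family_cohort()].
#' @param r2_threshold,p_threshold flagging thresholds (strict
#'   comparisons).
#' @param n_perm,seed permutation settings.
#' @param ani_params list of arguments passed to [ani_distance_matrix()].
#' @param dist optional precomputed distance matrix (skips ANI).
#' @return list with `species_label`, `shared_flag`, `r_squared`,
#'   `p_value`, `n_genomes`, `dist` (the ANI distance matrix).
#' @export
family_association <- function(population, cohort, r2_threshold = 0.5,
                               p_threshold = 0.05, n_perm = 999,
                               seed = NULL, ani_params = list(),
                               dist = NULL) {
  gs <- one_genome_per_sample(population$genomes)
  fam <- sample_family(cohort)[vapply(gs, `[[`, "", "sample_id")]
  if (length(unique(fam)) < 2L)
    stop("no between-family contrast: all genomes of ",
         population$species_label, " come from one family", call. = FALSE)
  if (is.null(dist))
    dist <- do.call(ani_distance_matrix, c(list(gs), ani_params))
  res <- permanova_single(dist, as.character(fam), n_perm = n_perm,
                          seed = seed, factor_name = "family")
  list(species_label = population$species_label,
       shared_flag = res$r_squared > r2_threshold &&
         res$p_value < p_threshold,
       r_squared = res$r_squared, p_value = res$p_value,
       n_genomes = length(gs), dist = dist)
}

#' Count sharing events and family prevalence of a population
#'
#' A sharing event is one within-family genome pair at or above the
#' sharing ANI threshold; `family_prevalence` counts distinct families
#' contributing at least one such pair. The ANI defining one "sharing"
#' has no canonical published value; the default 99.5 sits between the
#' ~95% species boundary and strain-identity thresholds and is
#' configurable — treat it as a tunable convention.
#'
#' @param population a candidate from [select_candidates()].
#' @param cohort a [family_cohort()].
#' @param sharing_ani ANI threshold in percent (inclusive).
#' @param dist optional precomputed ANI distance matrix (d = 1 - ANI/100).
#' @param per_family when TRUE, count at most one event per family
#'   (alternative convention); default counts every qualifying pair.
#' @param ani_params list of arguments for [ani_distance_matrix()].
#' @return list with `species_label`, `sharing_times`,
#'   `family_prevalence`.
#' @export
count_sharing <- function(population, cohort, sharing_ani = 99.5,
                          dist = NULL, per_family = FALSE,
                          ani_params = list()) {
  gs <- one_genome_per_sample(population$genomes)
  if (is.null(dist))
    dist <- do.call(ani_distance_matrix, c(list(gs), ani_params))
  ids <- rownames(dist)
  samp <- stats::setNames(vapply(gs, `[[`, "", "sample_id"),
                          vapply(gs, `[[`, "", "genome_id"))[ids]
  fam <- sample_family(cohort)[samp]
  ani <- (1 - dist) * 100
  n <- nrow(dist)
  events_fam <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (fam[i] == fam[j] && ani[i, j] >= sharing_ani - 1e-9)
      events_fam <- c(events_fam, fam[i])
  }
  times <- if (per_family) length(unique(events_fam)) else length(events_fam)
  list(species_label = population$species_label,
       sharing_times = times,
       family_prevalence = length(unique(events_fam)))
}

#' Classical multidimensional scaling (Torgerson / PCoA)
#'
#' Eigendecomposition of the Gower-centered matrix; the top-k
#' non-negative eigenpairs give the coordinates, ordered by eigenvalue.
#' Sign convention: on each axis the largest-magnitude loading is made
#' positive, so the embedding is deterministic. If fewer than k positive
#' eigenvalues exist, fewer axes are returned with a warning.
#'
#' @param d labelled distance matrix (n >= 3).
#' @param k requested number of axes.
#' @return matrix labels x k' (k' <= k) of coordinates, with eigenvalues
#'   as attribute `eig`.
#' @export
classical_mds <- function(d, k = 2) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  g <- gower_center(d)
  eig <- eigen(g, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- which(eig$values > tol)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes", call. = FALSE)
    k <- length(pos)
  }
  if (k == 0L) return(matrix(0, n, 0, dimnames = list(rownames(d), NULL)))
  idx <- pos[seq_len(k)]
  coords <- eig$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(eig$values[idx]), nrow = k)
  for (a in seq_len(k)) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  dimnames(coords) <- list(rownames(d), paste0("MDS", seq_len(k)))
  attr(coords, "eig") <- eig$values
  coords
}

#' Sample-by-sample intraspecies genetic-composition distance
#'
#' Convention (the underlying quantity has no single published
#' definition): per sample, concatenate the major-allele frequencies at
#' the union of polymorphic sites of every profiled species; a species
#' absent from a sample contributes zeros, a present species contributes
#' frequency 1 at sites where it is not polymorphic. Bray-Curtis over the
#' concatenated vectors.
#'
#' @param snv_profiles named list of [snv_profile()].
#' @param cohort a [family_cohort()].
#' @param genome_meta data.frame mapping `genome_id` to `sample_id` and
#'   `species_label` (e.g. [genome_table()]).
#' @return labelled distance matrix over the samples present in the
#'   profiles.
#' @export
genetic_composition_distance <- function(snv_profiles, cohort, genome_meta) {
  gm <- genome_meta
  samples <- intersect(cohort$samples$sample_id, unique(gm$sample_id))
  no_profile <- setdiff(cohort$samples$sample_id, samples)
  if (length(no_profile))
    stop("sample(s) with no profiled species: ",
         paste(no_profile, collapse = ", "), call. = FALSE)
  if (length(samples) < 2L)
    stop("need SNV profiles for at least 2 samples", call. = FALSE)
  profile_by_genome <- stats::setNames(snv_profiles,
                                       vapply(snv_profiles, `[[`, "",
                                              "genome_id"))
  blocks <- list()
  for (sp in sort(unique(gm$species_label))) {
    gsp <- gm[gm$species_label == sp, ]
    site_key <- unique(unlist(lapply(gsp$genome_id, function(gid) {
      s <- profile_by_genome[[gid]]$sites
      if (!is.null(s) && nrow(s)) paste(s$contig, s$position)
      else character(0)
    })))
    site_key <- sort(site_key)
    if (!length(site_key)) next
    block <- matrix(0, nrow = length(samples), ncol = length(site_key),
                    dimnames = list(samples, site_key))
    for (r in seq_len(nrow(gsp))) {
      smp <- gsp$sample_id[r]
      if (!smp %in% samples) next
      s <- profile_by_genome[[gsp$genome_id[r]]]$sites
      block[smp, ] <- 1                    # present, monomorphic default
      if (!is.null(s) && nrow(s)) {
        counts <- as.matrix(s[, c("A", "C", "G", "T")])
        major <- apply(counts, 1, max) / rowSums(counts)
        block[smp, paste(s$contig, s$position)] <- major
      }
    }
    colnames(block) <- paste(sp, site_key)
    blocks[[sp]] <- block
  }
  if (!length(blocks))
    stop("no polymorphic sites in any profile", call. = FALSE)
  bray_curtis(do.call(cbind, blocks))
}

#' Full sharing analysis of candidate populations
#'
#' Runs [family_association()] and [count_sharing()] on every candidate,
#' reusing one ANI distance matrix per population.
#'
#' @inheritParams family_association
#' @inheritParams count_sharing
#' @param candidates list from [select_candidates()].
#' @return list with `table` (one row per population: species_label,
#'   n_genomes, r_squared, p_value, shared_flag, sharing_times,
#'   family_prevalence) and `dists` (named list of ANI distance matrices).
#' @export
sharing_analysis <- function(candidates, cohort, r2_threshold = 0.5,
                             p_threshold = 0.05, sharing_ani = 99.5,
                             n_perm = 999, seed = NULL,
                             ani_params = list()) {
  rows <- list(); dists <- list()
  for (i in seq_along(candidates)) {
    pop <- candidates[[i]]
    fa <- family_association(pop, cohort, r2_threshold, p_threshold,
                             n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else seed + i,
                             ani_params = ani_params)
    cs <- count_sharing(pop, cohort, sharing_ani, dist = fa$dist)
    dists[[pop$species_label]] <- fa$dist
    rows[[i]] <- data.frame(species_label = pop$species_label,
                            n_genomes = fa$n_genomes,
                            r_squared = fa$r_squared,
                            p_value = fa$p_value,
                            shared_flag = fa$shared_flag,
                            sharing_times = cs$sharing_times,
                            family_prevalence = cs$family_prevalence,
                            stringsAsFactors = FALSE)
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(species_label = character(), n_genomes = integer(),
                    r_squared = numeric(), p_value = numeric(),
                    shared_flag = logical(), sharing_times = integer(),
                    family_prevalence = integer()),
       dists = dists)
}
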