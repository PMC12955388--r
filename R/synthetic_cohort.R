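# Family-structured synthetic cohorts with known ground truth: planted
# strain transmissions (near-identical genomes within a family) and a
# planted family abundance effect. Strain evolution is substitution-only so
# an exact Hamming-identity oracle exists for every ANI computation.

.BASE_INT <- c(A = 65L, C = 67L, G = 71L, T = 84L)  # utf8 codes
.N_INT <- 78L

#' Simulation configuration for a synthetic family cohort
#'
#' Defaults emulate the analysed study design: 25 families with 2-4
#' enrolled members each (father, mother, children), three ethnic groups
#' and regions, a handful of genome-resolved species plus a wider abundance
#' table, 2% within-species strain divergence from the species ancestor and
#' 0.01% divergence between transmitted (shared) strains.
#'
#' @param n_families number of families.
#' @param members_per_family integer vector of length `n_families`, a single
#'   integer, or NULL to draw uniformly from 2:4 per family.
#' @param n_species number of genome-resolved species (one genome per
#'   sample per species).
#' @param n_abundance_taxa total taxa in the abundance matrix (>=
#'   `n_species`; the first `n_species` labels coincide with the
#'   genome-resolved species).
#' @param genome_length ancestral genome length in bp.
#' @param substitution_rate_within_species substitutions/site separating a
#'   host strain from the species ancestor.
#' @param transmission_divergence substitutions/site between the two
#'   strains of a planted transmission pair; must be below the
#'   within-species rate.
#' @param transmission_pairs data.frame with columns `family_id`,
#'   `species_label`: planted within-family sharing events. NULL for none.
#' @param family_effect_size dimensionless scale of the per-family,
#'   per-taxon log-abundance shift (0 switches the family effect off).
#' @param abundance_noise_sd sd of the iid log-abundance noise.
#' @param diversity_coupling when > 0, families drawn with higher alpha
#'   diversity also get more similar members (richness and noise coupled to
#'   one family deviate); 0 disables the coupling.
#' @param depth sequencing depth at which SNV allele counts are drawn.
#' @param residual_het_rate per-site rate of residual within-host
#'   heterogeneity generating polymorphic sites in single-strain genomes.
#' @param seed RNG seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(n_families = 25, members_per_family = NULL,
                              n_species = 3, n_abundance_taxa = 40,
                              genome_length = 20000,
                              substitution_rate_within_species = 0.02,
                              transmission_divergence = 1e-4,
                              transmission_pairs = NULL,
                              family_effect_size = 1,
                              abundance_noise_sd = 0.5,
                              diversity_coupling = 0,
                              depth = 50, residual_het_rate = 1e-4,
                              seed = 1) {
  stopifnot_scalar_number(substitution_rate_within_species,
                          "substitution_rate_within_species", 0, 0.5)
  stopifnot_scalar_number(transmission_divergence, "transmission_divergence",
                          0, 0.5)
  if (!is.null(transmission_pairs) && nrow(transmission_pairs) > 0 &&
      transmission_divergence >= substitution_rate_within_species)
    stop("transmission_divergence must be smaller than ",
         "substitution_rate_within_species", call. = FALSE)
  stopifnot_scalar_number(residual_het_rate, "residual_het_rate", 0, 0.5)
  if (n_abundance_taxa < n_species)
    stop("n_abundance_taxa must be >= n_species", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = members_per_family,
                 n_species = as.integer(n_species),
                 n_abundance_taxa = as.integer(n_abundance_taxa),
                 genome_length = as.integer(genome_length),
                 substitution_rate_within_species =
                   substitution_rate_within_species,
                 transmission_divergence = transmission_divergence,
                 transmission_pairs = transmission_pairs,
                 family_effect_size = family_effect_size,
                 abundance_noise_sd = abundance_noise_sd,
                 diversity_coupling = diversity_coupling,
                 depth = as.integer(depth),
                 residual_het_rate = residual_het_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Mutate a genome by independent point substitutions
#'
#' Each non-N site is substituted independently with probability
#' `substitution_rate` to a uniformly chosen different base. Length is
#' preserved (no indels), so the Hamming distance to the input is
#' Binomial(#non-N sites, rate).
#'
#' @param sequence non-empty nucleotide string (A/C/G/T/N).
#' @param substitution_rate per-site substitution probability in \[0, 0.5\].
#' @param seed optional seed making the call reproducible in isolation;
#'   NULL mutates in the ambient RNG stream.
#' @return mutated sequence (same length).
#' @export
mutate_genome <- function(sequence, substitution_rate, seed = NULL) {
  stopifnot_scalar_number(substitution_rate, "substitution_rate", 0, 0.5)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  with_seed(seed, {
    v <- utf8ToInt(sequence)
    eligible <- which(v != .N_INT)
    if (substitution_rate > 0 && length(eligible)) {
      hit <- eligible[stats::runif(length(eligible)) < substitution_rate]
      if (length(hit)) {
        b <- match(v[hit], .BASE_INT)
        off <- sample.int(3L, length(hit), replace = TRUE)
        v[hit] <- .BASE_INT[((b - 1L + off) %% 4L) + 1L]
      }
    }
    intToUtf8(v)
  })
}

random_genome <- function(length_bp) {
  intToUtf8(.BASE_INT[sample.int(4L, length_bp, replace = TRUE)])
}

# Remove in-frame stop codons inside gene regions of an ancestor genome.
# '+' genes: replace TAA/TAG/TGA codons (first base T -> C).
# '-' genes: genomic triplets whose reverse complement is a stop are
# TTA/CTA/TCA; replace the last base (A -> G).
strip_stops <- function(seq, genes) {
  v <- strsplit(seq, "")[[1]]
  stops_fwd <- c("TAA", "TAG", "TGA")
  stops_rev <- c("TTA", "CTA", "TCA")
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]
    starts <- seq(s, e - 2L, by = 3L)
    cod <- paste0(v[starts], v[starts + 1L], v[starts + 2L])
    if (genes$strand[i] == "+") {
      bad <- which(cod %in% stops_fwd)
      if (length(bad)) v[starts[bad]] <- "C"
    } else {
      bad <- which(cod %in% stops_rev)
      if (length(bad)) v[starts[bad] + 2L] <- "G"
    }
  }
  paste(v, collapse = "")
}

# Codon-aware gene models tiling >= 50% of a genome: 900 bp genes every
# 1500 bp (60% coverage), every 4th gene on the minus strand.
tile_gene_models <- function(species_label, contig, genome_length,
                             gene_len = 900L, period = 1500L) {
  starts <- seq(1L, genome_length - gene_len + 1L, by = period)
  n <- length(starts)
  if (!n) return(data.frame(gene_id = character(), contig = character(),
                            start = integer(), end = integer(),
                            strand = character()))
  data.frame(gene_id = sprintf("%s_g%03d", species_label, seq_len(n)),
             contig = contig,
             start = starts, end = starts + gene_len - 1L,
             strand = ifelse(seq_len(n) %% 4L == 0L, "-", "+"),
             stringsAsFactors = FALSE)
}

# KO pool: the SCFA-module KOs from the packaged fixture plus generic ones,
# assigned round-robin so every module step is hit somewhere.
annotate_genes <- function(genes) {
  mods <- read_module_definitions(system.file("extdata", "scfa_modules.txt",
                                              package = "famshare"))
  mod_kos <- unique(unlist(lapply(mods, function(m) unlist(m$steps))))
  generic <- sprintf("K%05d", 10000 + seq_len(40))
  pool <- c(mod_kos, generic)
  n <- nrow(genes)
  recs <- data.frame(gene_id = genes$gene_id, annotation_type = "KO",
                     label = pool[((seq_len(n) - 1L) %% length(pool)) + 1L],
                     stringsAsFactors = FALSE)
  caz <- genes$gene_id[seq_len(n) %% 5L == 2L]
  if (length(caz))
    recs <- rbind(recs, data.frame(gene_id = caz, annotation_type = "CAZyme",
                                   label = sprintf("GH%d", 1 + (seq_along(caz) %% 30)),
                                   stringsAsFactors = FALSE))
  res <- genes$gene_id[seq_len(n) %% 7L == 3L]
  if (length(res))
    recs <- rbind(recs, data.frame(gene_id = res,
                                   annotation_type = "resistance",
                                   label = sprintf("ARO:%07d", 3000000 + seq_along(res)),
                                   stringsAsFactors = FALSE))
  recs
}

draw_snv_sites <- function(strain_seq, contig, depth, rate) {
  L <- nchar(strain_seq)
  n_sites <- stats::rbinom(1L, L, rate)
  if (n_sites == 0L)
    return(data.frame(contig = character(), position = integer(),
                      ref = character(), A = integer(), C = integer(),
                      G = integer(), T = integer()))
  pos <- sort(sample.int(L, n_sites))
  v <- utf8ToInt(strain_seq)[pos]
  keep <- v != .N_INT
  pos <- pos[keep]; v <- v[keep]
  if (!length(pos))
    return(data.frame(contig = character(), position = integer(),
                      ref = character(), A = integer(), C = integer(),
                      G = integer(), T = integer()))
  ref_idx <- match(v, .BASE_INT)
  alt_idx <- ((ref_idx - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L
  maf <- stats::runif(length(pos), 0.1, 0.45)
  minor <- pmax(1L, round(maf * depth))
  counts <- matrix(0L, nrow = length(pos), ncol = 4L,
                   dimnames = list(NULL, names(.BASE_INT)))
  counts[cbind(seq_along(pos), ref_idx)] <- depth - minor
  counts[cbind(seq_along(pos), alt_idx)] <- minor
  data.frame(contig = contig, position = pos,
             ref = names(.BASE_INT)[ref_idx],
             A = counts[, "A"], C = counts[, "C"],
             G = counts[, "G"], T = counts[, "T"],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic family cohort with planted ground truth
#'
#' Produces, deterministically from the configuration seed: cohort
#' metadata; one ancestral genome per species with codon-aware gene models
#' tiling >= 50% of it; per-host strains derived from the ancestor by point
#' mutation, except planted transmission pairs whose two strains descend
#' from one common donor; a log-normal abundance matrix with an additive
#' per-family random effect; SNV profiles at fixed depth; KO / CAZyme /
#' resistance gene annotations; and a truth record of what was planted.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: list with elements `cohort`,
#'   `genomes`, `ancestors`, `abundance`, `snv_profiles`, `gene_models`,
#'   `annotations`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  nf <- config$n_families
  sizes <- config$members_per_family
  if (is.null(sizes)) sizes <- sample(2:4, nf, replace = TRUE)
  if (length(sizes) == 1L) sizes <- rep(sizes, nf)
  if (length(sizes) != nf)
    stop("members_per_family must have length 1 or n_families", call. = FALSE)
  family_ids <- sprintf("F%02d", seq_len(nf))
  ethnicities <- sample(c("Daur", "Evenki", "Buryat"), nf, replace = TRUE)
  regions <- sample(c("regionA", "regionB", "regionC"), nf, replace = TRUE)
  rows <- lapply(seq_len(nf), function(f) {
    m <- sizes[f]
    role <- c("father", "mother", rep("child", max(0L, m - 2L)))[seq_len(m)]
    sex <- ifelse(role == "father", "M",
                  ifelse(role == "mother", "F",
                         sample(c("M", "F"), m, replace = TRUE)))
    age <- ifelse(role == "child", round(stats::runif(m, 1, 13), 1),
                  round(stats::runif(m, 28, 55), 1))
    data.frame(sample_id = sprintf("%s_S%d", family_ids[f], seq_len(m)),
               family_id = family_ids[f], role = role,
               ethnicity = ethnicities[f], sex = sex, age = age,
               region = regions[f], stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  cohort <- family_cohort(meta)
  n_samples <- nrow(meta)

  species <- sprintf("sp%d", seq_len(config$n_species))
  trans <- config$transmission_pairs
  if (!is.null(trans) && nrow(trans)) {
    for (i in seq_len(nrow(trans))) {
      fam <- as.character(trans$family_id[i])
      if (!fam %in% family_ids)
        stop("transmission planted in unknown family ", fam, call. = FALSE)
      if (sum(meta$family_id == fam) < 2L)
        stop("transmission planted in family ", fam,
             " with fewer than 2 members", call. = FALSE)
      if (!as.character(trans$species_label[i]) %in% species)
        stop("transmission planted for unknown species ",
             trans$species_label[i], call. = FALSE)
    }
  }

  ancestors <- list(); gene_models <- list(); genomes <- list()
  snv_profiles <- list()
  for (sp in species) {
    contig <- paste0(sp, "_c1")
    genes <- tile_gene_models(sp, contig, config$genome_length)
    anc <- strip_stops(random_genome(config$genome_length), genes)
    ancestors[[sp]] <- stats::setNames(anc, contig)
    gene_models[[sp]] <- genes
    # donors for planted transmissions in this species
    donors <- list()
    if (!is.null(trans) && nrow(trans)) {
      for (fam in trans$family_id[trans$species_label == sp])
        donors[[as.character(fam)]] <-
          mutate_genome(anc, config$substitution_rate_within_species)
    }
    for (i in seq_len(n_samples)) {
      fam <- meta$family_id[i]
      member_rank <- match(meta$sample_id[i], cohort$families[[fam]])
      if (!is.null(donors[[fam]]) && member_rank <= 2L)
        strain <- mutate_genome(donors[[fam]], config$transmission_divergence)
      else
        strain <- mutate_genome(anc, config$substitution_rate_within_species)
      gid <- paste0(meta$sample_id[i], "_", sp)
      g <- genome_asset(gid, meta$sample_id[i], sp,
                        stats::setNames(strain, contig),
                        completeness = round(stats::runif(1, 70, 100), 1),
                        contamination = round(stats::runif(1, 0, 5), 1))
      genomes[[gid]] <- g
      snv_profiles[[gid]] <- snv_profile(gid,
        draw_snv_sites(strain, contig, config$depth,
                       config$residual_het_rate))
    }
  }

  taxa <- c(species, sprintf("tax%02d", seq_len(config$n_abundance_taxa -
                                                  config$n_species)))
  baseline <- stats::rnorm(length(taxa), mean = 2, sd = 1)
  fam_z <- stats::rnorm(nf)                     # diversity-coupling deviate
  u <- matrix(stats::rnorm(nf * length(taxa)), nrow = nf,
              dimnames = list(family_ids, taxa))
  ab <- matrix(0, nrow = n_samples, ncol = length(taxa),
               dimnames = list(meta$sample_id, taxa))
  fam_of <- meta$family_id
  for (i in seq_len(n_samples)) {
    f <- match(fam_of[i], family_ids)
    sd_i <- config$abundance_noise_sd *
      exp(-config$diversity_coupling * fam_z[f])
    ab[i, ] <- exp(baseline + config$family_effect_size * u[f, ] +
                     stats::rnorm(length(taxa), sd = sd_i))
  }
  if (config$diversity_coupling > 0) {
    # low-diversity families lose rare taxa: mask taxa with small baseline
    # in families with negative deviate
    for (f in seq_len(nf)) {
      if (fam_z[f] < 0) {
        n_drop <- min(length(taxa) - 2L,
                      ceiling(-fam_z[f] * config$diversity_coupling *
                                length(taxa) / 3))
        drop <- order(baseline)[seq_len(n_drop)]
        ab[fam_of == family_ids[f], drop] <- 0
      }
    }
  }

  all_genes <- do.call(rbind, gene_models)
  truth <- list(shared = if (is.null(trans))
                  data.frame(family_id = character(),
                             species_label = character())
                else trans[, c("family_id", "species_label")],
                effects = c(family = config$family_effect_size))
  structure(list(cohort = cohort, genomes = unname(genomes),
                 ancestors = ancestors, abundance = ab,
                 snv_profiles = snv_profiles, gene_models = all_genes,
                 annotations = annotate_genes(all_genes),
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples / %d families, %d ",
                     "genomes (%d species), %d planted transmissions\n"),
              nrow(x$cohort$samples), length(x$cohort$families),
              length(x$genomes), x$config$n_species, nrow(x$truth$shared)))
  invisible(x)
}

#' Write a synthetic cohort as a complete plain-text input bundle
#'
#' Emits everything the pipeline reads: `metadata.tsv`, `genomes.fasta` +
#' `genomes.tsv`, `abundance.tsv` (RPKM), `counts.tsv` + `lengths.tsv`
#' (read counts from which RPKM can be recomputed), `snv.tsv`,
#' `genes.tsv`, `annotations.tsv`, `modules.txt` (SCFA module fixture) and
#' `truth.tsv`.
#'
#' @param sc a [generate_cohort()] result.
#' @param dir output directory (created).
#' @param total_reads nominal mapped reads per sample used to derive the
#'   integer count table from the RPKM matrix.
#' @return `dir`, invisibly.
#' @export
write_input_bundle <- function(sc, dir, total_reads = 1e7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata(sc$cohort, file.path(dir, "metadata.tsv"))
  write_genomes(sc$genomes, dir)
  write_abundance(sc$abundance, file.path(dir, "abundance.tsv"))
  taxa <- colnames(sc$abundance)
  len <- ifelse(taxa %in% sprintf("sp%d", seq_len(sc$config$n_species)),
                sc$config$genome_length, 2e6)
  counts <- round(sweep(sc$abundance, 2, (len / 1000) * (total_reads / 1e6),
                        `*`))
  write_abundance(counts, file.path(dir, "counts.tsv"))
  write_tsv(data.frame(label = taxa, length_bp = len,
                       total_reads = total_reads),
            file.path(dir, "lengths.tsv"))
  write_snv_profiles(sc$snv_profiles, file.path(dir, "snv.tsv"))
  write_tsv(sc$gene_models, file.path(dir, "genes.tsv"))
  write_tsv(sc$annotations, file.path(dir, "annotations.tsv"))
  file.copy(system.file("extdata", "scfa_modules.txt", package = "famshare"),
            file.path(dir, "modules.txt"), overwrite = TRUE)
  write_tsv(sc$truth$shared, file.path(dir, "truth.tsv"))
  invisible(dir)
}
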