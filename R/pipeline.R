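# Orchestration: run the full family-sharing analysis on an input bundle
# (typically one written by write_input_bundle) and emit one TSV per stage
# plus a manifest that records every threshold, so a run is reproducible
# from the manifest alone. All stages are single-threaded and seeded.

default_pipeline_params <- function() {
  list(min_completeness = 50, max_contamination = 10,
       primary = 0.90, secondary = 0.95,
       min_members = 2, min_family_frac = 0.30,
       r2_threshold = 0.5, p_threshold = 0.05, sharing_ani = 99.5,
       module_cutoff = 0.66, rho_min = 0.6, p_max = 0.05,
       n_perm = 999, fragment_len = 1000, k = 16, min_af = 0.3,
       probe_stride = 25)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Marginal PERMANOVA over the metadata factors, dropping factors that are
# constant in this cohort (they carry no contrast).
metadata_permanova <- function(d, cohort, n_perm, seed) {
  meta <- cohort$samples
  meta <- meta[match(rownames(d), meta$sample_id), ]
  factors <- data.frame(family = meta$family_id, role = meta$role,
                        ethnicity = meta$ethnicity, sex = meta$sex,
                        age = meta$age, region = meta$region,
                        stringsAsFactors = FALSE)
  constant <- vapply(factors, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant)) {
    stage_log("permanova", "dropping constant factor(s): %s",
              paste(names(factors)[constant], collapse = ", "))
    factors <- factors[, !constant, drop = FALSE]
  }
  if (ncol(factors) == 0L) stop("no non-constant factor", call. = FALSE)
  permanova_marginal(d, factors, n_perm = n_perm, seed = seed)
}

#' Run the full family-sharing analysis pipeline
#'
#' Reads an input bundle (see [write_input_bundle()] for the layout),
#' executes quality filtering, dereplication, abundance/diversity,
#' marginal PERMANOVA at the community and intraspecies-genetic levels,
#' candidate selection, family-association and sharing counts, MDS of
#' flagged populations, nucleotide diversity and pN/pS, module detection
#' and co-occurrence networks, writing one TSV per stage plus
#' `manifest.json` into `out_dir`. Any stage error aborts with the stage
#' name; partial outputs are retained next to a `FAILED` marker.
#'
#' @param input_dir directory with the input bundle.
#' @param out_dir report directory (created).
#' @param params named list overriding [default_pipeline_params()]
#'   entries.
#' @param seed integer seed for every permutation stream.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(input_dir, out_dir, params = list(), seed = 1) {
  p <- utils::modifyList(default_pipeline_params(), params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "read_inputs"
    cohort <- read_metadata(file.path(input_dir, "metadata.tsv"))
    genomes <- read_genomes(input_dir)
    stage_log(stage, "%d samples, %d genomes", nrow(cohort$samples),
              length(genomes))

    stage <- "quality_filter"
    genomes <- quality_filter(genomes, p$min_completeness,
                              p$max_contamination)
    stage_log(stage, "%d genomes pass completeness >= %g, contamination <= %g",
              length(genomes), p$min_completeness, p$max_contamination)
    write_tsv(genome_table(genomes), file.path(out_dir, "filtered_genomes.tsv"))

    stage <- "dereplicate"
    clusters <- dereplicate(genomes, primary = p$primary,
                            secondary = p$secondary,
                            fragment_len = p$fragment_len, k = p$k,
                            min_af = p$min_af,
                            probe_stride = p$probe_stride)
    stage_log(stage, "%d clusters from %d genomes", length(clusters),
              length(genomes))
    write_tsv(do.call(rbind, lapply(clusters, function(cl)
      data.frame(cluster_id = cl$cluster_id,
                 genome_id = cl$members,
                 representative = cl$representative))),
      file.path(out_dir, "clusters.tsv"))

    stage <- "abundance"
    counts_path <- file.path(input_dir, "counts.tsv")
    if (file.exists(counts_path) &&
        file.exists(file.path(input_dir, "lengths.tsv"))) {
      counts <- read_abundance(counts_path)
      lens <- read_tsv_strict(file.path(input_dir, "lengths.tsv"),
                              required = c("label", "length_bp",
                                           "total_reads"))
      ab <- rpkm(counts, stats::setNames(lens$length_bp, lens$label),
                 lens$total_reads[1])
    } else {
      ab <- read_abundance(file.path(input_dir, "abundance.tsv"))
    }
    write_abundance(ab, file.path(out_dir, "abundance_rpkm.tsv"))
    div <- shannon_diversity(ab)
    write_tsv(div, file.path(out_dir, "shannon.tsv"))
    bc <- bray_curtis(ab)
    write_distance_matrix(bc, file.path(out_dir, "bray_curtis.tsv"))
    stage_log(stage, "%d samples x %d taxa", nrow(ab), ncol(ab))

    stage <- "genetic_distance"
    profiles <- read_snv_profiles(file.path(input_dir, "snv.tsv"))
    gmeta <- genome_table(genomes)
    gd <- genetic_composition_distance(profiles, cohort, gmeta)
    write_distance_matrix(gd, file.path(out_dir, "genetic_composition.tsv"))

    stage <- "permanova"
    perm_comm <- metadata_permanova(bc, cohort, p$n_perm, seed)
    write_tsv(perm_comm, file.path(out_dir, "permanova_community.tsv"))
    perm_gen <- metadata_permanova(gd, cohort, p$n_perm, seed + 1)
    write_tsv(perm_gen, file.path(out_dir, "permanova_genetic.tsv"))
    stage_log(stage, "community top factor: %s (R2 = %.3f)",
              perm_comm$factor[which.max(perm_comm$r_squared)],
              max(perm_comm$r_squared))

    stage <- "family_contrasts"
    wb <- within_between_test(bc, cohort)
    trends <- data.frame(
      analysis = c("within_vs_between_community",
                   "within_vs_between_genetic"),
      statistic = c(stats::median(wb$within) - stats::median(wb$between),
                    NA),
      p_value = c(wb$wilcoxon_p, NA), n = c(length(wb$within), NA))
    wbg <- within_between_test(gd, cohort)
    trends$statistic[2] <- stats::median(wbg$within) -
      stats::median(wbg$between)
    trends$p_value[2] <- wbg$wilcoxon_p
    trends$n[2] <- length(wbg$within)
    cp <- tryCatch(child_parent_trend(bc, cohort), error = function(e) NULL)
    if (!is.null(cp))
      trends <- rbind(trends, data.frame(analysis = "child_parent_age",
                                         statistic = cp$rho,
                                         p_value = cp$p_value,
                                         n = cp$n_pairs))
    dv <- tryCatch(diversity_similarity_trend(bc, div, cohort),
                   error = function(e) NULL)
    if (!is.null(dv))
      trends <- rbind(trends, data.frame(analysis = "diversity_similarity",
                                         statistic = dv$rho,
                                         p_value = dv$p_value,
                                         n = dv$n_pairs))
    write_tsv(trends, file.path(out_dir, "trends.tsv"))

    stage <- "sharing"
    candidates <- select_candidates(genomes, cohort, p$min_members,
                                    p$min_family_frac)
    stage_log(stage, "%d candidate population(s)", length(candidates))
    ani_params <- list(fragment_len = p$fragment_len, k = p$k,
                       min_af = p$min_af, probe_stride = p$probe_stride,
                       primary = p$primary)
    sh <- sharing_analysis(candidates, cohort,
                           r2_threshold = p$r2_threshold,
                           p_threshold = p$p_threshold,
                           sharing_ani = p$sharing_ani,
                           n_perm = p$n_perm, seed = seed + 100,
                           ani_params = ani_params)
    write_tsv(sh$table, file.path(out_dir, "sharing.tsv"))
    flagged <- sh$table$species_label[sh$table$shared_flag]
    stage_log(stage, "%d population(s) flagged shared", length(flagged))
    for (sp in flagged) {
      coords <- classical_mds(sh$dists[[sp]], k = 2)
      write_tsv(data.frame(genome_id = rownames(coords), coords),
                file.path(out_dir, sprintf("mds_%s.tsv", sp)))
    }

    stage <- "microdiversity"
    genes <- read_gene_models(file.path(input_dir, "genes.tsv"))
    annots <- read_annotations(file.path(input_dir, "annotations.tsv"))
    gseq <- lapply(genomes, `[[`, "sequence")
    names(gseq) <- vapply(genomes, `[[`, "", "genome_id")
    pi_rows <- list(); sel_rows <- list()
    empty_sites <- data.frame(contig = character(), position = integer(),
                              ref = character(), A = integer(),
                              C = integer(), G = integer(), T = integer())
    for (g in genomes) {
      prof <- profiles[[g$genome_id]] %||%
        snv_profile(g$genome_id, empty_sites)
      pi_rows[[g$genome_id]] <-
        data.frame(genome_id = g$genome_id, sample_id = g$sample_id,
                   species_label = g$species_label,
                   pi = nucleotide_diversity(prof, genome_length(g)))
      gg <- genes[genes$contig %in% names(g$sequence), , drop = FALSE]
      if (nrow(gg)) {
        sel <- pnps(prof, gg, g$sequence)
        sel$genome_id <- g$genome_id
        sel$species_label <- g$species_label
        sel_rows[[g$genome_id]] <- sel
      }
    }
    pi_tab <- do.call(rbind, pi_rows)
    write_tsv(pi_tab, file.path(out_dir, "pi.tsv"))
    sel_tab <- do.call(rbind, sel_rows)
    write_tsv(sel_tab, file.path(out_dir, "pnps.tsv"))
    # pool changes per gene across genomes, rank extremes
    agg <- do.call(rbind, lapply(split(sel_tab, sel_tab$gene_id),
      function(x) data.frame(gene_id = x$gene_id[1],
                             n_changes = sum(x$n_changes),
                             s_changes = sum(x$s_changes),
                             nonsyn_sites = sum(x$nonsyn_sites),
                             syn_sites = sum(x$syn_sites))))
    agg$pn <- agg$n_changes / agg$nonsyn_sites
    agg$ps <- agg$s_changes / agg$syn_sites
    agg$pnps <- ifelse(agg$s_changes >= 1, agg$pn / agg$ps, NA)
    agg$classification <- ifelse(is.na(agg$pnps), "undefined",
                          ifelse(agg$pnps < 1, "purifying",
                          ifelse(agg$pnps > 1, "positive", "neutral")))
    ranked <- tryCatch(rank_selection(agg, annots), error = function(e) NULL)
    if (!is.null(ranked)) {
      write_tsv(ranked$top, file.path(out_dir, "pnps_top.tsv"))
      write_tsv(ranked$bottom, file.path(out_dir, "pnps_bottom.tsv"))
    }
    stage_log(stage, "pi for %d genomes, pN/pS for %d gene records",
              nrow(pi_tab), nrow(sel_tab))

    stage <- "modules"
    modules <- read_module_definitions(file.path(input_dir, "modules.txt"))
    ko <- annots[annots$annotation_type == "KO", ]
    gene_species <- stats::setNames(
      sub("_g[0-9]+$", "", genes$gene_id), genes$gene_id)
    ko_sets <- lapply(split(ko$label, gene_species[ko$gene_id]), unique)
    presence <- detect_modules(ko_sets, modules, cutoff = p$module_cutoff)
    write_tsv(data.frame(label = rownames(presence), presence * 1L,
                         check.names = FALSE),
              file.path(out_dir, "modules.tsv"))

    stage <- "network"
    net_ab <- correlation_network(t(ab), rho_min = p$rho_min,
                                  p_max = p$p_max)
    write_tsv(net_ab, file.path(out_dir, "network_abundance.tsv"))
    write_tsv(data.frame(taxon = core_nodes(net_ab)),
              file.path(out_dir, "network_abundance_core.tsv"))
    gen_prof <- with(pi_tab, tapply(pi, list(species_label, sample_id),
                                    mean))
    gen_prof[is.na(gen_prof)] <- 0
    net_gen <- if (nrow(gen_prof) >= 2L)
      correlation_network(gen_prof, rho_min = p$rho_min, p_max = p$p_max)
    else data.frame(taxon_a = character(), taxon_b = character(),
                    rho = numeric(), p_value = numeric(),
                    sign = character())
    write_tsv(net_gen, file.path(out_dir, "network_genetic.tsv"))
    write_tsv(data.frame(taxon = core_nodes(net_gen)),
              file.path(out_dir, "network_genetic_core.tsv"))
    stage_log(stage, "%d abundance edges, %d genetic edges",
              nrow(net_ab), nrow(net_gen))

    stage <- "manifest"
    inputs <- list.files(input_dir, full.names = TRUE)
    inputs <- inputs[!dir.exists(inputs)]
    manifest <- list(
      package = "famshare",
      version = as.character(utils::packageVersion("famshare")),
      seed = seed, parameters = p,
      input_files = as.list(stats::setNames(
        unname(tools::md5sum(sort(inputs))), basename(sort(inputs)))),
      n_samples = nrow(cohort$samples), n_genomes = length(genomes),
      n_candidates = length(candidates),
      flagged_populations = as.list(flagged))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res <- list(cohort = cohort, abundance = ab, sharing = sh$table,
                permanova_community = perm_comm,
                permanova_genetic = perm_gen, trends = trends,
                pi = pi_tab, modules = presence,
                network_abundance = net_ab, network_genetic = net_gen)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' One-command demonstration: simulate a cohort, then analyse it
#'
#' Generates a small synthetic cohort (6 families, 3 species, planted
#' transmissions of species sp1 in every family), writes the input bundle
#' to `out_dir/input` and the full report to `out_dir/report`. Runs in
#' well under five minutes on one CPU and is byte-deterministic for a
#' fixed seed.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving both simulation and analysis.
#' @return invisibly, the [run_pipeline()] result list.
#' @export
famshare_demo <- function(out_dir, seed = 1) {
  cfg <- simulation_config(
    n_families = 6, members_per_family = c(2, 3, 2, 3, 2, 3),
    n_species = 3, n_abundance_taxa = 20, genome_length = 6000,
    transmission_pairs = data.frame(family_id = sprintf("F%02d", 1:6),
                                    species_label = "sp1"),
    seed = seed)
  sc <- generate_cohort(cfg)
  input <- file.path(out_dir, "input")
  write_input_bundle(sc, input)
  run_pipeline(input, file.path(out_dir, "report"),
               params = list(n_perm = 199), seed = seed)
}

# ---- minimal CLI -----------------------------------------------------------

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      flags[[gsub("-", "_", key)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR [--seed N] [--families N]
#' [--species N] [--genome-length N]`, `run --input DIR --out DIR
#' [--seed N] [--nperm N]`, `demo --out DIR [--seed N]`. Installed as the
#' `exec/famshare` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
famshare_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: famshare <simulate|run|demo> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  fl <- parse_flags(args[-1])
  seed <- as.integer(fl$seed %||% 1)
  switch(cmd,
    simulate = {
      cfg <- simulation_config(
        n_families = as.integer(fl$families %||% 25),
        n_species = as.integer(fl$species %||% 3),
        genome_length = as.integer(fl$genome_length %||% 20000),
        seed = seed)
      write_input_bundle(generate_cohort(cfg), fl$out %||% "famshare_input")
    },
    run = {
      if (is.null(fl$input)) stop("run requires --input DIR", call. = FALSE)
      run_pipeline(fl$input, fl$out %||% "famshare_report",
                   params = if (!is.null(fl$nperm))
                     list(n_perm = as.integer(fl$nperm)) else list(),
                   seed = seed)
    },
    demo = famshare_demo(fl$out %||% "famshare_demo", seed = seed),
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
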