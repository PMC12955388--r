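# Within-species genetic statistics: nucleotide diversity (pi) from SNV
# allele frequencies, and gene-level pN/pS under NG86 equal-weight site
# counting with the bacterial genetic code (codon table 11; identical
# codon->amino-acid assignments to the standard table).

.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  code <- Biostrings::GENETIC_CODE
  bases <- DNA_BASES
  syn <- numeric(length(code)); names(syn) <- names(code)
  for (cod in names(code)) {
    aa <- code[[cod]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (code[[mut]] == aa) s <- s + 1
      }
    }
    syn[cod] <- s / 3                     # synonymous sites per codon
  }
  .codon_env$tab <- list(code = code, syn_sites = syn)
  .codon_env$tab
}

#' Nucleotide diversity of one genome from its SNV profile
#'
#' Per polymorphic site, pi_site = 1 - sum_b f_b^2 over allele
#' frequencies; genome-wide pi is the sum over sites divided by genome
#' length (monomorphic sites contribute 0). Sites failing the coverage or
#' minor-allele-frequency filters are treated as monomorphic.
#'
#' @param profile an [snv_profile()].
#' @param genome_length genome length in bp (> 0).
#' @param min_total minimum total allele count for a site to be used.
#' @param min_maf minimum minor allele frequency.
#' @return per-site average nucleotide diversity (scalar).
#' @export
nucleotide_diversity <- function(profile, genome_length, min_total = 5,
                                 min_maf = 0.05) {
  if (genome_length <= 0) stop("genome_length must be > 0", call. = FALSE)
  sites <- profile$sites
  if (nrow(sites) == 0L) return(0)
  counts <- as.matrix(sites[, c("A", "C", "G", "T")])
  total <- rowSums(counts)
  if (any(total == 0))
    stop("site with zero total allele count in profile ",
         profile$genome_id, call. = FALSE)
  freq <- counts / total
  maf <- 1 - apply(freq, 1, max)
  use <- total >= min_total & maf >= min_maf
  if (!any(use)) return(0)
  pi_site <- 1 - rowSums(freq[use, , drop = FALSE]^2)
  sum(pi_site) / genome_length
}

#' NG86 synonymous / nonsynonymous site counts of a coding sequence
#'
#' Per codon, each of the three positions contributes the fraction of its
#' three possible single-nucleotide changes that are synonymous to the
#' synonymous site count, the remainder to the nonsynonymous count; syn +
#' nonsyn = 3 per counted codon. Codons containing N are skipped.
#' Reference stop codons are counted, with stop-to-stop changes treated
#' as synonymous.
#'
#' @param gene_sequence in-frame coding sequence (length divisible by 3).
#' @return named vector `c(nonsyn_sites, syn_sites)`.
#' @export
count_sites <- function(gene_sequence) {
  gene_sequence <- toupper(gene_sequence)
  L <- nchar(gene_sequence)
  if (L %% 3 != 0) stop("gene length must be divisible by 3", call. = FALSE)
  tab <- codon_table()
  starts <- seq(1L, L, by = 3L)
  codons <- substring(gene_sequence, starts, starts + 2L)
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  syn <- sum(tab$syn_sites[codons])
  c(nonsyn_sites = 3 * length(codons) - syn, syn_sites = syn)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Gene-level pN/pS from an SNV profile
#'
#' Each polymorphic site inside a gene is resolved to its codon (minus
#' strand genes are reverse-complemented first) and every minor allele is
#' classified as synonymous or nonsynonymous against the reference codon
#' (multi-allelic sites contribute one change per minor allele;
#' stop-gain changes are nonsynonymous). pN = nonsynonymous changes /
#' nonsynonymous sites, pS likewise; the ratio is reported only when at
#' least `min_syn_changes` synonymous changes were observed, otherwise
#' pN/pS is the `undefined` sentinel (NA), never infinity.
#'
#' @param profile an [snv_profile()].
#' @param gene_models data.frame of gene models (1-based inclusive,
#'   strand +/-); lengths must be divisible by 3.
#' @param genome_sequence named character vector of contig sequences (or
#'   a single string for single-contig genomes).
#' @param min_syn_changes minimum synonymous changes for a defined ratio.
#' @param min_total,min_maf site filters as in [nucleotide_diversity()].
#' @return data.frame with one row per gene: gene_id, n_changes,
#'   s_changes, nonsyn_sites, syn_sites, pn, ps, pnps, classification
#'   (purifying / neutral / positive / undefined). SNVs falling in no
#'   gene are counted in attribute `n_unassigned`.
#' @export
pnps <- function(profile, gene_models, genome_sequence,
                 min_syn_changes = 1, min_total = 5, min_maf = 0.05) {
  if (is.null(names(genome_sequence)) && length(genome_sequence) == 1L)
    names(genome_sequence) <- unique(gene_models$contig)[1]
  tab <- codon_table()
  sites <- profile$sites
  counts <- if (nrow(sites)) as.matrix(sites[, c("A", "C", "G", "T")])
            else matrix(0, 0, 4)
  total <- rowSums(counts)
  assigned <- rep(FALSE, nrow(sites))
  out <- vector("list", nrow(gene_models))
  for (gi in seq_len(nrow(gene_models))) {
    g <- gene_models[gi, ]
    contig_seq <- genome_sequence[[g$contig]]
    if (is.null(contig_seq) || is.na(contig_seq))
      stop("gene ", g$gene_id, ": contig ", g$contig,
           " not in genome sequence", call. = FALSE)
    raw <- substring(contig_seq, g$start, g$end)
    coding <- if (g$strand == "-") revcomp(raw) else raw
    sc <- count_sites(coding)
    n_changes <- 0L; s_changes <- 0L
    if (nrow(sites)) {
      in_gene <- which(sites$contig == g$contig &
                         sites$position >= g$start &
                         sites$position <= g$end)
      assigned[in_gene] <- TRUE
      for (si in in_gene) {
        if (total[si] < min_total) next
        cpos <- if (g$strand == "+") sites$position[si] - g$start + 1L
                else g$end - sites$position[si] + 1L
        codon_idx <- (cpos - 1L) %/% 3L
        within <- (cpos - 1L) %% 3L + 1L
        ref_codon <- substring(coding, codon_idx * 3L + 1L,
                               codon_idx * 3L + 3L)
        if (grepl("N", ref_codon, fixed = TRUE)) next
        ref_aa <- tab$code[[ref_codon]]
        ref_base <- sites$ref[si]
        for (b in DNA_BASES) {
          if (b == ref_base || counts[si, b] == 0) next
          if (counts[si, b] / total[si] < min_maf) next
          cb <- if (g$strand == "-") comp_base[[b]] else b
          mut <- ref_codon
          substr(mut, within, within) <- cb
          if (tab$code[[mut]] == ref_aa) s_changes <- s_changes + 1L
          else n_changes <- n_changes + 1L
        }
      }
    }
    pn <- n_changes / sc[["nonsyn_sites"]]
    ps <- if (sc[["syn_sites"]] > 0) s_changes / sc[["syn_sites"]] else NA_real_
    ratio <- if (s_changes >= min_syn_changes && !is.na(ps) && ps > 0)
      pn / ps else NA_real_
    classification <- if (is.na(ratio)) "undefined"
      else if (ratio < 1) "purifying"
      else if (ratio > 1) "positive" else "neutral"
    out[[gi]] <- data.frame(gene_id = g$gene_id, n_changes = n_changes,
                            s_changes = s_changes,
                            nonsyn_sites = sc[["nonsyn_sites"]],
                            syn_sites = sc[["syn_sites"]],
                            pn = pn, ps = ps, pnps = ratio,
                            classification = classification,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_unassigned") <- sum(!assigned)
  res
}

#' Rank genes by pN/pS and join annotations
#'
#' Genes with a defined ratio are sorted descending (ties broken by
#' gene_id); the top and bottom `top_n` are returned with their KO /
#' CAZyme / resistance labels. Undefined-ratio genes never appear.
#'
#' @param selections data.frame from [pnps()].
#' @param annotations annotation data.frame (`gene_id, annotation_type,
#'   label`), or NULL.
#' @param top_n rows per end of the ranking.
#' @return list with `top` and `bottom` data.frames (columns of
#'   `selections` plus `annotation`).
#' @export
rank_selection <- function(selections, annotations = NULL, top_n = 10) {
  def <- selections[!is.na(selections$pnps), , drop = FALSE]
  if (nrow(def) == 0L) stop("no gene with a defined pN/pS", call. = FALSE)
  def <- def[order(-def$pnps, def$gene_id), , drop = FALSE]
  join <- function(df) {
    df$annotation <- vapply(df$gene_id, function(g) {
      if (is.null(annotations)) return("")
      a <- annotations[annotations$gene_id == g, ]
      paste(sprintf("%s:%s", a$annotation_type, a$label), collapse = ";")
    }, "")
    rownames(df) <- NULL
    df
  }
  asc <- def[order(def$pnps, def$gene_id), , drop = FALSE]
  list(top = join(utils::head(def, top_n)),
       bottom = join(utils::head(asc, top_n)))
}

#' Pooled pN/pS over a set of genes
#'
#' (sum N changes / sum nonsynonymous sites) / (sum S changes / sum
#' synonymous sites); NA when no synonymous change was observed.
#'
#' @param selections data.frame from [pnps()].
#' @return pooled ratio (scalar).
#' @export
pooled_pnps <- function(selections) {
  S <- sum(selections$s_changes)
  if (S == 0) return(NA_real_)
  (sum(selections$n_changes) / sum(selections$nonsyn_sites)) /
    (S / sum(selections$syn_sites))
}
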