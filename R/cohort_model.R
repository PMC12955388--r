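# Domain types shared by every pipeline stage, plus readers/writers for the
# plain-text formats the pipeline touches (FASTA genomes + TSV tables).
# Coordinates are 1-based inclusive throughout; conversion, if any, happens
# only at I/O boundaries.

FAMILY_ROLES <- c("father", "mother", "child", "other")
SEX_LEVELS <- c("M", "F")
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a family cohort from a sample metadata table
#'
#' A cohort is the grouping backbone of the analysis: a table of samples
#' with family structure, plus a derived map `family_id -> member sample
#' ids`. Families of size 1 are allowed; they simply contribute no
#' within-family pairs.
#'
#' @param samples data.frame with columns `sample_id`, `family_id`, `role`
#'   (one of father/mother/child/other), `ethnicity`, `sex` (M/F), `age`
#'   (years, >= 0), `region`.
#' @return An object of class `family_cohort`: a list with `samples` (the
#'   validated table) and `families` (named list of member sample ids).
#' @export
family_cohort <- function(samples) {
  required <- c("sample_id", "family_id", "role", "ethnicity", "sex",
                "age", "region")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) == 0L)
    stop("cohort metadata has no samples", call. = FALSE)
  samples <- samples[required]
  samples$sample_id <- as.character(samples$sample_id)
  samples$family_id <- as.character(samples$family_id)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(samples$role), FAMILY_ROLES)
  if (length(bad_role))
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         "; allowed: ", paste(FAMILY_ROLES, collapse = ", "), call. = FALSE)
  bad_sex <- setdiff(unique(samples$sex), SEX_LEVELS)
  if (length(bad_sex))
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "),
         "; allowed: M, F", call. = FALSE)
  samples$age <- as.numeric(samples$age)
  if (anyNA(samples$age) || any(samples$age < 0))
    stop("age must be a non-negative number for every sample", call. = FALSE)
  families <- split(samples$sample_id, samples$family_id)
  structure(list(samples = samples, families = families),
            class = "family_cohort")
}

#' @export
print.family_cohort <- function(x, ...) {
  sizes <- lengths(x$families)
  cat(sprintf("family_cohort: %d samples in %d families (sizes %s)\n",
              nrow(x$samples), length(x$families),
              paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' Read cohort metadata from a TSV file
#'
#' @param path TSV with header `sample_id, family_id, role, ethnicity, sex,
#'   age, region`.
#' @return A [family_cohort()].
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path, required = c("sample_id", "family_id", "role",
                                           "ethnicity", "sex", "age",
                                           "region"))
  if (nrow(df) == 0L)
    stop("metadata file ", path, " contains no samples", call. = FALSE)
  family_cohort(df)
}

#' Write cohort metadata to a TSV file
#' @param cohort a [family_cohort()]
#' @param path output path
#' @export
write_metadata <- function(cohort, path) {
  write_tsv(cohort$samples, path)
}

#' Family of each sample as a named character vector
#' @param cohort a [family_cohort()]
#' @keywords internal
sample_family <- function(cohort) {
  stats::setNames(cohort$samples$family_id, cohort$samples$sample_id)
}

#' Construct a genome asset (MAG analog)
#'
#' @param genome_id,sample_id,species_label identifiers.
#' @param sequence nucleotide string over A/C/G/T/N (case-folded to upper).
#'   Multi-contig genomes may pass a named character vector of contigs;
#'   contigs keep separate coordinates for gene models but are treated as
#'   one genome for ANI, pi and abundance.
#' @param completeness,contamination CheckM-style percentages in \[0, 100\].
#' @return An object of class `genome_asset`.
#' @export
genome_asset <- function(genome_id, sample_id, species_label, sequence,
                         completeness, contamination) {
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("genome ", genome_id, ": sequence contains characters outside ",
         "{A,C,G,T,N}", call. = FALSE)
  stopifnot_scalar_number(completeness, "completeness", 0, 100)
  stopifnot_scalar_number(contamination, "contamination", 0, 100)
  if (is.null(names(sequence)) && length(sequence) == 1L)
    names(sequence) <- genome_id
  structure(list(genome_id = as.character(genome_id),
                 sample_id = as.character(sample_id),
                 species_label = as.character(species_label),
                 sequence = sequence,
                 completeness = completeness,
                 contamination = contamination),
            class = "genome_asset")
}

#' @export
print.genome_asset <- function(x, ...) {
  cat(sprintf("genome_asset %s (%s, sample %s): %d bp, compl %.1f, contam %.1f\n",
              x$genome_id, x$species_label, x$sample_id,
              sum(nchar(x$sequence)), x$completeness, x$contamination))
  invisible(x)
}

genome_length <- function(genome) sum(nchar(genome$sequence))

#' Metadata table of a genome list
#' @param genomes list of [genome_asset()]
#' @return data.frame with one row per genome (no sequences).
#' @export
genome_table <- function(genomes) {
  data.frame(genome_id = vapply(genomes, `[[`, "", "genome_id"),
             sample_id = vapply(genomes, `[[`, "", "sample_id"),
             species_label = vapply(genomes, `[[`, "", "species_label"),
             completeness = vapply(genomes, `[[`, 0, "completeness"),
             contamination = vapply(genomes, `[[`, 0, "contamination"),
             length_bp = vapply(genomes, genome_length, 0L),
             stringsAsFactors = FALSE)
}

#' Read genome assets from a directory
#'
#' Expects one or more FASTA files (`*.fa`, `*.fasta`, `*.fna`) and a
#' metadata sidecar `genomes.tsv` with columns `genome_id, sample_id,
#' species_label, completeness, contamination`. FASTA record names are
#' `genome_id` or `genome_id|contig_id` for multi-contig genomes.
#' Sequences are uppercased; N is legal.
#'
#' @param dir directory containing the FASTA file(s) and `genomes.tsv`.
#' @return list of [genome_asset()].
#' @export
read_genomes <- function(dir) {
  meta_path <- file.path(dir, "genomes.tsv")
  meta <- read_tsv_strict(meta_path,
                          required = c("genome_id", "sample_id",
                                       "species_label", "completeness",
                                       "contamination"))
  fastas <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (!length(fastas))
    stop("no FASTA file found in ", dir, call. = FALSE)
  seqs <- character(0)
  for (f in fastas) {
    ss <- tryCatch(Biostrings::readDNAStringSet(f),
                   error = function(e)
                     stop("malformed FASTA in ", f, ": ", conditionMessage(e),
                          call. = FALSE))
    v <- toupper(as.character(ss))
    names(v) <- sub("\\s.*$", "", names(v))
    seqs <- c(seqs, v)
  }
  rec_genome <- sub("\\|.*$", "", names(seqs))
  lapply(seq_len(nrow(meta)), function(i) {
    gid <- meta$genome_id[i]
    idx <- which(rec_genome == gid)
    if (!length(idx))
      stop("metadata row for genome ", gid,
           " has no FASTA record in ", dir, call. = FALSE)
    contigs <- seqs[idx]
    names(contigs) <- ifelse(grepl("\\|", names(contigs)),
                             sub("^[^|]*\\|", "", names(contigs)),
                             names(contigs))
    genome_asset(gid, meta$sample_id[i], meta$species_label[i], contigs,
                 meta$completeness[i], meta$contamination[i])
  })
}

#' Write genome assets (FASTA + metadata sidecar) to a directory
#' @param genomes list of [genome_asset()]
#' @param dir output directory (created if absent)
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- unlist(lapply(genomes, function(g) {
    s <- g$sequence
    nm <- if (length(s) == 1L && names(s)[1] == g$genome_id) g$genome_id
          else paste(g$genome_id, names(s), sep = "|")
    stats::setNames(unname(s), nm)
  }))
  set <- Biostrings::DNAStringSet(recs)
  Biostrings::writeXStringSet(set, file.path(dir, "genomes.fasta"), width = 80)
  write_tsv(genome_table(genomes)[, c("genome_id", "sample_id",
                                      "species_label", "completeness",
                                      "contamination")],
            file.path(dir, "genomes.tsv"))
  invisible(dir)
}

#' Filter genomes on assembly quality
#'
#' Retains genomes with `completeness >= min_completeness` and
#' `contamination <= max_contamination` (both boundaries inclusive, as is
#' conventional for MAG quality screens). Input order is preserved and the
#' operation is idempotent.
#'
#' @param genomes list of [genome_asset()]
#' @param min_completeness,max_contamination thresholds in \[0, 100\].
#' @return filtered list of [genome_asset()] (possibly empty).
#' @export
quality_filter <- function(genomes, min_completeness = 50,
                           max_contamination = 10) {
  stopifnot_scalar_number(min_completeness, "min_completeness", 0, 100)
  stopifnot_scalar_number(max_contamination, "max_contamination", 0, 100)
  keep <- vapply(genomes, function(g)
    g$completeness >= min_completeness && g$contamination <= max_contamination,
    logical(1))
  genomes[keep]
}

# ---- distance matrices -----------------------------------------------------

#' Validate a labelled symmetric dissimilarity matrix
#'
#' @param d square numeric matrix with identical row/column dimnames.
#' @param unit_interval require values in \[0, 1\] (TRUE for Bray-Curtis and
#'   1 - ANI matrices).
#' @return `d`, invisibly, if valid; otherwise an error.
#' @export
validate_distance_matrix <- function(d, unit_interval = FALSE) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row/column labels",
         call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-10)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(d))) > 1e-12)
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (unit_interval && any(d > 1 + 1e-12))
    stop("distances must lie in [0, 1]", call. = FALSE)
  invisible(d)
}

#' Write / read a labelled distance matrix as TSV
#' @param d labelled square matrix
#' @param path file path
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_distance_matrix(m)
  m
}

# ---- abundance -------------------------------------------------------------

#' Read an abundance (or read-count) matrix from TSV
#'
#' First column `sample_id`; remaining columns one per species/genome label.
#' Values must be non-negative with no missing cells (absence is 0).
#' @param path file path
#' @return numeric matrix, samples x taxa, with dimnames.
#' @export
read_abundance <- function(path) {
  df <- read_tsv_strict(path, required = "sample_id")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("abundance matrix has missing cells in ", path,
                     call. = FALSE)
  if (any(m < 0)) stop("abundance values must be non-negative in ", path,
                       call. = FALSE)
  m
}

#' @rdname read_abundance
#' @param m samples x taxa matrix
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# ---- SNV profiles ----------------------------------------------------------

#' Construct an SNV profile for one genome
#'
#' @param genome_id genome the sites belong to.
#' @param sites data.frame with columns `contig`, `position` (1-based),
#'   `ref` (reference base) and integer allele counts `A`, `C`, `G`, `T`.
#' @return object of class `snv_profile`.
#' @export
snv_profile <- function(genome_id, sites) {
  required <- c("contig", "position", "ref", "A", "C", "G", "T")
  missing <- setdiff(required, names(sites))
  if (length(missing))
    stop("SNV sites table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sites <- sites[required]
  total <- sites$A + sites$C + sites$G + sites$T
  if (nrow(sites) && any(total < 1))
    stop("SNV profile ", genome_id, ": site with zero total allele count",
         call. = FALSE)
  structure(list(genome_id = as.character(genome_id), sites = sites),
            class = "snv_profile")
}

#' Read / write SNV profiles (long TSV, one row per site)
#'
#' Columns: `genome_id, contig, position, ref, A, C, G, T`.
#' @param path file path
#' @return named list of [snv_profile()] keyed by genome_id.
#' @export
read_snv_profiles <- function(path) {
  df <- read_tsv_strict(path, required = c("genome_id", "contig", "position",
                                           "ref", "A", "C", "G", "T"))
  lapply(split(df, df$genome_id), function(chunk)
    snv_profile(chunk$genome_id[1], chunk[, -1]))
}

#' @rdname read_snv_profiles
#' @param profiles list of [snv_profile()]
#' @export
write_snv_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (nrow(p$sites) == 0L) return(NULL)
    cbind(genome_id = p$genome_id, p$sites)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(genome_id = character(), contig = character(),
                        position = integer(), ref = character(),
                        A = integer(), C = integer(), G = integer(),
                        T = integer())
  write_tsv(df, path)
}

# ---- gene models and annotations -------------------------------------------

#' Read gene models from TSV
#'
#' Columns `gene_id, contig, start, end, strand` with 1-based inclusive
#' coordinates and strand `+`/`-`. Protein-coding genes used for pN/pS must
#' have length divisible by 3 (checked at use, not at read).
#' @param path file path
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_id", "contig", "start",
                                           "end", "strand"))
  if (any(df$end < df$start))
    stop("gene model with end < start in ", path, call. = FALSE)
  if (length(setdiff(unique(df$strand), c("+", "-"))))
    stop("strand must be '+' or '-' in ", path, call. = FALSE)
  df
}

#' Read a gene annotation table from TSV
#'
#' Columns `gene_id, annotation_type, label`; `annotation_type` is one of
#' `KO`, `CAZyme`, `resistance`.
#' @param path file path
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_id", "annotation_type",
                                           "label"))
  bad <- setdiff(unique(df$annotation_type), c("KO", "CAZyme", "resistance"))
  if (length(bad))
    stop("unknown annotation_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df
}
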