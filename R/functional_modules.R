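# Presence/absence calling of metabolic modules from gene->KO annotations.
# Module grammar: ordered steps, each step a flat set of alternative KOs
# (any one present satisfies the step); a module is present in a genome
# when the fraction of satisfied steps reaches the coverage cutoff.

#' Read metabolic module definitions
#'
#' File format: one module per block; first line `module_id<TAB>name`; one
#' step per following line as comma-separated alternative KO identifiers;
#' blocks separated by a line containing `//`. A small fixture of
#' SCFA-production modules ships in
#' `system.file("extdata", "scfa_modules.txt", package = "famshare")` — it
#' is illustrative; supply a real catalog for production use.
#'
#' @param path module definition file.
#' @return named list of module definitions, each a list with `module_id`,
#'   `name`, `steps` (list of character vectors).
#' @export
read_module_definitions <- function(path) {
  if (!file.exists(path)) stop("module file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  blocks <- split(lines, cumsum(lines == "//"))
  mods <- list()
  for (b in blocks) {
    b <- b[b != "//"]
    if (!length(b)) next
    header <- strsplit(b[1], "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
      stop("module header must be 'module_id<TAB>name': ", b[1],
           call. = FALSE)
    steps <- lapply(b[-1], function(l) {
      alts <- trimws(strsplit(l, ",", fixed = TRUE)[[1]])
      alts <- alts[nzchar(alts)]
      if (!length(alts)) stop("empty step in module ", header[1],
                              call. = FALSE)
      alts
    })
    if (!length(steps))
      stop("module ", header[1], " has no steps", call. = FALSE)
    mods[[header[1]]] <- list(module_id = header[1], name = header[2],
                              steps = steps)
  }
  mods
}

#' Coverage of one module by a genome's KO set
#'
#' @param ko_set character vector of KO identifiers annotated in a genome.
#' @param module one module definition (see [read_module_definitions()]).
#' @return fraction of steps with at least one alternative present, in
#'   \[0, 1\].
#' @export
module_coverage <- function(ko_set, module) {
  hit <- vapply(module$steps, function(alts) any(alts %in% ko_set),
                logical(1))
  mean(hit)
}

#' Call module presence/absence across genomes
#'
#' A module is called present when its coverage reaches the cutoff
#' (inclusive comparison: coverage >= cutoff).
#'
#' @param genome_ko_sets named list of KO identifier vectors, one per
#'   genome.
#' @param modules list of module definitions.
#' @param cutoff coverage cutoff in (0, 1\]; the default 0.66 matches the
#'   common module-detection convention.
#' @return logical matrix genomes x modules.
#' @export
detect_modules <- function(genome_ko_sets, modules, cutoff = 0.66) {
  stopifnot_scalar_number(cutoff, "cutoff", 0, 1)
  if (cutoff <= 0) stop("cutoff must be in (0, 1]", call. = FALSE)
  cov <- vapply(modules, function(m)
    vapply(genome_ko_sets, module_coverage, 0, module = m),
    numeric(length(genome_ko_sets)))
  if (length(genome_ko_sets) == 1L)
    cov <- matrix(cov, nrow = 1L,
                  dimnames = list(names(genome_ko_sets), names(modules)))
  out <- cov >= cutoff
  dimnames(out) <- list(names(genome_ko_sets), names(modules))
  out
}
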