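test_that("select_candidates applies the inclusive 30%-of-families rule", {
  ch <- make_cohort(10, 2)
  mk <- function(sp, fams, members = 1:2) {
    unlist(lapply(fams, function(f) lapply(members, function(m)
      make_genome(sprintf("%s_F%d_S%d", sp, f, m),
                  sprintf("F%d_S%d", f, m), species = sp))),
      recursive = FALSE)
  }
  gx <- mk("spX", 1:3)                 # pairs in 3/10 families: boundary in
  gy <- mk("spY", 1:10, members = 1)   # 1 member everywhere: out
  gz <- mk("spZ", 1:2)                 # pairs in 2/10: out
  cand <- select_candidates(c(gx, gy, gz), ch)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$species_label, "spX")
  expect_equal(cand[[1]]$families_with_pairs, sprintf("F%d", 1:3))
})

test_that("count_sharing enumerates within-family pairs at the threshold", {
  mkpop <- function(samples, species = "sp") {
    list(species_label = species,
         genomes = lapply(seq_along(samples), function(i)
           make_genome(paste0("g", i), samples[i], species = species)))
  }
  # one 3-member family, all pairs above threshold -> (3, 1)
  ch3 <- make_cohort(1, 3)
  pop <- mkpop(ch3$samples$sample_id)
  d <- dist_mat(matrix(0.001, 3, 3) - diag(0.001, 3), paste0("g", 1:3))
  cs <- count_sharing(pop, ch3, sharing_ani = 99.5, dist = d)
  expect_equal(cs$sharing_times, 3)
  expect_equal(cs$family_prevalence, 1)
  # nothing at threshold -> (0, 0)
  d0 <- dist_mat(matrix(0.03, 3, 3) - diag(0.03, 3), paste0("g", 1:3))
  cs0 <- count_sharing(pop, ch3, sharing_ani = 99.5, dist = d0)
  expect_equal(cs0$sharing_times, 0)
  expect_equal(cs0$family_prevalence, 0)
  # two families with one qualifying pair each -> (2, 2)
  ch22 <- make_cohort(2, 2)
  pop2 <- mkpop(ch22$samples$sample_id)
  d2 <- matrix(0.04, 4, 4); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- 0.002
  d2[3, 4] <- d2[4, 3] <- 0.004
  cs2 <- count_sharing(pop2, ch22, sharing_ani = 99.5,
                       dist = dist_mat(d2, paste0("g", 1:4)))
  expect_equal(cs2$sharing_times, 2)
  expect_equal(cs2$family_prevalence, 2)
  # per-family counting collapses multiplicity
  d3 <- dist_mat(matrix(0.001, 3, 3) - diag(0.001, 3), paste0("g", 1:3))
  expect_equal(count_sharing(pop, ch3, dist = d3,
                             per_family = TRUE)$sharing_times, 1)
  # invariants: prevalence <= times <= sum of within-family pairs
  expect_lte(cs2$family_prevalence, cs2$sharing_times)
  expect_lte(cs2$sharing_times, 2 * choose(2, 2))
})

test_that("family_association flags planted separation, not flat matrices", {
  ch <- make_cohort(4, 2)
  samples <- ch$samples$sample_id
  pop <- list(species_label = "sp",
              genomes = lapply(seq_along(samples), function(i)
                make_genome(paste0("g", i), samples[i], species = "sp")))
  ids <- paste0("g", 1:8)
  # forced separation: within-family d = 0.0002, cross-family 0.04
  fam <- rep(1:4, each = 2)
  d <- matrix(0.04, 8, 8)
  for (i in 1:8) for (j in 1:8) if (fam[i] == fam[j]) d[i, j] <- 0.0002
  diag(d) <- 0
  fa <- family_association(pop, ch, dist = dist_mat(d, ids),
                           n_perm = 999, seed = 1)
  expect_true(fa$shared_flag)
  expect_gt(fa$r_squared, 0.9)
  expect_lt(fa$p_value, 0.05)
  # all pairwise distances identical: no family signal, F = 1 for every
  # relabeling, so p = 1 and the flag stays down
  flat <- dist_mat(matrix(0.3, 8, 8) - diag(0.3, 8), ids)
  fa0 <- family_association(pop, ch, dist = flat, n_perm = 199, seed = 1)
  expect_false(fa0$shared_flag)
  expect_equal(fa0$p_value, 1)
  # single-family population has no between-family contrast
  ch1 <- make_cohort(1, 3)
  pop1 <- list(species_label = "sp",
               genomes = lapply(ch1$samples$sample_id, function(s)
                 make_genome(paste0("g_", s), s)))
  expect_error(family_association(pop1, ch1,
                                  dist = dist_mat(matrix(0, 3, 3),
                                                  paste0("g_", ch1$samples$sample_id))),
               "between-family")
})

test_that("shuffled family labels rarely raise the flag", {
  # null calibration of the joint (R2 > 0.5, p < 0.05) rule at modest n
  set.seed(12)
  ch <- make_cohort(6, 3)
  samples <- ch$samples$sample_id
  n <- length(samples)
  hits <- 0
  reps <- 40
  for (r in 1:reps) {
    x <- matrix(stats::rnorm(n * 5), n)
    d <- as.matrix(stats::dist(x)); d <- d / max(d)
    shuffled <- sample(samples)
    pop <- list(species_label = "sp",
                genomes = lapply(seq_len(n), function(i)
                  make_genome(paste0("g", i), shuffled[i], species = "sp")))
    fa <- family_association(pop, ch, dist = dist_mat(d, paste0("g", 1:n)),
                             n_perm = 199, seed = r)
    if (fa$shared_flag) hits <- hits + 1
  }
  expect_lte(hits / reps, 0.10)
})

test_that("classical_mds reconstructs embeddable configurations", {
  # equilateral triangle
  d3 <- dist_mat(matrix(1, 3, 3) - diag(1, 3), c("a", "b", "c"))
  xy <- classical_mds(d3, k = 2)
  rec <- as.matrix(stats::dist(xy))
  expect_equal(unname(rec[upper.tri(rec)]), rep(1, 3), tolerance = 1e-8)
  # construct-then-recover from known planar points
  set.seed(13)
  pts <- matrix(stats::rnorm(14), 7)
  d <- dist_mat(as.matrix(stats::dist(pts)), sprintf("p%d", 1:7))
  co <- classical_mds(d, k = 2)
  expect_equal(as.matrix(stats::dist(co)), unname(d), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicate points coincide
  pts2 <- rbind(pts, pts[1, ])
  d2 <- dist_mat(as.matrix(stats::dist(pts2)), sprintf("p%d", 1:8))
  co2 <- classical_mds(d2, k = 2)
  expect_equal(co2["p8", ], co2["p1", ], tolerance = 1e-8)
  # requesting more axes than positive eigenvalues warns
  expect_warning(classical_mds(d3, k = 3), "positive eigenvalue")
  # deterministic sign convention: largest |loading| positive
  expect_true(all(apply(co, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("genetic_composition_distance follows the stated convention", {
  ch <- family_cohort(data.frame(
    sample_id = c("s1", "s2"), family_id = c("F1", "F1"),
    role = c("father", "mother"), ethnicity = "Daur", sex = c("M", "F"),
    age = 40, region = "regionA"))
  site <- function(pos, A, C) data.frame(contig = "c1", position = pos,
                                         ref = "A", A = A, C = C,
                                         G = 0L, T = 0L)
  # sample1 frequencies (1.0, 0.5) vs sample2 (0.5, 0.5): BC = 0.5/2.5
  p1 <- snv_profile("g1", site(10, 10L, 10L))        # site 10 only, 0.5
  p2 <- snv_profile("g2", rbind(site(5, 10L, 10L), site(10, 10L, 10L)))
  meta <- data.frame(genome_id = c("g1", "g2"), sample_id = c("s1", "s2"),
                     species_label = "sp1")
  d <- genetic_composition_distance(list(p1, p2), ch, meta)
  expect_equal(d["s1", "s2"], 0.2)
  # identical profiles -> 0
  d0 <- genetic_composition_distance(list(p1, snv_profile("g2",
    site(10, 10L, 10L))), ch, meta)
  expect_equal(d0["s1", "s2"], 0)
  # samples sharing no species -> 1
  meta2 <- data.frame(genome_id = c("g1", "g2"),
                      sample_id = c("s1", "s2"),
                      species_label = c("sp1", "sp2"))
  d1 <- genetic_composition_distance(list(p1, p2), ch, meta2)
  expect_equal(d1["s1", "s2"], 1)
  # sample with no profiled species errors
  ch3 <- family_cohort(rbind(ch$samples,
    data.frame(sample_id = "s3", family_id = "F1", role = "child",
               ethnicity = "Daur", sex = "M", age = 5,
               region = "regionA")))
  expect_error(genetic_composition_distance(list(p1, p2), ch3, meta), "s3")
})

test_that("end-to-end sharing recovery on a planted cohort", {
  cfg <- simulation_config(
    n_families = 8, members_per_family = 3, n_species = 2,
    n_abundance_taxa = 6, genome_length = 3000,
    transmission_pairs = data.frame(family_id = sprintf("F%02d", 1:8),
                                    species_label = "sp1"),
    seed = 21)
  sc <- generate_cohort(cfg)
  cand <- select_candidates(sc$genomes, sc$cohort)
  expect_equal(vapply(cand, `[[`, "", "species_label"), c("sp1", "sp2"))
  sh <- sharing_analysis(cand, sc$cohort, n_perm = 199, seed = 3)
  flagged <- sh$table$species_label[sh$table$shared_flag]
  expect_equal(flagged, "sp1")
  expect_gte(sh$table$sharing_times[sh$table$species_label == "sp1"], 8)
  expect_equal(sh$table$family_prevalence[sh$table$species_label == "sp1"], 8)
})
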