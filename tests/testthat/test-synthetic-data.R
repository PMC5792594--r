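test_that("species design validates ingroup monophyly and subset structure", {
  d <- species_design()
  expect_length(d$species_ids, 13)
  expect_length(d$ingroup_ids, 5)
  expect_length(d$outgroup_ids, 8)
  expect_error(species_design(ingroup_ids = c("ing1", "out1")),
               "monophyletic")
  expect_error(species_design(ingroup_ids = character(0)), "subset")
  expect_error(species_design(ingroup_ids = species_design()$species_ids),
               "subset")
})

test_that("family spec rejects inconsistent identity targets", {
  expect_error(family_spec("F", within_identity = 0.5, between_identity = 0.6),
               "between_identity")
  expect_error(family_spec("F", within_identity = 0.5, between_identity = 0.5),
               "between_identity")
  expect_error(family_spec("F", within_identity = 0), "within_identity")
})

test_that("a bundle covers all 13 species, one proteome each", {
  b <- small_bundle()
  expect_length(b$proteomes, 13)
  expect_setequal(names(b$proteomes), species_design()$species_ids)
  expect_true(all(lengths(b$proteomes) > 0))
})

test_that("within_identity = 1 plants identical sequences (no substitutions)", {
  b <- simulate_gene_families(
    species_design(),
    list(family_spec("F", n_subfamilies = 1, within_identity = 1,
                     between_identity = 0.3)),
    decoy_count = 0, seed = 3, verify = FALSE)
  seqs <- unlist(unname(b$proteomes))
  expect_length(unique(seqs), 1)
  expect_equal(pairwise_identity(seqs[[1]], seqs[[2]]), 1.0)
})

test_that("realized identities bracket the targets (brute-force oracle)", {
  b <- simulate_gene_families(
    species_design(),
    list(family_spec("F", n_subfamilies = 3, within_identity = 0.9,
                     between_identity = 0.3, clade_specific = TRUE)),
    decoy_count = 0, seed = 13, verify = FALSE)
  seqs <- unlist(unname(b$proteomes))
  tg <- b$truth$genes
  sf <- setNames(tg$subfamily_id, tg$gene)
  ids <- tg$gene
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      id <- pairwise_identity(seqs[[ids[i]]], seqs[[ids[j]]])
      if (sf[[ids[i]]] == sf[[ids[j]]]) {
        expect_gte(id, 0.9)
      } else {
        expect_lte(id, 0.3)
      }
    }
  }
})

test_that("clade-specific families have zero members in outgroup species", {
  b <- small_bundle()
  d <- b$design
  tg <- b$truth$genes
  spec_sfs <- b$truth$subfamilies$subfamily_id[b$truth$subfamilies$clade_specific]
  spec_species <- tg$species[!is.na(tg$subfamily_id) &
                               tg$subfamily_id %in% spec_sfs]
  expect_true(all(spec_species %in% d$ingroup_ids))
  shared_sfs <- setdiff(b$truth$subfamilies$subfamily_id, spec_sfs)
  for (s in shared_sfs) {
    expect_setequal(unique(tg$species[!is.na(tg$subfamily_id) &
                                        tg$subfamily_id == s]),
                    d$species_ids)
  }
})

test_that("generation is a pure function of (config, seed)", {
  gen <- function() simulate_gene_families(
    species_design(), list(family_spec("F", n_subfamilies = 2)),
    decoy_count = 5, seed = 99, verify = FALSE)
  expect_identical(gen(), gen())
})

test_that("unachievable between target fails loudly", {
  expect_error(
    simulate_gene_families(species_design(),
                           list(family_spec("F", between_identity = 0.05)),
                           decoy_count = 0, seed = 1),
    "floor")
})

test_that("decoys span lengths that straddle the protein-length screen", {
  b <- default_bundle()
  tg <- b$truth$genes
  decoys <- tg$gene[!tg$is_domain_bearing]
  seqs <- unlist(unname(b$proteomes))
  lens <- nchar(seqs[decoys])
  expect_true(all(lens >= 200 & lens <= 800))
  expect_true(any(lens <= 350 | lens >= 650))
})

test_that("expression table has the study's 5 wild + 6 cultivated design", {
  b <- small_bundle()
  ex <- simulate_expression(b$truth, seed = 2)
  expect_equal(sum(ex$groups == "wild"), 5)
  expect_equal(sum(ex$groups == "cultivated"), 6)
  expect_equal(ncol(ex$values), 11)
  expect_equal(rownames(ex$values), b$truth$genes$gene)
  expect_true(all(ex$values >= 0))
  expect_identical(simulate_expression(b$truth, seed = 2),
                   simulate_expression(b$truth, seed = 2))
  expect_error(simulate_expression(b$truth, n_wild = 0, seed = 1), ">= 1")
})

test_that("pathway genes exceed the global median in both groups for >= 95% of seeds", {
  truth <- list(genes = data.frame(gene = sprintf("g%03d", 1:60),
                                   stringsAsFactors = FALSE),
                pathway_genes = sprintf("g%03d", 1:5))
  hits <- vapply(1:200, function(s) {
    ex <- simulate_expression(truth, seed = s)
    m <- group_mean_expression(ex)
    path <- m$gene %in% truth$pathway_genes
    all(m$mean_wild[path] > median(m$mean_wild)) &&
      all(m$mean_cultivated[path] > median(m$mean_cultivated))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("kinetics obey the closed form and the half-saturation identity", {
  km <- 9.24; kcat <- 0.57; e0 <- 0.01
  kd <- simulate_kinetics(km, kcat, e0, concs = c(0.5, km, 20))
  expect_equal(kd$rate[2], kcat * e0 / 2)  # S = Km
  expect_equal(kd$rate, kcat * e0 * kd$conc / (km + kd$conc), tolerance = 1e-15)
  expect_error(simulate_kinetics(km, kcat, e0, concs = c(-1, 2, 3)),
               "positive")
  expect_error(simulate_kinetics(km, kcat, e0, concs = c(1, 1, 3)),
               "distinct")
  expect_error(simulate_kinetics(-1, kcat, e0, concs = 1:3), "> 0")
  noisy <- simulate_kinetics(km, kcat, e0, concs = 1:5, noise_sd = 0.05,
                             seed = 4)
  expect_true(all(noisy$rate >= 0))
  expect_identical(noisy,
                   simulate_kinetics(km, kcat, e0, concs = 1:5,
                                     noise_sd = 0.05, seed = 4))
})
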