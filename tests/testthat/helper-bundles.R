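# memoized synthetic bundles shared across test files (generation and the
# identity-matrix oracle are the expensive parts of the suite)
.bundle_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.bundle_cache[[key]])) .bundle_cache[[key]] <- fn()
  .bundle_cache[[key]]
}

# small bundle: one shared + one clade-specific family, two subfamilies each
small_bundle <- function() {
  cached("small", function() {
    simulate_gene_families(
      species_design(),
      list(family_spec("FAMA"), family_spec("FAMB", clade_specific = TRUE)),
      decoy_count = 10, seed = 7)
  })
}

# the default study-scale bundle (3 shared + 3 clade-specific families)
default_bundle <- function() {
  cached("default", function() {
    simulate_gene_families(species_design(), default_family_specs(),
                           decoy_count = 20, seed = 101)
  })
}

small_idmat <- function() {
  cached("small_idmat", function() {
    b <- small_bundle()
    seqs <- unlist(unname(b$proteomes))
    members <- b$truth$genes$gene[b$truth$genes$is_domain_bearing]
    build_identity_matrix(seqs[members])
  })
}

# assignment taken straight from the planted truth (bypasses clustering)
assignment_from_truth <- function(truth) {
  tg <- truth$genes[truth$genes$is_domain_bearing, ]
  subfamily_assignment(data.frame(gene = tg$gene,
                                  subfamily_id = tg$subfamily_id,
                                  species = tg$species,
                                  stringsAsFactors = FALSE))
}

# reduced pipeline configuration used where full study scale is not the point
small_pipeline_config <- function(seed = 5) {
  pipeline_config(
    seed = seed,
    family_specs = list(family_spec("FAMA", n_subfamilies = 1),
                        family_spec("FAMB", n_subfamilies = 1,
                                    clade_specific = TRUE)),
    decoy_count = 6)
}
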