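test_that("pairwise identity matches hand alignments and is symmetric", {
  expect_equal(pairwise_identity("MKVLA", "MKVLA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AATA"), 0.75)  # 3 matches / 4 columns
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)   # disjoint alphabets
  expect_error(pairwise_identity("AB1", "AAA"), "non-amino-acid")
  expect_error(pairwise_identity("", "AAA"), "non-empty")

  set.seed(42)
  for (i in 1:8) {
    a <- paste(sample(AA_ALPHABET, 60, replace = TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET, 50, replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("the identity matrix is consistent with the pairwise kernel", {
  idm <- small_idmat()
  expect_true(isSymmetric(idm, tol = 1e-12))
  expect_true(all(diag(idm) == 1))
  expect_true(all(idm >= 0 & idm <= 1))

  b <- small_bundle()
  seqs <- unlist(unname(b$proteomes))
  set.seed(7)
  ids <- sample(rownames(idm), 4)
  for (i in 1:3) {
    expect_equal(idm[ids[i], ids[i + 1]],
                 pairwise_identity(seqs[[ids[i]]], seqs[[ids[i + 1]]]))
  }
  expect_error(build_identity_matrix(c(a = "MKV", a = "MKV")), "duplicate")
  expect_error(build_identity_matrix(c(a = "MKV")), "at least 2")
})

test_that("neighbor joining solves the 2- and 3-taxon closed forms", {
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(D2)
  expect_setequal(t2$tip.label, c("a", "b"))
  expect_equal(sort(t2$edge.length), c(2, 2))

  D3 <- matrix(c(0, 5, 9,
                 5, 0, 8,
                 9, 8, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  # closed form: la = (dab + dac - dbc)/2 = 3, lb = 2, lc = 6
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["a"]], 3)
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 6)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "asymmetric")
})

test_that("NJ inverts additive matrices from known trees exactly", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr)
    out <- neighbor_joining(D)
    Dout <- ape::cophenetic.phylo(out)[rownames(D), colnames(D)]
    expect_lt(max(abs(Dout - D)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), out)), 0)
  }
})

test_that("subfamily partition handles the degenerate identity regimes", {
  ids <- c("a", "b", "c", "d")
  high <- matrix(0.9, 4, 4, dimnames = list(ids, ids)); diag(high) <- 1
  tree <- neighbor_joining(1 - high)
  one <- partition_subfamilies(tree, high, tau = 0.55)
  expect_equal(length(unique(one$genes$subfamily_id)), 1)

  low <- matrix(0.1, 4, 4, dimnames = list(ids, ids)); diag(low) <- 1
  tree2 <- neighbor_joining(1 - low)
  singles <- partition_subfamilies(tree2, low, tau = 0.55)
  expect_equal(length(unique(singles$genes$subfamily_id)), 4)
})

test_that("planted subfamilies are recovered perfectly from tree + identity", {
  b <- small_bundle()
  idm <- small_idmat()
  tree <- neighbor_joining(1 - idm)
  tg <- b$truth$genes[b$truth$genes$is_domain_bearing, ]
  asg <- partition_subfamilies(tree, idm, tau = 0.55,
                               species = setNames(tg$species, tg$gene))
  # a partition: every member exactly once
  expect_setequal(asg$genes$gene, tg$gene)
  expect_false(anyDuplicated(asg$genes$gene) > 0)
  truth_labels <- setNames(tg$subfamily_id, tg$gene)[asg$genes$gene]
  expect_equal(mclust::adjustedRandIndex(asg$genes$subfamily_id, truth_labels),
               1.0)
})

test_that("reciprocal best hits recover one-to-one orthologs and drop ties", {
  b <- simulate_gene_families(
    species_design(),
    list(family_spec("F1", n_subfamilies = 1),
         family_spec("F2", n_subfamilies = 1)),
    decoy_count = 0, seed = 5, verify = FALSE)
  pro <- b$proteomes[c("ing1", "ing2", "out1")]
  groups <- rbh_one_to_one(pro)
  expect_length(groups, 2)
  tg <- b$truth$genes
  for (g in groups) {
    fams <- tg$family_id[match(unname(g), tg$gene)]
    expect_length(unique(fams), 1)  # each group is one planted family
    expect_setequal(names(g), names(pro))
  }

  # an equal-score duplicate makes the component non-one-to-one -> discarded
  dup <- list(spA = c(g1 = "MKVLAWCD"),
              spB = c(g2 = "MKVLAWCD", g3 = "MKVLAWCD"))
  expect_length(rbh_one_to_one(dup), 0)
  expect_error(rbh_one_to_one(list(spA = c(g1 = "MKV"), spB = character(0))),
               "empty proteome")
  expect_error(rbh_one_to_one(list(spA = c(g1 = "MKV"))), "at least 2")
})

test_that("a single ortholog group gives a degenerate bootstrap of 100s", {
  b <- simulate_gene_families(
    species_design(),
    list(family_spec("F", n_subfamilies = 1)),
    decoy_count = 0, seed = 8, verify = FALSE)
  tg <- b$truth$genes
  sets <- list(setNames(tg$gene, tg$species))
  st <- species_tree_bootstrap(sets, b$proteomes, n_boot = 25, seed = 1)
  expect_true(all(st$node.label[!is.na(st$node.label)] == 100))
  expect_error(species_tree_bootstrap(sets, b$proteomes, n_boot = 0), "n_boot")
})

test_that("50 ortholog groups from the guide tree give a fully supported ingroup", {
  d <- species_design()
  specs <- lapply(sprintf("ORTH%02d", 1:50),
                  function(f) family_spec(f, n_subfamilies = 1))
  b <- simulate_gene_families(d, specs, decoy_count = 0, seed = 11,
                              verify = FALSE)
  tg <- b$truth$genes
  sets <- lapply(split(tg, tg$subfamily_id),
                 function(df) setNames(df$gene, df$species))
  st <- species_tree_bootstrap(sets, b$proteomes, n_boot = 100, seed = 3)
  rooted <- ape::root(st, outgroup = intersect(st$tip.label, d$outgroup_ids),
                      resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, d$ingroup_ids))
  ing_node <- ape::getMRCA(st, d$ingroup_ids)
  support <- st$node.label[ing_node - length(st$tip.label)]
  expect_equal(support, 100)
})
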