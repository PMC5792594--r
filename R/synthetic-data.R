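#' Species design for a simulated comparative study
#'
#' Describes the species panel: a rooted binary guide tree with branch
#' lengths (substitutions/site), and which tips form the ingroup clade. The
#' default panel has 5 ingroup and 8 outgroup species, the comparative
#' setting of the study this package emulates (five Asteraceae genomes
#' against eight other eudicots).
#'
#' @param species_ids character vector of species labels. Default: the tips
#'   of the default guide tree (`ing1..ing5`, `out1..out8`).
#' @param ingroup_ids subset of `species_ids` forming the ingroup; must be a
#'   non-empty strict subset and monophyletic in the guide tree.
#' @param guide_tree rooted binary `phylo` with branch lengths. Default: a
#'   fixed 13-tip tree with a monophyletic 5-species ingroup.
#' @return object of class `species_design`.
#' @export
species_design <- function(species_ids = NULL, ingroup_ids = NULL,
                           guide_tree = NULL) {
  if (is.null(guide_tree)) {
    guide_tree <- ape::read.tree(text = paste0(
      "(((ing1:0.05,ing2:0.05):0.03,(ing3:0.04,(ing4:0.03,ing5:0.03):0.02)",
      ":0.04):0.15,((out1:0.08,out2:0.08):0.05,((out3:0.07,out4:0.07):0.04,",
      "(out5:0.06,(out6:0.05,(out7:0.04,out8:0.04):0.02):0.03):0.05):0.03)",
      ":0.10);"))
  }
  if (is.null(species_ids)) species_ids <- guide_tree$tip.label
  if (is.null(ingroup_ids)) {
    ingroup_ids <- grep("^ing", species_ids, value = TRUE)
  }
  if (!setequal(species_ids, guide_tree$tip.label)) {
    stop("species_ids must match the guide tree tips")
  }
  if (length(ingroup_ids) == 0 || !all(ingroup_ids %in% species_ids) ||
      length(ingroup_ids) >= length(species_ids)) {
    stop("ingroup_ids must be a non-empty strict subset of species_ids")
  }
  if (!ape::is.rooted(guide_tree)) stop("guide tree must be rooted")
  if (!ape::is.monophyletic(guide_tree, ingroup_ids)) {
    stop("ingroup is not monophyletic in the guide tree")
  }
  structure(list(species_ids = species_ids, ingroup_ids = ingroup_ids,
                 outgroup_ids = setdiff(species_ids, ingroup_ids),
                 guide_tree = guide_tree),
            class = "species_design")
}

#' Specification of one planted gene family
#'
#' @param family_id label.
#' @param n_subfamilies number of subfamilies planted for this family.
#' @param within_identity target lower bound on pairwise identity within a
#'   subfamily, fraction in (0, 1].
#' @param between_identity target upper bound on pairwise identity between
#'   subfamilies, in `[0, within_identity)`.
#' @param clade_specific if `TRUE`, members exist only in ingroup species
#'   (the family is gained on the ingroup stem).
#' @param members_per_species gene copies per species per subfamily.
#' @param domain_length domain length in residues; the default 400 lies
#'   inside the (350, 650) protein-length screen so planted members pass it.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(family_id, n_subfamilies = 2, within_identity = 0.9,
                        between_identity = 0.3, clade_specific = FALSE,
                        members_per_species = 1, domain_length = 400) {
  if (!(within_identity > 0 && within_identity <= 1)) {
    stop("within_identity must be in (0, 1]")
  }
  if (between_identity < 0 || between_identity >= within_identity) {
    stop("between_identity must be in [0, within_identity)")
  }
  if (n_subfamilies < 1 || members_per_species < 1) {
    stop("n_subfamilies and members_per_species must be >= 1")
  }
  structure(list(family_id = family_id, n_subfamilies = n_subfamilies,
                 within_identity = within_identity,
                 between_identity = between_identity,
                 clade_specific = isTRUE(clade_specific),
                 members_per_species = members_per_species,
                 domain_length = domain_length),
            class = "family_spec")
}

# predicted pairwise identity between two sequences that each re-mutated a
# fraction q of the free (non-anchor) positions of a common ancestor
pred_between_identity <- function(q, cf) {
  cf + (1 - cf) * ((1 - q)^2 + (1 - (1 - q)^2) / 20)
}

# predicted identity between two tips whose connecting path carries m
# mutation events over n_free free positions (anchors cf conserved)
pred_path_identity <- function(m, cf, n_free) {
  u <- (1 - 1 / n_free)^m
  cf + (1 - cf) * (u + (1 - u) / 20)
}

#' Simulate multi-species proteomes with planted gene families
#'
#' Each family descends from a random ancestral domain sequence. A fixed
#' fraction of anchor columns (emulating invariant catalytic residues) is
#' never mutated; it carries the superfamily signal that the profile search
#' detects. Subfamily seeds are derived from the ancestor with a mutation
#' count chosen by bisection so that realized between-subfamily identity
#' stays at or below the target; each seed is then evolved along the guide
#' tree (restricted to the ingroup clade for clade-specific families) with
#' per-branch substitution counts `round(rate x branch length x length)`,
#' the rate again tuned by bisection so realized within-subfamily identity
#' stays at or above the target. Decoys are i.i.d. uniform-residue sequences
#' of length 200-800 without the domain, so some deliberately violate the
#' (350, 650) length screen. Realized identities are verified against the
#' brute-force alignment oracle ([pairwise_identity()]) on bundles of at
#' most 200 planted genes; generation fails loudly if a target is missed.
#'
#' @param design a [species_design()].
#' @param specs list of [family_spec()]s (all sharing `domain_length`).
#' @param decoy_count number of domain-free decoy sequences.
#' @param seed integer seed; all output is a pure function of (config, seed).
#' @param conserved_frac fraction of anchor columns (default 0.15).
#' @param verify verify realized identities on bundles <= 200 genes.
#' @return a bundle: list with `design`, `proteomes` (per-species named
#'   character vectors), `truth` (gene and subfamily tables plus
#'   `pathway_genes`), `seed_alignment` (the ungapped subfamily seed
#'   sequences, profile training material), and `params`.
#' @export
simulate_gene_families <- function(design, specs, decoy_count = 20, seed,
                                   conserved_frac = 0.15, verify = TRUE) {
  if (missing(seed)) stop("seed is required")
  if (!inherits(design, "species_design")) stop("design must be a species_design")
  if (length(specs) == 0) stop("specs must be non-empty")
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "family_spec")) stop("each spec must be a family_spec")
    s
  })
  L <- unique(vapply(specs, `[[`, numeric(1), "domain_length"))
  if (length(L) != 1) {
    stop("all family specs in a bundle must share domain_length")
  }
  set.seed(seed)

  n_anchor <- round(conserved_frac * L)
  anchors <- sort(sample.int(L, n_anchor))
  free <- setdiff(seq_len(L), anchors)
  n_free <- length(free)
  cf <- n_anchor / L
  ancestor <- random_aa_seq(L)

  # between-subfamily mutation count: smallest q with predicted identity at
  # least 3 sigma under the tightest between target
  target_b <- min(vapply(specs, `[[`, numeric(1), "between_identity"))
  margin_b <- 3 * sqrt(target_b * (1 - target_b) / L)
  goal_b <- target_b - margin_b
  if (pred_between_identity(1, cf) > goal_b) {
    stop("between_identity target ", target_b,
         " is below the achievable floor given conserved_frac ", conserved_frac)
  }
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pred_between_identity(mid, cf) > goal_b) lo <- mid else hi <- mid
  }
  m_between <- min(n_free, ceiling(hi * n_free))

  genes <- list(); proteomes <- stats::setNames(
    vector("list", length(design$species_ids)), design$species_ids)
  for (sp in design$species_ids) proteomes[[sp]] <- character(0)
  subfam_rows <- list(); seed_aln <- character(0)
  gene_counter <- 0L
  next_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("g%04d", gene_counter)
  }

  dup_bl <- 0.01  # recent-duplicate branch length for extra per-species copies

  for (spec in specs) {
    tips <- if (spec$clade_specific) design$ingroup_ids else design$species_ids
    tree_f <- ape::keep.tip(design$guide_tree, tips)
    depth <- max(ape::node.depth.edgelength(tree_f))
    dmax <- if (length(tips) > 1) max(ape::cophenetic.phylo(tree_f)) else 0
    if (spec$members_per_species > 1) dmax <- max(dmax, 2 * depth + 2 * dup_bl)

    # within-subfamily rate: largest rate keeping the worst tip pair 3 sigma
    # above the within target
    margin_w <- 3 * sqrt(spec$within_identity * (1 - spec$within_identity) / L)
    goal_w <- min(1, spec$within_identity + margin_w)
    rate <- 0
    if (dmax > 0 && goal_w < 1) {
      lo <- 0; hi <- 10 / (dmax * L) * n_free  # generous upper bracket
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (pred_path_identity(mid * dmax * L, cf, n_free) >= goal_w) {
          lo <- mid
        } else hi <- mid
      }
      rate <- lo
    }

    for (k in seq_len(spec$n_subfamilies)) {
      sf_id <- paste0(spec$family_id, ".sf", k)
      sf_seed <- mutate_positions(ancestor, sample(free, m_between))
      seed_aln[[sf_id]] <- sf_seed
      subfam_rows[[sf_id]] <- data.frame(
        subfamily_id = sf_id, family_id = spec$family_id,
        clade_specific = spec$clade_specific, stringsAsFactors = FALSE)

      # evolve the seed along the family tree
      node_seq <- list()
      root <- length(tree_f$tip.label) + 1L
      node_seq[[root]] <- sf_seed
      ord <- ape::reorder.phylo(tree_f, "cladewise")
      tip_seq <- stats::setNames(character(length(tips)), tree_f$tip.label)
      if (length(tips) == 1) {
        tip_seq[tips] <- sf_seed
      } else {
        for (e in seq_len(nrow(ord$edge))) {
          par <- ord$edge[e, 1]; chi <- ord$edge[e, 2]
          m <- min(n_free, round(rate * ord$edge.length[e] * L))
          child_seq <- mutate_positions(node_seq[[par]],
                                        if (m > 0) sample(free, m) else integer(0))
          if (chi <= length(tree_f$tip.label)) {
            tip_seq[tree_f$tip.label[chi]] <- child_seq
          } else {
            node_seq[[chi]] <- child_seq
          }
        }
      }

      for (sp in tips) {
        for (j in seq_len(spec$members_per_species)) {
          g <- next_gene()
          s <- tip_seq[[sp]]
          if (spec$members_per_species > 1) {
            m <- min(n_free, round(rate * dup_bl * L))
            s <- mutate_positions(s, if (m > 0) sample(free, m) else integer(0))
          }
          proteomes[[sp]][[g]] <- s
          genes[[g]] <- data.frame(gene = g, species = sp,
                                   family_id = spec$family_id,
                                   subfamily_id = sf_id,
                                   is_domain_bearing = TRUE,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  }

  # decoys: i.i.d. uniform residues, lengths 200-800
  if (decoy_count > 0) {
    sp_cycle <- rep_len(design$species_ids, decoy_count)
    for (i in seq_len(decoy_count)) {
      g <- next_gene()
      len <- sample(200:800, 1)
      sp <- sp_cycle[i]
      proteomes[[sp]][[g]] <- random_aa_seq(len)
      genes[[g]] <- data.frame(gene = g, species = sp, family_id = NA_character_,
                               subfamily_id = NA_character_,
                               is_domain_bearing = FALSE,
                               stringsAsFactors = FALSE)
    }
  }

  truth_genes <- do.call(rbind, genes)
  rownames(truth_genes) <- NULL
  truth_subfam <- do.call(rbind, subfam_rows)
  rownames(truth_subfam) <- NULL

  # planted pathway genes: the first clade-specific subfamily (or the first
  # subfamily if none is clade-specific)
  sf_path <- truth_subfam$subfamily_id[truth_subfam$clade_specific][1]
  if (is.na(sf_path)) sf_path <- truth_subfam$subfamily_id[1]
  pathway_genes <- truth_genes$gene[!is.na(truth_genes$subfamily_id) &
                                      truth_genes$subfamily_id == sf_path]

  truth <- list(genes = truth_genes, subfamilies = truth_subfam,
                pathway_genes = pathway_genes)

  bundle <- list(design = design, proteomes = proteomes, truth = truth,
                 seed_alignment = seed_aln,
                 params = list(seed = seed, conserved_frac = conserved_frac,
                               domain_length = L, decoy_count = decoy_count,
                               m_between = m_between, anchors = anchors))

  n_members <- sum(truth_genes$is_domain_bearing)
  if (verify && n_members <= 200) verify_bundle_identities(bundle, specs)
  bundle
}

# brute-force oracle check of realized identities against the targets
verify_bundle_identities <- function(bundle, specs) {
  tg <- bundle$truth$genes[bundle$truth$genes$is_domain_bearing, ]
  all_seq <- unlist(unname(bundle$proteomes))
  spec_by_fam <- stats::setNames(specs, vapply(specs, `[[`, "", "family_id"))
  for (fam in unique(tg$family_id)) {
    spec <- spec_by_fam[[fam]]
    fam_genes <- tg[tg$family_id == fam, ]
    for (sf in unique(fam_genes$subfamily_id)) {
      members <- fam_genes$gene[fam_genes$subfamily_id == sf]
      if (length(members) < 2) next
      for (i in seq_len(length(members) - 1)) {
        for (j in (i + 1):length(members)) {
          id <- pairwise_identity(all_seq[[members[i]]], all_seq[[members[j]]])
          if (id < spec$within_identity) {
            stop("realized within-subfamily identity ", round(id, 3),
                 " below target ", spec$within_identity, " in ", sf)
          }
        }
      }
    }
  }
  # between-subfamily: all pairs of subfamily seeds (includes cross-family)
  seeds <- bundle$seed_alignment
  sf_fam <- stats::setNames(bundle$truth$subfamilies$family_id,
                            bundle$truth$subfamilies$subfamily_id)
  if (length(seeds) > 1) {
    for (i in seq_len(length(seeds) - 1)) {
      for (j in (i + 1):length(seeds)) {
        tb <- max(spec_by_fam[[sf_fam[[names(seeds)[i]]]]]$between_identity,
                  spec_by_fam[[sf_fam[[names(seeds)[j]]]]]$between_identity)
        id <- pairwise_identity(seeds[[i]], seeds[[j]])
        if (id > tb) {
          stop("realized between-subfamily identity ", round(id, 3),
               " above target ", tb, " for ", names(seeds)[i], " vs ",
               names(seeds)[j])
        }
      }
    }
  }
  invisible(TRUE)
}

#' Simulate an expression table with planted high-expression pathway genes
#'
#' Per-gene log-normal baseline shared between groups (so wild and
#' cultivated means fall on a correlated diagonal), independent
#' multiplicative log-normal sample noise per column, and a strong upward
#' shift of the planted pathway genes. Unit-agnostic, FPKM-like values;
#' zeros are permitted downstream (a pseudocount of 1 is added before any
#' log transform).
#'
#' @param truth truth table from [simulate_gene_families()] (or any list with
#'   `genes$gene` and `pathway_genes`).
#' @param n_wild,n_cultivated sample counts per group (defaults 5 and 6, the
#'   study's RNA-seq design).
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal baseline parameters.
#' @param cond_sdlog between-group (wild vs cultivated) log-sd.
#' @param noise_sdlog per-sample log-sd.
#' @param pathway_shift additive shift on the log baseline of pathway genes.
#' @return object of class `expression_table`: list with `values` (gene x
#'   sample matrix) and `groups` (named vector sample -> "wild"/"cultivated").
#' @export
simulate_expression <- function(truth, n_wild = 5, n_cultivated = 6, seed,
                                base_meanlog = 3, base_sdlog = 1.2,
                                cond_sdlog = 0.2, noise_sdlog = 0.35,
                                pathway_shift = 4) {
  if (missing(seed)) stop("seed is required")
  if (n_wild < 1 || n_cultivated < 1) stop("n_wild and n_cultivated must be >= 1")
  genes <- truth$genes$gene
  if (length(genes) == 0) stop("truth is empty")
  set.seed(seed)
  shift <- ifelse(genes %in% truth$pathway_genes, pathway_shift, 0)
  base <- exp(rnorm(length(genes), base_meanlog + shift, base_sdlog))
  mean_w <- base * exp(rnorm(length(genes), 0, cond_sdlog))
  mean_c <- base * exp(rnorm(length(genes), 0, cond_sdlog))
  samples <- c(sprintf("wild_%d", seq_len(n_wild)),
               sprintf("cult_%d", seq_len(n_cultivated)))
  groups <- stats::setNames(rep(c("wild", "cultivated"), c(n_wild, n_cultivated)),
                            samples)
  vals <- matrix(0, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (s in samples) {
    mu <- if (groups[[s]] == "wild") mean_w else mean_c
    vals[, s] <- mu * exp(rnorm(length(genes), 0, noise_sdlog))
  }
  structure(list(values = vals, groups = groups), class = "expression_table")
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' Rates follow `v = kcat * E0 * S / (Km + S)` with multiplicative Gaussian
#' noise `(1 + N(0, noise_sd))`; `noise_sd = 0` gives exact closed-form
#' values. Negative noisy rates are truncated at zero.
#'
#' @param km Michaelis constant, uM (> 0).
#' @param kcat turnover number, 1/s (> 0).
#' @param enzyme_conc enzyme concentration E0, uM (> 0).
#' @param concs substrate concentrations, uM; strictly positive and distinct.
#' @param noise_sd relative noise standard deviation (fraction).
#' @param seed optional integer seed (required when `noise_sd > 0` for
#'   reproducibility).
#' @return object of class `kinetic_dataset`: list with `conc`, `rate`
#'   (uM/s), `enzyme_conc`, `noise_sd` and the generating parameters.
#' @export
simulate_kinetics <- function(km, kcat, enzyme_conc, concs, noise_sd = 0,
                              seed = NULL) {
  if (km <= 0 || kcat <= 0 || enzyme_conc <= 0) {
    stop("km, kcat and enzyme_conc must be > 0")
  }
  if (any(concs <= 0)) stop("substrate concentrations must be strictly positive")
  if (anyDuplicated(concs)) stop("substrate concentrations must be distinct")
  if (!is.null(seed)) set.seed(seed)
  v <- kcat * enzyme_conc * concs / (km + concs)
  if (noise_sd > 0) v <- pmax(0, v * (1 + rnorm(length(concs), 0, noise_sd)))
  structure(list(conc = concs, rate = v, enzyme_conc = enzyme_conc,
                 noise_sd = noise_sd,
                 params = list(km = km, kcat = kcat)),
            class = "kinetic_dataset")
}
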