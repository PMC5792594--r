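#' Pairwise global protein identity
#'
#' Needleman-Wunsch global alignment with free terminal gaps
#' (BLOSUM62, gap open 10, gap extend 1, via Biostrings "overlap" type).
#' Identity = identical aligned pairs / alignment columns, where terminal
#' gap columns are excluded from the denominator and internal gaps are
#' counted — the conventional coverage-robust definition.
#'
#' @param a,b protein sequences (character scalars, 20-letter alphabet).
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  assert_aa(a); assert_aa(b)
  # canonical argument order: co-optimal alignments can differ between
  # (a, b) and (b, a); fixing the order makes the identity symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "overlap")
  ncol_aln <- Biostrings::nchar(aln)
  if (ncol_aln == 0) return(0)
  Biostrings::nmatch(aln) / ncol_aln
}

#' All-pairs identity matrix
#'
#' Computes each of the n(n-1)/2 pairs once ([pairwise_identity()] scoring);
#' the result is symmetric with unit diagonal.
#'
#' @param proteins named character vector (gene id -> sequence), >= 2 entries.
#' @return symmetric numeric matrix with dimnames = gene ids.
#' @export
build_identity_matrix <- function(proteins) {
  if (length(proteins) < 2) stop("need at least 2 proteins")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) stop("duplicate or missing gene ids")
  for (s in proteins) assert_aa(s)
  n <- length(proteins)
  M <- diag(1, n)
  dimnames(M) <- list(ids, ids)
  for (j in 2:n) {
    # elementwise alignment in the same canonical (lexicographic) argument
    # order as pairwise_identity(), so the matrix matches the kernel exactly
    prev <- proteins[seq_len(j - 1)]
    swap <- prev > proteins[[j]]
    pat <- ifelse(swap, proteins[[j]], prev)
    sub <- ifelse(swap, prev, proteins[[j]])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pat), Biostrings::AAStringSet(sub),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "overlap")
    cols <- Biostrings::nchar(aln)
    idv <- ifelse(cols == 0, 0, Biostrings::nmatch(aln) / cols)
    M[seq_len(j - 1), j] <- idv
    M[j, seq_len(j - 1)] <- idv
  }
  M
}

fmt_bl <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration. Negative branch-length estimates are clamped
#' to zero with the deficit transferred to the sibling edge (their sum is
#' preserved), so additive input matrices are inverted exactly: the realized
#' leaf-to-leaf path lengths reproduce the input distances.
#'
#' @param distances symmetric numeric matrix with zero diagonal and
#'   dimnames (or a `dist` object).
#' @param tol asymmetry tolerance.
#' @return an unrooted `phylo` tree (trifurcating root for >= 3 taxa).
#' @export
neighbor_joining <- function(distances, tol = 1e-8) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (max(abs(D - t(D))) > tol) stop("distance matrix is asymmetric beyond tolerance")
  if (any(abs(diag(D)) > tol)) stop("distance matrix diagonal must be zero")
  labels <- rownames(D)
  bad <- grepl("[(),:;]", labels)
  if (any(bad)) stop("taxon labels may not contain Newick metacharacters")

  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", labels[1], fmt_bl(D[1, 2] / 2),
                   labels[2], fmt_bl(D[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }

  frags <- labels
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    k <- which.min(Q)  # column-major first minimum: deterministic tie-break
    i <- (k - 1) %% m + 1
    j <- (k - 1) %/% m + 1
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_bl(li),
                        frags[j], fmt_bl(lj))
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dnew),
                c(dnew, 0))
    frags <- c(frags[others], new_frag)
    rownames(D2) <- colnames(D2) <- paste0("n", seq_len(m - 1))
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[1], fmt_bl(la),
                 frags[2], fmt_bl(lb), frags[3], fmt_bl(lc))
  ape::read.tree(text = txt)
}

#' Partition superfamily members into subfamilies
#'
#' Operationalizes the dual criterion: subfamilies are the maximal
#' monophyletic clades of the all-member tree in which every leaf pair has
#' identity strictly above `tau` (default 0.55, i.e. "higher than 55%").
#' The tree is midpoint-rooted if unrooted, then traversed root-to-tip,
#' accepting the first clade that passes the all-pairs test; leaves failing
#' with all neighbors end up as singletons. The result is always a
#' partition of the input genes.
#'
#' @param tree `phylo` whose tips are the gene ids (typically the
#'   [neighbor_joining()] tree of `1 - identity`).
#' @param idmat identity matrix from [build_identity_matrix()].
#' @param tau strict identity threshold.
#' @param species optional named vector gene -> species, attached to the
#'   assignment (needed for specificity calls).
#' @return object of class `subfamily_assignment`: list with `genes`
#'   (data.frame gene, subfamily_id, species) and `tau`.
#' @export
partition_subfamilies <- function(tree, idmat, tau = 0.55, species = NULL) {
  ids <- rownames(idmat)
  if (!setequal(tree$tip.label, ids)) {
    stop("tree leaves and identity matrix ids do not match")
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), type = "tips")

  clade_ok <- function(node) {
    tips <- tree$tip.label[desc[[node]]]
    if (length(tips) == 1) return(TRUE)
    sub <- idmat[tips, tips]
    all(sub[upper.tri(sub)] > tau)
  }

  groups <- list()
  stack <- ntip + 1L  # root
  while (length(stack) > 0) {
    node <- stack[[1]]
    stack <- stack[-1]
    if (clade_ok(node)) {
      groups[[length(groups) + 1L]] <- tree$tip.label[desc[[node]]]
    } else {
      children <- tree$edge[tree$edge[, 1] == node, 2]
      stack <- c(children, stack)
    }
  }
  rows <- do.call(rbind, lapply(seq_along(groups), function(k) {
    data.frame(gene = groups[[k]], subfamily_id = sprintf("SF%03d", k),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(species)) {
    rows$species <- unname(species[rows$gene])
  } else {
    rows$species <- NA_character_
  }
  subfamily_assignment(rows, tau = tau)
}

#' Construct a subfamily assignment from a gene table
#'
#' @param genes data.frame with columns `gene`, `subfamily_id`, and
#'   optionally `species`.
#' @param tau identity threshold recorded with the assignment.
#' @return object of class `subfamily_assignment`.
#' @export
subfamily_assignment <- function(genes, tau = NA_real_) {
  stopifnot(is.data.frame(genes), all(c("gene", "subfamily_id") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("a gene may belong to only one subfamily")
  if (!"species" %in% names(genes)) genes$species <- NA_character_
  rownames(genes) <- NULL
  structure(list(genes = genes, tau = tau), class = "subfamily_assignment")
}

#' @export
print.subfamily_assignment <- function(x, ...) {
  cat("Subfamily assignment:", nrow(x$genes), "genes in",
      length(unique(x$genes$subfamily_id)), "subfamilies",
      if (!is.na(x$tau)) sprintf("(identity threshold > %.2f)", x$tau) else "",
      "\n")
  invisible(x)
}

# alignment score used for best-hit search (same scoring as identity)
alignment_scores <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), subject,
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "overlap", scoreOnly = TRUE)
}

#' One-to-one orthology by reciprocal best hits
#'
#' For each species pair, the best hit of every gene is found by
#' global-alignment score; a gene pair is an RBH edge when mutually best
#' (ties produce edges to every tied gene). Ortholog groups are the
#' connected components of the RBH graph that contain exactly one gene per
#' species across all species; every other component is discarded.
#'
#' @param proteomes named list species -> named character vector of
#'   sequences (>= 2 species, none empty).
#' @return list of ortholog groups, each a named character vector
#'   species -> gene.
#' @export
rbh_one_to_one <- function(proteomes) {
  if (length(proteomes) < 2) stop("need at least 2 species")
  if (any(lengths(proteomes) == 0)) {
    stop("species with empty proteome: ",
         paste(names(proteomes)[lengths(proteomes) == 0], collapse = ", "))
  }
  species <- names(proteomes)
  edges <- list()
  pairs <- utils::combn(species, 2, simplify = FALSE)
  for (pr in pairs) {
    s1 <- pr[1]; s2 <- pr[2]
    p1 <- proteomes[[s1]]; p2 <- proteomes[[s2]]
    S <- matrix(NA_real_, nrow = length(p1), ncol = length(p2),
                dimnames = list(names(p1), names(p2)))
    for (j in seq_along(p2)) S[, j] <- alignment_scores(p1, p2[[j]])
    best12 <- apply(S, 1, function(x) which(x == max(x)), simplify = FALSE)
    best21 <- apply(S, 2, function(x) which(x == max(x)), simplify = FALSE)
    for (i in seq_along(p1)) {
      for (j in best12[[i]]) {
        if (i %in% best21[[j]]) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = paste0(s1, "|", names(p1)[i]),
            to = paste0(s2, "|", names(p2)[j]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(edges) == 0) return(list())
  ed <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  out <- list()
  for (grp in groups) {
    parsed <- parse_fasta_headers(grp)
    if (length(grp) == length(species) &&
        setequal(parsed$species, species) &&
        anyDuplicated(parsed$species) == 0) {
      out[[length(out) + 1L]] <- stats::setNames(parsed$gene, parsed$species)
    }
  }
  out
}

#' Bootstrapped neighbor-joining species tree from one-to-one orthologs
#'
#' The distance between two species is the mean `1 - identity` over the
#' ortholog groups; the tree is the NJ tree of that matrix. Support values
#' come from resampling ortholog groups with replacement `n_boot` times and
#' recording the percentage of replicates containing each internal
#' bipartition (stored in `node.label`).
#'
#' @param orthosets list of ortholog groups (named vectors species -> gene),
#'   e.g. from [rbh_one_to_one()].
#' @param proteomes named list species -> named character vector.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @return `phylo` with integer percentage supports in `node.label`.
#' @export
species_tree_bootstrap <- function(orthosets, proteomes, n_boot = 100,
                                   seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (length(orthosets) < 1) stop("need at least one ortholog group")
  species <- sort(names(orthosets[[1]]))
  if (length(species) < 3) stop("need at least 3 species")
  G <- length(orthosets)
  dists <- array(0, dim = c(length(species), length(species), G),
                 dimnames = list(species, species, NULL))
  for (g in seq_len(G)) {
    set <- orthosets[[g]]
    seqs <- stats::setNames(
      vapply(species, function(sp) proteomes[[sp]][[set[[sp]]]], ""), species)
    dists[, , g] <- 1 - build_identity_matrix(seqs)[species, species]
  }
  main <- neighbor_joining(apply(dists, c(1, 2), mean))
  set.seed(seed)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(G, G, replace = TRUE)
    boots[[b]] <- neighbor_joining(apply(dists[, , idx, drop = FALSE],
                                         c(1, 2), mean))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  main$node.label <- ifelse(is.na(counts), NA, round(100 * counts / n_boot))
  main
}
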