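toy_expression <- function() {
  vals <- rbind(const = rep(7, 11),
                ramp = c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50, 60))
  colnames(vals) <- c(sprintf("w%d", 1:5), sprintf("c%d", 1:6))
  groups <- setNames(rep(c("wild", "cultivated"), c(5, 6)), colnames(vals))
  structure(list(values = vals, groups = groups), class = "expression_table")
}

test_that("group means are plain arithmetic means per class of columns", {
  m <- group_mean_expression(toy_expression())
  expect_equal(m$mean_wild[m$gene == "const"], 7)
  expect_equal(m$mean_cultivated[m$gene == "const"], 7)
  expect_equal(m$mean_all[m$gene == "const"], 7)
  expect_equal(m$mean_wild[m$gene == "ramp"], 3)  # mean(1:5)
  expect_equal(m$mean_cultivated[m$gene == "ramp"], mean(c(10, 20, 30, 40, 50, 60)))

  ex <- toy_expression()
  expect_error(group_mean_expression(ex$values, ex$groups[-1]),
               "missing from group map")
})

test_that("group means agree with an independent streaming pass to 1e-12", {
  b <- small_bundle()
  ex <- simulate_expression(b$truth, seed = 33)
  m <- group_mean_expression(ex)
  # independent oracle: incremental (streaming) mean, one sample at a time
  stream_mean <- function(cols) {
    acc <- rep(0, nrow(ex$values)); n <- 0
    for (s in cols) {
      n <- n + 1
      acc <- acc + (ex$values[, s] - acc) / n
    }
    acc
  }
  w <- names(ex$groups)[ex$groups == "wild"]
  c_ <- names(ex$groups)[ex$groups == "cultivated"]
  expect_equal(m$mean_wild, unname(stream_mean(w)), tolerance = 1e-12)
  expect_equal(m$mean_cultivated, unname(stream_mean(c_)), tolerance = 1e-12)
  expect_equal(m$mean_all, unname(stream_mean(colnames(ex$values))),
               tolerance = 1e-12)
})

two_class_setup <- function(n_spec, n_shared) {
  genes <- data.frame(
    gene = sprintf("g%03d", seq_len(n_spec + n_shared)),
    subfamily_id = rep(c("SFS", "SFN"), c(n_spec, n_shared)),
    species = rep(c("i1", "o1"), c(n_spec, n_shared)),
    stringsAsFactors = FALSE)
  asg <- subfamily_assignment(genes)
  calls <- call_clade_specific(asg, ingroup = "i1")
  list(asg = asg, calls = calls, genes = genes)
}

test_that("the rank-sum comparison behaves at the extremes and under label swap", {
  s <- two_class_setup(5, 5)
  means <- data.frame(gene = s$genes$gene,
                      mean_all = c(101:105, 1:5))
  res <- compare_specific_vs_nonspecific(means, s$calls, s$asg)
  expect_equal(res$statistic, 25)  # U at its maximum n1*n2
  expect_equal(res$p_value, 2 / choose(10, 5))  # minimal two-sided exact p
  expect_equal(res$method, "exact")

  # swapping class labels leaves the two-sided p unchanged
  s2 <- two_class_setup(5, 5)
  means_swapped <- data.frame(gene = s$genes$gene,
                              mean_all = c(1:5, 101:105))
  res2 <- compare_specific_vs_nonspecific(means_swapped, s2$calls, s2$asg)
  expect_equal(res2$p_value, res$p_value)

  big <- two_class_setup(30, 30)
  means_big <- data.frame(gene = big$genes$gene, mean_all = seq_len(60))
  expect_equal(compare_specific_vs_nonspecific(means_big, big$calls,
                                               big$asg)$method,
               "normal approximation")

  one_class <- two_class_setup(5, 5)
  means_missing <- means[1:5, , drop = FALSE]  # shared class absent
  expect_error(compare_specific_vs_nonspecific(means_missing, one_class$calls,
                                               one_class$asg),
               "non-empty")
})

test_that("candidate ranking is deterministic and insensitive to bystanders", {
  s <- two_class_setup(6, 4)
  set.seed(9)
  means <- data.frame(gene = s$genes$gene, mean_wild = 0, mean_cultivated = 0,
                      mean_all = c(10, 30, 30, 5, 50, 2, 99, 98, 97, 96))
  r <- rank_candidates(s$calls, means, s$asg, top_k = 4)
  expect_equal(r$rank, 1:4)
  expect_equal(r$gene[1], "g005")          # highest mean
  expect_equal(r$gene[2:3], c("g002", "g003"))  # tie broken by gene id
  expect_true(all(r$subfamily_id == "SFS"))

  # permuting input row order changes nothing
  perm <- sample(nrow(means))
  r2 <- rank_candidates(s$calls, means[perm, ], s$asg, top_k = 4)
  expect_identical(as.data.frame(r), as.data.frame(r2))

  # removing a non-candidate gene changes nothing
  means3 <- means[means$gene != "g007", ]
  r3 <- rank_candidates(s$calls, means3, s$asg, top_k = 4)
  expect_identical(as.data.frame(r), as.data.frame(r3))

  # top_k larger than the pool returns the whole pool
  rall <- rank_candidates(s$calls, means, s$asg, top_k = 50)
  expect_equal(nrow(rall), 6)
  expect_error(rank_candidates(s$calls, means, s$asg, top_k = 0), "top_k")

  # no candidates -> empty ranking with a warning, not an error
  none <- two_class_setup(2, 2)
  none$calls$specific <- FALSE
  expect_warning(r0 <- rank_candidates(none$calls, means[1:4, ], none$asg),
                 "no clade-specific")
  expect_equal(nrow(r0), 0)
})

test_that("planted high-expression clade-specific genes top the shortlist", {
  b <- small_bundle()
  ex <- simulate_expression(b$truth, seed = 55)
  means <- group_mean_expression(ex)
  asg <- assignment_from_truth(b$truth)
  calls <- call_clade_specific(asg, b$design$ingroup_ids)
  r <- rank_candidates(calls, means, asg, top_k = 36)
  path <- b$truth$pathway_genes
  expect_setequal(r$gene[seq_along(path)], path)
})
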