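test_that("profile construction drops gap-majority columns and tracks counts", {
  aln <- c("AC-D", "AC-D", "AC-A", "A--D")  # column 3 is gap-majority
  prof <- build_profile(aln)
  expect_equal(prof$length, 3)
  expect_error(build_profile(c("AC", "ACD")), "ragged")
  expect_error(build_profile(c("AC1")), "non-amino-acid")

  single <- build_profile("ACD")
  expect_equal(single$consensus, "ACD")
  expect_equal(AA_ALPHABET[apply(single$scores, 2, which.max)],
               c("A", "C", "D"))
})

test_that("maximum attainable window score equals the per-column brute force", {
  prof <- build_profile(small_bundle()$seed_alignment)
  # independent oracle: enumerate residues per column
  best_by_column <- vapply(seq_len(prof$length), function(j) {
    max(vapply(seq_len(20), function(a) prof$scores[a, j], numeric(1)))
  }, numeric(1))
  expect_equal(profile_max_score(prof), sum(best_by_column))
  hit <- scan_sequence(prof, prof$consensus, search_config())
  expect_equal(hit$score, profile_max_score(prof), tolerance = 1e-9)
})

test_that("the consensus self-match reaches the E-value resolution floor", {
  cfg <- search_config()
  prof <- build_profile(small_bundle()$seed_alignment)
  hit <- scan_sequence(prof, prof$consensus, cfg)
  expect_lte(hit$e_value, 1 / cfg$n_shuffles)
  expect_equal(hit$start, 0)
  expect_equal(hit$end, prof$length)
})

test_that("planted domain genes outscore every decoy and E-values are monotone", {
  b <- small_bundle()
  prof <- build_profile(b$seed_alignment)
  cfg <- search_config()
  hits <- scan_proteome(prof, b$proteomes, cfg)
  tg <- b$truth$genes
  member_scores <- hits$score[hits$gene %in% tg$gene[tg$is_domain_bearing]]
  decoy_scores <- hits$score[hits$gene %in% tg$gene[!tg$is_domain_bearing]]
  expect_length(member_scores, sum(tg$is_domain_bearing))
  expect_gt(min(member_scores), max(decoy_scores))

  # monotone: higher score on the same-composition null implies lower E
  shuf <- paste(sample(strsplit(prof$consensus, "")[[1]]), collapse = "")
  h_cons <- scan_sequence(prof, prof$consensus, cfg)
  h_shuf <- scan_sequence(prof, shuf, cfg)
  expect_gt(h_cons$score, h_shuf$score)
  expect_lt(h_cons$e_value, h_shuf$e_value)
})

test_that("null E-values are reproduced under an independent shuffle seed", {
  b <- small_bundle()
  prof <- build_profile(b$seed_alignment)
  member <- b$truth$genes$gene[b$truth$genes$is_domain_bearing][1]
  seqs <- unlist(unname(b$proteomes))
  set.seed(1)
  null_copy <- paste(sample(strsplit(seqs[[member]], "")[[1]]), collapse = "")
  p1 <- scan_sequence(prof, null_copy, search_config(seed = 11))$e_value
  p2 <- scan_sequence(prof, null_copy, search_config(seed = 12))$e_value
  expect_gt(p1, 0); expect_lte(p1, 1)
  expect_gt(p2, 0); expect_lte(p2, 1)
  expect_lt(abs(p1 - p2), 0.25)  # Monte-Carlo error at 200 shuffles
})

test_that("the screen applies strict bounds and is idempotent", {
  cfg <- search_config()
  hits <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    species = "s",
    score = c(100, 100, 100, 100, 5),
    e_value = c(1e-12, 1e-12, 1e-10, 1e-12, 0.5),
    start = 0L, end = 10L,
    protein_length = c(400L, 350L, 400L, 650L, 400L))
  kept <- filter_hits(hits, cfg)
  expect_equal(kept$gene, "a")  # 350 and 650 excluded; e == e_max excluded
  expect_identical(filter_hits(kept, cfg), kept)
  empty <- hits[0, ]
  expect_equal(nrow(filter_hits(empty, cfg)), 0)
})

test_that("domtbl import skips comments, converts coordinates, flags bad rows", {
  row <- function(target, tlen, evalue, score, af, at) {
    paste(target, "-", tlen, "DOMAIN", "PF00000.1", 420, evalue, score, "0.1",
          1, 1, evalue, evalue, score, "0.1", 1, 420, af, at, af, at, "0.95",
          "description here")
  }
  path <- tempfile(fileext = ".domtbl")
  writeLines(c("# comment line",
               "#  another comment",
               row("spA|g0001", 400, "1.2e-50", "150.3", 10, 20),
               row("spB|g0002", 500, "3e-12", "88.1", 1, 400),
               row("plain_gene", 600, "0.5", "10.0", 5, 50)),
             path)
  hits <- read_domtbl(path)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$species[1], "spA")
  expect_equal(hits$gene[1], "g0001")
  expect_equal(hits$start[1], 9L)  # 1-based inclusive 10 -> 0-based 9
  expect_equal(hits$end[1], 20L)
  expect_equal(hits$e_value[2], 3e-12)
  expect_true(is.na(hits$species[3]))

  writeLines(c(row("spA|g1", 400, "1e-20", "99", 10, 20),
               row("spA|g2", 400, "not_a_number", "99", 10, 20)), path)
  expect_error(read_domtbl(path), "line 2")
})
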