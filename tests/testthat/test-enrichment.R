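make_meta <- function(conds) {
  do.call(rbind, lapply(names(conds), function(cond) {
    data.frame(sample_id = paste0(cond, "_", seq_len(conds[[cond]])),
               condition = cond, replicate = seq_len(conds[[cond]]),
               stringsAsFactors = FALSE)
  }))
}

# Build a count_matrix directly from a peptide x sample integer matrix.
cm_from_matrix <- function(mat, meta) {
  lst <- lapply(colnames(mat), function(s) {
    rep(rownames(mat), times = mat[, s])
  })
  names(lst) <- colnames(mat)
  build_count_matrix(lst, meta)
}

test_that("build_count_matrix counts multiplicities per sample", {
  meta <- data.frame(sample_id = c("s1", "s2"), condition = "R0",
                     replicate = 1:2)
  cm <- build_count_matrix(list(s1 = c("PEPTIDE", "PEPTIDE", "QWERTY"),
                                s2 = c("QWERTY")), meta)
  expect_equal(cm$counts["PEPTIDE", ], c(s1 = 2L, s2 = 0L))
  expect_equal(cm$counts["QWERTY", ], c(s1 = 1L, s2 = 1L))

  expect_message(
    cm0 <- build_count_matrix(list(s1 = c("PEPTIDE"), s2 = character(0)),
                              meta),
    "zero column")
  expect_equal(sum(cm0$counts[, "s2"]), 0)

  bad_meta <- data.frame(sample_id = c("s1", "s1"), condition = "R0",
                         replicate = 1:2)
  expect_error(build_count_matrix(list(s1 = "PEPTIDE"), bad_meta),
               "duplicate sample_id")
  expect_error(build_count_matrix(list(sX = "PEPTIDE"), meta),
               "not in sample sheet")
})

test_that("ppm normalization scales each column to one million", {
  m <- matrix(c(2, 1, 1, 4, 4, 8), ncol = 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  ppm <- normalize_ppm(m)
  expect_equal(ppm[, "s1"], c(A = 5e5, B = 2.5e5, C = 2.5e5))
  expect_equal(unname(colSums(ppm)), rep(1e6, 2))

  m0 <- cbind(m, s3 = c(0, 0, 0))
  expect_error(normalize_ppm(m0), "s3")
})

test_that("one-tailed Welch test matches t.test and its symmetries", {
  # degenerate: identical constant groups
  expect_equal(welch_t_one_tailed(c(5, 5, 5), c(5, 5, 5)),
               c(t = 0, p = 0.5))
  # textbook case against the stats::t.test oracle
  res <- welch_t_one_tailed(c(10, 11, 12), c(1, 2, 3))
  oracle <- t.test(c(10, 11, 12), c(1, 2, 3), alternative = "greater",
                   var.equal = FALSE)
  expect_equal(unname(res["t"]), unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(unname(res["p"]), oracle$p.value, tolerance = 1e-12)
  # random cases
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), mean = runif(1, 0, 5))
    b <- rnorm(sample(2:6, 1), mean = runif(1, 0, 5))
    res <- welch_t_one_tailed(a, b)
    oracle <- t.test(a, b, alternative = "greater", var.equal = FALSE)
    expect_equal(unname(res["p"]), oracle$p.value, tolerance = 1e-10)
    # one-tailed symmetry
    swapped <- welch_t_one_tailed(b, a)
    expect_equal(unname(swapped["t"]), -unname(res["t"]), tolerance = 1e-10)
    expect_equal(unname(swapped["p"]), 1 - unname(res["p"]),
                 tolerance = 1e-10)
  }
  expect_error(welch_t_one_tailed(1, c(1, 2)), "replicates")
})

test_that("call_enriched applies the ratio and p-value criterion per control", {
  meta <- make_meta(c(R2_target = 6, R0 = 3, R2_beads = 3))
  peps <- c("AAAAA", "CCCCC", "DDDDD")
  # AAAAA: strongly target-enriched; CCCCC flat; DDDDD control-enriched
  mat <- rbind(
    AAAAA = c(rep(100, 6), rep(1, 6)),
    CCCCC = c(rep(50, 6), rep(50, 6)),
    DDDDD = c(rep(10, 6), rep(60, 6))
  )
  colnames(mat) <- meta$sample_id
  cm <- cm_from_matrix(mat, meta)
  res <- call_enriched(cm, "R2_target", c("R0", "R2_beads"))
  res <- res[match(peps, res$peptide), ]
  expect_true(res$is_hit[1])
  expect_false(res$is_hit[2])   # ratio ~1 everywhere
  expect_false(res$is_hit[3])   # depleted in target
  expect_true(all(res$ratio_R0[1] >= 2, res$p_R0[1] <= 0.05))

  expect_error(call_enriched(cm, "R2_unrelated", "R0"), "absent")
})

test_that("high replicate variance blocks hits despite a large ratio", {
  meta <- make_meta(c(R2_target = 6, R0 = 3))
  # one dominant replicate: mean ratio is high but Welch p is weak
  mat <- rbind(SPIKE = c(600, 1, 1, 1, 1, 1, rep(1, 3)),
               FILL = c(rep(1000, 6), rep(1000, 3)))
  colnames(mat) <- meta$sample_id
  cm <- cm_from_matrix(mat, meta)
  res <- call_enriched(cm, "R2_target", "R0")
  row <- res[res$peptide == "SPIKE", ]
  expect_gt(row$ratio_R0, 2)
  expect_gt(row$p_R0, 0.05)
  expect_false(row$is_hit)
})

test_that("hit calls are invariant under uniform scaling of a sample", {
  meta <- make_meta(c(R2_target = 3, R0 = 3))
  set.seed(9)
  mat <- matrix(rpois(60, 20), nrow = 10,
                dimnames = list(rand_peptides(10, seed = 2), meta$sample_id))
  cm1 <- cm_from_matrix(mat, meta)
  mat2 <- mat
  mat2[, 1] <- mat2[, 1] * 7L   # uniform rescale of one sample
  cm2 <- cm_from_matrix(mat2, meta)
  r1 <- call_enriched(cm1, "R2_target", "R0")
  r2 <- call_enriched(cm2, "R2_target", "R0")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("pooled control mode tests one combined group", {
  meta <- make_meta(c(R2_target = 3, R0 = 2, R2_beads = 2))
  mat <- rbind(HIT = c(90, 100, 110, 1, 1, 1, 1))
  colnames(mat) <- meta$sample_id
  cm <- cm_from_matrix(mat, meta)
  res <- call_enriched(cm, "R2_target", c("R0", "R2_beads"),
                       control_mode = "pooled")
  expect_named(res, c("peptide", "ratio_pooled", "p_pooled", "is_hit"))
})

test_that("BLOSUM62 clustering groups similar motifs and splits distant ones", {
  # two identical peptides always co-cluster below n clusters
  hits <- c("WWWWWWWW", "WWWWWWWW", "AAAAAAAA", "DDDDDDDD", "KKKKKKKK")
  for (k in 1:4) {
    cl <- cluster_hits(hits, k)
    expect_equal(cl[[1]], cl[[2]])
  }
  # n_clusters = n puts each distinct profile in its own cluster
  distinct <- c("WWWWWWWW", "AAAAAAAA", "DDDDDDDD", "KKKKKKKK")
  expect_equal(length(unique(cluster_hits(distinct, 4))), 4)

  # two Hamming-distant motif families split perfectly at k = 2
  fam_a <- c("WYFWYFWYFWYF", "WYFWYFWYFWYL", "WYFWYFWYFWYV")
  fam_b <- c("DEKDEKDEKDEK", "DEKDEKDEKDER", "DEKDEKDEKDEH")
  cl <- cluster_hits(c(fam_a, fam_b), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)
  expect_true(cl[[1]] != cl[[4]])

  expect_error(cluster_hits(c("AAAA", "AAAAA"), 2), "equal length")
})
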