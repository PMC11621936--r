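seg <- function(chrom, start, end, cn) {
  data.frame(chrom = chrom, start = start, end = end, copy_number = cn)
}

test_that("delta CNV subtracts parental from resistant position-wise", {
  a <- seg("chr1", c(1, 101, 201), c(100, 200, 300), c(2, 1, 3))
  expect_true(all(delta_cnv(a, a)$delta == 0))

  par <- seg("chr1", 1, 300, 2)
  res <- seg("chr1", c(1, 100, 201), c(99, 200, 300), c(2, 1, 2))
  d <- delta_cnv(res, par)
  expect_equal(d$delta[d$start <= 99], 0)
  in_loss <- d$start >= 100 & d$end <= 200
  expect_true(all(d$delta[in_loss] == -1))
  expect_equal(attr(d, "argmin")$start, 100)
})

test_that("delta CNV is antisymmetric and imputes missing chromosomes", {
  set.seed(70)
  for (i in 1:15) {
    n <- sample(2:6, 1)
    brk <- sort(sample(1:500, n))
    mk <- function() seg("chr1", c(1, brk + 1), c(brk, 600),
                         sample(0:4, n + 1, replace = TRUE))
    a <- mk(); b <- mk()
    ab <- delta_cnv(a, b); ba <- delta_cnv(b, a)
    expect_equal(ab$delta, -ba$delta)
  }
  extra <- rbind(seg("chr1", 1, 100, 2), seg("chr2", 1, 50, 4))
  base <- seg("chr1", 1, 100, 2)
  expect_warning(d <- delta_cnv(extra, base), "chr2")
  expect_equal(d$delta[d$chrom == "chr2"], 2)  # 4 - imputed diploid 2
})

test_that("CNV locus counting merges adjacent qualifying segments", {
  all2 <- seg("chr1", c(1, 101), c(100, 200), c(2, 2))
  expect_equal(count_cnv_loci(all2), list(n_loss = 0L, n_gain = 0L))

  # copies {2, 1, 1 adjacent, 3, 0}: adjacent losses merge -> 2 losses, 1 gain
  pr <- seg("chr1", c(1, 101, 201, 301, 401),
            c(100, 200, 300, 400, 500), c(2, 1, 1, 3, 0))
  expect_equal(count_cnv_loci(pr), list(n_loss = 2L, n_gain = 1L))

  # splitting a segment into two adjacent halves changes nothing
  split_pr <- seg("chr1", c(1, 101, 151, 201, 301, 401),
                  c(100, 150, 200, 300, 400, 500), c(2, 1, 1, 1, 3, 0))
  expect_equal(count_cnv_loci(split_pr), count_cnv_loci(pr))

  # non-adjacent qualifying segments stay separate loci
  gap <- seg("chr1", c(1, 200), c(100, 300), c(1, 1))
  expect_equal(count_cnv_loci(gap)$n_loss, 2L)
})

test_that("generated profiles report their planted loss counts", {
  sim <- gen_cnv_profiles(4, 300,
                          planted_region = list(start = 41, end = 90),
                          group_labels = c(TRUE, TRUE, FALSE, FALSE),
                          background_rate = 0, seed = 3)
  for (cl in names(sim$profiles)) {
    ct <- count_cnv_loci(sim$profiles[[cl]])
    expect_equal(ct$n_loss, if (sim$truth$group[[cl]]) 1L else 0L)
    expect_equal(ct$n_gain, 0L)
  }
})

test_that("shared-loss Fisher tests flag group-confined losses", {
  sim <- gen_cnv_profiles(8, 200,
                          planted_region = list(start = 51, end = 100),
                          group_labels = c(rep(TRUE, 5), rep(FALSE, 3)),
                          background_rate = 0, seed = 9)
  genes <- data.frame(gene = sprintf("g%d", 1:4), chrom = "chr1",
                      start = c(1, 51, 76, 151), end = c(50, 75, 100, 200))
  lm <- shared_loss_matrix(sim$profiles, genes)
  expect_equal(dim(lm), c(4L, 8L))
  expect_true(all(lm[c("g2", "g3"), 1:5] == 1))
  expect_true(all(lm[c("g1", "g4"), ] == 0))

  res <- shared_loss_test(lm, sim$truth$group)
  # loss in all 5 of the group, none of the other 3: [[5,0],[0,3]]
  expect_equal(res$p[res$gene %in% c("g2", "g3")],
               rep(1 / choose(8, 5), 2), tolerance = 1e-12)
  expect_equal(res$p[res$gene %in% c("g1", "g4")], rep(1, 2))
  # only planted genes attain the minimum attainable p
  expect_setequal(res$gene[res$p == min(res$p)], c("g2", "g3"))
})

test_that("a proportional loss pattern is Fisher-null", {
  lm <- rbind(g1 = c(1, 1, 0, 0, 1, 1, 0, 0))
  groups <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(shared_loss_test(lm, groups)$p, 1)
})

test_that("group count comparison is an exact Mann-Whitney test", {
  expect_equal(compare_group_counts(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(compare_group_counts(c(2, 2, 5), c(2, 2, 5))$p, 1)
  set.seed(71)
  for (i in 1:20) {
    a <- rpois(sample(2:6, 1), 3); b <- rpois(sample(2:6, 1), 5)
    expect_equal(compare_group_counts(a, b)$p, mwu_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("a planted 3-fold loss burden is recovered", {
  sens <- gen_cnv_profiles(5, 1000,
                           planted_region = list(start = 1, end = 2),
                           group_labels = rep(FALSE, 5),
                           background_rate = 0.06, seed = 21)$profiles
  res <- gen_cnv_profiles(3, 1000,
                          planted_region = list(start = 1, end = 2),
                          group_labels = rep(FALSE, 3),
                          background_rate = 0.02, seed = 22)$profiles
  loss_of <- function(p) count_cnv_loci(p)$n_loss
  ratio <- mean(vapply(sens, loss_of, numeric(1))) /
    mean(vapply(res, loss_of, numeric(1)))
  expect_gt(ratio, 3 * 0.8)
  expect_lt(ratio, 3 * 1.25)
})

test_that("gene copy number correlates with AUC as planted", {
  expect_equal(gene_cn_vs_auc(c(1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4))$r, 1)
  expect_error(gene_cn_vs_auc(c(2, 2, 2), c(0.1, 0.2, 0.3)), "constant")
  hits <- 0L
  for (s in 1:100) {
    set.seed(3000 + s)
    cn <- sample(0:4, 20, replace = TRUE)
    auc <- 0.8 - 0.5 * cn / 4 + rnorm(20, 0, 0.1)
    if (gene_cn_vs_auc(cn, auc)$r < -0.8) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
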