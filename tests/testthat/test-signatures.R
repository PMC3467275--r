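test_that("rod screen applies the de novo rule arithmetic", {
  b <- 10
  th <- signature_thresholds()
  rod <- signature_matrix(c(1, 1, 4, 8), c(0, 0, 0, 0), b)
  expect_true(rod_signature_screen(rod, b, thresholds = th)[["g1"]])
  # constant strong activating mark fails the de novo (early-absence) rule
  ubiq <- signature_matrix(c(8, 8, 8, 8), c(0, 0, 0, 0), b)
  expect_false(rod_signature_screen(ubiq, b, thresholds = th)[["g1"]])
  # high repressive mark fails the K27-absence rule
  nonrod <- signature_matrix(c(1, 1, 4, 8), c(6, 6, 6, 6), b)
  expect_false(rod_signature_screen(nonrod, b, thresholds = th)[["g1"]])
  # late level below the activation floor fails
  weak <- signature_matrix(c(1, 1, 1.5, 2), c(0, 0, 0, 0), b)
  expect_false(rod_signature_screen(weak, b, thresholds = th)[["g1"]])
  # gene-body requirement: body without the gain vetoes the flag
  flatbody <- signature_matrix(c(1, 1, 1, 1), c(0, 0, 0, 0), b)
  expect_false(rod_signature_screen(rod, b, body_mat = flatbody,
                                    thresholds = th, use_body = TRUE)[["g1"]])
  expect_true(rod_signature_screen(rod, b, body_mat = rod,
                                   thresholds = th, use_body = TRUE)[["g1"]])
})

test_that("signature labels follow the precedence rules", {
  b <- 10
  mats <- rbind(
    signature_matrix(c(0, 0, 0, 0), c(0, 0, 0, 0), b, genes = "silent"),
    signature_matrix(c(1, 1, 4, 8), c(0.5, 0.5, 0.5, 0.5), b, genes = "rod"),
    signature_matrix(c(1.5, 1.5, 1.5, 1.5), c(6, 6, 6, 6), b, genes = "nonrod"),
    signature_matrix(c(8, 8, 8, 8), c(0.5, 0.5, 0.5, 0.5), b, genes = "ubiq"),
    signature_matrix(c(8, 6, 2, 1), c(1, 2, 3, 5), b, genes = "down"))
  labels <- classify_signatures(mats, b)
  expect_equal(as.character(labels$label),
               c("NO_MARK", "ROD_SPECIFIC", "NONROD_RETINAL", "UBIQUITOUS",
                 "OTHER"))
  expect_equal(labels$gene, rownames(mats))
  # exactly one label per gene, always defined
  expect_false(anyNA(labels$label))
})

test_that("pooled t-test matches the textbook closed form", {
  tt <- pooled_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-6)
  expect_equal(tt$stars, "ns")

  same <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(pooled_t_test(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(pooled_t_test(1, c(1, 2)), ">= 2")

  # dual route: agree with stats::t.test(var.equal = TRUE) on random data
  set.seed(8)
  for (i in 1:5) {
    x <- stats::rnorm(sample(3:20, 1), mean = stats::runif(1, 0, 5))
    y <- stats::rnorm(sample(3:20, 1), mean = stats::runif(1, 0, 5))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    mine <- pooled_t_test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("star annotation bands match the reporting convention", {
  expect_equal(p_stars(c(0.5, 0.03, 0.005, 5e-4)),
               c("ns", "*", "**", "***"))
})

test_that("average-linkage clustering reproduces hand-computed merges", {
  # two identical rows merge first at height zero
  x <- rbind(a = c(1, 2), b = c(1, 2), c = c(10, 12))
  cl <- hierarchical_cluster(x)
  expect_equal(cl$hclust$height[1], 0)

  # distances {d12=1, d13=10, d23=10}: first merge (1,2), final height 10
  d <- structure(c(1, 10, 10), Size = 3L, Diag = FALSE, Upper = FALSE,
                 class = "dist")
  cl2 <- hierarchical_cluster(d)
  expect_equal(cl2$hclust$height, c(1, 10))

  expect_error(hierarchical_cluster(x[1, , drop = FALSE]), ">= 2 rows")
})

test_that("uncentered correlation distance handles zero rows", {
  x <- rbind(a = c(1, 1, 1, 1), b = c(2, 2, 2, 2), c = c(0, 0, 0, 0))
  d <- as.matrix(uncentered_cor_dist(x))
  expect_equal(d["a", "b"], 0)       # proportional rows are identical
  expect_equal(d["a", "c"], 1)       # zero-variance row: distance 1
  expect_equal(d["b", "c"], 1)
})

test_that("clustering recovers planted profile archetypes", {
  set.seed(15)
  arch <- rbind(c(1, 1, 5, 9, 0, 0, 0, 0),    # late activation, no repression
                c(1, 1, 1, 1, 6, 6, 6, 6),    # repressed throughout
                c(8, 8, 8, 8, 0, 0, 0, 0),    # constant activation
                c(8, 6, 2, 0, 0, 1, 2, 4))    # decaying activation
  truth <- rep(1:4, each = 25)
  mat <- arch[truth, ] + matrix(stats::rnorm(100 * 8, 0, 0.5), 100)
  cl <- hierarchical_cluster(mat, k = 4)
  expect_gte(rand_index(cl$clusters, truth), 0.9)
})

test_that("promoter-vs-body comparison runs per mark and stage", {
  d <- default_dataset()
  rod <- d$truth$gene[d$truth$class == "ROD"]
  down <- d$truth$gene[d$truth$class == "DOWN"]
  res_rod <- compare_promoter_body(d$occ$wt_promoter, d$occ$wt_body, rod)
  expect_equal(nrow(res_rod), 8)
  expect_true(all(c("mark", "stage", "p", "stars") %in% names(res_rod)))
  # rod genes: body planted equal to promoter, so late stages stay ns
  late_k4 <- res_rod$p[res_rod$mark == "H3K4me2" & res_rod$stage == "PN15"]
  expect_gt(late_k4, 0.05)
  # down genes carry TSS-confined repressive mark at PN15: promoter >> body
  res_down <- compare_promoter_body(d$occ$wt_promoter, d$occ$wt_body, down)
  k27_late <- res_down[res_down$mark == "H3K27me3" & res_down$stage == "PN15", ]
  expect_lt(k27_late$p, 0.05)
  expect_gt(k27_late$mean_promoter, k27_late$mean_body)
  expect_error(compare_promoter_body(d$occ$wt_promoter, d$occ$wt_body,
                                     rod[1]), ">= 2")
})

test_that("genotype comparison reports folds and flags degenerate cases", {
  mat <- signature_matrix(c(4, 4, 4, 4), c(1, 1, 1, 1), b = 10,
                          genes = c("g1", "g2", "g3"))
  mat <- mat + matrix(seq(0, 2.3, 0.1), 3)  # give genes distinct levels
  same <- compare_genotypes(mat, mat)
  expect_equal(same$fold, 1)
  expect_equal(same$test$p, 1)

  zero <- compare_genotypes(mat, mat * 0)
  expect_true(is.infinite(zero$fold))
  expect_true(zero$infinite_fold)
})
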