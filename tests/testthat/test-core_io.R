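test_that("count table reader enforces invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tA\tB", "o1\t1\t2", "o2\t0\t3", "o3\t4\t0"), f)
  t <- read_count_table(f)
  expect_s3_class(t, "count_table")
  expect_equal(dim(t), c(3L, 2L))

  writeLines(c("otu_id\tA\tB", "o1\t0\t2", "o2\t0\t3"), f)
  expect_error(read_count_table(f), "empty sample column: A")

  writeLines(c("otu_id\tA\tB", "o1\t1\t2", "o1\t4\t1"), f)
  expect_error(read_count_table(f), "o1")

  writeLines(c("otu_id\tA\tB", "o1\t-1\t2", "o2\t4\t1"), f)
  expect_error(read_count_table(f), "non-negative")

  writeLines(c("# Constructed from biom file", "#OTU ID\tA\tB",
               "o1\t1\t2", "o2\t4\t1"), f)
  expect_equal(dim(read_count_table(f, "biom_tsv")), c(2L, 2L))
})

test_that("CSS normalization follows the cumulative-sum formula", {
  m <- matrix(c(1, 2, 3, 4, 100), ncol = 1,
              dimnames = list(paste0("o", 1:5), "s1"))
  v <- css_normalize(count_table(m, allow_zero_samples = TRUE))
  # nonzero median 3 -> s = 1 + 2 + 3 = 6; count 3 maps to log2(501)
  expect_equal(unname(v["o3", 1]), log2(3 / 6 * 1000 + 1))
  expect_equal(unname(v["o1", 1]), log2(1 / 6 * 1000 + 1))

  # identical columns give identical output columns
  t2 <- count_table(cbind(a = c(5, 1, 9), b = c(5, 1, 9)) |>
                      `rownames<-`(paste0("o", 1:3)))
  v2 <- css_normalize(t2)
  expect_equal(unname(v2[, 1]), unname(v2[, 2]))

  # independent two-line direct computation on a random table
  t3 <- toy_counts(20, 10, seed = 42)
  v3 <- css_normalize(t3)
  s <- apply(unclass(t3), 2, function(x)
    sum(x[x <= quantile(x[x > 0], 0.5)]))
  expect_equal(unclass(v3), log2(sweep(unclass(t3), 2, s, "/") * 1000 + 1),
               ignore_attr = TRUE)

  # q = 1 reduces to total-sum scaling
  v4 <- css_normalize(t3, q = 1, log2_plus1 = FALSE)
  expect_equal(unclass(v4),
               sweep(unclass(t3), 2, colSums(t3), "/") * 1000,
               ignore_attr = TRUE)
})

test_that("relative-abundance and CLR transforms", {
  m <- matrix(c(2, 2, 4), ncol = 1, dimnames = list(paste0("o", 1:3), "s"))
  expect_equal(unname(transform_abundance(count_table(m), "relative_abundance")[, 1]),
               c(0.25, 0.25, 0.5))
  m1 <- matrix(1, 4, 1, dimnames = list(paste0("o", 1:4), "s"))
  expect_equal(unname(transform_abundance(count_table(m1), "CLR")[, 1]),
               rep(0, 4))
  t <- toy_counts(15, 8, seed = 3)
  clr <- transform_abundance(t, "CLR")
  expect_true(all(abs(colSums(clr)) < 1e-9))
  expect_error(transform_abundance(t, "CLR", pseudocount = 0), "positive")
})

test_that("dissimilarity toy values and invariants", {
  m <- cbind(u = c(2, 2, 0), v = c(0, 2, 2))
  rownames(m) <- paste0("o", 1:3)
  d <- dissimilarity(count_table(m), "bray_curtis")
  expect_equal(unname(d["u", "v"]), 0.5)

  mj <- cbind(A = c(1, 1, 0), B = c(0, 1, 1))
  rownames(mj) <- paste0("o", 1:3)
  dj <- dissimilarity(count_table(mj), "jaccard")
  expect_equal(unname(dj["A", "B"]), 1 - 1 / 3)

  ident <- cbind(a = c(3, 1), b = c(3, 1))
  rownames(ident) <- c("o1", "o2")
  for (met in c("bray_curtis", "jaccard"))
    expect_equal(unname(dissimilarity(count_table(ident), met)["a", "b"]), 0)

  # property: symmetry, zero diagonal, range on random tables
  for (s in 1:5) {
    t <- toy_counts(12, 7, seed = s)
    for (met in c("bray_curtis", "jaccard")) {
      d <- dissimilarity(t, met)
      expect_true(all(abs(d - t(unclass(d))) < 1e-12))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0 & d <= 1))
    }
  }

  # all-zero pair defined as 0 with a warning
  mz <- cbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  rownames(mz) <- c("o1", "o2")
  expect_warning(dz <- dissimilarity(count_table(mz, allow_zero_samples = TRUE),
                                     "bray_curtis"), "all-zero")
  expect_equal(unname(dz["a", "b"]), 0)
})

test_that("PCoA recovers planar configurations and reports eigenvalues", {
  pts <- cbind(c(0, 3, 1, 5, 2.5), c(0, 0, 4, 3, -2))
  rownames(pts) <- paste0("p", 1:5)
  dm <- as.matrix(dist(pts)) / 10          # scale into [0, 1]
  d <- dist_matrix(dm, "bray_curtis")
  p <- pcoa(d, k = 2)
  pro <- vegan::procrustes(pts / 10, p$coordinates, symmetric = FALSE)
  expect_lt(pro$ss, 1e-8)
  # eigenvalue sum equals trace of the centered matrix
  a <- -0.5 * dm^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  expect_equal(sum(p$eigenvalues), sum(diag(g)), tolerance = 1e-9)

  # all-equal points -> all eigenvalues 0
  d0 <- dist_matrix(matrix(0.5, 4, 4,
                           dimnames = list(letters[1:4], letters[1:4])) -
                      diag(0.5, 4), "bray_curtis")
  d00 <- dist_matrix(matrix(0, 4, 4,
                            dimnames = list(letters[1:4], letters[1:4])),
                     "bray_curtis")
  expect_true(all(abs(pcoa(d00, 2)$eigenvalues) < 1e-12))
  expect_error(pcoa(d0, k = 4), "n - 1")
})

test_that("PERMANOVA separates disjoint groups and matches adonis2", {
  set.seed(10)
  m <- cbind(matrix(rpois(24, 10), 4) + 1, matrix(0, 4, 6))
  m <- rbind(m, cbind(matrix(0, 4, 6), matrix(rpois(24, 10), 4) + 1))
  rownames(m) <- paste0("o", 1:8)
  colnames(m) <- paste0("s", 1:12)
  d <- dissimilarity(count_table(m), "bray_curtis")
  r <- permanova(d, rep(c("a", "b"), each = 6), n_perm = 99, seed = 1)
  expect_gt(r$R2, 0.9)
  expect_equal(r$p_value, 1 / (1 + 99))
  expect_true(r$R2 >= 0 && r$R2 <= 1)

  # cross-check statistic and R2 against vegan::adonis2
  t <- toy_counts(15, 12, seed = 8)
  grp <- rep(c("x", "y", "z"), each = 4)
  d2 <- dissimilarity(t, "bray_curtis")
  ours <- permanova(d2, grp, n_perm = 199, seed = 2)
  ad <- vegan::adonis2(as.dist(unclass(d2)) ~ grp,
                       permutations = 199)
  expect_equal(ours$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ad$R2[1], tolerance = 1e-10)

  expect_error(permanova(d2, rep("x", 12)), "two groups")
})

test_that("Kruskal-Wallis/Dunn detects separation and matches the rank formula", {
  r <- kruskal_dunn(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
  expect_lt(r$pairs$q[1], 0.05)
  expect_false(r$letters[["a"]] == r$letters[["b"]])

  # identical groups: no letter separation
  r2 <- kruskal_dunn(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_true(any(strsplit(r2$letters[["a"]], "")[[1]] %in%
                    strsplit(r2$letters[["b"]], "")[[1]]))

  # H matches the hand-computed tie-free formula on 3 small groups
  v <- c(2.1, 3.5, 1.2, 6.3, 5.5, 7.1, 9.9, 8.4, 10.2)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  rk <- rank(v); n <- length(v)
  hand <- 12 / (n * (n + 1)) * sum(tapply(rk, g, function(x)
    length(x) * mean(x)^2)) - 3 * (n + 1)
  expect_equal(kruskal_dunn(v, g)$H, hand, tolerance = 1e-10)

  # constant data
  rc <- kruskal_dunn(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(rc$H, 0)
  expect_equal(rc$p_value, 1)

  # BH q-values never below p
  expect_true(all(r$pairs$q >= r$pairs$p - 1e-12))
})

test_that("taxa aggregation pools below-threshold groups into other", {
  m <- rbind(o1 = c(40, 40), o2 = c(40, 40), o3 = c(19, 19), o4 = c(1, 1))
  colnames(m) <- c("s1", "s2")
  tax <- taxonomy_table(data.frame(
    otu_id = paste0("o", 1:4), kingdom = "Bacteria",
    genus = c("g1", "g1", "g2", "g3")))
  ag <- aggregate_taxa(count_table(m), tax, "genus", min_mean_ra = 0.005)
  # same-genus OTUs merge to their sum
  expect_equal(unname(ag["g1", "s1"]), 0.8)
  # g3 at 1% stays; columns sum to 1
  expect_true("g3" %in% rownames(ag))
  expect_true(all(abs(colSums(ag) - 1) < 1e-9))

  # a taxon at exactly the threshold is retained (strict <)
  m2 <- rbind(o1 = c(995, 995), o2 = c(5, 5))
  colnames(m2) <- c("s1", "s2")
  tax2 <- taxonomy_table(data.frame(otu_id = c("o1", "o2"),
                                    kingdom = "Bacteria",
                                    genus = c("big", "edge")))
  ag2 <- aggregate_taxa(count_table(m2), tax2, "genus", min_mean_ra = 0.005)
  expect_true("edge" %in% rownames(ag2))
  expect_error(aggregate_taxa(count_table(m2), tax2, "species"), "unknown rank")
})
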