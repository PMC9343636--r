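test_that("network construction applies the double threshold strictly", {
  ids <- paste0("o", 1:4)
  rho <- matrix(0, 4, 4, dimnames = list(ids, ids))
  q <- matrix(1, 4, 4, dimnames = list(ids, ids))
  rho[1, 2] <- rho[2, 1] <- 0.3     # exactly at the threshold: excluded
  q[1, 2] <- q[2, 1] <- 0.001
  rho[1, 3] <- rho[3, 1] <- -0.31   # passes both rules
  q[1, 3] <- q[3, 1] <- 0.04
  rho[2, 4] <- rho[4, 2] <- 0.9     # fails the FDR rule
  q[2, 4] <- q[4, 2] <- 0.2
  n <- build_network(rho, q)
  expect_equal(nrow(n$edges), 1)
  expect_equal(n$edges$sign, "neg")
  expect_setequal(n$nodes$otu_id, c("o1", "o3"))

  # fdr = 1, r = 0 with all-nonzero rho gives the complete graph
  rho2 <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(rho2) <- 1
  n2 <- build_network(rho2, q, r_threshold = 0, fdr = 1.01)
  expect_equal(nrow(n2$edges), choose(4, 2))
})

test_that("complexity indices match closed forms and add over components", {
  path3 <- toy_network(cbind(c("a", "b"), c("b", "c")))
  gs <- graph_stats(path3)
  expect_equal(gs$abc, 2 * sqrt(1 / 2), tolerance = 1e-10)
  expect_equal(gs$ga, 2 * (2 * sqrt(2) / 3), tolerance = 1e-10)

  k4 <- t(combn(paste0("k", 1:4), 2))
  gk <- graph_stats(toy_network(k4))
  expect_equal(gk$ga, 6, tolerance = 1e-12)
  expect_equal(gk$bertz, 2 * 6 * log2(12) - 4 * 3 * log2(3))

  # additivity over disjoint components
  both <- toy_network(rbind(cbind(c("a", "b"), c("b", "c")), k4))
  gb <- graph_stats(both)
  expect_equal(gb$abc, gs$abc + gk$abc, tolerance = 1e-10)
  expect_equal(gb$ga, gs$ga + gk$ga, tolerance = 1e-10)
})

test_that("betweenness matches a brute-force shortest-path count", {
  edges <- cbind(c("a", "a", "b", "c", "d", "d"),
                 c("b", "c", "c", "d", "e", "f"))
  net <- toy_network(edges)
  gs <- graph_stats(net)
  # brute force over all simple paths between each ordered pair
  ids <- net$nodes$otu_id
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- TRUE
    adj[edges[r, 2], edges[r, 1]] <- TRUE
  }
  all_paths <- function(from, to, visited = from) {
    if (from == to) return(list(visited))
    out <- list()
    for (nb in ids[adj[from, ]]) if (!nb %in% visited)
      out <- c(out, all_paths(nb, to, c(visited, nb)))
    out
  }
  btw <- setNames(numeric(length(ids)), ids)
  for (s in ids) for (t in ids) if (s < t) {
    paths <- all_paths(s, t)
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) for (v in setdiff(p, c(s, t)))
      btw[v] <- btw[v] + 1 / length(shortest)
  }
  expect_equal(setNames(gs$nodes$betweenness, gs$nodes$otu_id), btw[gs$nodes$otu_id])
})

test_that("hub set is the ten highest-degree nodes with lexicographic ties", {
  set.seed(1)
  star_edges <- cbind("hub", paste0("leaf", sprintf("%02d", 1:12)))
  net <- toy_network(star_edges)
  gs <- graph_stats(net)
  expect_equal(length(gs$hubs), 10)
  expect_equal(gs$hubs[1], "hub")
  # ties at degree 1 broken by otu_id order
  expect_equal(gs$hubs[-1], paste0("leaf", sprintf("%02d", 1:9)))
})

test_that("meta-network merge keeps provenance counts and mean rho", {
  n1 <- toy_network(cbind(c("a", "b"), c("b", "c"), c(0.5, 0.4)),
                    context = list(compartment = "Se", age = 76))
  n2 <- toy_network(cbind(c("a", "x"), c("b", "y"), c(0.7, -0.6)),
                    context = list(compartment = "S1", age = 90))
  mm <- merge_meta(list(n1, n2))
  expect_equal(nrow(mm$edges), 3)               # a-b shared, b-c, x-y
  ab <- mm$edges[mm$edges$otu_a == "a" & mm$edges$otu_b == "b", ]
  expect_equal(ab$n_contexts, 2)
  expect_equal(ab$rho, 0.6)
  # disjoint networks sum their edge counts
  n3 <- toy_network(cbind("p", "q"), context = list(compartment = "BS",
                                                    age = 48))
  expect_equal(nrow(merge_meta(list(n2, n3))$edges), 3)
  # identical networks: unchanged edges, provenance length 2
  mm2 <- merge_meta(list(n1, n1))
  expect_equal(nrow(mm2$edges), nrow(n1$edges))
  expect_true(all(mm2$edges$n_contexts == 2))
})

test_that("module detection separates joined cliques", {
  cl1 <- t(combn(paste0("a", 1:5), 2))
  cl2 <- t(combn(paste0("b", 1:5), 2))
  net <- toy_network(rbind(cl1, cl2, c("a1", "b1")))
  mm <- merge_meta(list(net))
  md <- detect_modules(mm, seed = 1)
  memb <- md$membership
  expect_equal(length(unique(memb[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:5)])), 1)
  expect_false(memb[["a1"]] == memb[["b1"]])
  expect_gte(md$modularity, 0)
})

test_that("edge-set Jaccard matches direct set arithmetic", {
  nA <- toy_network(cbind(c("a", "b", "c"), c("b", "c", "d")))
  nB <- toy_network(cbind(c("b", "c", "d"), c("c", "d", "e")))
  ej <- edge_jaccard(list(A = nA, B = nB), display_threshold = 0.02)
  expect_equal(ej$J["A", "B"], 2 / 4)
  expect_equal(ej$similarity_edges$jaccard, 0.5)
  # identical and disjoint
  expect_equal(edge_jaccard(list(x = nA, y = nA))$J["x", "y"], 1)
  nC <- toy_network(cbind("p", "q"))
  expect_equal(edge_jaccard(list(x = nA, y = nC))$J["x", "y"], 0)
})

test_that("hypergeometric enrichment equals brute-force tail enumeration", {
  tax <- taxonomy_table(data.frame(
    otu_id = paste0("o", 1:12),
    kingdom = rep(c("Bacteria", "Fungi"), each = 6),
    class = rep(c("c1", "c2", "c3", "c4"), each = 3)))
  set.seed(7)
  for (rep in 1:20) {
    n_edge <- sample(3:12, 1)
    pairs <- t(replicate(n_edge, sample(paste0("o", 1:12), 2)))
    pairs <- pairs[!duplicated(t(apply(pairs, 1, sort))), , drop = FALSE]
    net <- toy_network(pairs)
    enr <- class_enrichment(net, tax, "class")
    lab <- seedtrans:::node_labels(net, tax, "class")
    ea <- lab[net$edges$otu_a]; eb <- lab[net$edges$otu_b]
    for (r in seq_len(nrow(enr))) {
      A <- enr$class_a[r]; B <- enr$class_b[r]
      k <- if (A == B) sum(ea == A & eb == A) else
        sum((ea == A & eb == B) | (ea == B & eb == A))
      nd <- sum(ea == A | eb == A)
      ns <- sum(ea == B | eb == B)
      expect_equal(enr$p[r],
                   hyper_tail_bruteforce(k, ns, nrow(net$edges) - ns, nd),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment extremes behave as expected", {
  tax <- taxonomy_table(data.frame(otu_id = c("a1", "a2", "b1", "b2"),
                                   kingdom = "Bacteria",
                                   class = c("A", "A", "B", "B")))
  # every edge joins A to B
  net <- toy_network(cbind(c("a1", "a2", "a1"), c("b1", "b2", "b2")))
  enr <- class_enrichment(net, tax, "class")
  ab <- enr[enr$class_a != enr$class_b, ]
  expect_equal(ab$k, 3)
  expect_equal(min(enr$p), ab$p)
  # single label: one pair, p = 1
  tax1 <- taxonomy_table(data.frame(otu_id = c("a1", "a2", "b1", "b2"),
                                    kingdom = "Bacteria", class = "A"))
  enr1 <- class_enrichment(net, tax1, "class")
  expect_equal(nrow(enr1), 1)
  expect_equal(enr1$p, 1)
})

test_that("binomial sign-bias test matches closed-form tails", {
  tax <- taxonomy_table(data.frame(
    otu_id = c(paste0("x", 1:12), paste0("y", 1:12)),
    kingdom = "Bacteria", class = rep(c("X", "Y"), each = 12)))
  # 90 positive edges inside X-Y plus 10 negative edges in one pair
  pos_edges <- cbind(paste0("x", rep(1:9, each = 10)),
                     paste0("y", rep(1:10, 9)), 0.5)
  neg_edges <- cbind(paste0("x", rep(10:12, length.out = 10)),
                     paste0("x", rep(c(11, 12, 10), length.out = 10)), -0.5)
  # make the negative pair a distinct label pair: relabel x10..x12 as Z
  tax$class[tax$otu_id %in% paste0("x", 10:12)] <- "Z"
  net <- toy_network(rbind(pos_edges, neg_edges))
  res <- binomial_cooccurrence(net, tax, "class")
  pi0 <- 0.9
  zz <- res[res$class_a == "B_Z" & res$class_b == "B_Z", ]
  expect_equal(zz$n_pos, 0)
  expect_equal(zz$p, min(1, 2 * pbinom(0, 10, pi0)), tolerance = 1e-12)
  xy <- res[res$class_a == "B_X" & res$class_b == "B_Y", ]
  expect_equal(xy$p, min(1, 2 * min(pbinom(90, 90, pi0),
                                    pbinom(89, 90, pi0,
                                           lower.tail = FALSE))),
               tolerance = 1e-12)
})

test_that("all-positive graph yields no sign bias", {
  tax <- taxonomy_table(data.frame(otu_id = c("a", "b", "c"),
                                   kingdom = "Fungi", class = "A"))
  net <- toy_network(cbind(c("a", "b"), c("b", "c"), c(0.5, 0.6)))
  res <- binomial_cooccurrence(net, tax, "class")
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")
})
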