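test_that("network construction matches an all-pairs cor.test oracle", {
  set.seed(10)
  m <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m[2, ] <- m[1, ] + rnorm(10, sd = 0.1)  # one strong pair
  em <- expr_matrix(m, setNames(rep("classA", 10), colnames(m)))
  for (rthr in c(0.3, 0.6, 0.9)) {
    net <- build_network(em, "classA", r_threshold = rthr)
    expected <- list()
    for (i in 1:4) for (j in (i + 1):5) {
      ct <- cor.test(m[i, ], m[j, ])
      if (abs(ct$estimate) >= rthr && ct$p.value < 0.05)
        expected[[length(expected) + 1]] <- c(paste0("g", i),
                                              paste0("g", j))
    }
    got <- apply(net$edges[c("gene_a", "gene_b")], 1, paste,
                 collapse = "|")
    want <- vapply(expected, function(p)
      paste(sort(p), collapse = "|"), character(1))
    expect_setequal(got, want)
  }
})

test_that("identical genes form a perfect-correlation edge; constants warn", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4), g3 = c(4, 1, 3, 2),
             g4 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  em <- expr_matrix(m, setNames(rep("classA", 4), colnames(m)))
  expect_warning(net <- build_network(em, "classA", r_threshold = 1),
                 "g4")
  expect_false("g4" %in% net$nodes)
  expect_true(any(net$edges$gene_a == "g1" & net$edges$gene_b == "g2"))
  expect_equal(net$edges$r[net$edges$gene_a == "g1" &
                             net$edges$gene_b == "g2"], 1)
  # too few samples
  em2 <- expr_matrix(m[, 1:2], setNames(rep("classA", 2), colnames(m)[1:2]))
  expect_error(build_network(em2, "classA"), ">= 3")
  expect_error(build_network(em, "classA", genes = "missing"), "missing")
})

test_that("negative correlations are signed edges counted by degree", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = -c(1, 2, 3, 4, 5) + 10,
             g3 = c(2, 1, 4, 3, 6))
  colnames(m) <- paste0("s", 1:5)
  em <- expr_matrix(m, setNames(rep("classA", 5), colnames(m)))
  net <- build_network(em, "classA", r_threshold = 0.9)
  e12 <- net$edges[net$edges$gene_a == "g1" & net$edges$gene_b == "g2", ]
  expect_equal(e12$sign, "negative")
  expect_equal(e12$r, -1)
  expect_gte(degree_centrality(net, "g2"), 1)
})

test_that("degree and clustering coefficient match brute force on random graphs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    net <- coexpression_network(random_edge_df(n, runif(1, 0.2, 0.7)),
                                nodes = sprintf("n%02d", 1:n))
    A <- adjacency_of(net)
    nm <- node_metrics(net)
    for (v in net$nodes) {
      expect_equal(degree_centrality(net, v), oracle_degree(A, v))
      expect_equal(clustering_coefficient(net, v), oracle_cc(A, v))
    }
    expect_equal(sum(nm$degree), 2 * nrow(net$edges))
    expect_true(all(nm$clustering_coefficient >= 0 &
                      nm$clustering_coefficient <= 1))
  }
  net0 <- star_network("hub", 0)
  expect_equal(degree_centrality(net0, "hub"), 0)
  expect_equal(clustering_coefficient(net0, "hub"), 0)
  expect_error(degree_centrality(net0, "ghost"), "ghost")
})

test_that("graph metrics agree with igraph on a random graph", {
  set.seed(12)
  net <- coexpression_network(random_edge_df(10, 0.4),
                              nodes = sprintf("n%02d", 1:10))
  g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE,
                                     vertices = net$nodes)
  nm <- node_metrics(net)
  expect_equal(nm$degree,
               unname(igraph::degree(g)[nm$gene_id]))
  cc_ig <- igraph::transitivity(g, type = "localundirected",
                                vids = nm$gene_id, isolates = "zero")
  cc_ig[nm$degree == 1] <- 0  # igraph returns NaN->0 only for isolates
  expect_equal(nm$clustering_coefficient, unname(cc_ig))
})

test_that("triangles and stars give the textbook clustering coefficients", {
  tri <- coexpression_network(data.frame(gene_a = c("a", "a", "b"),
                                         gene_b = c("b", "c", "c")))
  expect_equal(clustering_coefficient(tri, "a"), 1)
  st <- star_network("hub", 3)
  expect_equal(clustering_coefficient(st, "hub"), 0)
  expect_equal(degree_centrality(st, "hub"), 3)
  # complete graph: every node has CC 1
  cg <- coexpression_network(random_edge_df(5, 1.1),
                             nodes = sprintf("n%02d", 1:5))
  expect_true(all(node_metrics(cg)$clustering_coefficient == 1))
})

test_that("edge sets shrink monotonically with stricter thresholds", {
  set.seed(13)
  m <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  em <- expr_matrix(m, setNames(rep("classA", 12), colnames(m)))
  edge_keys <- function(net)
    apply(net$edges[1:2], 1, paste, collapse = "|")
  prev <- NULL
  for (rthr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    keys <- edge_keys(build_network(em, "classA", r_threshold = rthr,
                                    p_threshold = 1))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  loose <- edge_keys(build_network(em, "classA", r_threshold = 0.1,
                                   p_threshold = 0.5))
  strict <- edge_keys(build_network(em, "classA", r_threshold = 0.1,
                                    p_threshold = 0.01))
  expect_true(all(strict %in% loose))
})

test_that("candidate location applies the at-least-one-network rule", {
  # hub passes in net_a only; mid passes degree but not CC; low passes
  # neither; iso only exists in net_b
  # 9 edges among hub's 10 neighbors: CC = 2*9/(10*9) = 0.2 exactly
  hub_edges <- rbind(
    data.frame(gene_a = "hub", gene_b = paste0("v", 1:10)),
    data.frame(gene_a = "v1", gene_b = paste0("v", 2:6)),
    data.frame(gene_a = c("v2", "v2", "v3", "v5"),
               gene_b = c("v3", "v4", "v4", "v6")))
  net_a <- coexpression_network(hub_edges)
  net_b <- star_network("mid", 10, prefix = "w")
  cand <- locate_candidates(net_a, net_b, degree_min = 10, cc_min = 0.2)
  expect_equal(cand$gene_id, "hub")
  expect_true(cand$in_a[1]); expect_false(cand$in_b[1])
  # degree 9 in both networks fails the default degree filter
  cand2 <- locate_candidates(star_network("x", 9), star_network("x", 9),
                             degree_min = 10)
  expect_equal(nrow(cand2), 0)
})

test_that("delta degree is symmetric and treats absent genes as degree 0", {
  net_a <- star_network("h", 17)
  net_b <- star_network("h", 1, prefix = "other")
  expect_equal(delta_degree("h", net_a, net_b), 16)
  expect_equal(delta_degree("h", net_b, net_a), 16)
  expect_equal(delta_degree("h", net_a, net_a), 0)
  expect_equal(delta_degree("absent", net_a, net_b), 0)
  expect_equal(delta_degree("leaf1", net_a, net_b), 1)
})

test_that("core-gene ranking follows delta degree with documented tie-breaks", {
  mk <- function(gene, k, prefix) star_network(gene, k, prefix = prefix)
  join <- function(...) {
    nets <- list(...)
    coexpression_network(do.call(rbind, lapply(nets, `[[`, "edges")))
  }
  net_a <- join(mk("p", 16, "pa"), mk("q", 12, "qa"), mk("r", 3, "ra"),
                mk("s", 9, "sa"))
  net_b <- join(mk("p", 2, "pb"), mk("q", 3, "qb"), mk("r", 12, "rb"),
                mk("s", 9, "sb"))
  core <- select_core_genes(c("p", "q", "r", "s"), net_a, net_b,
                            ddeg_min = 8)
  expect_equal(core$gene_id, c("p", "q", "r"))  # dd 14, 9, 9; s has 0
  expect_equal(core$delta_degree, c(14L, 9L, 9L))
  # q and r tie at dd 9 and max degree 12: gene id breaks the tie above;
  # with unequal max degrees the larger-max gene ranks first
  net_a2 <- join(mk("q", 12, "qa"), mk("r", 4, "ra"))
  net_b2 <- join(mk("q", 3, "qb"), mk("r", 13, "rb"))
  core2 <- select_core_genes(c("q", "r"), net_a2, net_b2, ddeg_min = 8)
  expect_equal(core2$gene_id, c("r", "q"))  # both dd 9; r max 13 > q 12
  expect_equal(select_core_genes(c("p", "q"), net_a, net_b,
                                 ddeg_min = 0)$gene_id, c("p", "q"))
  expect_equal(nrow(select_core_genes(character(), net_a, net_b)), 0)
})

test_that("a planted class-A module yields its genes as top core genes", {
  cfg <- synthetic_config(
    60, n_per_class = c(classA = 20, classB = 20),
    modules = list(planted_module(1:12, "classA", latent_loading = 2)),
    noise_sd = 0.5, seed = 21)
  em <- generate_expression(cfg)
  net_a <- build_network(em, "classA", r_threshold = 0.8)
  net_b <- build_network(em, "classB", r_threshold = 0.8)
  module <- paste0("g", 1:12)
  dd <- delta_degree(rownames(em$values), net_a, net_b)
  names(dd) <- rownames(em$values)
  expect_true(all(dd[module] >= 8))
  expect_true(all(dd[setdiff(names(dd), module)] < 8))
  cand <- locate_candidates(net_a, net_b)
  expect_true(all(module %in% cand$gene_id))
  core <- select_core_genes(cand, net_a, net_b, ddeg_min = 8)
  expect_true(core$gene_id[1] %in% module)
})
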