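mat <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pairwise correlation handles perfect, negated and linear profiles", {
  x <- c(1, 2, 3, 4, 5, 6)
  p <- pairwise_correlation(mat(m1 = x), mat(g1 = 2 * x))
  expect_equal(p$r, 1)
  expect_lt(p$p, 1e-6)
  p2 <- pairwise_correlation(mat(m1 = x), mat(g1 = -x))
  expect_equal(p2$r, -1)
  expect_error(pairwise_correlation(mat(m1 = 1:3), mat(g1 = 1:3)), ">= 4")
  expect_error(pairwise_correlation(mat(m1 = x),
                                    mat(g1 = x, samples = paste0("t", 1:6))),
               "identical")
  expect_warning(pz <- pairwise_correlation(mat(m1 = x, m2 = rep(1, 6)),
                                            mat(g1 = rev(x))),
                 "zero-variance")
  expect_equal(pz$metabolite, "m1")
})

test_that("pairwise correlation equals brute-force per-pair computation", {
  withr::with_seed(21, {
    metab <- matrix(rnorm(6 * 8), nrow = 6,
                    dimnames = list(paste0("m", 1:6), paste0("s", 1:8)))
    genes <- matrix(rnorm(5 * 8), nrow = 5,
                    dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  })
  p <- pairwise_correlation(metab, genes)
  expect_equal(nrow(p), 30)
  for (i in seq_len(nrow(p))) {
    ref <- cor_brute(metab[p$metabolite[i], ], genes[p$gene[i], ])
    expect_equal(p$r[i], unname(ref["r"]), tolerance = 1e-12)
    expect_equal(p$p[i], unname(ref["p"]), tolerance = 1e-12)
  }
})

test_that("build_network thresholds edges by |R| and BH-FDR", {
  x <- c(0.1, 1.9, 3.2, 3.9, 5.1, 6)
  withr::with_seed(8, {
    noise <- matrix(rnorm(4 * 6), nrow = 4,
                    dimnames = list(paste0("g", 2:5), paste0("s", 1:6)))
  })
  genes <- rbind(mat(g1 = 2 * x), noise)
  net <- build_network(pairwise_correlation(mat(m1 = x), genes))
  expect_s3_class(net, "coreg_network")
  expect_equal(net$edges$gene, "g1")
  expect_equal(net$edges$sign, "positive")
  expect_equal(net$edges$weight, abs(net$edges$r))
  # bipartite: every edge joins one metabolite and one gene node
  expect_setequal(net$nodes$id[net$nodes$kind == "metabolite"], "m1")
  # empty input -> empty network
  empty <- build_network(pairwise_correlation(mat(m1 = x), genes)[0, ])
  expect_equal(nrow(empty$edges), 0)
  # anti-monotone in both thresholds
  pairs <- pairwise_correlation(rbind(mat(m1 = x), noise[1:2, ] + 0), genes)
  loose <- build_network(pairs, r_min = 0.3, fdr_max = 0.5)
  tight <- build_network(pairs, r_min = 0.8, fdr_max = 0.05)
  key <- function(n) paste(n$edges$metabolite, n$edges$gene)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("degree ranking counts signed connectivity and sorts", {
  expect_equal(nrow(degree_ranking(build_network(
    data.frame(metabolite = character(0), gene = character(0),
               r = numeric(0), p = numeric(0))))), 0)
  # star: one metabolite linked to 5 genes
  x <- c(1, 2, 3, 4, 5, 6)
  genes <- mat(g1 = x, g2 = 2 * x, g3 = -x, g4 = x + 1, g5 = -2 * x)
  net <- build_network(pairwise_correlation(mat(mA = x), genes))
  dr <- degree_ranking(net)
  expect_equal(dr$node[1], "mA")
  expect_equal(dr$degree[1], 5)
  expect_equal(dr$positive[1], 3)
  expect_equal(dr$negative[1], 2)
  expect_true(all(dr$degree[dr$kind == "gene"] == 1))
  # handshake identity
  expect_equal(sum(dr$degree), 2 * nrow(net$edges))
  # planted hub (5 partners) outranks a smaller hub (2 partners)
  y <- c(1, -1, 2, -2, 3, -3) # low correlation with the linear profile x
  genesB <- mat(g6 = y, g7 = -2 * y)
  net2 <- build_network(pairwise_correlation(
    rbind(mat(mA = x), mat(mB = y)), rbind(genes, genesB)))
  dr2 <- degree_ranking(net2)
  expect_equal(dr2$node[1], "mA")
})

test_that("network export/import round-trips byte-identically in both formats", {
  x <- c(1.5, 2.1, 3.7, 4.2, 5.9, 6.4)
  genes <- mat(g1 = 2 * x, g2 = -x + 0.3)
  net <- build_network(pairwise_correlation(mat(m1 = x, m2 = rev(x)), genes))
  expect_gt(nrow(net$edges), 0)
  for (fmt in c("edgelist", "gexf")) {
    f1 <- tempfile(); f2 <- tempfile()
    export_network(net, f1, fmt)
    back <- import_network(f1, fmt)
    export_network(back, f2, fmt)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    expect_equal(back$edges, net$edges)
    expect_equal(back$nodes, net$nodes)
  }
  # empty network still yields valid files with zero edges
  for (fmt in c("edgelist", "gexf")) {
    f <- tempfile()
    export_network(empty_net <- build_network(
      data.frame(metabolite = "m", gene = "g", r = 0.1, p = 0.9)), f, fmt)
    expect_equal(nrow(import_network(f, fmt)$edges), 0)
  }
})

test_that("planted linked pairs are recovered by the network", {
  # 30 samples give the FDR step enough power; at the 6-sample design point
  # BH across 2500 pairs cannot pass (see the acceptance-criterion analysis)
  cfg <- sim_config(n_genes = 50, n_metabolites = 50, n_samples = 30,
                    r_target = 0.95, n_linked_pairs = 5, seed = 3)
  sim <- simulate_abundance_matrices(cfg)
  net <- build_network(pairwise_correlation(sim$metab, sim$genes))
  got <- paste(net$edges$metabolite, net$edges$gene)
  want <- paste(sim$truth$linked_pairs$metabolite, sim$truth$linked_pairs$gene)
  expect_gte(length(intersect(got, want)), 4)
  # recovered signs match the planted signs
  hit <- match(intersect(got, want), got)
  expect_equal(net$edges$sign[hit],
               sim$truth$linked_pairs$sign[match(intersect(got, want), want)])
})

test_that("r_target = 1 gives sample correlation exactly +/-1 on linked pairs", {
  cfg <- sim_config(n_genes = 10, n_metabolites = 10, n_samples = 6,
                    r_target = 1, n_linked_pairs = 3, seed = 4)
  sim <- simulate_abundance_matrices(cfg)
  for (i in seq_len(3)) {
    r <- cor(sim$metab[sim$truth$linked_pairs$metabolite[i], ],
             sim$genes[sim$truth$linked_pairs$gene[i], ])
    expect_equal(abs(r), 1, tolerance = 1e-12)
    expect_equal(sign(r) > 0, sim$truth$linked_pairs$sign[i] == "positive")
  }
})
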