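test_that("summary uses the edges-per-node and directed-density conventions", {
  tax <- generate_taxonomy(seed = 8)
  web <- generate_foodweb(tax, n_basal = 8, connectance = 0.05, seed = 3)
  s <- web_summary(web)
  n <- length(web$nodes); e <- nrow(web$edges)
  expect_equal(s$average_degree, e / n)          # E/n, not 2E/n
  expect_equal(s$density, e / (n * (n - 1)))

  # complete directed graph on 5 nodes
  pairs <- expand.grid(prey = letters[1:5], predator = letters[1:5],
                       stringsAsFactors = FALSE)
  complete <- food_web(pairs[pairs$prey != pairs$predator, ])
  cs <- web_summary(complete)
  expect_equal(cs$density, 1)
  expect_equal(cs$average_degree, 4)

  # density is undefined, not zero, below two nodes
  single <- food_web(nodes = "alone")
  expect_equal(web_summary(single)$average_degree, 0)
  expect_true(is.na(web_summary(single)$density))
})

test_that("centralities match exhaustive path-enumeration oracles", {
  fixtures <- list(make_fixture("chain3")$web,
                   make_fixture("table4")$web,
                   make_fixture("two_triangles")$web,
                   make_fixture("five_at_2_5")$web)
  set.seed(42)
  for (s in c(5, 6)) {
    tax <- generate_taxonomy(seed = s, shape = c(1, 1, 1, 1, 2, 4))
    fixtures[[length(fixtures) + 1]] <-
      generate_foodweb(tax, n_basal = 2, connectance = 0.15, seed = s)
  }
  for (web in fixtures) {
    dc <- degree_centrality(web)
    expect_equal(setNames(dc$raw, dc$node), oracle_degree_centrality(web),
                 tolerance = 1e-12)
    bc <- betweenness_centrality(web)
    expect_equal(setNames(bc$raw, bc$node), oracle_betweenness(web),
                 tolerance = 1e-10)
    cc <- closeness_centrality(web)
    expect_equal(setNames(cc$raw, cc$node), oracle_closeness(web),
                 tolerance = 1e-10)
    kz <- katz_centrality(web, alpha = 0.1, beta = 1)
    expect_equal(setNames(kz$raw, kz$node), oracle_katz(web),
                 tolerance = 1e-8)
  }
})

test_that("betweenness on a directed path singles out the middle vertex", {
  web <- make_fixture("chain3")$web
  bc <- betweenness_centrality(web)
  expect_equal(bc$normalized[bc$node == "Grazer"], 1)
  expect_equal(bc$normalized[bc$node != "Grazer"], c(0, 0))
  # below 3 nodes everything is zero by convention
  tiny <- food_web(data.frame(prey = "a", predator = "b"))
  expect_equal(betweenness_centrality(tiny)$raw, c(0, 0))
})

test_that("degree centrality of a star center counts all leaves", {
  leaves <- paste0("prey", 1:6)
  star <- food_web(data.frame(prey = leaves, predator = "hub"))
  dc <- degree_centrality(star)
  expect_equal(dc$raw[dc$node == "hub"], 6 / 6)
  expect_equal(dc$normalized[dc$node == "hub"], 1)
})

test_that("trophic levels solve the diet-average system", {
  expect_equal(trophic_levels(make_fixture("chain3")$web)$levels,
               c(Alga = 1, Fish = 3, Grazer = 2))
  tl <- trophic_levels(make_fixture("five_at_2_5")$web)
  expect_equal(unname(tl$levels[paste0("Pred", 1:5)]), rep(2.5, 5))
  expect_true(tl$basal[["Detritus"]])
  expect_equal(tl$levels[["Detritus"]], 1)

  # agreement with the fixed-point oracle on random basal-anchored webs
  for (seed in c(1, 12, 33)) {
    tax <- generate_taxonomy(seed = seed)
    web <- generate_foodweb(tax, n_basal = 10, connectance = 0.05,
                            weighted = TRUE, seed = seed)
    s <- trophic_levels(web)$levels
    expect_equal(s, oracle_trophic(web), tolerance = 1e-10)
    expect_true(all(s[!trophic_levels(web)$basal] > 1))
    # diet fractions only: uniform weight scaling leaves levels unchanged
    scaled <- web
    scaled$edges$weight <- scaled$edges$weight * 7
    expect_equal(trophic_levels(scaled)$levels, s, tolerance = 1e-12)
  }
})

test_that("trophic precondition failures raise structured errors with fallback", {
  cyc <- food_web(data.frame(prey = c("a", "b", "c"),
                             predator = c("b", "c", "a")))
  expect_error(trophic_levels(cyc), "no basal node")
  # unreachable consumer: a basal exists elsewhere but the cycle is closed
  mixed <- food_web(data.frame(prey = c("p", "a", "b", "c"),
                               predator = c("q", "b", "c", "a")))
  expect_error(trophic_levels(mixed), "a, b, c")
  fb <- trophic_levels(mixed, fallback = TRUE)
  expect_equal(length(fb$levels), 5)
  expect_true(all(fb$levels >= 1))
})

test_that("katz centrality grows downstream and respects the spectral bound", {
  chain <- food_web(data.frame(prey = c("a", "b", "c"),
                               predator = c("b", "c", "d")))
  kz <- katz_centrality(chain, alpha = 0.1, beta = 1)
  raw <- setNames(kz$raw, kz$node)
  expect_true(all(diff(raw[c("a", "b", "c", "d")]) > 0))
  expect_equal(sqrt(sum(raw^2)), 1, tolerance = 1e-12)

  # edgeless graph: pure beta, degenerate normalization maps to 0
  empty <- food_web(nodes = c("x", "y", "z"))
  ke <- katz_centrality(empty)
  expect_equal(ke$raw, rep(1 / sqrt(3), 3))
  expect_equal(ke$normalized, rep(0, 3))

  # two isomorphic components get identical values
  two <- food_web(data.frame(prey = c("a1", "b1"), predator = c("b1", "c1")))
  two$edges <- rbind(two$edges,
                     data.frame(prey = c("a2", "b2"),
                                predator = c("b2", "c2"), weight = 1))
  two <- food_web(two$edges)
  kt <- katz_centrality(two)
  v <- setNames(kt$raw, kt$node)
  expect_equal(unname(v[c("a1", "b1", "c1")]), unname(v[c("a2", "b2", "c2")]))

  # a reciprocal pair has spectral radius 1: alpha = 2 cannot converge
  recip <- food_web(data.frame(prey = c("a", "b"), predator = c("b", "a")))
  expect_error(katz_centrality(recip, alpha = 2, auto_shrink = FALSE),
               "spectral radius")
  expect_warning(katz_centrality(recip, alpha = 0.95), "shrunk")
})

test_that("directed clustering and flow hierarchy behave on canonical shapes", {
  # any DAG is perfectly hierarchical
  tax <- generate_taxonomy(seed = 10)
  dag <- generate_foodweb(tax, n_basal = 8, connectance = 0.05, seed = 10)
  expect_equal(flow_hierarchy(dag), 1)

  cyc <- food_web(data.frame(prey = c("a", "b", "c"),
                             predator = c("b", "c", "a")))
  expect_equal(flow_hierarchy(cyc), 0)
  expect_gt(average_clustering(cyc), 0)

  # no edges: vacuously acyclic, zero clustering
  bare <- food_web(nodes = c("u", "v"))
  expect_equal(flow_hierarchy(bare), 1)
  expect_equal(average_clustering(bare), 0)

  # self-loops count as cyclic edges
  loopy <- food_web(data.frame(prey = c("a", "a"), predator = c("a", "b")))
  expect_equal(flow_hierarchy(loopy), 0.5)

  # directed clustering agrees with the brute-force triple-loop oracle
  for (name in c("two_triangles", "modular_toy", "chain3", "five_at_2_5")) {
    web <- make_fixture(name)$web
    expect_equal(average_clustering(web), oracle_clustering(web),
                 tolerance = 1e-12)
  }

  # coarsening a DAG never lifts hierarchy above the original
  casc <- simplify_cascade(dag, tax, default_scheme())
  hs <- vapply(casc, function(x) flow_hierarchy(x$web), 0)
  expect_true(all(hs <= flow_hierarchy(dag)))

  # the coherence reading stays in (0, 1] and is 1 on a perfectly
  # coherent chain
  expect_equal(flow_hierarchy(make_fixture("chain3")$web,
                              method = "coherence"), 1)
  expect_lte(flow_hierarchy(cyc, method = "coherence"), 1)
})

test_that("min-max normalization follows the worked example and invariances", {
  expect_equal(minmax_normalize(c(a = 2, b = 4, c = 6)),
               c(a = 0, b = 0.5, c = 1))
  expect_equal(minmax_normalize(c(x = 3, y = 3)), c(x = 0, y = 0))
  set.seed(7)
  x <- rnorm(20)
  norm1 <- minmax_normalize(x)
  expect_equal(minmax_normalize(norm1), norm1)            # idempotent
  expect_equal(minmax_normalize(2.5 * x + 10), norm1)     # affine-invariant
  expect_true(all(norm1 >= 0 & norm1 <= 1))
})
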