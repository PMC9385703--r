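test_that("lumping the lizard toy web at genus merges the shared prey edge", {
  fx <- make_fixture("table4")
  res <- simplify_web(fx$web, fx$taxonomy, fx$scheme, "low")
  expect_setequal(res$web$nodes, c("Podarcis", "Insect A", "Insect B"))
  expect_equal(nrow(res$web$edges), 2)
  merged <- res$web$edges[res$web$edges$prey == "Insect B", ]
  expect_equal(merged$predator, "Podarcis")
  expect_equal(merged$weight, 2)
  expect_equal(total_weight(res$web), total_weight(fx$web))
  expect_equal(res$n_self_loops, 0L)
  # the mapping is total over the original nodes
  expect_setequal(res$mapping$original, fx$web$nodes)
})

test_that("raw level is the identity simplification", {
  fx <- make_fixture("table4")
  res <- simplify_web(fx$web, fx$taxonomy, fx$scheme, "raw")
  expect_true(webs_identical(res$web, fx$web))
  expect_equal(res$mapping$original, res$mapping$group)
})

test_that("map_node resolves rules, raggedness and unknown-taxon policies", {
  fx <- make_fixture("table4")
  expect_equal(map_node("Podarcis muralis", fx$taxonomy, fx$scheme, "low"),
               "Podarcis")
  expect_equal(map_node("Podarcis muralis", fx$taxonomy, fx$scheme, "raw"),
               "Podarcis muralis")
  # insects carry no family: at the family level they fall back to class
  expect_equal(map_node("Insect A", fx$taxonomy, fx$scheme, "med"),
               "Insecta")
  # unknown taxon: passthrough keeps the label, strict raises
  expect_equal(map_node("und entity", fx$taxonomy, fx$scheme, "low"),
               "und entity")
  expect_error(map_node("und entity", fx$taxonomy, fx$scheme, "low",
                        unknown = "strict"), "und entity")
  # group-label policy uses the vernacular column
  tax <- taxonomy_table(data.frame(taxon = "Ectopria thoracica",
                                   phylum = "Arthropoda",
                                   genus = "Ectopria",
                                   group = "Beetles_water"))
  expect_equal(map_node("Ectopria thoracica", tax, fx$scheme, "low",
                        unknown = "group-label"), "Beetles_water")
  # taxon with only phylum filled lands on the phylum at the genus level
  ragged <- taxonomy_table(data.frame(taxon = "Mystery", phylum = "Mollusca"))
  expect_equal(map_node("Mystery", ragged, default_scheme(), "low"),
               "Mollusca")
})

test_that("homonym genera in different phyla are not silently merged", {
  tax <- taxonomy_table(data.frame(
    taxon = c("Morus bassanus", "Morus alba"),
    phylum = c("Chordata", "Tracheophyta"),
    genus = c("Morus", "Morus"),
    species = c("Morus bassanus", "Morus alba")))
  web <- food_web(data.frame(prey = "Morus alba",
                             predator = "Morus bassanus"))
  res <- simplify_web(web, tax, default_scheme(), "low")
  expect_setequal(res$web$nodes, c("Morus_Chordata", "Morus_Tracheophyta"))
  expect_equal(res$n_self_loops, 0L)
})

test_that("self-loops from lumped predator-prey pairs are retained and counted", {
  tax <- taxonomy_table(data.frame(
    taxon = c("Gammarus pulex", "Gammarus fossarum"),
    phylum = "Arthropoda", genus = "Gammarus",
    species = c("Gammarus pulex", "Gammarus fossarum")))
  web <- food_web(data.frame(prey = "Gammarus fossarum",
                             predator = "Gammarus pulex"))
  res <- simplify_web(web, tax, default_scheme(), "low")
  expect_equal(res$n_self_loops, 1L)
  expect_equal(total_weight(res$web), 1)  # conservation under retention
  dropped <- simplify_web(web, tax, default_scheme(), "low",
                          drop_self_loops = TRUE)
  expect_equal(dropped$n_self_loops, 1L)
  expect_equal(nrow(dropped$web$edges), 0)
})

test_that("simplification agrees with the brute-force grouping oracle", {
  tax <- generate_taxonomy(seed = 2, shape = c(2, 2, 2, 1, 2, 2))
  for (seed in c(3, 17, 91)) {
    web <- generate_foodweb(tax, n_basal = 5, connectance = 0.08,
                            weighted = TRUE, seed = seed)
    for (level in c("low", "med-high", "top")) {
      res <- simplify_web(web, tax, default_scheme(), level)
      oracle <- oracle_simplify(web, res$mapping)
      got <- setNames(res$web$edges$weight,
                      paste(res$web$edges$prey, res$web$edges$predator,
                            sep = " -> "))
      expect_mapequal(as.list(got), oracle)
      expect_equal(total_weight(res$web), total_weight(web))
    }
  }
})

test_that("cascade equals direct simplification and shrinks monotonically", {
  tax <- generate_taxonomy(seed = 4)
  web <- generate_foodweb(tax, n_basal = 8, connectance = 0.06,
                          weighted = TRUE, seed = 9)
  casc <- simplify_cascade(web, tax, default_scheme())
  ns <- vapply(casc, function(x) length(x$web$nodes), 0)
  es <- vapply(casc, function(x) nrow(x$web$edges), 0)
  expect_true(all(diff(ns) <= 0))
  expect_true(all(diff(es) <= 0))
  expect_true(all(vapply(casc, function(x) total_weight(x$web), 0) ==
                    total_weight(web)))

  # stepwise: simplify the low web one level further and compare with the
  # direct med simplification of the raw web
  low <- casc[["low"]]
  lifted <- lift_taxonomy(tax, low$mapping)
  stepwise <- simplify_web(low$web, lifted, default_scheme(), "med")
  expect_true(webs_identical(stepwise$web, casc[["med"]]$web))

  # and the med web straight to top equals the direct top web
  med <- casc[["med"]]
  lifted2 <- lift_taxonomy(tax, med$mapping)
  step2 <- simplify_web(med$web, lifted2, default_scheme(), "top")
  expect_true(webs_identical(step2$web, casc[["top"]]$web))
})

test_that("a kingdom-level scheme collapses to at most the kingdom count", {
  tax <- generate_taxonomy(seed = 6, shape = c(3, 1, 1, 1, 2, 2),
                           n_kingdoms = 3)
  scheme <- simplification_scheme(
    data.frame(group_key = "default", level = "top", target = "kingdom"),
    levels = c("raw", "top"))
  web <- generate_foodweb(tax, n_basal = 3, connectance = 0.2, seed = 21)
  res <- simplify_web(web, tax, scheme, "top")
  expect_lte(length(res$web$nodes), 3)
})
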