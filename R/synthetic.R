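## Seeded generators of taxonomically annotated food webs, plus the small
## hand-built fixtures used throughout the tests and documentation. The
## generator produces basal-anchored directed webs via a niche-score
## ordering: it exercises the simplification and metric machinery, not the
## degree distributions of any empirical web.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a nested synthetic taxonomy
#'
#' Builds a fully nested lineage tree with deterministic names
#' (`P1`, `P1.C2`, ..., species `P1.C1.O1.F1.G2.S1`); the species label is
#' the taxon key. An optional raggedness fraction blanks a random suffix of
#' fine ranks (species up to family) per row, emulating real tables where
#' not every entity is resolved to species.
#'
#' @param seed integer seed; the same seed always yields the same table.
#' @param shape integer vector of length 6: phyla, classes per phylum,
#'   orders per class, families per order, genera per family, species per
#'   genus.
#' @param n_kingdoms number of kingdoms; phyla are assigned round-robin.
#' @param raggedness fraction of rows with deleted fine ranks (0 = none).
#' @return a [taxonomy_table].
#' @export
generate_taxonomy <- function(seed = 1, shape = c(2, 2, 2, 2, 2, 2),
                              n_kingdoms = 1, raggedness = 0) {
  stopifnot(length(shape) == 6, all(shape >= 1), raggedness >= 0,
            raggedness <= 1)
  expand <- function(parents, count, tag) {
    unlist(lapply(parents, function(p)
      paste0(p, ".", tag, seq_len(count))))
  }
  phyla <- paste0("P", seq_len(shape[1]))
  classes <- expand(phyla, shape[2], "C")
  orders <- expand(classes, shape[3], "O")
  families <- expand(orders, shape[4], "F")
  genera <- expand(families, shape[5], "G")
  species <- expand(genera, shape[6], "S")
  up <- function(x) sub("\\.[A-Z][0-9]+$", "", x)
  gen <- up(species); fam <- up(gen); ord <- up(fam); cls <- up(ord)
  phy <- up(cls)
  kng <- paste0("K", (match(phy, phyla) - 1) %% n_kingdoms + 1)
  df <- data.frame(taxon = species, kingdom = kng, phylum = phy,
                   class = cls, order = ord, family = fam, genus = gen,
                   species = species, group = NA_character_,
                   stringsAsFactors = FALSE)
  if (raggedness > 0) {
    with_seed(seed, {
      hit <- stats::runif(nrow(df)) < raggedness
      depth <- sample(1:3, nrow(df), replace = TRUE)
      for (i in which(hit)) {
        blank <- c("species", "genus", "family")[seq_len(depth[i])]
        df[i, blank] <- NA_character_
      }
    })
  }
  taxonomy_table(df)
}

#' Generate a seeded basal-anchored food web
#'
#' Every species gets a niche score; the `n_basal` lowest-score species are
#' producers (no prey). Each consumer preys on at least one lower-score
#' species, which guarantees by construction that every node is reachable
#' from a basal node (the trophic-level precondition holds on every
#' output); further prey links among lower-score species are added
#' independently so the realized directed connectance approaches `C`.
#' Optional weights are i.i.d. integers 1-5, so summed merge weights are
#' exactly checkable after lumping.
#'
#' @param taxonomy a [taxonomy_table]; its taxa become the nodes.
#' @param n_basal number of producers (>= 1; `n_basal = n` gives an
#'   edgeless web of producers).
#' @param connectance target directed connectance C = E / (n (n - 1)),
#'   with 0 < C < 1; infeasible values raise an error stating the feasible
#'   range for this node count.
#' @param weighted logical; draw integer weights 1-5.
#' @param seed integer seed; output is fully reproducible.
#' @param name network name.
#' @return a [food_web].
#' @export
generate_foodweb <- function(taxonomy, n_basal, connectance = 0.1,
                             weighted = FALSE, seed = 1,
                             name = "synthetic") {
  sp <- taxonomy$taxon
  n <- length(sp)
  stopifnot(n >= 1, n_basal >= 1, n_basal <= n)
  if (n_basal == n) {
    return(food_web(nodes = sp, name = name, weighted = weighted))
  }
  stopifnot(connectance > 0, connectance < 1)
  with_seed(seed, {
    score <- stats::runif(n)
    ord <- order(score)
    ranked <- sp[ord]                    # ascending niche score
    n_cons <- n - n_basal
    target_e <- round(connectance * n * (n - 1))
    m_all <- sum((n_basal + 1):n - 1)    # candidate prey->consumer pairs
    if (target_e < n_cons || target_e > m_all) {
      stop(sprintf(
        paste0("infeasible connectance %.4f for %d species with %d basal; ",
               "feasible range [%.4f, %.4f]"),
        connectance, n, n_basal, n_cons / (n * (n - 1)),
        m_all / (n * (n - 1))), call. = FALSE)
    }
    prey <- character(0); pred <- character(0)
    mandatory_prey <- integer(n_cons)
    for (i in seq_len(n_cons)) {
      r <- n_basal + i                   # position of this consumer
      mandatory_prey[i] <- sample.int(r - 1, 1)
      prey <- c(prey, ranked[mandatory_prey[i]])
      pred <- c(pred, ranked[r])
    }
    p_extra <- (target_e - n_cons) / max(1, m_all - n_cons)
    for (i in seq_len(n_cons)) {
      r <- n_basal + i
      cand <- setdiff(seq_len(r - 1), mandatory_prey[i])
      if (length(cand) > 0 && p_extra > 0) {
        take <- cand[stats::runif(length(cand)) < p_extra]
        prey <- c(prey, ranked[take])
        pred <- c(pred, rep(ranked[r], length(take)))
      }
    }
    w <- if (weighted) sample(1:5, length(prey), replace = TRUE) else
      rep(1, length(prey))
    food_web(data.frame(prey = prey, predator = pred, weight = w,
                        stringsAsFactors = FALSE),
             nodes = sp, name = name, weighted = weighted)
  })
}

#' Hand-built worked fixtures
#'
#' Named small webs with their taxonomy and scheme, matching the worked
#' cases used in the documentation and tests:
#' \describe{
#'   \item{table4}{two Podarcis lizard species eating two insect genera
#'     (three unit interactions); lumping at genus merges the two lizards
#'     and sums the Insect B weight to 2.}
#'   \item{chain3}{a three-node producer chain with trophic levels 1, 2, 3.}
#'   \item{five_at_2_5}{a grazer on detritus plus five predators each
#'     eating both, so all five sit at trophic level 2.5.}
#'   \item{two_triangles}{two directed 3-cycles joined by one bridge edge —
#'     the bridge carries the maximal edge betweenness.}
#'   \item{modular_toy}{two reciprocal 4-cliques joined by one bridge.}
#' }
#'
#' @param name fixture name.
#' @return list with elements `web`, `taxonomy`, `scheme`.
#' @export
make_fixture <- function(name) {
  switch(name,
    table4 = {
      web <- food_web(data.frame(
        prey = c("Insect A", "Insect B", "Insect B"),
        predator = c("Podarcis muralis", "Podarcis muralis",
                     "Podarcis siculus"),
        weight = 1, stringsAsFactors = FALSE), name = "table4")
      tax <- taxonomy_table(data.frame(
        taxon = c("Podarcis muralis", "Podarcis siculus", "Insect A",
                  "Insect B"),
        kingdom = "Animalia",
        phylum = c("Chordata", "Chordata", "Arthropoda", "Arthropoda"),
        class = c("Reptilia", "Reptilia", "Insecta", "Insecta"),
        order = c("Squamata", "Squamata", NA, NA),
        family = c("Lacertidae", "Lacertidae", NA, NA),
        genus = c("Podarcis", "Podarcis", "Insect A", "Insect B"),
        species = c("Podarcis muralis", "Podarcis siculus", NA, NA),
        stringsAsFactors = FALSE))
      scheme <- simplification_scheme(data.frame(
        group_key = "default", level = c("low", "med", "med-high"),
        target = c("genus", "family", "class"), stringsAsFactors = FALSE),
        levels = c("raw", "low", "med", "med-high"))
      list(web = web, taxonomy = tax, scheme = scheme)
    },
    chain3 = {
      web <- food_web(data.frame(prey = c("Alga", "Grazer"),
                                 predator = c("Grazer", "Fish"),
                                 stringsAsFactors = FALSE), name = "chain3")
      list(web = web, taxonomy = trivial_taxonomy(web),
           scheme = default_scheme())
    },
    five_at_2_5 = {
      preds <- paste0("Pred", 1:5)
      web <- food_web(data.frame(
        prey = c("Detritus", rep(c("Detritus", "Grazer"), 5)),
        predator = c("Grazer", rep(preds, each = 2)),
        stringsAsFactors = FALSE), name = "five_at_2_5")
      list(web = web, taxonomy = trivial_taxonomy(web),
           scheme = default_scheme())
    },
    two_triangles = {
      ## reciprocal triangles so the single bridge carries every cross
      ## path and is the unique betweenness maximum
      tri <- function(v) data.frame(
        prey = c(v, rev(v)), predator = c(v[c(2, 3, 1)], rev(v)[c(2, 3, 1)]),
        stringsAsFactors = FALSE)
      web <- food_web(rbind(tri(c("a", "b", "c")), tri(c("d", "e", "f")),
                            data.frame(prey = "c", predator = "d",
                                       stringsAsFactors = FALSE)),
                      name = "two_triangles")
      list(web = web, taxonomy = trivial_taxonomy(web),
           scheme = default_scheme())
    },
    modular_toy = {
      cl1 <- c("m1", "m2", "m3", "m4"); cl2 <- c("q1", "q2", "q3", "q4")
      clique <- function(v) {
        pairs <- expand.grid(prey = v, predator = v,
                             stringsAsFactors = FALSE)
        pairs[pairs$prey != pairs$predator, ]
      }
      web <- food_web(rbind(clique(cl1), clique(cl2),
                            data.frame(prey = "m4", predator = "q1",
                                       stringsAsFactors = FALSE)),
                      name = "modular_toy")
      list(web = web, taxonomy = trivial_taxonomy(web),
           scheme = default_scheme())
    },
    stop("unknown fixture `", name, "`; available: table4, chain3, ",
         "five_at_2_5, two_triangles, modular_toy", call. = FALSE))
}

trivial_taxonomy <- function(web) {
  taxonomy_table(data.frame(taxon = web$nodes, kingdom = "Animalia",
                            genus = web$nodes, stringsAsFactors = FALSE))
}
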