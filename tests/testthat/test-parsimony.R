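test_that("universe closure contains tips, nests by depth, and is guarded", {
  tips <- c(A = "K-P", B = "K-P")
  u0 <- build_universe(tips, depth = 0)
  expect_identical(u0$keys, "K-P")
  u1 <- build_universe(tips, depth = 1)
  expect_true(all(u0$keys %in% u1$keys))
  u2 <- build_universe(tips, depth = 2)
  expect_true(all(u1$keys %in% u2$keys))
  expect_error(build_universe(tips, depth = 4), "depth")
  expect_error(build_universe(tips, depth = 2, max_states = 10),
               "universe exceeds")
})

test_that("depth-2 closure of the case-study tips holds the key ancestors", {
  fx <- folate_fixture()
  u <- build_universe(fx$amorphea_tips, depth = 2)
  for (k in c("B-K-P", "B-B-K-P", "B-B;K-P", "B;K-P", "K-P", "."))
    expect_true(k %in% u$keys, info = k)
})

test_that("two identical tips reconstruct at zero cost", {
  tr <- read_newick("(A,B);")
  fit <- sankoff(tr, c(A = "K-P", B = "K-P"))
  expect_identical(fit$total_cost, 0)
  expect_identical(fit$root_states, "K-P")
  expect_length(fit$reconstructions, 1L)
  expect_length(extract_events(fit), 0L)
})

test_that("three-tip reconstruction costs one event of a sensible type", {
  tr <- read_newick("((A,B),C);")
  tips <- c(A = "K-P", B = "K-P", C = "B-K-P")
  fit <- sankoff(tr, tips, universe_depth = 1)
  expect_equal(fit$total_cost, 1)
  # exhaustive check over all ancestral assignments in the same universe
  D <- archevol:::universe_distance_matrix(fit$universe)
  expect_equal(oracle_min_cost(tr, archevol:::as_profiles(tips), D), 1)
  evs <- extract_events(fit)
  expect_length(evs, 1L)
  expect_true(evs[[1L]]$type %in% c("fission_domain_loss",
                                    "domain_duplication", "gene_gain"))
})

test_that("sankoff equals exhaustive enumeration on many small trees", {
  profs <- case_study_profiles()
  keys <- vapply(profs, profile_text, "")
  shapes <- c("((A,B),(C,D));", "(((A,B),C),D);", "((A,(B,C)),(D,E));",
              "(((A,B),(C,D)),E);", "((((A,B),C),D),E);", "(A,B,(C,D));")
  set.seed(404)
  for (sh in shapes) {
    tr <- read_newick(sh)
    for (rep in 1:3) {
      tipsel <- sample(seq_along(profs), length(tr$tip.label),
                       replace = TRUE)
      tips <- setNames(profs[tipsel], tr$tip.label)
      uni <- archevol:::universe_from_profiles(profs)
      fit <- sankoff(tr, tips, universe = uni, max_mprs = 64L)
      D <- fit$distance_matrix
      expect_equal(fit$total_cost,
                   oracle_min_cost(tr, archevol:::as_profiles(tips), D),
                   info = paste(sh, rep))
      # all MPRs share the minimal total cost, evaluated independently
      for (r in fit$reconstructions) {
        s <- 0
        for (e in seq_len(nrow(tr$edge))) {
          lab <- archevol:::node_labels(tr)
          s <- s + D[r$assignment[[lab[tr$edge[e, 1L]]]],
                     r$assignment[[lab[tr$edge[e, 2L]]]]]
        }
        expect_equal(s, fit$total_cost)
      }
    }
  }
})

test_that("root constraints never decrease the minimal cost", {
  tr <- read_newick("((A,B),C);")
  tips <- c(A = "K-P", B = "K-P", C = "B-K-P")
  free <- sankoff(tr, tips, universe_depth = 1)
  for (k in c("B-K-P", "K-P", "B-B-K-P")) {
    con <- sankoff(tr, tips, root_constraint = k, universe_depth = 1)
    expect_gte(con$total_cost + 1e-9, free$total_cost)
  }
  expect_error(sankoff(tr, tips, universe = build_universe(tips, depth = 0),
                       root_constraint = "B;B;K;P"),
               "outside the state universe")
})

test_that("missing tip profiles are reported", {
  tr <- read_newick("((A,B),C);")
  expect_error(sankoff(tr, c(A = "K-P", B = "K-P")), "tip missing")
})

test_that("permuting a uniform clade changes neither cost nor counts", {
  tips <- c(A = "B-K-P", B = "B-K-P", C = "B-K-P", D = "K-P", E = "B-B;K-P")
  t1 <- read_newick("(((A,B),C),(D,E));")
  t2 <- read_newick("(((C,A),B),(D,E));")
  f1 <- sankoff(t1, tips, universe_depth = 1, max_mprs = 1024L)
  f2 <- sankoff(t2, tips, universe_depth = 1, max_mprs = 1024L)
  expect_false(f1$mpr_truncated || f2$mpr_truncated)
  expect_equal(f1$total_cost, f2$total_cost)
  count_sigs <- function(f) unique(vapply(f$reconstructions, function(r)
    paste(count_by_type(extract_events(r)), collapse = ","), ""))
  expect_setequal(count_sigs(f1), count_sigs(f2))
  expect_identical(f1$root_states, f2$root_states)
})

test_that("count_by_type tallies classifications and the fission total", {
  expect_identical(count_by_type(list())[["fissions_total"]], 0L)
  evs <- list(
    list(branch = "x", event = event_separation("B-K-P", 1),
         type = "fission_separation"),
    list(branch = "y", event = event_deletion("B-K-P", 1, 1),
         type = "fission_domain_loss"),
    list(branch = "z", event = event_gene_loss("K-P"), type = "gene_loss"))
  ct <- count_by_type(evs)
  expect_identical(ct[["fissions_total"]], 2L)
  expect_identical(ct[["gene_loss"]], 1L)
})

test_that("sankoff minimal cost matches phangorn on a symmetric matrix", {
  skip_if_not_installed("phangorn")
  profs <- case_study_profiles()
  uni <- archevol:::universe_from_profiles(profs)
  # symmetrise the transition costs so the comparison is rooting-invariant
  D <- archevol:::universe_distance_matrix(uni)
  D <- pmin(D, t(D))
  tr <- read_newick("(((A,B),C),(D,E));")
  tips <- setNames(profs[c(1L, 3L, 4L, 5L, 6L)], tr$tip.label)
  keys <- uni$keys
  tipstate <- vapply(tips, profile_text, "")
  dat <- phangorn::phyDat(matrix(match(tipstate, keys), ncol = 1,
                                 dimnames = list(tr$tip.label, NULL)),
                          type = "USER", levels = seq_along(keys))
  ph_cost <- phangorn::parsimony(ape::unroot(tr), dat, method = "sankoff",
                                 cost = D)
  expect_equal(unname(ph_cost), oracle_min_cost(tr, tips, D))
})
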