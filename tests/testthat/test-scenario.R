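test_that("an empty scenario propagates the root state everywhere", {
  tr <- read_newick("((A,B),C);")
  sc <- arch_scenario("B-K-P")
  states <- play_scenario(tr, sc)
  for (st in states) expect_identical(st, "B-K-P")
})

test_that("a tip gene loss empties only that tip", {
  tr <- read_newick("((A,B),C);")
  sc <- arch_scenario("B-K-P", list(
    list(branch = "C", event = event_gene_loss("B-K-P"))))
  states <- play_scenario(tr, sc)
  expect_identical(states$C, character(0))
  expect_identical(states$A, "B-K-P")
  expect_identical(states$B, "B-K-P")
})

test_that("inapplicable events are reported with branch and event", {
  tr <- read_newick("((A,B),C);")
  sc <- arch_scenario("K-P", list(
    list(branch = "A", event = event_fusion("B", "K-P"))))
  expect_error(play_scenario(tr, sc), "branch 'A'.*fusion")
  rep <- validate_scenario(tr, sc, c(A = "K-P", B = "K-P", C = "K-P"))
  expect_false(rep$valid)
  expect_length(rep$violations, 1L)
})

test_that("the folate scenario validates and a tampered one does not", {
  fx <- folate_fixture()
  rep <- validate_scenario(fx$amorphea_tree, fx$narrative_scenario,
                           fx$amorphea_tips)
  expect_true(rep$valid)
  expect_true(all(rep$tip_report$match))
  # drop Laccaria's domain-loss event: Laccaria must mismatch
  keep <- vapply(fx$narrative_scenario$placements, function(p)
    p$branch != "Laccaria_bicolor", TRUE)
  tampered <- arch_scenario(fx$narrative_scenario$root_state,
                            fx$narrative_scenario$placements[keep])
  rep2 <- validate_scenario(fx$amorphea_tree, tampered, fx$amorphea_tips)
  expect_false(rep2$valid)
  bad <- rep2$tip_report[!rep2$tip_report$match, "taxon"]
  expect_identical(bad, "Laccaria_bicolor")
})

test_that("scenario summaries count classifications and price events", {
  fx <- folate_fixture()
  ss <- summarize_scenario(fx$narrative_scenario, tree = fx$amorphea_tree,
                           observed_tips = fx$amorphea_tips)
  expect_identical(ss$counts[["fissions_total"]], 9L)
  expect_identical(ss$counts[["fission_separation"]], 4L)
  expect_identical(ss$counts[["fission_domain_loss"]], 5L)
  expect_identical(ss$counts[["domain_contraction"]], 1L)
  expect_identical(ss$counts[["domain_duplication"]], 1L)
  expect_identical(ss$counts[["gene_loss"]], 3L)
  expect_equal(ss$total_cost, 14)
  # an invalid scenario is refused
  tampered <- arch_scenario("K-P", list(
    list(branch = "Wallemia_sebi", event = event_gene_loss("B-K-P"))))
  expect_error(
    summarize_scenario(tampered, tree = fx$amorphea_tree,
                       observed_tips = fx$amorphea_tips),
    "invalid")
})

test_that("summaries are invariant to event order across branches", {
  fx <- folate_fixture()
  sc <- fx$narrative_scenario
  set.seed(11)
  shuffled <- arch_scenario(sc$root_state,
                            sc$placements[sample(length(sc$placements))])
  expect_identical(summarize_scenario(shuffled)$counts,
                   summarize_scenario(sc)$counts)
  rep <- validate_scenario(fx$amorphea_tree, shuffled, fx$amorphea_tips)
  expect_true(rep$valid)
})

test_that("forward-sampled scenarios always validate", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  for (seed in 1:10) {
    sim <- simulate_evolution(tr, "B-K-P", seed = seed)
    sc <- scenario_from_simulation(sim)
    rep <- validate_scenario(tr, sc, sim$tip_profiles)
    expect_true(rep$valid, info = paste("seed", seed))
  }
})

test_that("sankoff never exceeds a valid scenario's cost", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  for (seed in 1:5) {
    sim <- simulate_evolution(tr, "B-K-P", seed = seed)
    sc <- scenario_from_simulation(sim)
    ss <- summarize_scenario(sc)
    states <- play_scenario(tr, sc)
    # include mid-branch intermediate profiles so the scenario's own path
    # is representable inside the universe
    mids <- list()
    labs <- archevol::node_labels(tr)
    for (v in seq_along(labs)) {
      par <- archevol:::node_parent(tr, v)
      if (is.na(par)) next
      st <- states[[labs[[par]]]]
      for (p in sc$placements) {
        if (p$branch != labs[[v]]) next
        st <- apply_event(st, p$event)
        mids[[length(mids) + 1L]] <- st
      }
    }
    uni <- archevol:::universe_from_profiles(c(unname(states), mids, list(
      archevol::parse_profile("B-K-P"))))
    fit <- sankoff(tr, sim$tip_profiles, universe = uni,
                   root_constraint = sc$root_state, max_mprs = 1L)
    expect_lte(fit$total_cost, ss$total_cost + 1e-9)
  }
})

test_that("scenario TSV round-trips", {
  fx <- folate_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scenario(fx$narrative_scenario, path)
  back <- read_scenario(path)
  expect_identical(profile_text(back$root_state),
                   profile_text(fx$narrative_scenario$root_state))
  expect_identical(length(back$placements),
                   length(fx$narrative_scenario$placements))
  rep <- validate_scenario(fx$amorphea_tree, back, fx$amorphea_tips)
  expect_true(rep$valid)
  expect_identical(summarize_scenario(back)$counts,
                   summarize_scenario(fx$narrative_scenario)$counts)
})
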