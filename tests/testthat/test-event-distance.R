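test_that("event distance identity and single-event cases", {
  for (p in list(character(0), "B-K-P", c("B-B", "K-P"))) {
    d <- event_distance(p, p)
    expect_identical(d$cost, 0)
    expect_length(d$events, 0L)
  }
  # the fungal fission: one separation under default costs
  d <- event_distance("B-B-K-P", "B-B;K-P")
  expect_identical(d$cost, 1)
  expect_identical(d$events[[1L]]$type, "fission_separation")
  # single-event loss/gain
  expect_identical(event_distance("K-P", character(0))$cost, 1)
  expect_identical(event_distance(character(0), "K-P")$cost, 10)
  expect_identical(brute_force_distance("K-P", character(0))$cost, 1)
  expect_identical(brute_force_distance(character(0), "K-P")$cost, 10)
})

test_that("duplication-then-separation pair costs two", {
  d <- event_distance("B-K-P", "B;B-K-P")
  expect_identical(d$cost, 2)
  bf <- brute_force_distance("B-K-P", "B;B-K-P", max_depth = 3L)
  expect_identical(bf$cost, 2)
})

test_that("returned paths actually transform source into target", {
  pairs <- list(c("B-K-P", "B-B;K-P"), c("B-B-K-P", "K-P"),
                c("B-B;K-P", "B-K-P"), c(".", "B-K-P"))
  for (pr in pairs) {
    src <- parse_profile(pr[[1L]]); tgt <- parse_profile(pr[[2L]])
    d <- event_distance(src, tgt)
    st <- src
    for (ev in d$events) st <- apply_event(st, ev)
    expect_identical(st, tgt)
    expect_equal(d$cost, sum(default_costs()[vapply(d$events, `[[`, "",
                                                    "type")]))
  }
})

test_that("best-first search agrees with brute force on random pairs", {
  set.seed(1201)
  for (i in seq_len(200L)) {
    a <- random_profile(); b <- random_profile()
    bf <- brute_force_distance(a, b, max_depth = 3L)
    d <- event_distance(a, b)
    if (bf$reachable && d$reachable && d$cost <= 3 + 1e-9) {
      # within brute-force depth both must agree exactly
      expect_equal(d$cost, bf$cost,
                   info = paste(profile_text(a), "->", profile_text(b)))
    } else if (bf$reachable && d$reachable) {
      # deeper optimum: brute force can only be an upper bound
      expect_lte(d$cost, bf$cost + 1e-9)
    }
  }
})

test_that("distance agrees with brute force on all case-study pairs", {
  profs <- case_study_profiles()
  for (a in profs) for (b in profs) {
    d <- event_distance(a, b)
    bf <- brute_force_distance(a, b, max_depth = 4L)
    info <- paste(profile_text(a), "->", profile_text(b))
    if (d$reachable && bf$reachable) {
      expect_equal(d$cost, bf$cost, info = info)
    } else if (!d$reachable) {
      # beyond the search cutoff: brute force must also price it above it
      expect_true(!bf$reachable || bf$cost > 12, info = info)
    }
  }
})

test_that("triangle inequality holds under a shared gain pool", {
  set.seed(7)
  for (i in seq_len(40L)) {
    a <- random_profile(); b <- random_profile(); cc <- random_profile()
    pool <- unique(c(a, b, cc))
    dab <- event_distance(a, b, gain_pool = pool, max_cost = 30)
    dbc <- event_distance(b, cc, gain_pool = pool, max_cost = 30)
    dac <- event_distance(a, cc, gain_pool = pool, max_cost = 30)
    if (dab$reachable && dbc$reachable && dac$reachable)
      expect_lte(dac$cost, dab$cost + dbc$cost + 1e-9)
  }
})

test_that("raising one event type's cost never lowers a distance", {
  profs <- case_study_profiles()
  base <- default_costs()
  for (ty in c("fission_separation", "domain_duplication", "gene_loss")) {
    up <- default_costs()
    up[[ty]] <- 2.5
    for (a in profs[1:4]) for (b in profs[1:4]) {
      d0 <- event_distance(a, b, costs = base)
      d1 <- event_distance(a, b, costs = up)
      if (d0$reachable && d1$reachable)
        expect_gte(d1$cost + 1e-9, d0$cost)
    }
  }
})

test_that("equal-cost optimal paths can be enumerated, capped", {
  d <- event_distance("B-K-P", "B;B-K-P", all_paths = TRUE)
  expect_gte(length(d$paths), 1L)
  for (p in d$paths) {
    expect_equal(p$cost, d$cost)
    st <- parse_profile("B-K-P")
    for (ev in p$events) st <- apply_event(st, ev)
    expect_identical(st, parse_profile("B;B-K-P"))
  }
  d2 <- event_distance("B-K-P", "B;B-K-P", all_paths = TRUE, max_paths = 1L)
  expect_length(d2$paths, 1L)
})

test_that("unreachable pairs are reported as such", {
  # two gains needed but only one affordable within the cutoff
  d <- event_distance(character(0), c("B", "K-P"), max_cost = 12)
  expect_false(d$reachable)
  expect_identical(d$cost, Inf)
  # reachable once the cutoff admits two gains
  d2 <- event_distance(character(0), c("B", "K-P"), max_cost = 25)
  expect_identical(d2$cost, 20)
})
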