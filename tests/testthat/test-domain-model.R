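test_that("architecture parsing round-trips and rejects bad tokens", {
  expect_identical(arch_tokens(parse_architecture("B-K-P")),
                   c("B", "K", "P"))
  expect_length(arch_tokens(parse_architecture("B-B-K-P")), 4L)
  expect_error(parse_architecture(""), "format error")
  expect_error(parse_architecture("B-Q-P"), "'Q'")
  expect_error(parse_architecture("B--P"), "format error")
  # round trip on every case-study architecture
  fx <- folate_fixture()
  for (a in unique(unlist(fx$eukaryote_table)))
    expect_identical(parse_architecture(a), a)
})

test_that("profile parsing has multiset semantics and canonical text", {
  expect_identical(parse_profile("B-B;K-P"), c("B-B", "K-P"))
  expect_identical(parse_profile("K-P; B-B"), c("B-B", "K-P"))
  expect_identical(parse_profile("."), character(0))
  expect_identical(profile_text(character(0)), ".")
  expect_identical(parse_profile("K-P;K-P"), c("K-P", "K-P"))
  # round trip for all fixture profiles
  fx <- folate_fixture()
  for (p in fx$eukaryote_table)
    expect_identical(parse_profile(profile_text(p)), p)
})

test_that("apply_event implements the grammar transitions", {
  expect_identical(apply_event("B-K-P", event_duplication("B-K-P", 1, 1)),
                   "B-B-K-P")
  expect_identical(apply_event("B-B-K-P", event_separation("B-B-K-P", 2)),
                   c("B-B", "K-P"))
  expect_identical(apply_event("B-B-K-P", event_deletion("B-B-K-P", 1, 2)),
                   "K-P")
  expect_identical(apply_event(c("B", "K-P"), event_fusion("B", "K-P")),
                   "B-K-P")
  expect_identical(apply_event("K-P", event_gene_loss("K-P")), character(0))
  expect_identical(apply_event(character(0), event_gene_gain("K-P")), "K-P")
  # missing input gene
  expect_error(apply_event("K-P", event_gene_loss("B-K-P")),
               "application error")
  # deletion that would empty a gene is not constructible
  expect_error(event_deletion("B-B", 1, 2), "gene_loss")
  # cap violations rejected
  expect_error(apply_event("B-B-K-P", event_duplication("B-B-K-P", 1, 2)),
               "cap error")
  expect_error(
    apply_event(c("B", "B", "K", "P"), event_gene_gain("K-P"),
                caps = arch_caps(max_genes_per_profile = 4)),
    "cap error")
})

test_that("classify_event separates fission subtypes from contraction", {
  expect_identical(classify_event("B-B-K-P", event_deletion("B-B-K-P", 1, 1)),
                   "fission_domain_loss")
  expect_identical(classify_event("B-B", event_deletion("B-B", 1, 1)),
                   "domain_contraction")
  for (at in 1:3)
    expect_identical(
      classify_event("B-B-K-P", event_separation("B-B-K-P", at)),
      "fission_separation")
  expect_identical(classify_event("B", event_gene_loss("B")), "gene_loss")
  expect_identical(classify_event(NA, event_gene_gain("B-K")), "gene_gain")
})

test_that("enumerate_events matches an independent generator", {
  profiles <- c(case_study_profiles(),
                list("B-K-P", c("B", "K-P"), c("K-P", "K-P"), "B-B"))
  for (p in profiles) {
    got <- enumerate_events(p)
    got_keys <- sort(vapply(got, function(x)
      paste(x$event$type, profile_text(x$profile), sep = "|"), ""),
      method = "radix")
    expect_identical(got_keys, oracle_neighbors(p), info = profile_text(p))
    # duplicate-free over (type, neighbour)
    expect_identical(anyDuplicated(got_keys), 0L)
    # apply/enumerate consistency
    for (x in got)
      expect_identical(apply_event(p, x$event), x$profile)
  }
})

test_that("single-gene neighbourhood has the expected size and members", {
  nb <- enumerate_events(parse_profile("B-K-P"))
  # frozen from the brute-force generator: 2 separations, 5 distinct
  # deletions, 6 duplications, 1 gene loss
  expect_length(nb, 14L)
  texts <- vapply(nb, function(x) profile_text(x$profile), "")
  expect_true(all(c("B;K-P", "B-K;P") %in%
                    texts[vapply(nb, function(x)
                      x$event$type == "fission_separation", TRUE)]))
  # both fusion orders from a two-gene profile
  nb2 <- enumerate_events(parse_profile("B;K-P"))
  fus <- vapply(nb2[vapply(nb2, function(x) x$event$type == "fusion", TRUE)],
                function(x) profile_text(x$profile), "")
  expect_setequal(fus, c("B-K-P", "K-P-B"))
})

test_that("fissions and duplications pair with reverse events", {
  # every separation a->b admits a fusion b->a; every duplication a->b a
  # deletion b->a (checked over the case-study profiles)
  for (p in case_study_profiles()) {
    for (x in enumerate_events(p)) {
      if (x$event$type == "fission_separation") {
        back <- enumerate_events(x$profile)
        keys <- vapply(back, function(y)
          paste(y$event$type, profile_text(y$profile), sep = "|"), "")
        expect_true(paste("fusion", profile_text(p), sep = "|") %in% keys)
      }
      if (x$event$type == "domain_duplication") {
        back <- enumerate_events(x$profile)
        keys <- vapply(back, function(y)
          paste(y$event$type, profile_text(y$profile), sep = "|"), "")
        expect_true(any(keys %in% paste(
          c("fission_domain_loss", "domain_contraction"),
          profile_text(p), sep = "|")))
      }
    }
  }
})

test_that("count_fused_architectures counts distinct multi-type genes", {
  expect_identical(count_fused_architectures(list()), 0L)
  expect_identical(count_fused_architectures(list("B-B", "B")), 0L)
  expect_identical(
    count_fused_architectures(list(c("B-K", "K-P"), "B-K-P", "K-P")), 3L)
})
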