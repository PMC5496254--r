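test_that("transcription_combinations enumerates non-empty subsets in order", {
  expect_identical(transcription_combinations(c("B", "C")),
                   list("B", "C", c("B", "C")))
  expect_identical(transcription_combinations(character()), list())

  acts <- paste0("X", 1:4)
  got <- transcription_combinations(acts)
  # independent oracle: enumerate all subsets via binary masks
  oracle <- Filter(length, lapply(0:15, function(m)
    sort(acts[bitwAnd(m, 2^(0:3)) > 0])))
  expect_equal(length(got), 15L)
  expect_false(any(duplicated(lapply(got, paste, collapse = ","))))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(oracle, paste, "", collapse = ","))
  expect_error(transcription_combinations(c("B", "B")), "duplicate")
})

test_that("the 4-gene worked example compiles as prescribed", {
  sys <- compile_network(worked_example_network())
  expect_length(sys$reactions, 24L)

  tr_a <- transcription_reactions_for(sys, "A")
  expect_length(tr_a, 3L)
  combos <- lapply(tr_a, function(r)
    sort(setdiff(r$reactants$species, "ProA.NoD")))
  expect_setequal(vapply(combos, paste, "", collapse = ","),
                  c("ProA.B", "ProA.C", "ProA.B,ProA.C"))
  # every transcription reaction of A carries the free repressor site
  for (r in tr_a) {
    expect_true("ProA.NoD" %in% r$reactants$species)
    expect_false(any(r$reactants$consumed))  # zero promoter delay: catalysts
  }
  # B, C, D are unregulated: basal transcription from constitutive promoter
  for (g in c("B", "C", "D")) {
    tr <- transcription_reactions_for(sys, g)
    expect_length(tr, 1L)
    expect_identical(tr[[1L]]$reactants$species, paste0("Pro", g))
  }
  # promoter sites start at 1 free / 0 bound; RNA and protein from node attrs
  cnt <- stats::setNames(sys$species$count, sys$species$name)
  expect_equal(unname(cnt[c("ProA.NoB", "ProA.B", "RA", "PA")]),
               c(1L, 0L, 0L, 0L))
})

test_that("a regulator-less gene gets basal machinery only", {
  sys <- compile_network(gene_network("X"))
  expect_length(sys$reactions, 4L)
  n_bind <- sum(vapply(sys$reactions, function(r)
    any(grepl("^Pro.*\\.No", r$reactants$species)), TRUE))
  expect_equal(n_bind, 0L)
})

test_that("k activators give 2^k - 1 transcription reactions", {
  for (k in c(2L, 5L)) {
    sys <- compile_network(star_network(k))
    tr <- transcription_reactions_for(sys, "X")
    # brute-force oracle: distinct non-empty activator subsets
    subsets <- unique(lapply(seq_len(2^k - 1), function(m)
      sort(paste0("A", which(bitwAnd(m, 2^(0:(k - 1))) > 0)))))
    expect_length(tr, length(subsets))
    expect_length(tr, 2L^k - 1L)
  }
})

test_that("count_reactions matches the closed form and the compiler", {
  expect_equal(count_reactions(worked_example_network()), 24L)
  expect_equal(count_reactions(gene_network("X")), 4L)
  set.seed(11)
  for (i in 1:5) {
    net <- generate_network("erdos_renyi", 10,
                            params = list(p = 0.17), seed = 100 + i)
    expect_equal(count_reactions(net),
                 length(compile_network(net)$reactions))
  }
})

test_that("compilation is deterministic", {
  net <- generate_network("scale_free", 12, seed = 5)
  expect_identical(compile_network(net), compile_network(net))
})

test_that("every promoter site has exactly one binding and one unbinding", {
  net <- generate_network("scale_free", 15, seed = 8)
  sys <- compile_network(net)
  free_sites <- grep("^Pro.*\\.No", sys$species$name, value = TRUE)
  expect_gt(length(free_sites), 0)
  for (site in free_sites) {
    bound <- sub("\\.No", ".", site)
    is_bind <- vapply(sys$reactions, function(r)
      site %in% r$reactants$species[r$reactants$consumed] &&
        bound %in% r$products$species, TRUE)
    is_unbind <- vapply(sys$reactions, function(r)
      bound %in% r$reactants$species[r$reactants$consumed] &&
        site %in% r$products$species, TRUE)
    expect_equal(sum(is_bind), 1L)
    expect_equal(sum(is_unbind), 1L)
  }
})

test_that("promoter copy number is conserved by every reaction", {
  # stoichiometry audit, no simulation: for each (gene, regulator) site the
  # net change of free + bound must be zero in every compiled reaction,
  # with and without a promoter delay
  net <- worked_example_network()
  for (delays in list(delay_params(),
                      delay_params(promoter_delay =
                                     delay_spec("constant", value = 2)))) {
    sys <- compile_network(net, delays = delays)
    free_sites <- grep("^Pro.*\\.No", sys$species$name, value = TRUE)
    for (site in free_sites) {
      pair <- c(site, sub("\\.No", ".", site))
      for (r in sys$reactions) {
        cons <- r$reactants[r$reactants$consumed &
                              r$reactants$species %in% pair, , drop = FALSE]
        prod <- r$products[r$products$species %in% pair, , drop = FALSE]
        expect_equal(sum(prod$stoich) - sum(cons$stoich), 0L)
      }
    }
  }
})

test_that("zero-delay compilation never consumes what it delays", {
  sys <- compile_network(generate_network("scale_free", 10, seed = 2))
  for (r in sys$reactions) {
    delayed <- r$products$species[r$products$kind != "none"]
    consumed <- r$reactants$species[r$reactants$consumed]
    expect_length(intersect(delayed, consumed), 0L)
  }
})

test_that("per-gene and per-edge rate overrides are honoured", {
  net <- worked_example_network()
  rates <- rate_params(transcription = 0.2,
                       overrides = list(transcription = c(B = 0.7),
                                        binding = c("D->A" = 0.9)))
  sys <- compile_network(net, rates)
  tr_b <- transcription_reactions_for(sys, "B")
  expect_equal(tr_b[[1L]]$rate, 0.7)
  expect_equal(transcription_reactions_for(sys, "C")[[1L]]$rate, 0.2)
  bind_d <- Filter(function(r) "ProA.NoD" %in% r$reactants$species &&
                     "ProA.D" %in% r$products$species, sys$reactions)
  expect_equal(bind_d[[1L]]$rate, 0.9)
})

test_that("unsigned networks refuse to compile", {
  net <- gene_network(c("A", "B"),
                      data.frame(source = "B", target = "A",
                                 sign = NA_character_))
  expect_error(compile_network(net), "unsigned")
})
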