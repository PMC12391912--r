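test_that("hill numbers reproduce their defining identities", {
  expect_equal(hill_number(1, 3), 1)
  expect_equal(hill_number(rep(0.25, 4), 2), 4)
  expect_equal(hill_number(c(0.8, 0.2), 1), 1.649385, tolerance = 1e-6)
  expect_equal(hill_number(c(0.5, 0.3, 0.2), 10), 2.158648, tolerance = 1e-6)
  expect_error(hill_number(numeric(0), 1), class = "divgrad_undefined_diversity")
  expect_error(hill_number(c(0, 0), 1), class = "divgrad_undefined_diversity")
})

test_that("hill numbers are scale invariant and monotone in q", {
  set.seed(41)
  for (rep in 1:50) {
    counts <- random_abundance()
    counts <- counts[counts > 0]
    if (length(counts) < 2) next
    for (q in c(0, 1, 2, 10)) {
      expect_equal(hill_number(counts, q), hill_number(counts * 7, q),
                   tolerance = 1e-10)
    }
    prof <- vapply(c(0, 0.5, 1, 2, 5, 10, Inf), function(q)
      hill_number(counts, q), numeric(1))
    expect_true(all(diff(prof) <= 1e-8))
  }
})

test_that("jackknife richness matches hand-computable cases", {
  r <- jackknife_richness(c(1, 1, 1))
  expect_equal(r$estimate, 5)   # 3 + 3 * (n-1)/n at n = 3
  expect_equal(r$order, 1L)
  r <- jackknife_richness(c(100, 100, 100))
  expect_equal(r$estimate, 3)   # no rare species: no adjustment
  expect_equal(r$order, 0L)
  expect_error(jackknife_richness(c(0, 0)), class = "divgrad_undefined_diversity")
})

test_that("jackknife richness agrees with the closed-form oracle and never drops below S", {
  set.seed(99)
  for (rep in 1:150) {
    counts <- random_abundance()
    got <- jackknife_richness(counts)
    want <- oracle_jackknife(counts)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-8)
    expect_equal(got$order, as.integer(want$order))
    expect_gte(got$estimate, sum(counts > 0))
  }
})

test_that("berger-parker handles ties and dominance", {
  expect_equal(berger_parker(c(0.6, 0.4)), 1 / 0.6)
  expect_equal(berger_parker(5), 1)
  tie <- berger_parker(c(0.5, 0.5))
  expect_true(is.na(tie))
  expect_true(attr(tie, "tie"))
})

test_that("diversity profiles are monotone in q and inactive without rare species", {
  # equal counts: every order returns the species number
  prof <- diversity_profile(c(10, 10, 10, 10))
  expect_equal(prof$D0, 4)
  expect_equal(unname(prof$D), rep(4, 3), tolerance = 1e-10)
  expect_true(prof$tie)

  empty <- diversity_profile(c(0, 0, 0))
  expect_equal(empty$S_raw, 0L)
  expect_true(is.na(empty$D0))

  set.seed(17)
  for (rep in 1:300) {
    counts <- random_abundance()
    if (sum(counts) == 0) next
    prof <- diversity_profile(counts)
    vals <- c(prof$D0, prof$D["D1"], prof$D["D2"], prof$D["D10"])
    expect_true(all(diff(unname(vals)) <= 1e-8))
    expect_gte(prof$D0, prof$S_raw)
    if (!prof$tie) expect_lte(prof$D_inf, prof$D[["D10"]] + 1e-8)
  }
})

test_that("biomass is the unit-weight sum, partitioned by migration", {
  attrs <- species_attributes()
  expect_setequal(attrs$species[attrs$migratory], c("wildebeest", "zebra"))
  z <- setNames(rep(0, 3), c("wildebeest", "zebra", "impala"))
  expect_equal(block_biomass(z, attrs), list(total = 0, migratory = 0, nonmigratory = 0))
  w <- setNames(c(10, 0, 0), c("wildebeest", "zebra", "impala"))
  m <- attrs$mass_kg[attrs$species == "wildebeest"]
  bb <- block_biomass(w, attrs)
  expect_equal(bb$total, 10 * m)
  expect_equal(bb$migratory, 10 * m)
  expect_equal(bb$nonmigratory, 0)
  set.seed(4)
  for (rep in 1:20) {
    cc <- setNames(rpois(19, 3) * runif(19, 0, 2), attrs$species)
    bb <- block_biomass(cc, attrs)
    expect_equal(bb$total, bb$migratory + bb$nonmigratory)
  }
  expect_error(block_biomass(c(unicorn = 1), attrs), "unicorn",
               class = "divgrad_configuration_error")
})

test_that("community summary covers every block once", {
  m <- community_summary(aggregate_blocks(tiny_grid(seed = 23)))
  expect_equal(nrow(m), 8 * 8 * 2)
  expect_true(all(!is.na(m$biomass_total)))
  has_animals <- m$S_raw > 0
  expect_true(all(!is.na(m$D0[has_animals])))
  expect_true(all(m$D0[has_animals] >= m$S_raw[has_animals]))
})
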