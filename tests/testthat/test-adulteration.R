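test_that("design enumeration yields 288 single and 51 combined recipes", {
  design <- enumerate_design(t1$pools, registry)
  expect_equal(sum(design$mode == "single"), 288L)
  expect_equal(sum(design$mode == "combined"), 51L)
  # deterministic ordering: pool, category, code, level
  expect_identical(design, enumerate_design(t1$pools, registry))

  empty <- enumerate_design(t1$pools, registry[0, ])
  expect_equal(nrow(empty), 0L)

  water_only <- enumerate_design(t1$pools, registry[registry$category == "water", ])
  expect_equal(sum(water_only$mode == "single"), 12L)  # 4 levels x 3 pools
  expect_equal(sum(water_only$mode == "combined"), 0L)

  two_levels <- default_dose_levels()
  two_levels <- lapply(two_levels, function(d) d[1:2])
  d2 <- enumerate_design(t1$pools, registry, two_levels)
  expect_equal(sum(d2$mode == "single"), 144L)  # 24 x 2 x 3
})

test_that("mass balance: water identity, dilution arithmetic, monotone doses", {
  poolB <- t1$pools[t1$pools$pool_id == "B", ]
  water <- registry[registry$code == "WATER", ]
  recipe0 <- data.frame(pool_id = "B", code = "WATER", category = "water",
                        mode = "single", level = 1L, added_mass = 0,
                        water_added = 0, target = "none")
  same <- apply_recipe(poolB, recipe0, water)
  for (v in composition_vars) expect_equal(same[[v]], poolB[[v]], tolerance = 1e-12)

  recipe40 <- recipe0
  recipe40$added_mass <- 40
  dil <- apply_recipe(poolB, recipe40, water)
  expect_equal(dil$protein, 3.44 * 100 / 140, tolerance = 1e-12)
  expect_lt(dil$fpd, poolB$fpd)  # dilution moves FPD toward zero

  recipe40$added_mass <- -1
  expect_error(apply_recipe(poolB, recipe40, water), "negative")

  # apparent protein strictly increasing in level for nitrogen adulterants
  for (code in registry$code[registry$category == "nitrogen"]) {
    spec <- registry[registry$code == code, ]
    prot <- vapply(default_dose_levels()$nitrogen, function(m) {
      r <- data.frame(pool_id = "B", code = code, category = "nitrogen",
                      mode = "single", level = 1L, added_mass = m,
                      water_added = 0, target = "none")
      apply_recipe(poolB, r, spec)$protein
    }, 0)
    expect_true(all(diff(prot) > 0))
  }
})

test_that("dose-response properties hold across the full simulated set", {
  ad <- simulate_adulterant_set(t1$pools, registry)
  expect_equal(nrow(ad), 339L)
  singles <- ad[ad$mode == "single", ]
  by_combo <- split(singles, paste(singles$pool_id, singles$code))
  for (d in by_combo) {
    d <- d[order(d$level), ]
    spec <- registry[registry$code == d$code[1], ]
    if (spec$category %in% c("protein_rich", "nitrogen")) {
      expect_true(all(diff(d$protein) >= -1e-12))
    }
    if (spec$category != "water" && spec$solids_fraction > 0) {
      expect_true(all(diff(d$ts) >= -1e-12))
    }
    if (spec$category == "water") {
      expect_true(all(diff(d$fpd) < 0))  # strictly decreasing in water
    }
  }
})

test_that("apply_recipe agrees with an independent mixing oracle", {
  withr::with_seed(314, {
    for (rep in 1:20) {
      pool <- t1$pools[sample(3, 1), ]
      spec <- registry[sample(nrow(registry), 1), ]
      added <- runif(1, 0, 5)
      water <- sample(c(0, 40), 1)
      recipe <- data.frame(pool_id = pool$pool_id, code = spec$code,
                           category = spec$category, mode = "single",
                           level = 1L, added_mass = added,
                           water_added = water, target = "none")
      got <- apply_recipe(pool, recipe, spec)
      want <- oracle_mix(pool, spec, added, water)
      for (v in names(want)) expect_equal(got[[v]], want[[v]], tolerance = 1e-9)
      # conservation: % w/w channels are component mass over total mass
      total <- 100 + water + added
      expect_equal(got$fat * total / 100, pool$fat, tolerance = 1e-9)
    }
  })
})

test_that("combined doses follow the closed-form mass balance", {
  poolB <- t1$pools[t1$pools$pool_id == "B", ]
  pure <- data.frame(code = "PURE", category = "protein_rich",
                     nitrogen_fraction = 0, protein_fraction = 1,
                     solids_fraction = 1, molar_mass = 0, dissociation_count = 0)
  # pure protein: dose = 0.40 x milk protein mass
  expect_equal(combined_dose(poolB, pure, "apparent_protein_+40%"),
               0.40 * poolB$protein, tolerance = 1e-12)
  expect_equal(combined_dose(poolB, pure, "apparent_protein_+40%",
                             target_fraction = 0), 0)
  # melamine (N 0.667) needs less than urea (N 0.467) for the same target
  mlm <- registry[registry$code == "MLM", ]
  ure <- registry[registry$code == "URE", ]
  expect_lt(combined_dose(poolB, mlm, "apparent_protein_+40%"),
            combined_dose(poolB, ure, "apparent_protein_+40%"))
  # inverse proportionality to the nitrogen channel
  expect_equal(combined_dose(poolB, mlm, "apparent_protein_+40%") /
                 combined_dose(poolB, ure, "apparent_protein_+40%"),
               ure$nitrogen_fraction / mlm$nitrogen_fraction, tolerance = 1e-12)
  # an adulterant with no protein channel cannot hit a protein target
  water <- registry[registry$code == "WATER", ]
  expect_error(combined_dose(poolB, water, "apparent_protein_+40%"),
               "contributes nothing")
})

test_that("combined recipes raise the target channel by 40% of the milk content", {
  ad <- simulate_adulterant_set(t1$pools, registry)
  comb <- ad[ad$mode == "combined", ]
  expect_equal(nrow(comb), 51L)
  for (i in seq_len(nrow(comb))) {
    pool <- t1$pools[t1$pools$pool_id == comb$pool_id[i], ]
    total <- 100 + comb$water_added[i] + comb$added_mass[i]
    if (comb$target[i] == "apparent_protein_+40%") {
      # apparent protein mass = 1.40 x milk protein mass
      expect_equal(comb$protein[i] * total / 100, 1.40 * pool$protein,
                   tolerance = 1e-9)
    } else {
      expect_equal(comb$ts[i] * total / 100,
                   pool$ts + 0.40 * pool$ts * 1, tolerance = 1e-9)
    }
  }
})
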