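test_that("the default archetypes cover all 17 types and sit in their leaves", {
  arch <- default_archetypes()
  expect_length(arch, 17)
  expect_setequal(names(arch), herd_types()$herd_type)

  # signature spot checks: fatteners send most out-moves to slaughter,
  # weanling sellers keep almost no male yearlings, traders turn stock
  # around fast
  expect_gt(arch$F$slaughter_out_fraction, 0.5)
  expect_lt(arch$BSW$male_1to2_fraction, 0.1)
  expect_gt(arch$T$short_stay_fraction, 0.5)

  # every archetype's nominal feature vector lands on its own leaf
  tree <- build_default_tree()
  for (ht in names(arch)) {
    ef <- expected_features(arch[[ht]])
    expect_true(all(ef[setdiff(names(ef), "pOutMovesToSL")] >= 0 &
                      ef[setdiff(names(ef), "pOutMovesToSL")] <= 1))
    expect_equal(classify_herd(tree, as.list(ef))$herd_type, ht,
                 info = ht)
  }
})

test_that("degenerate archetype parameters are rejected", {
  expect_error(
    archetype_spec("D", c(0, 10), dairy_fraction = 0.9, cross_fraction = 0.05,
                   calved_fraction = 0.4, calf_fraction = 0.2,
                   yearling_fraction = 0.2, male_1to2_fraction = 0.1,
                   calf_male_fraction = 0.5, adult_male_fraction = 0.1,
                   out_rate = 0.5, in_rate = 0.1)
  )
  expect_error(
    archetype_spec("D", c(10, 20), dairy_fraction = 0.8, cross_fraction = 0.3,
                   calved_fraction = 0.4, calf_fraction = 0.2,
                   yearling_fraction = 0.2, male_1to2_fraction = 0.1,
                   calf_male_fraction = 0.5, adult_male_fraction = 0.1,
                   out_rate = 0.5, in_rate = 0.1)
  )
})

test_that("generated herds honour structural zeroes and determinism", {
  arch <- default_archetypes()

  # an all-female profile yields no male animals
  allf <- archetype_spec("Rdf", c(30, 40), dairy_fraction = 0.9,
                         cross_fraction = 0.05, calved_fraction = 0,
                         calf_fraction = 0.4, yearling_fraction = 0.5,
                         male_1to2_fraction = 0, calf_male_fraction = 0,
                         adult_male_fraction = 0,
                         out_rate = 0.5, in_rate = 0.5)
  expect_equal(allf$female_fraction, 1)
  h <- generate_herd(allf, "AF", seed = 3)
  expect_true(all(h$animals$sex == "female"))

  # no slaughter fraction -> no slaughter movements
  h2 <- generate_herd(arch$Rdf, "NS", seed = 3)
  expect_false(any(h2$movements$destination_kind == "slaughter" &
                     arch$Rdf$slaughter_out_fraction == 0))
  h3 <- generate_herd(arch$T, "T1", seed = 3)
  spec_no_sl <- arch$T
  spec_no_sl$slaughter_out_fraction <- 0
  h4 <- generate_herd(spec_no_sl, "T1", seed = 3)
  expect_equal(sum(h4$movements$destination_kind == "slaughter"), 0)

  # identical seed, identical herd; different seed differs
  expect_identical(generate_herd(arch$D, "D1", seed = 8),
                   generate_herd(arch$D, "D1", seed = 8))
  expect_false(identical(generate_herd(arch$D, "D1", seed = 8)$animals,
                         generate_herd(arch$D, "D1", seed = 9)$animals))
})

test_that("a generated register is valid, labelled and reproducible", {
  gen <- generate_registry(herds_per_type = 3, seed = 13)
  expect_equal(nrow(validate_registry(gen$registry)), 0)
  primary <- gen$truth[gen$truth$role == "primary", ]
  expect_equal(nrow(primary), 3 * 17)
  expect_equal(sort(unique(primary$herd_type)),
               sort(herd_types()$herd_type))
  expect_true(all(gen$truth$herd_type[gen$truth$role == "counterpart"] ==
                    "counterpart"))

  gen2 <- generate_registry(herds_per_type = 3, seed = 13)
  expect_identical(gen$registry$animals, gen2$registry$animals)
  expect_identical(gen$registry$movements, gen2$registry$movements)
  expect_identical(gen$truth, gen2$truth)
})

test_that("feature means over many herds converge to the archetype nominals", {
  arch <- default_archetypes()
  tree <- build_default_tree()
  for (ht in c("D", "BSY", "T", "Rdf")) {
    spec <- arch[[ht]]
    feats <- lapply(1:25, function(i) {
      h <- generate_herd(spec, paste0(ht, i), seed = 1000 + i)
      reg <- herd_registry(h$animals, h$movements)
      compute_features(reg, paste0(ht, i))
    })
    feats <- dplyr::bind_rows(feats)
    nominal <- expected_features(spec)
    for (v in names(nominal)) {
      se <- stats::sd(feats[[v]]) / sqrt(nrow(feats))
      # 3 standard errors, floored at the integer-rounding granularity of
      # the movement bookkeeping
      tol <- max(3 * se, 0.02)
      expect_lt(abs(mean(feats[[v]]) - nominal[[v]]), tol + 1e-12,
                label = paste(ht, v, "deviation"))
    }
  }
})
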