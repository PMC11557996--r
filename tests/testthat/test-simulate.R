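test_that("Yule trees are ultrametric at the requested height and seeded", {
  cfg <- sim_config(n_tips = 50, tree_height = 100, seed = 1)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 50L)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_true(all(abs(depths - 100) < 1e-9))

  tr2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(simulate_tree(sim_config(n_tips = 3, seed = 1)), NA)
  expect_error(sim_config(n_tips = 2), "n_tips")
})

test_that("trait generation is deterministic and honours a zero-noise config", {
  cfg <- sim_config(n_tips = 30, sigma2_resid = 0, covariate_effect = 0,
                    seed = 5)
  tree <- simulate_tree(cfg)
  d <- simulate_allometric_dataset(tree, cfg)
  expect_equal(d$log10_scl, cfg$a + cfg$b * d$log10_fl, tolerance = 1e-12)

  cfg2 <- sim_config(n_tips = 30, seed = 6)
  d1 <- simulate_allometric_dataset(tree, cfg2)
  d2 <- simulate_allometric_dataset(tree, cfg2)
  expect_identical(d1, d2)
  expect_equal(attr(d1, "truth")$b, 0.96)
  expect_equal(sum(d1$terrestrial), round(0.2 * 30))
})

test_that("independent residuals show no phylogenetic signal when refit", {
  base <- sim_config(n_tips = 150, lambda_resid = 0, seed = 7)
  tree <- simulate_tree(base)
  hits <- 0L
  reps <- 20
  for (i in seq_len(reps)) {
    d <- simulate_allometric_dataset(
      tree, sim_config(n_tips = 150, lambda_resid = 0, seed = 300 + i))
    f <- pgls(log10_scl ~ log10_fl, d, tree)
    hits <- hits + (f$lambda < 0.2)
  }
  expect_gte(hits, ceiling(0.9 * reps))
})

test_that("simulated predictor covariance approximates sigma2_x * C", {
  base <- sim_config(n_tips = 100, seed = 8)
  tree <- simulate_tree(base)
  C <- unclass(vcv_matrix(tree))
  reps <- 1000
  xs <- matrix(NA_real_, reps, 100)
  for (i in seq_len(reps)) {
    d <- simulate_allometric_dataset(
      tree, sim_config(n_tips = 100, seed = 400 + i))
    xs[i, ] <- d$log10_fl
  }
  S <- stats::cov(xs)
  target <- base$sigma2_x * C
  rel <- norm(S - target, "F") / norm(target, "F")
  expect_lt(rel, 0.15)
})

test_that("specimen tables encode dimorphism, gravidity and maturity structure", {
  cfg <- sim_config(n_tips = 40, seed = 9)
  tree <- simulate_tree(cfg)
  species <- simulate_allometric_dataset(tree, cfg)
  sim <- simulate_specimen_table(species, cfg, n_per_species = 4,
                                 dimorphism_ratio = 2, unsexed_fraction = 0)
  mx <- sim$maxima
  for (sp in unique(mx$species)) {
    f <- mx$max_scl_mm[mx$species == sp & mx$sex == "female"]
    m <- mx$max_scl_mm[mx$species == sp & mx$sex == "male"]
    expect_equal(f / m, 2, tolerance = 1e-12)
  }
  expect_true(all(sim$specimens$sex %in% c("female", "male")))

  # gravid flags only at or above 60% of the female maximum
  sim2 <- simulate_specimen_table(species, cfg, n_per_species = 6)
  sp2 <- sim2$specimens
  fmax <- setNames(sim2$maxima$max_scl_mm[sim2$maxima$sex == "female"],
                   sim2$maxima$species[sim2$maxima$sex == "female"])
  grav <- sp2[sp2$gravid, ]
  expect_true(all(grav$scl_mm >= 0.6 * fmax[grav$species]))

  # determinism
  sim3 <- simulate_specimen_table(species, cfg, n_per_species = 6)
  expect_identical(sim2$specimens, sim3$specimens)
})

test_that("the whole pipeline runs end-to-end on generated data alone", {
  cfg <- sim_config(n_tips = 40, seed = 10)
  tree <- simulate_tree(cfg)
  species <- simulate_allometric_dataset(tree, cfg)
  sim <- simulate_specimen_table(species, cfg, n_per_species = 5)
  flt <- apply_maturity_filter(sim$specimens, sim$maxima)
  expect_gt(nrow(flt$retained), 0)
  agg <- aggregate_species(flt$retained)
  agg$terrestrial <- species$terrestrial[match(agg$species, species$species)]
  specs <- build_model_set("log10_scl", "log10_fl", "terrestrial", data = agg)
  fits <- fit_model_set(specs, agg, tree)
  sel <- select_best_model(fits[vapply(fits, function(f) f$k > 1,
                                       logical(1))])
  expect_s3_class(sel$best, "pgls_fit")
  expect_true(is.finite(sel$best$aicc))
  slope <- sel$best$coefficients$estimate[2]
  expect_true(classify_allometry(slope) %in%
                c("strong negative", "moderate negative", "weak negative",
                  "near-isometric", "weak positive", "moderate positive",
                  "strong positive"))
})
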